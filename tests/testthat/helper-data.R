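# Shared fixtures, built in code.

# A small balanced dataset with iid (model-true) pair effects.
make_iid_data <- function(p = 10, r = 4, beta = 0, tau2 = 0.5, omega2 = 0.5,
                          sigma2 = 0.5, seed = 1, mu = 0) {
  simulate_paired_data(
    n_pairs = p, n_replicates = r, beta = beta, tau2 = tau2, omega2 = omega2,
    sigma2 = sigma2, mu = mu, phylogenetic = FALSE, seed = seed
  )$data
}

make_phylo_data <- function(p = 10, r = 4, beta = 0, tau2 = 0.5, omega2 = 0.5,
                            sigma2 = 0.5, seed = 1, mu = 0) {
  simulate_paired_data(
    n_pairs = p, n_replicates = r, beta = beta, tau2 = tau2, omega2 = omega2,
    sigma2 = sigma2, mu = mu, phylogenetic = TRUE, seed = seed
  )$data
}

# Hand-built dataset: one pair, two species, given replicate values.
one_pair_data <- function(nat, inv) {
  tibble::tibble(
    pair = "p1",
    species = rep(c("p1_nat", "p1_inv"), c(length(nat), length(inv))),
    origin = rep(c(0L, 1L), c(length(nat), length(inv))),
    replicate = c(seq_along(nat), seq_along(inv)),
    value = c(nat, inv)
  )
}

# Strip validation-cache attributes so validation re-runs from scratch.
unvalidated <- function(data) {
  attr(data, "balanced") <- NULL
  data
}
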