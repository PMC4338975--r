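#' Simulate a Yule (pure-birth) phylogeny
#'
#' Grows a tree from a single lineage: while `k` lineages are extant the
#' waiting time to the next birth is exponential with rate `k * birth_rate`,
#' and the splitting lineage is chosen uniformly at random. The process is
#' observed at the instant of the birth that brings the number of lineages to
#' `n_tips`, so the tree is ultrametric and the most recent cherry has
#' pendant edges of length zero. The time from the origin of the initial
#' lineage to its first split is kept as the root edge, so the expected total
#' depth (origin to present) is `sum(1/(1:(n_tips - 1))) / birth_rate`.
#'
#' Because the Brownian tip values produced from these trees are rescaled to
#' a target variance afterwards (see [simulate_paired_data()]), the birth
#' rate only sets the time units and is unidentifiable downstream.
#'
#' @param n_tips Number of tips (`>= 2`), one per species pair.
#' @param birth_rate Speciation rate per lineage, `> 0`.
#' @param seed Optional integer seed; when supplied the global RNG state is
#'   left untouched.
#' @return An [ape::read.tree()]-compatible `phylo` object with `root.edge`,
#'   tip labels `t1 ... tn` in order of lineage creation.
#' @examples
#' tr <- simulate_yule_tree(5, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2 || n_tips != round(n_tips)) {
    abort("`n_tips` must be an integer >= 2.", class = "phypairs_domain_error")
  }
  if (birth_rate <= 0) {
    abort("`birth_rate` must be positive.", class = "phypairs_domain_error")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, .yule_phylo(n_tips, birth_rate)))
  }
  .yule_phylo(n_tips, birth_rate)
}

.yule_phylo <- function(n, rate) {
  n_rec <- 2L * n - 1L # lineage records ever created
  parent_rec <- integer(n_rec) # 0 for the initial lineage
  birth <- numeric(n_rec)
  node_id <- integer(n_rec) # internal node id once a lineage splits
  end_time <- numeric(n_rec)

  waits <- rexp(n - 1L, rate = rate * seq_len(n - 1L))
  active <- 1L
  t <- 0
  next_rec <- 2L
  for (k in seq_len(n - 1L)) {
    t <- t + waits[k]
    j <- if (k == 1L) 1L else sample.int(k, 1L)
    rec <- active[j]
    node_id[rec] <- n + k # root gets n + 1
    end_time[rec] <- t
    c1 <- next_rec
    c2 <- next_rec + 1L
    next_rec <- next_rec + 2L
    parent_rec[c(c1, c2)] <- rec
    birth[c(c1, c2)] <- t
    active[j] <- c1
    active <- c(active, c2)
  }
  present <- t
  # surviving lineages become tips, labelled in order of creation
  tip_recs <- sort(active)
  node_id[tip_recs] <- rank(tip_recs)
  end_time[tip_recs] <- present

  child_recs <- 2:n_rec
  edge <- cbind(node_id[parent_rec[child_recs]], node_id[child_recs])
  storage.mode(edge) <- "integer"
  tree <- list(
    edge = edge,
    edge.length = end_time[child_recs] - birth[child_recs],
    tip.label = paste0("t", seq_len(n)),
    Nnode = n - 1L,
    root.edge = waits[1]
  )
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

#' Simulate Brownian trait evolution on a phylogeny
#'
#' Assigns the root node the value 0 and adds an independent Gaussian
#' increment with variance equal to the branch length along every branch
#' (unit diffusion rate), so that the covariance of two tips equals the
#' length of their shared root-to-tip path. The root edge, if present, is
#' ignored: a shared increment below the root would shift all tips equally
#' and is absorbed by centering downstream.
#'
#' @param tree A `phylo` object with non-negative branch lengths.
#' @param seed Optional integer seed (global RNG untouched when supplied).
#' @return A named numeric vector of tip values, in `tree$tip.label` order.
#' @export
simulate_brownian_tips <- function(tree, seed = NULL) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be a `phylo` object.", class = "phypairs_domain_error")
  }
  if (any(tree$edge.length < 0)) {
    abort("Branch lengths must be non-negative.", class = "phypairs_domain_error")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, .bm_tips(tree)))
  }
  .bm_tips(tree)
}

.bm_tips <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise") # parents precede children
  n <- length(tree$tip.label)
  val <- numeric(n + tree$Nnode)
  inc <- rnorm(nrow(tree$edge), mean = 0, sd = sqrt(tree$edge.length))
  for (e in seq_len(nrow(tree$edge))) {
    val[tree$edge[e, 2L]] <- val[tree$edge[e, 1L]] + inc[e]
  }
  setNames(val[seq_len(n)], tree$tip.label)
}

#' Center and rescale tip values into pair effects
#'
#' Centers a vector of (typically Brownian) tip values to mean zero and
#' rescales it so its sample variance (denominator `n - 1`) equals `tau2`
#' exactly. With `tau2 = 0` the result is a zero vector regardless of input.
#' The relative configuration of the values - and hence the phylogenetic
#' correlation pattern among pairs - is preserved; only location and scale
#' change.
#'
#' @param x Numeric vector of at least two tip values.
#' @param tau2 Target sample variance, `>= 0`.
#' @return A numeric vector of pair effects with mean 0 and sample variance
#'   `tau2`.
#' @examples
#' scale_pair_effects(c(1, 3), tau2 = 2)
#' @export
scale_pair_effects <- function(x, tau2) {
  if (length(x) < 2) {
    abort("At least two tip values are required.", class = "phypairs_domain_error")
  }
  if (tau2 < 0) {
    abort("`tau2` must be non-negative.", class = "phypairs_domain_error")
  }
  if (tau2 == 0) {
    return(rep(0, length(x)) |> setNames(names(x)))
  }
  centred <- x - mean(x)
  s2 <- sum(centred^2) / (length(x) - 1)
  if (s2 == 0) {
    abort("Tip values are constant; cannot rescale to a positive variance.",
          class = "phypairs_domain_error")
  }
  centred * sqrt(tau2 / s2)
}

# Fast internal generator: returns the response as an r0+r1 = 2r by p matrix in
# canonical order (native replicates then invasive replicates, one column per
# pair) plus the latent draws. Uses the current RNG state. Draw order: tree,
# Brownian increments, species effects, replicate errors.
.sim_components <- function(p, r, beta, tau2, omega2, sigma2, mu = 0,
                            phylogenetic = TRUE, tree = NULL) {
  if (phylogenetic) {
    if (is.null(tree)) tree <- .yule_phylo(p, rate = 1)
    tips <- .bm_tips(tree)
    alpha <- unname(scale_pair_effects(tips, tau2))
  } else {
    tree <- NULL
    alpha <- rnorm(p, 0, sqrt(tau2))
  }
  gamma <- rnorm(2L * p, 0, sqrt(omega2)) # per species: nat, inv, nat, inv, ...
  eps <- rnorm(2L * p * r, 0, sqrt(sigma2))

  Y <- matrix(eps, nrow = 2L * r, ncol = p)
  Y <- Y + mu
  Y[(r + 1L):(2L * r), ] <- Y[(r + 1L):(2L * r), ] + beta
  Y <- sweep(Y, 2L, alpha, "+")
  gm <- matrix(gamma, nrow = 2L, ncol = p) # row 1 native, row 2 invasive
  Y[seq_len(r), ] <- sweep(Y[seq_len(r), , drop = FALSE], 2L, gm[1L, ], "+")
  Y[(r + 1L):(2L * r), ] <- sweep(Y[(r + 1L):(2L * r), , drop = FALSE], 2L, gm[2L, ], "+")

  list(Y = Y, alpha = alpha, gamma = gamma, eps = eps, tree = tree)
}

#' Simulate a phylogenetically paired dataset
#'
#' Generates replicate trait measurements on `n_pairs` species pairs from the
#' model `y = mu + beta * origin + pair effect + species effect + error`. By
#' default the pair effects are phylogenetically correlated: a fresh Yule tree
#' with one tip per pair is simulated, Brownian trait evolution is run along
#' it, and the tip values are centered and rescaled so their sample variance
#' equals `tau2` exactly (see [scale_pair_effects()]). With
#' `phylogenetic = FALSE` the pair effects are instead iid `N(0, tau2)`, which
#' matches the fitted mixed model exactly. Species effects are iid
#' `N(0, omega2)` (one per species) and errors iid `N(0, sigma2)` (one per
#' replicate). Each pair contributes one native (`origin = 0`) and one
#' invasive (`origin = 1`) species.
#'
#' @param n_pairs Number of species pairs `p` (default 30).
#' @param n_replicates Replicates per species `r` (default 5).
#' @param beta Origin effect (invasive minus native); 0 under the null.
#' @param tau2,omega2,sigma2 Generating variance components for pair, species
#'   and error.
#' @param mu Intercept (trait mean of the native group).
#' @param phylogenetic Use Brownian-on-Yule pair effects (`TRUE`, default) or
#'   iid normal pair effects.
#' @param tree Optional `phylo` object to reuse instead of simulating a fresh
#'   Yule tree (its number of tips must equal `n_pairs`).
#' @param seed Optional integer seed; the global RNG state is untouched when
#'   supplied.
#' @return An object of class `paired_sim`: a list with `data` (a tibble in
#'   the canonical long format), `tree` (`phylo` or `NULL`), `latent` (the
#'   drawn pair effects, species effects and errors) and `config`.
#' @examples
#' sim <- simulate_paired_data(n_pairs = 5, n_replicates = 3, beta = 0.5, seed = 42)
#' sim$data
#' @export
simulate_paired_data <- function(n_pairs = 30, n_replicates = 5, beta = 0,
                                 tau2 = 0.5, omega2 = 0.5, sigma2 = 0.5,
                                 mu = 0, phylogenetic = TRUE, tree = NULL,
                                 seed = NULL) {
  if (n_pairs < 2) abort("`n_pairs` must be >= 2.", class = "phypairs_domain_error")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.", class = "phypairs_domain_error")
  if (!is.finite(beta)) abort("`beta` must be finite.", class = "phypairs_domain_error")
  if (any(c(tau2, omega2, sigma2) < 0)) {
    abort("Variance components must be non-negative.", class = "phypairs_domain_error")
  }
  if (!is.null(tree) && length(tree$tip.label) != n_pairs) {
    abort("`tree` must have one tip per pair.", class = "phypairs_domain_error")
  }
  draw <- function() {
    .sim_components(n_pairs, n_replicates, beta, tau2, omega2, sigma2,
                    mu = mu, phylogenetic = phylogenetic, tree = tree)
  }
  comp <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  p <- n_pairs
  r <- n_replicates
  wid <- max(2L, nchar(as.character(p)))
  pair_ids <- sprintf("p%0*d", wid, seq_len(p))
  species_ids <- paste0(rep(pair_ids, each = 2L), c("_nat", "_inv"))
  data <- tibble::tibble(
    pair = rep(pair_ids, each = 2L * r),
    species = rep(species_ids, each = r),
    origin = rep(rep(c(0L, 1L), each = r), times = p),
    replicate = rep(seq_len(r), times = 2L * p),
    value = as.vector(comp$Y)
  )
  attr(data, "balanced") <- TRUE

  out <- list(
    data = data,
    tree = comp$tree,
    latent = list(
      pair_effects = setNames(comp$alpha, pair_ids),
      species_effects = setNames(comp$gamma, species_ids),
      errors = comp$eps
    ),
    config = list(
      n_pairs = p, n_replicates = r, beta = beta, tau2 = tau2,
      omega2 = omega2, sigma2 = sigma2, mu = mu,
      phylogenetic = phylogenetic, seed = seed
    )
  )
  class(out) <- "paired_sim"
  out
}

#' @export
print.paired_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated paired dataset: %d pairs x 2 species x %d replicates (%d rows)\n",
    cfg$n_pairs, cfg$n_replicates, nrow(x$data)
  ))
  cat(sprintf(
    "  beta = %g, tau2 = %g, omega2 = %g, sigma2 = %g, %s pair effects\n",
    cfg$beta, cfg$tau2, cfg$omega2, cfg$sigma2,
    if (cfg$phylogenetic) "phylogenetic (Yule + Brownian)" else "iid normal"
  ))
  invisible(x)
}

#' @export
autoplot.paired_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$pair, y = .data$value,
                 colour = factor(.data$origin, labels = c("native", "invasive")))
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5), alpha = 0.7) +
    ggplot2::labs(x = "pair", y = "trait value", colour = "origin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
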