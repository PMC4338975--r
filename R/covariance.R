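#' Two-layer compound-symmetry covariance block for one species pair
#'
#' Builds the marginal covariance matrix of the `2 * r` measurements on one
#' pair (r replicates on each of its two species) implied by the mixed model
#' with a pair random effect (variance `tau2`), a species-within-pair random
#' effect (variance `omega2`) and replicate noise (variance `sigma2`):
#' diagonal entries are `tau2 + omega2 + sigma2`, off-diagonal entries within
#' one species are `tau2 + omega2`, and entries linking the two species are
#' `tau2`. Rows/columns are ordered with the `r` replicates of the first
#' species followed by the `r` replicates of the second.
#'
#' @param tau2 Pair-level variance, `>= 0`.
#' @param omega2 Species-within-pair variance, `>= 0`.
#' @param sigma2 Residual variance, `> 0` for a positive-definite block.
#' @param r Replicates per species (`>= 1`); a second value may be given for
#'   an unbalanced pair, e.g. `r = c(3, 5)`.
#' @return A symmetric `sum(r) x sum(r)` matrix.
#' @examples
#' pair_covariance(1, 1, 1, r = 2)
#' @export
pair_covariance <- function(tau2, omega2, sigma2, r) {
  if (any(c(tau2, omega2, sigma2) < 0)) {
    abort("Variance components must be non-negative.", class = "phypairs_domain_error")
  }
  if (length(r) == 1) r <- c(r, r)
  if (length(r) != 2 || any(r < 1) || any(r != round(r))) {
    abort("`r` must be one or two positive integers.", class = "phypairs_domain_error")
  }
  n <- sum(r)
  species <- rep(1:2, times = r)
  m <- matrix(tau2, n, n)
  same_sp <- outer(species, species, "==")
  m[same_sp] <- m[same_sp] + omega2
  diag(m) <- diag(m) + sigma2
  m
}

#' Correlation summaries of the two-layer compound-symmetry structure
#'
#' Converts variance components to the two correlation parameters of the
#' structure: `rho = (tau2 + omega2) / (tau2 + omega2 + sigma2)`, the common
#' correlation of any two replicate measurements within one species, and
#' `theta = tau2 / (tau2 + omega2 + sigma2)`, the common correlation of
#' measurements on the two different species of a pair. Always
#' `0 <= theta <= rho < 1` when `sigma2 > 0`.
#'
#' @inheritParams pair_covariance
#' @return A one-row tibble with columns `rho` and `theta`.
#' @examples
#' cs_correlations(1, 1, 1) # rho = 2/3, theta = 1/3
#' @export
cs_correlations <- function(tau2, omega2, sigma2) {
  if (any(c(tau2, omega2, sigma2) < 0)) {
    abort("Variance components must be non-negative.", class = "phypairs_domain_error")
  }
  total <- tau2 + omega2 + sigma2
  if (total <= 0) {
    abort("Total variance must be positive.", class = "phypairs_domain_error")
  }
  tibble::tibble(rho = (tau2 + omega2) / total, theta = tau2 / total)
}
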