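# -------------------------------------------------------------------------
# Internal canonical representation of a paired dataset.
#
# A "canon" is a list with:
#   y        numeric response in canonical order (pair-major, native species
#            replicates first, then invasive)
#   p, N     number of pairs / total observations
#   balanced TRUE when every species has the same replicate count
#   r        replicates per species (balanced case)
#   Y        2r x p response matrix (balanced case)
#   sizes    p x 2 matrix of replicate counts (native, invasive)
#   rows     list of row-index vectors per pair (general case)
#   df       the validated tibble (absent for matrix-born canons)
# -------------------------------------------------------------------------

.canon_from_df <- function(data) {
  df <- if (isTRUE(attr(data, "balanced")) || isFALSE(attr(data, "balanced"))) {
    data
  } else {
    validate_pair_data(data)
  }
  pairs <- unique(df$pair)
  p <- length(pairs)
  rows <- split(seq_len(nrow(df)), factor(df$pair, levels = pairs))
  sizes <- t(vapply(rows, function(ix) {
    c(sum(df$origin[ix] == 0L), sum(df$origin[ix] == 1L))
  }, numeric(2)))
  balanced <- length(unique(as.vector(sizes))) == 1L
  dimnames(sizes) <- NULL
  canon <- list(
    y = df$value, p = p, N = nrow(df), balanced = balanced,
    sizes = sizes, rows = rows, df = df, pairs = pairs
  )
  if (balanced) {
    canon$r <- sizes[1, 1]
    canon$Y <- matrix(df$value, nrow = 2L * canon$r, ncol = p)
  }
  canon
}

.canon_from_Y <- function(Y) {
  r <- nrow(Y) %/% 2L
  p <- ncol(Y)
  list(
    y = as.vector(Y), p = p, N = length(Y), balanced = TRUE,
    sizes = matrix(r, p, 2), r = r, Y = Y
  )
}

# Design matrix for one pair block: intercept + origin indicator.
.block_X <- function(r0, r1, null = FALSE) {
  if (null) matrix(1, r0 + r1, 1) else cbind(1, rep(c(0, 1), c(r0, r1)))
}

# Covariance derivative patterns for one block.
.block_G <- function(r0, r1) {
  n <- r0 + r1
  sp <- rep(1:2, c(r0, r1))
  G_omega <- matrix(0, n, n)
  G_omega[outer(sp, sp, "==")] <- 1
  list(
    tau2 = matrix(1, n, n),
    omega2 = G_omega,
    sigma2 = diag(n)
  )
}

.free_components <- function(model) {
  switch(model,
    pair_species = c("tau2", "omega2", "sigma2"),
    pair = c("tau2", "sigma2"),
    anova = "sigma2"
  )
}

.model_canonical <- function(model) {
  key <- tolower(as.character(model)[1])
  out <- c(
    m1 = "anova", model1 = "anova", anova = "anova", ols = "anova",
    fixed = "anova",
    m2 = "pair", model2 = "pair", pair = "pair",
    m3 = "pair_species", model3 = "pair_species", pair_species = "pair_species",
    species_pair = "pair_species"
  )[key]
  if (is.na(out)) {
    abort(paste0("Unknown model: ", model,
                 ". Use 'anova' (M1), 'pair' (M2) or 'pair_species' (M3)."),
          class = "phypairs_domain_error")
  }
  unname(out)
}

# -------------------------------------------------------------------------
# REML log-likelihood (full, not profiled) at a variance-component triple.
# Returns the GLS fixed effects and their covariance as by-products.
# -------------------------------------------------------------------------
.reml_ll <- function(canon, vc, null = FALSE) {
  tau2 <- vc[["tau2"]]; omega2 <- vc[["omega2"]]; sigma2 <- vc[["sigma2"]]
  q <- if (null) 1L else 2L
  if (sigma2 <= 0) {
    return(list(ll = -Inf, coef = rep(NA_real_, q), Phi = NULL, yPy = NA_real_))
  }
  if (canon$balanced) {
    r <- canon$r
    Vb <- pair_covariance(tau2, omega2, sigma2, r)
    Xb <- .block_X(r, r, null)
    ch <- chol(Vb)
    logdet_b <- 2 * sum(log(diag(ch)))
    Vbi <- chol2inv(ch)
    VX <- Vbi %*% Xb
    S <- canon$p * crossprod(Xb, VX)
    VY <- Vbi %*% canon$Y
    yVy <- sum(canon$Y * VY)
    xvy <- crossprod(Xb, VY %*% rep(1, canon$p))
    logdet_tot <- canon$p * logdet_b
  } else {
    S <- matrix(0, q, q)
    xvy <- matrix(0, q, 1)
    yVy <- 0
    logdet_tot <- 0
    for (b in seq_len(canon$p)) {
      ix <- canon$rows[[b]]
      r0 <- canon$sizes[b, 1]; r1 <- canon$sizes[b, 2]
      Vb <- pair_covariance(tau2, omega2, sigma2, c(r0, r1))
      Xb <- .block_X(r0, r1, null)
      ch <- chol(Vb)
      logdet_tot <- logdet_tot + 2 * sum(log(diag(ch)))
      Vbi <- chol2inv(ch)
      yb <- canon$y[ix]
      Vyb <- Vbi %*% yb
      S <- S + crossprod(Xb, Vbi %*% Xb)
      xvy <- xvy + crossprod(Xb, Vyb)
      yVy <- yVy + sum(yb * Vyb)
    }
  }
  Phi <- solve(S)
  coef <- drop(Phi %*% xvy)
  yPy <- yVy - drop(crossprod(xvy, Phi %*% xvy))
  ll <- -0.5 * (logdet_tot + determinant(S, logarithm = TRUE)$modulus +
                  yPy + (canon$N - q) * log(2 * pi))
  list(ll = as.numeric(ll), coef = coef, Phi = Phi, yPy = yPy)
}

# Profiled -2 REML criterion over variance ratios lambda = vc / sigma2.
.reml_prof_m2 <- function(canon, lt, lo, null = FALSE) {
  q <- if (null) 1L else 2L
  at1 <- .reml_ll_ratios(canon, lt, lo, null)
  sigma2 <- at1$yPy / (canon$N - q)
  list(
    crit = (canon$N - q) * (1 + log(2 * pi) + log(sigma2)) + at1$logdet_tot + at1$logdetS,
    sigma2 = sigma2
  )
}

# Pieces of the REML criterion at vc = (lt, lo, 1).
.reml_ll_ratios <- function(canon, lt, lo, null = FALSE) {
  q <- if (null) 1L else 2L
  if (canon$balanced) {
    r <- canon$r
    Vb <- pair_covariance(lt, lo, 1, r)
    Xb <- .block_X(r, r, null)
    ch <- chol(Vb)
    Vbi <- chol2inv(ch)
    S <- canon$p * crossprod(Xb, Vbi %*% Xb)
    VY <- Vbi %*% canon$Y
    yVy <- sum(canon$Y * VY)
    xvy <- crossprod(Xb, VY %*% rep(1, canon$p))
    logdet_tot <- canon$p * 2 * sum(log(diag(ch)))
  } else {
    S <- matrix(0, q, q); xvy <- matrix(0, q, 1); yVy <- 0; logdet_tot <- 0
    for (b in seq_len(canon$p)) {
      ix <- canon$rows[[b]]
      r0 <- canon$sizes[b, 1]; r1 <- canon$sizes[b, 2]
      Vb <- pair_covariance(lt, lo, 1, c(r0, r1))
      Xb <- .block_X(r0, r1, null)
      ch <- chol(Vb)
      logdet_tot <- logdet_tot + 2 * sum(log(diag(ch)))
      Vbi <- chol2inv(ch)
      yb <- canon$y[ix]
      Vyb <- Vbi %*% yb
      S <- S + crossprod(Xb, Vbi %*% Xb)
      xvy <- xvy + crossprod(Xb, Vyb)
      yVy <- yVy + sum(yb * Vyb)
    }
  }
  Phi <- solve(S)
  yPy <- yVy - drop(crossprod(xvy, Phi %*% xvy))
  list(
    yPy = yPy, logdet_tot = logdet_tot,
    logdetS = as.numeric(determinant(S, logarithm = TRUE)$modulus)
  )
}

# -------------------------------------------------------------------------
# Balanced-design sufficient statistics.
# -------------------------------------------------------------------------
.balanced_stats <- function(canon) {
  Y <- canon$Y; r <- canon$r; p <- canon$p
  m0 <- if (r == 1L) Y[1, ] else colMeans(Y[seq_len(r), , drop = FALSE])
  m1 <- if (r == 1L) Y[2, ] else colMeans(Y[(r + 1L):(2L * r), , drop = FALSE])
  d <- m1 - m0
  dbar <- mean(d)
  pm <- (m0 + m1) / 2
  grand <- mean(pm)
  ss_e <- sum(Y^2) - r * sum(m0^2 + m1^2)
  list(
    r = r, p = p, m0 = m0, m1 = m1, d = d, dbar = dbar, pm = pm, grand = grand,
    ss_e = ss_e, df_e = 2 * p * (r - 1),
    ss_sp = r * sum((d - dbar)^2) / 2,            # species(pair), origin-adjusted
    ss_sp_null = r * sum(d^2) / 2,                # species(pair), unadjusted
    ss_pair = 2 * r * sum((pm - grand)^2),
    ss_sp2 = r * (sum((m0 - mean(m0))^2) + sum((m1 - mean(m1))^2)), # species within origin
    ss_sp2_null = r * (sum((m0 - grand)^2) + sum((m1 - grand)^2))
  )
}

#' ANOVA method-of-moments variance components for a balanced design
#'
#' Closed-form estimators from the balanced nested ANOVA decomposition:
#' `sigma2 = MS_error`, `omega2 = (MS_species(pair) - MS_error) / r` and
#' `tau2 = (MS_pair - MS_species(pair)) / (2 r)`, where the species-within-pair
#' mean square is adjusted for the origin effect. Estimates are returned raw
#' and may be negative; REML clips them to the non-negative orthant. On
#' balanced data with an interior solution these equal the REML estimates.
#'
#' @param data A balanced paired dataset with at least 2 replicates per
#'   species.
#' @return A one-row tibble with columns `tau2`, `omega2`, `sigma2`.
#' @export
moment_estimates <- function(data) {
  canon <- .canon_from_df(data)
  if (!canon$balanced) {
    abort("Moment estimators require a balanced design.",
          class = "phypairs_domain_error")
  }
  if (canon$r < 2) {
    abort("Moment estimators require at least 2 replicates per species.",
          class = "phypairs_domain_error")
  }
  st <- .balanced_stats(canon)
  ms_e <- st$ss_e / st$df_e
  ms_sp <- st$ss_sp / (st$p - 1)
  ms_pair <- st$ss_pair / (st$p - 1)
  tibble::tibble(
    tau2 = (ms_pair - ms_sp) / (2 * st$r),
    omega2 = (ms_sp - ms_e) / st$r,
    sigma2 = ms_e
  )
}

# -------------------------------------------------------------------------
# Closed-form balanced REML with orthant handling. Candidate fits on the
# boundary of the parameter space are compared by their REML log-likelihood.
# -------------------------------------------------------------------------
.fit_balanced <- function(canon, model, null = FALSE) {
  st <- .balanced_stats(canon)
  p <- st$p; r <- st$r; N <- canon$N
  q <- if (null) 1L else 2L
  ss_sp <- if (null) st$ss_sp_null else st$ss_sp
  df_sp <- if (null) p else p - 1L
  ss_sp2 <- if (null) st$ss_sp2_null else st$ss_sp2
  df_sp2 <- if (null) 2L * p - 1L else 2L * p - 2L
  ms_pair <- st$ss_pair / (p - 1)
  rss_ols <- st$ss_e + ss_sp2 # residual SS of the fixed-effects-only model

  vc_ols <- c(tau2 = 0, omega2 = 0, sigma2 = rss_ols / (N - q))
  cand_m2 <- function() {
    sigma2 <- (st$ss_e + ss_sp) / (st$df_e + df_sp)
    tau2 <- (ms_pair - sigma2) / (2 * r)
    if (tau2 > 0 && sigma2 > 0) c(tau2 = tau2, omega2 = 0, sigma2 = sigma2) else vc_ols
  }
  cand_sp <- function() {
    ms_e <- st$ss_e / st$df_e
    omega2 <- (ss_sp2 / df_sp2 - ms_e) / r
    if (omega2 > 0 && ms_e > 0) c(tau2 = 0, omega2 = omega2, sigma2 = ms_e) else vc_ols
  }

  vc <- switch(model,
    pair_species = {
      ms_e <- st$ss_e / st$df_e
      ms_sp <- ss_sp / df_sp
      est <- c(
        tau2 = (ms_pair - ms_sp) / (2 * r),
        omega2 = (ms_sp - ms_e) / r,
        sigma2 = ms_e
      )
      if (all(est > 0)) {
        est
      } else {
        .best_candidate(canon, unique(list(cand_m2(), cand_sp(), vc_ols)), null)
      }
    },
    pair = {
      est <- cand_m2()
      if (est[["tau2"]] > 0) est else .best_candidate(canon, list(vc_ols), null)
    },
    anova = vc_ols
  )
  vc
}

.best_candidate <- function(canon, candidates, null = FALSE) {
  lls <- vapply(candidates, function(vc) {
    if (vc[["sigma2"]] <= 0) return(-Inf)
    .reml_ll(canon, vc, null)$ll
  }, numeric(1))
  candidates[[which.max(lls)]]
}

# -------------------------------------------------------------------------
# General REML by profiled optimization over variance ratios (log scale),
# with explicit boundary candidates.
# -------------------------------------------------------------------------
.start_ratios <- function(canon, null = FALSE) {
  # crude moment-style starts from per-species means; clipped away from zero
  sp_means <- numeric(0); d <- numeric(0); pmns <- numeric(0)
  ss_e <- 0; df_e <- 0
  for (b in seq_len(canon$p)) {
    ix <- canon$rows[[b]]
    r0 <- canon$sizes[b, 1]; r1 <- canon$sizes[b, 2]
    yb <- canon$y[ix]
    m0 <- mean(yb[seq_len(r0)]); m1 <- mean(yb[(r0 + 1):(r0 + r1)])
    ss_e <- ss_e + sum((yb - rep(c(m0, m1), c(r0, r1)))^2)
    df_e <- df_e + (r0 - 1) + (r1 - 1)
    d <- c(d, m1 - m0); pmns <- c(pmns, (m0 + m1) / 2)
  }
  vy <- var(canon$y)
  floor_v <- max(1e-4 * vy, 1e-12)
  rbar <- canon$N / (2 * canon$p)
  sigma0 <- if (df_e > 0) ss_e / df_e else vy / 2
  omega0 <- var(d) / 2 - sigma0 / rbar
  tau0 <- var(pmns) - omega0 / 2 - sigma0 / (2 * rbar)
  sigma0 <- max(sigma0, floor_v)
  c(
    tau = max(tau0, floor_v) / sigma0,
    omega = max(omega0, floor_v) / sigma0,
    sigma = sigma0
  )
}

.fit_optim <- function(canon, model, null = FALSE) {
  q <- if (null) 1L else 2L
  start <- .start_ratios(canon, null)
  crit2 <- function(lt, lo) .reml_prof_m2(canon, lt, lo, null)$crit

  best <- NULL
  keep <- function(cand) {
    if (is.null(best) || cand$crit < best$crit - 1e-12) best <<- cand
    invisible(NULL)
  }
  finish <- function(lt, lo, crit, convergence = 0L) {
    sigma2 <- .reml_prof_m2(canon, lt, lo, null)$sigma2
    list(lt = lt, lo = lo, crit = crit, sigma2 = sigma2,
         converged = convergence == 0L)
  }

  if (model == "pair_species") {
    opt <- optim(
      par = log(c(start[["tau"]], start[["omega"]])),
      fn = function(par) crit2(exp(par[1]), exp(par[2])),
      method = "Nelder-Mead",
      control = list(maxit = 200, reltol = 1e-12)
    )
    keep(finish(exp(opt$par[1]), exp(opt$par[2]), opt$value, opt$convergence))
    o1 <- optimize(function(l) crit2(0, exp(l)), interval = c(-30, 15))
    keep(finish(0, exp(o1$minimum), o1$objective))
    o2 <- optimize(function(l) crit2(exp(l), 0), interval = c(-30, 15))
    keep(finish(exp(o2$minimum), 0, o2$objective))
  } else if (model == "pair") {
    o <- optimize(function(l) crit2(exp(l), 0), interval = c(-30, 15))
    keep(finish(exp(o$minimum), 0, o$objective))
  }
  keep(finish(0, 0, crit2(0, 0)))

  vc <- c(
    tau2 = best$lt * best$sigma2,
    omega2 = best$lo * best$sigma2,
    sigma2 = best$sigma2
  )
  # components that drifted to numerical zero are on the boundary
  tol <- 1e-8 * sum(vc)
  vc[c("tau2", "omega2")][vc[c("tau2", "omega2")] < tol] <- 0
  attr(vc, "converged") <- best$converged
  vc
}

.fit_core <- function(canon, model, null = FALSE, method = "auto") {
  if (model == "pair_species" && max(canon$sizes) < 2) {
    abort(paste0("Model with species and pair random effects is not identifiable ",
                 "with a single replicate per species (omega2 and sigma2 are confounded)."),
          class = "phypairs_domain_error")
  }
  q <- if (null) 1L else 2L

  # degenerate data: no variation at all
  if (var(canon$y) == 0) {
    coef <- if (null) mean(canon$y) else c(mean(canon$y), 0)
    free <- .free_components(model)
    return(list(
      vc = c(tau2 = 0, omega2 = 0, sigma2 = 0), free = free,
      boundary = setNames(rep(TRUE, length(free)), free),
      coef = coef, Phi = matrix(0, q, q), loglik = NA_real_,
      converged = TRUE, method_used = "degenerate"
    ))
  }

  converged <- TRUE
  if (model == "anova" || (canon$balanced && method != "optim" &&
                             (canon$r >= 2 || model != "pair_species"))) {
    vc <- .fit_balanced_or_anova(canon, model, null)
    method_used <- if (model == "anova") "ols" else "closed_form"
  } else {
    vc <- .fit_optim(canon, model, null)
    converged <- isTRUE(attr(vc, "converged"))
    attr(vc, "converged") <- NULL
    method_used <- "optim"
  }

  free <- .free_components(model)
  tol <- 1e-8 * sum(vc)
  boundary <- setNames(vc[free] <= tol, free)
  ll <- .reml_ll(canon, vc, null)
  list(
    vc = vc, free = free, boundary = boundary,
    coef = ll$coef, Phi = ll$Phi, loglik = ll$ll,
    converged = converged && is.finite(ll$ll), method_used = method_used
  )
}

.fit_balanced_or_anova <- function(canon, model, null) {
  if (model == "anova") {
    if (canon$balanced) return(.fit_balanced(canon, "anova", null))
    # OLS residual variance with the REML (unbiased) divisor
    X <- if (null) matrix(1, canon$N, 1) else {
      x <- unlist(lapply(seq_len(canon$p), function(b) {
        rep(c(0, 1), canon$sizes[b, ])
      }))
      cbind(1, x)
    }
    fitted <- X %*% solve(crossprod(X), crossprod(X, canon$y))
    rss <- sum((canon$y - fitted)^2)
    return(c(tau2 = 0, omega2 = 0, sigma2 = rss / (canon$N - ncol(X))))
  }
  .fit_balanced(canon, model, null)
}

# -------------------------------------------------------------------------
# Public fitting interface.
# -------------------------------------------------------------------------

#' Fit a paired-design model by REML
#'
#' Fits one of three competing models for replicated measurements on
#' native/invasive species pairs, with a fixed origin effect throughout:
#'
#' * `"anova"` (Model 1): fixed-effect one-way ANOVA; all observations
#'   treated as independent.
#' * `"pair"` (Model 2): random intercept for pair; single-layer compound
#'   symmetry within pairs.
#' * `"pair_species"` (Model 3): random intercepts for pair and for species
#'   within pair; two-layer compound symmetry.
#'
#' Variance components are estimated by restricted maximum likelihood over
#' the non-negative orthant and fixed effects by generalized least squares at
#' the REML estimates. On balanced designs with an interior solution the REML
#' estimates coincide with the closed-form ANOVA moment estimators
#' ([moment_estimates()]) and are computed in closed form; boundary solutions
#' are resolved by comparing the restricted likelihood of the candidate edge
#' models, and unbalanced designs use a profiled Nelder-Mead optimization
#' over log variance ratios with explicit boundary candidates.
#'
#' @param data A paired dataset (long-format data frame; see
#'   [validate_pair_data()]).
#' @param model `"pair_species"` (default), `"pair"` or `"anova"`; the aliases
#'   `"M3"`/`"M2"`/`"M1"` are accepted.
#' @param method `"auto"` (closed form on balanced designs, optimizer
#'   otherwise), `"closed_form"`, or `"optim"` to force the general
#'   optimizer.
#' @return An object of class `pair_fit` with components `coefficients`
#'   (`mu`, `beta`), `vcov` (model-based GLS covariance of the fixed
#'   effects), `vc` (named variance components), `boundary` (which free
#'   components were estimated at zero), `loglik` (REML log-likelihood),
#'   `converged` and bookkeeping fields. Methods: [tidy()], [glance()],
#'   `print()`, [kr_test()].
#' @examples
#' sim <- simulate_paired_data(n_pairs = 10, n_replicates = 3, beta = 0.5, seed = 7)
#' fit <- fit_pair_model(sim$data)
#' fit
#' kr_test(fit)
#' @export
fit_pair_model <- function(data, model = c("pair_species", "pair", "anova"),
                           method = c("auto", "closed_form", "optim")) {
  model <- .model_canonical(if (is.character(model)) model[1] else model)
  method <- match.arg(method)
  canon <- .canon_from_df(data)
  if (method == "closed_form" && !canon$balanced) {
    abort("`method = 'closed_form'` requires a balanced design.",
          class = "phypairs_domain_error")
  }
  core <- .fit_core(canon, model, null = FALSE, method = method)
  structure(
    list(
      model = model,
      model_index = match(model, c("anova", "pair", "pair_species")),
      coefficients = setNames(core$coef, c("mu", "beta")),
      vcov = core$Phi,
      vc = core$vc,
      free = core$free,
      boundary = core$boundary,
      loglik = core$loglik,
      converged = core$converged,
      method_used = core$method_used,
      balanced = canon$balanced,
      n_pairs = canon$p,
      nobs = canon$N,
      canon = canon
    ),
    class = "pair_fit"
  )
}

#' Generalized least squares fixed effects at given variance components
#'
#' Solves the GLS normal equations for the intercept and origin effect under
#' the two-layer compound-symmetry covariance implied by the supplied
#' variance components (see [pair_covariance()]). With
#' `tau2 = omega2 = 0` this reproduces ordinary least squares, i.e. the
#' origin group means.
#'
#' @inheritParams fit_pair_model
#' @inheritParams pair_covariance
#' @return A list with `coefficients` (named vector `mu`, `beta`) and `vcov`
#'   (their model-based covariance matrix).
#' @export
gls_origin <- function(data, tau2, omega2, sigma2) {
  if (any(c(tau2, omega2) < 0) || sigma2 <= 0) {
    abort("Need tau2 >= 0, omega2 >= 0, sigma2 > 0.", class = "phypairs_domain_error")
  }
  canon <- .canon_from_df(data)
  ll <- .reml_ll(canon, c(tau2 = tau2, omega2 = omega2, sigma2 = sigma2))
  list(coefficients = setNames(ll$coef, c("mu", "beta")), vcov = ll$Phi)
}

#' @export
print.pair_fit <- function(x, ...) {
  labels <- c(anova = "Model 1 (fixed-effect one-way ANOVA)",
              pair = "Model 2 (random effect: pair)",
              pair_species = "Model 3 (random effects: pair + species)")
  cat(labels[[x$model]], "\n")
  cat(sprintf("  REML fit to %d observations on %d pairs%s\n", x$nobs, x$n_pairs,
              if (x$balanced) " (balanced)" else ""))
  cat(sprintf("  origin effect: %.4g (SE %.4g)\n",
              x$coefficients[["beta"]], sqrt(x$vcov[2, 2])))
  vc <- x$vc
  cat(sprintf("  variance components: tau2 = %.4g, omega2 = %.4g, sigma2 = %.4g\n",
              vc[["tau2"]], vc[["omega2"]], vc[["sigma2"]]))
  if (any(x$boundary)) {
    cat("  boundary estimates:", paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  if (is.finite(x$loglik)) cat(sprintf("  REML log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Tidy a paired-design model fit
#'
#' @param x A `pair_fit` object.
#' @param effects `"fixed"` for the fixed effects (default) or `"ran_pars"`
#'   for the variance components.
#' @param ... Unused.
#' @return A tibble with one row per term.
#' @export
tidy.pair_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    tibble::tibble(
      effect = "fixed",
      term = c("(Intercept)", "origin"),
      estimate = unname(x$coefficients),
      std.error = sqrt(diag(x$vcov))
    )
  } else {
    tibble::tibble(
      effect = "ran_pars",
      term = c("var_pair", "var_species", "var_residual"),
      estimate = unname(x$vc[c("tau2", "omega2", "sigma2")])
    )
  }
}

#' Fit-level summary of a paired-design model
#'
#' @param x A `pair_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the REML log-likelihood, the implied
#'   within-species and between-species correlations, and fit metadata.
#' @export
glance.pair_fit <- function(x, ...) {
  total <- sum(x$vc)
  tibble::tibble(
    logLik = x$loglik,
    nobs = x$nobs,
    n_pairs = x$n_pairs,
    rho = if (total > 0) (x$vc[["tau2"]] + x$vc[["omega2"]]) / total else 0,
    theta = if (total > 0) x$vc[["tau2"]] / total else 0,
    converged = x$converged,
    boundary = any(x$boundary)
  )
}

#' Serialize a fit to JSON
#'
#' @param fit A `pair_fit` object.
#' @return A JSON string with estimates, standard errors, variance
#'   components, REML log-likelihood and convergence metadata.
#' @export
fit_json <- function(fit) {
  stopifnot(inherits(fit, "pair_fit"))
  jsonlite::toJSON(
    list(
      package = "phypairs",
      version = as.character(utils::packageVersion("phypairs")),
      model = fit$model,
      coefficients = as.list(fit$coefficients),
      std_errors = as.list(setNames(sqrt(diag(fit$vcov)), c("mu", "beta"))),
      variance_components = as.list(fit$vc),
      reml_loglik = fit$loglik,
      converged = fit$converged,
      boundary = as.list(fit$boundary)
    ),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
}
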