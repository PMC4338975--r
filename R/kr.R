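# -------------------------------------------------------------------------
# Kenward-Roger (1997) first-order adjustment for the origin contrast.
#
# The covariance model is linear in the variance components,
# V = tau2 * G_tau + omega2 * G_omega + sigma2 * I with 0/1 pattern matrices
# G, so all derivatives of V are assembled analytically and the second
# derivative term of the adjustment vanishes. Per-pair blocks keep every
# matrix small; on balanced designs all blocks are identical and are
# computed once.
# -------------------------------------------------------------------------

# Accumulate the block-level quantities needed by the adjustment:
#   S     = X' V^-1 X
#   C[i]  = X' V^-1 G_i V^-1 X
#   U[ij] = X' V^-1 G_i V^-1 G_j V^-1 X
#   T[ij] = tr(V^-1 G_i V^-1 G_j)
.kr_accumulate <- function(canon, vc, free) {
  k <- length(free)
  q <- 2L
  S <- matrix(0, q, q)
  Cm <- lapply(seq_len(k), function(i) matrix(0, q, q))
  Um <- matrix(list(), k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) Um[[i, j]] <- matrix(0, q, q)
  Tm <- matrix(0, k, k)

  block_quants <- function(r0, r1, mult) {
    Vb <- pair_covariance(vc[["tau2"]], vc[["omega2"]], vc[["sigma2"]], c(r0, r1))
    Xb <- .block_X(r0, r1)
    G <- .block_G(r0, r1)[free]
    Vbi <- chol2inv(chol(Vb))
    VX <- Vbi %*% Xb
    B <- lapply(G, function(g) Vbi %*% g %*% Vbi) # V^-1 G V^-1, symmetric
    Fj <- lapply(G, function(g) g %*% VX)
    S <<- S + mult * crossprod(Xb, VX)
    for (i in seq_len(k)) {
      Cm[[i]] <<- Cm[[i]] + mult * crossprod(Xb, B[[i]] %*% Xb)
      Ei <- B[[i]] %*% Xb
      for (j in seq_len(k)) {
        Um[[i, j]] <<- Um[[i, j]] + mult * crossprod(Ei, Fj[[j]])
        if (j >= i) Tm[i, j] <<- Tm[i, j] + mult * sum(B[[i]] * G[[j]])
      }
    }
  }

  if (canon$balanced) {
    block_quants(canon$r, canon$r, canon$p)
  } else {
    for (b in seq_len(canon$p)) {
      block_quants(canon$sizes[b, 1], canon$sizes[b, 2], 1)
    }
  }
  Tm[lower.tri(Tm)] <- t(Tm)[lower.tri(Tm)]
  list(S = S, C = Cm, U = Um, T = Tm, k = k)
}

# Adjusted covariance, scaled F statistic and moment-matched denominator df
# for the single-df origin contrast L = (0, 1).
.kr_core <- function(canon, vc, free, beta) {
  acc <- .kr_accumulate(canon, vc, free)
  k <- acc$k
  Phi <- solve(acc$S)

  # expected REML information and asymptotic covariance of the vc estimates
  info <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      info[i, j] <- 0.5 * (acc$T[i, j] -
                             2 * sum(diag(Phi %*% acc$U[[i, j]])) +
                             sum(diag(Phi %*% acc$C[[i]] %*% Phi %*% acc$C[[j]])))
      info[j, i] <- info[i, j]
    }
  }
  W <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(W)) {
    # no usable curvature (e.g. every component at the boundary): fall back
    # to the unadjusted Wald statistic with the residual df
    se2 <- Phi[2, 2]
    fstat <- beta^2 / se2
    den_df <- canon$N - 2
    return(list(
      f = fstat, den_df = den_df, p = pf(fstat, 1, den_df, lower.tail = FALSE),
      se = sqrt(se2), lambda = 1, adjusted = FALSE
    ))
  }

  adj <- matrix(0, 2, 2)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      adj <- adj + W[i, j] * (acc$U[[i, j]] - acc$C[[i]] %*% Phi %*% acc$C[[j]])
    }
  }
  Phi_adj <- Phi + 2 * (Phi %*% adj %*% Phi)

  f_raw <- beta^2 / Phi_adj[2, 2]

  # moment matching for the denominator df (single-df contrast)
  Theta <- matrix(0, 2, 2)
  Theta[2, 2] <- 1 / Phi[2, 2]
  M <- Phi %*% Theta %*% Phi
  a_vec <- vapply(seq_len(k), function(i) sum(M * acc$C[[i]]), numeric(1))
  A1 <- drop(crossprod(a_vec, W %*% a_vec))
  A2 <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      A2 <- A2 + W[i, j] * sum(diag(M %*% acc$C[[i]] %*% M %*% acc$C[[j]]))
    }
  }
  B <- (A1 + 6 * A2) / 2
  g <- (2 * A1 - 5 * A2) / (3 * A2)
  den <- 3 + 2 * (1 - g)
  c1 <- g / den; c2 <- (1 - g) / den; c3 <- (3 - g) / den
  Estar <- 1 / (1 - A2)
  Vstar <- 2 * (1 + c1 * B) / ((1 - c2 * B)^2 * (1 - c3 * B))
  rho <- Vstar / (2 * Estar^2)
  m <- if (rho > 1 + 1e-12) 4 + 3 / (rho - 1) else Inf
  lambda <- if (is.finite(m)) m / (Estar * (m - 2)) else 1 / Estar

  fstat <- lambda * f_raw
  p <- if (is.finite(m)) {
    pf(fstat, 1, m, lower.tail = FALSE)
  } else {
    stats::pchisq(fstat, 1, lower.tail = FALSE)
  }
  list(
    f = fstat, den_df = m, p = p, se = sqrt(Phi_adj[2, 2]),
    lambda = lambda, adjusted = TRUE
  )
}

.test_row <- function(estimate, f, den_df, p, method, boundary = FALSE) {
  tibble::tibble(
    term = "origin", estimate = estimate, f_stat = f, num_df = 1L,
    den_df = den_df, p_value = p, method = method, boundary = boundary
  )
}

#' Kenward-Roger F-test of the origin effect
#'
#' Tests the fixed origin effect of a mixed-model fit ([fit_pair_model()]
#' with `model = "pair"` or `"pair_species"`) with the first-order
#' Kenward-Roger (1997) small-sample adjustment: the asymptotic GLS
#' covariance of the fixed effects is inflated to account for the
#' variability of the REML variance-component estimates, and the denominator
#' degrees of freedom of the scaled Wald F statistic are moment-matched. On
#' a balanced design with an interior Model 3 fit the result is exact and
#' identical to [exact_f_test()] (denominator df = number of pairs - 1).
#'
#' Variance components estimated on the boundary (zero) are dropped from the
#' adjustment - the limit of zero information weight - and the result is
#' flagged in the `boundary` column.
#'
#' @param fit A converged `pair_fit` with a pair or pair + species random
#'   effect.
#' @return A one-row tibble: `term`, `estimate`, `f_stat`, `num_df`,
#'   `den_df`, `p_value`, `method = "kenward_roger"`, `boundary`.
#' @export
kr_test <- function(fit) {
  stopifnot(inherits(fit, "pair_fit"))
  if (fit$model == "anova") {
    abort("Kenward-Roger applies to the mixed models; use `ols_f_test()` for Model 1.",
          class = "phypairs_domain_error")
  }
  if (!fit$converged) {
    abort("Fit did not converge; cannot test.", class = "phypairs_fit_error")
  }
  if (fit$vc[["sigma2"]] <= 0) {
    abort("Residual variance is zero; the test is undefined.",
          class = "phypairs_fit_error")
  }
  free <- fit$free[!fit$boundary]
  if (length(free) == 0) free <- "sigma2"
  res <- .kr_core(fit$canon, fit$vc, free, fit$coefficients[["beta"]])
  if (any(fit$boundary)) {
    warn("Variance component(s) on the boundary; adjustment terms for them were dropped.",
         class = "phypairs_boundary_warning")
  }
  .test_row(fit$coefficients[["beta"]], res$f, res$den_df, res$p,
            "kenward_roger", boundary = any(fit$boundary))
}

#' Exact F-test for a balanced paired design
#'
#' The classical balanced-ANOVA test of the origin effect:
#' `F = MS_origin / MS_species(pair)` with 1 and `p - 1` degrees of freedom,
#' where `p` is the number of pairs. Algebraically identical to the paired
#' t-test on per-species means (`t^2 = F`). Exact under the two-layer
#' compound-symmetry model - and indeed under any distribution of pair
#' effects, since they cancel from the within-pair species contrasts.
#'
#' @param data A balanced paired dataset.
#' @return A one-row test tibble (see [kr_test()]) with
#'   `method = "exact_balanced"`.
#' @export
exact_f_test <- function(data) {
  canon <- .canon_from_df(data)
  if (!canon$balanced) {
    abort("The exact F-test requires a balanced design.",
          class = "phypairs_domain_error")
  }
  st <- .balanced_stats(canon)
  ms_sp <- st$ss_sp / (st$p - 1)
  ms_origin <- st$p * st$r * st$dbar^2 / 2
  if (ms_sp == 0) {
    f <- if (ms_origin == 0) 0 else Inf
  } else {
    f <- ms_origin / ms_sp
  }
  p_val <- if (is.infinite(f)) 0 else pf(f, 1, st$p - 1, lower.tail = FALSE)
  .test_row(st$dbar, f, st$p - 1, p_val, "exact_balanced")
}

#' One-way ANOVA F-test treating all replicates as independent
#'
#' The fixed-effect one-way ANOVA of origin on all replicate measurements
#' (Model 1): equivalent to the squared pooled-variance two-sample t-test,
#' with `N - 2` denominator degrees of freedom. Ignores both layers of
#' correlation, so it is anti-conservative whenever pair or species variance
#' is present.
#'
#' @param data A paired dataset.
#' @return A one-row test tibble with `method = "classical_ols"`.
#' @export
ols_f_test <- function(data) {
  canon <- .canon_from_df(data)
  x <- if (canon$balanced) {
    rep(rep(c(0, 1), each = canon$r), canon$p)
  } else {
    unlist(lapply(seq_len(canon$p), function(b) rep(c(0, 1), canon$sizes[b, ])))
  }
  y <- canon$y
  n0 <- sum(x == 0); n1 <- sum(x == 1)
  if (n0 < 1 || n1 < 1 || canon$N < 3) {
    abort("Need observations in both origin groups and N >= 3.",
          class = "phypairs_domain_error")
  }
  beta <- mean(y[x == 1]) - mean(y[x == 0])
  rss <- sum((y[x == 0] - mean(y[x == 0]))^2) + sum((y[x == 1] - mean(y[x == 1]))^2)
  s2 <- rss / (canon$N - 2)
  vb <- s2 * (1 / n0 + 1 / n1)
  f <- if (vb == 0) { if (beta == 0) 0 else Inf } else beta^2 / vb
  p_val <- if (is.infinite(f)) 0 else pf(f, 1, canon$N - 2, lower.tail = FALSE)
  .test_row(beta, f, canon$N - 2, p_val, "classical_ols")
}

#' Parametric bootstrap test of the origin effect
#'
#' Fits the chosen model without the origin term (the null), simulates `B`
#' datasets from that null fit (normal random effects and errors at the null
#' REML estimates), refits the alternative to each, and compares the
#' observed F statistic with the bootstrap distribution. The p-value uses
#' the `(1 + #\{F* >= F_obs\}) / (B + 1)` convention, so it is never zero and
#' the test is valid. Intended for unbalanced designs where the
#' Kenward-Roger F may not follow an F distribution.
#'
#' @param data A paired dataset.
#' @param model Model to test under (see [fit_pair_model()]).
#' @param B Number of bootstrap resamples, at least 99.
#' @param seed Optional integer seed (global RNG untouched when supplied).
#' @return A one-row test tibble with `method = "parametric_bootstrap"` and
#'   `den_df = NA`; the attribute `"n_failed"` counts resamples whose refit
#'   failed (they are excluded from the comparison).
#' @export
bootstrap_test <- function(data, model = "pair_species", B = 999, seed = NULL) {
  if (B < 99) {
    abort("`B` must be at least 99 for a meaningful bootstrap p-value.",
          class = "phypairs_domain_error")
  }
  model <- .model_canonical(model)
  canon <- .canon_from_df(data)

  observed_f <- function(cn) {
    if (model == "anova") {
      return(.ols_f_from_canon(cn))
    }
    core <- .fit_core(cn, model)
    if (!core$converged) abort("Fit failed.", class = "phypairs_fit_error")
    free <- core$free[!core$boundary]
    if (length(free) == 0) free <- "sigma2"
    .kr_core(cn, core$vc, free, core$coef[2])$f
  }

  run <- function() {
    f_obs <- observed_f(canon)
    null_fit <- .fit_core(canon, model, null = TRUE)
    if (!null_fit$converged) {
      abort("Null fit did not converge.", class = "phypairs_fit_error")
    }
    mu0 <- null_fit$coef[1]
    vc0 <- null_fit$vc
    n_failed <- 0L
    f_star <- numeric(B)
    for (bb in seq_len(B)) {
      ystar <- .sim_from_null(canon, mu0, vc0)
      cn <- .canon_replace_y(canon, ystar)
      f_star[bb] <- tryCatch(observed_f(cn), error = function(e) {
        n_failed <<- n_failed + 1L
        NA_real_
      })
    }
    ok <- !is.na(f_star)
    p_val <- (1 + sum(f_star[ok] >= f_obs)) / (sum(ok) + 1)
    list(f = f_obs, p = p_val, n_failed = n_failed)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  fit <- fit_pair_model(if (is.null(canon$df)) data else canon$df, model = model)
  out <- .test_row(fit$coefficients[["beta"]], res$f, NA_real_, res$p,
                   "parametric_bootstrap")
  attr(out, "n_failed") <- res$n_failed
  out
}

.ols_f_from_canon <- function(canon) {
  x <- unlist(lapply(seq_len(canon$p), function(b) rep(c(0, 1), canon$sizes[b, ])))
  y <- canon$y
  beta <- mean(y[x == 1]) - mean(y[x == 0])
  rss <- sum((y[x == 0] - mean(y[x == 0]))^2) + sum((y[x == 1] - mean(y[x == 1]))^2)
  s2 <- rss / (canon$N - 2)
  beta^2 / (s2 * (1 / sum(x == 0) + 1 / sum(x == 1)))
}

.sim_from_null <- function(canon, mu, vc) {
  alpha <- rnorm(canon$p, 0, sqrt(vc[["tau2"]]))
  gamma <- rnorm(2L * canon$p, 0, sqrt(vc[["omega2"]]))
  y <- rnorm(canon$N, 0, sqrt(vc[["sigma2"]])) + mu
  pos <- 0L
  for (b in seq_len(canon$p)) {
    r0 <- canon$sizes[b, 1]; r1 <- canon$sizes[b, 2]
    ix <- pos + seq_len(r0 + r1)
    y[ix] <- y[ix] + alpha[b] + rep(gamma[c(2L * b - 1L, 2L * b)], c(r0, r1))
    pos <- pos + r0 + r1
  }
  y
}

.canon_replace_y <- function(canon, y) {
  canon$y <- y
  if (canon$balanced) canon$Y <- matrix(y, nrow = 2L * canon$r, ncol = canon$p)
  canon$df <- NULL
  canon
}
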