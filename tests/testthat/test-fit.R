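test_that("constant data collapses to boundary estimates", {
  d <- one_pair_data(nat = rep(3, 4), inv = rep(3, 4))
  d2 <- dplyr::mutate(one_pair_data(nat = rep(3, 4), inv = rep(3, 4)),
                      pair = "p2", species = sub("p1", "p2", species))
  fit <- fit_pair_model(dplyr::bind_rows(d, d2), model = "pair_species")
  expect_equal(unname(fit$coefficients), c(3, 0))
  expect_equal(unname(fit$vc), c(0, 0, 0))
  expect_true(all(fit$boundary))
  expect_true(fit$converged)
})

test_that("moment estimators recover textbook degenerate patterns", {
  # no residual scatter: replicates identical within species, species vary
  d <- dplyr::bind_rows(
    one_pair_data(nat = rep(1, 3), inv = rep(2, 3)),
    one_pair_data(nat = rep(5, 3), inv = rep(3, 3)) |>
      dplyr::mutate(pair = "p2", species = sub("p1", "p2", species))
  )
  me <- moment_estimates(d)
  expect_equal(me$sigma2, 0)

  # fully constant data
  dc <- dplyr::bind_rows(
    one_pair_data(nat = rep(2, 3), inv = rep(2, 3)),
    one_pair_data(nat = rep(2, 3), inv = rep(2, 3)) |>
      dplyr::mutate(pair = "p2", species = sub("p1", "p2", species))
  )
  expect_equal(unlist(moment_estimates(dc)),
               c(tau2 = 0, omega2 = 0, sigma2 = 0))

  expect_error(moment_estimates(one_pair_data(nat = 1:2, inv = 1:3)),
               class = "phypairs_domain_error")
})

test_that("moment estimators are unbiased under the generating model", {
  truth <- c(tau2 = 1, omega2 = 0.5, sigma2 = 0.2)
  n_sim <- 600
  est <- matrix(NA_real_, n_sim, 3)
  for (i in seq_len(n_sim)) {
    d <- make_iid_data(p = 15, r = 4, tau2 = truth[1], omega2 = truth[2],
                       sigma2 = truth[3], seed = 5000 + i)
    est[i, ] <- unlist(moment_estimates(d))
  }
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, sd) / sqrt(n_sim)
  expect_true(all(abs(bias) < 4 * mc_se + 1e-3),
              info = paste("bias:", paste(signif(bias, 3), collapse = ", ")))
})

test_that("REML equals the ANOVA moment estimators on balanced interior fits", {
  for (seed in 1:20) {
    d <- make_iid_data(p = 10, r = 4, tau2 = 0.8, omega2 = 0.6, sigma2 = 0.4,
                       beta = 0.3, seed = seed)
    me <- unlist(moment_estimates(d))
    if (any(me <= 0)) next # boundary case: equivalence only claimed interior
    fit <- fit_pair_model(d, model = "pair_species")
    expect_equal(unname(fit$vc), unname(me), tolerance = 1e-6)

    # the general optimizer must agree with the closed form
    fit_opt <- fit_pair_model(d, model = "pair_species", method = "optim")
    expect_equal(unname(fit_opt$vc), unname(me), tolerance = 1e-6)
    expect_equal(fit_opt$loglik, fit$loglik, tolerance = 1e-9)
  }
})

test_that("REML log-likelihood at the optimum dominates the clipped moment estimates", {
  for (seed in c(1:8, 101:108)) {
    # small omega2 makes boundary solutions likely in the second batch
    omega2 <- if (seed > 100) 0.02 else 0.5
    d <- make_iid_data(p = 8, r = 3, tau2 = 0.4, omega2 = omega2,
                       sigma2 = 0.6, seed = seed)
    fit <- fit_pair_model(d, model = "pair_species")
    me <- unname(pmax(unlist(moment_estimates(d)), c(0, 0, 1e-8)))
    ll_me <- phypairs:::.reml_ll(phypairs:::.canon_from_df(d),
                                 c(tau2 = me[1], omega2 = me[2], sigma2 = me[3]))$ll
    expect_gte(fit$loglik + 1e-8, ll_me)
  }
})

test_that("REML matches lme4 on balanced and unbalanced data", {
  suppressMessages(requireNamespace("lme4"))
  d <- make_phylo_data(p = 12, r = 4, beta = 0.5, tau2 = 0.8, omega2 = 0.6,
                       sigma2 = 0.3, seed = 11)
  d_unb <- unvalidated(d[-c(3, 17, 44, 45, 80), ])

  for (dat in list(d, d_unb)) {
    fit <- fit_pair_model(dat, model = "pair_species")
    lf <- lme4::lmer(value ~ origin + (1 | pair) + (1 | species),
                     data = validate_pair_data(dat), REML = TRUE)
    vc_l <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$vc[["tau2"]], vc_l$vcov[vc_l$grp == "pair"], tolerance = 1e-4)
    expect_equal(fit$vc[["omega2"]], vc_l$vcov[vc_l$grp == "species"], tolerance = 1e-4)
    expect_equal(fit$vc[["sigma2"]], vc_l$vcov[vc_l$grp == "Residual"], tolerance = 1e-4)
    expect_equal(unname(fit$coefficients), unname(lme4::fixef(lf)), tolerance = 1e-5)
    expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-5)

    fit2 <- fit_pair_model(dat, model = "pair")
    lf2 <- lme4::lmer(value ~ origin + (1 | pair),
                      data = validate_pair_data(dat), REML = TRUE)
    vc_l2 <- as.data.frame(lme4::VarCorr(lf2))
    expect_equal(fit2$vc[["tau2"]], vc_l2$vcov[vc_l2$grp == "pair"], tolerance = 1e-4)
    expect_equal(fit2$vc[["sigma2"]], vc_l2$vcov[vc_l2$grp == "Residual"],
                 tolerance = 1e-4)
  }
})

test_that("GLS fixed effects reduce to group means in the OLS limit", {
  d <- make_iid_data(p = 6, r = 3, beta = 0.7, seed = 4)
  g <- gls_origin(d, tau2 = 0, omega2 = 0, sigma2 = 1)
  nat_mean <- mean(d$value[d$origin == 0])
  inv_mean <- mean(d$value[d$origin == 1])
  expect_equal(g$coefficients[["mu"]], nat_mean)
  expect_equal(g$coefficients[["beta"]], inv_mean - nat_mean)
})

test_that("on balanced designs the GLS origin effect is the mean within-pair contrast", {
  d <- make_iid_data(p = 8, r = 4, beta = 0.5, seed = 12)
  sp_means <- d |>
    dplyr::summarise(m = mean(value), .by = c(pair, origin)) |>
    tidyr::pivot_wider(names_from = origin, values_from = m)
  dbar <- mean(sp_means$`1` - sp_means$`0`)
  for (vc in list(c(0.1, 0.9, 0.3), c(2, 0.01, 1), c(0, 0, 1))) {
    g <- gls_origin(d, vc[1], vc[2], vc[3])
    expect_equal(g$coefficients[["beta"]], dbar, tolerance = 1e-10)
  }
})

test_that("single-origin data cannot be fit", {
  d <- one_pair_data(nat = rnorm(4), inv = rnorm(4))
  d$origin <- 0L
  expect_error(fit_pair_model(d), class = "phypairs_validation_error")
  expect_error(gls_origin(d, 0.1, 0.1, 0.1), class = "phypairs_validation_error")
})

test_that("a single replicate per species leaves Model 3 unidentified", {
  d <- make_iid_data(p = 8, r = 1, seed = 3)
  expect_error(fit_pair_model(d, model = "pair_species"),
               class = "phypairs_domain_error")
  expect_s3_class(fit_pair_model(d, model = "pair"), "pair_fit")
})

test_that("the GLS origin estimate is unbiased under the phylogenetic generator", {
  n_sim <- 400
  betas <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    d <- make_phylo_data(p = 30, r = 5, beta = 0.5, tau2 = 0.5, omega2 = 0.5,
                         sigma2 = 0.5, seed = 20000 + i)
    betas[i] <- fit_pair_model(d)$coefficients[["beta"]]
  }
  mc_se <- sd(betas) / sqrt(n_sim)
  expect_lt(abs(mean(betas) - 0.5), 4 * mc_se)
})

test_that("Model 2 overestimates the between-species correlation (pseudo-independence)", {
  n_sim <- 500
  theta_true <- cs_correlations(0.5, 0.5, 0.5)$theta
  theta_m2 <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    d <- make_iid_data(p = 15, r = 4, tau2 = 0.5, omega2 = 0.5, sigma2 = 0.5,
                       seed = 40000 + i)
    fit2 <- fit_pair_model(d, model = "pair")
    theta_m2[i] <- fit2$vc[["tau2"]] / (fit2$vc[["tau2"]] + fit2$vc[["sigma2"]])
  }
  # Model 2's single correlation parameter sits between theta and rho,
  # so it exceeds the true between-species-within-pair correlation on average
  expect_gt(mean(theta_m2), theta_true + 4 * sd(theta_m2) / sqrt(n_sim))
})

test_that("tidy and glance expose estimates in broom conventions", {
  d <- make_iid_data(p = 8, r = 3, beta = 0.4, seed = 21)
  fit <- fit_pair_model(d)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "origin"))
  expect_equal(td$estimate[2], fit$coefficients[["beta"]])
  tr <- tidy(fit, effects = "ran_pars")
  expect_equal(tr$estimate, unname(fit$vc))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  expect_true(gl$rho >= gl$theta)
  expect_match(fit_json(fit), "\"reml_loglik\"")
})
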