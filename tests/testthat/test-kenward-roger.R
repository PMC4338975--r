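test_that("Kenward-Roger equals the exact balanced F on interior Model 3 fits", {
  set.seed(314)
  n_checked <- 0
  for (i in 1:60) {
    p <- sample(6:30, 1)
    r <- sample(2:5, 1)
    beta <- sample(c(0, 0.5), 1)
    d <- make_iid_data(p = p, r = r, beta = beta, tau2 = 1, omega2 = 1,
                       sigma2 = 0.25, seed = 600 + i)
    fit <- fit_pair_model(d, model = "pair_species")
    if (any(fit$boundary)) next # exactness only claimed for interior fits
    n_checked <- n_checked + 1
    kt <- kr_test(fit)
    et <- exact_f_test(d)
    expect_lt(abs(kt$p_value - et$p_value), 1e-8)
    expect_equal(kt$den_df, p - 1, tolerance = 1e-6)
    expect_equal(kt$f_stat, et$f_stat, tolerance = 1e-8)
  }
  expect_gte(n_checked, 55) # interior solutions dominate in this regime
})

test_that("Kenward-Roger agrees with an independent implementation off balance", {
  d <- make_phylo_data(p = 14, r = 4, beta = 0.3, tau2 = 1.5, omega2 = 0.5,
                       sigma2 = 0.4, seed = 77)
  d_unb <- validate_pair_data(unvalidated(d[-c(2, 9, 30, 31, 55, 100), ]))

  fit3 <- fit_pair_model(d_unb, model = "pair_species")
  expect_false(any(fit3$boundary)) # interior fit: both implementations comparable
  kt3 <- kr_test(fit3)
  fit2 <- fit_pair_model(d_unb, model = "pair")
  kt2 <- kr_test(fit2)

  # the unbalanced KR df must differ from the balanced p - 1 bookkeeping
  expect_gt(kt3$den_df, 0)
  expect_true(is.finite(kt3$p_value))

  if (requireNamespace("pbkrtest", quietly = TRUE) &&
      requireNamespace("lme4", quietly = TRUE)) {
    lf3 <- lme4::lmer(value ~ origin + (1 | pair) + (1 | species),
                      data = d_unb, REML = TRUE)
    sm3 <- lme4::lmer(value ~ 1 + (1 | pair) + (1 | species),
                      data = d_unb, REML = TRUE)
    kr3 <- pbkrtest::KRmodcomp(lf3, sm3)$stats
    expect_equal(kt3$den_df, kr3$ddf, tolerance = 1e-5)
    expect_equal(kt3$p_value, kr3$p.value, tolerance = 1e-6)

    lf2 <- lme4::lmer(value ~ origin + (1 | pair), data = d_unb, REML = TRUE)
    sm2 <- lme4::lmer(value ~ 1 + (1 | pair), data = d_unb, REML = TRUE)
    kr2 <- pbkrtest::KRmodcomp(lf2, sm2)$stats
    expect_equal(kt2$den_df, kr2$ddf, tolerance = 1e-5)
    # both sides optimize numerically off balance; agreement is limited by
    # the optimizers, not the adjustment
    expect_equal(kt2$p_value, kr2$p.value, tolerance = 1e-5)
  }
})

test_that("KR denominator df is invariant to pair relabeling and affine response maps", {
  d <- make_iid_data(p = 9, r = 3, beta = 0.4, tau2 = 1, omega2 = 1,
                     sigma2 = 0.3, seed = 15)
  fit <- fit_pair_model(d)
  kt <- kr_test(fit)

  relabeled <- d
  perm <- setNames(sample(unique(d$pair)), unique(d$pair))
  relabeled$pair <- unname(perm[d$pair])
  relabeled$species <- paste0(relabeled$pair, sub("^p[0-9]+", "", d$species))
  kt_rel <- kr_test(fit_pair_model(unvalidated(relabeled)))
  expect_equal(kt_rel$den_df, kt$den_df, tolerance = 1e-9)
  expect_equal(kt_rel$p_value, kt$p_value, tolerance = 1e-9)

  affine <- dplyr::mutate(d, value = -2.5 * value + 7)
  kt_aff <- kr_test(fit_pair_model(unvalidated(affine)))
  expect_equal(kt_aff$den_df, kt$den_df, tolerance = 1e-8)
  expect_equal(kt_aff$p_value, kt$p_value, tolerance = 1e-8)
})

test_that("p-values are monotone in the size of the origin contrast", {
  base <- make_iid_data(p = 10, r = 3, beta = 0, tau2 = 0.5, omega2 = 0.5,
                        sigma2 = 0.5, seed = 13)
  shifts <- c(0, 0.4, 0.8, 1.6)
  p_kr <- p_exact <- p_ols <- numeric(length(shifts))
  for (k in seq_along(shifts)) {
    d <- dplyr::mutate(base, value = value + shifts[k] * (origin == 1))
    d <- unvalidated(d)
    p_kr[k] <- kr_test(fit_pair_model(d))$p_value
    p_exact[k] <- exact_f_test(d)$p_value
    p_ols[k] <- ols_f_test(d)$p_value
  }
  expect_gt(p_kr[1], 0.1) # the baseline leaves room to shrink
  expect_true(all(diff(p_kr) < 0))
  expect_true(all(diff(p_exact) < 0))
  expect_true(all(diff(p_ols) < 0))
})

test_that("boundary fits still yield valid, flagged KR tests", {
  found <- FALSE
  for (seed in 1:40) {
    d <- make_iid_data(p = 6, r = 2, tau2 = 0.3, omega2 = 0.005, sigma2 = 1,
                       seed = seed)
    fit <- fit_pair_model(d, model = "pair_species")
    if (!any(fit$boundary)) next
    found <- TRUE
    expect_warning(kt <- kr_test(fit), class = "phypairs_boundary_warning")
    expect_true(kt$boundary)
    expect_gte(kt$p_value, 0)
    expect_lte(kt$p_value, 1)
    expect_gt(kt$den_df, 0)
  }
  expect_true(found)
})

test_that("exact balanced F-test matches the paired t-test on species means", {
  for (seed in 1:10) {
    d <- make_phylo_data(p = sample(3:20, 1), r = sample(2:5, 1), beta = 0.3,
                         seed = 900 + seed)
    et <- exact_f_test(d)
    sp <- d |>
      dplyr::summarise(m = mean(value), .by = c(pair, origin)) |>
      tidyr::pivot_wider(names_from = origin, values_from = m)
    tt <- t.test(sp$`1`, sp$`0`, paired = TRUE)
    expect_equal(et$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(et$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(et$den_df, nrow(sp) - 1)
  }
})

test_that("exact F degenerates gracefully and keeps its df bookkeeping", {
  # no origin signal: species means identical within every pair
  d <- dplyr::bind_rows(
    one_pair_data(nat = c(1, 3), inv = c(3, 1)),
    one_pair_data(nat = c(0, 2), inv = c(2, 0)) |>
      dplyr::mutate(pair = "p2", species = sub("p1", "p2", species))
  )
  et <- exact_f_test(d)
  expect_equal(et$f_stat, 0)
  expect_equal(et$p_value, 1)
  expect_equal(et$den_df, 1) # p = 2 pairs

  expect_error(exact_f_test(one_pair_data(nat = 1:3, inv = 1:2)),
               class = "phypairs_domain_error")
})

test_that("the one-way ANOVA test matches the pooled two-sample t-test", {
  d <- make_iid_data(p = 30, r = 5, beta = 0.3, seed = 5)
  ot <- ols_f_test(d)
  expect_equal(ot$den_df, 298)
  tt <- t.test(value ~ origin, data = d, var.equal = TRUE)
  expect_equal(ot$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(ot$p_value, tt$p.value, tolerance = 1e-12)

  # identical origin-group means by construction: same replicate values
  # repeat in every species
  flat <- dplyr::mutate(d, value = rep(c(1, 2, 4, 2, 1), times = 60))
  expect_equal(ols_f_test(unvalidated(flat))$f_stat, 0)
  expect_equal(ols_f_test(unvalidated(flat))$p_value, 1)
})

test_that("an overwhelming origin effect is detected at extreme significance", {
  d <- make_iid_data(p = 30, r = 5, beta = 10, tau2 = 0.01, omega2 = 0.01,
                     sigma2 = 0.01, seed = 6)
  expect_lt(kr_test(fit_pair_model(d))$p_value, 1e-6)
})

test_that("parametric bootstrap is deterministic, valid and bounded below", {
  d <- make_iid_data(p = 8, r = 3, beta = 10, tau2 = 0.01, omega2 = 0.01,
                     sigma2 = 0.01, seed = 2)
  bt1 <- bootstrap_test(d, B = 199, seed = 10)
  bt2 <- bootstrap_test(d, B = 199, seed = 10)
  expect_identical(bt1$p_value, bt2$p_value)
  expect_equal(bt1$p_value, 1 / 200) # observed F beats every resample
  expect_true(is.na(bt1$den_df))
  expect_equal(attr(bt1, "n_failed"), 0L)

  expect_error(bootstrap_test(d, B = 50), class = "phypairs_domain_error")
})

test_that("bootstrap test is calibrated under the null", {
  n_outer <- 150
  rejections <- 0
  for (i in seq_len(n_outer)) {
    d <- make_iid_data(p = 8, r = 3, beta = 0, tau2 = 0.4, omega2 = 0.4,
                       sigma2 = 0.4, seed = 70000 + i)
    p <- bootstrap_test(d, B = 99, seed = 80000 + i)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_outer
  # 95% binomial band around 0.05 at n = 150, plus the mild conservatism of
  # the (1 + x)/(B + 1) convention
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.11)
  expect_gt(rejections, 0) # the test is not degenerate
})
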