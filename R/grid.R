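# -------------------------------------------------------------------------
# Type I error / power simulation study over a variance-component grid.
# -------------------------------------------------------------------------

#' Variance-component grid conditions
#'
#' Builds the full factorial of pair, species and residual variance values
#' crossed with the origin effect size(s). The default values reproduce the
#' 4 x 4 x 4 = 64-condition grid used throughout the package's simulation
#' study.
#'
#' @param values Variance-component levels used for each of `tau2`, `omega2`
#'   and `sigma2`.
#' @param beta Origin effect size(s): 0 for the null (Type I error), 0.5 for
#'   the alternative (power).
#' @return A tibble with columns `tau2`, `omega2`, `sigma2`, `beta`.
#' @export
grid_conditions <- function(values = c(0.1, 0.2, 0.5, 1.0), beta = 0) {
  tidyr::crossing(tau2 = values, omega2 = values, sigma2 = values, beta = beta)
}

# Deterministic per-dataset substream seed below 2^31, derived from the
# master seed, the condition (by value, not position) and the dataset index,
# so conditions are independent work units and results do not depend on the
# order in which they are evaluated.
.condition_key <- function(tau2, omega2, sigma2, beta) {
  m <- 2147483629
  k <- 0
  for (v in c(tau2, omega2, sigma2, beta)) {
    k <- (k * 1000003 + round(v * 1e6) %% m) %% m
  }
  k
}

.derive_seed <- function(master, key, index) {
  m <- 2147483629
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + as.numeric(key)) %% m
  s <- (s * 48271 + as.numeric(index)) %% m
  as.integer(s)
}

#' Run the Type I error / power simulation grid
#'
#' For every condition, simulates `n_datasets` paired datasets from the
#' phylogenetically explicit generator (fresh Yule tree and Brownian pair
#' effects per dataset; see [simulate_paired_data()]), analyzes each with
#' the requested models, and records how often the origin effect is declared
#' significant at level `alpha`. Model 1 uses the classical one-way ANOVA
#' F-test ([ols_f_test()]); Models 2 and 3 are fit by REML and tested with
#' the Kenward-Roger F ([kr_test()]). With `beta = 0` in the conditions the
#' rejection rate estimates the Type I error; with `beta != 0`, the power.
#'
#' Datasets whose fit fails are counted as non-rejections (conservative for
#' Type I error) and reported in `n_failed`. The whole grid is reproducible
#' from `seed`: every dataset draws from its own deterministic substream, so
#' results are identical regardless of the order in which conditions are
#' evaluated.
#'
#' @param conditions A tibble of conditions ([grid_conditions()]).
#' @param n_datasets Simulated datasets per condition.
#' @param models Subset of `c("anova", "pair", "pair_species")` (aliases
#'   `"M1"`, `"M2"`, `"M3"` accepted).
#' @param alpha Significance level for the rejection rule `p < alpha`.
#' @param n_pairs,n_replicates Design size per dataset.
#' @param phylogenetic Passed to the generator; `TRUE` reproduces the
#'   deliberately tree-structured (misspecified) pair effects.
#' @param mu Intercept of the generator.
#' @param seed Master seed (integer).
#' @return A `pair_grid` tibble with one row per condition x model:
#'   the condition columns, `model`, `n_datasets`, `n_reject`,
#'   `rejection_rate`, `mc_se` (binomial Monte-Carlo standard error),
#'   `n_boundary`, `n_failed`. Attributes record `alpha`, `seed` and the
#'   design size.
#' @examples
#' \donttest{
#' g <- run_grid(grid_conditions(values = c(0.1, 1.0)), n_datasets = 50, seed = 1)
#' summarize_grid(g)
#' }
#' @export
run_grid <- function(conditions, n_datasets = 300,
                     models = c("anova", "pair", "pair_species"),
                     alpha = 0.05, n_pairs = 30, n_replicates = 5,
                     phylogenetic = TRUE, mu = 0, seed = 1) {
  if (n_datasets < 1) abort("`n_datasets` must be >= 1.", class = "phypairs_domain_error")
  models <- unique(vapply(models, .model_canonical, character(1)))
  p <- n_pairs; r <- n_replicates
  n_cond <- nrow(conditions)

  res <- vector("list", n_cond)
  for (ci in seq_len(n_cond)) {
    cond <- conditions[ci, ]
    key <- .condition_key(cond$tau2, cond$omega2, cond$sigma2, cond$beta)
    reject <- setNames(integer(length(models)), models)
    boundary <- setNames(integer(length(models)), models)
    failed <- setNames(integer(length(models)), models)
    for (k in seq_len(n_datasets)) {
      Y <- withr::with_seed(
        .derive_seed(seed, key, k),
        .sim_components(p, r, cond$beta, cond$tau2, cond$omega2, cond$sigma2,
                        mu = mu, phylogenetic = phylogenetic)$Y
      )
      canon <- .canon_from_Y(Y)
      for (mdl in models) {
        p_val <- tryCatch({
          if (mdl == "anova") {
            ols_p <- .ols_p_from_canon(canon)
            ols_p
          } else {
            core <- .fit_core(canon, mdl)
            if (!core$converged) abort("fit failed", class = "phypairs_fit_error")
            free <- core$free[!core$boundary]
            if (length(free) == 0) free <- "sigma2"
            if (any(core$boundary)) boundary[[mdl]] <- boundary[[mdl]] + 1L
            .kr_core(canon, core$vc, free, core$coef[2])$p
          }
        }, error = function(e) {
          failed[[mdl]] <<- failed[[mdl]] + 1L
          NA_real_
        })
        if (!is.na(p_val) && p_val < alpha) reject[[mdl]] <- reject[[mdl]] + 1L
      }
    }
    res[[ci]] <- tibble::tibble(
      tau2 = cond$tau2, omega2 = cond$omega2, sigma2 = cond$sigma2,
      beta = cond$beta, model = models,
      n_datasets = n_datasets, n_reject = unname(reject),
      rejection_rate = unname(reject) / n_datasets,
      n_boundary = unname(boundary), n_failed = unname(failed)
    )
  }
  out <- dplyr::bind_rows(res)
  out$mc_se <- sqrt(out$rejection_rate * (1 - out$rejection_rate) / out$n_datasets)
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "n_pairs") <- n_pairs
  attr(out, "n_replicates") <- n_replicates
  attr(out, "phylogenetic") <- phylogenetic
  class(out) <- c("pair_grid", class(out))
  out
}

.ols_p_from_canon <- function(canon) {
  f <- .ols_f_from_canon(canon)
  pf(f, 1, canon$N - 2, lower.tail = FALSE)
}

#' Summarize a simulation grid
#'
#' Computes, for each model: the raw per-condition maximum rejection rate;
#' the marginal mean rejection rate at each level of each variance component
#' (the trend curves, averaging over the other two components); and the
#' maximum of those marginal means (the quantity a smoothed trend curve
#' peaks at, which is how the headline inflation figures of the simulation
#' study are read).
#'
#' @param result A `pair_grid` from [run_grid()].
#' @return A list of class `pair_grid_summary` with tibbles `maxima` (per
#'   model: `max_condition_rate`, `max_marginal_rate`, `mean_rate`) and
#'   `marginal` (per model x component x level: `mean_rate`).
#' @export
summarize_grid <- function(result) {
  if (nrow(result) == 0) abort("Empty grid result.", class = "phypairs_domain_error")
  long <- result |>
    tidyr::pivot_longer(c("tau2", "omega2", "sigma2"),
                        names_to = "component", values_to = "level")
  marginal <- long |>
    dplyr::summarise(
      mean_rate = mean(.data$rejection_rate),
      n_conditions = dplyr::n(),
      .by = c("model", "beta", "component", "level")
    ) |>
    dplyr::arrange(.data$model, .data$component, .data$level)
  maxima <- result |>
    dplyr::summarise(
      max_condition_rate = max(.data$rejection_rate),
      mean_rate = mean(.data$rejection_rate),
      .by = c("model", "beta")
    ) |>
    dplyr::left_join(
      marginal |>
        dplyr::summarise(max_marginal_rate = max(.data$mean_rate),
                         .by = c("model", "beta")),
      by = c("model", "beta")
    )
  structure(list(maxima = maxima, marginal = marginal),
            class = "pair_grid_summary")
}

#' @export
print.pair_grid_summary <- function(x, ...) {
  cat("Rejection-rate maxima by model:\n")
  print(x$maxima)
  cat("\nMarginal mean rejection rate by variance component:\n")
  print(x$marginal, n = Inf)
  invisible(x)
}

#' Plot grid rejection rates against each variance component
#'
#' One panel per model and variance component: per-condition rejection rates
#' (points) with the marginal mean trend, and the nominal level as a dashed
#' reference line.
#'
#' @param object A `pair_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_grid <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  labels <- c(anova = "Model 1", pair = "Model 2", pair_species = "Model 3")
  long <- object |>
    tidyr::pivot_longer(c("tau2", "omega2", "sigma2"),
                        names_to = "component", values_to = "level") |>
    dplyr::mutate(model = labels[.data$model])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$rejection_rate)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "grey40") +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed", colour = "grey60") +
    ggplot2::facet_grid(model ~ component) +
    ggplot2::labs(x = "variance component value", y = "rejection rate") +
    ggplot2::theme_minimal()
}

#' Analyze a dataset under all three competing models
#'
#' Produces the per-trait, per-model comparison table: the estimated origin
#' effect and its significance under Model 1 (one-way ANOVA), Model 2 (pair
#' random effect, Kenward-Roger test) and Model 3 (pair + species random
#' effects, Kenward-Roger test).
#'
#' @param data A paired dataset, or a named list of paired datasets (one per
#'   trait).
#' @return A tibble with columns `trait`, `model`, `estimate`, `f_stat`,
#'   `den_df`, `p_value`, `method`.
#' @examples
#' sim <- simulate_paired_data(n_pairs = 19, n_replicates = 5, beta = 0.5, seed = 3)
#' compare_models(sim$data)
#' @export
compare_models <- function(data) {
  datasets <- if (is.data.frame(data)) list(trait = data) else data
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("trait", seq_along(datasets))
  }
  purrr::imap(datasets, function(d, nm) {
    rows <- list(
      ols_f_test(d) |> dplyr::mutate(model = "anova"),
      kr_row(d, "pair"),
      kr_row(d, "pair_species")
    )
    dplyr::bind_rows(rows) |> dplyr::mutate(trait = nm)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("trait", "model", "estimate", "f_stat", "den_df",
                  "p_value", "method")
}

kr_row <- function(d, model) {
  fit <- fit_pair_model(d, model = model)
  suppressWarnings(kr_test(fit)) |> dplyr::mutate(model = model)
}
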