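#' Default Monte-Carlo settings for the experiment harness
#'
#' The experiment functions run thousands of replicates, so they default
#' to lighter Monte-Carlo settings than single-dataset analysis: 2000
#' draws, a 41-point bias grid, a 5-value `alpha1` grid, and nearest-PSD
#' projection of plug-in covariance matrices (a hard error on a rare
#' finite-sample PSD violation would abort a whole experiment).
#' Coverage estimates are unaffected in expectation; only the
#' Monte-Carlo noise of individual interval endpoints grows slightly.
#'
#' @param alpha,gamma nominal levels, see [focus_config()].
#' @param ... overrides passed to [focus_config()].
#' @return A `focus_config`.
#' @export
experiment_config <- function(alpha = 0.05, gamma = 0.2, ...) {
  args <- list(alpha = alpha, gamma = gamma,
               alpha1_grid = alpha * c(1, 3, 5, 7, 9) / 10,
               n_draws = 2000L, grid_size = 41L, psd_action = "project")
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(focus_config, args)
}

design_label <- function(d) {
  sprintf("lC=%g,lS=%g,tau=%g,tauC=%g", d$lambda_core, d$lambda_add,
          d$tau_bar, d$tau_bar_core)
}

#' Estimation error experiment: RMSE of Core, Full and Focused estimators
#'
#' For each design cell, draws the fixed-effects truth once (so the
#' direct effects `tau` are common to all replicates of the cell), then
#' generates `reps` independent summary datasets, fits the Core, Full
#' and Focused estimators, and reports the RMSE of each about `theta0`,
#' the Focused/Core RMSE ratio and the percentage RMSE reduction, with
#' Monte-Carlo standard errors.
#'
#' @param designs a list of [simulation_design()] objects.
#' @param reps replications per cell.
#' @param seed base seed; per-replicate seeds are derived by counter.
#' @param config a [focus_config()]; only the LIML controls are used.
#' @return A `data.frame`, one row per design cell.
#' @export
run_rmse_experiment <- function(designs, reps = 1000L, seed = 1L,
                                config = experiment_config()) {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  rows <- lapply(seq_along(designs), function(ci) {
    d <- designs[[ci]]
    truth <- design_truth(d, seed = derive_seed(seed, ci))
    err <- matrix(NA_real_, reps, 3L,
                  dimnames = list(NULL, c("core", "full", "focused")))
    sel_full <- logical(reps)
    for (r in seq_len(reps)) {
      dat <- generate_summary_data(truth, seed = derive_seed(seed, ci, r))
      sel <- focused_estimate(dat, config)
      err[r, ] <- c(sel$est_core$theta_hat, sel$est_full$theta_hat,
                    sel$theta_focused) - d$theta0
      sel_full[r] <- sel$selected == "full"
    }
    rmse <- sqrt(colMeans(err^2))
    # delta-method MC SE of an RMSE: sd(err^2) / (2 * rmse * sqrt(R))
    rmse_se <- apply(err^2, 2L, stats::sd) / (2 * rmse * sqrt(reps))
    data.frame(cell = design_label(d), lambda_core = d$lambda_core,
               lambda_add = d$lambda_add, tau_bar = d$tau_bar,
               tau_bar_core = d$tau_bar_core, reps = reps,
               b_true = truth$b_true,
               rmse_core = rmse[["core"]], rmse_full = rmse[["full"]],
               rmse_focused = rmse[["focused"]],
               se_rmse_core = rmse_se[["core"]],
               se_rmse_focused = rmse_se[["focused"]],
               prop_full_selected = mean(sel_full),
               rel_rmse_focused = rmse[["focused"]] / rmse[["core"]],
               pct_reduction = 100 * (1 - rmse[["focused"]] /
                                        rmse[["core"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coverage and length experiment for the interval constructions
#'
#' For each design cell and each requested method, reports the empirical
#' coverage of `theta0`, its Monte-Carlo standard error, the mean
#' interval length and the length relative to the mean Core-interval
#' length.  All methods within a replicate share the same fitted
#' selection object, and the Monte-Carlo interval seeds are derived per
#' replicate, so cross-method comparisons are paired.
#'
#' @param designs a list of [simulation_design()] objects.
#' @param methods subset of `c("core", "full", "naive", "1step",
#'   "2step", "focused")`.
#' @param alpha nominal non-coverage level.
#' @param gamma size distortion for the focused interval.
#' @param reps replications per cell.
#' @param seed base seed.
#' @param config a [focus_config()]; its `alpha1_2step`, `alpha1_grid`,
#'   `n_draws` and `grid_size` drive the interval constructions.
#' @return A `data.frame`, one row per design cell x method.
#' @export
run_coverage_experiment <- function(designs,
                                    methods = c("core", "focused"),
                                    alpha = 0.05, gamma = 0.2,
                                    reps = 500L, seed = 1L,
                                    config = experiment_config(
                                      alpha = alpha, gamma = gamma)) {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  methods <- match.arg(methods,
                       c("core", "full", "naive", "1step", "2step",
                         "focused"), several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(designs)) {
    d <- designs[[ci]]
    truth <- design_truth(d, seed = derive_seed(seed, ci))
    cover <- matrix(NA_real_, reps, length(methods),
                    dimnames = list(NULL, methods))
    len <- cover
    n_fallback <- 0L
    for (r in seq_len(reps)) {
      dat <- generate_summary_data(truth, seed = derive_seed(seed, ci, r))
      sel <- focused_estimate(dat, config)
      mc_seed <- derive_seed(seed, ci, r, 7L)
      for (m in methods) {
        iv <- switch(m,
          core = interval_standard(sel$est_core, alpha),
          full = interval_standard(sel$est_full, alpha),
          naive = interval_naive(sel, alpha),
          "1step" = interval_1step(sel, alpha, config$n_draws, mc_seed),
          "2step" = interval_2step(sel, alpha, config$alpha1_2step,
                                   config$n_draws, config$grid_size,
                                   mc_seed),
          focused = suppressWarnings(
            interval_focused(sel, alpha, gamma, config, mc_seed)))
        if (m == "focused" && !is.null(iv$meta$fallback))
          n_fallback <- n_fallback + 1L
        cover[r, m] <- (iv$lower <= d$theta0 && d$theta0 <= iv$upper)
        len[r, m] <- iv$upper - iv$lower
      }
    }
    core_len <- if ("core" %in% methods) mean(len[, "core"]) else NA_real_
    for (m in methods) {
      cv <- mean(cover[, m])
      rows[[length(rows) + 1L]] <- data.frame(
        cell = design_label(d), lambda_core = d$lambda_core,
        lambda_add = d$lambda_add, tau_bar = d$tau_bar,
        tau_bar_core = d$tau_bar_core, method = m, alpha = alpha,
        gamma = if (m == "focused") gamma else NA_real_, reps = reps,
        coverage = cv, se_coverage = sqrt(cv * (1 - cv) / reps),
        mean_length = mean(len[, m]),
        rel_length_core = mean(len[, m]) / core_len,
        n_fallback = if (m == "focused") n_fallback else 0L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
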