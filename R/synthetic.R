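#' Simulation design for two-sample summary data
#'
#' Describes a world of `p` uncorrelated variants, `n_core` of them
#' forming a trusted core set, with instrument strength calibrated by
#' concentration parameters and direct (pleiotropic) effects on the
#' outcome drawn uniformly on a local-to-zero scale.  Defaults are the
#' benchmark design used throughout the package's experiments: `n =
#' 1000`, `p = 110`, `n_core = 10`, `theta0 = 0.2`, association variances
#' `1/n`, concentration parameters 40.
#'
#' @param n per-study sample size (`n = n_X = n_Y`), which sets the
#'   association variances.
#' @param p total number of variants.
#' @param n_core size of the core set.
#' @param lambda_core,lambda_add concentration parameters (average
#'   instrument strength) of the core and additional sets.
#' @param tau_bar scale of direct effects on the additional set:
#'   `tau_j ~ U[0, tau_bar / sqrt(n p)]`.
#' @param tau_bar_core same for the core set (default 0: valid core).
#' @param theta0 true causal effect.
#' @param se2_x,se2_y per-variant association variances (default `1/n`).
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n = 1000L, p = 110L, n_core = 10L,
                              lambda_core = 40, lambda_add = 40,
                              tau_bar = 0, tau_bar_core = 0,
                              theta0 = 0.2, se2_x = 1 / n, se2_y = 1 / n) {
  if (n_core < 1L || n_core >= p)
    stopf("need 1 <= n_core < p, got n_core = %d, p = %d", n_core, p)
  if (lambda_core <= 0 || lambda_add <= 0 || se2_x <= 0 || se2_y <= 0)
    stopf("strength and variance parameters must be positive")
  if (tau_bar < 0 || tau_bar_core < 0) stopf("tau bars must be >= 0")
  structure(list(n = as.integer(n), p = as.integer(p),
                 n_core = as.integer(n_core), lambda_core = lambda_core,
                 lambda_add = lambda_add, tau_bar = tau_bar,
                 tau_bar_core = tau_bar_core, theta0 = theta0,
                 se2_x = se2_x, se2_y = se2_y),
            class = "simulation_design")
}

#' Fixed-effects simulation truth for a design
#'
#' Calibrates true exposure associations from the concentration
#' parameters -- equal within each set, \eqn{\beta_{Xj} =
#' \bar\beta_C/\sqrt{|S_0|}} with \eqn{\bar\beta_C =
#' \sqrt{\lambda_C |S_0| \sigma_X^2}} (and analogously for the additional
#' set) -- and draws the direct effects \eqn{\tau_j \sim U[0,
#' \bar\tau/\sqrt{np}]} once.  The `tau` draws are fixed effects: they
#' are held fixed across all replicates generated from the same truth
#' object.  Also records the population components and the population
#' bias \eqn{b = (\eta_C+\eta_S)^{-1}\sum_{j\in S}\Omega_j^{-1}
#' \beta_{Xj}\tau_j}.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed for the `tau` draws.
#' @return A `simulation_truth` list: `beta_x`, `tau`, `beta_y`, `se_x`,
#'   `se_y`, `core_mask`, `b_true`, `components` (population mode).
#' @export
design_truth <- function(design, seed = 1L) {
  p <- design$p; nc <- design$n_core
  core_mask <- c(rep(TRUE, nc), rep(FALSE, p - nc))
  se_x <- rep(sqrt(design$se2_x), p)
  se_y <- rep(sqrt(design$se2_y), p)
  bbar_c <- sqrt(design$lambda_core * nc * design$se2_x)
  bbar_s <- sqrt(design$lambda_add * (p - nc) * design$se2_x)
  beta_x <- ifelse(core_mask, bbar_c / sqrt(nc), bbar_s / sqrt(p - nc))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, 104729L))
  bound <- design$tau_bar / sqrt(design$n * p)
  bound_c <- design$tau_bar_core / sqrt(design$n * p)
  tau <- numeric(p)
  tau[!core_mask] <- if (bound > 0)
    stats::runif(p - nc, 0, bound) else 0
  tau[core_mask] <- if (bound_c > 0) stats::runif(nc, 0, bound_c) else 0
  beta_y <- beta_x * design$theta0 + tau
  comp <- population_components(beta_x, se_x, se_y, core_mask,
                                design$theta0)
  aidx <- which(!core_mask)
  b_true <- sum(beta_x[aidx] * tau[aidx] / comp$omega[aidx]) /
    (comp$eta_core + comp$eta_add)
  structure(list(design = design, beta_x = beta_x, tau = tau,
                 beta_y = beta_y, se_x = se_x, se_y = se_y,
                 core_mask = core_mask, b_true = b_true,
                 components = comp, seed = seed),
            class = "simulation_truth")
}

#' Generate one two-sample summary dataset from a truth object
#'
#' Draws \eqn{\hat\beta_{Xj} \sim N(\beta_{Xj}, \sigma_{Xj}^2)} and
#' \eqn{\hat\beta_{Yj} \sim N(\beta_{Yj}, \sigma_{Yj}^2)}, all `2p`
#' estimates mutually independent (the two-sample, uncorrelated-variants
#' contract).
#'
#' @param truth a `simulation_truth` from [design_truth()].
#' @param seed integer seed for this replicate.
#' @return A [summary_data] object.
#' @export
generate_summary_data <- function(truth, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  p <- length(truth$beta_x)
  bx <- stats::rnorm(p, truth$beta_x, truth$se_x)
  by <- stats::rnorm(p, truth$beta_y, truth$se_y)
  summary_data(beta_x_hat = bx, se_x = truth$se_x, beta_y_hat = by,
               se_y = truth$se_y, core = truth$core_mask)
}

#' Concentration parameter of an instrument subset
#'
#' Average instrument strength \eqn{\sum_j \hat\beta_{Xj}^2 / (|subset|
#' \sigma_{Xj}^2)}.  The naive version is biased upward by one unit in
#' expectation; `corrected = TRUE` subtracts \eqn{\sigma_{Xj}^2} from
#' each squared association.
#'
#' @param data a [summary_data] object.
#' @param subset integer row indices; `NULL` for all variants.
#' @param corrected use the de-noised squared associations.
#' @return scalar.
#' @export
concentration_parameter <- function(data, subset = NULL,
                                    corrected = FALSE) {
  if (is.null(subset)) subset <- seq_len(nrow(data))
  bx2 <- data$beta_x_hat[subset]^2
  if (corrected) bx2 <- bx2 - data$se_x[subset]^2
  sum(bx2 / data$se_x[subset]^2) / length(subset)
}
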