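#' LIML profile criterion for summary data
#'
#' The limited information maximum likelihood criterion
#' \deqn{Q(\theta) = \sum_{j \in \mathrm{subset}}
#'   \frac{(\hat\beta_{Yj} - \hat\beta_{Xj}\theta)^2}
#'        {\sigma_{Yj}^2 + \sigma_{Xj}^2\theta^2},}
#' whose minimizer over \eqn{\theta} is the LIML estimate on the given
#' instrument subset.
#'
#' @param theta scalar evaluation point.
#' @param data a [summary_data] object.
#' @param subset integer vector of row indices; `NULL` means all variants.
#' @return non-negative scalar criterion value.
#' @export
liml_objective <- function(theta, data, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(data))
  if (length(subset) == 0L) stopf("subset must be non-empty")
  liml_objective_fast(theta, data$beta_x_hat[subset], data$se_x[subset],
                      data$beta_y_hat[subset], data$se_y[subset])
}

# scalar theta, raw vectors; hot path shared with fit loops
liml_objective_fast <- function(theta, bx, sx, by, sy) {
  sum((by - bx * theta)^2 / (sy^2 + sx^2 * theta^2))
}

new_causal_estimate <- function(theta_hat, variance, subset_label,
                                objective_value, search_meta) {
  structure(list(theta_hat = theta_hat, variance = variance,
                 subset_label = subset_label,
                 objective_value = objective_value,
                 search_meta = search_meta),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("causal_estimate [%s]: theta_hat = %.6g", x$subset_label,
              x$theta_hat))
  if (is.finite(x$variance))
    cat(sprintf("  (se = %.6g)", sqrt(x$variance)))
  cat(sprintf("\n  objective = %.6g\n", x$objective_value))
  invisible(x)
}

#' LIML point estimation on an instrument subset
#'
#' Minimizes [liml_objective()] by a two-stage search: a coarse grid over
#' the bracket locates the basin (guarding against the criterion's
#' possible multimodality in \eqn{\theta}), then bounded scalar
#' minimization refines within the best grid cell.  Ties between equally
#' good grid minima resolve to the smaller \eqn{|\theta|} for
#' reproducibility.
#'
#' @param data a [summary_data] object.
#' @param subset integer row indices; `NULL` for all variants.
#' @param bracket length-2 numeric search interval.  Summary-data effect
#'   sizes are standardized, so the default `c(-10, 10)` is generous.
#' @param tol convergence tolerance passed to [stats::optimize()].
#' @param grid_points number of coarse grid points.
#' @param subset_label label stored on the returned estimate.
#' @return A `causal_estimate` (variance slot `NA`; see
#'   [variance_estimate()]).
#' @export
fit_liml <- function(data, subset = NULL, bracket = c(-10, 10), tol = 1e-8,
                     grid_points = 201L, subset_label = "full") {
  if (is.null(subset)) subset <- seq_len(nrow(data))
  if (length(subset) == 0L) stopf("subset must be non-empty")
  if (length(bracket) != 2L || any(!is.finite(bracket)) ||
      bracket[1] >= bracket[2])
    stopf("bracket must be finite with lower < upper")
  bx <- data$beta_x_hat[subset]; sx <- data$se_x[subset]
  by <- data$beta_y_hat[subset]; sy <- data$se_y[subset]
  if (all(bx == 0)) stopf("irrelevant instruments: all beta_x_hat zero in subset")
  fit <- fit_liml_fast(bx, sx, by, sy, bracket, tol, grid_points)
  # optimize() cannot land exactly on an endpoint; use a margin on the
  # bracket scale to detect a minimizer pinned at the boundary
  if (min(abs(fit$theta - bracket)) <= max(tol, 1e-4 * diff(bracket)))
    stopf("bracket too small: minimizer %.6g within tol of an endpoint",
          fit$theta)
  new_causal_estimate(fit$theta, NA_real_, subset_label, fit$objective,
                      list(bracket = bracket, tol = tol,
                           grid_points = grid_points))
}

fit_liml_fast <- function(bx, sx, by, sy, bracket = c(-10, 10),
                          tol = 1e-8, grid_points = 201L) {
  grid <- seq(bracket[1], bracket[2], length.out = grid_points)
  vals <- vapply(grid, liml_objective_fast, 0, bx = bx, sx = sx,
                 by = by, sy = sy)
  near <- which(vals <= min(vals) * (1 + 1e-12) + 1e-300)
  i <- near[which.min(abs(grid[near]))]
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_points, i + 1L)]
  opt <- stats::optimize(liml_objective_fast, c(lo, hi), bx = bx, sx = sx,
                         by = by, sy = sy, tol = tol)
  list(theta = opt$minimum, objective = opt$objective)
}

#' Plug-in asymptotic variance of the Core or Full LIML estimator
#'
#' Computes \eqn{\hat\Delta_C = \hat\eta_C^{-2}(\hat\eta_C+\hat\zeta_C)}
#' or \eqn{\hat\Delta_F = (\hat\eta_C+\hat\eta_S)^{-2}
#' (\hat\eta_C+\hat\eta_S+\hat\zeta_C+\hat\zeta_S)}.  The weights
#' \eqn{\hat\Omega_j} are evaluated at the core estimate
#' \eqn{\hat\theta_C} for both variances.
#'
#' @param data a [summary_data] object.
#' @param theta_plug the core LIML estimate \eqn{\hat\theta_C}.
#' @param subset_kind `"core"` or `"full"`.
#' @return positive scalar variance.
#' @export
variance_estimate <- function(data, theta_plug,
                              subset_kind = c("core", "full")) {
  subset_kind <- match.arg(subset_kind)
  comp <- plug_in_components(data, theta_plug)
  variance_from_components(comp, subset_kind)
}

variance_from_components <- function(comp, subset_kind) {
  if (subset_kind == "core") {
    comp$eta_core^-2 * (comp$eta_core + comp$zeta_core)
  } else {
    tot <- comp$eta_core + comp$eta_add
    if (tot <= 0) stopf("instruments too weak: eta_core + eta_add <= 0")
    tot^-2 * (tot + comp$zeta_core + comp$zeta_add)
  }
}
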