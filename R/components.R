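#' Per-variant variance weights
#'
#' Computes the per-variant weight \eqn{\Omega_j = \sigma_{Yj}^2 + \theta^2
#' \sigma_{Xj}^2} that standardizes the LIML criterion and all asymptotic
#' variance components at an evaluation point \eqn{\theta}.
#'
#' @param theta scalar evaluation point.
#' @param se_x,se_y positive standard-error vectors of equal length.
#' @return positive numeric vector of the same length.
#' @export
compute_omega <- function(theta, se_x, se_y) {
  if (length(theta) != 1L || !is.finite(theta)) stopf("'theta' must be a finite scalar")
  if (length(se_x) != length(se_y)) stopf("se vectors must have equal length")
  if (any(!is.finite(se_x)) || any(!is.finite(se_y)) ||
      any(se_x <= 0) || any(se_y <= 0))
    stopf("standard errors must be finite and strictly positive")
  se_y^2 + theta^2 * se_x^2
}

new_component_set <- function(theta_eval, mode, omega, eta_core, eta_add,
                              zeta_core, zeta_add, xi_add) {
  structure(list(theta_eval = theta_eval, mode = mode, omega = omega,
                 eta_core = eta_core, eta_add = eta_add,
                 zeta_core = zeta_core, zeta_add = zeta_add,
                 xi_add = xi_add),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf(paste0("component_set (%s mode, theta = %.6g)\n",
                     "  eta_core = %.6g  eta_add = %.6g\n",
                     "  zeta_core = %.6g  zeta_add = %.6g  xi_add = %.6g\n"),
              x$mode, x$theta_eval, x$eta_core, x$eta_add,
              x$zeta_core, x$zeta_add, x$xi_add))
  invisible(x)
}

#' Plug-in asymptotic variance components
#'
#' Computes the estimated components \eqn{\hat\eta_C, \hat\eta_S,
#' \hat\zeta_C, \hat\zeta_S, \hat\xi_S} from observed summary data at an
#' evaluation point `theta` (in practice the core LIML estimate).  The
#' \eqn{\hat\eta} terms use the de-noised squared association
#' \eqn{\hat\beta_{Xj}^2 - \sigma_{Xj}^2}, which makes them asymptotically
#' unbiased for the population values under many weak instruments;
#' individual terms may therefore be negative, and only the core total is
#' guarded.  Empty additional sets yield zero sums.
#'
#' @param data a [summary_data] object.
#' @param theta scalar evaluation point for \eqn{\hat\Omega_j}.
#' @return A `component_set` with `mode = "plug-in"`.
#' @export
plug_in_components <- function(data, theta) {
  omega <- compute_omega(theta, data$se_x, data$se_y)
  cidx <- which(data$core)
  aidx <- which(!data$core)
  bx2c <- data$beta_x_hat[cidx]^2 - data$se_x[cidx]^2
  bx2a <- data$beta_x_hat[aidx]^2 - data$se_x[aidx]^2
  eta_core <- sum(bx2c / omega[cidx])
  eta_add <- sum(bx2a / omega[aidx])
  zeta_core <- sum(data$se_x[cidx]^2 * data$se_y[cidx]^2 / omega[cidx]^2)
  zeta_add <- sum(data$se_x[aidx]^2 * data$se_y[aidx]^2 / omega[aidx]^2)
  xi_add <- 2 * theta^2 * sum(data$se_x[aidx]^4 / omega[aidx]^2)
  if (eta_core <= 0)
    stopf("core instruments too weak: plug-in eta_core = %.4g <= 0", eta_core)
  new_component_set(theta, "plug-in", omega, eta_core, eta_add,
                    zeta_core, zeta_add, xi_add)
}

#' Population variance components
#'
#' Computes the population components \eqn{\eta_C, \eta_S, \zeta_C,
#' \zeta_S, \xi_S} from the true variant-exposure associations, for use in
#' simulation truth objects and oracle checks.  Unlike
#' [plug_in_components()] the \eqn{\eta} terms use \eqn{\beta_{Xj}^2} with
#' no measurement-error correction.
#'
#' @param beta_x true exposure association vector.
#' @param se_x,se_y positive standard-error vectors.
#' @param core_mask logical core-membership vector.
#' @param theta0 true causal effect (evaluation point for \eqn{\Omega_j}).
#' @return A `component_set` with `mode = "population"`.
#' @export
population_components <- function(beta_x, se_x, se_y, core_mask, theta0) {
  p <- length(beta_x)
  if (length(se_x) != p || length(se_y) != p || length(core_mask) != p)
    stopf("all vectors must have length %d", p)
  omega <- compute_omega(theta0, se_x, se_y)
  cidx <- which(as.logical(core_mask))
  aidx <- which(!as.logical(core_mask))
  eta_core <- sum(beta_x[cidx]^2 / omega[cidx])
  eta_add <- sum(beta_x[aidx]^2 / omega[aidx])
  zeta_core <- sum(se_x[cidx]^2 * se_y[cidx]^2 / omega[cidx]^2)
  zeta_add <- sum(se_x[aidx]^2 * se_y[aidx]^2 / omega[aidx]^2)
  xi_add <- 2 * theta0^2 * sum(se_x[aidx]^4 / omega[aidx]^2)
  new_component_set(theta0, "population", omega, eta_core, eta_add,
                    zeta_core, zeta_add, xi_add)
}

#' Joint asymptotic covariance of the estimator triple
#'
#' Assembles the symmetric 3x3 covariance matrix of the limiting triple
#' \eqn{K = (K_F, K_C, K_b)} -- the full-estimator error, core-estimator
#' error and bias-estimator error -- from a set of variance components.
#' The entries are
#' \deqn{\Delta_F = (\eta_C+\eta_S)^{-2}(\eta_C+\eta_S+\zeta_C+\zeta_S),}
#' \deqn{\Delta_C = \eta_C^{-2}(\eta_C+\zeta_C),}
#' \deqn{\Delta_B = (\eta_C+\eta_S)^{-2}[\eta_S+\zeta_S+\xi_S+
#'   \eta_C^{-2}\eta_S^2(\eta_C+\zeta_C)],}
#' \deqn{\Delta_E = \eta_C^{-1}(\eta_C+\eta_S)^{-1}(\eta_C+\zeta_C),}
#' \deqn{\Delta_A = -\Delta_E \eta_C^{-1}\eta_S,}
#' \deqn{\Delta_D = \eta_C^{-1}(\eta_C+\eta_S)^{-2}\eta_C(\eta_S+\zeta_S)
#'   - \Delta_E(\eta_C+\eta_S)^{-1}\eta_S.}
#'
#' The population matrix is positive semidefinite by construction; the
#' plug-in matrix carries no finite-sample guarantee, so an eigenvalue
#' check is applied.  With `psd_action = "error"` (default) a violation
#' beyond `tol` raises an error reporting the offending eigenvalues; with
#' `"project"` the matrix is replaced by its nearest PSD projection
#' (negative eigenvalues clipped to zero) and flagged via the `projected`
#' attribute.
#'
#' @param components a `component_set`.
#' @param tol relative eigenvalue tolerance: smallest eigenvalue must be
#'   `>= -tol * largest`.
#' @param psd_action `"error"` or `"project"` on a PSD violation.
#' @return An object of class `delta_matrix`: list with the six scalar
#'   entries, the assembled matrix `mat`, and a `degenerate` flag (set when
#'   the additional set is empty so `delta_B = 0`).
#' @export
delta_matrix <- function(components, tol = 1e-8,
                         psd_action = c("error", "project")) {
  psd_action <- match.arg(psd_action)
  eta_c <- components$eta_core
  eta_s <- components$eta_add
  zeta_c <- components$zeta_core
  zeta_s <- components$zeta_add
  xi_s <- components$xi_add
  if (eta_c <= 0) stopf("eta_core must be positive, got %.4g", eta_c)
  if (eta_c + eta_s <= 0) stopf("eta_core + eta_add must be positive")
  d_f <- (eta_c + eta_s)^-2 * (eta_c + eta_s + zeta_c + zeta_s)
  d_c <- eta_c^-2 * (eta_c + zeta_c)
  d_b <- (eta_c + eta_s)^-2 *
    (eta_s + zeta_s + xi_s + eta_c^-2 * eta_s^2 * (eta_c + zeta_c))
  d_e <- eta_c^-1 * (eta_c + eta_s)^-1 * (eta_c + zeta_c)
  d_a <- -d_e * eta_c^-1 * eta_s
  # Delta_D kept token-for-token as derived (eta_C^-1 ... eta_C factor
  # deliberately not cancelled).
  d_d <- eta_c^-1 * (eta_c + eta_s)^-2 * eta_c * (eta_s + zeta_s) -
    d_e * (eta_c + eta_s)^-1 * eta_s
  mat <- matrix(c(d_f, d_e, d_d,
                  d_e, d_c, d_a,
                  d_d, d_a, d_b), 3L, 3L, byrow = TRUE,
                dimnames = list(c("K_F", "K_C", "K_b"),
                                c("K_F", "K_C", "K_b")))
  degenerate <- (eta_s == 0 && zeta_s == 0 && xi_s == 0)
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  projected <- FALSE
  if (min(ev) < -tol * max(abs(ev))) {
    if (psd_action == "error") {
      stopf(paste0("delta matrix is not positive semidefinite within ",
                   "tolerance: eigenvalues (%s); consider psd_action = ",
                   "'project'"), paste(signif(ev, 4), collapse = ", "))
    }
    ed <- eigen(mat, symmetric = TRUE)
    mat <- ed$vectors %*% diag(pmax(ed$values, 0)) %*% t(ed$vectors)
    mat <- (mat + t(mat)) / 2
    dimnames(mat) <- list(c("K_F", "K_C", "K_b"), c("K_F", "K_C", "K_b"))
    d_f <- mat[1, 1]; d_c <- mat[2, 2]; d_b <- mat[3, 3]
    d_e <- mat[1, 2]; d_d <- mat[1, 3]; d_a <- mat[2, 3]
    projected <- TRUE
  }
  structure(list(delta_F = d_f, delta_C = d_c, delta_B = d_b,
                 delta_E = d_e, delta_A = d_a, delta_D = d_d,
                 mat = mat, degenerate = degenerate,
                 projected = projected),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat("delta_matrix (covariance of K = (K_F, K_C, K_b))\n")
  print(signif(x$mat, 6))
  if (x$degenerate) cat("  [degenerate: additional set empty]\n")
  if (x$projected) cat("  [projected to nearest PSD]\n")
  invisible(x)
}
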