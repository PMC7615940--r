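#' Configuration for estimation, selection and interval construction
#'
#' Collects every tunable used by [focused_estimate()] and the interval
#' constructors.  Defaults: 95% nominal coverage, size distortion
#' `gamma = 0.2`, 5000 Monte-Carlo draws, a 101-point bias grid, and an
#' `alpha1` grid of nine equal steps `alpha * (1:9)/10`.
#'
#' @param alpha nominal non-coverage level, in (0, 1).
#' @param gamma maximum allowable size distortion for the focused
#'   interval, in (0, 1 - alpha).
#' @param alpha1_grid candidate splits `alpha1` (with `alpha2 = alpha -
#'   alpha1`) searched by the focused interval.
#' @param alpha1_2step the fixed split used by the 2-step interval.
#' @param n_draws Monte-Carlo draws for the limiting distribution
#'   (minimum 1000).
#' @param grid_size number of bias grid points spanning the region `phi`.
#' @param bracket,liml_tol,grid_points LIML search controls, see
#'   [fit_liml()].
#' @param k number of k-means clusters for candidate subsets.
#' @param psd_action,psd_tol policy for plug-in covariance matrices that
#'   fail the positive-semidefiniteness check, see [delta_matrix()].
#' @param fallback_2step if `TRUE` (default) an infeasible focused
#'   interval falls back to the 2-step construction with a warning.
#' @return A named list of class `focus_config`.
#' @export
focus_config <- function(alpha = 0.05, gamma = 0.2,
                         alpha1_grid = alpha * (1:9) / 10,
                         alpha1_2step = alpha / 2,
                         n_draws = 5000L, grid_size = 101L,
                         bracket = c(-10, 10), liml_tol = 1e-8,
                         grid_points = 201L, k = 3L,
                         psd_action = "error", psd_tol = 1e-8,
                         fallback_2step = TRUE) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  if (gamma <= 0 || gamma >= 1 - alpha)
    stopf("gamma must be in (0, 1 - alpha)")
  if (n_draws < 1000L) stopf("n_draws must be >= 1000")
  if (any(alpha1_grid <= 0) || any(alpha1_grid >= alpha))
    stopf("alpha1_grid values must lie strictly inside (0, alpha)")
  structure(list(alpha = alpha, gamma = gamma, alpha1_grid = alpha1_grid,
                 alpha1_2step = alpha1_2step, n_draws = as.integer(n_draws),
                 grid_size = as.integer(grid_size), bracket = bracket,
                 liml_tol = liml_tol, grid_points = as.integer(grid_points),
                 k = as.integer(k), psd_action = psd_action,
                 psd_tol = psd_tol, fallback_2step = fallback_2step),
            class = "focus_config")
}

new_confidence_interval <- function(lower, upper, method, alpha,
                                    alpha1 = NA_real_, alpha2 = NA_real_,
                                    gamma = NA_real_, b_star = NA_real_,
                                    n_draws = NA_integer_,
                                    seed = NA_integer_, meta = list()) {
  structure(list(lower = lower, upper = upper, method = method,
                 alpha = alpha, alpha1 = alpha1, alpha2 = alpha2,
                 gamma = gamma, b_star = b_star, n_draws = n_draws,
                 seed = seed, meta = meta),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("%s %.1f%% CI: [%.6g, %.6g]", x$method,
              100 * (1 - x$alpha), x$lower, x$upper))
  if (!is.na(x$gamma)) cat(sprintf("  (gamma = %g, b* = %.4g)",
                                   x$gamma, x$b_star))
  cat("\n")
  invisible(x)
}

interval_width <- function(ci) ci$upper - ci$lower

# --- Monte-Carlo machinery ------------------------------------------------

draw_k_sample <- function(delta, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ed <- eigen(delta$mat, symmetric = TRUE)
  lam <- ed$values
  if (min(lam) < -1e-8 * max(abs(lam), 1e-300))
    stopf("delta matrix not PSD when drawing K; eigenvalues (%s)",
          paste(signif(lam, 4), collapse = ", "))
  lam <- pmax(lam, 0)
  z <- matrix(stats::rnorm(3L * n_draws), n_draws, 3L)
  k <- z %*% (t(ed$vectors) * sqrt(lam))
  colnames(k) <- c("K_F", "K_C", "K_b")
  k
}

# Lambda(b) for one bias value given a shared K sample.
# W(b) = max((b + K_b)^2 - Delta_B, 0) + Delta_F - Delta_C;
# Lambda = (b + K_F) on {W <= 0}, K_C otherwise.  The selection event
# simplifies to |b + K_b| <= sqrt(Delta_B + Delta_C - Delta_F) when
# Delta_C >= Delta_F and is empty otherwise.
lambda_given_k <- function(b, k, delta) {
  gap <- delta$delta_C - delta$delta_F
  out <- k[, 2L]
  if (gap >= 0) {
    sel <- (b + k[, 3L])^2 <= delta$delta_B + gap
    out[sel] <- b + k[sel, 1L]
  }
  out
}

# sorted Lambda draws for every value of a bias grid; hot path shared by
# the 2-step and focused constructions
sorted_lambda_grid <- function(grid, k, delta) {
  kf <- k[, 1L]; kc <- k[, 2L]; kb <- k[, 3L]
  gap <- delta$delta_C - delta$delta_F
  thr <- if (gap >= 0) sqrt(delta$delta_B + gap) else -1
  lapply(grid, function(b) {
    lam <- kc
    if (thr >= 0) {
      sel <- abs(b + kb) <= thr
      lam[sel] <- b + kf[sel]
    }
    sort.int(lam, method = "quick")
  })
}

#' Simulate the limiting distribution of the focused estimator
#'
#' Draws the trivariate normal \eqn{K = (K_F, K_C, K_b) \sim N(0, \Delta)}
#' and assembles \eqn{\Lambda(b') = I\{W(b') \le 0\}(b' + K_F) + (1 -
#' I\{W(b') \le 0\})K_C}, with \eqn{W(b') = \max((b'+K_b)^2-\Delta_B, 0) +
#' \Delta_F - \Delta_C}, at an assumed bias value `b_prime`.
#'
#' @param b_prime scalar bias value.
#' @param delta a [delta_matrix()].
#' @param n_draws number of Monte-Carlo draws (minimum 1000).
#' @param seed integer seed.
#' @return A `lambda_draws` object: `draws`, the underlying `k_draws`
#'   matrix, per-draw `w_values`, `b_prime`, `n_draws`, `seed`.
#' @export
simulate_lambda <- function(b_prime, delta, n_draws = 5000L, seed = NULL) {
  if (n_draws < 1000L) stopf("n_draws must be >= 1000")
  k <- draw_k_sample(delta, n_draws, seed)
  w <- pmax((b_prime + k[, 3L])^2 - delta$delta_B, 0) +
    delta$delta_F - delta$delta_C
  draws <- ifelse(w <= 0, b_prime + k[, 1L], k[, 2L])
  structure(list(b_prime = b_prime, draws = draws, k_draws = k,
                 w_values = w, n_draws = n_draws,
                 seed = seed %||% NA_integer_),
            class = "lambda_draws")
}

#' Shortest interval containing a given mass of a Monte-Carlo sample
#'
#' Finds the shortest contiguous window of the sorted sample containing at
#' least `ceiling(level * n)` draws; ties resolve to the smallest left
#' endpoint.  This highest-density convention (rather than equal tails) is
#' used uniformly for the 1-step, 2-step and focused constructions so
#' their lengths are comparable.
#'
#' @param draws numeric sample.
#' @param level required mass fraction, in (0, 1].
#' @return numeric `c(lower, upper)`.
#' @export
shortest_mass_interval <- function(draws, level) {
  n <- length(draws)
  m <- ceiling(level * n)
  if (m < 1L || m > n) stopf("level %g infeasible for %d draws", level, n)
  if (n * level < 30) stopf("sample too small: n * level must be >= 30")
  s <- sort(draws)
  if (m == n) return(c(s[1L], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1L)]
  i <- which.min(widths)  # first minimum = smallest left endpoint
  c(s[i], s[i + m - 1L])
}

# as shortest_mass_interval but on pre-sorted draws, no guards (hot path)
shortest_window_sorted <- function(s, m) {
  n <- length(s)
  if (m >= n) return(c(s[1L], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1L)]
  i <- which.min(widths)
  c(s[i], s[i + m - 1L])
}

#' Normal confidence region for the asymptotic bias
#'
#' The (1 - alpha1) interval \eqn{\hat b \pm z_{1-\alpha_1/2}
#' \sqrt{\hat\Delta_B}} for the asymptotic bias, discretized to
#' `grid_size` equally spaced points including both endpoints.  With
#' `delta_B_hat = 0` the region degenerates to the single point
#' \eqn{\hat b}.
#'
#' @param bias a `bias_estimate`.
#' @param alpha1 level of the region.
#' @param grid_size number of grid points.
#' @return A `phi_region`: `lower`, `upper`, `grid`, `alpha1`.
#' @export
phi_region <- function(bias, alpha1, grid_size = 101L) {
  if (alpha1 <= 0 || alpha1 >= 1) stopf("alpha1 must be in (0,1)")
  half <- stats::qnorm(1 - alpha1 / 2) * sqrt(bias$delta_B_hat)
  lower <- bias$b_hat - half
  upper <- bias$b_hat + half
  grid <- if (half == 0) bias$b_hat else
    seq(lower, upper, length.out = grid_size)
  structure(list(lower = lower, upper = upper, grid = grid,
                 alpha1 = alpha1), class = "phi_region")
}

# --- Interval constructions ----------------------------------------------

#' Standard (Wald-type) confidence interval for a single LIML fit
#'
#' \eqn{\hat\theta \pm z_{1-\alpha/2}\sqrt{\hat\Delta}} using the
#' estimate's plug-in variance.
#'
#' @param estimate a `causal_estimate` with its variance slot filled.
#' @param alpha nominal non-coverage level.
#' @return A `confidence_interval` with method `"core"` or `"full"`.
#' @export
interval_standard <- function(estimate, alpha = 0.05) {
  if (!is.finite(estimate$variance) || estimate$variance <= 0)
    stopf("estimate must carry a positive variance")
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(estimate$variance)
  new_confidence_interval(estimate$theta_hat - half,
                          estimate$theta_hat + half,
                          method = estimate$subset_label, alpha = alpha)
}

#' Naive post-selection interval
#'
#' The standard interval of whichever estimator was selected, ignoring
#' the sampling uncertainty in model selection.  Provided as a baseline:
#' its coverage can fall arbitrarily far below nominal.
#'
#' @param selection a `selection_result`.
#' @param alpha nominal non-coverage level.
#' @return A `confidence_interval` with method `"naive"`.
#' @export
interval_naive <- function(selection, alpha = 0.05) {
  est <- if (selection$selected == "core") selection$est_core else
    selection$est_full
  ci <- interval_standard(est, alpha)
  ci$method <- "naive"
  ci$meta <- list(selected = selection$selected)
  ci
}

#' 1-step post-selection interval
#'
#' Simulates the limiting law \eqn{\Lambda(\hat b)} at the estimated bias,
#' takes the shortest (1 - alpha) mass interval \eqn{[a_l, a_u]}, and
#' returns \eqn{[\hat\theta - a_u, \hat\theta - a_l]}.  Accurate when
#' \eqn{\hat b} is close to the truth, but carries no worst-case
#' guarantee.
#'
#' @param selection a `selection_result`.
#' @param alpha nominal non-coverage level.
#' @param n_draws,seed Monte-Carlo controls.
#' @return A `confidence_interval` with method `"1step"`.
#' @export
interval_1step <- function(selection, alpha = 0.05, n_draws = 5000L,
                           seed = NULL) {
  lam <- simulate_lambda(selection$bias$b_hat, selection$delta, n_draws,
                         seed)
  a <- shortest_mass_interval(lam$draws, 1 - alpha)
  new_confidence_interval(selection$theta_focused - a[2L],
                          selection$theta_focused - a[1L],
                          method = "1step", alpha = alpha,
                          n_draws = n_draws, seed = seed %||% NA_integer_,
                          meta = list(a_l = a[1L], a_u = a[2L]))
}

#' 2-step uniformly valid post-selection interval
#'
#' First builds a (1 - alpha1) region `phi` for the bias, then for every
#' grid value \eqn{b'} in `phi` takes the shortest (1 - alpha2) interval
#' of \eqn{\Lambda(b')} (one shared K sample across the grid), and
#' returns the outer envelope shifted by \eqn{\hat\theta}.  Uniformly
#' valid but conservative.
#'
#' @param selection a `selection_result`.
#' @param alpha nominal non-coverage level.
#' @param alpha1 level spent on the bias region (`alpha2 = alpha -
#'   alpha1`).
#' @param n_draws,grid_size,seed Monte-Carlo controls.
#' @return A `confidence_interval` with method `"2step"`.
#' @export
interval_2step <- function(selection, alpha = 0.05, alpha1 = alpha / 2,
                           n_draws = 5000L, grid_size = 101L,
                           seed = NULL) {
  alpha2 <- alpha - alpha1
  if (alpha2 <= 0) stopf("alpha1 must be smaller than alpha")
  phi <- phi_region(selection$bias, alpha1, grid_size)
  k <- draw_k_sample(selection$delta, n_draws,
                     if (is.null(seed)) NULL else derive_seed(seed, 1L))
  m <- ceiling((1 - alpha2) * n_draws)
  a_l <- Inf; a_u <- -Inf
  for (s in sorted_lambda_grid(phi$grid, k, selection$delta)) {
    a <- shortest_window_sorted(s, m)
    if (a[1L] < a_l) a_l <- a[1L]
    if (a[2L] > a_u) a_u <- a[2L]
  }
  lo <- selection$theta_focused - a_u
  hi <- selection$theta_focused - a_l
  new_confidence_interval(lo, hi, method = "2step", alpha = alpha,
                          alpha1 = alpha1, alpha2 = alpha2,
                          n_draws = n_draws, seed = seed %||% NA_integer_,
                          meta = list(a_l = a_l, a_u = a_u,
                                      phi = c(phi$lower, phi$upper)))
}

#' Focused post-selection interval with a minimum coverage constraint
#'
#' Searches, over splits `alpha1 + alpha2 = alpha`, for the single bias
#' value \eqn{b^*(\alpha,\gamma)} in the (1 - alpha1) region `phi` whose
#' shortest (1 - alpha2) interval for \eqn{\Lambda(b^*)} retains at least
#' `1 - alpha2 - gamma` Monte-Carlo mass of \eqn{\Lambda(b'')} for every
#' other grid value \eqn{b''} in `phi`.  Among feasible values the
#' shortest interval wins (ties to the smaller grid index), then the
#' shortest across `alpha1` values.  The returned interval is
#' \eqn{[\hat\theta - a_u(b^*), \hat\theta - a_l(b^*)]}.  By
#' construction it is contained in the 2-step envelope at the same
#' `alpha1` under shared draws, and its asymptotic coverage can fall at
#' most `gamma` below nominal.
#'
#' One K sample is drawn per `alpha1` value and shared across the whole
#' bias grid; the feasibility check is therefore internally consistent.
#' If no feasible bias value exists for any split (possible for very
#' small `gamma`), the 2-step interval is returned with a warning and
#' `meta$fallback = "2step"` (or an error if `fallback_2step` is
#' disabled).
#'
#' @param selection a `selection_result`.
#' @param alpha nominal non-coverage level.
#' @param gamma maximum allowable size distortion, in (0, 1 - alpha).
#' @param config a [focus_config()]; supplies the `alpha1` grid, bias
#'   grid size, draw count and fallback policy.
#' @param seed integer seed (overrides nothing in `config`; each `alpha1`
#'   uses a seed derived from it).
#' @return A `confidence_interval` with method `"focused"`, recording
#'   `alpha1`, `alpha2`, `gamma`, `b_star` and the window `(a_l, a_u)`.
#' @export
interval_focused <- function(selection, alpha = 0.05, gamma = 0.2,
                             config = focus_config(alpha = alpha,
                                                   gamma = gamma),
                             seed = NULL) {
  if (gamma <= 0 || gamma >= 1 - alpha)
    stopf("gamma must be in (0, 1 - alpha)")
  delta <- selection$delta
  best <- NULL
  for (i in seq_along(config$alpha1_grid)) {
    alpha1 <- config$alpha1_grid[i]
    alpha2 <- alpha - alpha1
    if (alpha2 <= 0) next
    phi <- phi_region(selection$bias, alpha1, config$grid_size)
    grid <- phi$grid
    g <- length(grid)
    k <- draw_k_sample(delta, config$n_draws,
                       if (is.null(seed)) NULL else derive_seed(seed, i))
    n <- nrow(k)
    m <- ceiling((1 - alpha2) * n)
    sorted <- sorted_lambda_grid(grid, k, delta)
    al <- numeric(g); au <- numeric(g)
    for (j in seq_len(g)) {
      w <- shortest_window_sorted(sorted[[j]], m)
      al[j] <- w[1L]; au[j] <- w[2L]
    }
    # min over b'' of the mass of Lambda(b'') inside [al(b'), au(b')]
    min_cov <- rep(Inf, g)
    for (j in seq_len(g)) {
      s <- sorted[[j]]
      cnt <- (findInterval(au, s) -
                findInterval(al, s, left.open = TRUE)) / n
      min_cov <- pmin(min_cov, cnt)
    }
    feasible <- which(min_cov >= 1 - alpha2 - gamma)
    if (length(feasible) == 0L) next
    widths <- au[feasible] - al[feasible]
    pick <- feasible[which.min(widths)]
    cand <- list(width = au[pick] - al[pick], a_l = al[pick],
                 a_u = au[pick], b_star = grid[pick], alpha1 = alpha1,
                 alpha2 = alpha2, min_cov = min_cov[pick])
    if (is.null(best) || cand$width < best$width) best <- cand
  }
  if (is.null(best)) {
    if (!config$fallback_2step)
      stopf("focused interval infeasible: phi-bar empty for every alpha1")
    warning("focused interval infeasible for every alpha1 split; ",
            "falling back to the 2-step interval", call. = FALSE)
    ci <- interval_2step(selection, alpha = alpha,
                         alpha1 = config$alpha1_2step,
                         n_draws = config$n_draws,
                         grid_size = config$grid_size, seed = seed)
    ci$method <- "focused"
    ci$gamma <- gamma
    ci$meta$fallback <- "2step"
    return(ci)
  }
  lo <- selection$theta_focused - best$a_u
  hi <- selection$theta_focused - best$a_l
  new_confidence_interval(lo, hi, method = "focused", alpha = alpha,
                          alpha1 = best$alpha1, alpha2 = best$alpha2,
                          gamma = gamma, b_star = best$b_star,
                          n_draws = config$n_draws,
                          seed = seed %||% NA_integer_,
                          meta = list(a_l = best$a_l, a_u = best$a_u,
                                      min_cov = best$min_cov))
}
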