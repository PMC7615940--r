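#' Asymptotically unbiased estimate of the Full estimator's bias
#'
#' Under local invalidity the asymptotic bias \eqn{b} of the Full LIML
#' estimator cannot be consistently estimated, but
#' \deqn{\hat b = (\hat\eta_C+\hat\eta_S)^{-1}\hat b_S, \qquad
#'   \hat b_S = \sum_{j \in S}\hat\Omega_j^{-1}\hat\beta_{Xj}\hat\beta_{Yj}
#'   - \hat\theta_C \sum_{j \in S}\hat\Omega_j^{-1}
#'     (\hat\beta_{Xj}^2-\sigma_{Xj}^2)}
#' is asymptotically unbiased for it, with asymptotic variance
#' \eqn{\Delta_B}.  All \eqn{\hat\Omega_j} use the core estimate
#' `theta_core`.
#'
#' @param data a [summary_data] object.
#' @param theta_core the core LIML estimate \eqn{\hat\theta_C}.
#' @return A `bias_estimate`: list with `b_hat`, `b_hat_S`, `delta_B_hat`
#'   and the underlying plug-in `components`.
#' @export
estimate_bias <- function(data, theta_core) {
  comp <- plug_in_components(data, theta_core)
  bias_from_components(data, theta_core, comp)
}

bias_from_components <- function(data, theta_core, comp) {
  aidx <- which(!data$core)
  om_a <- comp$omega[aidx]
  b_hat_S <- sum(data$beta_x_hat[aidx] * data$beta_y_hat[aidx] / om_a) -
    theta_core * sum((data$beta_x_hat[aidx]^2 - data$se_x[aidx]^2) / om_a)
  tot <- comp$eta_core + comp$eta_add
  if (tot <= 0) stopf("instruments too weak: eta_core + eta_add <= 0")
  b_hat <- b_hat_S / tot
  delta_B_hat <- tot^-2 *
    (comp$eta_add + comp$zeta_add + comp$xi_add +
       comp$eta_core^-2 * comp$eta_add^2 *
         (comp$eta_core + comp$zeta_core))
  structure(list(b_hat = b_hat, b_hat_S = b_hat_S,
                 delta_B_hat = delta_B_hat, components = comp),
            class = "bias_estimate")
}

#' AMSE difference statistic between Full and Core estimators
#'
#' \deqn{\hat W = \max(\hat b^2 - \hat\Delta_B, 0) + \hat\Delta_F -
#'   \hat\Delta_C,} the estimated asymptotic mean squared error of the
#' Full estimator minus that of the Core estimator.  The truncation at
#' zero is applied before the variance difference is added, since a
#' squared bias cannot be negative.  The Full model is selected on the
#' event \eqn{\{\hat W \le 0\}} (boundary inclusive).
#'
#' @param bias a `bias_estimate` from [estimate_bias()].
#' @param delta_F_hat,delta_C_hat plug-in variances of the Full and Core
#'   estimators.
#' @return scalar \eqn{\hat W}.
#' @export
compute_W <- function(bias, delta_F_hat, delta_C_hat) {
  stopifnot(is.finite(bias$b_hat), is.finite(bias$delta_B_hat),
            is.finite(delta_F_hat), is.finite(delta_C_hat))
  max(bias$b_hat^2 - bias$delta_B_hat, 0) + delta_F_hat - delta_C_hat
}

new_selection_result <- function(W_hat, amse_core, amse_full, selected,
                                 theta_focused, est_core, est_full, bias,
                                 comp, delta, candidate = NULL) {
  structure(list(W_hat = W_hat, amse_core = amse_core,
                 amse_full = amse_full, selected = selected,
                 theta_focused = theta_focused, est_core = est_core,
                 est_full = est_full, bias = bias, components = comp,
                 delta = delta, candidate = candidate),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Focused instrument selection\n")
  cat(sprintf("  theta_core = %.6g (se %.4g)   theta_full = %.6g (se %.4g)\n",
              x$est_core$theta_hat, sqrt(x$est_core$variance),
              x$est_full$theta_hat, sqrt(x$est_full$variance)))
  cat(sprintf("  b_hat = %.6g   W_hat = %.6g\n", x$bias$b_hat, x$W_hat))
  cat(sprintf("  AMSE: core %.6g, full %.6g -> selected: %s\n",
              x$amse_core, x$amse_full, x$selected))
  cat(sprintf("  theta_focused = %.6g\n", x$theta_focused))
  invisible(x)
}

#' Focused estimation: fit, compare AMSE, select
#'
#' Fits the Core and Full LIML estimators, estimates the asymptotic bias
#' of the Full estimator, compares estimated AMSEs via [compute_W()], and
#' returns the Focused point estimate
#' \eqn{\hat\theta = I\{\hat W \le 0\}\hat\theta_F + (1 - I\{\hat W \le
#' 0\})\hat\theta_C} together with a full audit trail (component
#' estimates, plug-in covariance matrix, both fits).
#'
#' @param data a [summary_data] object with non-empty core and additional
#'   sets.
#' @param config a [focus_config()] list (bracket, tolerance, PSD policy).
#' @return A `selection_result`.
#' @export
focused_estimate <- function(data, config = focus_config()) {
  cidx <- which(data$core)
  if (length(cidx) == 0L || length(cidx) == nrow(data))
    stopf("need non-empty core and additional sets")
  est_c <- fit_liml(data, cidx, bracket = config$bracket,
                    tol = config$liml_tol,
                    grid_points = config$grid_points,
                    subset_label = "core")
  est_f <- fit_liml(data, NULL, bracket = config$bracket,
                    tol = config$liml_tol,
                    grid_points = config$grid_points,
                    subset_label = "full")
  comp <- plug_in_components(data, est_c$theta_hat)
  d_c <- variance_from_components(comp, "core")
  d_f <- variance_from_components(comp, "full")
  est_c$variance <- d_c
  est_f$variance <- d_f
  bias <- bias_from_components(data, est_c$theta_hat, comp)
  W <- compute_W(bias, d_f, d_c)
  amse_full <- max(bias$b_hat^2 - bias$delta_B_hat, 0) + d_f
  selected <- if (W <= 0) "full" else "core"
  theta_foc <- if (selected == "full") est_f$theta_hat else est_c$theta_hat
  delta <- delta_matrix(comp, tol = config$psd_tol,
                        psd_action = config$psd_action)
  new_selection_result(W, d_c, amse_full, selected, theta_foc,
                       est_c, est_f, bias, comp, delta)
}

#' Candidate additional-instrument subsets by k-means on Wald ratios
#'
#' Clusters the additional variants into `k` groups by k-means on their
#' Wald ratio estimates \eqn{\hat\beta_{Yj}/\hat\beta_{Xj}} (a variant's
#' single-instrument causal-effect estimate), then returns every
#' non-empty union of clusters: \eqn{2^k - 1} candidate subsets.
#' Clusters are relabelled by ascending center so the candidate list is
#' deterministic given the seed.
#'
#' @param data a [summary_data] object.
#' @param k number of clusters (additional-set size must be `>= k`).
#' @param seed integer RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return Named list of integer vectors of row indices into `data`; names
#'   like `"c1"`, `"c1+c3"` identify the cluster unions.
#' @export
partition_additional <- function(data, k = 3L, seed = 1L, nstart = 10L) {
  aidx <- which(!data$core)
  if (length(aidx) < k)
    stopf("additional set size %d smaller than k = %d", length(aidx), k)
  if (any(data$beta_x_hat[aidx] == 0))
    stopf("Wald ratio undefined: beta_x_hat = 0 for an additional variant")
  ratio <- data$beta_y_hat[aidx] / data$beta_x_hat[aidx]
  if (k == 1L) {
    out <- list(aidx)
    names(out) <- "c1"
    return(out)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(ratio, centers = k, nstart = nstart)
  relabel <- order(km$centers[, 1])
  lab <- match(km$cluster, relabel)
  clusters <- lapply(seq_len(k), function(g) aidx[lab == g])
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(seq_len(k), m, simplify = FALSE)), recursive = FALSE)
  out <- lapply(combos, function(cm) sort(unlist(clusters[cm])))
  names(out) <- vapply(combos, function(cm)
    paste0("c", cm, collapse = "+"), "")
  out
}

#' Select among several candidate additional-instrument subsets
#'
#' Treats each candidate subset in turn as the additional set \eqn{S},
#' computes its estimated AMSE \eqn{\max(\hat b^2-\hat\Delta_B,0) +
#' \hat\Delta_F}, and selects the candidate with the smallest estimated
#' AMSE, falling back to the Core model when no candidate beats
#' \eqn{\hat\Delta_C}.  Ties resolve to the candidate with fewer
#' instruments, then lexicographically by name.  Post-selection intervals
#' downstream condition on the winning candidate as if it were the only
#' additional set.
#'
#' @param data a [summary_data] object.
#' @param candidates list of integer index vectors as returned by
#'   [partition_additional()].
#' @param config a [focus_config()] list.
#' @return A `selection_result`; `selected` is the winning candidate's
#'   name (or `"core"`), `candidate` holds its indices.
#' @export
multi_candidate_select <- function(data, candidates, config = focus_config()) {
  if (length(candidates) == 0L) stopf("candidates must be non-empty")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("cand", seq_along(candidates))
  fits <- lapply(candidates, function(idx)
    focused_estimate(subset_additional(data, idx), config))
  amse <- vapply(fits, function(f) f$amse_full, 0)
  sizes <- lengths(candidates)
  ord <- order(amse, sizes, names(candidates))
  best <- ord[1L]
  res <- fits[[best]]
  # boundary amse_full == amse_core resolves to the candidate, matching
  # the two-model rule {W_hat <= 0} -> full
  if (res$amse_core < amse[best]) {
    res$selected <- "core"
    res$theta_focused <- res$est_core$theta_hat
  } else {
    res$selected <- names(candidates)[best]
    res$theta_focused <- res$est_full$theta_hat
  }
  res$candidate <- candidates[[best]]
  res$W_hat <- amse[best] - res$amse_core
  res
}
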