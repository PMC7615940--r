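# Fixtures are built in code; no binary data.

# tiny deterministic dataset: one core + one additional variant
tiny_data <- function(by_core = 0.2, by_add = 0.3, bx = c(1, 1),
                      se = 0.1) {
  summary_data(beta_x_hat = bx, se_x = rep(se, 2),
               beta_y_hat = c(by_core, by_add), se_y = rep(se, 2),
               core = c(TRUE, FALSE))
}

# seeded random dataset in the benchmark design (p = 110, |S0| = 10)
bench_data <- function(seed = 1, tau_bar = 0, lambda_core = 40,
                       lambda_add = 40, ...) {
  des <- simulation_design(lambda_core = lambda_core,
                           lambda_add = lambda_add, tau_bar = tau_bar,
                           ...)
  truth <- design_truth(des, seed = seed)
  generate_summary_data(truth, seed = seed + 1000L)
}

# exactly proportional, noiseless dataset: beta_y_hat = theta0 * beta_x_hat
proportional_data <- function(theta0 = 0.2, p = 12L, n_core = 4L,
                              bx = 0.5, se = 0.05) {
  summary_data(beta_x_hat = rep(bx, p), se_x = rep(se, p),
               beta_y_hat = rep(bx * theta0, p), se_y = rep(se, p),
               core = seq_len(p) <= n_core)
}

# hand-built delta_matrix with a diagonal covariance (PSD by
# construction); var_kb lets tests decouple the K_b draw variance from
# the Delta_B used inside W, to force one branch of the indicator
diag_delta <- function(d_f, d_c, d_b, var_kb = d_b) {
  structure(list(delta_F = d_f, delta_C = d_c, delta_B = d_b,
                 delta_E = 0, delta_A = 0, delta_D = 0,
                 mat = diag(c(d_f, d_c, var_kb)), degenerate = FALSE,
                 projected = FALSE),
            class = "delta_matrix")
}

# minimal selection_result stub for interval unit tests
stub_selection <- function(theta = 0.5, b_hat = 0, delta,
                           var_core = delta$delta_C) {
  est_core <- structure(list(theta_hat = theta, variance = var_core,
                             subset_label = "core", objective_value = 0,
                             search_meta = list()),
                        class = "causal_estimate")
  est_full <- structure(list(theta_hat = theta, variance = delta$delta_F,
                             subset_label = "full", objective_value = 0,
                             search_meta = list()),
                        class = "causal_estimate")
  bias <- structure(list(b_hat = b_hat, b_hat_S = b_hat,
                         delta_B_hat = delta$delta_B,
                         components = NULL),
                    class = "bias_estimate")
  structure(list(W_hat = 0, amse_core = delta$delta_C,
                 amse_full = delta$delta_F, selected = "full",
                 theta_focused = theta, est_core = est_core,
                 est_full = est_full, bias = bias, components = NULL,
                 delta = delta, candidate = NULL),
            class = "selection_result")
}
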