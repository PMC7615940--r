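test_that("estimate_bias reproduces the hand oracle", {
  d <- tiny_data(by_core = 0.2, by_add = 0.3)
  bias <- estimate_bias(d, theta_core = 0.2)
  om <- 0.0104
  b_s <- (0.3 - 0.2 * 0.99) / om            # 9.80769...
  expect_equal(bias$b_hat_S, b_s)
  eta_tot <- (1 - 0.01) / om * 2
  expect_equal(bias$b_hat, b_s / eta_tot)
  expect_gte(bias$delta_B_hat, 0)
})

test_that("empty additional set gives zero bias by the empty-sum rule", {
  # bypass the mixed-set constructor check deliberately
  d <- data.frame(variant = c("a", "b"), beta_x_hat = c(0.5, 0.6),
                  se_x = c(0.1, 0.1), beta_y_hat = c(0.1, 0.12),
                  se_y = c(0.1, 0.1), core = c(TRUE, TRUE))
  class(d) <- c("summary_data", "data.frame")
  bias <- estimate_bias(d, 0.2)
  expect_identical(bias$b_hat, 0)
  expect_identical(bias$b_hat_S, 0)
})

test_that("compute_W applies truncation before the variance difference", {
  bias1 <- structure(list(b_hat = 1, delta_B_hat = 2),
                     class = "bias_estimate")
  expect_equal(compute_W(bias1, 0.5, 0.7), -0.2)
  bias2 <- structure(list(b_hat = 2, delta_B_hat = 1),
                     class = "bias_estimate")
  expect_equal(compute_W(bias2, 0.3, 0.3), 3)
  expect_equal(compute_W(bias2, 0.5, 0.5 + 3), 0)
})

test_that("bias estimator is asymptotically unbiased (MC recovery)", {
  des <- simulation_design(tau_bar = 8)
  truth <- design_truth(des, seed = 9)
  R <- 2000
  bh <- numeric(R)
  for (r in 1:R) {
    dat <- generate_summary_data(truth, seed = r)
    th_c <- fit_liml(dat, core_idx(dat))$theta_hat
    bh[r] <- estimate_bias(dat, th_c)$b_hat
  }
  mc_se <- sd(bh) / sqrt(R)
  expect_lt(abs(mean(bh) - truth$b_true), 3 * mc_se)
})

test_that("focused_estimate picks Full for valid, Core for invalid extras", {
  # noiseless proportional data: bias truncates to zero, Full has the
  # smaller variance, W < 0
  d <- proportional_data(theta0 = 0.2, p = 20, n_core = 5, bx = 0.5,
                         se = 0.05)
  sel <- focused_estimate(d)
  expect_lt(sel$W_hat, 0)
  expect_identical(sel$selected, "full")
  expect_equal(sel$theta_focused, sel$est_full$theta_hat)
  expect_gte(sel$amse_full, sel$est_full$variance)

  # grossly invalid additional variants (|tau| huge relative to the
  # standard errors, Wald ratios still inside the search bracket)
  d2 <- d
  d2$beta_y_hat[!d2$core] <- d2$beta_y_hat[!d2$core] + 0.5
  sel2 <- focused_estimate(d2)
  expect_gt(sel2$W_hat, 0)
  expect_identical(sel2$selected, "core")
  expect_equal(sel2$theta_focused, sel2$est_core$theta_hat)
})

test_that("selection rule and audit trail are internally consistent", {
  truth <- design_truth(simulation_design(tau_bar = 6), seed = 12)
  for (r in 1:25) {
    dat <- generate_summary_data(truth, seed = 400 + r)
    sel <- focused_estimate(dat)
    expect_identical(sel$selected == "full", sel$W_hat <= 0)
    expect_equal(sel$theta_focused,
                 if (sel$selected == "full") sel$est_full$theta_hat
                 else sel$est_core$theta_hat)
    expect_equal(sel$W_hat, sel$amse_full - sel$amse_core)
    expect_gte(sel$amse_full, sel$est_full$variance)
  }
  # determinism: identical input and seed give identical results
  dat <- generate_summary_data(truth, seed = 401)
  s1 <- focused_estimate(dat)
  s2 <- focused_estimate(dat)
  expect_identical(s1, s2)
})

test_that("partition_additional forms cluster unions on Wald ratios", {
  d <- bench_data(seed = 31)
  p1 <- partition_additional(d, k = 1)
  expect_length(p1, 1L)
  expect_identical(p1[[1]], add_idx(d))

  p3 <- partition_additional(d, k = 3, seed = 2)
  expect_length(p3, 7L)   # 2^3 - 1 unions
  expect_setequal(p3[["c1+c2+c3"]], add_idx(d))

  # three well-separated ratio clusters are recovered exactly
  bx <- rep(1, 32)
  ratios <- c(rep(0, 2), rep(0.2, 10), rep(5, 10), rep(10, 10))
  ds <- summary_data(bx, rep(0.01, 32), ratios, rep(0.01, 32),
                     core = seq_len(32) <= 2)
  ps <- partition_additional(ds, k = 3, seed = 5)
  expect_identical(ps[["c1"]], 3:12)
  expect_identical(ps[["c2"]], 13:22)
  expect_identical(ps[["c3"]], 23:32)

  dzero <- summary_data(c(1, 0, 1), rep(0.1, 3), c(0.2, 0.2, 0.2),
                        rep(0.1, 3), c(TRUE, FALSE, FALSE))
  expect_error(partition_additional(dzero, k = 1), "Wald ratio")
})

test_that("multi_candidate_select reduces, discriminates, and falls back", {
  d <- bench_data(seed = 41, tau_bar = 2)
  single <- multi_candidate_select(d, list(S = add_idx(d)))
  ref <- focused_estimate(d)
  expect_equal(single$theta_focused, ref$theta_focused)
  expect_identical(single$selected == "S", ref$selected == "full")

  # valid cluster vs grossly invalid cluster: the valid one should win
  # at the rate the asymptotic theory predicts.  Selecting core over a
  # valid candidate happens when max(b_hat^2 - dB, 0) > dC - dF with
  # b_hat ~ N(0, dB), i.e. with probability P(|Z| > sqrt(1 + (dC-dF)/dB))
  # -- an intrinsic feature of the truncated-AMSE rule, not noise.
  des <- simulation_design(p = 30, n_core = 10, lambda_core = 200,
                           lambda_add = 80)
  truth <- design_truth(des, seed = 3)
  truth$tau[21:30] <- 0.2           # invalidate half the additional set
  truth$beta_y <- truth$beta_x * 0.2 + truth$tau
  comp_valid <- population_components(truth$beta_x[1:20],
                                      truth$se_x[1:20],
                                      truth$se_y[1:20],
                                      truth$core_mask[1:20], 0.2)
  dmv <- delta_matrix(comp_valid)
  p_oracle <- 2 * pnorm(sqrt(1 + (dmv$delta_C - dmv$delta_F) /
                               dmv$delta_B)) - 1
  wins <- 0L
  R <- 200
  for (r in 1:R) {
    dat <- generate_summary_data(truth, seed = 600 + r)
    cands <- list(valid = 11:20, invalid = 21:30, union = 11:30)
    res <- multi_candidate_select(dat, cands)
    wins <- wins + (res$selected == "valid")
  }
  expect_gte(wins / R, 0.75)
  expect_lt(abs(wins / R - p_oracle),
            3 * sqrt(p_oracle * (1 - p_oracle) / R) + 0.03)

  # all candidates grossly invalid -> core wins
  truth2 <- truth
  truth2$tau[11:30] <- 0.2
  truth2$beta_y <- truth2$beta_x * 0.2 + truth2$tau
  dat2 <- generate_summary_data(truth2, seed = 700)
  res2 <- multi_candidate_select(dat2, list(a = 11:20, b = 21:30,
                                            ab = 11:30))
  expect_identical(res2$selected, "core")
})
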