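test_that("simulate_lambda obeys the selection indicator", {
  # Delta_F > Delta_C: W(b) >= Delta_F - Delta_C > 0, all draws are K_C
  dm <- diag_delta(2, 1, 1)
  lam <- simulate_lambda(5, dm, n_draws = 4000, seed = 1)
  expect_identical(lam$draws, lam$k_draws[, 2])
  expect_lt(abs(mean(lam$draws)), 3 * sqrt(1 / 4000))

  # Delta_F <= Delta_C and Delta_B -> infinity relative to the K_b
  # scale: truncation kills the bias term, W = Delta_F - Delta_C <= 0,
  # draws are b' + K_F
  dm2 <- diag_delta(1, 2, 1e8, var_kb = 1)
  lam2 <- simulate_lambda(3, dm2, n_draws = 4000, seed = 2)
  expect_identical(lam2$draws, 3 + lam2$k_draws[, 1])
  expect_lt(abs(mean(lam2$draws) - 3), 3 * sqrt(1 / 4000))
})

test_that("simulate_lambda matches a scalar-loop oracle on shared draws", {
  d <- bench_data(seed = 51, tau_bar = 4)
  sel <- focused_estimate(d)
  lam <- simulate_lambda(0.03, sel$delta, n_draws = 2000, seed = 9)
  k <- lam$k_draws
  dm <- sel$delta
  oracle <- numeric(2000)
  for (i in 1:2000) {
    w <- max((0.03 + k[i, 3])^2 - dm$delta_B, 0) +
      dm$delta_F - dm$delta_C
    oracle[i] <- if (w <= 0) 0.03 + k[i, 1] else k[i, 2]
  }
  expect_identical(lam$draws, oracle)
})

test_that("shortest_mass_interval matches exhaustive window search", {
  expect_equal(shortest_mass_interval(rep(2.5, 100), 0.5), c(2.5, 2.5))
  draws <- 0:99
  got <- shortest_mass_interval(draws, 0.5)
  # exhaustive oracle over all windows of ceiling(0.5 * 100) points
  m <- 50
  widths <- vapply(1:(100 - m + 1),
                   function(i) draws[i + m - 1] - draws[i], 0)
  expect_equal(got[2] - got[1], min(widths))
  expect_equal(got, c(0, 49))  # tie -> smallest left endpoint
  set.seed(13)
  z <- rnorm(2e4)
  a <- shortest_mass_interval(z, 0.95)
  expect_equal(a[1], -1.96, tolerance = 0.06)
  expect_equal(a[2], 1.96, tolerance = 0.06)
  expect_error(shortest_mass_interval(rnorm(20), 0.5), "30")
})

test_that("phi_region is the normal interval for the bias", {
  bias <- structure(list(b_hat = 0, delta_B_hat = 1),
                    class = "bias_estimate")
  phi <- phi_region(bias, 0.05, grid_size = 11)
  expect_equal(phi$lower, -1.959964, tolerance = 1e-6)
  expect_equal(phi$upper, 1.959964, tolerance = 1e-6)
  expect_length(phi$grid, 11)
  expect_equal(range(phi$grid), c(phi$lower, phi$upper))

  bias0 <- structure(list(b_hat = 0.4, delta_B_hat = 0),
                     class = "bias_estimate")
  phi0 <- phi_region(bias0, 0.05)
  expect_identical(phi0$grid, 0.4)
})

test_that("phi_region covers the true bias at its nominal rate", {
  des <- simulation_design(tau_bar = 4)
  truth <- design_truth(des, seed = 15)
  R <- 1000
  hit <- logical(R)
  for (r in 1:R) {
    dat <- generate_summary_data(truth, seed = r)
    th_c <- fit_liml(dat, core_idx(dat))$theta_hat
    phi <- phi_region(estimate_bias(dat, th_c), 0.05)
    hit[r] <- phi$lower <= truth$b_true && truth$b_true <= phi$upper
  }
  cov <- mean(hit)
  expect_lt(abs(cov - 0.95), 3 * sqrt(0.95 * 0.05 / R))
})

test_that("standard and naive intervals are Wald arithmetic", {
  est <- structure(list(theta_hat = 0, variance = 1,
                        subset_label = "core"),
                   class = "causal_estimate")
  ci <- interval_standard(est, 0.05)
  expect_equal(ci$lower, -1.959964, tolerance = 1e-6)
  expect_equal(ci$upper, 1.959964, tolerance = 1e-6)
  est2 <- est; est2$variance <- 4
  ci2 <- interval_standard(est2, 0.05)
  expect_equal(ci2$upper - ci2$lower, 2 * (ci$upper - ci$lower))

  d <- bench_data(seed = 61, tau_bar = 16)
  sel <- focused_estimate(d)
  nv <- interval_naive(sel, 0.05)
  ref <- if (sel$selected == "core") sel$est_core else sel$est_full
  std <- interval_standard(ref, 0.05)
  expect_equal(c(nv$lower, nv$upper), c(std$lower, std$upper))
  expect_identical(nv$method, "naive")
})

test_that("1-step reduces to the core interval when Lambda is K_C", {
  # forced Delta_F > Delta_C: every Lambda draw is K_C ~ N(0, Delta_C)
  dm <- diag_delta(0.02, 0.01, 0.005)
  sel <- stub_selection(theta = 0.5, b_hat = 0.1, delta = dm)
  ci <- interval_1step(sel, alpha = 0.05, n_draws = 20000, seed = 3)
  std <- interval_standard(sel$est_core, 0.05)
  expect_equal(ci$lower, std$lower, tolerance = 0.01)
  expect_equal(ci$upper, std$upper, tolerance = 0.01)
})

test_that("2-step envelope behaves as an envelope", {
  d <- bench_data(seed = 71, tau_bar = 6)
  sel <- focused_estimate(d)
  ci2 <- interval_2step(sel, n_draws = 4000, seed = 5)
  ci1 <- interval_1step(sel, n_draws = 4000, seed = 5)
  expect_gte(ci2$upper - ci2$lower, ci1$upper - ci1$lower)
  # single-point grid reduces to the single-b' interval
  one <- interval_2step(sel, grid_size = 1, n_draws = 4000, seed = 5)
  phi <- phi_region(sel$bias, 0.025, grid_size = 1)
  lam <- sort(mrfocus:::lambda_given_k(
    phi$grid, mrfocus:::draw_k_sample(sel$delta, 4000,
                                      mrfocus:::derive_seed(5, 1L)),
    sel$delta))
  a <- mrfocus:::shortest_window_sorted(lam, ceiling(0.975 * 4000))
  expect_equal(c(one$lower, one$upper),
               sort(c(sel$theta_focused - a[2], sel$theta_focused - a[1])))
})

test_that("focused interval: determinism, containment, gamma monotonicity", {
  d <- bench_data(seed = 81, tau_bar = 8)
  sel <- focused_estimate(d)
  cfg <- focus_config(n_draws = 2000, grid_size = 41)
  f1 <- interval_focused(sel, config = cfg, seed = 11)
  f2 <- interval_focused(sel, config = cfg, seed = 11)
  expect_identical(f1, f2)

  # containment in the 2-step envelope at the same alpha1, shared draws
  for (s in 1:10) {
    dat <- bench_data(seed = 90 + s, tau_bar = (s %% 3) * 6)
    sl <- focused_estimate(dat)
    cfg1 <- focus_config(alpha1_grid = 0.025, n_draws = 2000,
                         grid_size = 41)
    fo <- interval_focused(sl, config = cfg1, seed = s)
    tw <- interval_2step(sl, alpha1 = 0.025, n_draws = 2000,
                         grid_size = 41, seed = s)
    expect_gte(fo$lower, tw$lower - 1e-12)
    expect_lte(fo$upper, tw$upper + 1e-12)
  }

  # width is non-increasing in gamma for shared draws
  widths <- vapply(c(0.05, 0.1, 0.2, 0.3), function(g) {
    ci <- interval_focused(sel, gamma = g,
                           config = focus_config(gamma = g,
                                                 n_draws = 2000,
                                                 grid_size = 41),
                           seed = 21)
    ci$upper - ci$lower
  }, 0)
  expect_true(all(diff(widths) <= 1e-12))

  expect_identical(f1$method, "focused")
  expect_equal(f1$alpha1 + f1$alpha2, f1$alpha)
  expect_true(is.finite(f1$b_star))
})
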