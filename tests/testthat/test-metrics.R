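test_that("nagelkerke R2 and LR follow their closed forms", {
  expect_equal(nagelkerke_r2(-10, -10, 50), 0)
  expect_equal(likelihood_ratio(-10, -10), 0)
  n <- 40
  expect_equal(nagelkerke_r2(-100 + n / 2, -100, n), 1 - exp(-1))
  expect_equal(likelihood_ratio(-80, -95), 2 * 15)
  # strictly increasing in the likelihood gap at fixed n
  gaps <- seq(0, 5, by = 0.5)
  vals <- vapply(gaps, function(g) nagelkerke_r2(-50 + g, -50, 20), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(nagelkerke_r2(-11, -10, 50), "maximized")
  expect_error(likelihood_ratio(-11, -10), "maximized")
})

test_that("R2 and LR agree with a brute-force Cox oracle on a toy fit", {
  time <- c(1.2, 2.5, 3.1, 4.7, 5.3, 6.8)
  event <- rep(1, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  b <- oracle_cox_beta(x, time, event)
  lhat <- oracle_log_pl(b, x, time, event)
  l0 <- oracle_log_pl(0, x, time, event)
  f <- fit_cox(matrix(x, ncol = 1), time, event)
  expect_equal(likelihood_ratio(f$loglik, f$loglik_null), 2 * (lhat - l0),
               tolerance = 1e-7)
  expect_equal(nagelkerke_r2(f$loglik, f$loglik_null, 6),
               1 - exp(-(2 / 6) * (lhat - l0)), tolerance = 1e-7)
})

test_that("CPE has its closed-form anchors and matches the pairwise oracle", {
  set.seed(21)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(cpe(c(0, 0), x), 0.5)
  b <- c(0.8, -1.1)
  expect_equal(cpe(b, x), oracle_cpe(b, x), tolerance = 1e-10)
  # perfect discrimination is approached as the linear predictors separate
  expect_gt(cpe(b * 50, x), 0.999)
  # documented non-property: CPE is not invariant to rescaling beta
  expect_gt(cpe(b * 2, x), cpe(b, x))
  expect_error(cpe(b, x[1, , drop = FALSE]), "2 samples")
})

test_that("C-index has its anchors and matches exhaustive enumeration", {
  ts <- toy_surv()
  expect_equal(c_index(ts$pi, ts$time, ts$event),
               oracle_c_index(ts$pi, ts$time, ts$event), tolerance = 1e-10)
  # perfect rule: PI exactly reverses the survival order, all events
  time <- c(1, 2, 3, 4, 5)
  expect_equal(c_index(-time, time, rep(1, 5)), 1)
  expect_equal(c_index(rep(0, 5), time, rep(1, 5)), 0.5)   # all pairs tied
  # invariant to strictly increasing transforms of PI
  expect_equal(c_index(exp(ts$pi), ts$time, ts$event),
               c_index(ts$pi, ts$time, ts$event))
  expect_error(c_index(c(1, 2), c(1, 2), c(0, 0)), "usable")
})

test_that("Brier score matches its closed forms and the literal oracle", {
  ts <- toy_surv()
  grid <- sort(unique(ts$time[ts$event == 1]))
  # perfect prediction: p_i(t) = o_i(t)
  perfect <- vapply(grid, function(t) as.numeric(ts$time > t),
                    numeric(length(ts$time)))
  expect_equal(brier_score(perfect, grid, ts$time, ts$event), rep(0, 5))
  expect_equal(integrated_brier(perfect, grid, ts$time, ts$event), 0)
  # no censoring, constant prediction 0.5: BS(t) = 0.25 everywhere
  time2 <- c(1.5, 2.5, 3.5, 4.5)
  grid2 <- c(1, 2, 3, 4)
  half <- matrix(0.5, 4, 4)
  expect_equal(brier_score(half, grid2, time2, rep(1, 4)), rep(0.25, 4))
  # censored fixture against the literal Graf summation + trapezoid oracle
  set.seed(22)
  p_mat <- matrix(runif(length(ts$time) * length(grid)), length(ts$time))
  expect_equal(brier_score(p_mat, grid, ts$time, ts$event),
               vapply(seq_along(grid), function(j)
                 oracle_brier_t(grid[j], p_mat[, j], ts$time, ts$event),
                 numeric(1)),
               tolerance = 1e-10)
  expect_equal(integrated_brier(p_mat, grid, ts$time, ts$event),
               oracle_ibs(p_mat, grid, ts$time, ts$event), tolerance = 1e-10)
})

test_that("a perfect predictor never loses to the null KM predictor on IBS", {
  for (s in 1:5) {
    sim <- simulate_bt(bt_sim_spec(n_genes = 10, n_samples = 60,
                                   signal_block = list(genes = c(1, 2), shift = 1),
                                   random_blocks = list()), seed = 300 + s)
    time <- sim$survival$time; event <- sim$survival$event
    grid <- sort(unique(time[event == 1]))
    perfect <- vapply(grid, function(t) as.numeric(time > t),
                      numeric(length(time)))
    km <- oracle_km(time, event)
    null_p <- matrix(rep(km(grid), each = length(time)), length(time))
    expect_lte(integrated_brier(perfect, grid, time, event),
               integrated_brier(null_p, grid, time, event))
  }
})
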