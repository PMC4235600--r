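test_that("fit_cox matches brute-force partial-likelihood maximization", {
  # 6-sample, 1 binary covariate, no censoring
  time <- c(1.2, 2.5, 3.1, 4.7, 5.3, 6.8)
  event <- rep(1, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  f <- fit_cox(matrix(x, ncol = 1), time, event)
  b_star <- oracle_cox_beta(x, time, event)
  expect_equal(unname(f$coefficients), b_star, tolerance = 1e-6)
  expect_equal(f$loglik, oracle_log_pl(b_star, x, time, event),
               tolerance = 1e-8)
  expect_equal(f$loglik_null, oracle_log_pl(0, x, time, event),
               tolerance = 1e-10)
  expect_gte(f$loglik, f$loglik_null)

  # censored continuous-covariate fixture
  set.seed(9)
  x2 <- rnorm(10)
  t2 <- rexp(10, exp(0.7 * x2))
  e2 <- rbinom(10, 1, 0.7)
  e2[1] <- 1
  f2 <- fit_cox(matrix(x2, ncol = 1), t2, e2)
  expect_equal(unname(f2$coefficients), oracle_cox_beta(x2, t2, e2),
               tolerance = 1e-6)
})

test_that("the partial likelihood estimate is invariant to data duplication", {
  set.seed(5)
  x <- matrix(rnorm(30), 15, 2)
  time <- rexp(15, exp(x[, 1] * 0.5))
  event <- rbinom(15, 1, 0.8); event[1:2] <- 1
  f1 <- fit_cox(x, time, event, ties = "breslow")
  f2 <- fit_cox(rbind(x, x), c(time, time), c(event, event), ties = "breslow")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("beta = 0 gives unit hazard ratios and centering changes nothing", {
  set.seed(6)
  x <- matrix(rnorm(40), 20, 2)
  time <- rexp(20); event <- rep(1, 20)
  pi0 <- prognostic_index(x, c(0, 0))
  expect_true(all(exp(pi0 - pi0[1]) == 1))
  f1 <- fit_cox(x, time, event)
  f2 <- fit_cox(sweep(x, 2, c(100, -50)), time, event)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("fit_cox validates its inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fit_cox(x, rep(1, 5), rep(0, 5)), "at least one event")
  expect_error(fit_cox(x, c(-1, 1, 1, 1, 1), rep(1, 5)), "positive")
  x[1, 1] <- NA
  expect_error(fit_cox(x, rep(1, 5), rep(1, 5)), "missing")
})

test_that("fit_cox recovers parameters of a known PH model", {
  set.seed(7)
  n <- 400
  x <- matrix(rnorm(2 * n), n, 2)
  beta_true <- c(0.8, -0.5)
  t_lat <- rexp(n, rate = exp(x %*% beta_true))   # exponential baseline
  cens <- rexp(n, rate = 0.15)
  f <- fit_cox(x, pmin(t_lat, cens), as.integer(t_lat <= cens))
  expect_true(all(abs(f$coefficients - beta_true) < 3 * f$se))
  expect_true(f$converged)
})

test_that("wald screen ranks match independent per-gene fits and flags failures", {
  set.seed(8)
  n <- 40
  x <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  x[3, ] <- x[3, ] + rep(c(1.5, 0), each = n / 2)
  time <- c(rexp(n / 2, 0.2), rexp(n / 2, 1))
  event <- rbinom(n, 1, 0.8); event[1] <- 1
  x[17, ] <- 5                                   # zero-variance gene
  sc <- wald_screen(x, time, event)
  expect_equal(sc$statistic[17], -Inf)
  expect_false(sc$ok[17])
  ref <- vapply(seq_len(20), function(g) {
    if (sd(x[g, ]) == 0) return(-Inf)
    f <- fit_cox(matrix(x[g, ], ncol = 1), time, event, iter_max = 10)
    abs(unname(f$coefficients / f$se))
  }, numeric(1))
  expect_equal(sc$statistic, ref, tolerance = 1e-8)
  expect_equal(order(sc$statistic, decreasing = TRUE),
               order(ref, decreasing = TRUE))
})

test_that("the wald statistic is invariant to covariate scaling", {
  set.seed(10)
  x <- matrix(rnorm(30), 1, 30, dimnames = list("g1", NULL))
  time <- rexp(30, exp(0.5 * x[1, ])); event <- rep(1, 30)
  s1 <- wald_screen(x, time, event)
  s2 <- wald_screen(x * 10, time, event)
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-6)
  expect_equal(s2$beta, s1$beta / 10, tolerance = 1e-6)  # beta and se scale inversely
})

test_that("prognostic index is the linear predictor", {
  x <- matrix(1:6, 3, 2)
  expect_equal(prognostic_index(x, c(0, 0)), rep(0, 3))
  expect_equal(prognostic_index(matrix(c(1, 2, 3), ncol = 1), 1), c(1, 2, 3))
  b <- c(0.5, -2)
  expect_equal(prognostic_index(rbind(x, x), b),
               c(prognostic_index(x, b), prognostic_index(x, b)))
  expect_error(prognostic_index(x, c(1, 2, 3)), "mismatch")
})

test_that("breslow baseline reduces to Kaplan-Meier-like decay at beta = 0", {
  set.seed(11)
  time <- sort(rexp(50)); event <- rep(1, 50)
  bl <- breslow_baseline(time, event)
  km <- oracle_km(time, event)
  expect_lt(max(abs(bl$fn(bl$times) - km(bl$times))), 0.05)
  expect_true(all(diff(bl$surv) <= 1e-12))     # non-increasing
  expect_equal(bl$fn(0), 1)
  # S(t|x) is a valid, monotone survival curve for any PI
  sc <- survival_curve(bl, c(-2, 0, 3))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(apply(sc, 1, function(r) all(diff(r) <= 1e-12))))
  # evaluation beyond the last event time carries the last value
  expect_equal(bl$fn(max(time) + 100), bl$surv[length(bl$surv)])
})
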