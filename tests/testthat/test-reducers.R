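# Small expression fixture with a survival-associated pair of genes.
reducer_fixture <- function(n_genes = 30, n = 50, seed = 31) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  risk <- x[1, ] * 0.8 + x[2, ] * 0.6
  time <- rexp(n, exp(risk))
  cens <- rexp(n, 0.15)
  list(x = x, time = pmin(time, cens), event = as.integer(time <= cens))
}

test_that("the wavelet reducer emits level-1 Haar approximations of the top genes", {
  fx <- reducer_fixture()
  red <- fit_reducer(fx$x, fx$time, fx$event, method = "wavelet", n_genes = 2)
  ft <- predict(red, fx$x)
  expect_equal(ncol(ft), 1L)
  expect_equal(unname(ft[, 1]),
               unname(colSums(fx$x[red$genes, ]) / sqrt(2)),
               tolerance = 1e-12)
  # odd selection is padded: 15 genes -> 8 features
  red15 <- fit_reducer(fx$x, fx$time, fx$event, method = "wavelet",
                       n_genes = 15)
  expect_equal(ncol(predict(red15, fx$x)), 8L)
  expect_error(fit_reducer(fx$x, fx$time, fx$event, n_genes = 1), ">= 2")
})

test_that("wavelet feature count is ceiling(n_genes/2) across the benchmark grid", {
  fx <- reducer_fixture(n_genes = 60)
  for (ng in c(5, 10, 15, 20, 30, 40)) {
    red <- fit_reducer(fx$x, fx$time, fx$event, method = "wavelet",
                       n_genes = ng)
    expect_equal(ncol(predict(red, fx$x)), ceiling(ng / 2))
  }
})

test_that("applying a reducer is stateless and uses train-derived state only", {
  fx <- reducer_fixture()
  for (m in c("wavelet", "pca", "pls")) {
    red <- fit_reducer(fx$x, fx$time, fx$event, method = m, n_genes = 8)
    f1 <- predict(red, fx$x)
    f2 <- predict(red, fx$x)      # identical copy of train
    expect_identical(f1, f2)
    # permuting gene rows does not change the output (selection is by id)
    perm <- sample(nrow(fx$x))
    f3 <- predict(red, fx$x[perm, ])
    expect_equal(f3, f1, tolerance = 1e-12)
  }
})

test_that("supervised PCA applies the cumulative-variance rule", {
  fx <- reducer_fixture(n_genes = 10, n = 80, seed = 33)
  # one dominant direction: shared factor dwarfs the noise
  set.seed(34)
  shared <- rnorm(80, sd = 6)
  x_dom <- fx$x + matrix(rep(shared, each = 10), 10, 80)
  red <- fit_reducer(x_dom, fx$time, fx$event, method = "pca", n_genes = 10)
  expect_equal(red$n_components, 1L)
  # isotropic noise: k from the realized eigenvalue shares (independent calc)
  red_iso <- fit_reducer(fx$x, fx$time, fx$event, method = "pca",
                         n_genes = 10)
  sel <- t(fx$x[red_iso$genes, ])
  ev <- eigen(cov(sel), symmetric = TRUE, only.values = TRUE)$values
  k_expected <- which(cumsum(ev) / sum(ev) >= 0.75)[1]
  expect_equal(red_iso$n_components, k_expected)
  # projected train features: zero mean, mutually orthogonal
  ft <- predict(red_iso, fx$x)
  expect_true(all(abs(colMeans(ft)) < 1e-10))
  cp <- crossprod(sweep(ft, 2, colMeans(ft)))
  expect_true(all(abs(cp[upper.tri(cp)]) < 1e-8))
  # degenerate submatrix errors
  x0 <- matrix(1, 4, 20, dimnames = list(paste0("g", 1:4), NULL))
  expect_error(fit_reducer(x0, fx$time[1:20], rep(1, 20), method = "pca",
                           n_genes = 4), "degenerate|zero-variance")
})

test_that("PLS-Cox components behave like supervised scores", {
  fx <- reducer_fixture()
  # rank-1 input: single score proportional to the shared column
  base <- rnorm(50)
  x1 <- matrix(rep(base, each = 6), 6, 50,
               dimnames = list(paste0("g", 1:6), NULL)) *
    matrix(c(1, 2, -1, 0.5, 1.5, -2), 6, 50)
  red1 <- fit_reducer(x1, fx$time, fx$event, method = "pls", n_genes = 6,
                      n_components = 1)
  sc <- predict(red1, x1)[, 1]
  expect_gt(abs(cor(sc, base)), 1 - 1e-8)
  # deflation makes train scores mutually orthogonal
  red <- fit_reducer(fx$x, fx$time, fx$event, method = "pls", n_genes = 12,
                     n_components = 3)
  ft <- predict(red, fx$x)
  cp <- crossprod(ft)
  cp_norm <- cp / sqrt(outer(diag(cp), diag(cp)))
  expect_true(all(abs(cp_norm[upper.tri(cp_norm)]) < 1e-8))
})

test_that("a pure-noise PLS component has no held-out discrimination", {
  # average held-out C over several splits hovers at 1/2
  cs <- numeric(8)
  for (s in seq_along(cs)) {
    set.seed(40 + s)
    x <- matrix(rnorm(30 * 60), 30, 60,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:60)))
    time <- rexp(60); event <- rbinom(60, 1, 0.8); event[1] <- 1
    tr <- 1:40; te <- 41:60
    red <- fit_reducer(x[, tr], time[tr], event[tr], method = "pls",
                       n_genes = 10, n_components = 1)
    fit <- fit_cox(predict(red, x[, tr]), time[tr], event[tr])
    pi_te <- prognostic_index(predict(red, x[, te]), fit$coefficients)
    cs[s] <- c_index(pi_te, time[te], event[te])
  }
  expect_lt(abs(mean(cs) - 0.5), 0.1)
})

test_that("gene ordering options control the wavelet pairing only", {
  fx <- reducer_fixture()
  r_wald <- fit_reducer(fx$x, fx$time, fx$event, method = "wavelet",
                        n_genes = 10, gene_order = "wald")
  r_abs <- fit_reducer(fx$x, fx$time, fx$event, method = "wavelet",
                       n_genes = 10, gene_order = "abs_wald")
  r_orig <- fit_reducer(fx$x, fx$time, fx$event, method = "wavelet",
                        n_genes = 10, gene_order = "original")
  expect_setequal(r_wald$genes, r_abs$genes)
  expect_setequal(r_wald$genes, r_orig$genes)
  expect_equal(r_wald$genes[order(r_wald$z, decreasing = TRUE)], r_wald$genes)
  expect_equal(r_abs$genes[order(abs(r_abs$z), decreasing = TRUE)],
               r_abs$genes)
  expect_false(is.unsorted(match(r_orig$genes, rownames(fx$x))))
})
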