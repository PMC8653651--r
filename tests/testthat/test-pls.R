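test_that("rmse implements the root-mean-square formula", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(1)
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(rmse(2 * y, 2 * yh), 2 * rmse(y, yh))
  expect_error(rmse(1:3, 1:4), "length")
  expect_error(rmse(numeric(), numeric()), "empty")
})

test_that("r_squared supports both definitions", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  expect_error(r_squared(rep(2, 5), y), "constant")
  # for least-squares fitted values the two definitions coincide;
  # for arbitrary predictions squared-Pearson is the larger
  set.seed(42)
  yr <- rnorm(50); yp <- 0.6 * yr + rnorm(50, sd = 0.5)
  fitted_vals <- fitted(lm(yr ~ yp))
  expect_equal(r_squared(yr, fitted_vals, "pearson"),
               r_squared(yr, fitted_vals, "one_minus_sse"))
  expect_gte(r_squared(yr, yp, "pearson"),
             r_squared(yr, yp, "one_minus_sse"))
})

test_that("PLS1 solves a rank-1 problem with one latent variable", {
  set.seed(7)
  t_scores <- rnorm(20)
  pvec <- rnorm(15)
  x <- t_scores %*% t(pvec)
  y <- t_scores
  m <- fit_pls(x, y, 1)
  expect_lt(rmse(y, predict(m, x)), 1e-8)
})

test_that("PLS at maximal latent variables reproduces ordinary least squares", {
  set.seed(3)
  x <- matrix(rnorm(30 * 5), 30, 5)
  y <- x %*% rnorm(5) + rnorm(30)
  m <- fit_pls(x, y, 5)
  ols <- unname(fitted(lm(y ~ x)))
  expect_lt(max(abs(predict(m, x) - ols)), 1e-6)
})

test_that("fit_pls is invariant to sample order", {
  d <- small_xy(5, n = 25, p = 12)
  m1 <- fit_pls(d$x, d$y, 4)
  perm <- sample(25)
  m2 <- fit_pls(d$x[perm, ], d$y[perm], 4)
  expect_lt(max(abs(m1$b - m2$b)), 1e-10)
})

test_that("fit_pls validates its inputs", {
  d <- small_xy(1, n = 10, p = 6)
  expect_error(fit_pls(d$x, d$y, 0), "nlvs")
  expect_error(fit_pls(d$x, d$y, 10), "nlvs")
  expect_error(fit_pls(d$x, rep(1, 10), 2), "zero variance")
  xm <- d$x; xm[1, 1] <- NA
  expect_error(fit_pls(xm, d$y, 2), "missing")
})

test_that("leave-one-out RMSECV matches a brute-force refit loop", {
  d <- small_xy(11, n = 20, p = 8)
  cv <- cross_validate(d$x, d$y, max_nlvs = 4, scheme = cv_loo())
  brute <- sapply(1:4, function(a) {
    preds <- sapply(1:20, function(i) {
      predict(fit_pls(d$x[-i, ], d$y[-i], a), d$x[i, , drop = FALSE])
    })
    rmse(d$y, preds)
  })
  expect_lt(max(abs(cv$rmsecv_by_nlv - brute)), 1e-10)
})

test_that("latent-variable ties break toward the smaller count", {
  expect_equal(ftirquant:::choose_nlvs(c(5, 3, 3, 4)), 2)
  expect_equal(ftirquant:::choose_nlvs(c(2, 2, 2)), 1)
})

test_that("k-fold folds are deterministic, stratified partitions", {
  y <- rep(seq(0, 100, by = 10), each = 4)
  f1 <- ftirquant:::cv_folds(cv_kfold(4, seed = 9), y)
  f2 <- ftirquant:::cv_folds(cv_kfold(4, seed = 9), y)
  expect_identical(f1, f2)
  idx <- unname(sort(unlist(f1)))
  expect_equal(idx, seq_along(y)) # a partition
  # stratification: every fold sees every level once
  for (f in f1) expect_equal(sort(y[f]), seq(0, 100, by = 10))
  expect_error(ftirquant:::cv_folds(cv_kfold(50), y), "infeasible")
})

test_that("noise-free two-component mixtures need two latent variables at most", {
  s <- simulate_spectra(default_design(), noise = noise_free(),
                        wavenumber = wavenumber_axis(373))
  cv <- cross_validate(s$absorbance, s$meta$fraction, max_nlvs = 2,
                       scheme = cv_loo())
  expect_lt(cv$rmsecv_by_nlv[2], 1e-6)
})

test_that("evaluate reports symmetric errors when test equals calibration", {
  s <- tiny_set()
  spec <- preprocessing_spec("snv", "none")
  fitted <- fit_preprocessor(spec, s)
  m <- apply_preprocessor(fitted, s$absorbance)
  model <- fit_pls(m, s$meta$fraction, 3)
  ev <- evaluate(model, fitted, s, s)
  expect_equal(ev$rmsep, ev$rmsec)
  expect_equal(ev$r2_cal, ev$r2_test)
  expect_equal(nrow(ev$predictions), 2 * n_samples(s))
  empty <- filter_samples(s, fraction > 1000)
  expect_error(evaluate(model, fitted, s, empty), "empty")
})

test_that("tidy and glance methods return well-formed tibbles", {
  d <- small_xy(2, n = 20, p = 10)
  m <- fit_pls(d$x, d$y, 3)
  expect_named(tidy(m), c("term", "index", "estimate"))
  expect_equal(nrow(tidy(m)), 10)
  cv <- cross_validate(d$x, d$y, max_nlvs = 3, scheme = cv_kfold(5, seed = 1))
  expect_equal(sum(tidy(cv)$chosen), 1)
  expect_equal(glance(cv)$chosen_nlvs, cv$chosen_nlvs)
})
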