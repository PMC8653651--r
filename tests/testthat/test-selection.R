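# One modest planted dataset shared by the selection tests.
sel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ps <- planted_set(seed = 11, n_points = 373, window = c(1150, 1350))
      sp <- split_train_test(ps$set, seed = 11)
      cache <<- list(x = sp$calibration$absorbance,
                     y = sp$calibration$meta$fraction,
                     win_idx = ps$win_idx, p = 373)
    }
    cache
  }
})

test_that("a single full-width window reproduces the full-spectrum model", {
  d <- small_xy(21, n = 25, p = 15)
  sch <- cv_kfold(5, seed = 2)
  mw <- mw_pls(d$x, d$y, widths = 15, scheme = sch, max_nlvs = 5)
  full <- cross_validate(d$x, d$y, max_nlvs = 5, scheme = sch)
  expect_equal(nrow(mw$windows), 1)
  expect_equal(mw$best$rmsecv, full$rmsecv)
  expect_equal(mw$selected, 1:15)
  expect_error(mw_pls(d$x, d$y, widths = 16), "widths")
  expect_error(mw_pls(d$x, d$y, widths = 1), "widths")
})

test_that("moving-window RMSECV matches hand-sliced cross_validate calls", {
  d <- small_xy(22, n = 25, p = 30)
  sch <- cv_kfold(5, seed = 3)
  mw <- mw_pls(d$x, d$y, widths = 5, scheme = sch, max_nlvs = 4)
  for (s in c(1, 7, 26)) {
    cv <- cross_validate(d$x[, s:(s + 4)], d$y, max_nlvs = 4, scheme = sch)
    expect_equal(mw$windows$rmsecv[mw$windows$start == s], cv$rmsecv)
  }
})

test_that("the moving window localizes a planted informative band", {
  fx <- sel_fixture()
  mw <- mw_pls(fx$x, fx$y, widths = 40, scheme = cv_kfold(5, seed = 1),
               max_nlvs = 8)
  overlap <- intersect(mw$selected, fx$win_idx)
  expect_gt(length(overlap), 0)
  expect_lt(length(mw$selected), fx$p)
})

test_that("MC-UVE stability is invariant to response scale", {
  fx <- sel_fixture()
  u1 <- mc_uve(fx$x, fx$y, n_runs = 50, nlvs = 4, seed = 5,
               cutoff_rule = "quantile_scan", scheme = cv_kfold(5, seed = 1))
  u2 <- mc_uve(fx$x, 3 * fx$y, n_runs = 50, nlvs = 4, seed = 5,
               cutoff_rule = "quantile_scan", scheme = cv_kfold(5, seed = 1))
  expect_lt(max(abs(u1$stability$s - u2$stability$s)), 1e-6)
})

test_that("degenerate resampling flags every channel", {
  fx <- sel_fixture()
  u <- mc_uve(fx$x[1:30, 1:40], fx$y[1:30], n_runs = 5,
              sampling_fraction = 1.0, nlvs = 3, seed = 1)
  expect_true(all(u$stability$flagged))
  expect_true(all(!is.finite(u$stability$s)))
})

test_that("MC-UVE separates planted channels and is seed-reproducible", {
  fx <- sel_fixture()
  u <- mc_uve(fx$x, fx$y, n_runs = 200, nlvs = 6, seed = 7,
              cutoff_rule = "quantile_scan", scheme = cv_kfold(5, seed = 1))
  s_abs <- abs(u$stability$s)
  expect_gt(mean(s_abs[fx$win_idx]), mean(s_abs[-fx$win_idx]))
  expect_lt(length(u$selected), fx$p)
  u2 <- mc_uve(fx$x, fx$y, n_runs = 200, nlvs = 6, seed = 7,
               cutoff_rule = "quantile_scan", scheme = cv_kfold(5, seed = 1))
  expect_identical(u$selected, u2$selected)
  expect_identical(u$cutoff, u2$cutoff)
})

test_that("the noise-augmented cut-off removes nearly everything on null data", {
  kept <- sapply(1:3, function(sd_) {
    set.seed(100 + sd_)
    x <- matrix(rnorm(60 * 120), 60, 120)
    y <- rnorm(60)
    u <- mc_uve(x, y, n_runs = 100, nlvs = 3, seed = sd_,
                cutoff_rule = "noise_augmented")
    length(u$selected) / 120
  })
  expect_lt(mean(kept), 0.05)
})

test_that("the quantile scan never loses to the no-cut-off baseline", {
  fx <- sel_fixture()
  u <- mc_uve(fx$x, fx$y, n_runs = 100, nlvs = 5, seed = 3,
              cutoff_rule = "quantile_scan", scheme = cv_kfold(5, seed = 1))
  baseline <- u$scan$rmsecv[u$scan$quantile == 0]
  expect_lte(min(u$scan$rmsecv), baseline)
})

test_that("iRF probabilities are exact acceptance frequencies", {
  fx <- sel_fixture()
  irf <- interval_random_frog(fx$x[, 1:60], fx$y, interval_width = 10,
                              n_iterations = 50, q0 = 3, seed = 2,
                              scheme = cv_kfold(5, seed = 1))
  expect_equal(irf$intervals$probability * irf$n_iterations,
               as.numeric(irf$intervals$n_j))
  expect_true(all(irf$intervals$probability >= 0 &
                    irf$intervals$probability <= 1))
  expect_true(all(irf$intervals$n_j <= irf$n_iterations))
  # one interval per channel, edge intervals truncated and flagged
  expect_equal(nrow(irf$intervals), 60)
  expect_true(all(irf$intervals$truncated[c(1, 60)]))
  w <- irf$intervals$end - irf$intervals$start + 1
  expect_true(all(w[irf$intervals$truncated] < 10))
  expect_true(all(w[!irf$intervals$truncated] == 10))
})

test_that("iRF is reproducible under one seed and finds the planted band", {
  fx <- sel_fixture()
  a <- interval_random_frog(fx$x, fx$y, n_iterations = 300, seed = 4,
                            scheme = cv_kfold(5, seed = 1))
  b <- interval_random_frog(fx$x, fx$y, n_iterations = 300, seed = 4,
                            scheme = cv_kfold(5, seed = 1))
  expect_identical(a$intervals, b$intervals)
  pj <- a$intervals$probability
  inwin <- a$intervals$start <= max(fx$win_idx) &
    a$intervals$end >= min(fx$win_idx)
  expect_gt(mean(pj[inwin]), mean(pj[!inwin]))
})

test_that("interval selection ranks by probability and minimizes RMSECV", {
  fx <- sel_fixture()
  # crafted result: a single certain interval must be returned verbatim
  iv <- ftirquant:::irf_intervals(fx$p, 20)
  iv$n_j <- 0L; iv$probability <- 0
  iv$n_j[200] <- 100L; iv$probability[200] <- 1
  crafted <- structure(list(intervals = iv, n_iterations = 100L,
                            config = list()), class = "irf_result")
  vars <- select_intervals_by_probability(crafted, fx$x, fx$y,
                                          scheme = cv_kfold(5, seed = 1))
  expect_equal(as.integer(vars), seq(iv$start[200], iv$end[200]))

  iv0 <- iv; iv0$n_j[] <- 0L; iv0$probability[] <- 0
  none <- structure(list(intervals = iv0, n_iterations = 100L,
                         config = list()), class = "irf_result")
  expect_error(select_intervals_by_probability(none, fx$x, fx$y),
               "n_iterations")

  # the scan's argmin is what gets returned
  irf <- interval_random_frog(fx$x, fx$y, n_iterations = 200, seed = 9,
                              scheme = cv_kfold(5, seed = 1))
  sel <- select_intervals_by_probability(irf, fx$x, fx$y,
                                         scheme = cv_kfold(5, seed = 1))
  scan <- attr(sel, "scan")
  expect_equal(attr(sel, "k"), scan$k[which.min(scan$rmsecv)])
})

test_that("infeasible interval widths are rejected", {
  fx <- sel_fixture()
  expect_error(interval_random_frog(fx$x[, 1:10], fx$y, interval_width = 11),
               "exceeds")
  expect_error(interval_random_frog(fx$x, fx$y, interval_width = 1), ">= 2")
})
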