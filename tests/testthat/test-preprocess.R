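test_that("SNV centers and scales each spectrum with sample sd", {
  expect_equal(snv(rbind(c(1, 2, 3)))[1, ], c(-1, 0, 1))
  set.seed(1)
  x <- matrix(rnorm(5 * 40, sd = 3), 5, 40) + 2
  z <- snv(x)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  expect_equal(snv(z), z) # idempotent
  xc <- x; xc[3, ] <- 5; rownames(xc) <- paste0("S", 1:5)
  expect_error(snv(xc), "S3")
})

test_that("MSC inverts per-spectrum linear scatter against the reference", {
  ref <- sin(seq(0, 3, length.out = 60)) + 2
  cal <- rbind(ref + rnorm(60, sd = 1e-3), ref - rnorm(60, sd = 1e-3))
  fit <- fit_msc(rbind(ref, ref))
  # the reference itself is a fixed point (a = 1, b = 0)
  expect_equal(apply_msc(fit, rbind(ref))[1, ], ref)
  # x = 2 ref + 5 is recovered exactly
  expect_lt(max(abs(apply_msc(fit, rbind(2 * ref + 5))[1, ] - ref)), 1e-10)
  # corrected calibration spectra regress on the reference with slope 1
  fit2 <- fit_msc(cal)
  corr <- apply_msc(fit2, cal)
  for (i in 1:2) {
    co <- coef(lm(corr[i, ] ~ fit2$reference))
    expect_lt(abs(co[2] - 1), 1e-10)
    expect_lt(abs(co[1]), 1e-10)
  }
  expect_error(apply_msc(list(), rbind(ref)), "unfitted")
})

test_that("Savitzky-Golay derivatives are exact on low-degree polynomials", {
  wn <- wavenumber_axis(201, 1000, 3000) # descending grid
  x <- rbind(rep(1, 201), wn^2, 0.5 * wn^3 - wn^2 + 4)
  d1 <- sg_derivative(x, wn, derivative = 1, window = 15, polyorder = 3)
  interior <- !attr(d1, "edge")
  expect_equal(sum(!interior), 14)
  expect_lt(max(abs(d1[1, ])), 1e-10)                       # constant -> 0
  expect_lt(max(abs(d1[2, interior] - 2 * wn[interior])) /
              max(abs(2 * wn)), 1e-8)                       # quadratic
  # smoothing (derivative 0) reproduces a cubic at interior points
  d0 <- sg_derivative(x, wn, derivative = 0, window = 15, polyorder = 3)
  expect_lt(max(abs(d0[3, interior] - x[3, interior])) / max(abs(x[3, ])), 1e-10)

  expect_error(sg_derivative(x, wn, window = 203), "exceeds")
  expect_error(sg_derivative(x, wn, window = 14), "odd")
  wn_bad <- wn; wn_bad[5] <- wn_bad[5] + 1
  expect_error(sg_derivative(x, wn_bad), "uniformly spaced")
})

test_that("the chain factory enumerates nine distinct named chains", {
  chains <- standard_chains()
  expect_length(chains, 9)
  expect_equal(anyDuplicated(names(chains)), 0)
  expect_true(all(c("Original", "SNV+first derivative",
                    "MSC+second derivative") %in% names(chains)))
  expect_equal(chain_name(chain_by_name("SNV+first derivative")),
               "SNV+first derivative")
  expect_error(chain_by_name("Detrend"), "unknown chain")
})

test_that("chains compose scatter-then-derivative and pass identity through", {
  s <- tiny_set()
  idn <- apply_chain(preprocessing_spec("none", "none"), s)
  expect_equal(idn$calibration$absorbance, s$absorbance, ignore_attr = TRUE)

  got <- apply_chain(preprocessing_spec("snv", "first"), s)
  manual <- sg_derivative(snv(s$absorbance), s$wavenumber,
                          derivative = 1, window = 15, polyorder = 3)
  expect_equal(got$calibration$absorbance, manual, ignore_attr = TRUE)
})

test_that("test-set transforms never read test-set statistics", {
  cal <- tiny_set(seed = 1)
  tst <- tiny_set(seed = 2)
  for (nm in c("MSC", "SNV+first derivative", "MSC+second derivative")) {
    fitted <- fit_preprocessor(chain_by_name(nm), cal)
    batch <- apply_preprocessor(fitted, tst$absorbance)
    one_by_one <- t(sapply(seq_len(n_samples(tst)), function(i) {
      apply_preprocessor(fitted, tst$absorbance[i, , drop = FALSE])[1, ]
    }))
    expect_equal(one_by_one, batch, ignore_attr = TRUE)
  }
})

test_that("invalid pretreatment settings are rejected", {
  expect_error(preprocessing_spec(sg_window = 14), "odd")
  expect_error(preprocessing_spec("snv", "second", sg_polyorder = 1),
               "derivative order")
})
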