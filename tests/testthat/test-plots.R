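test_that("autoplot methods return ggplot objects for every result type", {
  ps <- planted_set(seed = 2, n_points = 187)
  sp <- split_train_test(ps$set, seed = 2)
  x <- sp$calibration$absorbance
  y <- sp$calibration$meta$fraction
  sch <- cv_kfold(5, seed = 1)

  expect_s3_class(autoplot(ps$set), "ggplot")

  cv <- cross_validate(x, y, max_nlvs = 5, scheme = sch)
  expect_s3_class(autoplot(cv), "ggplot")

  mw <- mw_pls(x, y, widths = 20, scheme = sch, max_nlvs = 4)
  expect_s3_class(autoplot(mw), "ggplot")

  uve <- mc_uve(x, y, n_runs = 40, nlvs = 3, seed = 1, scheme = sch)
  expect_s3_class(autoplot(uve), "ggplot")
  expect_s3_class(autoplot(uve, wavenumber = ps$set$wavenumber), "ggplot")

  irf <- interval_random_frog(x, y, n_iterations = 50, seed = 1, scheme = sch)
  expect_s3_class(autoplot(irf), "ggplot")

  fitted <- fit_preprocessor(preprocessing_spec("snv", "none"), sp$calibration)
  m <- apply_preprocessor(fitted, x)
  model <- fit_pls(m, y, 3)
  ev <- evaluate(model, fitted, sp$calibration, sp$test)
  expect_s3_class(autoplot(ev), "ggplot")
})
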