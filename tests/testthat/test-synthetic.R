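test_that("generate_component evaluates band sums correctly", {
  wn <- wavenumber_axis(361, 400, 4000)
  empty <- component_profile("e", tibble::tibble(
    center = numeric(), amplitude = numeric(), width = numeric(),
    shape = character()))
  expect_equal(generate_component(empty, wn), rep(0, length(wn)))

  # apex of a unit gaussian lands exactly on an on-grid center
  wn2 <- wavenumber_axis(3601, 400, 4000) # grid step 1: 1027 is on-grid
  g <- component_profile("g", tibble::tibble(
    center = 1027, amplitude = 1, width = 10, shape = "gaussian"))
  expect_equal(generate_component(g, wn2)[wn2 == 1027], 1.0)

  # additivity: two-band profile equals the sum of single-band evaluations
  b1 <- tibble::tibble(center = 1027, amplitude = 0.7, width = 12,
                       shape = "gaussian")
  b2 <- tibble::tibble(center = 2900, amplitude = 0.4, width = 30,
                       shape = "lorentzian")
  two <- generate_component(component_profile("t", rbind(b1, b2)), wn)
  sep <- generate_component(component_profile("a", b1), wn) +
    generate_component(component_profile("b", b2), wn)
  expect_equal(two, sep)

  bad <- component_profile("x", tibble::tibble(
    center = 8000, amplitude = 1, width = 10, shape = "gaussian"))
  expect_error(generate_component(bad, wn), "8000")
})

test_that("the default design matches the 210-sample mixture layout", {
  d <- default_design()
  expect_length(d$levels, 19)
  expect_equal(d$levels, seq(5, 95, by = 5))
  expect_equal(length(d$levels) * d$reps_per_level, 190)
  expect_equal(design_size(d), 210)
})

test_that("noise-free mixing is exact Beer-Lambert interpolation", {
  wn <- wavenumber_axis(301)
  pr <- default_profiles()
  s <- simulate_spectra(mixture_design(c(30, 60), 2, 1, 1),
                        noise = noise_free(), wavenumber = wn)
  pure_t <- generate_component(pr$target, wn)
  pure_a <- generate_component(pr$adulterant, wn)
  # fraction 0 sample is exactly the pure target
  expect_equal(unname(s$absorbance[s$meta$fraction == 0, , drop = FALSE][1, ]),
               pure_t)
  # 30 % sample is the exact convex combination
  expect_equal(unname(s$absorbance[s$meta$fraction == 30, , drop = FALSE][1, ]),
               0.3 * pure_a + 0.7 * pure_t)
})

test_that("simulated labels follow the design and stay in bounds", {
  s <- simulate_spectra(default_design(), wavenumber = wavenumber_axis(187))
  fr <- s$meta$fraction
  expect_true(all(fr >= 0 & fr <= 100))
  tab <- table(fr[fr > 0 & fr < 100])
  expect_equal(unname(c(tab)), rep(10, 19))
  expect_equal(sum(fr == 0), 10)
  expect_equal(sum(fr == 100), 10)
})

test_that("least squares on the pure spectra recovers the mixing fraction", {
  wn <- wavenumber_axis(373)
  pr <- default_profiles()
  s <- simulate_spectra(default_design(), noise = noise_free(),
                        wavenumber = wn)
  basis <- cbind(generate_component(pr$target, wn),
                 generate_component(pr$adulterant, wn))
  rec <- apply(s$absorbance, 1, function(r) {
    co <- qr.solve(basis, r)
    100 * co[2] / sum(co)
  })
  expect_lt(max(abs(rec - s$meta$fraction)), 1e-8)
})

test_that("simulation is bit-identical under one seed and seed-sensitive", {
  wn <- wavenumber_axis(151)
  a <- simulate_spectra(default_design(), noise = noise_model(seed = 7),
                        wavenumber = wn)
  b <- simulate_spectra(default_design(), noise = noise_model(seed = 7),
                        wavenumber = wn)
  c <- simulate_spectra(default_design(), noise = noise_model(seed = 8),
                        wavenumber = wn)
  expect_identical(a$absorbance, b$absorbance)
  expect_false(identical(a$absorbance, c$absorbance))
})

test_that("growing the design never perturbs existing samples", {
  wn <- wavenumber_axis(151)
  small <- simulate_spectra(mixture_design(c(20, 50), 3, 2, 2),
                            noise = noise_model(seed = 3), wavenumber = wn)
  big <- simulate_spectra(mixture_design(c(20, 35, 50), 4, 2, 3),
                          noise = noise_model(seed = 3), wavenumber = wn)
  key <- function(s) paste(s$meta$fraction,
                           ave(s$meta$fraction, s$meta$fraction, FUN = seq_along))
  ks <- key(small); kb <- key(big)
  shared <- intersect(ks, kb)
  expect_gt(length(shared), 0)
  expect_equal(small$absorbance[match(shared, ks), ],
               big$absorbance[match(shared, kb), ],
               ignore_attr = TRUE)
})

test_that("noise-free spectra are linear in the fraction with a fixed direction", {
  wn <- wavenumber_axis(201)
  s <- simulate_spectra(mixture_design(c(10, 20, 40, 80), 1, 1, 0),
                        noise = noise_free(), wavenumber = wn)
  base <- s$absorbance[s$meta$fraction == 0, ]
  dirs <- sapply(c(10, 20, 40, 80), function(cc) {
    (s$absorbance[s$meta$fraction == cc, ] - base) / cc
  })
  expect_lt(max(abs(dirs - dirs[, 1])), 1e-12)
})

test_that("planted profiles confine between-class variance to the window", {
  n_points <- 747
  wn <- wavenumber_axis(n_points)
  pp <- planted_profiles(wn, c(1150, 1350))
  diff <- generate_component(pp$adulterant, wn) -
    generate_component(pp$target, wn)
  inside <- wn >= 1150 & wn <= 1350
  expect_lt(sum(diff[!inside]^2) / sum(diff^2), 1e-6)
})

test_that("invalid noise and design parameters are rejected", {
  expect_error(noise_model(additive_sd = -1), "must be >= 0")
  expect_error(mixture_design(c(0, 50), 2), "strictly inside")
  expect_error(mixture_design(c(50, 100), 2), "strictly inside")
})
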