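#' Mid-infrared wavenumber axis
#'
#' Builds an evenly spaced wavenumber axis in canonical descending order. The
#' default mirrors a 4 cm^-1-resolution MIR acquisition: 7467 points spanning
#' 400-4000 cm^-1. Axis length is a parameter throughout the package; reduced
#' axes (e.g. 747 points) keep every algorithm exercised at a fraction of the
#' cost.
#'
#' @param n_points Number of points (>= 2).
#' @param wn_min,wn_max Axis limits in cm^-1.
#' @return Numeric vector of wavenumbers, descending.
#' @export
wavenumber_axis <- function(n_points = 7467, wn_min = 400, wn_max = 4000) {
  n_points <- as.integer(n_points)
  if (n_points < 2) rlang::abort("`n_points` must be >= 2.")
  if (!(wn_min < wn_max)) rlang::abort("`wn_min` must be < `wn_max`.")
  seq(wn_max, wn_min, length.out = n_points)
}

#' Component absorption profile
#'
#' Describes the noise-free absorbance spectrum of one pure powder as a sum of
#' band shapes: each band has a center (cm^-1), an apex amplitude (absorbance
#' units), a full width at half maximum (cm^-1) and a shape (`"gaussian"` or
#' `"lorentzian"`). An optional broad background band models the O-H envelope.
#'
#' @param name Component name.
#' @param bands Data frame with columns `center`, `amplitude`, `width`,
#'   `shape`.
#' @param background Optional numeric `c(center, amplitude, width)` for a broad
#'   gaussian envelope.
#' @return A `component_profile` object.
#' @export
component_profile <- function(name, bands, background = NULL) {
  bands <- tibble::as_tibble(bands)
  need <- c("center", "amplitude", "width", "shape")
  if (!all(need %in% names(bands))) {
    rlang::abort("`bands` needs columns center, amplitude, width, shape.")
  }
  if (any(bands$amplitude < 0)) rlang::abort("band amplitudes must be >= 0.")
  if (any(bands$width <= 0)) rlang::abort("band widths must be > 0.")
  if (!all(bands$shape %in% c("gaussian", "lorentzian"))) {
    rlang::abort("band shape must be 'gaussian' or 'lorentzian'.")
  }
  if (!is.null(background)) {
    stopifnot(length(background) == 3, background[3] > 0, background[2] >= 0)
  }
  structure(list(name = name, bands = bands, background = background),
            class = "component_profile")
}

#' @export
print.component_profile <- function(x, ...) {
  cat(sprintf("<component_profile> %s: %d bands%s\n", x$name, nrow(x$bands),
              if (is.null(x$background)) "" else " + broad background"))
  invisible(x)
}

band_shape <- function(wn, center, amplitude, width, shape) {
  if (shape == "gaussian") {
    amplitude * exp(-4 * log(2) * ((wn - center) / width)^2)
  } else {
    amplitude * (width / 2)^2 / ((wn - center)^2 + (width / 2)^2)
  }
}

#' Evaluate a component profile on an axis
#'
#' Deterministic, noise-free sum of the profile's band shapes.
#'
#' @param profile A [component_profile()].
#' @param wavenumber Wavenumber axis (cm^-1).
#' @return Numeric absorbance vector, one value per axis point.
#' @export
generate_component <- function(profile, wavenumber) {
  rng <- range(wavenumber)
  out <- numeric(length(wavenumber))
  if (nrow(profile$bands) > 0) {
    bad <- profile$bands$center < rng[1] | profile$bands$center > rng[2]
    if (any(bad)) {
      rlang::abort(sprintf(
        "band center(s) outside axis range [%g, %g]: %s cm^-1",
        rng[1], rng[2], paste(profile$bands$center[bad], collapse = ", ")
      ))
    }
    for (i in seq_len(nrow(profile$bands))) {
      b <- profile$bands[i, ]
      out <- out + band_shape(wavenumber, b$center, b$amplitude, b$width, b$shape)
    }
  }
  if (!is.null(profile$background)) {
    bg <- profile$background
    out <- out + band_shape(wavenumber, bg[1], bg[2], bg[3], "gaussian")
  }
  out
}

# Shared band table for the two default components. Centers follow the
# characteristic MIR absorptions of dried plant polysaccharide/cellulose
# powders: O-H envelope 3600-3000, alkyl C-H 2917/2850, C-O stretches
# 1732/1604/1371/1318, CH2 1417, C-O-C 1027, C-H bend 808 cm^-1. Amplitudes
# are generator configuration, not measurements.
default_band_centers <- function() {
  c(2917, 2850, 1732, 1604, 1417, 1371, 1318, 1027, 808)
}

#' Default pure-component profiles
#'
#' Two profiles sharing the characteristic band centers of dried botanical
#' powders but differing in relative band amplitudes, plus an adulterant-only
#' shoulder near 1604 cm^-1. Raw mixtures therefore look alike by eye while
#' remaining linearly separable, which is the regime the calibration workflow
#' is built for.
#'
#' @return Named list with elements `target` and `adulterant`.
#' @export
default_profiles <- function() {
  centers <- default_band_centers()
  widths <- c(40, 40, 30, 45, 30, 25, 25, 60, 35)
  amp_t <- c(0.32, 0.22, 0.12, 0.25, 0.10, 0.11, 0.09, 0.85, 0.10)
  amp_a <- c(0.26, 0.27, 0.19, 0.16, 0.13, 0.08, 0.13, 0.70, 0.16)
  shapes <- rep(c("gaussian", "lorentzian"), length.out = length(centers))
  target <- component_profile(
    "target",
    tibble::tibble(center = centers, amplitude = amp_t, width = widths,
                   shape = shapes),
    background = c(3300, 0.45, 520)
  )
  adulterant <- component_profile(
    "adulterant",
    tibble::tibble(
      center = c(centers, 1580),
      amplitude = c(amp_a, 0.12),
      width = c(widths, 28),
      shape = c(shapes, "gaussian")
    ),
    background = c(3310, 0.40, 540)
  )
  list(target = target, adulterant = adulterant)
}

#' Profiles differing only inside a planted window
#'
#' Builds a pair of component profiles that are identical except for one
#' gaussian band centered inside `window` (a wavenumber interval, cm^-1).
#' Noise-free between-class spectral variance is then confined to that window,
#' giving wavelength-selection algorithms a known ground truth to recover.
#'
#' @param wavenumber Axis the profiles will be evaluated on.
#' @param window Length-2 numeric, wavenumber bounds of the informative band.
#' @param amplitude Apex amplitude of the planted difference band.
#' @return List with `target`, `adulterant` and the `window` (sorted).
#' @export
planted_profiles <- function(wavenumber, window, amplitude = 0.5) {
  window <- sort(window)
  shared <- tibble::tibble(
    center = c(3300, 2900, 2000, 1400, 900, 600),
    amplitude = c(0.40, 0.30, 0.15, 0.25, 0.60, 0.20),
    width = c(400, 60, 80, 50, 90, 40),
    shape = "gaussian"
  )
  shared <- shared[shared$center >= min(wavenumber) &
                     shared$center <= max(wavenumber), ]
  center <- mean(window)
  width <- diff(window) / 6 # +-3 FWHM inside the window: tails are negligible
  target <- component_profile("target", shared)
  adulterant <- component_profile(
    "adulterant",
    dplyr::bind_rows(shared, tibble::tibble(
      center = center, amplitude = amplitude, width = width, shape = "gaussian"
    ))
  )
  list(target = target, adulterant = adulterant, window = window)
}

#' Two-component mixture design
#'
#' @param levels Adulterant fractions in % w/w, each strictly inside (0, 100).
#' @param reps_per_level Replicates per level.
#' @param n_pure_target,n_pure_adulterant Counts of pure-component samples
#'   (fractions 0 and 100).
#' @return A `mixture_design` object.
#' @export
mixture_design <- function(levels, reps_per_level,
                           n_pure_target = 0, n_pure_adulterant = 0) {
  levels <- as.numeric(levels)
  if (any(levels <= 0 | levels >= 100)) {
    rlang::abort("mixture levels must lie strictly inside (0, 100) % w/w.")
  }
  if (anyDuplicated(levels)) rlang::abort("mixture levels must be distinct.")
  structure(
    list(levels = sort(levels), reps_per_level = as.integer(reps_per_level),
         n_pure_target = as.integer(n_pure_target),
         n_pure_adulterant = as.integer(n_pure_adulterant)),
    class = "mixture_design"
  )
}

#' The default 210-sample mixture design
#'
#' Nineteen adulteration levels, 5 to 95 % w/w in steps of 5, with ten
#' replicates each (190 adulterated samples), plus ten pure-target and ten
#' pure-adulterant samples: 210 in total.
#'
#' @return A [mixture_design()].
#' @export
default_design <- function() {
  mixture_design(seq(5, 95, by = 5), reps_per_level = 10,
                 n_pure_target = 10, n_pure_adulterant = 10)
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf(
    "<mixture_design> %d levels x %d reps + %d pure target + %d pure adulterant = %d samples\n",
    length(x$levels), x$reps_per_level, x$n_pure_target, x$n_pure_adulterant,
    design_size(x)
  ))
  invisible(x)
}

#' @rdname mixture_design
#' @param x A `mixture_design`.
#' @export
design_size <- function(x) {
  length(x$levels) * x$reps_per_level + x$n_pure_target + x$n_pure_adulterant
}

#' Measurement-artifact model for simulated spectra
#'
#' Distortions applied on top of the noise-free Beer-Lambert mixture: a
#' per-sample multiplicative gain `1 + a` (scatter), an additive offset, a
#' smooth random polynomial baseline, and white noise per channel. All
#' standard deviations are in absorbance units except the dimensionless
#' multiplicative slope.
#'
#' @param additive_sd White-noise sd per channel.
#' @param multiplicative_slope_sd Sd of the scatter gain deviation `a`.
#' @param offset_sd Sd of the constant offset.
#' @param baseline_poly_degree Degree of the random baseline polynomial.
#' @param baseline_coeff_sd Sd of each baseline polynomial coefficient.
#' @param seed Integer seed; all draws derive from it via per-sample
#'   substreams keyed on (level, replicate).
#' @return A `noise_model` object.
#' @export
noise_model <- function(additive_sd = 0.002, multiplicative_slope_sd = 0.05,
                        offset_sd = 0.01, baseline_poly_degree = 2,
                        baseline_coeff_sd = 0.005, seed = 1L) {
  sds <- c(additive_sd, multiplicative_slope_sd, offset_sd, baseline_coeff_sd)
  if (any(sds < 0)) rlang::abort("noise standard deviations must be >= 0.")
  structure(
    list(additive_sd = additive_sd,
         multiplicative_slope_sd = multiplicative_slope_sd,
         offset_sd = offset_sd,
         baseline_poly_degree = as.integer(baseline_poly_degree),
         baseline_coeff_sd = baseline_coeff_sd,
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' @rdname noise_model
#' @return `noise_free()`: a model with every sd equal to zero.
#' @export
noise_free <- function(seed = 1L) {
  noise_model(0, 0, 0, 2, 0, seed = seed)
}

# Substream seed for one sample, keyed on (fraction level, replicate) so that
# enlarging the design never perturbs existing samples. Kept below 2^31.
sample_substream <- function(seed, fraction, rep) {
  key <- round(fraction * 100) * 101 + rep # double arithmetic: no overflow
  as.integer((as.numeric(seed) + 7919 * key) %% 2147483629)
}

#' Simulate a labelled mixture spectra set
#'
#' Each sample with adulterant fraction `c` (% w/w) has the noise-free
#' spectrum `(c/100) * adulterant + (1 - c/100) * target` (Beer-Lambert linear
#' mixing of the pure-component profiles), to which the [noise_model()]
#' distortions are applied: `x = (1 + a) * clean + b + baseline(wn) + eps`.
#' Randomness is drawn from per-sample substreams of the model seed, so the
#' output is bit-identical under a fixed seed and unchanged for existing
#' samples when the design grows.
#'
#' @param design A [mixture_design()].
#' @param target,adulterant [component_profile()]s of the pure components.
#' @param noise A [noise_model()].
#' @param wavenumber Wavenumber axis; defaults to the full 7467-point axis.
#' @return A [spectra_set()] whose metadata carries the true fraction; all
#'   samples start `"unassigned"`.
#' @examples
#' s <- simulate_spectra(default_design(), wavenumber = wavenumber_axis(373))
#' glance(s)
#' @export
simulate_spectra <- function(design,
                             target = default_profiles()$target,
                             adulterant = default_profiles()$adulterant,
                             noise = noise_model(),
                             wavenumber = wavenumber_axis()) {
  stopifnot(inherits(design, "mixture_design"), inherits(noise, "noise_model"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  pure_t <- generate_component(target, wavenumber)
  pure_a <- generate_component(adulterant, wavenumber)
  fractions <- c(
    rep(0, design$n_pure_target),
    rep(design$levels, each = design$reps_per_level),
    rep(100, design$n_pure_adulterant)
  )
  reps <- c(
    seq_len(design$n_pure_target),
    rep(seq_len(design$reps_per_level), times = length(design$levels)),
    seq_len(design$n_pure_adulterant)
  )
  p <- length(wavenumber)
  u <- seq(-1, 1, length.out = p) # scaled axis for the baseline polynomial
  X <- matrix(0, nrow = length(fractions), ncol = p)
  for (i in seq_along(fractions)) {
    c_i <- fractions[i]
    clean <- (c_i / 100) * pure_a + (1 - c_i / 100) * pure_t
    set.seed(sample_substream(noise$seed, c_i, reps[i]))
    a <- stats::rnorm(1, 0, noise$multiplicative_slope_sd)
    b <- stats::rnorm(1, 0, noise$offset_sd)
    coef <- stats::rnorm(noise$baseline_poly_degree, 0, noise$baseline_coeff_sd)
    baseline <- numeric(p)
    for (d in seq_len(noise$baseline_poly_degree)) {
      baseline <- baseline + coef[d] * u^d
    }
    eps <- stats::rnorm(p, 0, noise$additive_sd)
    X[i, ] <- (1 + a) * clean + b + baseline + eps
  }
  ids <- sprintf("S%03d", seq_along(fractions))
  rownames(X) <- ids
  spectra_set(wavenumber, X,
              tibble::tibble(id = ids, fraction = fractions,
                             subset = "unassigned"))
}
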