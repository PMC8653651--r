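#' Standard normal variate transform
#'
#' Centers and scales every spectrum (row) to mean 0 and unit spread, using
#' the sample (n-1) standard deviation — the common chemometric convention;
#' a population-sd variant would change the numbers slightly.
#'
#' @param x Numeric matrix, samples x wavenumbers (rows with >= 2 points).
#' @return Matrix of the same shape; each row has mean 0 and sd 1.
#' @export
snv <- function(x) {
  x <- as_spectra_matrix(x)
  if (ncol(x) < 2) rlang::abort("SNV needs spectra with at least 2 points.")
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  zero <- s < .Machine$double.eps
  if (any(zero)) {
    who <- rownames(x)[zero]
    if (is.null(who)) who <- which(zero)
    rlang::abort(sprintf("constant spectrum (sd = 0) for sample(s): %s",
                         paste(who, collapse = ", ")))
  }
  (x - m) / s
}

#' Multiplicative scatter correction
#'
#' `fit_msc()` stores the mean calibration spectrum as the reference;
#' `apply_msc()` regresses each spectrum `x` on the reference
#' (`x ~ a * ref + b`, ordinary least squares) and returns `(x - b) / a`.
#' Fitting on the calibration set only and reusing the stored reference for
#' test spectra prevents test-set leakage.
#'
#' @param x Numeric matrix of calibration spectra (>= 2 rows).
#' @return `fit_msc()`: an `msc_fit` holding the reference spectrum.
#' @export
fit_msc <- function(x) {
  x <- as_spectra_matrix(x)
  if (nrow(x) < 2) rlang::abort("MSC needs at least 2 calibration spectra.")
  structure(list(reference = colMeans(x)), class = "msc_fit")
}

#' @rdname fit_msc
#' @param fit An `msc_fit` from [fit_msc()].
#' @param new Matrix of spectra to correct.
#' @return `apply_msc()`: the corrected matrix.
#' @export
apply_msc <- function(fit, new) {
  if (!inherits(fit, "msc_fit")) {
    rlang::abort("`fit` must come from fit_msc(); the preprocessor is unfitted.")
  }
  new <- as_spectra_matrix(new)
  ref <- fit$reference
  if (ncol(new) != length(ref)) {
    rlang::abort("spectra and MSC reference have different channel counts.")
  }
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  out <- new
  for (i in seq_len(nrow(new))) {
    xi <- new[i, ]
    a <- sum((xi - mean(xi)) * rc) / denom
    b <- mean(xi) - a * mean(ref)
    if (abs(a) < 1e-12) {
      rlang::abort(sprintf("MSC slope ~ 0 for sample %s; cannot invert.",
                           rownames(new)[i] %||% i))
    }
    out[i, ] <- (xi - b) / a
  }
  out
}

#' Savitzky-Golay smoothing derivative
#'
#' Local-polynomial convolution derivative of each spectrum with respect to
#' wavenumber, scaled by the axis spacing so the output is per cm^-1 (the
#' descending canonical axis has negative spacing, which carries the correct
#' sign). Edge points are computed with one-sided fits and flagged in the
#' `"edge"` attribute rather than dropped.
#'
#' @param x Numeric matrix, samples x wavenumbers.
#' @param wavenumber Uniformly spaced axis (relative tolerance 1e-6).
#' @param derivative Derivative order (0 = smoothing only).
#' @param window Odd window length in points (default 15).
#' @param polyorder Polynomial order; must exceed `derivative` and be less
#'   than `window`.
#' @return Matrix of derivatives with a logical `"edge"` attribute marking the
#'   one-sided (window/2) points at each end.
#' @export
sg_derivative <- function(x, wavenumber, derivative = 1, window = 15,
                          polyorder = 3) {
  x <- as_spectra_matrix(x)
  p <- ncol(x)
  if (length(wavenumber) != p) rlang::abort("axis length does not match spectra.")
  if (window %% 2 != 1) rlang::abort("`window` must be odd.")
  if (window > p) rlang::abort("`window` exceeds the number of spectral points.")
  if (polyorder >= window) rlang::abort("`polyorder` must be < `window`.")
  if (derivative > polyorder) rlang::abort("`derivative` must be <= `polyorder`.")
  d <- diff(wavenumber)
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
    rlang::abort("Savitzky-Golay needs a uniformly spaced axis.")
  }
  out <- t(apply(x, 1, function(row) {
    signal::sgolayfilt(row, p = polyorder, n = window, m = derivative, ts = d[1])
  }))
  dimnames(out) <- dimnames(x)
  half <- (window - 1) / 2
  edge <- rep(FALSE, p)
  edge[c(seq_len(half), p - seq_len(half) + 1)] <- TRUE
  attr(out, "edge") <- edge
  out
}

#' Pretreatment chain specification
#'
#' A chain applies an optional scatter correction (SNV or MSC) first, then an
#' optional Savitzky-Golay derivative — the order implied by the conventional
#' naming "SNV + first derivative". The nine standard chains (raw spectrum
#' plus the eight combinations) are enumerated by [standard_chains()].
#'
#' @param scatter One of `"none"`, `"msc"`, `"snv"`.
#' @param derivative One of `"none"`, `"first"`, `"second"`.
#' @param sg_window Savitzky-Golay window in points (odd, default 15).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3, supporting
#'   both derivative orders with one setting).
#' @return A `preprocessing_spec`.
#' @export
preprocessing_spec <- function(scatter = c("none", "msc", "snv"),
                               derivative = c("none", "first", "second"),
                               sg_window = 15, sg_polyorder = 3) {
  scatter <- match.arg(scatter)
  derivative <- match.arg(derivative)
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    rlang::abort("`sg_window` must be odd and > `sg_polyorder`.")
  }
  dord <- c(none = 0L, first = 1L, second = 2L)[[derivative]]
  if (dord > sg_polyorder) {
    rlang::abort("derivative order must be <= `sg_polyorder`.")
  }
  structure(
    list(scatter = scatter, derivative = derivative,
         sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder)),
    class = "preprocessing_spec"
  )
}

#' @export
print.preprocessing_spec <- function(x, ...) {
  cat("<preprocessing_spec>", chain_name(x), "\n")
  invisible(x)
}

#' @rdname preprocessing_spec
#' @param spec A `preprocessing_spec`.
#' @return `chain_name()`: the conventional display name (e.g.
#'   `"SNV+first derivative"`).
#' @export
chain_name <- function(spec) {
  sc <- c(none = "", msc = "MSC", snv = "SNV")[[spec$scatter]]
  dv <- c(none = "", first = "first derivative",
          second = "second derivative")[[spec$derivative]]
  if (sc == "" && dv == "") return("Original")
  if (sc == "") return(paste0(toupper(substring(dv, 1, 1)), substring(dv, 2)))
  if (dv == "") return(sc)
  paste0(sc, "+", dv)
}

#' The nine standard pretreatment chains
#'
#' Raw spectrum plus MSC, SNV, first and second derivative, and the four
#' scatter-plus-derivative combinations.
#'
#' @param sg_window,sg_polyorder Savitzky-Golay settings shared by all chains.
#' @return Named list of nine [preprocessing_spec()]s.
#' @export
standard_chains <- function(sg_window = 15, sg_polyorder = 3) {
  combos <- expand.grid(scatter = c("none", "msc", "snv"),
                        derivative = c("none", "first", "second"),
                        stringsAsFactors = FALSE)
  specs <- purrr::pmap(combos, function(scatter, derivative) {
    preprocessing_spec(scatter, derivative, sg_window, sg_polyorder)
  })
  names(specs) <- purrr::map_chr(specs, chain_name)
  specs[order(match(names(specs), c(
    "Original", "MSC", "SNV", "First derivative", "Second derivative",
    "MSC+first derivative", "SNV+first derivative",
    "MSC+second derivative", "SNV+second derivative")))]
}

#' Look up a standard chain by display name
#' @param name One of the nine names of [standard_chains()].
#' @inheritParams standard_chains
#' @return A [preprocessing_spec()].
#' @export
chain_by_name <- function(name, sg_window = 15, sg_polyorder = 3) {
  chains <- standard_chains(sg_window, sg_polyorder)
  if (!name %in% names(chains)) {
    rlang::abort(sprintf("unknown chain '%s'; expected one of: %s",
                         name, paste(names(chains), collapse = ", ")))
  }
  chains[[name]]
}

#' Fit a pretreatment chain on calibration spectra
#'
#' Fitting stores whatever the chain must learn from the calibration set (the
#' MSC reference spectrum); everything else is stateless. Applying the fitted
#' chain to new spectra never reads statistics of the new set as a whole, so
#' transforming a test set one sample at a time gives the batch result.
#'
#' @param spec A [preprocessing_spec()].
#' @param calibration Calibration spectra matrix or [spectra_set()].
#' @param wavenumber Axis (taken from the spectra set when omitted).
#' @return A `fitted_preprocessor`.
#' @export
fit_preprocessor <- function(spec, calibration, wavenumber = NULL) {
  if (inherits(calibration, "spectra_set")) {
    wavenumber <- calibration$wavenumber
    calibration <- calibration$absorbance
  }
  if (is.null(wavenumber)) rlang::abort("`wavenumber` is required with a matrix.")
  msc_fit <- if (spec$scatter == "msc") fit_msc(calibration) else NULL
  structure(list(spec = spec, msc = msc_fit, wavenumber = wavenumber),
            class = "fitted_preprocessor")
}

#' @rdname fit_preprocessor
#' @param fitted A `fitted_preprocessor`.
#' @param x Spectra matrix or [spectra_set()] to transform.
#' @return `apply_preprocessor()`: object of the same kind as `x`, transformed;
#'   matrices carry the `"edge"` flag attribute when a derivative was taken.
#' @export
apply_preprocessor <- function(fitted, x) {
  if (!inherits(fitted, "fitted_preprocessor")) {
    rlang::abort("`fitted` must come from fit_preprocessor().")
  }
  is_set <- inherits(x, "spectra_set")
  m <- if (is_set) x$absorbance else as_spectra_matrix(x)
  spec <- fitted$spec
  m2 <- switch(spec$scatter,
               none = m,
               snv = snv(m),
               msc = apply_msc(fitted$msc, m))
  dord <- c(none = 0L, first = 1L, second = 2L)[[spec$derivative]]
  edge <- rep(FALSE, ncol(m2))
  if (dord > 0) {
    m2 <- sg_derivative(m2, fitted$wavenumber, derivative = dord,
                        window = spec$sg_window, polyorder = spec$sg_polyorder)
    edge <- attr(m2, "edge")
  }
  if (is_set) {
    out <- spectra_set(x$wavenumber, m2, x$meta)
    attr(out$absorbance, "edge") <- edge
    out
  } else {
    attr(m2, "edge") <- edge
    m2
  }
}

#' Apply a pretreatment chain to calibration and further sets
#'
#' Convenience wrapper: fits the chain on the calibration set and applies it
#' to the calibration set and any additional sets (test spectra, unknowns),
#' so no set other than the calibration set informs the transform.
#'
#' @inheritParams fit_preprocessor
#' @param ... Further matrices or [spectra_set()]s to transform.
#' @return List with `fitted`, `calibration`, and one transformed element per
#'   extra set (named as passed).
#' @export
apply_chain <- function(spec, calibration, ..., wavenumber = NULL) {
  fitted <- fit_preprocessor(spec, calibration, wavenumber)
  rest <- purrr::map(rlang::list2(...), ~ apply_preprocessor(fitted, .x))
  c(list(fitted = fitted,
         calibration = apply_preprocessor(fitted, calibration)),
    rest)
}

as_spectra_matrix <- function(x) {
  if (inherits(x, "spectra_set")) return(x$absorbance)
  if (!is.matrix(x)) x <- rbind(x)
  storage.mode(x) <- "double"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
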