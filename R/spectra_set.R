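#' Construct a spectra set
#'
#' A `spectra_set` bundles a wavenumber axis, an absorbance matrix (one row per
#' sample) and per-sample metadata: the adulterant mass fraction in % w/w and a
#' subset tag (`"calibration"`, `"test"` or `"unassigned"`). The axis is stored
#' in canonical descending order (4000 to 400 cm^-1, spectrometer convention);
#' ascending input is reversed, together with the matrix columns.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly monotone.
#' @param absorbance Numeric matrix, samples x wavenumbers. Row names, when
#'   present, become sample ids.
#' @param meta Optional data frame with columns `id`, `fraction` (% w/w, may be
#'   `NA`) and `subset`. Missing columns are filled with defaults.
#'
#' @return An object of class `spectra_set` with elements `wavenumber`,
#'   `absorbance` and `meta` (a tibble).
#' @examples
#' wn <- wavenumber_axis(101)
#' a <- matrix(rnorm(303), nrow = 3)
#' spectra_set(wn, a)
#' @export
spectra_set <- function(wavenumber, absorbance, meta = NULL) {
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) < 2) {
    rlang::abort("`wavenumber` needs at least 2 points.")
  }
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) {
    rlang::abort("`wavenumber` must be strictly monotone.")
  }
  if (!is.matrix(absorbance)) absorbance <- rbind(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != length(wavenumber)) {
    rlang::abort(sprintf(
      "absorbance has %d columns but the axis has %d points.",
      ncol(absorbance), length(wavenumber)
    ))
  }
  if (anyNA(absorbance)) rlang::abort("absorbance contains missing values.")
  if (all(d > 0)) { # normalize to descending
    wavenumber <- rev(wavenumber)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }

  n <- nrow(absorbance)
  ids <- rownames(absorbance)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  if (is.null(meta)) {
    meta <- tibble::tibble(id = ids, fraction = NA_real_, subset = "unassigned")
  } else {
    meta <- tibble::as_tibble(meta)
    if (!"id" %in% names(meta)) meta$id <- ids
    if (!"fraction" %in% names(meta)) meta$fraction <- NA_real_
    if (!"subset" %in% names(meta)) meta$subset <- "unassigned"
    meta <- meta[, c("id", "fraction", "subset",
                     setdiff(names(meta), c("id", "fraction", "subset")))]
  }
  if (nrow(meta) != n) {
    rlang::abort(sprintf("meta has %d rows but there are %d spectra.", nrow(meta), n))
  }
  if (anyDuplicated(meta$id)) {
    rlang::abort(sprintf("duplicate sample ids: %s",
                         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", ")))
  }
  ok <- is.na(meta$fraction) | (meta$fraction >= 0 & meta$fraction <= 100)
  if (!all(ok)) {
    rlang::abort("fractions must lie in [0, 100] % w/w (or be NA).")
  }
  bad <- !meta$subset %in% c("calibration", "test", "unassigned")
  if (any(bad)) {
    rlang::abort(sprintf("unknown subset tag(s): %s",
                         paste(unique(meta$subset[bad]), collapse = ", ")))
  }
  rownames(absorbance) <- meta$id
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance, meta = meta),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d spectra x %d wavenumbers (%.1f-%.1f cm^-1)\n",
    nrow(x$absorbance), length(x$wavenumber),
    max(x$wavenumber), min(x$wavenumber)
  ))
  tab <- table(x$meta$subset)
  cat("subsets:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  fr <- x$meta$fraction
  if (any(!is.na(fr))) {
    cat(sprintf("adulterant fraction: %g-%g %% w/w (%d labelled)\n",
                min(fr, na.rm = TRUE), max(fr, na.rm = TRUE), sum(!is.na(fr))))
  }
  invisible(x)
}

#' Number of samples / variables in a spectra set
#' @param x A `spectra_set`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname n_samples
#' @export
n_wavenumbers <- function(x) length(x$wavenumber)

#' Subset the samples of a spectra set
#'
#' `filter_samples()` keeps the samples for which the dplyr-style predicates on
#' the metadata hold; `restrict_wavenumbers()` keeps a subset of spectral
#' channels (by column index into the canonical descending axis).
#'
#' @param x A `spectra_set`.
#' @param ... Logical predicates on the metadata columns, as in [dplyr::filter()].
#' @return A `spectra_set` with fewer samples (or channels).
#' @export
filter_samples <- function(x, ...) {
  keep <- dplyr::mutate(x$meta, .row = dplyr::row_number())
  keep <- dplyr::filter(keep, ...)
  idx <- keep$.row
  spectra_set(x$wavenumber, x$absorbance[idx, , drop = FALSE],
              x$meta[idx, , drop = FALSE])
}

#' @rdname filter_samples
#' @param index Integer vector of channel (column) indices to keep.
#' @export
restrict_wavenumbers <- function(x, index) {
  index <- sort(unique(as.integer(index)))
  if (length(index) < 2) rlang::abort("need at least 2 channels.")
  if (any(index < 1 | index > n_wavenumbers(x))) {
    rlang::abort("channel index out of range.")
  }
  spectra_set(x$wavenumber[index], x$absorbance[, index, drop = FALSE], x$meta)
}

#' Tidy a spectra set into a long tibble
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `fraction`, `subset`, `wavenumber`,
#'   `absorbance` (one row per sample x channel).
#' @importFrom generics tidy
#' @export
tidy.spectra_set <- function(x, ...) {
  long <- tibble::tibble(
    id = rep(x$meta$id, each = length(x$wavenumber)),
    wavenumber = rep(x$wavenumber, times = nrow(x$absorbance)),
    absorbance = as.vector(t(x$absorbance))
  )
  dplyr::left_join(long, x$meta, by = "id")[
    , c("id", "fraction", "subset", "wavenumber", "absorbance")]
}

#' @export
as.data.frame.spectra_set <- function(x, ...) as.data.frame(tidy(x))

#' @importFrom generics glance
#' @export
glance.spectra_set <- function(x, ...) {
  tibble::tibble(
    n_samples = n_samples(x),
    n_wavenumbers = n_wavenumbers(x),
    wn_max = max(x$wavenumber),
    wn_min = min(x$wavenumber),
    n_calibration = sum(x$meta$subset == "calibration"),
    n_test = sum(x$meta$subset == "test")
  )
}
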