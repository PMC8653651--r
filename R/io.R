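#' Write a spectra set to disk
#'
#' Two dialects are supported. `"wide"` writes one delimited text file:
#' first column `wavenumber`, one column per sample (header row of sample
#' ids), plus a sibling `<stem>_meta.<ext>` metadata table with columns
#' `id`, `fraction_percent`, `subset`. `"jcamp"` writes one JCAMP-DX 4.24
#' single-spectrum file per sample (`##XYDATA=(X++(Y..Y))`, AFFN values,
#' cm^-1 vs absorbance) into a directory, with the fraction and subset
#' carried in private `##$FRACTION` / `##$SUBSET` records.
#'
#' @param x A [spectra_set()].
#' @param path File path (`"wide"`) or directory (`"jcamp"`).
#' @param dialect `"wide"` or `"jcamp"`.
#' @param delim Field delimiter for the wide dialect.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, dialect = c("wide", "jcamp"), delim = "\t") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "spectra_set"))
  if (dialect == "wide") {
    tab <- tibble::as_tibble(t(x$absorbance), .name_repair = "minimal")
    names(tab) <- x$meta$id
    tab <- dplyr::bind_cols(tibble::tibble(wavenumber = x$wavenumber), tab)
    readr::write_delim(tab, path, delim = delim)
    meta <- tibble::tibble(id = x$meta$id,
                           fraction_percent = x$meta$fraction,
                           subset = x$meta$subset)
    readr::write_delim(meta, meta_path_for(path), delim = delim)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(n_samples(x))) {
      write_jcamp_one(x$wavenumber, x$absorbance[i, ], x$meta[i, ],
                      file.path(path, paste0(x$meta$id[i], ".jdx")))
    }
  }
  invisible(path)
}

meta_path_for <- function(path) {
  ext <- tools::file_ext(path)
  if (nzchar(ext)) {
    sub(paste0("\\.", ext, "$"), paste0("_meta.", ext), path)
  } else {
    paste0(path, "_meta")
  }
}

write_jcamp_one <- function(wavenumber, y, meta_row, file) {
  n <- length(wavenumber)
  deltax <- (wavenumber[n] - wavenumber[1]) / (n - 1)
  con <- file(file, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("##TITLE=%s", meta_row$id),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1.0",
    "##YFACTOR=1.0",
    sprintf("##FIRSTX=%.10g", wavenumber[1]),
    sprintf("##LASTX=%.10g", wavenumber[n]),
    sprintf("##DELTAX=%.10g", deltax),
    sprintf("##NPOINTS=%d", n),
    sprintf("##FIRSTY=%.10g", y[1]),
    sprintf("##$FRACTION=%s",
            if (is.na(meta_row$fraction)) "NA" else format(meta_row$fraction)),
    sprintf("##$SUBSET=%s", meta_row$subset),
    "##XYDATA=(X++(Y..Y))"
  )
  writeLines(hdr, con)
  per_line <- 6L
  for (s in seq(1, n, by = per_line)) {
    e <- min(n, s + per_line - 1L)
    writeLines(paste(c(sprintf("%.6f", wavenumber[s]),
                       sprintf("%.12g", y[s:e])), collapse = " "), con)
  }
  writeLines("##END=", con)
}

#' Read spectra from disk
#'
#' Reads the dialects written by [write_spectra()]: a wide delimited table
#' (first column wavenumber, one column per sample) with an optional sibling
#' metadata table joined by sample id, or a directory of JCAMP-DX files
#' (`(X++(Y..Y))` XYDATA; the axis is reconstructed from
#' FIRSTX/DELTAX/NPOINTS and cross-checked against the abscissa values on
#' each data line). The returned axis is normalized to descending order;
#' samples without metadata are tagged `"unassigned"`.
#'
#' @param path Wide file, single JCAMP file, or directory of `.jdx`/`.dx`
#'   files.
#' @param dialect `"wide"` or `"jcamp"`.
#' @param delim Field delimiter for the wide dialect.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, dialect = c("wide", "jcamp"), delim = "\t") {
  dialect <- match.arg(dialect)
  if (dialect == "wide") read_spectra_wide(path, delim)
  else read_spectra_jcamp(path)
}

read_spectra_wide <- function(path, delim) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  hdr <- strsplit(readLines(path, n = 1), delim, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr)) { # before readr repairs the names
    rlang::abort(sprintf("duplicate sample ids in %s: %s", path,
                         paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  }
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    rlang::abort(sprintf("malformed spectra table %s: %s", path,
                         paste(utils::head(prob$expected, 3), collapse = "; ")))
  }
  if (ncol(tab) < 2) rlang::abort("spectra table needs wavenumber + >= 1 sample.")
  ids <- names(tab)[-1]
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate sample ids in %s: %s", path,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  num_ok <- vapply(tab, is.numeric, logical(1))
  if (!all(num_ok)) {
    rlang::abort(sprintf("non-numeric cells in column(s): %s",
                         paste(names(tab)[!num_ok], collapse = ", ")))
  }
  wn <- tab[[1]]
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  rownames(m) <- ids
  meta <- read_meta_maybe(meta_path_for(path), delim, ids)
  spectra_set(wn, m, meta)
}

read_meta_maybe <- function(meta_path, delim, ids) {
  if (!file.exists(meta_path)) return(NULL)
  meta <- readr::read_delim(meta_path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  names(meta)[names(meta) == "fraction_percent"] <- "fraction"
  meta <- tibble::tibble(id = as.character(meta$id),
                         fraction = as.numeric(meta$fraction),
                         subset = as.character(meta$subset))
  found <- match(ids, meta$id)
  out <- tibble::tibble(id = ids,
                        fraction = meta$fraction[found],
                        subset = meta$subset[found])
  out$subset[is.na(out$subset)] <- "unassigned"
  out
}

jcamp_field <- function(lines, name) {
  hit <- grep(sprintf("^##\\$?%s=", name), lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  sub("^##[^=]*=", "", hit[1])
}

read_jcamp_one <- function(file) {
  lines <- readLines(file, warn = FALSE)
  np <- as.integer(jcamp_field(lines, "NPOINTS"))
  firstx <- as.numeric(jcamp_field(lines, "FIRSTX"))
  deltax <- as.numeric(jcamp_field(lines, "DELTAX"))
  xf <- as.numeric(jcamp_field(lines, "XFACTOR") %||% "1")
  yf <- as.numeric(jcamp_field(lines, "YFACTOR") %||% "1")
  if (is.na(np) || is.na(firstx) || is.na(deltax)) {
    rlang::abort(sprintf("%s: missing NPOINTS/FIRSTX/DELTAX.", file))
  }
  start <- grep("^##XYDATA=", lines)
  endln <- grep("^##END=", lines)
  if (length(start) != 1 || length(endln) < 1) {
    rlang::abort(sprintf("%s: no (X++(Y..Y)) XYDATA block.", file))
  }
  body <- lines[(start + 1):(endln[1] - 1)]
  ys <- numeric(np)
  pos <- 1L
  for (ln in body) {
    toks <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(toks) < 2) next
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) rlang::abort(sprintf("%s: non-numeric XYDATA line.", file))
    x_here <- vals[1] * xf
    x_expect <- firstx + (pos - 1) * deltax
    if (abs(x_here - x_expect) > max(1e-6, abs(deltax) / 2)) {
      rlang::abort(sprintf(
        "%s: abscissa %.6f disagrees with FIRSTX+DELTAX grid (%.6f).",
        file, x_here, x_expect))
    }
    nv <- length(vals) - 1L
    ys[pos:(pos + nv - 1L)] <- vals[-1] * yf
    pos <- pos + nv
  }
  if (pos - 1L != np) {
    rlang::abort(sprintf("%s: %d Y values found, NPOINTS=%d.", file, pos - 1L, np))
  }
  fraction <- jcamp_field(lines, "FRACTION")
  subset <- jcamp_field(lines, "SUBSET") %||% "unassigned"
  list(
    wavenumber = firstx + deltax * (seq_len(np) - 1),
    y = ys,
    id = jcamp_field(lines, "TITLE") %||% basename(file),
    fraction = if (is.null(fraction) || fraction == "NA") NA_real_
               else as.numeric(fraction),
    subset = subset
  )
}

read_spectra_jcamp <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.(jdx|dx|jcm)$", full.names = TRUE,
                    ignore.case = TRUE))
  } else path
  if (length(files) == 0) rlang::abort(sprintf("no JCAMP files under %s", path))
  specs <- purrr::map(files, read_jcamp_one)
  axis0 <- specs[[1]]$wavenumber
  for (s in specs[-1]) {
    if (length(s$wavenumber) != length(axis0) ||
        max(abs(s$wavenumber - axis0)) > 1e-6) {
      rlang::abort(sprintf("axis mismatch across JCAMP files (sample %s).", s$id))
    }
  }
  ids <- purrr::map_chr(specs, "id")
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate sample ids: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- do.call(rbind, purrr::map(specs, "y"))
  rownames(m) <- ids
  spectra_set(axis0, m,
              tibble::tibble(id = ids,
                             fraction = purrr::map_dbl(specs, "fraction"),
                             subset = purrr::map_chr(specs, "subset")))
}

#' Write study report tables to disk
#'
#' Emits the pretreatment-screening table (one row per chain), the
#' selection-comparison table (one column per method: full spectrum plus each
#' selection algorithm, rows N.W / nLVs / RMSECV / R^2) and the paired
#' predicted-vs-actual values for both subsets as delimited text files.
#'
#' @param report A `study_report` from [run_study()] (or a list with any of
#'   `preprocessing_table`, `selection_table`, `final`).
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, delim = "\t") {
  has_pre <- !is.null(report$preprocessing_table) &&
    nrow(report$preprocessing_table) > 0
  has_sel <- !is.null(report$selection_table) && nrow(report$selection_table) > 0
  has_final <- !is.null(report$final)
  if (!has_pre && !has_sel && !has_final) {
    rlang::abort("empty report: nothing to write.")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  if (has_pre) {
    f <- file.path(dir, "preprocessing_table.tsv")
    readr::write_delim(report$preprocessing_table, f, delim = delim)
    written <- c(written, f)
  }
  if (has_sel) {
    f <- file.path(dir, "selection_table.tsv")
    long <- report$selection_table
    wide <- tibble::tibble(metric = c("N.W", "nLVs", "RMSECV", "R2"))
    for (i in seq_len(nrow(long))) {
      wide[[long$method[i]]] <- c(long$n_wavelengths[i], long$nlvs[i],
                                  long$rmsecv[i], long$r2[i])
    }
    readr::write_delim(wide, f, delim = delim)
    written <- c(written, f)
  }
  if (has_final) {
    f <- file.path(dir, "predicted_vs_actual.tsv")
    readr::write_delim(report$final$predictions, f, delim = delim)
    g <- file.path(dir, "final_metrics.tsv")
    readr::write_delim(glance(report$final), g, delim = delim)
    written <- c(written, f, g)
  }
  if (!is.null(report$provenance)) {
    f <- file.path(dir, "provenance.tsv")
    readr::write_delim(tibble::as_tibble(report$provenance), f, delim = delim)
    written <- c(written, f)
  }
  invisible(written)
}
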