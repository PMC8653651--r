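#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods give the standard diagnostic figures: overlaid
#' spectra coloured by adulterant fraction, RMSECV against the number of
#' latent variables, the MC-UVE stability profile with its cut-off, the iRF
#' per-channel selection probability, the moving-window error curve, and the
#' predicted-vs-actual scatter for calibration and test sets.
#'
#' @param object The result object.
#' @param ... Unused.
#' @param max_spectra Cap on the number of spectra drawn.
#' @return A ggplot object.
#' @name ftirquant-autoplot
NULL

#' @rdname ftirquant-autoplot
#' @export
autoplot.spectra_set <- function(object, ..., max_spectra = 30) {
  ids <- object$meta$id
  if (length(ids) > max_spectra) {
    ids <- ids[round(seq(1, length(ids), length.out = max_spectra))]
  }
  long <- tidy(filter_samples(object, id %in% ids))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavenumber, y = .data$absorbance,
    group = .data$id, colour = .data$fraction)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance",
                  colour = "% w/w") +
    ggplot2::theme_minimal()
}

#' @rdname ftirquant-autoplot
#' @export
autoplot.pls_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nlvs, y = .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::labs(x = "Number of latent variables", y = "RMSECV (% w/w)") +
    ggplot2::theme_minimal()
}

#' @rdname ftirquant-autoplot
#' @param wavenumber Optional axis for the x coordinate (index otherwise).
#' @export
autoplot.uve_profile <- function(object, wavenumber = NULL, ...) {
  d <- tidy(object)
  d$x <- if (is.null(wavenumber)) d$index else wavenumber[d$index]
  d <- d[is.finite(d$s), ]
  pl <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$s,
                                        colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x, yend = 0),
                          linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$cutoff,
                        linetype = "dashed") +
    ggplot2::labs(x = if (is.null(wavenumber)) "Channel index"
                  else expression(Wavenumber ~ (cm^-1)),
                  y = "Stability S", colour = "kept") +
    ggplot2::theme_minimal()
  if (!is.null(wavenumber)) pl <- pl + ggplot2::scale_x_reverse()
  pl
}

#' @rdname ftirquant-autoplot
#' @export
autoplot.irf_result <- function(object, wavenumber = NULL, ...) {
  d <- tibble::tibble(index = seq_along(object$channel_probability),
                      probability = object$channel_probability)
  d$x <- if (is.null(wavenumber)) d$index else wavenumber[d$index]
  pl <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (is.null(wavenumber)) "Channel index"
                  else expression(Wavenumber ~ (cm^-1)),
                  y = "Selection probability") +
    ggplot2::theme_minimal()
  if (!is.null(wavenumber)) pl <- pl + ggplot2::scale_x_reverse()
  pl
}

#' @rdname ftirquant-autoplot
#' @export
autoplot.mwpls_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start, y = .data$rmsecv,
                                  colour = factor(.data$width))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best$start, linetype = "dashed") +
    ggplot2::labs(x = "Window start channel", y = "RMSECV (% w/w)",
                  colour = "width") +
    ggplot2::theme_minimal()
}

#' @rdname ftirquant-autoplot
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$actual, y = .data$predicted,
                                  colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Actual adulterant fraction (% w/w)",
                  y = "Predicted (% w/w)", colour = NULL) +
    ggplot2::theme_minimal()
}
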