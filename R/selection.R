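#' Moving-window PLS interval scan
#'
#' Exhaustively scans contiguous wavenumber windows (stride 1, fully inside
#' the axis) for each requested width, cross-validating a PLS model restricted
#' to every window. The favourable interval is the window with the lowest
#' RMSECV; ties go to the narrower width, then the lower start index.
#'
#' @param x Predictor matrix or [spectra_set()] (preprocessed calibration).
#' @param y Response (% w/w); taken from the set's metadata when `x` is a
#'   [spectra_set()].
#' @param widths Window widths in channels (each in `[2, p]`).
#' @param scheme Cross-validation scheme for scoring windows.
#' @param max_nlvs Largest latent-variable count scored per window.
#' @return An `mwpls_result`: `windows` tibble (`width`, `start`, `end`,
#'   `rmsecv`, `nlvs`), `best` row, and `selected` channel indices.
#' @export
mw_pls <- function(x, y = NULL, widths, scheme = cv_kfold(5), max_nlvs = 10) {
  d <- xy_input(x, y); x <- d$x; y <- d$y
  p <- ncol(x)
  widths <- as.integer(widths)
  if (any(widths < 2 | widths > p)) {
    rlang::abort(sprintf("window widths must lie in [2, %d].", p))
  }
  rows <- list()
  for (w in sort(unique(widths))) {
    starts <- seq_len(p - w + 1)
    res <- purrr::map(starts, function(s) {
      cv <- cross_validate(x[, s:(s + w - 1), drop = FALSE], y,
                           max_nlvs = min(max_nlvs, w), scheme = scheme)
      c(rmsecv = cv$rmsecv, nlvs = cv$chosen_nlvs)
    })
    rows[[as.character(w)]] <- tibble::tibble(
      width = w, start = starts, end = starts + w - 1,
      rmsecv = purrr::map_dbl(res, "rmsecv"),
      nlvs = as.integer(purrr::map_dbl(res, "nlvs"))
    )
  }
  windows <- dplyr::bind_rows(rows)
  ord <- order(windows$rmsecv, windows$width, windows$start)
  best <- windows[ord[1], ]
  structure(
    list(windows = windows, best = best,
         selected = seq(best$start, best$end)),
    class = "mwpls_result"
  )
}

#' @export
print.mwpls_result <- function(x, ...) {
  cat(sprintf(
    "<mwpls_result> %d windows scanned; best: channels %d-%d (width %d), RMSECV = %.4g %%\n",
    nrow(x$windows), x$best$start, x$best$end, x$best$width, x$best$rmsecv))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mwpls_result <- function(x, ...) x$windows

#' @importFrom generics glance
#' @export
glance.mwpls_result <- function(x, ...) {
  tibble::tibble(best_start = x$best$start, best_end = x$best$end,
                 best_width = x$best$width, rmsecv = x$best$rmsecv,
                 nlvs = x$best$nlvs, n_selected = length(x$selected))
}

#' Monte-Carlo uninformative variable elimination
#'
#' Runs `n_runs` Monte-Carlo resamplings: each draws `sampling_fraction` of
#' the calibration samples without replacement, fits a PLS model with a fixed
#' latent-variable count and records its coefficient vector `b`. The
#' stability of channel `j` is `S_j = mean(b_j) / sd(b_j)` over the runs
#' (sample sd); channels whose `|S_j|` falls below the cut-off are deemed
#' uninformative and eliminated.
#'
#' Two cut-off rules are offered, the choice being genuinely open for a
#' regression task: `"noise_augmented"` appends `p` artificial noise channels
#' before the runs and uses the largest `|S|` they reach; `"quantile_scan"`
#' scans |S|-quantile cut-offs (including the no-cut-off baseline) and keeps
#' the one whose surviving channel set minimizes RMSECV.
#'
#' Channels with `sd(b_j) = 0` get a signed infinite stability and are
#' flagged, not dropped.
#'
#' @inheritParams mw_pls
#' @param n_runs Number of Monte-Carlo runs (>= 2).
#' @param sampling_fraction Fraction of samples drawn per run, in (0, 1];
#'   1 makes every run identical, so every channel is flagged (degenerate).
#' @param nlvs Latent-variable count for every run (commonly the
#'   full-spectrum choice).
#' @param cutoff_rule `"noise_augmented"` or `"quantile_scan"`.
#' @param seed Integer seed for the resampling (and noise channels).
#' @param scheme CV scheme for the quantile scan.
#' @return A `uve_profile`: `stability` tibble (`index`, `s`, `flagged`,
#'   `selected`), `cutoff`, `selected` indices and the configuration.
#' @export
mc_uve <- function(x, y = NULL, n_runs = 500, sampling_fraction = 0.8,
                   nlvs = 5, cutoff_rule = c("noise_augmented", "quantile_scan"),
                   seed = 1L, scheme = cv_kfold(5)) {
  cutoff_rule <- match.arg(cutoff_rule)
  d <- xy_input(x, y); x <- d$x; y <- d$y
  n <- nrow(x); p <- ncol(x)
  if (n_runs < 2) rlang::abort("`n_runs` must be >= 2.")
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    rlang::abort("`sampling_fraction` must be in (0, 1].")
  }
  n_sub <- round(sampling_fraction * n)
  if (n_sub < nlvs + 1) {
    rlang::abort("subsample too small for the requested latent variables.")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  x_run <- x
  if (cutoff_rule == "noise_augmented") {
    # amplitude is irrelevant to S (mean/sd ratio is scale-free); tiny scale
    # keeps the noise block from influencing the PLS subspace
    noise_block <- matrix(stats::rnorm(n * p), n, p) * 1e-10
    x_run <- cbind(x, noise_block)
  }
  B <- matrix(0, n_runs, ncol(x_run))
  for (m in seq_len(n_runs)) {
    # fraction 1 degenerates to identical runs (bit-equal b, sd exactly 0)
    idx <- if (n_sub == n) seq_len(n) else sample.int(n, n_sub)
    fit <- fit_pls(x_run[idx, , drop = FALSE], y[idx],
                   min(nlvs, n_sub - 1, ncol(x_run)))
    B[m, ] <- fit$b
  }
  mu <- colMeans(B)
  sdv <- apply(B, 2, stats::sd)
  s_all <- ifelse(sdv < .Machine$double.eps, sign(mu) * Inf, mu / sdv)
  flagged_all <- sdv < .Machine$double.eps
  s <- s_all[seq_len(p)]
  flagged <- flagged_all[seq_len(p)]

  if (cutoff_rule == "noise_augmented") {
    s_noise <- s_all[(p + 1):(2 * p)]
    finite <- abs(s_noise[is.finite(s_noise)])
    cutoff <- if (length(finite) > 0) max(finite) else Inf
    scan <- NULL
  } else {
    qs <- c(0, 0.50, 0.60, 0.70, 0.80, 0.90, 0.95)
    abs_s <- abs(s[is.finite(s)])
    cand <- stats::quantile(abs_s, qs, names = FALSE)
    cand[1] <- 0 # baseline: no cut-off
    scan <- purrr::map_dfr(seq_along(cand), function(i) {
      keep <- which(abs(s) >= cand[i])
      if (length(keep) < 2) return(tibble::tibble(
        quantile = qs[i], cutoff = cand[i], n_kept = length(keep),
        rmsecv = Inf))
      cv <- cross_validate(x[, keep, drop = FALSE], y,
                           max_nlvs = min(nlvs, length(keep)), scheme = scheme)
      tibble::tibble(quantile = qs[i], cutoff = cand[i],
                     n_kept = length(keep), rmsecv = cv$rmsecv)
    })
    cutoff <- scan$cutoff[which.min(scan$rmsecv)]
  }
  selected <- which(abs(s) >= cutoff)
  structure(
    list(stability = tibble::tibble(index = seq_len(p), s = s,
                                    flagged = flagged,
                                    selected = seq_len(p) %in% selected),
         cutoff = cutoff, selected = selected, scan = scan,
         config = list(n_runs = n_runs, sampling_fraction = sampling_fraction,
                       nlvs = nlvs, cutoff_rule = cutoff_rule, seed = seed)),
    class = "uve_profile"
  )
}

#' @export
print.uve_profile <- function(x, ...) {
  cat(sprintf(
    "<uve_profile> %d MC runs; cut-off |S| >= %.3g keeps %d / %d channels (%d flagged)\n",
    x$config$n_runs, x$cutoff, length(x$selected), nrow(x$stability),
    sum(x$stability$flagged)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.uve_profile <- function(x, ...) x$stability

#' @importFrom generics glance
#' @export
glance.uve_profile <- function(x, ...) {
  tibble::tibble(n_runs = x$config$n_runs, cutoff = x$cutoff,
                 n_selected = length(x$selected),
                 n_flagged = sum(x$stability$flagged))
}

# centered sliding intervals with edge truncation: one interval per channel,
# so an axis of p points yields p intervals of nominal width w
irf_intervals <- function(p, width) {
  half_lo <- floor(width / 2)
  purrr::map_dfr(seq_len(p), function(j) {
    s <- max(1L, j - half_lo)
    e <- min(p, j + (width - half_lo) - 1L)
    tibble::tibble(interval = j, start = s, end = e,
                   truncated = (e - s + 1L) < width)
  })
}

interval_vars <- function(intervals, which_int) {
  sort(unique(unlist(purrr::map(which_int, function(j) {
    seq(intervals$start[j], intervals$end[j])
  }))))
}

subset_rmsecv <- function(x, y, vars, scheme, nlvs_cap) {
  cv <- cross_validate(x[, vars, drop = FALSE], y,
                       max_nlvs = min(nlvs_cap, length(vars)), scheme = scheme)
  cv$rmsecv
}

#' Interval random frog
#'
#' Stochastic reversible-jump-style search over spectral intervals. The axis
#' is fractionated into one nominal-`interval_width` interval per channel
#' (centered sliding windows, truncated and flagged at the edges). Starting
#' from `q0` random intervals, each iteration draws a candidate subset size
#' around the current size (normal proposal, sd `proposal_sd_factor * Q`),
#' fills the candidate with the best-ranked intervals from the union of the
#' current subset and random additions (ranking by the mean absolute PLS
#' coefficient of each interval's channels in a model on the pooled
#' channels), and accepts it if its k-fold RMSECV is lower — otherwise with
#' probability `downhill_accept_prob * (RMSECV_current / RMSECV_candidate)`.
#' After `n_iterations` iterations each interval's selection probability is
#' the fraction of iterations whose accepted subset contained it.
#'
#' @inheritParams mw_pls
#' @param interval_width Nominal interval width in channels (default 20).
#' @param n_iterations Number of search iterations.
#' @param q0 Initial subset size (number of intervals).
#' @param proposal_sd_factor Proposal sd as a fraction of the current size.
#' @param downhill_accept_prob Base probability of accepting a worse subset.
#' @param nlvs_cap Latent-variable cap inside the search.
#' @param seed Integer seed.
#' @return An `irf_result`: `intervals` tibble (`interval`, `start`, `end`,
#'   `truncated`, `n_j`, `probability`), iteration count, and per-channel
#'   probabilities `channel_probability` (max over covering intervals).
#' @export
interval_random_frog <- function(x, y = NULL, interval_width = 20,
                                 n_iterations = 1000, q0 = 10,
                                 proposal_sd_factor = 0.3,
                                 downhill_accept_prob = 0.1,
                                 nlvs_cap = 10, seed = 1L,
                                 scheme = cv_kfold(5)) {
  d <- xy_input(x, y); x <- d$x; y <- d$y
  p <- ncol(x)
  interval_width <- as.integer(interval_width)
  if (interval_width < 2) rlang::abort("`interval_width` must be >= 2.")
  if (interval_width > p) rlang::abort("`interval_width` exceeds the axis length.")
  if (n_iterations < 10) rlang::abort("`n_iterations` must be >= 10.")
  intervals <- irf_intervals(p, interval_width)
  n_int <- nrow(intervals)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  rank_pool <- function(pool) {
    vars <- interval_vars(intervals, pool)
    fit <- fit_pls(x[, vars, drop = FALSE], y,
                   min(nlvs_cap, length(vars), nrow(x) - 1))
    b <- numeric(p); b[vars] <- fit$b
    score <- purrr::map_dbl(pool, function(j) {
      mean(abs(b[seq(intervals$start[j], intervals$end[j])]))
    })
    pool[order(-score, pool)] # ties -> lower interval index
  }

  current <- sort(sample.int(n_int, min(q0, n_int)))
  rmsecv_cur <- subset_rmsecv(x, y, interval_vars(intervals, current),
                              scheme, nlvs_cap)
  counts <- integer(n_int)
  for (it in seq_len(n_iterations)) {
    q_now <- length(current)
    q_star <- round(stats::rnorm(1, q_now, proposal_sd_factor * q_now))
    q_star <- max(1L, min(n_int, as.integer(q_star)))
    # the candidate pool is the union of the current subset and random
    # challenger intervals, so incumbents always compete for their place
    n_extra <- min(max(q_star - q_now, 0L) + max(1L, q_now %/% 2L),
                   n_int - q_now)
    pool <- current
    if (n_extra > 0) {
      pool <- c(current, sample(setdiff(seq_len(n_int), current), n_extra))
    }
    candidate <- sort(rank_pool(pool)[seq_len(min(q_star, length(pool)))])
    if (!identical(candidate, current)) {
      rmsecv_cand <- subset_rmsecv(x, y, interval_vars(intervals, candidate),
                                   scheme, nlvs_cap)
      accept <- rmsecv_cand <= rmsecv_cur ||
        stats::runif(1) < downhill_accept_prob * (rmsecv_cur / rmsecv_cand)
      if (accept) {
        current <- candidate
        rmsecv_cur <- rmsecv_cand
      }
    }
    counts[current] <- counts[current] + 1L
  }
  intervals$n_j <- counts
  intervals$probability <- counts / n_iterations
  channel_prob <- numeric(p)
  for (j in seq_len(n_int)) {
    rng <- seq(intervals$start[j], intervals$end[j])
    channel_prob[rng] <- pmax(channel_prob[rng], intervals$probability[j])
  }
  structure(
    list(intervals = intervals, n_iterations = n_iterations,
         channel_probability = channel_prob,
         config = list(interval_width = interval_width, q0 = q0,
                       proposal_sd_factor = proposal_sd_factor,
                       downhill_accept_prob = downhill_accept_prob,
                       nlvs_cap = nlvs_cap, seed = seed)),
    class = "irf_result"
  )
}

#' @export
print.irf_result <- function(x, ...) {
  cat(sprintf(
    "<irf_result> %d intervals (width %d), %d iterations; top probability %.3f\n",
    nrow(x$intervals), x$config$interval_width, x$n_iterations,
    max(x$intervals$probability)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.irf_result <- function(x, ...) x$intervals

#' @importFrom generics glance
#' @export
glance.irf_result <- function(x, ...) {
  tibble::tibble(n_intervals = nrow(x$intervals),
                 n_iterations = x$n_iterations,
                 max_probability = max(x$intervals$probability),
                 n_nonzero = sum(x$intervals$n_j > 0))
}

#' Choose the best intervals by selection probability
#'
#' Ranks intervals by selection probability (descending, ties to the lower
#' start index) and, for each top-k union of channels (k = 1..`k_max`),
#' computes the RMSECV of a PLS model on that union. Returns the union with
#' the lowest RMSECV; ties go to the smaller k.
#'
#' @param irf An [interval_random_frog()] result.
#' @inheritParams mw_pls
#' @param k_max Largest number of top intervals considered.
#' @param nlvs_cap Latent-variable cap for the scoring models.
#' @return Integer vector of selected channel indices with attributes `k`
#'   (number of intervals used) and `scan` (tibble of k vs RMSECV).
#' @export
select_intervals_by_probability <- function(irf, x, y = NULL,
                                            scheme = cv_kfold(5),
                                            k_max = 20, nlvs_cap = 10) {
  d <- xy_input(x, y); x <- d$x; y <- d$y
  iv <- irf$intervals
  nz <- iv[iv$probability > 0, ]
  if (nrow(nz) == 0) {
    rlang::abort("all interval probabilities are zero; increase `n_iterations`.")
  }
  nz <- nz[order(-nz$probability, nz$start), ]
  k_max <- min(k_max, nrow(nz))
  scan <- purrr::map_dfr(seq_len(k_max), function(k) {
    vars <- interval_vars(iv, nz$interval[seq_len(k)])
    tibble::tibble(k = k, n_vars = length(vars),
                   rmsecv = if (length(vars) >= 2)
                     subset_rmsecv(x, y, vars, scheme, nlvs_cap) else Inf)
  })
  best_k <- scan$k[which.min(scan$rmsecv)]
  vars <- interval_vars(iv, nz$interval[seq_len(best_k)])
  structure(vars, k = best_k, scan = scan)
}

xy_input <- function(x, y) {
  if (inherits(x, "spectra_set")) {
    if (is.null(y)) y <- x$meta$fraction
    x <- x$absorbance
  }
  if (is.null(y)) rlang::abort("`y` is required when `x` is a matrix.")
  if (anyNA(y)) rlang::abort("the response contains missing labels.")
  list(x = as_spectra_matrix(x), y = as.numeric(y))
}
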