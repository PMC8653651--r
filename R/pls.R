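#' Root-mean-square error
#'
#' `sqrt(mean((y_real - y_pre)^2))`, the figure of merit used throughout the
#' workflow: RMSECV under cross-validation, RMSEC on the calibration set and
#' RMSEP on the independent test set, all in % w/w here.
#'
#' @param y_real,y_pre Actual and predicted values (equal nonzero length).
#' @return Nonnegative scalar.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
rmse <- function(y_real, y_pre) {
  if (length(y_real) != length(y_pre)) {
    rlang::abort("`y_real` and `y_pre` differ in length.")
  }
  if (length(y_real) == 0) rlang::abort("empty input.")
  sqrt(mean((y_real - y_pre)^2))
}

#' Coefficient of determination
#'
#' Default definition `1 - SSE/SST` with SST about the mean of `y_real`; the
#' squared Pearson correlation is selectable. The two agree for a fitted
#' least-squares line but differ for held-out predictions, so the definition
#' in use is carried in reports.
#'
#' @inheritParams rmse
#' @param method `"one_minus_sse"` (default) or `"pearson"`.
#' @return Scalar, at most 1 under the default definition.
#' @export
r_squared <- function(y_real, y_pre, method = c("one_minus_sse", "pearson")) {
  method <- match.arg(method)
  if (length(y_real) != length(y_pre)) {
    rlang::abort("`y_real` and `y_pre` differ in length.")
  }
  if (length(y_real) < 2) rlang::abort("need at least 2 observations.")
  if (stats::sd(y_real) < .Machine$double.eps) {
    rlang::abort("`y_real` is constant; R^2 is undefined.")
  }
  if (method == "pearson") {
    stats::cor(y_real, y_pre)^2
  } else {
    1 - sum((y_real - y_pre)^2) / sum((y_real - mean(y_real))^2)
  }
}

#' Fit a PLS1 regression model
#'
#' Univariate-response partial least squares by NIPALS deflation on the
#' mean-centered predictor matrix and response; no variance scaling is
#' applied (derivative spectra have meaningful relative magnitudes, and
#' autoscaling would inflate noise channels). The regression vector is
#' exposed in centered coordinates: `prediction = (x - x_mean) %*% b + y_mean`.
#'
#' If deflation exhausts the predictive subspace before `nlvs` components
#' (e.g. a rank-1 problem), the remaining components are degenerate; the
#' model keeps the last well-defined coefficient vector for them and records
#' the effective rank in `rank`.
#'
#' @param x Predictor matrix (samples x wavenumbers), no missing values.
#' @param y Response vector in % w/w.
#' @param nlvs Number of latent variables, `1 <= nlvs <= min(n - 1, p)`.
#' @return A `pls_model`: means, weights `w`, loadings `p_load`, score
#'   regressions `q`, coefficient path `b_path` (p x nlvs, cumulative), final
#'   coefficients `b`, `nlvs`, effective `rank`.
#' @export
fit_pls <- function(x, y, nlvs) {
  x <- as_spectra_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) rlang::abort("length(y) must equal nrow(x).")
  if (anyNA(x) || anyNA(y)) rlang::abort("missing values are not allowed.")
  nlvs <- as.integer(nlvs)
  if (nlvs < 1 || nlvs > min(n - 1, p)) {
    rlang::abort(sprintf("`nlvs` must be in [1, %d].", min(n - 1, p)))
  }
  if (stats::sd(y) < .Machine$double.eps) rlang::abort("`y` has zero variance.")

  x_mean <- colMeans(x)
  y_mean <- mean(y)
  Xc <- sweep(x, 2, x_mean)
  yc <- y - y_mean
  scale0 <- sqrt(sum(crossprod(Xc, yc)^2))

  W <- matrix(0, p, nlvs); P <- matrix(0, p, nlvs); q <- numeric(nlvs)
  rank <- 0L
  for (a in seq_len(nlvs)) {
    wv <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(wv^2))
    if (nw <= 1e-12 * max(scale0, 1e-300)) break # subspace exhausted
    wv <- wv / nw
    t <- Xc %*% wv
    tt <- sum(t^2)
    if (tt <= .Machine$double.eps) break
    pv <- crossprod(Xc, t)[, 1] / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% rbind(pv)
    yc <- yc - qa * t[, 1]
    W[, a] <- wv; P[, a] <- pv; q[a] <- qa
    rank <- a
  }
  if (rank == 0L) rlang::abort("x carries no covariance with y; cannot fit.")

  # cumulative coefficient path: b_a = W_a (P_a' W_a)^{-1} q_a
  b_path <- matrix(0, p, nlvs)
  Wr <- W[, seq_len(rank), drop = FALSE]
  Pr <- P[, seq_len(rank), drop = FALSE]
  PtW <- crossprod(Pr, Wr) # upper triangular in exact arithmetic
  for (a in seq_len(rank)) {
    sol <- solve(PtW[seq_len(a), seq_len(a), drop = FALSE], q[seq_len(a)])
    b_path[, a] <- Wr[, seq_len(a), drop = FALSE] %*% sol
  }
  if (rank < nlvs) {
    for (a in seq((rank + 1), nlvs)) b_path[, a] <- b_path[, rank]
  }
  structure(
    list(x_mean = x_mean, y_mean = y_mean, w = W, p_load = P, q = q,
         b_path = b_path, b = b_path[, nlvs], nlvs = nlvs, rank = rank,
         wavenumber = colnames(x)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables (effective rank %d), %d channels\n",
              x$nlvs, x$rank, length(x$b)))
  invisible(x)
}

#' @export
predict.pls_model <- function(object, newdata, nlvs = object$nlvs, ...) {
  newdata <- as_spectra_matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    rlang::abort("newdata channel count does not match the fitted model.")
  }
  b <- object$b_path[, nlvs]
  drop(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}

#' @importFrom generics tidy
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    term = x$wavenumber %||% as.character(seq_along(x$b)),
    index = seq_along(x$b),
    estimate = x$b
  )
}

#' @importFrom generics glance
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(nlvs = x$nlvs, rank = x$rank,
                 n_wavenumbers = length(x$b), y_mean = x$y_mean)
}

#' Cross-validation schemes
#'
#' `cv_loo()` is leave-one-out; `cv_kfold()` splits into `k` folds built as
#' contiguous blocks of a seeded y-stratified shuffle (samples ordered by
#' response, shuffled within ties, dealt round-robin), so every fold spans
#' the concentration range.
#'
#' @param k Number of folds.
#' @param seed Integer seed for the stratified shuffle.
#' @return A `cv_scheme` description.
#' @export
cv_loo <- function() structure(list(type = "loo"), class = "cv_scheme")

#' @rdname cv_loo
#' @export
cv_kfold <- function(k = 21, seed = 1L) {
  if (k < 2) rlang::abort("`k` must be >= 2.")
  structure(list(type = "kfold", k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

cv_folds <- function(scheme, y) {
  n <- length(y)
  if (scheme$type == "loo") return(as.list(seq_len(n)))
  k <- scheme$k
  if (k > n) rlang::abort(sprintf("k = %d folds infeasible for n = %d.", k, n))
  # fold construction uses its own RNG stream and leaves the caller's intact
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(scheme$seed)
  ord <- order(y, stats::runif(n)) # stratified: sorted by y, ties shuffled
  fold_of <- integer(n)
  fold_of[ord] <- rep(seq_len(k), length.out = n)
  split(seq_len(n), fold_of)
}

# argmin with ties broken toward fewer latent variables
choose_nlvs <- function(rmsecv) which.min(rmsecv)

#' Cross-validate a PLS model over latent-variable counts
#'
#' For each number of latent variables from 1 to `max_nlvs`, held-out
#' predictions are assembled over all folds and scored by RMSECV. The chosen
#' count minimizes RMSECV, ties going to the smaller count (parsimony); no
#' one-standard-error rule is applied. The reported `r2` is computed from the
#' held-out predictions at the chosen count.
#'
#' @inheritParams fit_pls
#' @param max_nlvs Largest latent-variable count to score (capped at what the
#'   smallest training fold supports).
#' @param scheme A [cv_loo()] or [cv_kfold()] scheme.
#' @param r2_method Passed to [r_squared()].
#' @return A `pls_cv` with `rmsecv_by_nlv`, `chosen_nlvs`, `r2`, the held-out
#'   `predictions` matrix (n x max_nlvs) and the scheme.
#' @export
cross_validate <- function(x, y, max_nlvs = 10, scheme = cv_loo(),
                           r2_method = c("one_minus_sse", "pearson")) {
  r2_method <- match.arg(r2_method)
  x <- as_spectra_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  folds <- cv_folds(scheme, y)
  min_train <- n - max(lengths(folds))
  max_feasible <- min(min_train - 1, ncol(x))
  if (max_feasible < 1) rlang::abort("folds leave too few training samples.")
  if (max_nlvs > max_feasible) max_nlvs <- max_feasible
  preds <- matrix(NA_real_, n, max_nlvs)
  for (fold in folds) {
    fit <- fit_pls(x[-fold, , drop = FALSE], y[-fold], max_nlvs)
    Xc <- sweep(x[fold, , drop = FALSE], 2, fit$x_mean)
    preds[fold, ] <- Xc %*% fit$b_path + fit$y_mean
  }
  rmsecv <- apply(preds, 2, function(p) rmse(y, p))
  chosen <- choose_nlvs(rmsecv)
  structure(
    list(rmsecv_by_nlv = rmsecv, chosen_nlvs = chosen,
         rmsecv = rmsecv[chosen],
         r2 = r_squared(y, preds[, chosen], r2_method),
         r2_method = r2_method, predictions = preds, y = y, scheme = scheme),
    class = "pls_cv"
  )
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv> %s; chosen nLVs = %d, RMSECV = %.4g %%, R2 = %.4f\n",
              if (x$scheme$type == "loo") "leave-one-out"
              else sprintf("%d-fold", x$scheme$k),
              x$chosen_nlvs, x$rmsecv, x$r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.pls_cv <- function(x, ...) {
  tibble::tibble(nlvs = seq_along(x$rmsecv_by_nlv),
                 rmsecv = x$rmsecv_by_nlv,
                 chosen = seq_along(x$rmsecv_by_nlv) == x$chosen_nlvs)
}

#' @importFrom generics glance
#' @export
glance.pls_cv <- function(x, ...) {
  tibble::tibble(chosen_nlvs = x$chosen_nlvs, rmsecv = x$rmsecv, r2 = x$r2,
                 scheme = if (x$scheme$type == "loo") "loo"
                          else sprintf("%d-fold", x$scheme$k))
}

#' Evaluate a fitted model on calibration and test sets
#'
#' Applies the fitted pretreatment chain (calibration-fitted; never reads
#' test statistics) to both raw sets, predicts, and reports RMSEC / RMSEP and
#' the calibration / test R^2 together with the paired predictions.
#'
#' @param model A [fit_pls()] model trained on the preprocessed calibration
#'   set (possibly restricted to selected channels via `variables`).
#' @param fitted_prep A [fit_preprocessor()] result fitted on calibration.
#' @param calibration,test Raw [spectra_set()]s with `fraction` labels.
#' @param variables Optional channel indices the model was trained on.
#' @param r2_method Passed to [r_squared()].
#' @return An `evaluation_report` with `rmsec`, `rmsep`, `r2_cal`, `r2_test`
#'   and a `predictions` tibble (`set`, `id`, `actual`, `predicted`).
#' @export
evaluate <- function(model, fitted_prep, calibration, test,
                     variables = NULL,
                     r2_method = c("one_minus_sse", "pearson")) {
  r2_method <- match.arg(r2_method)
  if (n_samples(test) == 0) rlang::abort("the test set is empty.")
  one_set <- function(spectra, label) {
    m <- apply_preprocessor(fitted_prep, spectra$absorbance)
    if (!is.null(variables)) m <- m[, variables, drop = FALSE]
    if (ncol(m) != length(model$x_mean)) {
      rlang::abort("variable set of the data does not match the model.")
    }
    tibble::tibble(set = label, id = spectra$meta$id,
                   actual = spectra$meta$fraction,
                   predicted = predict(model, m))
  }
  pred <- dplyr::bind_rows(one_set(calibration, "calibration"),
                           one_set(test, "test"))
  cal <- pred[pred$set == "calibration", ]
  tst <- pred[pred$set == "test", ]
  structure(
    list(rmsec = rmse(cal$actual, cal$predicted),
         rmsep = rmse(tst$actual, tst$predicted),
         r2_cal = r_squared(cal$actual, cal$predicted, r2_method),
         r2_test = r_squared(tst$actual, tst$predicted, r2_method),
         r2_method = r2_method, predictions = pred),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> RMSEC = %.4g, RMSEP = %.4g %% w/w; R2(cal) = %.4f, R2(test) = %.4f\n",
    x$rmsec, x$rmsep, x$r2_cal, x$r2_test))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.evaluation_report <- function(x, ...) x$predictions

#' @importFrom generics glance
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(rmsec = x$rmsec, rmsep = x$rmsep,
                 r2_cal = x$r2_cal, r2_test = x$r2_test,
                 r2_method = x$r2_method)
}
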