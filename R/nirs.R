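#' Select representative samples by PCA-score distance
#'
#' Reduces the spectra to their first three principal components
#' (standardized wavelengths) and ranks samples by Mahalanobis distance from
#' the center of that score space.  The selection takes the most extreme
#' samples first and then fills the remaining places stratified across
#' distance ranks, so the chosen subset spans the whole range of variation
#' rather than only its fringe.  Ties (e.g. duplicated spectra) are broken
#' by index order, so one member of a duplicate pair is always taken before
#' the second.
#'
#' @param spectra Matrix or data frame, samples x wavelengths.
#' @param k Number of samples to select (k <= n).
#' @param n_components Number of score dimensions (default 3).
#' @param extreme_fraction Fraction of k taken from the far tail before the
#'   distance-stratified fill (default 0.5).
#' @return Integer vector of selected row indices, sorted increasing.
#' @export
select_representative <- function(spectra, k, n_components = 3,
                                  extreme_fraction = 0.5) {
  X <- as.matrix(spectra)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  if (k == n) return(seq_len(n))
  keep <- apply(X, 2, sd) > 0
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  m <- min(n_components, ncol(pc$x))
  sc <- pc$x[, seq_len(m), drop = FALSE]
  d2 <- mahalanobis(sc, colMeans(sc), cov(sc))
  # duplicates share a score vector: later occurrences are deferred so one
  # member of each duplicate set is taken before any set contributes twice
  key <- apply(round(sc, 9), 1, paste, collapse = ",")
  occurrence <- stats::ave(rep(1, n), key, FUN = cumsum)
  ord <- order(occurrence, -d2, seq_len(n))  # extreme first, ties by index
  n_ext <- min(k, ceiling(extreme_fraction * k))
  chosen <- ord[seq_len(n_ext)]
  remaining <- setdiff(ord, chosen)
  n_fill <- k - n_ext
  # stratified fill: spread across the distance-ranked remainder, exhausting
  # each duplicate-occurrence stratum before touching the next
  for (lv in sort(unique(occurrence[remaining]))) {
    if (n_fill <= 0) break
    block <- remaining[occurrence[remaining] == lv]
    if (n_fill >= length(block)) {
      take <- block
    } else {
      pick <- unique(round(seq(1, length(block), length.out = n_fill)))
      i <- 1
      while (length(pick) < n_fill) {    # top up after rounding collisions
        if (!(i %in% pick)) pick <- c(pick, i)
        i <- i + 1
      }
      take <- block[sort(pick)[seq_len(n_fill)]]
    }
    chosen <- c(chosen, take)
    n_fill <- n_fill - length(take)
  }
  sort(chosen)
}

#' Fit a latent-variable calibration of spectra to a constituent
#'
#' Partial least squares (PLS) regression of a measured constituent on the
#' spectra, with the number of latent components chosen by k-fold
#' cross-validation minimizing the root-mean-square error of prediction.
#' PLS is a standard latent-variable calibration for collinear spectral
#' data; orthogonal-signal-correction variants re-partition the same
#' subspace for interpretability and do not change the prediction contract
#' checked here.
#'
#' @param spectra_train Matrix samples x wavelengths.
#' @param y_train Constituent values (\% of dry matter).
#' @param max_components Upper bound on latent components; capped at the
#'   rank of the centered training spectra and at n_train - 2.
#' @param cv_folds Folds for cross-validation (default 5; use
#'   \code{cv_folds = nrow(spectra_train)} for leave-one-out).
#' @param seed Seed for the fold shuffle.
#' @return Object of class \code{nirs_calibration}: the fitted model,
#'   \code{n_components}, \code{training_rmse}, \code{cv_trace} (RMSE per
#'   candidate component count).
#' @export
fit_calibration <- function(spectra_train, y_train, max_components = 10,
                            cv_folds = 5, seed = 1) {
  if (!requireNamespace("mixOmics", quietly = TRUE)) {
    stop("fit_calibration needs the mixOmics package", call. = FALSE)
  }
  X <- as.matrix(spectra_train)
  if (is.null(colnames(X))) colnames(X) <- paste0("w", seq_len(ncol(X)))
  y <- as.numeric(y_train)
  n <- nrow(X)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  ncomp_max <- max(1, min(max_components, numerical_rank(X), n - 2))
  cv_folds <- min(cv_folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  press <- matrix(NA_real_, cv_folds, ncomp_max)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    nc_f <- min(ncomp_max, numerical_rank(X[tr, , drop = FALSE]),
                sum(tr) - 2)
    m <- pls_quiet(X[tr, , drop = FALSE], y[tr], nc_f)
    pr <- predict(m, X[!tr, , drop = FALSE])$predict[, 1, , drop = FALSE]
    for (cmp in seq_len(nc_f)) {
      press[f, cmp] <- sum((pr[, 1, cmp] - y[!tr])^2)
    }
  }
  cv_rmse <- sqrt(colSums(press, na.rm = TRUE) / n)
  best <- which.min(cv_rmse)
  model <- pls_quiet(X, y, best)
  fitted_tr <- predict(model, X)$predict[, 1, best]
  out <- list(model = model, n_components = best,
              training_rmse = sqrt(mean((fitted_tr - y)^2)),
              cv_trace = setNames(cv_rmse, seq_len(ncomp_max)),
              wavelengths = colnames(X))
  class(out) <- "nirs_calibration"
  out
}

#' Predict constituent values from spectra
#'
#' @param object A [fit_calibration()] model.
#' @param spectra Matrix samples x wavelengths (same grid as training).
#' @param ... Unused.
#' @return Numeric vector of predicted constituent values.
#' @export
predict.nirs_calibration <- function(object, spectra, ...) {
  X <- as.matrix(spectra)
  if (is.null(colnames(X))) colnames(X) <- object$wavelengths
  predict(object$model, X)$predict[, 1, object$n_components]
}

#' Evaluate a calibration on a held-out test set
#'
#' @param model A [fit_calibration()] model.
#' @param spectra_test,y_test Held-out spectra and reference values.
#' @return List with \code{rmsep} (root-mean-square error of prediction, on
#'   the constituent scale) and \code{r_squared}
#'   (\code{1 - SS_res / SS_tot}; can be negative for a predictor worse
#'   than the mean, which is flagged).
#' @export
evaluate_calibration <- function(model, spectra_test, y_test) {
  if (!nrow(as.matrix(spectra_test))) {
    stop("empty test set", call. = FALSE)
  }
  pred <- predict(model, spectra_test)
  if (length(pred) != length(y_test)) stop("length mismatch", call. = FALSE)
  rmsep <- sqrt(mean((pred - y_test)^2))
  sst <- sum((y_test - mean(y_test))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum((pred - y_test)^2) / sst
  if (is.finite(r2) && r2 <= 0) {
    warning("calibration predicts no better than the test-set mean ",
            "(R^2 <= 0)", call. = FALSE)
  }
  list(rmsep = rmsep, r_squared = r2, n = length(y_test))
}

#' @export
print.nirs_calibration <- function(x, ...) {
  cat(sprintf(
    "PLS calibration: %d latent component(s), training RMSE %.4g\n",
    x$n_components, x$training_rmse))
  invisible(x)
}

pls_quiet <- function(X, y, ncomp) {
  suppressMessages(mixOmics::pls(X, y, ncomp = ncomp, mode = "regression"))
}

# Numerical rank of the centered matrix: singular values above a relative
# threshold.  qr()'s default tolerance overstates the rank of noiseless
# low-rank spectra, which would push PLS past the identifiable subspace.
numerical_rank <- function(X, rel_tol = 1e-7) {
  d <- svd(scale(X, scale = FALSE), nu = 0, nv = 0)$d
  if (!length(d) || d[1] == 0) return(0L)
  sum(d > d[1] * rel_tol)
}
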