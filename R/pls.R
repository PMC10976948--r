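# Thin R layer over the compiled SIMPLS core. Used as the internal
# latent-variable regressor of the wavelength selectors (class labels coded
# 1/2/3) and as the engine of PLS-DA.

#' Fit a partial least squares regression (SIMPLS)
#'
#' Centres `X` and `Y` and extracts up to `ncomp` latent components;
#' coefficients for every component count are kept, so predictions at any
#' smaller number of components are free.
#'
#' @param X numeric sample x feature matrix.
#' @param Y numeric response vector or matrix (one column per response).
#' @param ncomp maximum number of latent components (capped at
#'   `min(ncol(X), nrow(X) - 1)`).
#' @return An object of class `pls_model`.
#' @export
pls_fit <- function(X, Y, ncomp = 10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  fit <- simpls_fit_cpp(X, Y, as.integer(ncomp))
  structure(list(coef = fit$coef, xmean = fit$xmean, ymean = fit$ymean,
                 ncomp = fit$ncomp, p = ncol(X), m = ncol(Y)),
            class = "pls_model")
}

#' @param object a `pls_model`.
#' @param newdata numeric matrix with `object$p` columns.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @rdname pls_fit
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " columns, model expects ", object$p)
  ncomp <- min(ncomp, object$ncomp)
  out <- simpls_predict_cpp(newdata, object$coef, object$xmean, object$ymean,
                            as.integer(ncomp))
  if (object$m == 1) drop(out) else out
}

#' Deterministic cross-validation folds
#'
#' Assigns each of `n` samples to one of `k` folds. With a seed the
#' assignment is a seeded shuffle (stratified by `labels` when given);
#' without one it is the cyclic assignment `1, 2, ..., k, 1, ...`.
#'
#' @param n sample count.
#' @param k fold count (`>= 2`).
#' @param seed optional RNG seed (local, global RNG state untouched).
#' @param labels optional class labels to stratify on.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k = 5, seed = NULL, labels = NULL) {
  stopifnot(k >= 2, n >= k)
  assign_one <- function(m) rep_len(seq_len(k), m)
  if (is.null(labels)) {
    ord <- if (is.null(seed)) seq_len(n) else with_seed(seed, sample.int(n))
    folds <- integer(n)
    folds[ord] <- assign_one(n)
  } else {
    stopifnot(length(labels) == n)
    folds <- integer(n)
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      ord <- if (is.null(seed)) rows
             else rows[with_seed(seed + as.integer(cl), sample.int(length(rows)))]
      folds[ord] <- assign_one(length(rows))
    }
  }
  folds
}

#' Cross-validated RMSE of univariate PLS per component count
#'
#' @param X sample x feature matrix.
#' @param y numeric response vector.
#' @param ncomp maximum components.
#' @param foldid integer fold assignment (see [make_folds()]).
#' @return Numeric vector of RMSECV values, one per component count (may be
#'   shorter than `ncomp` if a training fold runs out of rank).
#' @export
pls_cv_rmse <- function(X, y, ncomp = 10, foldid) {
  X <- as.matrix(X)
  pls1_cv_rmse_cpp(X, as.numeric(y), as.integer(ncomp), as.integer(foldid))
}
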