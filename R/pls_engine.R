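## Single-response NIPALS PLS on a centered design.  Returns the loading
## structure needed to form coefficients for every component count up to
## ncomp in one pass; deflation of X only (y loadings taken on the fly).
.nipals <- function(X, y, ncomp, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  xc <- colMeans(X)
  yc <- mean(y)
  Xc <- sweep(X, 2, xc)
  yr <- y - yc
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  a <- 0L
  nw1 <- tt1 <- NA_real_
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xc, yr)
    nw <- sqrt(sum(w^2))
    if (k == 1L) nw1 <- nw
    if (nw1 == 0 || nw < tol * nw1) break
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (k == 1L) tt1 <- tt
    if (tt1 == 0 || tt < tol * tt1) break
    pk <- crossprod(Xc, t) / tt
    qk <- sum(yr * t) / tt
    Xc <- Xc - t %*% t(pk)
    yr <- yr - qk * t
    W[, k] <- w
    P[, k] <- pk
    q[k] <- qk
    a <- k
  }
  if (a == 0L) stop("design has no covariance with the response")
  list(W = W[, seq_len(a), drop = FALSE],
       P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], xCenter = xc, yCenter = yc, maxComp = a)
}

## Coefficient vector (original column units) for the first `a` components.
.nipalsCoef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$q[seq_len(a)]))
}

#' Fit a PLS regression model
#'
#' Deterministic single-response partial least squares fitted by NIPALS.
#' Columns are centered internally and the response is centered; no
#' autoscaling is applied, so the coefficient vector lives in original
#' column units and predictions are
#' `y_center + (x - x_center) %*% coefficients`.
#'
#' @param X design matrix (samples x columns); the variance-filtered,
#'   stacked field blocks.
#' @param y activities (pIC50), length `nrow(X)`.
#' @param nComponents number of latent components; must not exceed the
#'   rank of the centered design.
#' @param blockIndex optional character vector naming the field block that
#'   owns each column (enables [fieldFractions()]).
#' @param scale logical; `TRUE` autoscales columns to unit variance before
#'   fitting (off by default).
#' @return a [PLSModel-class] with fitted statistics (`r2_fit`, fitted
#'   values) in `stats`.
#' @export
fitPLS <- function(X, y, nComponents, blockIndex = NULL, scale = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  if (nrow(X) < nComponents + 2)
    stop("need at least nComponents + 2 samples")
  Xorig <- X
  sds <- rep(1, ncol(X))
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  fit <- .nipals(X, y, nComponents)
  if (fit$maxComp < nComponents)
    stop("nComponents = ", nComponents, " exceeds the design rank (",
         fit$maxComp, ")")
  b <- .nipalsCoef(fit, nComponents) / sds
  xc <- colMeans(Xorig)
  fitted <- unname(drop(fit$yCenter + sweep(Xorig, 2, xc) %*% b))
  r2 <- stats::cor(fitted, y)^2
  if (is.null(blockIndex)) blockIndex <- rep("X", ncol(X))
  model <- new("PLSModel", nComponents = as.integer(nComponents),
               coefficients = b, xCenter = xc,
               xSD = apply(Xorig, 2, stats::sd),
               yCenter = fit$yCenter, blockIndex = blockIndex,
               stats = list(r2_fit = r2, fitted = fitted))
  model@stats$field_pct <- fieldFractions(model)
  model
}

#' Predict activities from a fitted PLS model
#'
#' @param object a [PLSModel-class].
#' @param newdata matrix of new rows over the same (retained) design
#'   columns as training.
#' @param ... unused.
#' @return numeric predicted activities.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@coefficients))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object@coefficients))
  drop(object@yCenter +
         sweep(newdata, 2, object@xCenter) %*% object@coefficients)
})

#' Leave-one-out cross-validation
#'
#' For each sample the model is refitted on the remaining `n - 1`
#' (re-centering each fold) and the held-out activity predicted.  Then
#' `PRESS = sum (yhat_-i - y_i)^2`,
#' `q2 = 1 - PRESS / sum (y_i - ybar)^2` with `ybar` the full-set mean
#' (the dominant convention; set `foldMean = TRUE` for the per-fold
#' variant), and `Spress = sqrt(PRESS / (n - Nc - 1))`, the standard
#' deviation of prediction error corrected for the model's degrees of
#' freedom.
#'
#' @param X design matrix.
#' @param y activities.
#' @param nComponents components per fold.
#' @param foldMean use each fold's own training mean in the q2 denominator.
#' @return list with `q2`, `spress`, `press` and `loo_predictions`.
#' @export
looCV <- function(X, y, nComponents, foldMean = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < nComponents + 3) stop("need at least nComponents + 3 samples")
  preds <- numeric(n)
  denom <- 0
  for (i in seq_len(n)) {
    fit <- .nipals(X[-i, , drop = FALSE], y[-i], nComponents)
    if (fit$maxComp < nComponents)
      stop("nComponents exceeds the design rank in LOO fold ", i)
    b <- .nipalsCoef(fit, nComponents)
    preds[i] <- fit$yCenter + sum((X[i, ] - fit$xCenter) * b)
    denom <- denom + (y[i] - mean(y[-i]))^2
  }
  press <- sum((preds - y)^2)
  if (!foldMean) denom <- sum((y - mean(y))^2)
  list(q2 = 1 - press / denom,
       spress = sqrt(press / (n - nComponents - 1)),
       press = press,
       loo_predictions = preds)
}

#' Scan component counts and select the best model
#'
#' Fits one NIPALS pass per LOO fold at the largest feasible component
#' count and reads off held-out predictions for every `Nc` up to `nMax`,
#' so the scan costs a single cross-validation.  The best `Nc` maximises
#' q2; ties are broken by lower Spress, then by the smaller `Nc`.
#'
#' @param X design matrix.
#' @param y activities.
#' @param nMax largest component count to scan; default 10.  Silently
#'   capped at the design rank and at `n - 3`.
#' @return list with `bestNc` and `scan`, a data.frame of `nc`, `q2`,
#'   `spress`, `r2_fit`.
#' @export
selectComponents <- function(X, y, nMax = 10) {
  if (nMax < 1) stop("nMax must be >= 1")
  X <- as.matrix(X)
  n <- nrow(X)
  nMax <- min(nMax, n - 3L)
  if (nMax < 1) stop("too few samples to cross-validate")
  full <- .nipals(X, y, nMax)
  nMax <- min(nMax, full$maxComp)
  preds <- matrix(NA_real_, n, nMax)
  for (i in seq_len(n)) {
    fit <- .nipals(X[-i, , drop = FALSE], y[-i], nMax)
    for (a in seq_len(min(nMax, fit$maxComp))) {
      b <- .nipalsCoef(fit, a)
      preds[i, a] <- fit$yCenter + sum((X[i, ] - fit$xCenter) * b)
    }
    ## folds that lose rank fall back to their largest feasible model
    if (fit$maxComp < nMax)
      preds[i, (fit$maxComp + 1):nMax] <- preds[i, fit$maxComp]
  }
  tss <- sum((y - mean(y))^2)
  scan <- do.call(rbind, lapply(seq_len(nMax), function(a) {
    press <- sum((preds[, a] - y)^2)
    bf <- .nipalsCoef(full, a)
    fitted <- full$yCenter +
      drop(sweep(X, 2, full$xCenter) %*% bf)
    data.frame(nc = a, q2 = 1 - press / tss,
               spress = sqrt(press / (n - a - 1)),
               r2_fit = stats::cor(fitted, y)^2)
  }))
  best <- order(-scan$q2, scan$spress, scan$nc)[1]
  list(bestNc = scan$nc[best], scan = scan)
}

#' Per-field contribution percentages
#'
#' The contribution of each field block to the model is
#' `sum_j |b_j| * s_j` over the block's columns, with `s_j` the training
#' column standard deviation, normalized to percentages summing to 100 --
#' the usual display of relative field weight in grid-field QSAR.
#'
#' @param model a [PLSModel-class] with `blockIndex` populated.
#' @return named numeric percentages, one per field block.
#' @export
fieldFractions <- function(model) {
  contrib <- abs(model@coefficients) * model@xSD
  tot <- c(tapply(contrib, model@blockIndex, sum))
  tot <- tot[unique(model@blockIndex)]
  if (sum(tot) <= 0) stop("all field contributions are zero")
  100 * tot / sum(tot)
}
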