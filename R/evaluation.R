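#' External-validation regression diagnostics
#'
#' Dual regression of observed against predicted activities: the ordinary
#' least-squares line `y = m x + n`, the through-origin line `y = c x`
#' (`c = sum(xy) / sum(x^2)`), the squared Pearson correlation `r2`, and
#' the through-origin determination coefficient
#' `r2_origin = 1 - sum((y - c x)^2) / sum(y^2)`.  A predictive model shows
#' slopes near 1, a small intercept and closeness of the two lines.
#'
#' By default the observed activities are regressed on the predictions
#' (`orientation = "obs_on_pred"`), the convention behind published
#' external-validation tables; `"pred_on_obs"` transposes the roles, as
#' used for training-set cross-validated diagnostics.
#'
#' @param observed experimental pIC50 values.
#' @param predicted model-predicted pIC50 values (same length, >= 3 points).
#' @param orientation which variable plays y in the regressions.
#' @return list with `m`, `n`, `r2`, `c`, `r2_origin`, `n_points`.
#' @examples
#' regressionValidation(c(1, 2, 3), c(2, 3, 5), orientation = "pred_on_obs")
#' @export
regressionValidation <- function(observed, predicted,
                                 orientation = c("obs_on_pred",
                                                 "pred_on_obs")) {
  orientation <- match.arg(orientation)
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 3) stop("need at least 3 points")
  if (anyNA(observed) || anyNA(predicted)) stop("NA values not allowed")
  if (orientation == "obs_on_pred") {
    x <- predicted; y <- observed
  } else {
    x <- observed; y <- predicted
  }
  if (stats::sd(x) == 0) stop("zero variance in the regressor")
  m <- stats::cov(x, y) / stats::var(x)
  n <- mean(y) - m * mean(x)
  r2 <- stats::cor(x, y)^2
  cc <- sum(x * y) / sum(x^2)
  r2o <- 1 - sum((y - cc * x)^2) / sum(y^2)
  list(m = m, n = n, r2 = r2, c = cc, r2_origin = r2o,
       n_points = length(x))
}

#' ROC curve and AUC for active/decoy discrimination
#'
#' Ranks molecules by descending score and sweeps the threshold to build
#' the ROC curve; tied scores advance the curve diagonally in one step.
#' The AUC follows the pair-counting (Mann-Whitney) convention: each
#' active-decoy pair contributes 1 when the active scores higher, 1/2 on a
#' tie -- identical to the trapezoidal area under the threshold-sweep
#' curve.
#'
#' @param scores numeric scores, higher = more likely active (e.g.
#'   predicted pIC50).
#' @param labels logical (TRUE = active) or character `"active"`/`"decoy"`.
#' @return list with `fpr`, `tpr` (curve points starting at (0,0)), `auc`,
#'   `n_actives`, `n_decoys`, and `ranked_labels` (logical, best first)
#'   for enrichment computations.
#' @export
rocAuc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "active"
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  nA <- sum(labels)
  nD <- sum(!labels)
  if (nA == 0 || nD == 0)
    stop("both actives and decoys must be present")
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  ## threshold sweep over unique score values (ties advance jointly)
  grp <- cumsum(!duplicated(s))
  ta <- tapply(l, grp, sum)
  td <- tapply(!l, grp, sum)
  tpr <- c(0, cumsum(ta) / nA)
  fpr <- c(0, cumsum(td) / nD)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = unname(fpr), tpr = unname(tpr), auc = unname(auc),
       n_actives = nA, n_decoys = nD, ranked_labels = l,
       ranked_scores = s)
}

#' Early enrichment from a ROC result
#'
#' Two readings of "enrichment in the first `fraction`": mode `"roc"`
#' interpolates the true-positive rate at a false-positive rate equal to
#' `fraction` and divides by `fraction` (the ROC enrichment); mode
#' `"top_fraction"` takes the top `ceiling(fraction * N)` of the ranked
#' list and divides the fraction of actives recovered there by `fraction`.
#' A perfect ranking saturates at `1 / fraction`; random scores give ~1.
#'
#' @param roc result of [rocAuc()].
#' @param fraction screening fraction in (0, 1); default 0.05.
#' @param mode `"roc"` (default) or `"top_fraction"`.
#' @return single enrichment value.
#' @export
rocEnrichment <- function(roc, fraction = 0.05,
                          mode = c("roc", "top_fraction")) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (mode == "roc") {
    tprAt <- stats::approx(roc$fpr, roc$tpr, xout = fraction,
                           ties = "ordered", rule = 2)$y
    tprAt / fraction
  } else {
    l <- roc$ranked_labels
    top <- ceiling(fraction * length(l))
    (sum(l[seq_len(top)]) / roc$n_actives) / fraction
  }
}

#' Normalized rank positions of actives under two models
#'
#' For each active molecule, its position in the ranked list of each model,
#' normalized to percent (`100 * rank / N`, rank 1 = best).  The paired
#' positions expose whether two pharmacophores recover the same actives
#' early or prioritize different chemical space.
#'
#' @param scoresA,scoresB named numeric score vectors over the same
#'   molecules (higher = better).
#' @param labels logical or `"active"`/`"decoy"`, aligned with `scoresA`.
#' @return data.frame with `mol_id`, `pos_a`, `pos_b` (percent), one row
#'   per active.
#' @export
rankOverlap <- function(scoresA, scoresB, labels) {
  if (is.null(names(scoresA)) || is.null(names(scoresB)))
    stop("score vectors must be named by mol_id")
  if (!setequal(names(scoresA), names(scoresB)))
    stop("score sets cover different molecules")
  scoresB <- scoresB[names(scoresA)]
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "active"
  N <- length(scoresA)
  posA <- 100 * rank(-scoresA, ties.method = "first") / N
  posB <- 100 * rank(-scoresB, ties.method = "first") / N
  data.frame(mol_id = names(scoresA)[labels],
             pos_a = unname(posA[labels]), pos_b = unname(posB[labels]),
             stringsAsFactors = FALSE)
}

#' Summary statistics for a group of measured activities
#'
#' Mean, sample standard deviation (n-1 denominator), median, min, max and
#' the count of compounds more potent than IC50 = 20 nM.  The potency count
#' applies the strict rule `pIC50 > 7.7` on one-decimal values (20 nM
#' corresponds to pIC50 7.70, itself excluded).
#'
#' @param values pIC50 values (>= 1).
#' @param label group label carried into the output.
#' @return list with `label`, `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `count_below_ic50_20nM`.
#' @export
groupSummary <- function(values, label = "") {
  if (length(values) < 1) stop("empty group")
  if (anyNA(values)) stop("NA activities in group")
  list(label = label, n = length(values),
       mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0,
       median = stats::median(values),
       min = min(values), max = max(values),
       count_below_ic50_20nM = sum(round(values, 1) > 7.7))
}
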