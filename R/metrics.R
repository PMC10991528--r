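#' Scored predictions container
#'
#' Aligns, per sample, the model's predicted probability, the hard 0/1
#' prediction, the true label, and the protected-group membership used for
#' fairness auditing.
#'
#' @param score predicted probabilities in `[0, 1]`.
#' @param label true binary labels in `{0, 1}`.
#' @param group category per sample (character or factor).
#' @param prediction hard 0/1 predictions; defaults to thresholding `score`
#'   at `threshold`.
#' @param threshold threshold used for the default predictions.
#' @return an object of class `scored_predictions`: a data.frame with columns
#'   `score`, `prediction`, `label`, `group`.
#' @export
scored_predictions <- function(score, label, group,
                               prediction = NULL, threshold = 0.5) {
  n <- length(score)
  if (length(label) != n || length(group) != n) {
    stopf("score, label and group must have equal length")
  }
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stopf("scores must lie in [0, 1]")
  }
  label <- validate_binary_labels(label)
  if (is.null(prediction)) prediction <- as.integer(score >= threshold)
  prediction <- validate_binary_labels(prediction)
  structure(
    data.frame(score = as.numeric(score), prediction = prediction,
               label = label, group = as.character(group),
               stringsAsFactors = FALSE),
    class = c("scored_predictions", "data.frame")
  )
}

#' Per-subgroup true- and false-positive rates
#'
#' For each category x of the protected attribute, the subgroup TPR is the
#' share of true positives among the group's positives and the subgroup FPR
#' the share of false positives among its negatives. A rate whose
#' conditioning set is empty (a group with no positives, or no negatives) is
#' reported as `NA` with its `*_defined` flag set to `FALSE`, never silently
#' as zero: silent drops would hide exactly the small subgroups most at risk.
#'
#' @param pred a [scored_predictions].
#' @param partition optional [partition_by_group()] result; when supplied,
#'   group membership is taken from its index sets (which must cover
#'   `nrow(pred)` rows) instead of `pred$group`.
#' @return an object of class `group_rates`: a data.frame with one row per
#'   category (`group`, `tpr`, `fpr`, `n_pos`, `n_neg`, `tpr_defined`,
#'   `fpr_defined`) and attributes `overall_tpr`, `overall_fpr` pooled over
#'   all samples.
#' @export
group_rates <- function(pred, partition = NULL) {
  stopifnot(inherits(pred, "scored_predictions"))
  grp <- if (is.null(partition)) {
    pred$group
  } else {
    stopifnot(inherits(partition, "group_partition"))
    g <- character(nrow(pred))
    for (ct in partition$categories) g[partition$index[[ct]]] <- ct
    g
  }
  if (sum(pred$label == 1L) < 1L) {
    stopf("group_rates needs at least one positive sample")
  }
  cats <- sort(unique(grp))
  rows <- lapply(cats, function(ct) {
    in_g <- grp == ct
    pos <- pred$label == 1L & in_g
    neg <- pred$label == 0L & in_g
    data.frame(
      group = ct,
      tpr = if (any(pos)) mean(pred$prediction[pos] == 1L) else NA_real_,
      fpr = if (any(neg)) mean(pred$prediction[neg] == 1L) else NA_real_,
      n_pos = sum(pos), n_neg = sum(neg),
      tpr_defined = any(pos), fpr_defined = any(neg),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_tpr") <- mean(pred$prediction[pred$label == 1L] == 1L)
  attr(out, "overall_fpr") <- if (any(pred$label == 0L)) {
    mean(pred$prediction[pred$label == 0L] == 1L)
  } else {
    NA_real_
  }
  class(out) <- c("group_rates", "data.frame")
  out
}

#' Equal Opportunity Difference
#'
#' The (signed) gap between the lowest and highest subgroup true-positive
#' rate, `min_x TPR_x - max_x TPR_x`. It is 0 exactly when all defined
#' subgroup TPRs coincide (the equal-opportunity criterion) and otherwise
#' negative, down to -1; more negative means more biased.
#'
#' @param rates a [group_rates] table.
#' @return signed value in `[-1, 0]`.
#' @export
eod <- function(rates) {
  stopifnot(inherits(rates, "group_rates"))
  tpr <- rates$tpr[rates$tpr_defined]
  if (length(tpr) < 2L) {
    stopf("EOD needs at least two groups with a defined TPR")
  }
  min(tpr) - max(tpr)
}

#' Average Odds Difference
#'
#' Half the gap between the smallest and largest per-group sum of TPR and
#' FPR, measuring the equalized-odds criterion: 0 when all groups share the
#' same (TPR + FPR) sum, otherwise negative down to -1.
#'
#' @param rates a [group_rates] table.
#' @return signed value in `[-1, 0]`.
#' @export
aod <- function(rates) {
  stopifnot(inherits(rates, "group_rates"))
  ok <- rates$tpr_defined & rates$fpr_defined
  s <- rates$tpr[ok] + rates$fpr[ok]
  if (length(s) < 2L) {
    stopf("AOD needs at least two groups with both rates defined")
  }
  (min(s) - max(s)) / 2
}

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity (TPR) and specificity (TNR); appropriate
#' for the class-imbalanced outcomes typical of clinical cohorts.
#'
#' @param pred a [scored_predictions].
#' @return value in `[0, 1]`.
#' @export
balanced_accuracy <- function(pred) {
  stopifnot(inherits(pred, "scored_predictions"))
  pos <- pred$label == 1L
  if (!any(pos) || all(pos)) {
    stopf("balanced accuracy needs both classes present")
  }
  (mean(pred$prediction[pos] == 1L) + mean(pred$prediction[!pos] == 0L)) / 2
}

#' Area under the ROC curve
#'
#' Computed as the rank statistic `P(score+ > score-) + 0.5 P(tie)`, which
#' equals the area under the TPR-versus-FPR curve over all thresholds.
#'
#' @param scores predicted probabilities (any monotone score works).
#' @param labels binary labels in `{0, 1}`.
#' @return value in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- validate_binary_labels(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fairness-accuracy score (weighted harmonic mean)
#'
#' Combines predictive performance and fairness into one number:
#' \deqn{\Delta = \frac{(1+\beta^2)\,\mathrm{BAcc}\,(1-|\mathrm{EOD}|)}
#'                     {\beta^2\,\mathrm{BAcc} + (1-|\mathrm{EOD}|)}}
#' The default `beta = 0.5` weighs predictive performance more than
#' fairness, the usual preference in clinical screening where losing true
#' positives has ethical cost. `beta -> 0` recovers BAcc exactly.
#'
#' @param bacc balanced accuracy in `(0, 1]`.
#' @param eod signed equal-opportunity difference, `|eod| <= 1`.
#' @param beta fairness weight, `>= 0`.
#' @return value in `[0, 1]`; defined as 0 in the degenerate case where both
#'   numerator terms vanish.
#' @export
delta_score <- function(bacc, eod, beta = 0.5) {
  stopifnot(bacc >= 0, bacc <= 1, abs(eod) <= 1, beta >= 0)
  fair <- 1 - abs(eod)
  den <- beta^2 * bacc + fair
  if (den == 0) return(0)
  (1 + beta^2) * bacc * fair / den
}

#' Practical fairness band on EOD
#'
#' Convenience predicate for the reporting convention that a model is
#' regarded as fair when its EOD lies within `[-band, band]` (conventionally
#' 0.1). This labels a working band, not a normative policy.
#'
#' @param eod signed EOD value(s).
#' @param band half-width of the band.
#' @return logical vector.
#' @export
eod_within_band <- function(eod, band = 0.1) {
  abs(eod) <= band
}

#' Full fairness report for one scored set
#'
#' Computes balanced accuracy, AUC-ROC, the subgroup rate table, EOD, AOD
#' and the fairness-accuracy score for one protected attribute.
#'
#' @param pred a [scored_predictions].
#' @param partition optional [partition_by_group()] result (see
#'   [group_rates()]).
#' @param beta fairness weight for [delta_score()].
#' @return an object of class `fairness_report`: list with `bacc`, `auc`,
#'   `rates`, `eod`, `aod`, `delta`, `beta`.
#' @export
fairness_report <- function(pred, partition = NULL, beta = 0.5) {
  rates <- group_rates(pred, partition)
  b <- balanced_accuracy(pred)
  e <- eod(rates)
  structure(
    list(bacc = b, auc = auc_roc(pred$score, pred$label), rates = rates,
         eod = e, aod = aod(rates), delta = delta_score(b, e, beta),
         beta = beta),
    class = "fairness_report"
  )
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("<fairness_report> BAcc %.4f | AUC %.4f | EOD %+.4f | AOD %+.4f | Delta(beta=%.2g) %.4f\n",
              x$bacc, x$auc, x$eod, x$aod, x$beta, x$delta))
  print(as.data.frame(x$rates))
  invisible(x)
}

#' Serialize a fairness report to JSON
#'
#' @param x a [fairness_report].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fairness_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fairness_report"))
  obj <- list(
    bacc = x$bacc, auc = x$auc, eod = x$eod, aod = x$aod,
    delta = x$delta, beta = x$beta,
    rates = as.data.frame(x$rates),
    overall_tpr = attr(x$rates, "overall_tpr"),
    overall_fpr = attr(x$rates, "overall_fpr")
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
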