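#' Calibrated equalized-odds post-processing: fit the mixing policy
#'
#' Works on calibrated probability scores. The generalized false-negative
#' rate of group x is the mean residual probability mass left on the
#' negative side among true positives, `g_x = mean(1 - score | C = 1,
#' X = x)`; it is the cost a screening application cares about. The policy
#' equalizes these costs *on average* by mixing each lower-cost group with
#' its trivial base-rate predictor: a fraction `alpha` of that group's
#' samples (chosen at random, seeded) has its score replaced by the group's
#' outcome base rate. The trivial predictor's cost for group x is
#' `1 - base_x`, so
#' \deqn{\alpha_x = (g_{max} - g_x) / ((1 - base_x) - g_x)}
#' makes the expected mixed cost equal to the worst group's. If even full
#' mixing cannot raise the cost enough, `alpha` is capped at 1 with a
#' warning.
#'
#' @param pred training-set [scored_predictions] with calibrated scores.
#' @param cost cost constraint; only `"fnr"` (generalized false-negative
#'   rate) is implemented, the constraint of interest when recall matters
#'   more than precision.
#' @param seed integer seed for the mixing randomness.
#' @return an object of class `cpp_policy`: data.frame of per-group `alpha`,
#'   `base_rate` and fitted `cost`, plus attributes `cost_kind` and `seed`.
#' @export
cpp_fit <- function(pred, cost = "fnr", seed = 1) {
  stopifnot(inherits(pred, "scored_predictions"))
  cost <- match.arg(cost, "fnr")
  cats <- sort(unique(pred$group))
  if (length(cats) < 2L) stopf("CPP needs at least two groups")
  rows <- lapply(cats, function(ct) {
    in_g <- pred$group == ct
    pos <- in_g & pred$label == 1L
    if (!any(pos)) {
      stopf("group '%s' has no positives; generalized FNR undefined", ct)
    }
    data.frame(group = ct,
               cost = mean(1 - pred$score[pos]),
               base_rate = mean(pred$label[in_g]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  g_max <- max(tab$cost)
  alpha <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$cost[i] >= g_max) next
    trivial <- 1 - tab$base_rate[i]
    if (trivial <= tab$cost[i]) {
      warnf("group '%s': trivial predictor cannot raise cost to the maximum; alpha capped at 1",
            tab$group[i])
      alpha[i] <- 1
    } else {
      alpha[i] <- min(1, (g_max - tab$cost[i]) / (trivial - tab$cost[i]))
    }
  }
  tab$alpha <- alpha
  attr(tab, "cost_kind") <- cost
  attr(tab, "seed") <- as.integer(seed)
  class(tab) <- c("cpp_policy", "data.frame")
  tab
}

#' Apply a calibrated equalized-odds mixing policy
#'
#' For each sample of a group with mixing rate `alpha > 0`, an independent
#' seeded Bernoulli(`alpha`) draw decides whether its score is replaced by
#' the group's base rate; predictions are re-thresholded at `threshold`.
#' Groups unseen at fit time pass through unchanged with a warning.
#'
#' @param policy a [cpp_fit()] result.
#' @param pred a [scored_predictions] to adjust.
#' @param threshold decision threshold for the re-derived hard predictions.
#' @return adjusted [scored_predictions].
#' @export
cpp_apply <- function(policy, pred, threshold = 0.5) {
  stopifnot(inherits(policy, "cpp_policy"), inherits(pred, "scored_predictions"))
  unseen <- setdiff(unique(pred$group), policy$group)
  if (length(unseen)) {
    warnf("group(s) unseen at fit time pass through unmixed: %s",
          paste(unseen, collapse = ", "))
  }
  score <- pred$score
  with_local_seed(attr(policy, "seed"), {
    for (i in seq_len(nrow(policy))) {
      if (policy$alpha[i] <= 0) next
      in_g <- which(pred$group == policy$group[i])
      mix <- in_g[stats::runif(length(in_g)) < policy$alpha[i]]
      score[mix] <- policy$base_rate[i]
    }
  })
  scored_predictions(score = score, label = pred$label, group = pred$group,
                     threshold = threshold)
}

#' Population sensitivity-guided threshold adjustment: fit per-group thresholds
#'
#' When outcome prevalence differs between groups, a model trained on the
#' pooled data tends to assign systematically lower scores to the
#' low-prevalence group, so a single decision threshold gives that group a
#' lower sensitivity. This post-processing step fits, on training data, a
#' separate decision threshold per unprivileged subgroup so that each
#' group's sensitivity aligns with the overall population's, while keeping
#' the group's false-positive rate within a margin of the overall FPR.
#'
#' Concretely, with reference threshold `t0` (default 0.5):
#' * the overall training sensitivity `S*` and FPR `F*` are computed at `t0`;
#' * a group whose sensitivity at `t0` already reaches `S*` is privileged
#'   and keeps `t0`;
#' * every other group receives the *largest* threshold `t <= t0` among its
#'   observed positive-sample scores (plus `t0`) with group sensitivity
#'   `>= S*` and group FPR `<= F* + delta` — the largest such `t` meets the
#'   sensitivity target with the least FPR inflation;
#' * if no candidate satisfies both, the candidate maximizing sensitivity
#'   subject to the FPR cap is used; if even `t0` violates the cap, the
#'   group keeps `t0` with a warning.
#'
#' Groups without positive training samples cannot be aligned and keep `t0`
#' with a warning. The result depends only on the set of (score, label,
#' group) triples, not their order.
#'
#' @param pred training-set [scored_predictions].
#' @param t0 reference threshold; the conventional 0.5, adjustable as a
#'   hyperparameter.
#' @param delta acceptable FPR margin above the overall population's FPR.
#' @return an object of class `threshold_policy`: list with `thresholds`
#'   (named per group), `t0`, `delta`, `overall_sensitivity`, `overall_fpr`,
#'   and `treated` (named logical).
#' @export
psta_fit <- function(pred, t0 = 0.5, delta = 0.10) {
  stopifnot(inherits(pred, "scored_predictions"))
  if (t0 <= 0 || t0 > 1) stopf("t0 must lie in (0, 1]")
  if (!nrow(pred)) stopf("empty input")
  if (!any(pred$label == 1L)) stopf("no positive samples; sensitivity undefined")
  s_star <- mean(pred$score[pred$label == 1L] >= t0)
  f_star <- if (any(pred$label == 0L)) {
    mean(pred$score[pred$label == 0L] >= t0)
  } else {
    0
  }
  cats <- sort(unique(pred$group))
  thresholds <- stats::setNames(rep(t0, length(cats)), cats)
  treated <- stats::setNames(rep(FALSE, length(cats)), cats)
  for (ct in cats) {
    in_g <- pred$group == ct
    pos <- pred$score[in_g & pred$label == 1L]
    neg <- pred$score[in_g & pred$label == 0L]
    if (!length(pos)) {
      warnf("group '%s' has no positive training samples; kept t0", ct)
      next
    }
    if (mean(pos >= t0) >= s_star) next # privileged: standard threshold
    cand <- sort(unique(c(pos[pos <= t0 & pos > 0], t0)), decreasing = TRUE)
    sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
    fpr <- if (length(neg)) {
      vapply(cand, function(t) mean(neg >= t), numeric(1))
    } else {
      rep(0, length(cand))
    }
    ok_cap <- fpr <= f_star + delta + 1e-12
    ok_both <- ok_cap & sens >= s_star
    if (any(ok_both)) {
      thresholds[ct] <- cand[which(ok_both)[1L]] # largest qualifying t
      treated[ct] <- TRUE
    } else if (any(ok_cap)) {
      # best attainable sensitivity under the cap; largest t on ties
      within <- which(ok_cap)
      best <- within[which.max(sens[within])]
      thresholds[ct] <- cand[best]
      treated[ct] <- TRUE
    } else {
      warnf("group '%s': FPR cap unsatisfiable even at t0; kept t0", ct)
    }
  }
  structure(
    list(thresholds = thresholds, t0 = t0, delta = delta,
         overall_sensitivity = s_star, overall_fpr = f_star,
         treated = treated),
    class = "threshold_policy"
  )
}

#' Apply per-group decision thresholds
#'
#' Re-derives hard predictions as `score >= threshold(group)`; scores are
#' unchanged. Groups missing from the policy fall back to its `t0` with a
#' warning.
#'
#' @param policy a [psta_fit()] result (or any `threshold_policy`).
#' @param pred a [scored_predictions].
#' @return [scored_predictions] with adjusted predictions.
#' @export
psta_apply <- function(policy, pred) {
  stopifnot(inherits(policy, "threshold_policy"),
            inherits(pred, "scored_predictions"))
  thr <- policy$thresholds[pred$group]
  if (anyNA(thr)) {
    unseen <- unique(pred$group[is.na(thr)])
    warnf("group(s) not in policy fall back to t0: %s",
          paste(unseen, collapse = ", "))
    thr[is.na(thr)] <- policy$t0
  }
  scored_predictions(score = pred$score, label = pred$label,
                     group = pred$group,
                     prediction = as.integer(pred$score >= thr))
}

#' Serialize a threshold or mixing policy to JSON
#'
#' @param x a `threshold_policy` or `cpp_policy`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
policy_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "threshold_policy")) {
    list(kind = "psta", thresholds = as.list(x$thresholds), t0 = x$t0,
         delta = x$delta, overall_sensitivity = x$overall_sensitivity,
         overall_fpr = x$overall_fpr, treated = as.list(x$treated))
  } else if (inherits(x, "cpp_policy")) {
    list(kind = "cpp", groups = as.data.frame(x),
         cost_kind = attr(x, "cost_kind"), seed = attr(x, "seed"))
  } else {
    stopf("not a serializable policy")
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
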