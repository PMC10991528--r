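# Shared fixtures and independent oracles used across the suite.

# Small deterministic cohort with a known sex split (4 male / 6 female).
toy_cohort <- function() {
  cohort(
    ids = sprintf("P%02d", 1:10),
    protected = data.frame(
      sex = c("male", "female", "female", "male", "female",
              "female", "male", "female", "male", "female"),
      stringsAsFactors = FALSE
    ),
    features = data.frame(score = c(3, 14, 9, 2, 21, 8, 5, 11, 1, 17)),
    labels = c(0, 1, 0, 0, 1, 0, 0, 1, 0, 1)
  )
}

# The worked reweighing example: group A 30+/70-, group B 10+/90-.
rw_example_cohort <- function() {
  cohort(
    ids = seq_len(200),
    protected = data.frame(grp = rep(c("A", "B"), each = 100),
                           stringsAsFactors = FALSE),
    features = data.frame(z = sin(seq_len(200))), # deterministic, label-free
    labels = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  )
}

# O(n^2) pairwise AUC, independent of the rank-based implementation.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# EOD as the largest absolute pairwise TPR difference, negated.
eod_brute <- function(tprs) {
  worst <- 0
  for (i in seq_along(tprs)) for (j in seq_along(tprs)) {
    worst <- max(worst, abs(tprs[i] - tprs[j]))
  }
  -worst
}

# AOD directly from the definition over all pairs of (TPR+FPR) sums.
aod_brute <- function(tprs, fprs) {
  s <- tprs + fprs
  worst <- 0
  for (i in seq_along(s)) for (j in seq_along(s)) {
    worst <- max(worst, abs(s[i] - s[j]))
  }
  -worst / 2
}

# Exhaustive-grid reference for the per-group threshold search: for one
# group, scan every candidate (observed positive scores <= t0, plus t0) and
# apply the selection rule literally.
psta_grid_oracle <- function(pos, neg, s_star, f_star, t0, delta) {
  if (mean(pos >= t0) >= s_star) return(t0)
  cand <- sort(unique(c(pos[pos <= t0 & pos > 0], t0)))
  feasible <- c()
  best_t <- NA_real_
  for (t in cand) {
    sens <- mean(pos >= t)
    fpr <- if (length(neg)) mean(neg >= t) else 0
    if (fpr <= f_star + delta + 1e-12) {
      feasible <- c(feasible, t)
      if (sens >= s_star) best_t <- max(best_t, t, na.rm = TRUE)
    }
  }
  if (!is.na(best_t)) return(best_t)
  if (!length(feasible)) return(t0)
  sens_f <- vapply(feasible, function(t) mean(pos >= t), numeric(1))
  top <- feasible[sens_f == max(sens_f)]
  max(top)
}

# Build a scored_predictions with explicit per-group rates for metric tests.
rates_fixture <- function(spec) {
  # spec: list(group = list(tp, fn, fp, tn))
  rows <- lapply(names(spec), function(g) {
    x <- spec[[g]]
    data.frame(
      label = rep(c(1, 1, 0, 0), c(x$tp, x$fn, x$fp, x$tn)),
      prediction = rep(c(1, 0, 1, 0), c(x$tp, x$fn, x$fp, x$tn)),
      group = g
    )
  })
  df <- do.call(rbind, rows)
  scored_predictions(score = ifelse(df$prediction == 1, 0.9, 0.1),
                     label = df$label, group = df$group,
                     prediction = df$prediction)
}
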