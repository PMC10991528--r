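#' Tukey pairwise comparison of subgroup rates across folds
#'
#' Treats cross-validation folds as replicates in a one-way layout (groups
#' as treatments) and applies the studentized-range (honest significant
#' difference) procedure: simultaneous 95% confidence intervals on all
#' pairwise mean differences, with a pair flagged significant when its
#' interval excludes 0. Fold dependence makes this an approximation, as it
#' is whenever the procedure is applied over k-fold replicates.
#'
#' With zero within-group variance across folds the intervals degenerate to
#' width 0 (with a warning): any non-zero mean difference is then flagged.
#'
#' @param fold_rates numeric matrix or data.frame, folds in rows and groups
#'   in columns, e.g. per-fold subgroup TPRs. No missing cells.
#' @param conf.level simultaneous confidence level.
#' @return data.frame with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean of group2 minus group1), `lwr`, `upr`, `p.value`,
#'   `significant`.
#' @export
tukey_pairwise <- function(fold_rates, conf.level = 0.95) {
  m <- as.matrix(fold_rates)
  if (anyNA(m)) stopf("fold_rates must not contain missing cells")
  k <- ncol(m)
  r <- nrow(m)
  if (k < 2L) stopf("need at least two groups")
  if (r < 2L) stopf("need at least two folds")
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(k))

  means <- colMeans(m)
  sse <- sum(sweep(m, 2L, means)^2)
  df <- k * (r - 1L)
  mse <- sse / df
  degenerate <- mse <= .Machine$double.eps
  if (degenerate) {
    warnf("zero within-group variance across folds; intervals have width 0")
  }
  se <- sqrt(mse / r) # balanced layout: se of a difference is sqrt(2) * this / sqrt(2)
  qcrit <- if (degenerate) 0 else stats::qtukey(conf.level, k, df)

  pairs <- utils::combn(colnames(m), 2L)
  out <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    diff = means[pairs[2L, ]] - means[pairs[1L, ]],
    stringsAsFactors = FALSE
  )
  half <- qcrit * se
  out$lwr <- out$diff - half
  out$upr <- out$diff + half
  out$p.value <- if (degenerate) {
    ifelse(out$diff != 0, 0, 1)
  } else {
    stats::ptukey(abs(out$diff) / se, k, df, lower.tail = FALSE)
  }
  out$significant <- out$lwr > 0 | out$upr < 0
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U comparison of two score samples
#'
#' Diagnostic for group-dependent score distributions: U counts the pairs in
#' which an `a`-sample score exceeds a `b`-sample score, with ties counted
#' half. The two-sided p-value is computed by exact enumeration of all
#' assignments when the pooled sample is small (`m + n <= exact_limit`),
#' and otherwise by the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b numeric score samples, both non-empty.
#' @param exact_limit largest pooled size for which the null distribution is
#'   enumerated exactly.
#' @return list with `statistic` (U), `p.value`, and `method`.
#' @export
mannwhitney_disparity <- function(a, b, exact_limit = 20) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  m <- length(a)
  n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2

  if (m + n <= exact_limit) {
    # Enumerate every way of assigning m of the pooled ranks to sample a.
    combos <- utils::combn(m + n, m)
    us <- apply(combos, 2L, function(idx) sum(r[idx])) - m * (m + 1) / 2
    p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
    p <- min(p, 1)
    return(list(statistic = u, p.value = p, method = "exact enumeration"))
  }

  N <- m + n
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  mu <- m * n / 2
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all observations identical
    return(list(statistic = u, p.value = 1,
                method = "normal approximation with tie correction"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(statistic = u, p.value = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation with tie correction")
}
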