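#' Suppression: remove protected attributes from the model's view
#'
#' Marks the given protected attributes as suppressed so that downstream
#' model fitting excludes them from the feature set, on the assumption that
#' access to the attribute is the source of bias. The attributes themselves
#' stay in the cohort: group membership is still needed to *evaluate*
#' fairness, just not to predict. Idempotent.
#'
#' @param x a [cohort].
#' @param attributes names of declared protected columns.
#' @return the cohort with the attributes marked suppressed.
#' @export
suppress_attributes <- function(x, attributes) {
  stopifnot(inherits(x, "cohort"))
  unknown <- setdiff(attributes, names(x$protected))
  if (length(unknown)) {
    stopf("unknown protected attribute(s): %s", paste(unknown, collapse = ", "))
  }
  attr(x, "suppressed") <- sort(unique(c(attr(x, "suppressed"), attributes)))
  x
}

#' Protected attributes visible to model fitting
#' @param x a [cohort].
#' @return character vector of non-suppressed protected attribute names.
#' @export
modeling_attributes <- function(x) {
  stopifnot(inherits(x, "cohort"))
  setdiff(names(x$protected), attr(x, "suppressed"))
}

#' Reweighing: sample weights that decouple group and outcome
#'
#' Assigns each sample in the (group, label) cell the weight
#' \deqn{w(x, c) = \hat P(C = c) / \hat P(C = c \mid X = x),}
#' directly proportional to the label's frequency in the whole population
#' and inversely proportional to its frequency within the subgroup. Under
#' these weights the protected attribute and the outcome are exactly
#' independent in the weighted empirical distribution, the total weighted
#' mass equals the sample count, and every group's weighted prevalence
#' equals the overall prevalence.
#'
#' @param x a [cohort].
#' @param attribute name of the protected attribute to decouple.
#' @return an object of class `sample_weights`: data.frame with columns
#'   `id`, `group`, `label`, `weight`; attribute `attribute` records the
#'   provenance.
#' @examples
#' co <- cohort(ids = 1:8,
#'              protected = data.frame(sex = rep(c("f", "m"), each = 4)),
#'              features = data.frame(z = rnorm(8)),
#'              labels = c(1, 1, 0, 0, 1, 0, 0, 0))
#' reweigh(co, "sex")
#' @export
reweigh <- function(x, attribute) {
  stopifnot(inherits(x, "cohort"))
  if (!attribute %in% names(x$protected)) {
    stopf("unknown protected attribute: %s", attribute)
  }
  g <- as.character(x$protected[[attribute]])
  c01 <- x$labels
  n <- length(c01)
  p_c <- table(factor(c01, levels = c(0, 1))) / n
  w <- numeric(n)
  for (ct in unique(g)) {
    in_g <- g == ct
    n_g <- sum(in_g)
    for (lab in c(0L, 1L)) {
      cell <- in_g & c01 == lab
      if (!any(cell)) next
      p_c_given_g <- sum(cell) / n_g
      w[cell] <- as.numeric(p_c[as.character(lab)]) / p_c_given_g
    }
  }
  out <- data.frame(id = x$ids, group = g, label = c01, weight = w,
                    stringsAsFactors = FALSE)
  attr(out, "attribute") <- attribute
  class(out) <- c("sample_weights", "data.frame")
  out
}

#' Write sample weights to CSV
#' @param w a [reweigh()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_weights <- function(w, path) {
  stopifnot(inherits(w, "sample_weights"))
  utils::write.csv(as.data.frame(w), path, row.names = FALSE)
  invisible(path)
}

#' Disparate impact removal: fit the quantile repair model
#'
#' Learns, for each selected numeric/ordinal feature, the empirical quantile
#' function of every subgroup and a common target distribution defined as
#' the per-rank median across the group quantile functions. Applying the
#' repair maps each value through its own group's rank to the target, so at
#' full repair (`lambda = 1`) all groups follow (up to discretization) the
#' same distribution over every repaired feature and group membership can no
#' longer be read off them. `lambda = 0` is the identity; intermediate
#' values interpolate linearly.
#'
#' @param x a [cohort] (typically the training split).
#' @param attribute protected attribute whose subgroup distributions are
#'   equalized.
#' @param features names of numeric/ordinal feature columns to repair;
#'   default: every numeric feature column. Categorical features are not
#'   repairable (quantiles of unordered categories are undefined) and
#'   naming one is an error.
#' @param lambda repair level in `[0, 1]`.
#' @return an object of class `repair_model`.
#' @export
dir_fit <- function(x, attribute, features = NULL, lambda = 1) {
  stopifnot(inherits(x, "cohort"))
  if (!attribute %in% names(x$protected)) {
    stopf("unknown protected attribute: %s", attribute)
  }
  if (lambda < 0 || lambda > 1) stopf("lambda must lie in [0, 1]")
  numeric_cols <- names(x$features)[vapply(x$features, is.numeric, logical(1))]
  features <- features %||% numeric_cols
  bad <- setdiff(features, numeric_cols)
  if (length(bad)) {
    stopf("cannot quantile-repair non-numeric feature(s): %s",
          paste(bad, collapse = ", "))
  }
  g <- as.character(x$protected[[attribute]])
  cats <- sort(unique(g))
  qfuns <- lapply(features, function(f) {
    v <- x$features[[f]]
    per_group <- lapply(cats, function(ct) {
      vals <- sort(v[g == ct & !is.na(v)])
      if (length(vals) < 2L) {
        stopf("group '%s' has fewer than 2 values for feature '%s'", ct, f)
      }
      vals
    })
    names(per_group) <- cats
    per_group
  })
  names(qfuns) <- features
  structure(
    list(attribute = attribute, features = features, lambda = lambda,
         groups = cats, qfuns = qfuns),
    class = "repair_model"
  )
}

# Inverse empirical CDF at rank u in (0, 1]: the ceiling(u * n)-th order
# statistic.
quantile_at <- function(sorted_vals, u) {
  n <- length(sorted_vals)
  idx <- pmin(pmax(ceiling(u * n), 1L), n)
  sorted_vals[idx]
}

#' Apply a fitted quantile repair to a cohort
#'
#' Each sample's value is ranked within its own subgroup's training
#' distribution and replaced by the interpolation
#' `(1 - lambda) * v + lambda * Q_target(rank)`. Unseen groups at apply time
#' fall back to the identity with a warning. The treated protected
#' attribute is marked suppressed in the output, since the repair exists to
#' remove it (and its trace in correlated features) from the model's view.
#'
#' @param model a [dir_fit()] result.
#' @param x a [cohort] to repair (training or held-out split).
#' @return the repaired cohort.
#' @export
dir_apply <- function(model, x) {
  stopifnot(inherits(model, "repair_model"), inherits(x, "cohort"))
  g <- as.character(x$protected[[model$attribute]])
  unseen <- setdiff(unique(g), model$groups)
  if (length(unseen)) {
    warnf("group(s) unseen at fit time left unrepaired: %s",
          paste(unseen, collapse = ", "))
  }
  lam <- model$lambda
  for (f in model$features) {
    v <- x$features[[f]]
    repaired <- v
    for (ct in intersect(unique(g), model$groups)) {
      in_g <- which(g == ct & !is.na(v))
      if (!length(in_g)) next
      train_vals <- model$qfuns[[f]][[ct]]
      # rank of v within its group's training distribution
      u <- findInterval(v[in_g], train_vals) / length(train_vals)
      u <- pmax(u, 1 / length(train_vals))
      qmat <- vapply(model$groups, function(gg) {
        quantile_at(model$qfuns[[f]][[gg]], u)
      }, numeric(length(u)))
      qmat <- matrix(qmat, nrow = length(u))
      targets <- if (ncol(qmat) <= 2L) {
        rowMeans(qmat)
      } else {
        apply(qmat, 1L, stats::median)
      }
      repaired[in_g] <- (1 - lam) * v[in_g] + lam * targets
    }
    x$features[[f]] <- repaired
  }
  suppress_attributes(x, model$attribute)
}
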