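#' Cross-validation scheme
#'
#' @param k outer fold count (e.g. 5 for very large cohorts, 10 otherwise).
#' @param inner_k inner fold count for hyperparameter tuning; 0 disables
#'   tuning.
#' @param stratified stratify outer folds on the outcome label (stabilizes
#'   subgroup rate estimates when prevalence is low).
#' @param seed integer seed controlling fold assignment and model fitting.
#' @return an object of class `cv_scheme`.
#' @export
cv_scheme <- function(k = 10, inner_k = 3, stratified = TRUE, seed = 1) {
  if (k < 2L) stopf("k must be at least 2")
  structure(list(k = as.integer(k), inner_k = as.integer(inner_k),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Scenario specification
#'
#' One cell of an evaluation grid: a model family combined with one
#' mitigation technique, targeting one protected attribute, evaluated under
#' a cross-validation scheme. `eval_attributes` may list further protected
#' attributes whose fairness is audited on the same predictions (for
#' spillover analysis of untreated attributes).
#'
#' @param model `"logistic"` or `"xgboost"`.
#' @param mitigation one of `"none"`, `"sup"`, `"rw"`, `"dir"`, `"cpp"`,
#'   `"psta"`.
#' @param attribute protected attribute under treatment (and primary
#'   evaluation attribute).
#' @param eval_attributes attributes to audit; defaults to `attribute`.
#' @param cv a [cv_scheme()].
#' @param options named list of mitigation options: `lambda` (DIR repair
#'   level), `t0` and `delta` (PSTA), `beta` (fairness weight in reports).
#' @param cohort_label free-text label identifying the cohort, used to key
#'   comparison grids.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(model = c("logistic", "xgboost"),
                          mitigation = c("none", "sup", "rw", "dir", "cpp", "psta"),
                          attribute,
                          eval_attributes = attribute,
                          cv = cv_scheme(),
                          options = list(),
                          cohort_label = "cohort") {
  model <- match.arg(model)
  mitigation <- match.arg(mitigation)
  stopifnot(inherits(cv, "cv_scheme"))
  known <- c("lambda", "t0", "delta", "beta", "cpp_seed")
  bad <- setdiff(names(options), known)
  if (length(bad)) stopf("unknown option(s): %s", paste(bad, collapse = ", "))
  eval_attributes <- unique(c(attribute, eval_attributes))
  structure(
    list(model = model, mitigation = mitigation, attribute = attribute,
         eval_attributes = eval_attributes, cv = cv, options = options,
         cohort_label = cohort_label),
    class = "scenario_spec"
  )
}

spec_hash <- function(spec) {
  fnv1a32(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA,
                           force = TRUE))
}

#' Run one cross-validated scenario
#'
#' Implements the evaluation protocol: stratified outer k-fold split;
#' per fold, pre-processing mitigation applied to the training split only
#' (suppression, reweighing, or quantile repair fitted on training data and
#' applied to both splits), model fitting with inner-CV hyperparameter
#' tuning, post-processing policies (score mixing or per-group thresholds)
#' fitted on the training predictions only, and all metrics computed on the
#' held-out fold. Folds whose training or test split lacks one of the
#' classes are skipped with a warning; a scenario with more than half its
#' folds skipped is an error.
#'
#' @param spec a [scenario_spec()].
#' @param x a [cohort].
#' @return an object of class `scenario_result`: list with `spec`, `folds`
#'   (per-fold metric lists, including per-attribute EOD/AOD and rate
#'   tables), `policies` (fitted post-processing policies per fold),
#'   `summary` (mean, sd and normal-approximation 95% CI per metric) and
#'   `provenance` (spec hash, seed, package version).
#' @export
run_scenario <- function(spec, x) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(x, "cohort"))
  if (!spec$attribute %in% names(x$protected)) {
    stopf("attribute '%s' not in cohort", spec$attribute)
  }
  missing_eval <- setdiff(spec$eval_attributes, names(x$protected))
  if (length(missing_eval)) {
    stopf("evaluation attribute(s) not in cohort: %s",
          paste(missing_eval, collapse = ", "))
  }
  k <- spec$cv$k
  beta <- spec$options$beta %||% 0.5
  fold_id <- with_local_seed(spec$cv$seed,
                             make_folds(x$labels, k, spec$cv$stratified))
  folds <- vector("list", k)
  policies <- vector("list", k)
  skipped <- 0L
  for (f in seq_len(k)) {
    te_idx <- which(fold_id == f)
    tr_idx <- which(fold_id != f)
    if (length(unique(x$labels[tr_idx])) < 2L ||
        length(unique(x$labels[te_idx])) < 2L) {
      warnf("fold %d skipped: single-class split", f)
      skipped <- skipped + 1L
      next
    }
    fold_seed <- (spec$cv$seed * 131L + f) %% .Machine$integer.max
    res <- run_fold(spec, x[tr_idx], x[te_idx], beta, fold_seed)
    folds[[f]] <- res$metrics
    policies[[f]] <- res$policy
  }
  if (skipped > k / 2) stopf("more than half of the folds were skipped")

  structure(
    list(spec = spec,
         folds = folds,
         policies = policies,
         summary = summarize_folds(folds),
         provenance = list(spec_hash = spec_hash(spec),
                           seed = spec$cv$seed,
                           package_version =
                             as.character(utils::packageVersion("fairdep")))),
    class = "scenario_result"
  )
}

run_fold <- function(spec, tr, te, beta, fold_seed) {
  attribute <- spec$attribute
  opts <- spec$options
  weights <- NULL
  if (spec$mitigation == "sup") {
    tr <- suppress_attributes(tr, attribute)
    te <- suppress_attributes(te, attribute)
  } else if (spec$mitigation == "rw") {
    weights <- reweigh(tr, attribute)$weight
  } else if (spec$mitigation == "dir") {
    rm_model <- dir_fit(tr, attribute, lambda = opts$lambda %||% 1)
    tr <- dir_apply(rm_model, tr)
    te <- dir_apply(rm_model, te)
  }

  model <- train_model(spec$model, model_frame(tr), tr$labels,
                       weights = weights, inner_k = spec$cv$inner_k,
                       seed = fold_seed)
  train_pred <- scored_predictions(predict(model, model_frame(tr)),
                                   tr$labels, tr$protected[[attribute]])
  test_pred <- scored_predictions(predict(model, model_frame(te)),
                                  te$labels, te$protected[[attribute]])

  policy <- NULL
  if (spec$mitigation == "cpp") {
    policy <- cpp_fit(train_pred, seed = opts$cpp_seed %||% fold_seed)
    test_pred <- cpp_apply(policy, test_pred)
  } else if (spec$mitigation == "psta") {
    policy <- psta_fit(train_pred, t0 = opts$t0 %||% 0.5,
                       delta = opts$delta %||% 0.10)
    test_pred <- psta_apply(policy, test_pred)
  }

  metrics <- fold_metrics(test_pred, te, spec$eval_attributes, attribute, beta)
  list(metrics = metrics, policy = policy)
}

model_frame <- function(x) {
  keep <- modeling_attributes(x)
  prot <- x$protected[, keep, drop = FALSE]
  prot[] <- lapply(prot, as.character)
  if (ncol(prot)) cbind(x$features, prot) else x$features
}

fold_metrics <- function(test_pred, te, eval_attributes, attribute, beta) {
  per_attr <- lapply(eval_attributes, function(a) {
    pr <- scored_predictions(score = test_pred$score, label = test_pred$label,
                             group = te$protected[[a]],
                             prediction = test_pred$prediction)
    rates <- group_rates(pr)
    list(
      eod = tryCatch(eod(rates), error = function(e) NA_real_),
      aod = tryCatch(aod(rates), error = function(e) NA_real_),
      rates = as.data.frame(rates)
    )
  })
  names(per_attr) <- eval_attributes
  b <- balanced_accuracy(test_pred)
  e <- per_attr[[attribute]]$eod
  list(
    bacc = b,
    auc = auc_roc(test_pred$score, test_pred$label),
    eod = e,
    aod = per_attr[[attribute]]$aod,
    abs_eod = abs(e),
    delta = if (is.na(e)) NA_real_ else delta_score(b, e, beta),
    attributes = per_attr
  )
}

summarize_folds <- function(folds) {
  done <- folds[!vapply(folds, is.null, logical(1))]
  metrics <- c("bacc", "auc", "eod", "aod", "abs_eod", "delta")
  out <- lapply(metrics, function(m) {
    v <- vapply(done, function(fl) fl[[m]], numeric(1))
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(list(mean = NA_real_, sd = NA_real_,
                  ci_lo = NA_real_, ci_hi = NA_real_, n_folds = 0L))
    }
    se <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
         ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se,
         n_folds = length(v))
  })
  names(out) <- metrics
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scenario_result> %s | %s on '%s' | k = %d\n",
              x$spec$model, x$spec$mitigation, x$spec$attribute, x$spec$cv$k))
  for (m in names(s)) {
    cat(sprintf("  %-8s %.4f (95%% CI %.4f..%.4f)\n", m, s[[m]]$mean,
                s[[m]]$ci_lo, s[[m]]$ci_hi))
  }
  invisible(x)
}

#' Serialize a scenario result to JSON
#'
#' Deterministic given the spec and seed: two runs of the same scenario on
#' the same cohort produce byte-identical JSON.
#'
#' @param x a [run_scenario()] result.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
scenario_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "scenario_result"))
  obj <- list(
    spec = unclass_deep(x$spec),
    folds = lapply(x$folds, function(fl) {
      if (is.null(fl)) return(NULL)
      fl$attributes <- lapply(fl$attributes, function(a) {
        list(eod = a$eod, aod = a$aod, rates = a$rates)
      })
      fl
    }),
    summary = x$summary,
    provenance = x$provenance
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
  }
  if (!is.data.frame(x)) x <- unclass(x)
  x
}

#' Compare mitigation methods by fairness-accuracy score
#'
#' Given scenario results sharing a (cohort, model, attribute) grid, computes
#' the mean per-fold fairness-accuracy score of every method in every
#' scenario cell, declares the method(s) with the highest score the winner
#' of the cell (ties are shared and flagged), and tallies wins and win
#' percentages per method.
#'
#' @param results list of [run_scenario()] results.
#' @param beta fairness weight used to (re)compute the score from each
#'   fold's balanced accuracy and EOD.
#' @return list with `table` (per cell and method: score and winner flag),
#'   `tally` (per method: wins, win percentage), and `ties` (cells whose win
#'   was shared).
#' @export
compare_methods <- function(results, beta = 0.5) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "scenario_result"))
    done <- r$folds[!vapply(r$folds, is.null, logical(1))]
    d <- vapply(done, function(fl) {
      if (is.na(fl$eod)) NA_real_ else delta_score(fl$bacc, fl$eod, beta)
    }, numeric(1))
    data.frame(
      scenario = paste(r$spec$cohort_label, r$spec$model, r$spec$attribute,
                       sep = "/"),
      method = r$spec$mitigation,
      delta = mean(d, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab[, c("scenario", "method")])) {
    stopf("duplicate (scenario, method) cells")
  }
  tab$winner <- FALSE
  ties <- character(0)
  for (sc in unique(tab$scenario)) {
    in_sc <- tab$scenario == sc
    best <- max(tab$delta[in_sc])
    win <- in_sc & abs(tab$delta - best) < 1e-12
    tab$winner[win] <- TRUE
    if (sum(win) > 1L) ties <- c(ties, sc)
  }
  n_cells <- length(unique(tab$scenario))
  methods <- sort(unique(tab$method))
  tally <- data.frame(
    method = methods,
    wins = vapply(methods, function(m) sum(tab$winner[tab$method == m]),
                  numeric(1)),
    stringsAsFactors = FALSE
  )
  tally$win_pct <- 100 * tally$wins / n_cells
  rownames(tally) <- NULL
  list(table = tab, tally = tally, ties = unique(ties))
}

#' Spillover of mitigation onto untreated attributes
#'
#' Quantifies the unintended fairness consequences of mitigating bias for
#' one protected attribute on other, untreated attributes: for each listed
#' attribute the change in `|EOD|` and `|AOD|` (fold means, mitigated minus
#' base). Positive values mean fairness for that attribute worsened.
#'
#' @param result a mitigated [run_scenario()] result whose
#'   `eval_attributes` include the attributes of interest.
#' @param base the corresponding unmitigated (`mitigation = "none"`) result.
#' @param attributes untreated attributes to examine.
#' @return data.frame with columns `attribute`, `d_abs_eod`, `d_abs_aod`.
#' @export
spillover_analysis <- function(result, base, attributes) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(base, "scenario_result"))
  attr_mean <- function(r, a, metric) {
    done <- r$folds[!vapply(r$folds, is.null, logical(1))]
    v <- vapply(done, function(fl) {
      if (is.null(fl$attributes[[a]])) {
        stopf("attribute '%s' was not evaluated in this result", a)
      }
      abs(fl$attributes[[a]][[metric]])
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }
  rows <- lapply(attributes, function(a) {
    data.frame(
      attribute = a,
      d_abs_eod = attr_mean(result, a, "eod") - attr_mean(base, a, "eod"),
      d_abs_aod = attr_mean(result, a, "aod") - attr_mean(base, a, "aod"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
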