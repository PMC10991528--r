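# Model fitting plumbing: a uniform probability-scorer interface over
# regularized logistic regression (glmnet) and gradient-boosted trees
# (xgboost), with optional per-sample weights and inner-CV tuning.

# Record how to turn a mixed-type feature frame into a numeric matrix:
# treatment-coded indicators for categorical columns (levels frozen at fit
# time) and median-filled numeric columns.
design_build <- function(df) {
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      list(name = nm, kind = "numeric",
           fill = stats::median(v, na.rm = TRUE))
    } else {
      list(name = nm, kind = "categorical",
           levels = sort(unique(as.character(v))))
    }
  })
  names(cols) <- names(df)
  structure(list(cols = cols), class = "design_info")
}

design_matrix <- function(info, df) {
  parts <- lapply(info$cols, function(cl) {
    v <- df[[cl$name]]
    if (cl$kind == "numeric") {
      v <- as.numeric(v)
      v[is.na(v)] <- cl$fill
      m <- matrix(v, ncol = 1L)
      colnames(m) <- cl$name
      m
    } else {
      v <- as.character(v)
      lev <- cl$levels
      if (length(lev) < 2L) {
        return(NULL) # constant column carries no information
      }
      m <- vapply(lev[-1L], function(l) as.numeric(v == l),
                  numeric(length(v)))
      m <- matrix(m, nrow = length(v))
      colnames(m) <- paste0(cl$name, ".", lev[-1L])
      m
    }
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stopf("no usable feature columns")
  do.call(cbind, parts)
}

#' Train a probability-scoring classifier
#'
#' Uniform interface over the two model families used throughout the
#' package: ridge-penalized logistic regression (glmnet, penalty chosen by
#' inner cross-validation over a small grid) and gradient-boosted trees
#' (xgboost, depth and learning rate tuned over a small grid). Both honor
#' per-sample weights and are deterministic given `seed`.
#'
#' @param kind `"logistic"` or `"xgboost"`.
#' @param features data.frame of predictors (numeric and/or categorical).
#' @param labels binary outcome in `{0, 1}`.
#' @param weights optional positive per-sample weights (normalized
#'   internally to sum to the sample count).
#' @param inner_k inner cross-validation folds for hyperparameter tuning;
#'   values below 3 disable tuning and use the family's near-unpenalized
#'   default (cross-validated tuning needs at least 3 folds).
#' @param seed integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @return an object of class `risk_model` with a [predict.risk_model()]
#'   method returning probabilities.
#' @export
train_model <- function(kind = c("logistic", "xgboost"), features, labels,
                        weights = NULL, inner_k = 3, seed = 1) {
  kind <- match.arg(kind)
  labels <- validate_binary_labels(labels)
  if (length(unique(labels)) < 2L) {
    stopf("training labels contain a single class")
  }
  if (!is.null(weights)) {
    if (any(weights <= 0)) stopf("weights must be positive")
    weights <- weights * length(weights) / sum(weights)
  }
  info <- design_build(features)
  x <- design_matrix(info, features)
  padded <- FALSE
  if (ncol(x) < 2L) { # glmnet requires >= 2 columns
    x <- cbind(x, .pad = 0)
    padded <- TRUE
  }
  fit <- if (kind == "logistic") {
    fit_logistic(x, labels, weights, inner_k, seed)
  } else {
    fit_xgboost(x, labels, weights, inner_k, seed)
  }
  structure(list(kind = kind, design = info, fit = fit, padded = padded),
            class = "risk_model")
}

fit_logistic <- function(x, y, w, inner_k, seed) {
  grid <- c(1e-1, 1e-2, 1e-3, 1e-4)
  w <- w %||% rep(1, length(y))
  if (inner_k >= 3L) {
    foldid <- with_local_seed(seed, make_folds(y, inner_k, stratified = TRUE))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", weights = w,
                            alpha = 0, lambda = grid, foldid = foldid,
                            type.measure = "deviance")
    lambda <- cv$lambda.min
  } else {
    lambda <- 1e-4
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", weights = w,
                        alpha = 0, lambda = grid)
  list(model = fit, lambda = lambda)
}

fit_xgboost <- function(x, y, w, inner_k, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y,
                                 weight = w %||% rep(1, length(y)))
  base <- list(objective = "binary:logistic", eval_metric = "logloss",
               nthread = 1)
  nrounds <- 60
  if (inner_k >= 3L) {
    grid <- expand.grid(max_depth = c(2, 4, 6), eta = c(0.05, 0.1, 0.3))
    losses <- vapply(seq_len(nrow(grid)), function(i) {
      params <- c(base, list(max_depth = grid$max_depth[i], eta = grid$eta[i],
                             seed = seed))
      cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = nrounds,
                            nfold = inner_k, verbose = 0, stratified = TRUE)
      min(cv$evaluation_log$test_logloss_mean)
    }, numeric(1))
    best <- which.min(losses)
    params <- c(base, list(max_depth = grid$max_depth[best],
                           eta = grid$eta[best], seed = seed))
  } else {
    params <- c(base, list(max_depth = 3, eta = 0.3, seed = seed))
  }
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = nrounds, verbose = 0)
  list(model = model, params = params, nrounds = nrounds)
}

#' Predict probabilities from a fitted risk model
#'
#' @param object a [train_model()] result.
#' @param newdata data.frame with the training feature columns.
#' @param ... unused.
#' @return numeric vector of predicted probabilities in `[0, 1]`.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  x <- design_matrix(object$design, newdata)
  if (object$padded) x <- cbind(x, .pad = 0)
  p <- if (object$kind == "logistic") {
    as.numeric(stats::predict(object$fit$model, newx = x,
                              s = object$fit$lambda, type = "response"))
  } else {
    as.numeric(stats::predict(object$fit$model, xgboost::xgb.DMatrix(x)))
  }
  pmin(pmax(p, 0), 1)
}

#' Extract logistic coefficients from a risk model
#'
#' @param object a logistic [train_model()] result.
#' @param ... unused.
#' @return named numeric vector including the intercept.
#' @export
coef.risk_model <- function(object, ...) {
  if (object$kind != "logistic") stopf("coefficients only for logistic models")
  cf <- stats::coef(object$fit$model, s = object$fit$lambda)
  stats::setNames(as.numeric(cf), rownames(cf))
}

# Fold assignment: per class, shuffle then deal round-robin, so folds are
# stratified on the outcome; uses the current RNG state.
make_folds <- function(labels, k, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  fold
}
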