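#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with the statistical structure that drives algorithmic
#' bias in clinical risk prediction: group-dependent outcome prevalence
#' (by default the roughly two-to-one female-to-male ratio reported for
#' depression), skewed subgroup sizes, and "proxy" features correlated with
#' a protected attribute so that merely removing that attribute does not
#' remove the bias.
#'
#' The outcome is drawn from a logistic model in the informative features
#' plus a per-group intercept solved numerically so that each group's
#' expected prevalence matches `prevalence`.
#'
#' @param n number of participants.
#' @param group_spec named list: one element per protected attribute, each a
#'   named numeric vector of category mixture proportions summing to 1.
#' @param prevalence named numeric vector of outcome probabilities in (0, 1),
#'   keyed by the categories of the *first* attribute in `group_spec` (the
#'   prevalence-bearing attribute).
#' @param n_features number of informative numeric features.
#' @param effect_scale log-odds coefficient of the strongest informative
#'   feature; the k-th feature has coefficient `effect_scale * 0.8^(k-1)`.
#' @param n_proxy number of proxy features correlated with the first
#'   protected attribute.
#' @param proxy_strength target correlation in `[0, 1]` between each proxy
#'   feature and the (numerically coded) first protected attribute.
#' @param proxy_effect log-odds coefficient of each proxy feature on the
#'   outcome. A non-zero value routes part of the between-group prevalence
#'   gap *through* the proxies — the structure that makes removing the
#'   protected attribute alone (suppression) insufficient while making
#'   distributional repair of the proxies effective.
#' @param noise_sd standard deviation of feature noise.
#' @param attr_correlation latent Gaussian-copula correlation between the
#'   first protected attribute and each further attribute (0 = independent;
#'   negative values induce negative association).
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 10000,
                             group_spec = list(sex = c(female = 0.5, male = 0.5)),
                             prevalence = c(female = 0.08, male = 0.04),
                             n_features = 5,
                             effect_scale = 0.8,
                             n_proxy = 2,
                             proxy_strength = 0.5,
                             proxy_effect = 0.6,
                             noise_sd = 1,
                             attr_correlation = 0,
                             seed = 1) {
  stopifnot(n >= 1, n_features >= 0, effect_scale >= 0, n_proxy >= 0,
            noise_sd > 0)
  if (!length(group_spec) || is.null(names(group_spec))) {
    stopf("group_spec must be a named list of attribute proportion vectors")
  }
  for (a in names(group_spec)) {
    p <- group_spec[[a]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p <= 0)) {
      stopf("proportions for '%s' must be named, positive and sum to 1", a)
    }
  }
  cats1 <- names(group_spec[[1L]])
  if (!setequal(names(prevalence), cats1)) {
    stopf("prevalence must be keyed by the categories of '%s'",
          names(group_spec)[1L])
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stopf("prevalences must lie strictly inside (0, 1)")
  }
  if (proxy_strength < 0 || proxy_strength > 1) {
    stopf("proxy_strength must lie in [0, 1]")
  }
  if (abs(attr_correlation) >= 1) stopf("attr_correlation must lie in (-1, 1)")
  structure(
    list(n = as.integer(n), group_spec = group_spec, prevalence = prevalence,
         n_features = as.integer(n_features), effect_scale = effect_scale,
         n_proxy = as.integer(n_proxy),
         proxy_strength = proxy_strength, proxy_effect = proxy_effect,
         noise_sd = noise_sd,
         attr_correlation = attr_correlation, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Read a synthetic cohort configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [synthetic_config()]; `group_spec` and `prevalence` as nested maps.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  names(y)[names(y) %in% c("FALSE", "no")] <- "n"
  if (!is.null(y$group_spec)) y$group_spec <- lapply(y$group_spec, unlist)
  if (!is.null(y$prevalence)) y$prevalence <- unlist(y$prevalence)
  do.call(synthetic_config, y)
}

#' Generate a synthetic cohort
#'
#' Protected attributes are sampled from their mixture proportions (further
#' attributes optionally coupled to the first through a Gaussian copula).
#' Informative features are standard normal with geometrically decaying
#' log-odds coefficients; proxy features are Gaussian with group-shifted
#' means calibrated so their correlation with the first attribute equals
#' `proxy_strength`. The outcome is Bernoulli with logistic probability
#' `plogis(b_g + eta)` where the group intercept `b_g` is found by bisection
#' so the group's expected prevalence matches the configuration.
#'
#' @param config a [synthetic_config()].
#' @return a [cohort]; proxy features are named `proxy1, proxy2, ...`.
#' @examples
#' cfg <- synthetic_config(n = 500, seed = 42)
#' co <- generate_cohort(cfg)
#' tapply(co$labels, co$protected$sex, mean)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    n <- config$n
    attrs <- sample_protected(config)
    g1 <- attrs[[1L]]

    feats <- list()
    if (config$n_features > 0) {
      for (k in seq_len(config$n_features)) {
        feats[[paste0("f", k)]] <- stats::rnorm(n)
      }
    }
    if (config$n_proxy > 0) {
      code <- group_code(g1, config$group_spec[[1L]])
      for (k in seq_len(config$n_proxy)) {
        feats[[paste0("proxy", k)]] <-
          proxy_feature(code, config$proxy_strength, config$noise_sd)
      }
    }
    features <- as.data.frame(feats)
    if (!ncol(features)) features <- data.frame(row.names = seq_len(n))

    eta <- rep(0, n)
    if (config$n_features > 0) {
      beta <- config$effect_scale * 0.8^(seq_len(config$n_features) - 1)
      eta <- eta + drop(
        as.matrix(features[, paste0("f", seq_len(config$n_features)),
                           drop = FALSE]) %*% beta)
    }
    if (config$n_proxy > 0 && config$proxy_effect != 0) {
      eta <- eta + config$proxy_effect * rowSums(
        features[, paste0("proxy", seq_len(config$n_proxy)), drop = FALSE])
    }

    p <- numeric(n)
    for (ct in names(config$prevalence)) {
      in_g <- as.character(g1) == ct
      b <- solve_group_intercept(eta[in_g], config$prevalence[[ct]])
      p[in_g] <- stats::plogis(b + eta[in_g])
    }
    labels <- stats::rbinom(n, 1L, p)

    cohort(
      ids = sprintf("S%06d", seq_len(n)),
      protected = as.data.frame(attrs, stringsAsFactors = FALSE),
      features = features,
      labels = labels
    )
  })
}

# Sample all protected attributes; attributes after the first share a latent
# Gaussian with the first at correlation attr_correlation.
sample_protected <- function(config) {
  n <- config$n
  specs <- config$group_spec
  z1 <- stats::rnorm(n)
  out <- list()
  for (j in seq_along(specs)) {
    p <- specs[[j]]
    z <- if (j == 1L || config$attr_correlation == 0) {
      if (j == 1L) z1 else stats::rnorm(n)
    } else {
      r <- config$attr_correlation
      r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    }
    cuts <- stats::qnorm(cumsum(p))
    cuts[length(cuts)] <- Inf
    out[[names(specs)[j]]] <- names(p)[findInterval(z, cuts) + 1L]
  }
  out
}

# Centered, unit-variance numeric coding of the categories (population
# moments from the configured proportions).
group_code <- function(g, proportions) {
  lev <- names(proportions)
  raw <- seq_along(lev) - 1
  mu <- sum(proportions * raw)
  s2 <- sum(proportions * (raw - mu)^2)
  code <- (raw - mu) / sqrt(max(s2, .Machine$double.eps))
  code[match(as.character(g), lev)]
}

# Gaussian feature whose population correlation with the unit-variance group
# code equals r; r = 1 degenerates to the code itself.
proxy_feature <- function(code, r, noise_sd) {
  if (r >= 1) return(code)
  a <- noise_sd * r / sqrt(1 - r^2)
  a * code + stats::rnorm(length(code), sd = noise_sd)
}

# Bisection on the intercept b so that mean(plogis(b + eta)) = target.
solve_group_intercept <- function(eta, target) {
  f <- function(b) mean(stats::plogis(b + eta)) - target
  lo <- -30; hi <- 30
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' Configuration for a synthetic scored population
#'
#' Emulates the per-group predicted-probability distributions an ML model
#' produces when trained under group-dependent prevalence: each group has its
#' own score law (a truncated normal on `[0, 1]`, so `location` is directly
#' interpretable on the probability scale) for positives and negatives.
#'
#' @param groups named list; each element a list with `n` (group size),
#'   `prevalence` (positive fraction), `pos` and `neg` (each `c(location,
#'   scale)` of the truncated-normal score law).
#' @param seed integer seed.
#' @return an object of class `scoreset_config`.
#' @examples
#' scoreset_config(groups = list(
#'   female = list(n = 100, prevalence = 0.1, pos = c(0.7, 0.15), neg = c(0.3, 0.15)),
#'   male   = list(n = 100, prevalence = 0.1, pos = c(0.55, 0.15), neg = c(0.25, 0.15))
#' ))
#' @export
scoreset_config <- function(groups, seed = 1) {
  if (!length(groups) || is.null(names(groups))) {
    stopf("groups must be a named list")
  }
  for (g in names(groups)) {
    el <- groups[[g]]
    if (is.null(el$n) || el$n < 1) stopf("group '%s' needs a size n >= 1", g)
    if (is.null(el$prevalence) || el$prevalence < 0 || el$prevalence > 1) {
      stopf("group '%s' needs prevalence in [0, 1]", g)
    }
    for (side in c("pos", "neg")) {
      if (length(el[[side]]) != 2L || el[[side]][2L] < 0) {
        stopf("group '%s' needs %s = c(location, scale >= 0)", g, side)
      }
    }
  }
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "scoreset_config")
}

#' Generate a scored population
#'
#' Draws labels per group at the configured prevalence and scores from the
#' configured truncated-normal laws, returning a [scored_predictions] with
#' hard predictions at threshold 0.5.
#'
#' @param config a [scoreset_config()].
#' @return a [scored_predictions].
#' @export
generate_scored_population <- function(config) {
  stopifnot(inherits(config, "scoreset_config"))
  with_local_seed(config$seed, {
    parts <- lapply(names(config$groups), function(g) {
      el <- config$groups[[g]]
      n_pos <- stats::rbinom(1L, el$n, el$prevalence)
      n_neg <- el$n - n_pos
      data.frame(
        score = c(rtnorm01(n_pos, el$pos[1L], el$pos[2L]),
                  rtnorm01(n_neg, el$neg[1L], el$neg[2L])),
        label = rep(c(1L, 0L), c(n_pos, n_neg)),
        group = g,
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, parts)
    scored_predictions(score = df$score, label = df$label, group = df$group)
  })
}
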