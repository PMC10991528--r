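# Scored two-group population with a configurable score gap for the
# post-processing tests.
shifted_population <- function(n_per_group = 5000, shift = 0.15, seed = 41) {
  generate_scored_population(scoreset_config(groups = list(
    female = list(n = n_per_group, prevalence = 0.10,
                  pos = c(0.60, 0.15), neg = c(0.30, 0.15)),
    male = list(n = n_per_group, prevalence = 0.04,
                pos = c(0.60 - shift, 0.15), neg = c(0.30 - shift, 0.15))
  ), seed = seed))
}

gfnr <- function(pred, grp) {
  pos <- pred$group == grp & pred$label == 1
  mean(1 - pred$score[pos])
}

test_that("equal generalized costs produce a pass-through policy", {
  sp <- generate_scored_population(scoreset_config(groups = list(
    a = list(n = 4000, prevalence = 0.1, pos = c(0.6, 0.1), neg = c(0.3, 0.1)),
    b = list(n = 4000, prevalence = 0.1, pos = c(0.6, 0.1), neg = c(0.3, 0.1))
  ), seed = 43))
  pol <- cpp_fit(sp, seed = 1)
  expect_lt(max(pol$alpha), 0.02) # sampling noise only
  out <- cpp_apply(pol, sp)
  untouched <- pol$group[pol$alpha == 0]
  expect_equal(out$score[sp$group %in% untouched],
               sp$score[sp$group %in% untouched])
})

test_that("the mixing rate matches its closed form and equalizes costs", {
  sp <- shifted_population(n_per_group = 10000, seed = 47)
  pol <- cpp_fit(sp, seed = 5)
  g_f <- gfnr(sp, "female")
  g_m <- gfnr(sp, "male")
  # male has the lower score hence higher cost; female gets mixed
  expect_gt(g_m, g_f)
  base_f <- mean(sp$label[sp$group == "female"])
  alpha_expected <- (g_m - g_f) / ((1 - base_f) - g_f)
  expect_equal(pol$alpha[pol$group == "female"], alpha_expected,
               tolerance = 1e-12)
  expect_equal(pol$alpha[pol$group == "male"], 0)

  out <- cpp_apply(pol, sp)
  expect_lt(abs(gfnr(out, "female") - gfnr(out, "male")), 0.01)
  expect_true(all(pol$alpha >= 0 & pol$alpha <= 1))
})

test_that("mixing is reproducible from the policy seed", {
  sp <- shifted_population(n_per_group = 2000, seed = 53)
  pol <- cpp_fit(sp, seed = 9)
  expect_identical(cpp_apply(pol, sp)$score, cpp_apply(pol, sp)$score)
})

test_that("a group without positives cannot be calibrated", {
  pred <- scored_predictions(score = c(0.2, 0.8, 0.4, 0.6),
                             label = c(1, 0, 0, 0),
                             group = c("a", "a", "b", "b"))
  expect_error(cpp_fit(pred), "no positives")
})

test_that("a single group keeps the reference threshold", {
  pred <- scored_predictions(score = c(0.2, 0.6, 0.8, 0.4),
                             label = c(0, 1, 1, 0),
                             group = rep("only", 4))
  pol <- psta_fit(pred)
  expect_equal(unname(pol$thresholds), 0.5)
  expect_false(any(pol$treated))
})

test_that("groups already at overall sensitivity keep the standard threshold", {
  sp <- generate_scored_population(scoreset_config(groups = list(
    a = list(n = 3000, prevalence = 0.1, pos = c(0.65, 0.1), neg = c(0.3, 0.1)),
    b = list(n = 3000, prevalence = 0.1, pos = c(0.65, 0.1), neg = c(0.3, 0.1))
  ), seed = 59))
  pol <- psta_fit(sp)
  # identical groups: at least one is at/above the overall sensitivity and
  # sampling noise may leave the other barely below; thresholds stay at or
  # just under t0
  expect_true(all(pol$thresholds <= 0.5))
  at_t0 <- pol$thresholds == 0.5
  expect_true(any(at_t0))
})

test_that("the fitted threshold equals the exhaustive-grid optimum", {
  for (seed in c(61, 67, 71)) {
    sp <- shifted_population(n_per_group = 2000, seed = seed)
    pol <- psta_fit(sp, t0 = 0.5, delta = 0.10)
    s_star <- mean(sp$score[sp$label == 1] >= 0.5)
    f_star <- mean(sp$score[sp$label == 0] >= 0.5)
    for (grp in c("female", "male")) {
      pos <- sp$score[sp$group == grp & sp$label == 1]
      neg <- sp$score[sp$group == grp & sp$label == 0]
      expect_equal(unname(pol$thresholds[grp]),
                   psta_grid_oracle(pos, neg, s_star, f_star, 0.5, 0.10),
                   tolerance = 1e-12)
    }
    # the shifted group is treated and its training sensitivity aligned
    expect_lt(pol$thresholds[["male"]], 0.5)
    male_pos <- sp$score[sp$group == "male" & sp$label == 1]
    expect_gte(mean(male_pos >= pol$thresholds[["male"]]), s_star)
    # FPR cap respected
    male_neg <- sp$score[sp$group == "male" & sp$label == 0]
    expect_lte(mean(male_neg >= pol$thresholds[["male"]]),
               f_star + 0.10 + 1e-12)
  }
})

test_that("fitting is invariant to sample order", {
  sp <- shifted_population(n_per_group = 1000, seed = 73)
  perm <- sample(nrow(sp))
  sp2 <- scored_predictions(score = sp$score[perm], label = sp$label[perm],
                            group = sp$group[perm],
                            prediction = sp$prediction[perm])
  expect_equal(psta_fit(sp)$thresholds, psta_fit(sp2)$thresholds)
})

test_that("groups without positives are left untreated with a warning", {
  pred <- scored_predictions(score = c(0.8, 0.3, 0.2, 0.4, 0.9, 0.1),
                             label = c(1, 0, 0, 0, 1, 0),
                             group = c("a", "a", "b", "b", "a", "a"))
  expect_warning(pol <- psta_fit(pred), "no positive")
  expect_equal(unname(pol$thresholds["b"]), 0.5)
})

test_that("applying thresholds only re-labels predictions", {
  sp <- shifted_population(n_per_group = 1000, seed = 79)
  pol <- psta_fit(sp)
  out <- psta_apply(pol, sp)
  expect_identical(out$score, sp$score)
  expect_identical(out$prediction,
                   as.integer(sp$score >= pol$thresholds[sp$group]))
  # all-t0 policy reproduces plain 0.5 thresholding
  pol0 <- pol
  pol0$thresholds[] <- 0.5
  expect_identical(psta_apply(pol0, sp)$prediction,
                   as.integer(sp$score >= 0.5))
})

test_that("lowering a group's threshold never lowers its TPR or FPR", {
  set.seed(83)
  for (rep in 1:20) {
    n <- 200
    sp <- scored_predictions(score = runif(n),
                             label = rbinom(n, 1, 0.3),
                             group = sample(c("a", "b"), n, replace = TRUE))
    pol <- psta_fit(sp)
    lower <- pol
    lower$thresholds["a"] <- max(pol$thresholds["a"] - 0.2, 0.01)
    r1 <- group_rates(psta_apply(pol, sp))
    r2 <- group_rates(psta_apply(lower, sp))
    a1 <- r1[r1$group == "a", ]
    a2 <- r2[r2$group == "a", ]
    if (a1$tpr_defined) expect_gte(a2$tpr, a1$tpr)
    if (a1$fpr_defined) expect_gte(a2$fpr, a1$fpr)
  }
})

test_that("unknown groups at apply time fall back to t0 with a warning", {
  sp <- shifted_population(n_per_group = 500, seed = 89)
  pol <- psta_fit(sp)
  extra <- scored_predictions(score = c(0.6, 0.4), label = c(1, 0),
                              group = c("other", "other"))
  expect_warning(out <- psta_apply(pol, extra), "fall back")
  expect_identical(out$prediction, c(1L, 0L))
})

test_that("policies serialize to JSON with their fitted context", {
  sp <- shifted_population(n_per_group = 500, seed = 97)
  pol <- psta_fit(sp)
  js <- jsonlite::fromJSON(policy_json(pol))
  expect_equal(js$kind, "psta")
  expect_equal(js$t0, 0.5)
  expect_equal(js$thresholds$male, unname(pol$thresholds["male"]))
  cpol <- cpp_fit(sp, seed = 3)
  js2 <- jsonlite::fromJSON(policy_json(cpol))
  expect_equal(js2$kind, "cpp")
  expect_equal(js2$seed, 3)
})
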