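test_that("subgroup rates follow the confusion-matrix definitions", {
  pred <- rates_fixture(list(
    A = list(tp = 8, fn = 2, fp = 2, tn = 8),
    B = list(tp = 5, fn = 5, fp = 1, tn = 9)
  ))
  gr <- group_rates(pred)
  expect_equal(gr$tpr[gr$group == "A"], 0.8)
  expect_equal(gr$fpr[gr$group == "A"], 0.2)
  expect_equal(gr$tpr[gr$group == "B"], 0.5)
  expect_equal(attr(gr, "overall_tpr"), 13 / 20)
})

test_that("a perfect classifier has unit TPR and zero FPR in every group", {
  pred <- rates_fixture(list(
    A = list(tp = 6, fn = 0, fp = 0, tn = 14),
    B = list(tp = 3, fn = 0, fp = 0, tn = 7)
  ))
  gr <- group_rates(pred)
  expect_true(all(gr$tpr == 1))
  expect_true(all(gr$fpr == 0))
})

test_that("a group without positives gets an undefined TPR flag, not zero", {
  pred <- rates_fixture(list(
    A = list(tp = 4, fn = 1, fp = 1, tn = 4),
    B = list(tp = 0, fn = 0, fp = 2, tn = 8)
  ))
  gr <- group_rates(pred)
  expect_false(gr$tpr_defined[gr$group == "B"])
  expect_true(is.na(gr$tpr[gr$group == "B"]))
  expect_true(gr$tpr_defined[gr$group == "A"])
  # EOD then lacks a second defined group
  expect_error(eod(gr), "two groups")
})

test_that("EOD is the min-minus-max subgroup TPR", {
  mk <- function(tprs) {
    spec <- lapply(tprs, function(t) {
      list(tp = round(t * 10), fn = 10 - round(t * 10), fp = 1, tn = 9)
    })
    names(spec) <- paste0("g", seq_along(tprs))
    group_rates(rates_fixture(spec))
  }
  expect_equal(eod(mk(c(0.8, 0.5))), -0.3)
  expect_equal(eod(mk(c(0.7, 0.7, 0.7))), 0)
  expect_equal(eod(mk(c(0.9, 0.7, 0.6))), -0.3)
})

test_that("AOD follows the half-gap of (TPR + FPR) sums", {
  pred <- rates_fixture(list(
    A = list(tp = 8, fn = 2, fp = 2, tn = 8),
    B = list(tp = 5, fn = 5, fp = 1, tn = 9)
  ))
  expect_equal(aod(group_rates(pred)), 0.5 * ((0.5 + 0.1) - (0.8 + 0.2)))
  # opposite error profiles with equal sums cancel
  pred2 <- rates_fixture(list(
    A = list(tp = 10, fn = 0, fp = 0, tn = 10),
    B = list(tp = 0, fn = 10, fp = 10, tn = 0)
  ))
  expect_equal(aod(group_rates(pred2)), 0)
  # identical groups are exactly fair
  pred3 <- rates_fixture(list(
    A = list(tp = 6, fn = 4, fp = 3, tn = 7),
    B = list(tp = 6, fn = 4, fp = 3, tn = 7)
  ))
  expect_equal(aod(group_rates(pred3)), 0)
  expect_equal(eod(group_rates(pred3)), 0)
})

test_that("balanced accuracy averages sensitivity and specificity", {
  perfect <- rates_fixture(list(A = list(tp = 5, fn = 0, fp = 0, tn = 5)))
  expect_equal(balanced_accuracy(perfect), 1)

  all_pos <- scored_predictions(score = rep(0.9, 10),
                                label = c(rep(1, 3), rep(0, 7)),
                                group = rep("a", 10))
  expect_equal(balanced_accuracy(all_pos), 0.5)

  mixed <- rates_fixture(list(A = list(tp = 8, fn = 2, fp = 4, tn = 6)))
  expect_equal(balanced_accuracy(mixed), (0.8 + 0.6) / 2)

  single <- scored_predictions(score = rep(0.9, 3), label = rep(1, 3),
                               group = rep("a", 3))
  expect_error(balanced_accuracy(single), "both classes")
})

test_that("AUC matches its defining properties", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(2)
  s <- runif(2000)
  l <- sample(0:1, 2000, replace = TRUE)
  expect_lt(abs(auc_roc(s, l) - 0.5), 0.05)
  expect_equal(auc_roc(-s + 1, l), 1 - auc_roc(s, l), tolerance = 1e-12)
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- round(runif(300), 2) # ties on purpose
  l <- rbinom(300, 1, plogis(3 * (s - 0.5)))
  ours <- auc_roc(s, l)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the fairness-accuracy score follows the harmonic-mean formula", {
  expect_equal(delta_score(1, 0), 1)
  expect_equal(delta_score(0.7, -0.3, beta = 1e-9), 0.7, tolerance = 1e-6)
  expect_equal(delta_score(0.729, -0.1, beta = 0.5),
               1.25 * 0.729 * 0.9 / (0.25 * 0.729 + 0.9),
               tolerance = 1e-12)
  expect_equal(delta_score(0.729, -0.1, beta = 0.5), 0.7578, tolerance = 1e-4)
  expect_equal(delta_score(0, -1), 0)
})

test_that("the score is monotone in accuracy and fairness", {
  baccs <- seq(0.05, 1, by = 0.05)
  eods <- seq(-0.95, 0, by = 0.05)
  for (e in c(-0.4, -0.1)) {
    d <- vapply(baccs, delta_score, numeric(1), eod = e)
    expect_true(all(diff(d) > 0))
  }
  for (b in c(0.6, 0.9)) {
    d <- vapply(eods, function(e) delta_score(b, e), numeric(1))
    expect_true(all(diff(d) > 0)) # less negative EOD, higher score
  }
})

test_that("EOD and AOD equal brute-force pairwise scans on random instances", {
  set.seed(42)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    tprs <- round(runif(k), 2)
    fprs <- round(runif(k), 2)
    spec <- lapply(seq_len(k), function(i) {
      list(tp = round(100 * tprs[i]), fn = 100 - round(100 * tprs[i]),
           fp = round(100 * fprs[i]), tn = 100 - round(100 * fprs[i]))
    })
    names(spec) <- paste0("g", seq_len(k))
    gr <- group_rates(rates_fixture(spec))
    expect_equal(eod(gr), eod_brute(gr$tpr), tolerance = 1e-12)
    expect_equal(aod(gr), aod_brute(gr$tpr, gr$fpr), tolerance = 1e-12)
    # permutation invariance in group order
    perm <- sample(k)
    gr2 <- group_rates(rates_fixture(spec[perm]))
    expect_equal(eod(gr2), eod(gr), tolerance = 1e-12)
    expect_equal(aod(gr2), aod(gr), tolerance = 1e-12)
    expect_lte(eod(gr), 0)
    expect_lte(aod(gr), 0)
  }
})

test_that("the practical fairness band flags |EOD| <= 0.1 by default", {
  expect_true(eod_within_band(-0.1))
  expect_false(eod_within_band(-0.11))
  expect_equal(eod_within_band(c(-0.05, -0.2), band = 0.1), c(TRUE, FALSE))
})

test_that("fairness_report assembles all metrics consistently", {
  pred <- rates_fixture(list(
    A = list(tp = 8, fn = 2, fp = 2, tn = 8),
    B = list(tp = 5, fn = 5, fp = 1, tn = 9)
  ))
  fr <- fairness_report(pred)
  expect_equal(fr$eod, -0.3)
  expect_equal(fr$delta, delta_score(fr$bacc, fr$eod, 0.5))
  js <- jsonlite::fromJSON(fairness_report_json(fr))
  expect_equal(js$eod, -0.3)
  expect_equal(nrow(js$rates), 2)
})
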