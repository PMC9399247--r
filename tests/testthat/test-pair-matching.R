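toy_comparisons <- function(sym, nonsym) {
  data.frame(hd = c(sym, nonsym),
             is_symmetric = rep(c(TRUE, FALSE), c(length(sym),
                                                  length(nonsym))))
}

test_that("pair enumeration yields n symmetric and n(n-1) nonsymmetric", {
  p1 <- enumerate_pairs("a")
  expect_equal(sum(p1$is_symmetric), 1L)
  expect_equal(sum(!p1$is_symmetric), 0L)
  p5 <- enumerate_pairs(sprintf("i%02d", 1:5), "lateral")
  expect_equal(sum(p5$is_symmetric), 5L)
  expect_equal(sum(!p5$is_symmetric), 20L)
  expect_true(all(p5$tooth_type == "lateral"))
  # ordered cross pairs: both (i, j) and (j, i) appear once
  ns <- p5[!p5$is_symmetric, ]
  expect_equal(nrow(unique(ns[, 1:2])), 20L)
  expect_error(enumerate_pairs(c("a", "a")), "duplicate")
})

test_that("ROC curve matches brute-force reclassification at every cut", {
  set.seed(11)
  cmp <- toy_comparisons(rnorm(30, 1, 0.3), rnorm(200, 2, 0.5))
  cmp$hd <- abs(cmp$hd)
  roc <- compute_roc(cmp)
  for (i in seq_along(roc$thresholds)) {
    r <- brute_rates(cmp$hd, cmp$is_symmetric, roc$thresholds[i])
    expect_equal(roc$sensitivity[i], unname(r["sens"]))
    expect_equal(roc$specificity[i], unname(r["spec"]))
  }
  expect_equal(roc$sensitivity[length(roc$thresholds)], 1.0)
})

test_that("ROC AUC agrees with an independent implementation", {
  set.seed(12)
  cmp <- toy_comparisons(abs(rnorm(40, 1, 0.4)), abs(rnorm(150, 1.8, 0.6)))
  roc <- compute_roc(cmp)
  ref <- pROC::roc(response = cmp$is_symmetric, predictor = cmp$hd,
                   direction = ">", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-9)
})

test_that("ROC endpoints behave for separated and identical classes", {
  expect_equal(compute_roc(toy_comparisons(c(1, 1.2), c(2, 3)))$auc, 1.0)
  expect_equal(compute_roc(toy_comparisons(c(1.5), c(1.5)))$auc, 0.5)
  expect_error(compute_roc(toy_comparisons(c(1), numeric(0))), "at least one")
})

test_that("threshold selection follows the exhaustive sweep", {
  r1 <- compute_roc(toy_comparisons(c(1, 1.2), c(2, 3)))
  expect_equal(threshold_full_specificity(r1), 1.2)
  expect_equal(threshold_full_sensitivity(r1), 1.2)
  r2 <- compute_roc(toy_comparisons(c(1, 2.5), c(2, 3)))
  expect_equal(threshold_full_specificity(r2), 1.0)
  expect_equal(threshold_full_sensitivity(r2), 2.5)
  # random sweeps
  for (s in 1:10) {
    set.seed(700 + s)
    cmp <- toy_comparisons(abs(rnorm(20, 1, .5)), abs(rnorm(80, 2, .7)))
    roc <- compute_roc(cmp)
    sw <- sweep_thresholds(cmp$hd, cmp$is_symmetric)
    thr <- threshold_full_specificity(roc)
    if (is.na(sw$full_spec)) {
      expect_true(isTRUE(attr(thr, "degenerate")))
      expect_lt(as.numeric(thr), min(cmp$hd))
    } else {
      expect_equal(as.numeric(thr), sw$full_spec)
    }
    expect_equal(threshold_full_sensitivity(roc), sw$full_sens)
  }
  # degenerate: a nonsymmetric value below every symmetric one
  r3 <- compute_roc(toy_comparisons(c(1, 2), c(0.5, 3)))
  t3 <- threshold_full_specificity(r3)
  expect_true(isTRUE(attr(t3, "degenerate")))
  expect_lt(as.numeric(t3), 0.5)
})

test_that("classification counts and rates are exact", {
  cmp <- toy_comparisons(c(1, 1.2), c(2, 3))
  rep <- classify_pairs(cmp, 1.2)
  expect_equal(rep[, c("tp", "fn", "tn", "fp")],
               data.frame(tp = 2L, fn = 0L, tn = 2L, fp = 0L))
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$accuracy, 100)
  # the printed-abstract arithmetic: 98/100 positives kept, 0/9900 negatives
  set.seed(13)
  sym <- c(runif(98, 0.5, 1.9), 2.2, 2.4)
  non <- runif(9900, 2.6, 6)
  rep2 <- classify_pairs(toy_comparisons(sym, non), 2.0)
  expect_equal(rep2$sensitivity, 98)
  expect_equal(rep2$accuracy, 100 * (98 + 9900) / 10000)
  expect_gt(rep2$accuracy, 99)
  # threshold below all values
  rep3 <- classify_pairs(cmp, 0.5)
  expect_equal(rep3$sensitivity, 0)
  expect_equal(rep3$specificity, 100)
})

test_that("classification is invariant under monotone HD transforms", {
  set.seed(14)
  cmp <- toy_comparisons(abs(rnorm(25, 1, .4)), abs(rnorm(100, 2, .6)))
  thr <- as.numeric(threshold_full_specificity(compute_roc(cmp)))
  base <- classify_pairs(cmp, thr)
  mono <- cmp
  mono$hd <- log1p(cmp$hd) * 3
  rep <- classify_pairs(mono, log1p(thr) * 3)
  expect_equal(rep[, c("tp", "fn", "tn", "fp", "sensitivity", "accuracy")],
               base[, c("tp", "fn", "tn", "fp", "sensitivity", "accuracy")])
})

test_that("Cohen's kappa matches hand computation and e1071", {
  tab <- rbind(c(20, 5), c(10, 15))
  k <- cohens_kappa(tab)
  expect_equal(k$kappa, 0.4)
  expect_equal(k$p_observed, 0.7)
  expect_equal(k$p_expected, 0.5)
  expect_equal(k$ci_lower, 0.4 - stats::qnorm(0.975) * k$se)
  ref <- e1071::classAgreement(tab)
  expect_equal(k$kappa, ref$kappa)
  # perfect and chance-level agreement
  expect_equal(cohens_kappa(diag(c(10, 20)))$kappa, 1)
  expect_equal(cohens_kappa(rbind(c(9, 21), c(21, 49)))$kappa, 0)
})

test_that("one-way ANOVA reproduces the textbook decomposition", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  a <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(a$F, 8.0)
  expect_equal(a$df1, 1L)
  expect_equal(a$df2, 2L)
  expect_equal(a$p_value, f_pvalue_quadrature(8, 1, 2), tolerance = 1e-6)
  # agreement with stats::oneway.test
  set.seed(15)
  g <- list(rnorm(12, 1), rnorm(9, 1.4), rnorm(15, 0.7))
  ours <- one_way_anova(g)
  ref <- stats::oneway.test(
    y ~ grp, data = data.frame(y = unlist(g),
                               grp = rep(seq_along(g), lengths(g))),
    var.equal = TRUE)
  expect_equal(ours$F, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  # zero within-group variance flag
  dz <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(dz$degenerate)
  expect_equal(dz$p_value, 0)
})

test_that("jitter export keeps all TP/FN and the smallest true negatives", {
  set.seed(16)
  sym <- c(runif(8, 0.5, 1.5), 2.5, 2.6)
  non <- runif(300, 2, 8)
  cmp <- toy_comparisons(sym, non)
  thr <- 1.6
  jit <- jitter_export(cmp, thr, tn_cap = 100)
  expect_equal(sum(jit$label == "TP"), 8L)
  expect_equal(sum(jit$label == "FN"), 2L)
  expect_equal(sum(jit$label == "TN"), 100L)
  # exported TN values are the order statistics of the TN set
  tn_all <- sort(non[non > thr])
  expect_equal(sort(jit$hd[jit$label == "TN"]), tn_all[1:100])
  # fewer negatives than the cap: all exported
  jit2 <- jitter_export(toy_comparisons(sym, non[1:50]), thr, tn_cap = 100)
  expect_equal(sum(jit2$label == "TN"), sum(non[1:50] > thr))
})
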