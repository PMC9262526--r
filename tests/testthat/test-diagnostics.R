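test_that("ROC AUC behaves at the extremes and equals the rank statistic", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_max, 1)
  r2 <- roc_curve(rep(5, 10), rep(0:1, 5))
  expect_equal(r2$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the all-pairs Mann-Whitney statistic", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(6:50, 1)
    scores <- sample(seq(0, 10, 0.5), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, auc_pairs(scores, labels), tolerance = 1e-12)
    # sensitivity is non-increasing in the threshold
    expect_true(all(diff(r$sensitivity) <= 1e-12))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(15)
  scores <- rnorm(80) + rep(c(0, 1.2), each = 40)
  labels <- rep(c(0, 1), each = 40)
  r <- roc_curve(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("the Youden threshold is the exhaustive maximizer, ties to the lower cut", {
  set.seed(16)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    scores <- sample(1:15, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels)
    cuts <- c(sort(unique(scores)), Inf)
    j <- vapply(cuts, function(t)
      mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1,
      numeric(1))
    expect_equal(r$youden_max, max(j), tolerance = 1e-12)
    expect_equal(youden_threshold(r), min(cuts[j == max(j)]))
  }
  # exactly tied cut-points resolve to the more sensitive (lower) one
  rt <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(youden_threshold(rt), 2)
})

test_that("the Youden rule is invariant to monotone score transforms", {
  set.seed(17)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5)
  r1 <- roc_curve(scores, labels)
  r2 <- roc_curve(exp(scores), labels)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$youden_max, r2$youden_max, tolerance = 1e-12)
  expect_equal(exp(r1$youden_threshold), r2$youden_threshold,
               tolerance = 1e-12)
})

test_that("scores at the threshold are called positive", {
  expect_identical(dichotomize_diagnosis(c(39, 38.999, 40), 39), c(1L, 0L, 1L))
  x <- runif(10)
  expect_length(dichotomize_diagnosis(x, 0.5), 10)
})

test_that("kappa matches hand computations and the printed banding rule", {
  perfect <- cohens_kappa(c(30, 0, 0, 20))
  expect_equal(perfect$kappa, 1)
  expect_identical(perfect$band, "excellent")
  k <- cohens_kappa(c(40, 10, 20, 30))  # p_o = 0.7, p_e = 0.5
  expect_equal(k$kappa, 0.4)
  expect_identical(k$band, "fair_to_good")
  # marginally independent table has kappa 0
  expect_equal(cohens_kappa(c(20, 20, 30, 30))$kappa, 0, tolerance = 1e-12)
  # symmetry in the two raters
  expect_equal(cohens_kappa(c(12, 7, 3, 28))$kappa,
               cohens_kappa(c(12, 3, 7, 28))$kappa, tolerance = 1e-12)
  # bands: 0.40-0.75 fair to good (a 0.628-style coefficient), < 0.40 poor
  expect_identical(cohens_kappa(c(45, 5, 5, 45))$band, "excellent")
  expect_identical(cohens_kappa(c(35, 15, 15, 35))$band, "fair_to_good")
  expect_identical(cohens_kappa(c(30, 20, 20, 30))$band, "poor")
  expect_identical(cohens_kappa(c(100, 0, 0, 0))$band, "undefined")
})

test_that("McNemar switches between corrected chi-square and exact binomial", {
  big <- mcnemar_paired_test(c(100, 20, 20, 100))
  expect_identical(big$method, "chi2_corrected")
  expect_equal(big$statistic, 1 / 40)
  expect_gt(big$p_value, 0.05)
  small <- mcnemar_paired_test(c(50, 10, 2, 50))
  expect_identical(small$method, "exact_binomial")
  expect_equal(small$p_value, 0.0386, tolerance = 1e-3)
  none <- mcnemar_paired_test(c(50, 0, 0, 50))
  expect_equal(none$p_value, 1)
  expect_equal(none$statistic, 0)
})

test_that("the per-element diagnostic table assembles all statistics", {
  co <- tiny_cohort(n = 120, seed = 19)
  th <- as.matrix(co[paste0("theta_b_", els6)])
  colnames(th) <- els6
  scores <- 50 + 10 * th + rnorm(length(th), 0, 2)
  dx <- as.matrix(co[paste0("dx_", els6)])
  tab <- diagnostic_table(scores, dx)
  expect_equal(nrow(tab), 6)
  expect_identical(tab$element, els6)
  expect_true(all(tab$auc > 0.5))
  expect_true(all(tab$kappa_band %in% c("excellent", "fair_to_good", "poor")))
  expect_true(all(tab$mcnemar_p >= 0 & tab$mcnemar_p <= 1))
})
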