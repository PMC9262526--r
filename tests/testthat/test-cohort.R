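test_that("the default design yields 300 baseline and 291 follow-up records", {
  co <- suppressMessages(generate_cohort(cohort_config(seed = 2)))
  expect_equal(nrow(co), 300)
  expect_equal(sum(!co$dropped), 291)
  expect_equal(sum(co$dropped), 9)
  expect_true(all(is.na(co$anchor[co$dropped])))
  expect_true(all(!is.na(co$anchor[!co$dropped])))
  q <- as.matrix(co[grep("^qol_", names(co))])
  expect_true(all(is.na(q) | (q >= 0 & q <= 100)))
  # total is the mean of the eight domain scores
  qb <- as.matrix(co[paste0("qol_b_", fddql_domains())])
  expect_equal(co$qol_b_total, rowMeans(qb))
})

test_that("generation is deterministic under a fixed seed", {
  c1 <- suppressMessages(generate_cohort(cohort_config(seed = 10)))
  c2 <- suppressMessages(generate_cohort(cohort_config(seed = 10)))
  expect_identical(c1, c2)
})

test_that("error-free clinicians label exactly the thresholded truth", {
  cfg <- cohort_config(n_baseline = 150, n_dropout = 5,
                       clinician_error_rate = 0, seed = 3)
  co <- suppressMessages(generate_cohort(cfg))
  th <- as.matrix(co[paste0("theta_b_", els6)])
  dx <- as.matrix(co[paste0("dx_", els6)])
  expect_equal(unname(dx + 0), unname((th > 0) + 0))
})

test_that("no treatment effect and vanishing noise give all-unchanged anchors", {
  cfg <- cohort_config(n_baseline = 60, n_dropout = 2,
                       treatment_effect = 0, progression_sd = 1e-9,
                       qol_noise_sd = 1e-9,
                       anchor_cuts = c(-2, -1, 0.5, 1), seed = 4)
  co <- generate_cohort(cfg)
  expect_true(all(co$anchor[!co$dropped] == 0))
})

test_that("cohorts round-trip through CSV exactly and bad files are rejected", {
  co <- tiny_cohort(n = 25, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  attributes(co) <- attributes(co)[c("names", "row.names", "class")]
  attr(back, "row.names") <- attr(co, "row.names")
  expect_equal(back, co)

  bad <- co; bad$anchor[which(!bad$dropped)[1]] <- 5L
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "anchor")

  bad2 <- co; bad2$qol_b_diet[1] <- 140
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad2, p3, row.names = FALSE)
  expect_error(read_cohort(p3), "\\[0, 100\\]")

  p4 <- withr::local_tempfile(fileext = ".csv")
  file.create(p4)
  expect_error(read_cohort(p4), "no records")
})

test_that("impossible designs are rejected up front", {
  expect_error(cohort_config(n_baseline = 10, n_dropout = 10), "n_dropout")
  expect_error(cohort_config(qol_noise_sd = 0), "positive")
  expect_error(cohort_config(anchor_cuts = c(1, 0, 2, 3)), "increasing")
  expect_error(cohort_config(treatment_effect = c(NA, 0, 0, 0, 0, 0)),
               "finite")
})

test_that("zero loadings decouple QoL change from severity change", {
  cfg <- cohort_config(n_baseline = 400, n_dropout = 1,
                       qol_loading = matrix(0, 6, 8), seed = 6)
  co <- suppressMessages(generate_cohort(cfg))
  fu <- co[!co$dropped, ]
  imp <- rowSums(as.matrix(fu[paste0("theta_b_", els6)]) -
                   as.matrix(fu[paste0("theta_f_", els6)]))
  dq <- fu$qol_f_total - fu$qol_b_total
  expect_lt(abs(cor(imp, dq)), 3 / sqrt(nrow(fu)))
})

test_that("raising one element's effect raises every positively loaded domain", {
  base_means <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    lo <- cohort_config(n_baseline = 250, n_dropout = 1, seed = s)
    eff <- lo$treatment_effect; eff[3] <- eff[3] + 0.8  # boost heat
    hi <- cohort_config(n_baseline = 250, n_dropout = 1,
                        treatment_effect = eff, seed = s)
    m <- function(cfg, dom) {
      co <- suppressMessages(generate_cohort(cfg))
      fu <- co[!co$dropped, ]
      mean(fu[[paste0("qol_f_", dom)]] - fu[[paste0("qol_b_", dom)]])
    }
    base_means[s, ] <- c(m(lo, "coping"), m(hi, "coping"))
  }
  # heat loads positively on coping: the boost must raise its mean change
  expect_true(all(base_means[, 2] > base_means[, 1]))
})

test_that("anchor calibration hits the published change distribution", {
  cfg <- cohort_config(seed = 1)
  targets <- c(39, 156, 3, 93)
  cal <- anchor_target_calibration(cfg, targets, n_rep = 50)
  counts <- vapply(1:50, function(s) {
    cal$seed <- s
    co <- suppressMessages(generate_cohort(cal))
    a <- co$anchor[!co$dropped]
    c(sum(a == 2), sum(a == 1), sum(a < 0), sum(a == 0))
  }, numeric(4))
  m <- rowMeans(counts)
  expect_true(all(abs(m - targets) <= 0.15 * targets))
})

test_that("degenerate calibration targets are handled", {
  cfg <- cohort_config(n_baseline = 60, n_dropout = 2,
                       treatment_effect = rep(1.5, 6), seed = 9)
  cal <- anchor_target_calibration(cfg, c(0, 58, 0, 0), n_rep = 20)
  co <- suppressMessages(generate_cohort(cal))
  expect_true(all(co$anchor[!co$dropped] == 1))
  expect_error(anchor_target_calibration(cfg, c(10, 10, 10, 10)), "sum")
  expect_error(anchor_target_calibration(cfg, c(-1, 59, 0, 0)),
               "non-negative")
})
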