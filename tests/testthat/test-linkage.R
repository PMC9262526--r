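test_that("responder classification is boundary-inclusive and monotone", {
  co <- data.frame(patient_id = 1:3, dropped = FALSE,
                   qol_b_total = c(50, 50, 50),
                   qol_f_total = c(54.6, 54.5, 48))
  mcid <- data.frame(domain = "total", weighted = 4.5485)
  lab <- classify_outcomes(co, mcid)
  expect_equal(lab$changed, c(1L, 0L, 0L))
  expect_equal(lab$d, c(4.6, 4.5, -2))
  # monotone in d: raising a change never loses responder status
  d <- seq(-10, 10, 0.5)
  cls <- as.integer(d >= 4.5485)
  expect_true(all(diff(cls) >= 0))
  # identical timepoints mean nobody responds while the MCID is positive
  co$qol_f_total <- co$qol_b_total
  expect_true(all(classify_outcomes(co, mcid)$changed == 0L))
  expect_error(classify_outcomes(co, data.frame(domain = "sleep",
                                                weighted = 1)),
               "missing domain")
})

test_that("the logistic fit recovers planted coefficients at large n", {
  set.seed(31)
  n <- 5000
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, els6))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * X[, 1]))
  fit <- fit_logistic(X, y)
  expect_equal(fit$B[fit$term == "liver"], 0.8, tolerance = 0.1)
  expect_equal(fit$B[fit$term == "Constant"], -1, tolerance = 0.15)
  # pure-noise predictors stay near zero and non-significant
  null_terms <- fit[fit$term %in% els6[-1], ]
  expect_true(all(abs(null_terms$B) < 0.1))
  expect_true(all(null_terms$P > 0.01))
  # internal consistency of the report columns
  expect_equal(fit$ExpB, exp(fit$B), tolerance = 1e-12)
  expect_equal(fit$Wald, (fit$B / fit$SE)^2, tolerance = 1e-9)
  expect_equal(fit$P, pchisq(fit$Wald, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the logistic fit matches a numerical-optimizer oracle", {
  set.seed(32)
  for (i in 1:30) {
    n <- sample(60:120, 1)
    p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    beta <- c(-0.3, runif(p, -0.8, 0.8))
    y <- rbinom(n, 1, plogis(cbind(1, X) %*% beta))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(X, y)
    nll <- function(b) {
      eta <- cbind(1, X) %*% b
      -sum(y * eta - log1p(exp(eta)))
    }
    start <- rep(0, p + 1)
    opt <- optim(start, nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    got <- c(fit$B[fit$term == "Constant"],
             fit$B[match(paste0("x", 1:p), fit$term)])
    expect_equal(got, opt$par, tolerance = 1e-6)
  }
})

test_that("degenerate designs are rejected and separation is flagged", {
  set.seed(33)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("u", "v")))
  expect_error(fit_logistic(X, rep(1, 30)), "single class")
  expect_error(fit_logistic(X[1:15, ], rbinom(15, 1, 0.5)), "more than 20")
  X2 <- cbind(X, w = X[, 1] * 2)
  expect_error(fit_logistic(X2, rbinom(30, 1, 0.5)), "rank-deficient")
  # perfectly separated outcome
  Xs <- matrix(c(rnorm(25, -3), rnorm(25, 3)), ncol = 1,
               dimnames = list(NULL, "u"))
  ys <- rep(c(0, 1), each = 25)
  fit <- suppressWarnings(fit_logistic(Xs, ys))
  expect_true(attr(fit, "separation"))
})

test_that("report formatting follows the 3-decimal and <0.001 conventions", {
  fit <- data.frame(term = c("liver", "Constant"), B = c(0.397, -3.696),
                    SE = c(0.119, 0.59), Wald = c(11.046, 39.189),
                    df = 1L, P = c(0.000894, 1e-10),
                    ExpB = exp(c(0.397, -3.696)))
  out <- format_logistic_table(fit)
  expect_identical(out$`Exp(B)`[1], "1.487")
  expect_identical(out$P, c("<0.001", "<0.001"))
  expect_identical(out$B[2], "-3.696")
})

test_that("the linkage report produces nine 7-row tables with BH supplement", {
  co <- tiny_cohort(n = 80, seed = 34)
  mcid <- mcid_table(co)
  ch <- element_score_changes(co, source = "latent")
  rep9 <- linkage_report(co, mcid, ch)
  expect_length(rep9, 9)
  expect_setequal(names(rep9), fddql_domains(include_total = TRUE))
  for (f in rep9) {
    expect_equal(nrow(f), 7)
    expect_identical(f$term, c(els6, "Constant"))
  }
  bh <- attr(rep9, "bh_adjusted")
  expect_equal(nrow(bh), 54)
  expect_true(all(bh$P_bh >= bh$P - 1e-12))
})

test_that("a dominant spleen-dampness loading dominates the total-score model", {
  hits <- 0L
  for (s in 1:20) {
    L <- default_qol_loading() * 0.3
    L["spleen_dampness", ] <- 6
    eff <- c(0.1, 0.1, 0.1, 0.5, 0.1, 0.1)
    cfg <- cohort_config(n_baseline = 300, n_dropout = 9, qol_loading = L,
                         treatment_effect = eff, seed = 400 + s)
    co <- suppressMessages(generate_cohort(cfg))
    mcid <- mcid_table(co)
    lab <- classify_outcomes(co, mcid)
    y <- lab$changed[lab$domain == "total"]
    ch <- element_score_changes(co, source = "latent")
    fit <- fit_logistic(ch, y)
    el <- fit$term[fit$term != "Constant"]
    w <- fit$Wald[fit$term != "Constant"]
    if (el[which.max(w)] == "spleen_dampness") hits <- hits + 1L
  }
  expect_gt(hits, 10)
})
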