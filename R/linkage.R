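#' Classify per-domain clinical outcomes by the MCID responder rule
#'
#' A patient shows a clinically significant change in a domain when the
#' improvement-signed score change `d` meets or exceeds the domain MCID
#' (boundary inclusive: `d == MCID` counts as changed).
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param mcid a [mcid_table()] (its `weighted` column is the MCID used).
#' @return data.frame with one row per non-dropped patient per domain:
#'   `patient_id`, `domain`, `d`, `changed` (0/1).
#' @export
classify_outcomes <- function(cohort, mcid) {
  doms <- sub("^qol_b_", "", grep("^qol_b_", names(cohort), value = TRUE))
  missing <- setdiff(doms, mcid$domain)
  if (length(missing))
    stop_("missing domain MCID: ", paste(missing, collapse = ", "))
  fu <- cohort[!cohort$dropped, ]
  rows <- lapply(doms, function(dm) {
    d <- fu[[paste0("qol_f_", dm)]] - fu[[paste0("qol_b_", dm)]]
    m <- mcid$weighted[mcid$domain == dm]
    data.frame(patient_id = fu$patient_id, domain = dm, d = d,
               changed = as.integer(d >= m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-element standardized score changes
#'
#' Improvement-signed change of the standardized CAT score
#' (baseline - follow-up: element scores decrease as patients improve). With
#' `source = "latent"` the latent severity change (baseline - follow-up
#' theta) is used instead of CAT-derived scores, which is useful for fast
#' simulation studies of the linkage stage alone.
#'
#' @param cohort cohort data.frame (non-dropped patients are used).
#' @param std_baseline,std_followup n x 6 matrices of standardized scores for
#'   the non-dropped patients (required for `source = "cat"`).
#' @param source `"cat"` or `"latent"`.
#' @return matrix with one column per element, rows aligned with the
#'   non-dropped patients.
#' @export
element_score_changes <- function(cohort, std_baseline = NULL,
                                  std_followup = NULL,
                                  source = c("cat", "latent")) {
  source <- match.arg(source)
  fu <- cohort[!cohort$dropped, ]
  els <- sub("^theta_b_", "", grep("^theta_b_", names(cohort), value = TRUE))
  if (source == "latent") {
    ch <- as.matrix(fu[paste0("theta_b_", els)]) -
      as.matrix(fu[paste0("theta_f_", els)])
  } else {
    if (is.null(std_baseline) || is.null(std_followup))
      stop_("std_baseline and std_followup are required for source = 'cat'")
    ch <- as.matrix(std_baseline) - as.matrix(std_followup)
  }
  colnames(ch) <- els
  ch
}

#' Logistic regression of a binary outcome on element score changes
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()] with a tight convergence tolerance) of the outcome on the
#' six element changes plus an intercept. Reports, per predictor and for the
#' constant, the coefficient B, its standard error, the Wald chi-square
#' `(B/SE)^2` on 1 df, the upper-tail P, and the odds ratio `Exp(B)`.
#' Quasi-separation (any |B| > 15) is flagged, not fatal.
#'
#' @param element_changes n x p numeric matrix of predictors (columns named).
#' @param outcomes binary outcome vector (0/1).
#' @param binary_coding if `TRUE`, predictors are dichotomized at
#'   `binary_cutoff` before fitting.
#' @param binary_cutoff cut-point for `binary_coding`.
#' @return object of class `logistic_fit`: a data.frame with rows for each
#'   predictor then `Constant` and columns `term`, `B`, `SE`, `Wald`, `df`,
#'   `P`, `ExpB`; attributes `n`, `converged`, `separation`, `iterations`.
#' @export
fit_logistic <- function(element_changes, outcomes, binary_coding = FALSE,
                         binary_cutoff = 0) {
  X <- as.matrix(element_changes)
  y <- as.integer(outcomes)
  if (length(y) != nrow(X)) stop_("outcomes must align with predictors")
  if (nrow(X) <= 20) stop_("need more than 20 observations")
  if (length(unique(y)) < 2) stop_("outcome has a single class")
  if (binary_coding) X <- 1 * (X >= binary_cutoff)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- colnames(X)[qrX$rank:ncol(X)]
    stop_("rank-deficient design; aliased columns near: ",
          paste(aliased, collapse = ", "))
  }
  df <- data.frame(.y = y, X)
  fit <- stats::glm(.y ~ ., family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  sm <- summary(fit)$coefficients
  ord <- c(rownames(sm)[-1], "(Intercept)")
  sm <- sm[ord, , drop = FALSE]
  B <- sm[, 1]; SE <- sm[, 2]
  wald <- (B / SE)^2
  out <- data.frame(term = c(colnames(X), "Constant"),
                    B = unname(B), SE = unname(SE), Wald = unname(wald),
                    df = 1L,
                    P = unname(stats::pchisq(wald, 1, lower.tail = FALSE)),
                    ExpB = unname(exp(B)), stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(X)
  attr(out, "converged") <- fit$converged
  attr(out, "iterations") <- fit$iter
  attr(out, "separation") <- any(abs(B) > 15)
  class(out) <- c("logistic_fit", "data.frame")
  out
}

#' Format a logistic fit the way the report tables print it
#'
#' B, S.E., Wald and Exp(B) to 3 decimals (half away from zero); P to 3
#' decimals with the `"<0.001"` convention.
#'
#' @param fit a [fit_logistic()] result (or a data.frame with the same
#'   columns).
#' @return character data.frame with columns
#'   `Independent variables, B, S.E., Wald, df, P, Exp(B)`.
#' @export
format_logistic_table <- function(fit) {
  f3 <- function(x) sprintf("%.3f", round_half_away(x, 3))
  p <- ifelse(fit$P < 0.001, "<0.001", f3(fit$P))
  out <- data.frame(`Independent variables` = fit$term,
                    B = f3(fit$B), S.E. = f3(fit$SE), Wald = f3(fit$Wald),
                    df = fit$df, P = p, `Exp(B)` = f3(fit$ExpB),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (n = ", attr(x, "n"), ", converged = ",
      attr(x, "converged"), ")\n", sep = "")
  if (isTRUE(attr(x, "separation")))
    cat("warning: quasi-separation detected (|B| > 15)\n")
  print(format_logistic_table(x), row.names = FALSE)
  invisible(x)
}

#' Outcome linkage report: one logistic table per QoL domain + total
#'
#' Fits, for each of the 9 outcomes (8 domains and the total score), a
#' logistic regression of the MCID responder label on the six element score
#' changes. A supplementary Benjamini-Hochberg adjusted P column over the
#' 9 x 6 element coefficients is attached as attribute `bh_adjusted`.
#'
#' @param cohort cohort data.frame.
#' @param mcid a [mcid_table()].
#' @param element_changes matrix from [element_score_changes()] (rows =
#'   non-dropped patients).
#' @param binary_coding,binary_cutoff passed to [fit_logistic()].
#' @return named list of 9 `logistic_fit` tables, class `linkage_report`.
#' @export
linkage_report <- function(cohort, mcid, element_changes,
                           binary_coding = FALSE, binary_cutoff = 0) {
  labels <- classify_outcomes(cohort, mcid)
  doms <- unique(labels$domain)
  fits <- lapply(doms, function(dm) {
    y <- labels$changed[labels$domain == dm]
    fit_logistic(element_changes, y, binary_coding, binary_cutoff)
  })
  names(fits) <- doms
  els <- colnames(element_changes)
  pgrid <- do.call(rbind, lapply(doms, function(dm) {
    f <- fits[[dm]]
    data.frame(domain = dm, term = f$term[f$term != "Constant"],
               P = f$P[f$term != "Constant"], stringsAsFactors = FALSE)
  }))
  pgrid$P_bh <- stats::p.adjust(pgrid$P, method = "BH")
  structure(fits, class = "linkage_report", bh_adjusted = pgrid)
}

#' @export
print.linkage_report <- function(x, ...) {
  for (dm in names(x)) {
    cat("\n== Outcome:", dm, "==\n")
    print(format_logistic_table(x[[dm]]), row.names = FALSE)
  }
  invisible(x)
}
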