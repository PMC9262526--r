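#' ROC curve of a continuous score against a binary gold standard
#'
#' Builds the ROC curve over all unique score cut-points (plus a +Inf
#' sentinel), with the positive-call convention `score >= threshold`. The
#' area under the curve is computed by the trapezoidal rule, which equals the
#' Mann-Whitney pair statistic P(score+ > score-) + 0.5 P(tie).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary gold-standard labels (0/1 or logical).
#' @return object of class `roc_result`: `thresholds` (ascending),
#'   `sensitivity`, `specificity`, `auc`, `youden_max`, `youden_threshold`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop_("both classes must be present to draw a ROC curve")
  thr <- c(sort(unique(scores)), Inf)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  # trapezoid over (FPR, TPR); thresholds descend => rates ascend from (0,0)
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(c(0, fpr)) * (c(0, tpr[-length(tpr)]) + tpr) / 2)
  j <- sens + spec - 1
  jmax <- max(j)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_max = jmax,
                 youden_threshold = min(thr[j == jmax])),
            class = "roc_result")
}

#' Diagnostic threshold at the Youden-index maximum
#'
#' Returns the cut-point maximizing sensitivity + specificity - 1. Ties are
#' broken toward the lowest threshold (the more sensitive rule).
#'
#' @param roc a [roc_curve()] result.
#' @return the threshold (on the score scale).
#' @export
youden_threshold <- function(roc) {
  if (!inherits(roc, "roc_result")) stop_("roc must be a roc_result")
  roc$youden_threshold
}

#' Dichotomize standardized scores at a diagnostic threshold
#'
#' Positive call iff `score >= threshold` (scores at the threshold are
#' called positive).
#'
#' @param score numeric score(s).
#' @param threshold diagnostic threshold.
#' @return integer vector of 0/1 calls.
#' @export
dichotomize_diagnosis <- function(score, threshold) {
  as.integer(score >= threshold)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f, Youden J %.4f at threshold %.4f\n",
              x$auc, x$youden_max, x$youden_threshold))
  invisible(x)
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == 2)) stop_("agreement table must be 2x2")
    counts <- c(a = table[1, 1], b = table[1, 2],
                c = table[2, 1], d = table[2, 2])
  } else if (length(table) == 4) {
    counts <- c(a = table[[1]], b = table[[2]], c = table[[3]], d = table[[4]])
  } else stop_("supply a 2x2 matrix or counts a, b, c, d")
  if (any(counts < 0) || sum(counts) == 0)
    stop_("counts must be non-negative with positive total")
  counts
}

#' Cohen's kappa for model-vs-clinician agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement, banded at the conventional cutoffs:
#' kappa >= 0.75 excellent, 0.40-0.75 fair to good, < 0.40 poor.
#'
#' @param table 2x2 matrix (rows: model +/-, columns: clinician +/-) or a
#'   length-4 vector of counts `a` (+/+), `b` (+/-), `c` (-/+), `d` (-/-).
#' @return list with `kappa`, `band`, `p_observed`, `p_expected`.
#' @export
cohens_kappa <- function(table) {
  x <- as_2x2(table)
  n <- sum(x)
  p_o <- (x["a"] + x["d"]) / n
  p_e <- ((x["a"] + x["b"]) * (x["a"] + x["c"]) +
          (x["c"] + x["d"]) * (x["b"] + x["d"])) / n^2
  if (1 - p_e < 1e-12)
    return(list(kappa = NA_real_, band = "undefined",
                p_observed = unname(p_o), p_expected = unname(p_e)))
  k <- unname((p_o - p_e) / (1 - p_e))
  # banding at the printed cutoffs; epsilon guards exact-boundary kappas
  # (e.g. a table with p_o = 0.7, p_e = 0.5) against representation error
  band <- if (k >= 0.75 - 1e-9) "excellent"
          else if (k >= 0.40 - 1e-9) "fair_to_good" else "poor"
  list(kappa = k, band = band,
       p_observed = unname(p_o), p_expected = unname(p_e))
}

#' McNemar paired test on the discordant cells
#'
#' For b + c >= 25 the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` on 1 df; for smaller discordant totals an
#' exact binomial test of b successes in b + c trials at p = 1/2. With no
#' discordant pairs the test is vacuous (p = 1).
#'
#' @inheritParams cohens_kappa
#' @return list with `statistic`, `p_value`, `method` (one of
#'   `"chi2_corrected"`, `"exact_binomial"`).
#' @export
mcnemar_paired_test <- function(table) {
  x <- as_2x2(table)
  b <- unname(x["b"]); cc <- unname(x["c"])
  disc <- b + cc
  if (disc == 0)
    return(list(statistic = 0, p_value = 1, method = "exact_binomial"))
  if (disc >= 25) {
    stat <- (abs(b - cc) - 1)^2 / disc
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chi2_corrected")
  } else {
    bt <- stats::binom.test(b, disc, p = 0.5)
    list(statistic = unname(bt$statistic), p_value = bt$p.value,
         method = "exact_binomial")
  }
}

#' Per-element diagnostic calibration and agreement table
#'
#' For each syndrome element: ROC of the standardized CAT score against the
#' clinician label, AUC, Youden-maximum diagnostic threshold, then agreement
#' (Cohen's kappa band and McNemar test) between the thresholded CAT
#' diagnosis and the clinician diagnosis.
#'
#' @param std_scores n x 6 matrix of standardized scores (columns named by
#'   element).
#' @param clinician_dx n x 6 matrix of 0/1 clinician labels.
#' @return data.frame with one row per element: `element`, `auc`,
#'   `youden_threshold`, `youden_max`, `kappa`, `kappa_band`,
#'   `mcnemar_statistic`, `mcnemar_p`, `mcnemar_method`.
#' @export
diagnostic_table <- function(std_scores, clinician_dx) {
  els <- colnames(std_scores)
  rows <- lapply(els, function(e) {
    dxcol <- if (paste0("dx_", e) %in% colnames(clinician_dx))
      paste0("dx_", e) else e
    dx <- clinician_dx[, dxcol]
    roc <- roc_curve(std_scores[, e], dx)
    call <- dichotomize_diagnosis(std_scores[, e], roc$youden_threshold)
    tab <- c(a = sum(call == 1 & dx == 1), b = sum(call == 1 & dx == 0),
             c = sum(call == 0 & dx == 1), d = sum(call == 0 & dx == 0))
    kp <- cohens_kappa(tab)
    mc <- mcnemar_paired_test(tab)
    data.frame(element = e, auc = roc$auc,
               youden_threshold = roc$youden_threshold,
               youden_max = roc$youden_max,
               kappa = kp$kappa, kappa_band = kp$band,
               mcnemar_statistic = mc$statistic, mcnemar_p = mc$p_value,
               mcnemar_method = mc$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
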