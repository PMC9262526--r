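#' Responsiveness of a QoL score to time-dependent change
#'
#' Tests whether paired baseline/follow-up scores moved. The difference
#' distribution is screened with Shapiro-Wilk at alpha = 0.05: normal
#' differences get the paired t-test, otherwise the Wilcoxon signed-rank test
#' (zero differences dropped; normal approximation with tie correction for
#' more than 25 non-zero differences). Identical baseline and follow-up
#' scores make the signed-rank test vacuous and are reported with p = 1 and
#' a degenerate flag.
#'
#' @param baseline,followup paired numeric vectors (n >= 6).
#' @param alpha normality-screen level.
#' @return list with `test` (`"paired_t"` or `"wilcoxon_signed_rank"`),
#'   `statistic`, `p_value`, `normality_p`, `degenerate`.
#' @export
responsiveness_test <- function(baseline, followup, alpha = 0.05) {
  if (length(baseline) != length(followup)) stop_("unpaired inputs")
  keep <- !is.na(baseline) & !is.na(followup)
  baseline <- baseline[keep]; followup <- followup[keep]
  n <- length(baseline)
  if (n < 6) stop_("need at least 6 pairs")
  d <- followup - baseline
  if (all(d == 0))
    return(list(test = "wilcoxon_signed_rank", statistic = NA_real_,
                p_value = 1, normality_p = NA_real_, degenerate = TRUE))
  sw <- stats::shapiro.test(d)$p.value
  if (sw >= alpha) {
    tt <- stats::t.test(followup, baseline, paired = TRUE)
    list(test = "paired_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, normality_p = sw, degenerate = FALSE)
  } else {
    nz <- sum(d != 0)
    wt <- suppressWarnings(stats::wilcox.test(
      followup, baseline, paired = TRUE, exact = nz <= 25, correct = TRUE))
    list(test = "wilcoxon_signed_rank", statistic = unname(wt$statistic),
         p_value = wt$p.value, normality_p = sw, degenerate = FALSE)
  }
}

#' Anchor-based MCID
#'
#' Restricts to patients who reported change on the global anchor, orients
#' each difference toward the reported direction (improvers keep the
#' improvement-signed change; worseners are sign-flipped so magnitudes do not
#' cancel), then takes the mean when the oriented differences pass the
#' Shapiro-Wilk normality screen and the median otherwise. A zero median is
#' clinically implausible as an MCID, so it falls back to the mean (flagged
#' `fallback_mean`) unless an expert-supplied value is given.
#'
#' @param diff improvement-signed score differences (follow-up - baseline for
#'   a higher-is-better instrument), one per patient.
#' @param anchor anchor responses in -2..2 (0 = no change), aligned with
#'   `diff`.
#' @param stratum which changed patients enter the estimate: `"pooled"` (all
#'   anchor != 0, default), `"improvers_only"` (anchor > 0), or
#'   `"somewhat_better"` (anchor == 1).
#' @param expert_value optional externally supplied MCID used when the median
#'   is zero.
#' @param alpha normality-screen level.
#' @return list with `value`, `method` (`"mean"`, `"median"`,
#'   `"fallback_mean"`, `"expert"`), `normality_p`, `n_changed`.
#' @export
anchor_based_mcid <- function(diff, anchor,
                              stratum = c("pooled", "improvers_only",
                                          "somewhat_better"),
                              expert_value = NULL, alpha = 0.05) {
  stratum <- match.arg(stratum)
  if (length(diff) != length(anchor)) stop_("diff and anchor must align")
  keep <- !is.na(diff) & !is.na(anchor)
  diff <- diff[keep]; anchor <- anchor[keep]
  sel <- switch(stratum,
                pooled = anchor != 0,
                improvers_only = anchor > 0,
                somewhat_better = anchor == 1)
  if (!any(sel)) stop_("no changed patients")
  oriented <- ifelse(anchor[sel] > 0, diff[sel], -diff[sel])
  n <- length(oriented)
  sw <- if (n >= 3 && stats::sd(oriented) > 0)
    stats::shapiro.test(oriented)$p.value else NA_real_
  if (!is.na(sw) && sw >= alpha) {
    return(list(value = mean(oriented), method = "mean",
                normality_p = sw, n_changed = n))
  }
  if (is.na(sw)) {  # too few / constant: mean and median coincide in spirit
    return(list(value = mean(oriented), method = "mean",
                normality_p = sw, n_changed = n))
  }
  med <- stats::median(oriented)
  if (med == 0) {
    if (!is.null(expert_value))
      return(list(value = expert_value, method = "expert",
                  normality_p = sw, n_changed = n))
    return(list(value = mean(oriented), method = "fallback_mean",
                normality_p = sw, n_changed = n))
  }
  list(value = med, method = "median", normality_p = sw, n_changed = n)
}

#' Distribution-based MCID
#'
#' Effect-size multiple of the baseline standard deviation (n - 1
#' denominator). The default effect size is 0.2; 0.5 is retained for
#' sensitivity analysis.
#'
#' @param baseline_scores baseline domain scores.
#' @param es effect size multiplier.
#' @return the MCID estimate.
#' @export
distribution_based_mcid <- function(baseline_scores, es = 0.2) {
  baseline_scores <- baseline_scores[!is.na(baseline_scores)]
  if (length(baseline_scores) < 2) stop_("need at least 2 baseline scores")
  s <- stats::sd(baseline_scores)
  if (s == 0) stop_("constant baseline scores")
  es * s
}

#' Equal-weight combination of the two MCID estimates
#'
#' @param anchor_value anchor-based estimate.
#' @param distribution_value distribution-based estimate.
#' @return their arithmetic mean.
#' @export
weighted_mcid <- function(anchor_value, distribution_value) {
  if (!is.finite(anchor_value) || !is.finite(distribution_value))
    stop_("both estimates must be finite")
  (anchor_value + distribution_value) / 2
}

#' Per-domain MCID table (8 domains + total)
#'
#' Combines the anchor-based and distribution-based estimates for every QoL
#' domain and the total score. The distribution-based component uses the
#' baseline SD of the full baseline sample; the anchor-based component uses
#' non-dropped patients with a non-zero anchor. The `weighted` column is the
#' exact mean of the other two (rounding to 4 decimals, half away from zero,
#' applied only in `report = TRUE` mode).
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param es effect size for the distribution-based component.
#' @param stratum,expert_values passed to [anchor_based_mcid()]
#'   (`expert_values` is an optional named list per domain).
#' @param report if `TRUE`, round the numeric columns to 4 decimals.
#' @return data.frame of class `mcid_table`: `domain`, `distribution_based`,
#'   `anchor_based`, `weighted`, `anchor_method`, `normality_p`, `es`.
#' @export
mcid_table <- function(cohort, es = 0.2, stratum = "pooled",
                       expert_values = NULL, report = FALSE) {
  doms <- c(sub("^qol_b_", "", grep("^qol_b_", names(cohort), value = TRUE)))
  fu <- cohort[!cohort$dropped, ]
  rows <- lapply(doms, function(dm) {
    dist <- distribution_based_mcid(cohort[[paste0("qol_b_", dm)]], es)
    d <- fu[[paste0("qol_f_", dm)]] - fu[[paste0("qol_b_", dm)]]
    anc <- anchor_based_mcid(d, fu$anchor, stratum = stratum,
                             expert_value = expert_values[[dm]])
    data.frame(domain = dm, distribution_based = dist,
               anchor_based = anc$value,
               weighted = weighted_mcid(anc$value, dist),
               anchor_method = anc$method, normality_p = anc$normality_p,
               es = es, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (report) {
    num <- c("distribution_based", "anchor_based", "weighted")
    out[num] <- lapply(out[num], round_half_away, digits = 4)
  }
  class(out) <- c("mcid_table", "data.frame")
  out
}

#' Responsiveness table over all domains
#'
#' @inheritParams mcid_table
#' @return data.frame with `domain`, `test`, `statistic`, `p_value`,
#'   `normality_p`.
#' @export
responsiveness_table <- function(cohort) {
  doms <- sub("^qol_b_", "", grep("^qol_b_", names(cohort), value = TRUE))
  fu <- cohort[!cohort$dropped, ]
  rows <- lapply(doms, function(dm) {
    r <- responsiveness_test(fu[[paste0("qol_b_", dm)]],
                             fu[[paste0("qol_f_", dm)]])
    data.frame(domain = dm, test = r$test, statistic = r$statistic,
               p_value = r$p_value, normality_p = r$normality_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
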