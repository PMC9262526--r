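#' Synthetic cohort configuration
#'
#' Parameters of the synthetic longitudinal cohort generator. Defaults
#' emulate the design of the study the pipeline targets: 300 baseline
#' patients, 9 dropouts (291 at follow-up), six latent syndrome-element
#' severities with clinician labels subject to a 5% error rate, eight
#' quality-of-life (QoL) domains plus a total score responding to severity
#' improvement, and a 5-level global anchor derived from the latent total
#' QoL change.
#'
#' Default per-element treatment effects follow the published mean CAT-score
#' decreases (liver and qi stagnation improve most; stomach and
#' spleen-dampness least). Default per-domain baseline QoL standard
#' deviations are chosen so that 0.2 x SD lands in the published
#' distribution-based MCID range.
#'
#' @param n_baseline number of baseline patients.
#' @param n_dropout number of patients lost to follow-up (must be <
#'   `n_baseline`).
#' @param elements,domains name vectors (defaults [syndrome_elements()],
#'   [fddql_domains()]).
#' @param severity_mean,severity_sd location/scale of the latent severities
#'   (logit scale), recycled over elements.
#' @param severity_cor equicorrelation of the latent severities.
#' @param prevalence_cutoff latent value above which the true diagnosis is
#'   positive, recycled over elements.
#' @param clinician_error_rate probability a clinician label flips from truth.
#' @param treatment_effect per-element mean latent severity decrease at
#'   follow-up.
#' @param progression_sd patient-level SD of the severity change around
#'   `treatment_effect`.
#' @param qol_baseline_mean,qol_baseline_sd per-domain baseline QoL location
#'   and scale (0-100 scale), recycled over the 8 domains.
#' @param qol_cor equicorrelation of baseline QoL domains.
#' @param qol_loading 6 x 8 matrix: QoL points of domain change per unit of
#'   element severity improvement.
#' @param qol_noise_sd residual SD of the QoL domain change, recycled.
#' @param anchor_cuts four strictly increasing thresholds on the latent total
#'   QoL change mapping to anchor levels -2, -1, 0, 1, 2.
#' @param anchor_misreport probability an anchor response is misreported to
#'   an adjacent level (default 0: anchor deterministic given latent change).
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_baseline = 300, n_dropout = 9,
                          elements = syndrome_elements(),
                          domains = fddql_domains(),
                          severity_mean = 0, severity_sd = 1,
                          severity_cor = 0.3,
                          prevalence_cutoff = 0,
                          clinician_error_rate = 0.05,
                          treatment_effect = c(0.424, 0.041, 0.095,
                                               0.042, 0.054, 0.186),
                          progression_sd = 0.3,
                          qol_baseline_mean = 55,
                          qol_baseline_sd = c(16.4175, 19.4770, 19.0855,
                                              19.5895, 14.4490, 16.8960,
                                              21.2525, 21.3200),
                          qol_cor = 0.3,
                          qol_loading = default_qol_loading(),
                          qol_noise_sd = 5,
                          anchor_cuts = c(-4.711, -3.711, 0.336, 3.672),
                          anchor_misreport = 0,
                          seed = 1L) {
  ne <- length(elements); nd <- length(domains)
  cfg <- list(n_baseline = as.integer(n_baseline),
              n_dropout = as.integer(n_dropout),
              elements = elements, domains = domains,
              severity_mean = rep_len(severity_mean, ne),
              severity_sd = rep_len(severity_sd, ne),
              severity_cor = severity_cor,
              prevalence_cutoff = rep_len(prevalence_cutoff, ne),
              clinician_error_rate = clinician_error_rate,
              treatment_effect = rep_len(treatment_effect, ne),
              progression_sd = progression_sd,
              qol_baseline_mean = rep_len(qol_baseline_mean, nd),
              qol_baseline_sd = rep_len(qol_baseline_sd, nd),
              qol_cor = qol_cor,
              qol_loading = qol_loading,
              qol_noise_sd = rep_len(qol_noise_sd, nd),
              anchor_cuts = anchor_cuts,
              anchor_misreport = anchor_misreport,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Default element-to-domain loading matrix
#'
#' Rows are syndrome elements, columns QoL domains; entry (e, d) is the QoL
#' change (points) per unit improvement of element e. The sparsity pattern
#' mirrors the qualitative associations the study reports: qi deficiency
#' drives daily activities; liver and qi stagnation drive anxiety; stomach
#' drives discomfort and diet; heat drives coping, health perceptions and
#' stress; spleen-dampness loads broadly (largest total-score impact) and
#' dominates sleep.
#'
#' @return a 6 x 8 numeric matrix with element/domain dimnames.
#' @export
default_qol_loading <- function() {
  L <- rbind(
    liver           = c(0, 6, 0, 2, 0, 1, 1, 2),
    stomach         = c(0, 0, 5, 2, 7, 1, 0, 0),
    heat            = c(0, 2, 0, 0, 2, 3, 6, 3),
    spleen_dampness = c(2, 1, 1, 5, 1, 2, 2, 2),
    qi_deficiency   = c(7, 0, 0, 1, 0, 2, 0, 1),
    qi_stagnation   = c(1, 6, 1, 0, 0, 0, 0, 2))
  colnames(L) <- fddql_domains()
  L
}

validate_cohort_config <- function(cfg) {
  num <- unlist(cfg[c("severity_mean", "severity_sd", "prevalence_cutoff",
                      "clinician_error_rate", "treatment_effect",
                      "progression_sd", "qol_baseline_mean",
                      "qol_baseline_sd", "qol_noise_sd", "anchor_cuts",
                      "qol_loading")])
  if (any(!is.finite(num))) stop_("non-finite value in cohort configuration")
  if (cfg$n_dropout >= cfg$n_baseline || cfg$n_dropout < 0)
    stop_("n_dropout must be non-negative and smaller than n_baseline")
  if (any(cfg$qol_noise_sd <= 0)) stop_("qol_noise_sd must be positive")
  if (any(diff(cfg$anchor_cuts) <= 0))
    stop_("anchor_cuts must be strictly increasing")
  if (length(cfg$anchor_cuts) != 4) stop_("anchor_cuts must have length 4")
  if (!all(dim(cfg$qol_loading) == c(length(cfg$elements),
                                     length(cfg$domains))))
    stop_("qol_loading must be ", length(cfg$elements), " x ",
          length(cfg$domains))
  if (cfg$clinician_error_rate < 0 || cfg$clinician_error_rate > 1)
    stop_("clinician_error_rate must be in [0, 1]")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration:", x$n_baseline, "baseline /",
      x$n_baseline - x$n_dropout, "follow-up patients\n")
  cat("Clinician error rate:", x$clinician_error_rate,
      " anchor cuts:", paste(signif(x$anchor_cuts, 3), collapse = ", "), "\n")
  invisible(x)
}

# Equicorrelated multivariate normal draws (n x k), sds/means recycled.
rmvn_equicorr <- function(n, mean, sd, rho) {
  k <- length(mean)
  S <- matrix(rho, k, k); diag(S) <- 1
  z <- matrix(stats::rnorm(n * k), n, k) %*% chol(S)
  sweep(sweep(z, 2, sd, "*"), 2, mean, "+")
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws latent severities from an equicorrelated multivariate normal,
#' derives clinician labels as thresholded truth with independent label
#' flips, moves severities at follow-up by the treatment effect plus
#' patient-level variation, propagates severity improvement into QoL domain
#' changes through the loading matrix plus Gaussian noise (clamped to
#' [0, 100] after noise, with a message when clamping occurs), computes the
#' total score as the mean of the 8 domains, and maps the latent total QoL
#' change onto the 5-level anchor via `anchor_cuts`. Dropouts are selected
#' uniformly at random and carry no follow-up values or anchor.
#'
#' @param config a [cohort_config()].
#' @return a data.frame (one row per patient) with columns `patient_id`,
#'   `dropped`, `anchor`, `theta_b_*`, `theta_f_*`, `dx_*` (six each) and
#'   `qol_b_*`, `qol_f_*` (eight domains plus `total`). The latent total QoL
#'   change used for the anchor is attached as attribute `latent_change`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_baseline
  ne <- length(config$elements); nd <- length(config$domains)

  theta_b <- rmvn_equicorr(n, config$severity_mean, config$severity_sd,
                           config$severity_cor)
  truth <- sweep(theta_b, 2, config$prevalence_cutoff, ">")
  flips <- matrix(stats::runif(n * ne) < config$clinician_error_rate, n, ne)
  dx <- truth != flips  # XOR: flip label where flips is TRUE
  improvement <- sweep(matrix(stats::rnorm(n * ne, 0, config$progression_sd),
                              n, ne), 2, config$treatment_effect, "+")
  theta_f <- theta_b - improvement

  qol_b <- clamp(rmvn_equicorr(n, config$qol_baseline_mean,
                               config$qol_baseline_sd, config$qol_cor))
  n_clamped <- attr(qol_b, "n_clamped")
  noise <- sweep(matrix(stats::rnorm(n * nd), n, nd), 2,
                 config$qol_noise_sd, "*")
  dqol <- improvement %*% config$qol_loading + noise
  qol_f <- clamp(qol_b + dqol)
  n_clamped <- n_clamped + attr(qol_f, "n_clamped")

  latent_change <- rowMeans(dqol)
  anchor <- as.integer(cut(latent_change,
                           c(-Inf, config$anchor_cuts, Inf))) - 3L
  if (config$anchor_misreport > 0) {
    mis <- stats::runif(n) < config$anchor_misreport
    shift <- sample(c(-1L, 1L), n, replace = TRUE)
    anchor[mis] <- pmin(pmax(anchor[mis] + shift[mis], -2L), 2L)
  }
  dropped <- rep(FALSE, n)
  dropped[sample.int(n, config$n_dropout)] <- TRUE

  qb <- cbind(qol_b, total = rowMeans(qol_b))
  qf <- cbind(qol_f, total = rowMeans(qol_f))
  theta_f[dropped, ] <- NA_real_
  qf[dropped, ] <- NA_real_
  anchor[dropped] <- NA_integer_

  out <- data.frame(patient_id = seq_len(n), dropped = dropped,
                    anchor = anchor)
  add_block <- function(df, m, prefix, nms) {
    colnames(m) <- paste0(prefix, nms)
    cbind(df, m)
  }
  out <- add_block(out, theta_b, "theta_b_", config$elements)
  out <- add_block(out, theta_f, "theta_f_", config$elements)
  out <- add_block(out, 1L * dx, "dx_", config$elements)
  out <- add_block(out, qb, "qol_b_", c(config$domains, "total"))
  out <- add_block(out, qf, "qol_f_", c(config$domains, "total"))
  if (n_clamped > 0)
    message("generate_cohort: clamped ", n_clamped,
            " QoL values to [0, 100]")
  attr(out, "latent_change") <- latent_change
  attr(out, "config") <- config
  out
}

# Latent total-QoL-change draws only, for anchor calibration.
simulate_latent_changes <- function(config, n_rep = 50) {
  set.seed(derive_seed(config$seed, 97))
  n <- (config$n_baseline - config$n_dropout) * n_rep
  ne <- length(config$elements); nd <- length(config$domains)
  improvement <- sweep(matrix(stats::rnorm(n * ne, 0, config$progression_sd),
                              n, ne), 2, config$treatment_effect, "+")
  noise <- sweep(matrix(stats::rnorm(n * nd), n, nd), 2,
                 config$qol_noise_sd, "*")
  rowMeans(improvement %*% config$qol_loading + noise)
}

#' Calibrate anchor cuts to target anchor counts
#'
#' Adjusts `anchor_cuts` so that the expected anchor distribution at
#' follow-up approximates the target counts, given the rest of the
#' configuration. Cuts are placed at the empirical quantiles of simulated
#' latent total QoL changes matching the target proportions; the lowest cut
#' (separating "obviously worse" from "somewhat worse") is placed one point
#' below the worse/no-change cut, since the targets pool the two worsened
#' levels.
#'
#' @param config a [cohort_config()].
#' @param target_counts integer vector `c(obviously_better, somewhat_better,
#'   worse, unchanged)`; must sum to the follow-up count and be non-negative.
#' @param n_rep number of simulated follow-up cohorts pooled for the
#'   quantile estimates.
#' @return the configuration with calibrated `anchor_cuts`.
#' @export
anchor_target_calibration <- function(config, target_counts, n_rep = 50) {
  if (length(target_counts) != 4 || any(target_counts < 0))
    stop_("target_counts must be 4 non-negative counts")
  n_follow <- config$n_baseline - config$n_dropout
  if (sum(target_counts) != n_follow)
    stop_("target_counts must sum to the follow-up count (", n_follow, ")")
  g <- simulate_latent_changes(config, n_rep)
  p_worse <- target_counts[3] / n_follow
  p_nochange <- target_counts[4] / n_follow
  p_better1 <- target_counts[2] / n_follow
  eps <- 1e-9
  c2 <- stats::quantile(g, min(max(p_worse, eps), 1 - eps), names = FALSE)
  c3 <- stats::quantile(g, min(p_worse + p_nochange, 1 - eps), names = FALSE)
  c4 <- stats::quantile(g, min(p_worse + p_nochange + p_better1, 1 - eps),
                        names = FALSE)
  c1 <- c2 - 1
  if (c3 <= c2) c3 <- c2 + 1e-6
  if (c4 <= c3) c4 <- c3 + 1e-6
  config$anchor_cuts <- c(c1, c2, c3, c4)
  validate_cohort_config(config)
  config
}

cohort_columns <- function(elements = syndrome_elements(),
                           domains = fddql_domains()) {
  c("patient_id", "dropped", "anchor",
    paste0("theta_b_", elements), paste0("theta_f_", elements),
    paste0("dx_", elements),
    paste0("qol_b_", c(domains, "total")),
    paste0("qol_f_", c(domains, "total")))
}

validate_cohort <- function(df, elements = syndrome_elements(),
                            domains = fddql_domains()) {
  cols <- cohort_columns(elements, domains)
  if (!identical(names(df), cols))
    stop_("malformed cohort header; expected columns: ",
          paste(cols, collapse = ", "))
  if (nrow(df) == 0) stop_("no records")
  a <- df$anchor
  if (any(!is.na(a) & (a < -2 | a > 2 | a != round(a))))
    stop_("anchor values must be integers in -2..2")
  if (any(!is.na(a[df$dropped == TRUE]) ))
    stop_("anchor must be missing for dropped patients")
  qcols <- grep("^qol_", names(df), value = TRUE)
  q <- as.matrix(df[qcols])
  if (any(!is.na(q) & (q < 0 | q > 100)))
    stop_("QoL scores must lie in [0, 100]")
  invisible(df)
}

#' Read / write a cohort as CSV
#'
#' One row per patient with the documented header; numeric fields are
#' written at full precision so `read_cohort(write_cohort(x))` round-trips
#' exactly.
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param path file path.
#' @param elements,domains name vectors used for validation.
#' @return `read_cohort` returns the validated cohort data.frame.
#' @export
write_cohort <- function(cohort, path, elements = syndrome_elements(),
                         domains = fddql_domains()) {
  validate_cohort(cohort, elements, domains)
  out <- cohort
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), NA, formatC(x, digits = 17, format = "g")))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, elements = syndrome_elements(),
                        domains = fddql_domains()) {
  if (!file.size(path) > 0) stop_("no records")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_("no records")
  df$dropped <- as.logical(df$dropped)
  df$anchor <- as.integer(df$anchor)
  validate_cohort(df, elements, domains)
  df
}
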