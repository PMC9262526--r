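---
title: "Methods: from adaptive syndrome scores to clinically meaningful change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from adaptive syndrome scores to clinically meaningful change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catmcid)
```

`catmcid` turns a computerized-adaptive-testing (CAT) model of six
traditional-Chinese-medicine syndrome elements into clinically interpretable
output: diagnostic thresholds referenced to clinician judgment, and
responder definitions referenced to what patients themselves perceive as
meaningful change on a quality-of-life (QoL) instrument. This vignette
documents the models, the defaults and why they are what they are, and what
the synthetic validation can and cannot show.

## 1. The measurement model

Each item in the bank measures exactly one of the six syndrome elements
(liver, stomach, heat, spleen-dampness, qi deficiency, qi stagnation) —
*between-item* multidimensionality. Responses follow Samejima's graded
response model (GRM): for an item with discrimination $a > 0$ and strictly
increasing thresholds $b_1 < \dots < b_{K-1}$ loading on element $e$,

$$P(X \ge k \mid \theta) = \mathrm{logit}^{-1}\!\big(a(\theta_e - b_k)\big),$$

with category probabilities as successive differences. The GRM with a simple
loading structure is the minimal polytomous model consistent with reporting
a separate score per syndrome element; nothing in the pipeline depends on a
richer within-item structure, and none is offered.

**Item selection** is D-optimal: the next item maximizes
$\det\big(\Sigma_0^{-1} + \sum_{j \in \text{admin}} I_j(\hat\theta) +
I_{\text{cand}}(\hat\theta)\big)$, where $\Sigma_0$ is the prior covariance.
Because each item's information matrix has a single non-zero diagonal entry,
the candidate contributes a rank-one update and the determinant ratio
reduces to $1 + I_c \cdot (A^{-1})_{ee}$ — items are scored by information
times current posterior variance on their element, which is also why
D-optimal selection automatically balances the six elements over a session.
Ties break to the lowest `item_id` so sessions are reproducible. The
exhaustive determinant search is retained in the test suite as an oracle and
agrees with the rank-one shortcut on every tested bank.

**Severity estimation** is maximum a posteriori (MAP): Newton–Raphson on the
log-posterior from the prior mean, step-halving whenever a step would
decrease the log-posterior, and a Fisher-scoring fallback (expected
information plus prior precision, always positive definite) when the
observed Hessian is unusable. Convergence is declared when the gradient norm
falls below `newton_tol` (default 1e-8, cap 100 iterations). Posterior SEs
come from the inverse negative Hessian at the mode. With no responses the
posterior is the prior exactly.

**Termination** is fixed-length: 20 answers, the deployed system's rule.
There is no exposure control or variable-length stopping; those are
out of scope.

The prior is standard normal and independent across elements by default
(configurable covariance). The reporting transform is the T-score
convention `score = 50 + 10·θ̂`, which puts typical scores in the 35–55
range seen in practice; the deployed system's own θ→score map is not
public, and any strictly monotone affine choice here is equivalent for
every downstream rank-based step (ROC, Youden, standardization).

Whether the deployed system selects from its 39 extracted items or the full
215-item bank is ambiguous; the engine therefore takes an optional
`active_items` pool (default: the full bank), so either reading can be run.

## 2. Score standardization

Raw reporting-scale scores are mapped to 0–100 by
$(\text{score} - \text{min}) / (\text{max} - \text{min}) \times 100$, with
the extremes fitted on the **pooled baseline + follow-up** sample so both
timepoints share one scale (the alternative — baseline-only extremes — is a
one-line change via `fit_standardizer`'s input). The map is affine and
strictly monotone, so it preserves ranks, and AUCs are identical before and
after standardization. Out-of-range future scores are clamped to [0, 100]
with a warning rather than rejected. Report tables round to 4 decimals,
half away from zero.

## 3. Diagnostic calibration and agreement

Per element, the standardized score is the test variable and the clinician
label the state variable. The ROC is built over all unique cut-points with
the positive-call convention **score ≥ threshold** (higher severity score ⇒
syndrome present; the direction is a package convention, stated here because
the clinical sources leave it implicit). AUC is trapezoidal, which equals
the Mann–Whitney pair statistic including the half-credit tie term; AUC >
0.8 is the accuracy bar. The diagnostic threshold is the Youden-index
maximizer, ties resolved to the **lower** threshold (the more sensitive
rule). Agreement uses Cohen's kappa with the printed bands (≥ 0.75
excellent, 0.40–0.75 fair to good, < 0.40 poor) and a McNemar test:
continuity-corrected chi-square $(|b-c|-1)^2/(b+c)$ when the discordant
total is at least 25, otherwise an exact binomial test at p = ½ — the
small-sample switch is a package decision, as the sources name only the
paired chi-square.

## 4. MCID triangulation

Responsiveness per domain is a paired t-test when the Shapiro–Wilk test
(α = 0.05) accepts normality of the differences and a Wilcoxon signed-rank
test otherwise; Shapiro–Wilk operationalizes "normal or skewed
distribution", which the sources invoke without naming a test.

The **anchor-based** MCID restricts to patients reporting change on the
global anchor (−2…+2), orients each difference toward the reported
direction (worseners sign-flipped so magnitudes do not cancel — the
pooled-orientation choice; `improvers_only` and `somewhat_better` strata are
available), then takes the mean under normality and the median otherwise. A
zero median is clinically implausible as an MCID; the estimator then falls
back to the sample mean with an explicit `fallback_mean` flag, or to a
user-supplied expert value — the original expert-opinion substitution is not
reconstructible from published material, so the package makes the fallback
explicit and overridable rather than silently imitating it.

The **distribution-based** MCID is ES × baseline SD with ES = 0.2 by
default (the final choice in the source analysis; 0.5 is retained for
sensitivity analysis). The **final** MCID is the exact arithmetic mean of
the two estimates; `verify_weighted_mcid()` re-derives the published
combined column from the published inputs and all nine domains agree within
1e-4.

## 5. Outcome linkage

A patient responds in a domain when the improvement-signed QoL change
satisfies $d \ge \text{MCID}$ (boundary inclusive). The element predictors
are the continuous signed changes of the standardized scores, oriented
baseline − follow-up so positive = improvement (element scores fall as
patients improve). Continuous coding is the default; a `binary_coding`
option dichotomizes the changes, since some published coefficient magnitudes
hint that a binary coding may have been used — the exact transformation
behind the published tables is not stated and their coefficients are not
reproducible without the patient data. Fits are unpenalized maximum
likelihood (IRLS with a 1e-12 deviance tolerance); quasi-separation (any
|B| > 15) is flagged, not corrected, mirroring apparently unpenalized
published fits. Reports follow the `B, S.E., Wald, df, P, Exp(B)` layout
with 3-decimal rounding and the `<0.001` convention. No multiplicity
correction is applied across the 9 × 6 grid (none was applied in the source
analysis); a Benjamini–Hochberg column is attached as supplementary output.

## 6. What the synthetic cohort emulates

The generator is first-class, tested code; its defaults are the study
conditions, fixed once:

* **Design**: 300 baseline patients, 9 uniform-random dropouts, 291 at
  follow-up. No dropout mechanism is published; uniform is the neutral
  choice.
* **Severities**: multivariate normal, mean 0, SD 1 per element,
  equicorrelation 0.3 — TCM syndrome elements co-occur, and the sources are
  silent on the dependence; 0.3 is a moderate, defensible value.
* **Clinician labels**: thresholded truth (θ > 0, ≈50% prevalence) with
  independent 5% label flips.
* **Treatment effects** (latent drop per element): 0.424, 0.041, 0.095,
  0.042, 0.054, 0.186 — one tenth of the published mean raw-score decreases
  under the 50 + 10θ transform, so liver and qi stagnation improve most and
  stomach/spleen-dampness least, as reported. Patient-level variation
  around these means has SD 0.3 (`progression_sd`, a package choice).
* **QoL**: eight domains, equicorrelation 0.3, baseline mean 55; the
  per-domain baseline SDs are the published distribution-based MCIDs
  divided by 0.2, so the distribution-based column lands in the published
  magnitude range by construction. Domain change = loading-weighted severity
  improvement + N(0, 5) noise, clamped to [0, 100] after noise (clamps are
  counted and reported); the total score is the mean of the eight domains —
  the instrument's true aggregation rule is not published, and this rule is
  isolated in one place.
* **Loadings**: the default 6 × 8 matrix mirrors the reported qualitative
  pattern (qi deficiency → daily activities; liver and qi stagnation →
  anxiety; stomach → discomfort and diet; heat → coping, health perceptions,
  stress; spleen-dampness broad, dominating sleep and the total score).
* **Anchor**: deterministic cut of the latent total QoL change at four
  thresholds (optional misreport probability, default 0). The default cuts
  were fixed once by `anchor_target_calibration()` against the published
  change distribution (39 obviously better / 156 somewhat better / 3 worse /
  93 unchanged out of 291) and are not data-dependent thereafter.

The generator does **not** model real disease epidemiology, item content,
floor/ceiling psychometrics of the QoL instrument, informative dropout, or
anchor recall bias. Passing tests therefore demonstrate that the pipeline's
statistics are computed correctly and behave as theory predicts on data
with the study's structure — not that the published patient-level numbers
(thresholds 39/44/52/41/47/43, kappa 0.628, the logistic coefficients)
recur; those depend on unavailable clinical data.

## 7. Numerical choices and degenerate inputs

* Tie-breaks: lowest `item_id` in selection; lowest threshold at Youden
  ties; both for reproducibility.
* Probabilities are floored at 1e-300 inside log-likelihoods; padded
  response categories (items with fewer than the maximum K) carry +Inf
  thresholds and exactly zero probability.
* Kappa banding applies a 1e-9 boundary epsilon so tables whose kappa is
  exactly a band edge (e.g. 0.4) are classified by the printed rule, not by
  floating-point representation; degenerate marginals (expected agreement
  1) report kappa as undefined.
* All-zero differences make the responsiveness test vacuous (p = 1,
  flagged); constant baselines, single-class labels, rank-deficient designs
  and empty cohort files raise immediate, specific errors.
* CSV and JSON writers emit 17 significant digits, so cohorts, banks and
  standardizer parameters round-trip bit-exactly.
* Every stage seed derives from one master seed (`run_pipeline(seed =)`),
  making the full bundle reproducible end to end.

## 8. Problem sizes used in validation

The shipped tests exercise: full 215-item banks and controlled 2–90-item
banks; CAT sessions of 5–20 items; simulated populations of 60–300
respondents for recovery, efficiency (D-optimal vs random) and the
AUC > 0.8 check on the default 300-patient cohort; 200-dataset exhaustive
oracles for ROC/Youden; 30-dataset optimizer oracles and an n = 5000
planted-coefficient recovery for the logistic stage; and a 50-replicate
null-loading calibration of the linkage grid's type-I error. These sizes
give stable Monte-Carlo behaviour at interactive runtimes.

## 9. Known limitations

* CAT measurement error attenuates the linkage coefficients: with 20 items
  over six elements, per-element posterior SD is sizeable relative to the
  default true change variation, so CAT-based element-change predictors
  carry substantial noise and the fitted B's shrink toward zero compared to
  fits on the latent changes (`element_score_changes(..., source =
  "latent")` quantifies the gap). This is a property of the design being
  emulated, not a defect of the fit.
* The anchor-based MCID inherits the anchor's quality; the generator's
  anchor is (by default) a deterministic function of latent change, which
  is more favourable than real global-rating items.
* Single-cohort min-max standardization makes the 0–100 scale
  sample-dependent; scores from new samples can clamp at the edges.
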