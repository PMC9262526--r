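# catmcid

Clinical interpretation of a computerized-adaptive-testing (CAT) model of
traditional-Chinese-medicine (TCM) syndrome elements, built as a tested,
reusable R pipeline.

## The problem

Quantitative TCM diagnosis models score patients on six syndrome elements —
liver, stomach, heat, spleen-dampness, qi deficiency and qi stagnation — via
an adaptive questionnaire, but a score is only clinically meaningful once it
is linked to outcomes patients and clinicians recognise. `catmcid`
implements that linkage end to end for a postprandial-distress-syndrome
population measured with a functional-digestive-disorder quality-of-life
(QoL) instrument (8 domains + total):

1. **CAT engine** — a multidimensional Samejima graded response model with
   between-item dimensionality. Cumulative category probabilities are
   `P(X ≥ k) = logistic(a(θ_e − b_k))`. Items are selected by **D-optimality**
   (maximize `det(Σ I_j(θ̂) + I_candidate(θ̂) + Σ₀⁻¹)`), severities are
   estimated by **maximum a posteriori** Newton–Raphson, and a session stops
   after a fixed 20 answers.
2. **Standardization** — `Score_std = (Score_CAT − Score_min) /
   (Score_max − Score_min) × 100`, with the extremes fitted on the pooled
   full sample.
3. **Diagnostic calibration** — per-element ROC against clinician
   diagnoses; accuracy bar AUC > 0.8; the diagnostic threshold is the cut
   maximizing the **Youden index** J = sensitivity + specificity − 1;
   agreement via Cohen's kappa (≥ 0.75 excellent, 0.40–0.75 fair to good,
   < 0.40 poor) and the McNemar paired test.
4. **MCID estimation** — the minimal clinically important difference per QoL
   domain is the equal-weight mean of an **anchor-based** estimate (mean or
   median change of patients reporting change on a 5-level global anchor,
   −2…+2) and a **distribution-based** estimate (effect size 0.2 × baseline
   SD), with a paired-t / Wilcoxon responsiveness check.
5. **Outcome linkage** — patients are responders when their QoL change
   `d ≥ MCID`; per-domain logistic regressions of responder status on the six
   element score changes report `B, S.E., Wald, df, P, Exp(B)`.

A synthetic-cohort generator reproduces the study design (300 baseline / 291
follow-up patients, clinician labels with 5% error, an anchor distribution
of roughly 39 obviously better / 156 somewhat better / 3 worse / 93
unchanged), so the entire pipeline is testable without any patient data.

## Worked example

```r
library(catmcid)
report <- run_pipeline(seed = 1)   # default study design: 300 patients
print(report)
```

```
CAT clinical-interpretation report (seed 1)
Patients: 300 baseline / 291 follow-up

Diagnostic calibration:
         element    auc youden_threshold  kappa mcnemar_p
           liver 0.8707          47.3192 0.5799    0.0000
         stomach 0.9068          51.6450 0.6725    0.3914
            heat 0.9130          56.2179 0.6799    0.6650
 spleen_dampness 0.8948          51.1655 0.6591    0.4008
   qi_deficiency 0.8857          36.8586 0.6468    0.1696
   qi_stagnation 0.8974          48.5274 0.6873    0.0801

MCID table:
             domain distribution_based anchor_based weighted anchor_method
         activities             3.1335       1.8177   2.4756          mean
            anxiety             3.9021       4.8902   4.3961          mean
               diet             3.7871       0.8818   2.3345        median
              sleep             3.6844       2.4686   3.0765          mean
         discomfort             2.6392       1.4952   2.0672          mean
 health_perceptions             3.4731       1.9324   2.7027          mean
             coping             4.1034       1.8365   2.9699          mean
             stress             4.2059       2.2398   3.2229          mean
              total             2.2496       1.9228   2.0862        median
```

Every element's AUC clears the 0.8 accuracy bar, kappas fall in the
fair-to-good band, and the per-domain MCIDs are in the 2–4.5 point range:
e.g. a patient's total QoL score must improve by at least 2.09 points (on
this synthetic cohort) before the change counts as clinically significant.
`report$linkage$total` then prints the logistic table linking the six
element score changes to that responder outcome, one row per element plus
the constant:

```
Logistic fit (n = 291, converged = TRUE)
 Independent variables      B  S.E.   Wald df      P Exp(B)
                 liver -0.005 0.008  0.464  1  0.496  0.995
               stomach  0.000 0.009  0.001  1  0.974  1.000
                  heat  0.008 0.009  0.825  1  0.364  1.008
       spleen_dampness  0.014 0.008  3.006  1  0.083  1.015
         qi_deficiency  0.015 0.008  3.219  1  0.073  1.015
         qi_stagnation -0.001 0.008  0.016  1  0.898  0.999
              Constant -0.783 0.144 29.486  1 <0.001  0.457
```

`verify_weighted_mcid()` checks the equal-weight MCID combination rule
against the published per-domain values shipped in
`inst/extdata/fddql_mcid_published.csv` (all nine agree within 1e-4).

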