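# raidose

Lesion dosimetry and theranostic dose prediction for radioiodine therapy of
iodine-avid disease.

Radioiodine (¹³¹I-NaI) therapy of differentiated thyroid cancer is usually
given as a fixed administered activity, yet the absorbed doses delivered to
individual metastatic lesions range over several orders of magnitude — a
plausible driver of the variation in treatment outcomes. `raidose` is for
medical physicists and imaging scientists analysing serial quantitative
SPECT/CT lesion measurements in that setting. It implements the full
pretherapy-dosimetry analysis chain:

* **Time–activity curve fitting** — weighted log-linear fits of the
  mono-exponential `A(t) = A0·exp(−λ_eff·t)` with analytic covariance,
  single-scan fallback (`λ_bio = 0`), and clamping of non-physical
  (accumulating) fits; cumulated activity `Ã = A0/λ_eff` with delta-method
  uncertainty.
* **MIRD self-dosimetry** — `D = Ã·S(m)` with mass-adjusted S values
  `S(m) = Δ_np/m` (non-penetrating self-dose; decay data from ICRP 107),
  and dose uncertainty `(u(D)/D)² = (u(Ã)/Ã)² + (u(m)/m)²`.
* **Theranostic prediction** — conversion of diagnostic ¹²³I kinetics into
  predicted therapeutic ¹³¹I uptake and dose:
  `λ_pred = max(0, λ_eff(123) − λ_phys(123)) + λ_phys(131)`,
  `A0_pred = A0·admin131/admin123`; plus a per-patient eligibility gate on a
  ≥30% uptake increase in at least one lesion.
* **Per-lesion RECIST response** — CR/PR/SD/PD on the CT longest axis with
  overall-response and clinical-benefit rates.
* **Nested-data statistics** — group-mean-centered Pearson/Spearman
  correlations (exact null degrees of freedom `n − g − 1`), Bland–Altman
  agreement (predicted − measured convention), Kruskal–Wallis between-patient
  test, and a one-way random-effects intraclass correlation.
* **Synthetic cohorts** — a hierarchical lognormal generator emulating a
  9-patient / 39-lesion trial structure (18 lung / 14 bone / 7 soft-tissue
  lesions, 370 MBq ¹²³I and 5.5 GBq ¹³¹I with the corresponding scan
  schedules), with retained simulation truth for recovery testing.

See `vignettes/lesion-dosimetry-methods.Rmd` for the models, assumptions and
design choices.

## Worked example

Fit a diagnostic ¹²³I series for a 2.6 cm³ lesion and predict the ¹³¹I
therapy dose for a 370 MBq → 5.5 GBq administration:

```r
library(raidose)
k123 <- isotope_constants("I123"); k131 <- isotope_constants("I131")

t   <- c(5, 24, 30, 48, 72)                      # h post administration
act <- c(3.607, 0.919, 0.631, 0.187, 0.033)      # MBq
fit <- fit_tac(t, act, sd_MBq = 0.05 * act, constants = k123)
fit
#> <tac_fit> I123: A0 = 5.073 MBq, lambda_eff = 0.069663 /h (T_eff = 9.95 h), n = 5

cumulated_activity(fit)$A_tilde_MBq_h
#> [1] 72.82  # MBq·h

pt <- predict_therapy(fit, 370, 5500, k123, k131, volume_cm3 = 2.6,
                      lesion_id = "L1")
pt
#> <predicted_therapy> L1: A0_pred = 75.41 MBq, lambda_eff_pred = 0.020844 /h, D_pred = 153.9 Gy
pt$dose_pred
#> <dose_estimate> L1: 153.9 Gy (sd 20.2 Gy)
```

The fitted effective half-life (9.95 h) decomposes into the 13.22-h ¹²³I
physical half-life and a ~41-h biological retention half-life; carrying the
biological component to ¹³¹I physics and scaling by the administration ratio
predicts a 153.9 Gy lesion dose with a 13% standard uncertainty (kinetic fit
plus 10% volume uncertainty in quadrature).

An end-to-end synthetic run, and the response-rate summary from a follow-up
size table:

```r
run <- run_pipeline(pipeline_config(cohort = cohort_config(site_mode = "fixture",
                                                           seed = 2026)))
run
#> <rai_run> 9 patients / 29 lesions; 9 eligible patient(s)
#>   median relative uptake change: 40.8
#>   predicted vs measured dose: centered r = 0.998, bias = 33.93 Gy

rr <- response_rates(classify_lesion(rep(20, 24),
                                     c(rep(14, 3), rep(21, 17), rep(25, 4)))$category)
rr$orr_percent; rr$cbr_percent
#> [1] 13
#> [1] 83
```

(29 of the 39 generated lesions survive the 10-mm size filter in this seed;
the centered correlation of 0.998 and the positive bias reflect 10%
measurement noise on an otherwise exact theranostic relationship.)

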