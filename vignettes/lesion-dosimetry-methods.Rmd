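---
title: "Lesion dosimetry and theranostic dose prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion dosimetry and theranostic dose prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raidose)
```

# The problem

Radioiodine (RAI) therapy of differentiated thyroid cancer delivers a fixed
administered activity of ¹³¹I-NaI, yet the absorbed doses actually received
by individual metastatic lesions span several orders of magnitude. A
theranostic workflow addresses this: a low-activity diagnostic ¹²³I-NaI study
quantifies each lesion's iodine kinetics, those kinetics are converted into a
prediction of the therapeutic ¹³¹I uptake and absorbed dose, and patients
whose uptake increased sufficiently after a redifferentiation drug (a MEK
inhibitor that restores sodium iodide symporter expression) proceed to
therapy. `raidose` implements this analysis chain — curve fitting, MIRD
self-dosimetry, theranostic conversion, eligibility gating, per-lesion
response classification, and the agreement statistics used to judge
predictive accuracy — together with a synthetic cohort generator so that
every stage is testable without clinical data.

# Kinetic model

Each lesion's serial activity is modelled as a mono-exponential washout

$$A(t) = A_0\, e^{-\lambda_{\mathrm{eff}} t}, \qquad
  \lambda_{\mathrm{eff}} = \lambda_{\mathrm{phys}} + \lambda_{\mathrm{bio}},$$

with $t$ the time post administration in hours. `fit_tac()` estimates
$(\ln A_0, \lambda_{\mathrm{eff}})$ by weighted linear least squares on
$\ln A$ versus $t$. When per-sample standard deviations are available the
log-scale variances $\log(1 + (\mathrm{sd}/A)^2)$ are treated as known and
the parameter covariance is $(X^\top W X)^{-1}$; otherwise the residual-based
covariance is used. The log-linear formulation was chosen over direct
nonlinear least squares because it is closed-form, its covariance is
analytic, and under multiplicative (lognormal) measurement noise it is the
maximum-likelihood fit; the test suite verifies agreement with a
variance-weighted nonlinear fit to better than 1% in
$\lambda_{\mathrm{eff}}$.

Two degenerate cases arise in practice and are handled explicitly:

* **Single scan.** With one time point $\lambda_{\mathrm{bio}}$ is
  unidentifiable; the fit falls back to physical decay only
  ($\lambda_{\mathrm{eff}} = \lambda_{\mathrm{phys}}$), back-extrapolates
  $A_0$, and sets `fallback_used`. This matches how a single 24-h diagnostic
  scan is conventionally converted across isotopes.
* **Apparent accumulation.** A fitted $\lambda_{\mathrm{eff}} \le 0$ makes
  the washout integral diverge. The decay constant is clamped to
  $\lambda_{\mathrm{phys}}$ (i.e. $\lambda_{\mathrm{bio}} = 0$), the
  intercept re-estimated, and the fit flagged; slower-than-physical
  clearance is never extrapolated to infinite time.

The cumulated activity is the analytic integral
$\tilde A = A_0/\lambda_{\mathrm{eff}}$ over $[0,\infty)$, with delta-method
variance
$\tilde A^2 [\mathrm{var}(\ln A_0) +
\mathrm{var}(\lambda)/\lambda^2 - 2\,\mathrm{cov}(\ln A_0,\lambda)/\lambda]$.
A model-based integral (rather than trapezoid-plus-tail) is the minimal
choice consistent with the mono-exponential model; with four or five scan
times out to 72–144 h the difference is small compared with the fit
uncertainty.

# Dosimetry

Absorbed dose follows the MIRD schema restricted to lesion self-dose with
mass-adjusted S values:

$$D = \tilde A \cdot S(m), \qquad S(m) = \Delta_{np}/m, \qquad m = \rho V.$$

$\Delta_{np}$ is the mean energy emitted per decay as non-penetrating
radiation (beta, conversion and Auger electrons), taken from standard decay
data (ICRP Publication 107): 0.1917 MeV for ¹³¹I and 0.0280 MeV for ¹²³I,
i.e. 0.1106 and 0.0162 Gy·g/(MBq·h). Physical half-lives are 13.2235 h
(¹²³I) and 8.0252 d (¹³¹I). All constants are overridable through
`isotope_constants()`. Photon self-dose and cross-dose are deliberately
omitted: for lesions of 0.3–43 cm³ the locally deposited electron energy
dominates, and the inverse-mass scaling $S \propto 1/m$ is exact in that
approximation. Density defaults to 1.0 g/cm³ for all sites, including bone,
since no site-specific densities are assumed; `mass_model()` makes both the
densities and the volume uncertainty configurable.

Dose uncertainty combines the relative uncertainty of $\tilde A$ with the
relative mass uncertainty in quadrature,
$(u(D)/D)^2 = (u(\tilde A)/\tilde A)^2 + (u(m)/m)^2$, following standard
uncertainty-propagation guidance for molecular radiotherapy dosimetry. The
default volume uncertainty is 10% relative — a deliberate, configurable
choice: oversized-VOI outlining of small lesions carries substantial volume
uncertainty, but no quantitative value is established, so a round
representative figure is used. When these delta-method uncertainties are
checked against Monte-Carlo propagation, the positive parameters
($\lambda_{\mathrm{eff}}$, volume) are sampled lognormally with matched
relative covariance; this is the natural error model for positive rates, and
with it the delta method agrees with $10^5$-draw Monte-Carlo to within 5% up
to $cv(\lambda) = 0.2$. (Sampling $\lambda$ as an untruncated normal instead
makes $1/\lambda$ heavy-tailed and inflates the Monte-Carlo sd by ~9% at
$cv(\lambda) = 0.15$; the discrepancy is a property of that sampling choice,
not of the propagation.)

# Theranostic conversion

The central assumption is that the biological clearance measured with ¹²³I is
unchanged at therapy. `predict_therapy()` therefore swaps the physical
component of the decay constant and rescales the amplitude by the ratio of
administered activities:

$$\lambda_{\mathrm{bio}} = \max(0,\ \lambda_{\mathrm{eff}}^{123} -
\lambda_{\mathrm{phys}}^{123}), \quad
\lambda_{\mathrm{eff}}^{\mathrm{pred}} = \lambda_{\mathrm{bio}} +
\lambda_{\mathrm{phys}}^{131}, \quad
A_0^{\mathrm{pred}} = A_0^{123}\,
\frac{A_{\mathrm{admin}}^{131}}{A_{\mathrm{admin}}^{123}}.$$

Predicted 24-h uptake concentration and predicted absorbed dose then follow
from the kinetic and dosimetry modules. The prediction is exactly
scale-equivariant in the administered therapy activity, and
$\lambda_{\mathrm{eff}}^{\mathrm{pred}} \ge \lambda_{\mathrm{phys}}^{131}$
always holds because of the clamp. When the assumption holds exactly — as in
the noise-free synthetic cohort — the predicted dose equals the delivered
dose to machine precision; the package's round-trip tests pin this. In real
cohorts the assumption fails in interesting ways (stunning, receptor
saturation, continued drug action), which is precisely what the Bland–Altman
bias measures; none of those mechanisms is modelled here.

Drug-effect metrics compare the predicted 24-h ¹³¹I uptake concentration
before and after the drug: the absolute change (post − pre, MBq/cm³) and the
relative change (post / pre). The eligibility gate passes a patient when at
least one lesion shows a relative increase of at least the threshold
(default 30%). The boundary is implemented **inclusively** (a relative
change of exactly 1.30 qualifies) because the source descriptions of the
rule are inconsistent ("more than 30%" versus "30% or more"); the threshold
is a plain argument, so the strict reading is one comparison away.

# Response classification

Response is classified per lesion on the CT longest axis, not per patient:
CR when the lesion disappeared (follow-up 0 mm), PD when the axis grew by at
least 20%, PR when it shrank by at least 30%, SD otherwise, with precedence
CR → PD → PR → SD for determinism. Overall response rate is the percentage
of CR+PR lesions; clinical benefit rate adds SD. Reported percentages use
half-up rounding (12.5% reports as 13%) to match clinical reporting
conventions; the raw fractions are always returned alongside. Bone lesions
are classified identically to other sites — measuring bone lesions with
these criteria is recognised as difficult, but no site-specific rule is
defined.

# Agreement and variability statistics

Because lesions are nested within patients, naive lesion-level correlations
conflate within- and between-patient effects. All correlations are therefore
computed on **group-mean-centered** data: each value minus its patient mean.
Centering removes one dimension per patient, so the exact null distribution
of the centered Pearson coefficient corresponds to $n - g$ effective
observations and the two-sided p-value uses a t approximation with
$n - g - 1$ degrees of freedom ($g$ = number of patients). This keeps the
test exactly calibrated under the null (verified by simulation at the
9-patient / 39-lesion structure); the common convention of quoting $n - 2$
degrees of freedom would be anti-conservative here (empirical size ≈0.09 at
this structure). Spearman's coefficient uses average ranks taken after
centering, with the same reference distribution.

Bland–Altman agreement uses the *predicted − measured* sign convention: a
positive bias means pretherapy dosimetry over-estimates the delivered dose.
The summary reports the mean difference, its sample sd, 1.96-sd limits of
agreement, and the per-lesion relative percentage differences
$100(\mathrm{measured} - \mathrm{predicted})/\mathrm{predicted}$ with their
median — both absolute and relative summaries are emitted, neither is
privileged.

Between-patient heterogeneity of the relative uptake change is tested with
the Kruskal–Wallis rank test (tie-corrected H, χ² reference with $g-1$
degrees of freedom, via `stats::kruskal.test`). At the trial's group sizes
(nine patients contributing 4–5 lesions each) the χ² reference is
conservative — its true size is about 0.03 at nominal 0.05, measured by
simulation — and it approaches nominal size once groups reach ~20
observations. This small-sample conservatism is inherent to the χ²
approximation and is documented rather than corrected, since the χ²
p-value is the field's standard report.

The intraclass correlation uses the one-way random-effects
method-of-moments estimator for unbalanced groups:
$\hat\sigma^2_w = MSW$, $\hat\sigma^2_b = (MSB - MSW)/n_0$ with
$n_0 = (N - \sum n_i^2/N)/(g-1)$, negative estimates truncated at zero, and
$ICC = \hat\sigma^2_b/(\hat\sigma^2_b + \hat\sigma^2_w)$. A
restricted-maximum-likelihood mixed model would be the fuller treatment;
the moment estimator was chosen because it is transparent, closed-form and
directly testable by parameter recovery (it recovers a simulated variance
ratio of 0.1 on 200 patients × 5 lesions within Monte-Carlo error).

# The synthetic cohort generator

`generate_cohort()` emulates the hierarchical structure of a 9-patient /
39-lesion redifferentiation trial. For patient $i$ and lesion $j$:

* volume $V_{ij} \sim \mathrm{Lognormal}(\log 2.6,\ 1.9)$ cm³ — median 2.6
  cm³, log-sd from the reported quartiles (0.7, 9.6 cm³);
* baseline 24-h ¹²³I uptake concentration
  $C_{ij} = \exp(\mu + b_i + w_{ij})$ with $b_i \sim N(0, 0.66^2)$,
  $w_{ij} \sim N(0, 2.1^2)$ and $\mu = \log 0.0042$; the total log-sd ≈2.2
  reproduces the reported four-orders-of-magnitude uptake range, the
  between-patient share (ICC ≈ 0.09) matches the reported patient-level
  intraclass correlation scale, and $\mu$ is set so the *predicted ¹³¹I*
  scale has its median near 0.2 MBq/cm³. The within/between split is not
  itself reported anywhere, so these two numbers are a modelling choice,
  fixed once;
* drug-effect multiplier
  $e_{ij} \sim \mathrm{Lognormal}(\log 16.7,\ 1.7)$ — median at the
  reported median relative change, spread covering the reported 0.7–819
  range. The effect is lesion-level; no patient-level effect component is
  modelled, so the generator's between-patient heterogeneity of *relative
  change* is null (the Kruskal–Wallis stage then exercises its null, not
  its alternative);
* biological half-life
  $T_{\mathrm{bio},ij} \sim \mathrm{Lognormal}(\log 80\ \mathrm{h},\ 0.5)$ —
  no measured value is available; a few-day retention half-life is the
  realistic scale for iodine-avid thyroid tissue, giving effective ¹³¹I
  half-lives around 2–3 days;
* the longest axis is the sphere-equivalent diameter
  $d = (6V/\pi)^{1/3}$ unless overridden (volumes and axes are not
  otherwise linked);
* activities are anchored at the 24-h concentration and propagated along
  the mono-exponential with the isotope-appropriate
  $\lambda_{\mathrm{eff}}$; the therapy series shares the lesion's
  biological clearance and rescales by the administration ratio
  (5500/370);
* each sample receives multiplicative lognormal noise with cv 10% by
  default (unit mean), the scale-proportional noise model appropriate for
  quantitative SPECT; scan times are exact by default with optional
  normal jitter.

Schedules and activities default to the trial's: 370 MBq ¹²³I with
post-drug scans at 5, 24, 30, 48, 72 h (a single 24-h scan pre-drug), and
5500 MBq ¹³¹I with scans at 24, 48, 72, 144 h. A `fixture` site mode
reproduces the exact 18 lung / 14 bone / 7 soft-tissue counts; the default
multinomial mode draws sites at those probabilities.

What the generator does **not** emulate: image formation (no
projection/reconstruction, partial-volume or breathing-motion effects —
oversized-VOI quantification is idealised as unbiased total-activity
measurement), prediction-breaking biology (stunning, saturation, drug-timing
effects — the generator's therapy kinetics satisfy the theranostic
assumption exactly), patient-level structure in the drug effect, and any
correlation between lesion volume and uptake. Passing round-trip and
recovery tests therefore demonstrates the correctness of the estimation
chain under its own assumptions, not the clinical accuracy of ¹²³I-based
prediction.

# Numerical choices and problem sizes

Tests and examples use deliberately modest problem sizes chosen to exercise
the statistics well: 1,000 lesions for decay-constant recovery (coverage of
the 3-SE interval ≥95% with known-variance weighting), 200 patients × 5
lesions for ICC recovery, 10,000 simulations for null calibration of the
correlation and Kruskal–Wallis tests, and $10^5$ draws for Monte-Carlo
uncertainty checks. Closed-form identities (two-point fits,
$\tilde A = A_0/\lambda$, inverse-mass S scaling, 3-4-5 quadrature) are
asserted to $10^{-9}$ relative. Times of $t = 0$ are represented as
$10^{-9}$ h where an exact-at-origin sample is needed, since scan times are
strictly positive by schema.

# Known limitations

* Mono-exponential kinetics only; no uptake-phase or bi-exponential
  modelling beyond the $\lambda_{\mathrm{bio}} \ge 0$ clamp. A short
  diagnostic half-life tends to over-estimate retention half-lives, and no
  correction for that is applied.
* Self-dose only; no cross-dose, photon dose, voxel dosimetry, or
  organ-at-risk (whole-body / marrow) dosimetry.
* Per-lesion response only; no per-patient RECIST sum-of-diameters, new
  lesions, or nodal rules.
* The ICC is a moment estimate, not REML; no multilevel regression,
  logistic dose–response or ROC threshold analysis is provided.
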