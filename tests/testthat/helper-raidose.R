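# Shared fixtures: small cohort configurations and a lesion-per-patient
# layout mirroring the 9-patient / 39-lesion trial structure.

trial_config <- function(seed = 1, ...) {
  cohort_config(site_mode = "fixture", seed = seed, ...)
}

noisefree_config <- function(seed = 1, ...) {
  trial_config(seed = seed, measurement_cv = 0, ...)
}

# Lesions-per-patient split of 39 across 9 patients used in calibration sims.
trial_group_sizes <- c(5, 4, 5, 4, 5, 4, 4, 4, 4)

k123 <- isotope_constants("I123")
k131 <- isotope_constants("I131")

# Draw from a bivariate normal via the Cholesky factor (for MC oracles).
rmvnorm2 <- function(n, mean, cov) {
  L <- chol(cov)
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  sweep(z %*% L, 2, mean, `+`)
}
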