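test_that("prediction with identical isotope and administration is the identity", {
  fit <- fit_tac(c(5, 24, 48), 80 * exp(-0.08 * c(5, 24, 48)), constants = k123)
  pt <- predict_therapy(fit, 370, 370, k123, k123, volume_cm3 = 2)
  expect_equal(pt$A0_pred_MBq, fit$A0_MBq, tolerance = 1e-12)
  expect_equal(pt$lambda_eff_pred_per_h, fit$lambda_eff_per_h, tolerance = 1e-12)
  expect_equal(uptake_concentration(pt$fit_pred, 24, 2),
               uptake_concentration(fit, 24, 2), tolerance = 1e-12)
})

test_that("pure-physical-decay case converts by administration ratio and half-life", {
  t <- c(1e-9, 24)
  fit <- fit_tac(t, 100 * exp(-k123$lambda_phys_per_h * t), constants = k123)
  pt <- predict_therapy(fit, 370, 5500, k123, k131, volume_cm3 = 2)
  expect_false(pt$lambda_bio_clamped)
  expect_equal(pt$A0_pred_MBq, 100 * 5500 / 370, tolerance = 1e-9)
  expect_equal(pt$lambda_eff_pred_per_h, k131$lambda_phys_per_h, tolerance = 1e-9)
  # Hand computation with the packaged half-lives (I-131 T1/2 = 8.0252 d).
  expect_equal(pt$uptake24_pred_MBq_per_cm3,
               (100 * 5500 / 370) * exp(-log(2) / (8.0252 * 24) * 24) / 2,
               tolerance = 1e-9)
})

test_that("prediction is scale-equivariant in the administered therapy activity", {
  fit <- fit_tac(c(5, 24, 48), 80 * exp(-0.06 * c(5, 24, 48)), constants = k123)
  p1 <- predict_therapy(fit, 370, 5500, k123, k131, volume_cm3 = 2)
  p3 <- predict_therapy(fit, 370, 3 * 5500, k123, k131, volume_cm3 = 2)
  expect_equal(p3$A0_pred_MBq, 3 * p1$A0_pred_MBq, tolerance = 1e-12)
  expect_equal(p3$uptake24_pred_MBq_per_cm3, 3 * p1$uptake24_pred_MBq_per_cm3,
               tolerance = 1e-12)
  expect_equal(p3$dose_pred$dose_Gy, 3 * p1$dose_pred$dose_Gy, tolerance = 1e-12)
})

test_that("predicted decay constant is never below the I-131 physical constant", {
  set.seed(17)
  for (i in 1:20) {
    lam <- runif(1, 0.001, 0.2) # some below lambda_phys(123): clamped cases
    t <- c(5, 24, 48, 72)
    fit <- fit_tac(t, 50 * exp(-lam * t), constants = k123)
    pt <- predict_therapy(fit, 370, 5500, k123, k131)
    expect_gte(pt$lambda_eff_pred_per_h, k131$lambda_phys_per_h)
    expect_equal(pt$lambda_bio_clamped, lam < k123$lambda_phys_per_h)
  }
  expect_error(predict_therapy(fit_tac(24, 1, constants = k123), 0, 5500),
               "admin123")
})

test_that("noise-free lesion round trip: predicted equals measured therapy dose", {
  cfg <- noisefree_config(seed = 21, n_patients = 3, n_lesions = 6)
  co <- generate_cohort(cfg)
  mm <- mass_model(volume_relative_sd = 0)
  series <- function(lid, phase) {
    d <- co$measurements[co$measurements$lesion_id == lid &
                           co$measurements$phase == phase, ]
    d[order(d$time_h), ]
  }
  for (lid in co$lesions$lesion_id) {
    post <- series(lid, "post_selumetinib")
    les <- co$lesions[co$lesions$lesion_id == lid, ]
    fit123 <- fit_tac(post$time_h, post$activity_MBq, constants = k123)
    pt <- predict_therapy(fit123, cfg$admin_123_MBq, cfg$admin_131_MBq,
                          k123, k131, volume_cm3 = les$volume_cm3,
                          site = les$site, massmodel = mm)
    ther <- series(lid, "therapy")
    fit131 <- fit_tac(ther$time_h, ther$activity_MBq, constants = k131)
    ca <- cumulated_activity(fit131)
    measured <- absorbed_dose(ca$A_tilde_MBq_h, les$volume_cm3, les$site, mm, k131)
    expect_equal(pt$dose_pred$dose_Gy, measured$dose_Gy, tolerance = 1e-3)
  }
})

test_that("effect metrics follow their definitions and volume cancels", {
  mk <- function(uptake, lam = 0.01, v = 1, id = "L1") {
    a0 <- uptake * v * exp(lam * 24)
    t <- c(1e-9, 24, 48)
    fit <- fit_tac(t, a0 * exp(-lam * t), constants = k131)
    predict_therapy(fit, 370, 370, k131, k131, volume_cm3 = v, lesion_id = id)
  }
  same <- effect_metrics(mk(1.5), mk(1.5))
  expect_equal(same$absolute_change, 0, tolerance = 1e-9)
  expect_equal(same$relative_change, 1, tolerance = 1e-9)
  em <- effect_metrics(mk(0.2), mk(2.1))
  expect_equal(em$absolute_change, 1.9, tolerance = 1e-9)
  expect_equal(em$relative_change, 10.5, tolerance = 1e-9)
  # Relative change is volume-invariant (same activities, different volume).
  for (v in c(0.5, 4)) {
    emv <- effect_metrics(mk(0.2 / v, v = v), mk(2.1 / v, v = v))
    expect_equal(emv$relative_change, 10.5, tolerance = 1e-9)
  }
  expect_error(effect_metrics(mk(1, id = "A"), mk(1, id = "B")), "same lesion")
})

test_that("eligibility gate requires a 30% increase in at least one lesion", {
  eff <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P3", "P4"),
    relative_change = c(1.31, 0.9, 0.8, 1.0, 1.30, 1.299)
  )
  gate <- eligibility_gate(eff)
  expect_equal(gate$eligible[gate$patient_id == "P1"], TRUE)   # one lesion suffices
  expect_equal(gate$eligible[gate$patient_id == "P2"], FALSE)  # no change
  expect_equal(gate$eligible[gate$patient_id == "P3"], TRUE)   # inclusive boundary
  expect_equal(gate$eligible[gate$patient_id == "P4"], FALSE)  # just below
  strict <- eligibility_gate(eff, threshold = 0.35)
  expect_false(any(strict$eligible[strict$patient_id %in% c("P3", "P4")]))
  expect_error(eligibility_gate(eff, threshold = 0), "threshold")
})
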