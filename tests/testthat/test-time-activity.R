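test_that("two-point fit solves the exact exponential", {
  fit <- fit_tac(c(1e-9, 24), c(100, 50), constants = k131)
  expect_equal(fit$A0_MBq, 100, tolerance = 1e-9)
  expect_equal(fit$lambda_eff_per_h, log(2) / 24, tolerance = 1e-9)
  expect_false(fit$fallback_used)
})

test_that("noise-free exponentials are reproduced to machine precision", {
  for (seed in 1:20) {
    set.seed(seed)
    a0 <- runif(1, 1, 1000)
    lam <- runif(1, 0.005, 0.2)
    n <- sample(2:6, 1)
    t <- sort(runif(n, 1, 150))
    fit <- fit_tac(t, a0 * exp(-lam * t), constants = k123)
    expect_equal(fit$A0_MBq, a0, tolerance = 1e-9)
    expect_equal(fit$lambda_eff_per_h, lam, tolerance = 1e-9)
  }
})

test_that("single-sample fallback fixes lambda to physical decay", {
  fit <- fit_tac(24, 10, constants = k131)
  expect_true(fit$fallback_used)
  expect_equal(fit$lambda_eff_per_h, k131$lambda_phys_per_h)
  expect_equal(fit$A0_MBq, 10 * exp(k131$lambda_phys_per_h * 24), tolerance = 1e-12)
})

test_that("degenerate inputs are refused or clamped", {
  expect_error(fit_tac(c(24, 48), c(0, 0), constants = k131), "zero")
  # Rising activities imply apparent accumulation: clamped to physical decay.
  expect_warning(fit <- fit_tac(c(24, 48, 72), c(10, 20, 40), constants = k131),
                 "non-physical")
  expect_true(fit$clamped)
  expect_equal(fit$lambda_eff_per_h, k131$lambda_phys_per_h)
  expect_error(fit_tac(c(48, 24), c(10, 20), constants = k131), "increasing")
})

test_that("noisy 5-point fit recovers truth and matches a nonlinear oracle", {
  skip_if_not_installed("minpack.lm")
  times <- c(5, 24, 30, 48, 72)
  a0 <- 40
  lam <- log(2) / 30
  set.seed(421)
  reps <- 50
  within3se <- logical(reps)
  for (i in seq_len(reps)) {
    act <- a0 * exp(-lam * times) * exp(rnorm(5, 0, 0.05))
    fit <- fit_tac(times, act, sd_MBq = 0.05 * act, constants = k123)
    se <- sqrt(fit$cov[2, 2])
    within3se[i] <- abs(fit$lambda_eff_per_h - lam) <= 3 * se
    # Independent oracle: variance-weighted nonlinear least squares on the
    # activities (weights matching the 5% multiplicative noise).
    nl <- minpack.lm::nlsLM(act ~ A * exp(-l * times),
                            start = list(A = max(act), l = 0.05),
                            weights = 1 / (0.05 * act)^2)
    expect_equal(fit$lambda_eff_per_h, coef(nl)[["l"]], tolerance = 0.01)
  }
  expect_gte(mean(within3se), 0.9)
})

test_that("cumulated activity is the analytic integral with its scaling laws", {
  fit <- fit_tac(c(1e-9, 24), c(100, 50), constants = k131)
  expect_equal(cumulated_activity(fit)$A_tilde_MBq_h, 2400 / log(2),
               tolerance = 1e-9)
  fit2 <- fit_tac(c(1e-9, 12), c(100, 50), constants = k131) # doubled lambda
  expect_equal(cumulated_activity(fit2)$A_tilde_MBq_h,
               cumulated_activity(fit)$A_tilde_MBq_h / 2, tolerance = 1e-9)
  bad <- structure(list(A0_MBq = 1, lambda_eff_per_h = 0,
                        cov = matrix(0, 2, 2)), class = "tac_fit")
  expect_error(cumulated_activity(bad), "diverges")
})

test_that("delta-method cumulated-activity sd matches Monte-Carlo propagation", {
  lam <- log(2) / 40
  cov <- matrix(c(0.03^2, 0.3 * 0.03 * 0.15 * lam,
                  0.3 * 0.03 * 0.15 * lam, (0.15 * lam)^2), 2, 2)
  fit <- structure(list(A0_MBq = 50, lambda_eff_per_h = lam, cov = cov,
                        n_points = 5, fallback_used = FALSE, clamped = FALSE,
                        isotope = "I131"), class = "tac_fit")
  ca <- cumulated_activity(fit)
  # Monte-Carlo oracle: joint normal on the log scale (the decay constant is
  # positive, so its uncertainty is modelled as lognormal with matched
  # relative covariance).
  set.seed(99)
  covl <- cov
  covl[2, 2] <- cov[2, 2] / lam^2
  covl[1, 2] <- covl[2, 1] <- cov[1, 2] / lam
  draws <- rmvnorm2(1e5, c(log(50), 0), covl)
  mc <- exp(draws[, 1]) / (lam * exp(draws[, 2]))
  expect_equal(ca$sd_MBq_h, sd(mc), tolerance = 0.05)
  expect_equal(ca$A_tilde_MBq_h, 50 / lam)
})

test_that("uptake concentration follows the fitted curve", {
  fit <- fit_tac(c(1e-9, 24), c(10, 5), constants = k131)
  expect_equal(uptake_concentration(fit, 24, 2), 2.5, tolerance = 1e-12)
  expect_equal(uptake_concentration(fit, 0, 2), fit$A0_MBq / 2, tolerance = 1e-12)
  # Round trip: concentration at 24 h times volume and decay recovers A0.
  v <- 3.7
  expect_equal(uptake_concentration(fit, 24, v) * v *
                 exp(fit$lambda_eff_per_h * 24),
               fit$A0_MBq, tolerance = 1e-12)
  expect_error(uptake_concentration(fit, 24, 0), "volume")
})

test_that("table-level fitting reproduces per-series fits", {
  co <- generate_cohort(noisefree_config(seed = 8))
  fits <- fit_tac_table(co$measurements)
  expect_true(all(fits$phase %in% c("pre_selumetinib", "post_selumetinib", "therapy")))
  expect_equal(nrow(fits), 3 * nrow(co$lesions))
  one <- co$measurements[co$measurements$lesion_id == "L001" &
                           co$measurements$phase == "therapy", ]
  direct <- fit_tac(one$time_h, one$activity_MBq, constants = k131)
  row <- fits[fits$lesion_id == "L001" & fits$phase == "therapy", ]
  expect_equal(row$lambda_eff_per_h, direct$lambda_eff_per_h)
  expect_equal(row$A0_MBq, direct$A0_MBq)
  # Noise-free fits recover the simulation truth.
  truth <- log(2) / co$lesions$true_biological_halflife_h + k131$lambda_phys_per_h
  ther <- fits[fits$phase == "therapy", ]
  expect_equal(ther$lambda_eff_per_h[match(co$lesions$lesion_id, ther$lesion_id)],
               truth, tolerance = 1e-8)
})
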