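test_that("group-mean centering removes patient offsets and is idempotent", {
  expect_equal(group_mean_center(c(1, 3), c("a", "a")), c(-1, 1))
  expect_equal(group_mean_center(5, "a"), 0) # single-lesion patient
  set.seed(41)
  v <- rnorm(30)
  g <- sample(letters[1:6], 30, replace = TRUE)
  c1 <- group_mean_center(v, g)
  expect_equal(group_mean_center(c1, g), c1)
  expect_true(all(abs(tapply(c1, g, mean)) < 1e-12))
})

test_that("centered correlation ignores patient-specific offsets", {
  set.seed(5)
  g <- rep(1:5, each = 4)
  x <- rnorm(20)
  offs <- c(-50, 10, 0, 100, 7)[g]
  y <- 2 * x + offs
  cc <- centered_correlation(x, y, g)
  expect_equal(cc$estimate, 1, tolerance = 1e-12)
  # Invariance: adding any patient-level constant to x changes nothing.
  x2 <- x + c(3, -8, 0.5, 12, -1)[g]
  y2 <- rnorm(20) + x
  expect_equal(centered_correlation(x2, y2, g)$estimate,
               centered_correlation(x, y2, g)$estimate, tolerance = 1e-12)
})

test_that("centered correlation matches a brute-force covariance-ratio oracle", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0, 0.7)
  y <- c(0.9, 2.1, 3.3, 4.8, 4.2, 1.1)
  g <- c("a", "a", "a", "b", "b", "b")
  cc <- centered_correlation(x, y, g)
  # Brute force: center within groups, then the covariance ratio directly.
  cx <- c(x[1:3] - mean(x[1:3]), x[4:6] - mean(x[4:6]))
  cy <- c(y[1:3] - mean(y[1:3]), y[4:6] - mean(y[4:6]))
  r_brute <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  expect_equal(cc$estimate, r_brute, tolerance = 1e-12)
  expect_equal(cc$df, 6 - 2 - 1)
  # Spearman agrees with rank-then-Pearson.
  sp <- centered_correlation(x, y, g, method = "spearman")
  expect_equal(sp$estimate, cor(rank(cx), rank(cy)), tolerance = 1e-12)
  # Degenerate: constant within patients has zero centered variance.
  cc0 <- centered_correlation(c(1, 1, 1, 2, 2, 2), y, g)
  expect_true(is.na(cc0$estimate))
})

test_that("Bland-Altman summaries follow the predicted-minus-measured convention", {
  eq <- bland_altman(c(3, 7, 9), c(3, 7, 9))
  expect_equal(eq$bias, 0)
  expect_equal(eq$sd_diff, 0)
  off <- bland_altman(c(10, 20), c(5, 15))
  expect_equal(off$bias, 5)
  expect_equal(off$sd_diff, 0)
  expect_equal(off$loa_lower, 5)
  expect_equal(off$loa_upper, 5)
  set.seed(61)
  p <- rlnorm(40, 2, 1)
  m <- rlnorm(40, 2, 1)
  ba <- bland_altman(p, m)
  expect_equal(ba$bias, mean(p) - mean(m), tolerance = 1e-12)
  expect_equal(ba$loa_upper - ba$bias, ba$bias - ba$loa_lower, tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "two pairs")
})

test_that("a multiplicative prediction bias is recovered in the relative difference", {
  set.seed(71)
  b <- 0.67 # measured = b * predicted on average
  pred <- rlnorm(4000, 3, 1.2)
  meas <- b * pred * exp(rnorm(4000, 0, 0.1) - 0.005)
  ba <- bland_altman(pred, meas)
  # mean relative difference = 100*(b - 1) within simulation error
  expect_equal(mean(ba$relative_diff_percent), 100 * (b - 1), tolerance = 0.02)
})

test_that("Kruskal-Wallis statistic matches the brute-force rank computation", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # Brute force: H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), no ties.
  r <- rank(c(1, 2, 3, 4, 5, 6))
  h_brute <- 12 / (6 * 7) * (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) - 3 * 7
  expect_equal(kw$H, h_brute, tolerance = 1e-12)
  expect_equal(h_brute, 3.857142857, tolerance = 1e-9)
  # df bookkeeping with 9 groups; widely separated groups reject clearly.
  set.seed(3)
  v <- rnorm(39)
  g <- rep(1:9, times = trial_group_sizes)
  v[g <= 3] <- v[g <= 3] + 100 * g[g <= 3]
  kw9 <- kruskal_wallis(v, g)
  expect_equal(kw9$df, 8L)
  expect_lt(kw9$p_value, 0.05)
  # All values identical: H defined as 0.
  expect_equal(kruskal_wallis(rep(2, 10), rep(1:2, 5))$H, 0)
})

test_that("ICC estimator handles the degenerate extremes", {
  set.seed(9)
  # No between-patient spread: truncated to exactly 0 when MSB <= MSW.
  v <- rnorm(60, 0, 3)
  g <- rep(1:6, each = 10)
  many <- replicate(30, icc_patients(rnorm(60, 0, 3), g)$icc)
  expect_true(any(many == 0)) # truncation occurs
  expect_lt(mean(many), 0.05)
  # Distinct constants per patient, zero within-variance: ICC = 1.
  v1 <- rep(c(1, 5, 9), each = 4)
  expect_equal(icc_patients(v1, rep(1:3, each = 4))$icc, 1)
  expect_error(icc_patients(c(1, 2), c(1, 1)), "two patients")
})

test_that("ICC recovers the simulated variance ratio", {
  set.seed(123)
  g <- rep(1:200, each = 5)
  v <- rnorm(200, 0, 1)[g] + rnorm(1000, 0, 3)
  est <- icc_patients(v, g)
  expect_equal(est$icc, 0.1, tolerance = 0.25)
  expect_equal(est$sigma2_within, 9, tolerance = 0.1)
})

test_that("noise-free theranostic pairs give perfect centered agreement", {
  df <- data.frame(lesion_id = sprintf("L%d", 1:6),
                   patient_id = rep(c("P1", "P2"), each = 3),
                   dose_Gy = c(2, 30, 400, 0.5, 12, 80))
  pairs <- theranostic_pairs(df, df)
  expect_equal(pairs$measured_Gy, pairs$predicted_Gy)
  expect_equal(pairs$relative_diff_percent, rep(0, 6))
  cc <- centered_correlation(pairs$predicted_Gy, pairs$measured_Gy,
                             pairs$patient_id)
  expect_equal(cc$estimate, 1, tolerance = 1e-12)
  expect_equal(bland_altman(pairs$predicted_Gy, pairs$measured_Gy)$bias, 0)
})
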