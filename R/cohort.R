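# Synthetic cohort generator: hierarchical lognormal uptake model.
#
# Each patient carries a normal random effect on the log 24-h uptake
# concentration; lesions add an independent within-patient deviation, a
# lognormal drug-effect multiplier and a lognormal biological half-life.
# Activities at the scan times follow the mono-exponential
# A(t) = A0 * exp(-lambda_eff * t) with lambda_eff = lambda_bio + lambda_phys,
# anchored at the 24-h reference concentration, with multiplicative lognormal
# measurement noise of fixed coefficient of variation per sample.

.SITES <- c("lung", "bone", "soft_tissue")

#' Configuration for the synthetic lesion cohort
#'
#' Defaults emulate the structure of a 9-patient / 39-lesion radioiodine
#' redifferentiation cohort: site mix 18 lung / 14 bone / 7 soft tissue,
#' lesion volumes lognormal around a 2.6 cm^3 median, a heavily right-skewed
#' drug-effect multiplier (median ~16.7), 370 MBq of diagnostic I-123 with
#' scans at 5, 24, 30, 48 and 72 h, and 5500 MBq of therapeutic I-131 with
#' scans at 24, 48, 72 and 144 h. The single pre-drug I-123 scan is at 24 h.
#'
#' @param n_patients Number of patients.
#' @param n_lesions Total number of lesions across the cohort.
#' @param site_probabilities Named probability vector over
#'   `c("lung", "bone", "soft_tissue")`; must sum to 1.
#' @param site_mode `"multinomial"` draws lesion sites at random with these
#'   probabilities; `"fixture"` assigns exactly
#'   `round(n_lesions * site_probabilities)` lesions per site (the trial-like
#'   fixed structure).
#' @param volume_lognormal `c(meanlog, sdlog)` of lesion volume in cm^3.
#' @param baseline_uptake_lognormal `c(meanlog, sd_between, sd_within)` of the
#'   24-h I-123 uptake concentration in MBq/cm^3: log-scale mean, and the
#'   between-patient and within-patient standard deviations.
#' @param effect_lognormal `c(meanlog, sdlog)` of the lesion-level drug-effect
#'   multiplier applied to the baseline uptake concentration.
#' @param biological_halflife_lognormal `c(meanlog, sdlog)` of the biological
#'   retention half-life in hours.
#' @param measurement_cv Fractional multiplicative noise per scan sample
#'   (coefficient of variation; 0 gives noise-free series).
#' @param schedule_123_pre,schedule_123,schedule_131 Scan times in hours post
#'   administration for the pre-drug I-123, post-drug I-123 and therapy I-131
#'   series.
#' @param admin_123_MBq,admin_131_MBq Administered activities in MBq.
#' @param time_jitter_sd_h Standard deviation (hours) of optional normal
#'   jitter on scan times; 0 (default) keeps the nominal schedule.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `cohort_config` (a validated list).
#'
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$lesions$site)
#' @export
cohort_config <- function(n_patients = 9,
                          n_lesions = 39,
                          site_probabilities = c(lung = 18, bone = 14, soft_tissue = 7) / 39,
                          site_mode = c("multinomial", "fixture"),
                          volume_lognormal = c(meanlog = log(2.6), sdlog = 1.9),
                          baseline_uptake_lognormal = c(meanlog = log(0.0042),
                                                        sd_between = 0.66,
                                                        sd_within = 2.1),
                          effect_lognormal = c(meanlog = log(16.7), sdlog = 1.7),
                          biological_halflife_lognormal = c(meanlog = log(80), sdlog = 0.5),
                          measurement_cv = 0.10,
                          schedule_123_pre = 24,
                          schedule_123 = c(5, 24, 30, 48, 72),
                          schedule_131 = c(24, 48, 72, 144),
                          admin_123_MBq = 370,
                          admin_131_MBq = 5500,
                          time_jitter_sd_h = 0,
                          seed = 1L) {
  site_mode <- match.arg(site_mode)
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      n_lesions = as.integer(n_lesions),
      site_probabilities = site_probabilities,
      site_mode = site_mode,
      volume_lognormal = unname(volume_lognormal),
      baseline_uptake_lognormal = unname(baseline_uptake_lognormal),
      effect_lognormal = unname(effect_lognormal),
      biological_halflife_lognormal = unname(biological_halflife_lognormal),
      measurement_cv = measurement_cv,
      schedule_123_pre = schedule_123_pre,
      schedule_123 = schedule_123,
      schedule_131 = schedule_131,
      admin_123_MBq = admin_123_MBq,
      admin_131_MBq = admin_131_MBq,
      time_jitter_sd_h = time_jitter_sd_h,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of a [cohort_config()] and stops with an
#' error naming the offending field on the first violation.
#'
#' @param config A `cohort_config` object or equivalent list.
#' @return The config, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, msg), call. = FALSE)
  }
  pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!pos_scalar(config$n_patients)) fail("n_patients", "must be a positive integer")
  if (!pos_scalar(config$n_lesions)) fail("n_lesions", "must be a positive integer")
  if (config$n_lesions < config$n_patients) {
    fail("n_lesions", "must be at least n_patients (every patient has a lesion)")
  }
  p <- config$site_probabilities
  if (length(p) != 3L || is.null(names(p)) || !setequal(names(p), .SITES)) {
    fail("site_probabilities", "must be named over lung, bone, soft_tissue")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    fail("site_probabilities", "must be non-negative and sum to 1 (within 1e-12)")
  }
  if (length(config$volume_lognormal) != 2L || config$volume_lognormal[2] < 0) {
    fail("volume_lognormal", "must be c(meanlog, sdlog >= 0)")
  }
  b <- config$baseline_uptake_lognormal
  if (length(b) != 3L || any(b[2:3] < 0)) {
    fail("baseline_uptake_lognormal", "must be c(meanlog, sd_between >= 0, sd_within >= 0)")
  }
  if (length(config$effect_lognormal) != 2L || config$effect_lognormal[2] < 0) {
    fail("effect_lognormal", "must be c(meanlog, sdlog >= 0)")
  }
  h <- config$biological_halflife_lognormal
  if (length(h) != 2L || h[2] < 0) {
    fail("biological_halflife_lognormal", "must be c(meanlog, sdlog >= 0)")
  }
  if (!is.numeric(config$measurement_cv) || config$measurement_cv < 0) {
    fail("measurement_cv", "must be >= 0")
  }
  for (field in c("schedule_123_pre", "schedule_123", "schedule_131")) {
    s <- config[[field]]
    if (length(s) < 1L || any(s <= 0) || any(diff(s) <= 0)) {
      fail(field, "must be strictly increasing positive times")
    }
  }
  if (!pos_scalar(config$admin_123_MBq)) fail("admin_123_MBq", "must be > 0")
  if (!pos_scalar(config$admin_131_MBq)) fail("admin_131_MBq", "must be > 0")
  if (!is.numeric(config$time_jitter_sd_h) || config$time_jitter_sd_h < 0) {
    fail("time_jitter_sd_h", "must be >= 0")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L || !is.finite(config$seed)) {
    fail("seed", "must be a single integer")
  }
  invisible(config)
}

# Evaluate code under a seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Sphere-equivalent diameter in mm of a volume in cm^3.
sphere_diameter_mm <- function(volume_cm3) 10 * (6 * volume_cm3 / pi)^(1 / 3)

#' Generate a synthetic patient/lesion cohort with serial activity series
#'
#' Draws a hierarchical cohort under [cohort_config()] and simulates, for each
#' lesion, three serial activity series: a pre-drug I-123 series, a post-drug
#' I-123 series (baseline concentration times the lesion's effect multiplier)
#' and a post-therapy I-131 series sharing the same biological clearance but
#' decaying with the I-131 physical half-life and scaled by the ratio of
#' administered activities. The simulation truth (baseline concentration,
#' effect multiplier, biological half-life) is retained in the lesion table
#' for recovery tests.
#'
#' @param config A validated [cohort_config()].
#' @return An object of class `rai_cohort`: a list of three data frames,
#'   `patients` (`patient_id`, `log_uptake_shift`), `lesions` (`lesion_id`,
#'   `patient_id`, `site`, `volume_cm3`, `longest_axis_mm`, `sub_threshold`,
#'   plus `true_*` simulation-truth columns) and `measurements`
#'   (`patient_id`, `lesion_id`, `phase`, `isotope`, `time_h`, `activity_MBq`,
#'   `activity_sd_MBq`), together with the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_local_seed(config$seed, {
    n_pat <- config$n_patients
    n_les <- config$n_lesions
    patient_id <- sprintf("P%02d", seq_len(n_pat))

    # Lesion allocation: one lesion per patient guaranteed, remainder multinomial.
    extra <- as.vector(stats::rmultinom(1, n_les - n_pat, rep(1 / n_pat, n_pat)))
    lesions_per_patient <- 1L + extra

    p <- config$site_probabilities[.SITES]
    if (config$site_mode == "fixture") {
      counts <- round(n_les * p)
      counts[which.max(counts)] <- counts[which.max(counts)] + (n_les - sum(counts))
      site <- sample(rep(.SITES, times = counts))
    } else {
      site <- sample(.SITES, n_les, replace = TRUE, prob = p)
    }

    vol <- stats::rlnorm(n_les, config$volume_lognormal[1], config$volume_lognormal[2])
    b <- config$baseline_uptake_lognormal
    patient_shift <- stats::rnorm(n_pat, 0, b[2])
    lesion_patient <- rep(seq_len(n_pat), times = lesions_per_patient)
    c24_pre <- exp(b[1] + patient_shift[lesion_patient] + stats::rnorm(n_les, 0, b[3]))
    effect <- stats::rlnorm(n_les, config$effect_lognormal[1], config$effect_lognormal[2])
    tbio <- stats::rlnorm(n_les, config$biological_halflife_lognormal[1],
                          config$biological_halflife_lognormal[2])
    lambda_bio <- log(2) / tbio

    lesions <- data.frame(
      lesion_id = sprintf("L%03d", seq_len(n_les)),
      patient_id = patient_id[lesion_patient],
      site = site,
      volume_cm3 = vol,
      longest_axis_mm = sphere_diameter_mm(vol),
      stringsAsFactors = FALSE
    )
    lesions$sub_threshold <- lesions$longest_axis_mm < 10
    lesions$true_c24_pre_MBq_per_cm3 <- c24_pre
    lesions$true_effect <- effect
    lesions$true_biological_halflife_h <- tbio

    k123 <- isotope_constants("I123")
    k131 <- isotope_constants("I131")
    lam123 <- lambda_bio + k123$lambda_phys_per_h
    lam131 <- lambda_bio + k131$lambda_phys_per_h
    # Anchor at the 24-h reference concentration, then propagate along the curve.
    a0_pre <- c24_pre * vol * exp(lam123 * 24)
    a0_post <- a0_pre * effect
    # Same biology at therapy: A0 rescales with the administered activity only.
    a0_ther <- a0_post * (config$admin_131_MBq / config$admin_123_MBq)

    phases <- list(
      list(phase = "pre_selumetinib", isotope = "I123",
           times = config$schedule_123_pre, a0 = a0_pre, lam = lam123),
      list(phase = "post_selumetinib", isotope = "I123",
           times = config$schedule_123, a0 = a0_post, lam = lam123),
      list(phase = "therapy", isotope = "I131",
           times = config$schedule_131, a0 = a0_ther, lam = lam131)
    )

    cv <- config$measurement_cv
    sdlog_noise <- sqrt(log(1 + cv^2))
    meas <- lapply(phases, function(ph) {
      nt <- length(ph$times)
      t_h <- rep(ph$times, times = n_les)
      if (config$time_jitter_sd_h > 0) {
        t_h <- pmax(t_h + stats::rnorm(n_les * nt, 0, config$time_jitter_sd_h), 0.1)
      }
      idx <- rep(seq_len(n_les), each = nt)
      true_a <- ph$a0[idx] * exp(-ph$lam[idx] * t_h)
      noise <- if (cv > 0) {
        exp(stats::rnorm(n_les * nt, -sdlog_noise^2 / 2, sdlog_noise))
      } else {
        1
      }
      act <- true_a * noise
      data.frame(
        patient_id = lesions$patient_id[idx],
        lesion_id = lesions$lesion_id[idx],
        phase = ph$phase,
        isotope = ph$isotope,
        time_h = t_h,
        activity_MBq = act,
        activity_sd_MBq = cv * act,
        stringsAsFactors = FALSE
      )
    })
    measurements <- do.call(rbind, meas)
    ord <- order(measurements$lesion_id, measurements$phase, measurements$time_h)
    measurements <- measurements[ord, , drop = FALSE]
    rownames(measurements) <- NULL

    structure(
      list(
        patients = data.frame(patient_id = patient_id,
                              log_uptake_shift = patient_shift,
                              stringsAsFactors = FALSE),
        lesions = lesions,
        measurements = measurements,
        config = config
      ),
      class = "rai_cohort"
    )
  })
}

#' @export
print.rai_cohort <- function(x, ...) {
  cat(sprintf(
    "<rai_cohort> %d patients, %d lesions (%s), %d measurements\n",
    nrow(x$patients), nrow(x$lesions),
    paste(sprintf("%s=%d", names(table(x$lesions$site)), table(x$lesions$site)),
          collapse = ", "),
    nrow(x$measurements)
  ))
  invisible(x)
}

#' Exclude lesions below the measurability threshold
#'
#' Removes lesions whose longest axis is smaller than `threshold_mm`
#' (strictly: a lesion of exactly the threshold size is retained), mirroring
#' the eligibility rule that lesions under 10 mm cannot be reliably measured
#' on CT.
#'
#' @param lesions Lesion table with a `longest_axis_mm` column.
#' @param threshold_mm Minimum measurable longest axis in mm (default 10).
#' @param quiet Suppress the message reporting how many lesions were excluded.
#' @return The filtered lesion table; the number of excluded lesions is
#'   attached as attribute `n_excluded`.
#' @examples
#' les <- data.frame(lesion_id = c("a", "b"), longest_axis_mm = c(9.9, 10))
#' apply_size_filter(les)$lesion_id
#' @export
apply_size_filter <- function(lesions, threshold_mm = 10, quiet = FALSE) {
  stopifnot(is.data.frame(lesions), "longest_axis_mm" %in% names(lesions))
  keep <- lesions$longest_axis_mm >= threshold_mm
  n_excluded <- sum(!keep)
  if (!quiet && n_excluded > 0) {
    message(sprintf("size filter: excluded %d lesion(s) with longest axis < %g mm",
                    n_excluded, threshold_mm))
  }
  out <- lesions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a cohort to CSV tables
#'
#' Writes `patients.csv`, `lesions.csv` and `measurements.csv` to `dir`.
#'
#' @param cohort An `rai_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rai_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(cohort$lesions, file.path(dir, "lesions.csv"), row.names = FALSE)
  utils::write.csv(cohort$measurements, file.path(dir, "measurements.csv"), row.names = FALSE)
  invisible(dir)
}
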