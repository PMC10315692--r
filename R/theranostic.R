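# Theranostic conversion: diagnostic I-123 kinetics -> predicted therapeutic
# I-131 uptake and absorbed dose.
#
# The biological clearance estimated from the diagnostic study is assumed
# unchanged at therapy; only the physical decay constant and the administered
# activity change. The amplitude scales with the ratio of administered
# activities and the decay constant swaps the physical component:
#   lambda_bio  = max(0, lambda_eff(123) - lambda_phys(123))
#   lambda_pred = lambda_bio + lambda_phys(131)
#   A0_pred     = A0(123) * admin131 / admin123

#' Predict therapeutic I-131 kinetics from a diagnostic I-123 fit
#'
#' Converts a fitted I-123 time-activity curve into the predicted I-131
#' therapy curve, accounting for the differences in physical half-life and
#' administered activity, then derives the predicted 24-h uptake
#' concentration and the predicted absorbed dose. A negative implied
#' biological decay constant (slower-than-physical apparent clearance) is
#' clamped to zero and flagged.
#'
#' @param fit123 A `tac_fit` of a diagnostic I-123 series.
#' @param admin123_MBq,admin131_MBq Administered activities in MBq (> 0).
#' @param constants123,constants131 [isotope_constants()] for the two
#'   isotopes.
#' @param volume_cm3 Lesion volume in cm^3 (needed for uptake concentration
#'   and dose; may be `NULL` to skip both).
#' @param site Lesion site for the mass model.
#' @param massmodel A [mass_model()].
#' @param reference_time_h Reference time for the predicted uptake
#'   concentration (default 24 h).
#' @param lesion_id Optional identifier carried through.
#'
#' @return An object of class `predicted_therapy`: `lesion_id`,
#'   `A0_pred_MBq`, `lambda_eff_pred_per_h`, `lambda_bio_clamped`,
#'   `fit_pred` (a `tac_fit` for the predicted curve, covariance carried over
#'   from the diagnostic fit), and — when `volume_cm3` is given —
#'   `uptake24_pred_MBq_per_cm3` and `dose_pred` (a `dose_estimate`).
#'
#' @examples
#' k123 <- isotope_constants("I123")
#' k131 <- isotope_constants("I131")
#' fit <- fit_tac(c(5, 24, 48), 50 * exp(-0.06 * c(5, 24, 48)), constants = k123)
#' predict_therapy(fit, 370, 5500, k123, k131, volume_cm3 = 2)
#' @export
predict_therapy <- function(fit123, admin123_MBq, admin131_MBq,
                            constants123 = isotope_constants("I123"),
                            constants131 = isotope_constants("I131"),
                            volume_cm3 = NULL, site = "soft_tissue",
                            massmodel = mass_model(),
                            reference_time_h = 24,
                            lesion_id = fit123$lesion_id %||% NA_character_) {
  stopifnot(inherits(fit123, "tac_fit"))
  if (!is.numeric(admin123_MBq) || admin123_MBq <= 0) {
    stop("admin123_MBq must be > 0", call. = FALSE)
  }
  if (!is.numeric(admin131_MBq) || admin131_MBq <= 0) {
    stop("admin131_MBq must be > 0", call. = FALSE)
  }
  lambda_bio_raw <- fit123$lambda_eff_per_h - constants123$lambda_phys_per_h
  # Flag only genuinely negative biological clearance, not rounding noise.
  clamped <- lambda_bio_raw < -1e-9
  lambda_bio <- max(0, lambda_bio_raw)
  lambda_pred <- lambda_bio + constants131$lambda_phys_per_h
  a0_pred <- fit123$A0_MBq * admin131_MBq / admin123_MBq

  # ln A0 shifts by a constant and lambda by a constant (or is clamped), so
  # the diagnostic covariance carries over; the clamp zeroes the lambda terms.
  cov <- fit123$cov
  if (clamped) cov[2, ] <- cov[, 2] <- 0
  fit_pred <- structure(
    list(
      A0_MBq = a0_pred,
      lambda_eff_per_h = lambda_pred,
      T_eff_h = log(2) / lambda_pred,
      cov = cov,
      n_points = fit123$n_points,
      fallback_used = fit123$fallback_used,
      clamped = fit123$clamped || clamped,
      isotope = constants131$isotope
    ),
    class = "tac_fit"
  )

  out <- list(
    lesion_id = lesion_id,
    A0_pred_MBq = a0_pred,
    lambda_eff_pred_per_h = lambda_pred,
    lambda_bio_per_h = lambda_bio,
    lambda_bio_clamped = clamped,
    fit_pred = fit_pred
  )
  if (!is.null(volume_cm3)) {
    out$uptake24_pred_MBq_per_cm3 <-
      uptake_concentration(fit_pred, reference_time_h, volume_cm3)
    ca <- cumulated_activity(fit_pred)
    out$dose_pred <- absorbed_dose(ca$A_tilde_MBq_h, volume_cm3, site,
                                   massmodel, constants131,
                                   A_tilde_sd_MBq_h = ca$sd_MBq_h,
                                   lesion_id = lesion_id)
  }
  structure(out, class = "predicted_therapy")
}

#' @export
print.predicted_therapy <- function(x, ...) {
  cat(sprintf(
    "<predicted_therapy> %s: A0_pred = %.4g MBq, lambda_eff_pred = %.5g /h%s\n",
    ifelse(is.na(x$lesion_id), "", x$lesion_id),
    x$A0_pred_MBq, x$lambda_eff_pred_per_h,
    if (!is.null(x$dose_pred)) sprintf(", D_pred = %.4g Gy", x$dose_pred$dose_Gy) else ""
  ))
  invisible(x)
}

#' Drug-effect metrics on predicted therapy uptake
#'
#' Absolute change (post minus pre) and relative change (post divided by pre)
#' of the predicted 24-h I-131 uptake concentration, before and after the
#' uptake-modulating drug.
#'
#' @param pred_pre,pred_post `predicted_therapy` objects for the same lesion,
#'   from the pre-drug and post-drug diagnostic series.
#' @return A list: `lesion_id`, `uptake_pre`, `uptake_post`,
#'   `absolute_change` (MBq/cm^3) and `relative_change` (dimensionless;
#'   `NA` when the pre-drug uptake is zero).
#' @export
effect_metrics <- function(pred_pre, pred_post) {
  stopifnot(inherits(pred_pre, "predicted_therapy"),
            inherits(pred_post, "predicted_therapy"))
  if (!identical(pred_pre$lesion_id, pred_post$lesion_id)) {
    stop("effect metrics require predictions for the same lesion", call. = FALSE)
  }
  up_pre <- pred_pre$uptake24_pred_MBq_per_cm3
  up_post <- pred_post$uptake24_pred_MBq_per_cm3
  if (is.null(up_pre) || is.null(up_post)) {
    stop("predictions must carry uptake concentrations (supply volume_cm3)", call. = FALSE)
  }
  list(
    lesion_id = pred_pre$lesion_id,
    uptake_pre = up_pre,
    uptake_post = up_post,
    absolute_change = up_post - up_pre,
    relative_change = if (up_pre > 0) up_post / up_pre else NA_real_
  )
}

#' Patient eligibility gate on uptake increase
#'
#' A patient proceeds to therapy when the predicted uptake increased by at
#' least `threshold` (default 30%) in at least one lesion: eligible iff
#' `max(relative_change) - 1 >= threshold`. The boundary is inclusive.
#'
#' @param effects Data frame with columns `patient_id` and `relative_change`
#'   (one row per lesion; `NA` relative changes are ignored).
#' @param threshold Fractional increase required (default 0.30).
#' @return Data frame: `patient_id`, `max_relative_change`, `eligible`.
#' @examples
#' eff <- data.frame(patient_id = c("P1", "P1", "P2"),
#'                   relative_change = c(1.31, 0.9, 1.0))
#' eligibility_gate(eff)
#' @export
eligibility_gate <- function(effects, threshold = 0.30) {
  stopifnot(is.data.frame(effects),
            all(c("patient_id", "relative_change") %in% names(effects)))
  if (threshold <= 0 || threshold >= 10) {
    stop("threshold must lie in (0, 10)", call. = FALSE)
  }
  mx <- tapply(effects$relative_change, effects$patient_id,
               function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  out <- data.frame(
    patient_id = names(mx),
    max_relative_change = as.numeric(mx),
    stringsAsFactors = FALSE
  )
  out$eligible <- !is.na(out$max_relative_change) &
    (out$max_relative_change - 1) >= threshold
  rownames(out) <- NULL
  out
}
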