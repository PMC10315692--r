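# MIRD self-dose dosimetry for small lesions.
#
# Absorbed dose D = A_tilde * S(m), with the non-penetrating self-dose
# S value scaled inversely with lesion mass: S(m) = Delta_np / m. Photon
# self-dose and cross-dose are neglected, as is standard for small-volume
# lesion dosimetry where locally deposited electron energy dominates.

#' Lesion mass model
#'
#' Maps lesion volume to mass (`m = rho * V`) with a per-site density and a
#' fractional volume uncertainty used in dose uncertainty propagation.
#'
#' @param density_g_per_cm3 Named densities by site; default 1.0 g/cm^3 for
#'   all sites (no site-specific densities are assumed, including bone).
#' @param volume_relative_sd Fractional standard uncertainty of lesion volume
#'   (default 0.10, reflecting outlining uncertainty for small lesions).
#' @return An object of class `mass_model`.
#' @export
mass_model <- function(density_g_per_cm3 = c(lung = 1, bone = 1, soft_tissue = 1),
                       volume_relative_sd = 0.10) {
  if (any(density_g_per_cm3 <= 0)) stop("densities must be > 0", call. = FALSE)
  if (volume_relative_sd < 0) stop("volume_relative_sd must be >= 0", call. = FALSE)
  structure(
    list(density_g_per_cm3 = density_g_per_cm3,
         volume_relative_sd = volume_relative_sd),
    class = "mass_model"
  )
}

site_density <- function(massmodel, site) {
  d <- massmodel$density_g_per_cm3
  out <- unname(d[site])
  if (any(is.na(out))) out[is.na(out)] <- 1
  out
}

#' Mass-adjusted self-dose S value
#'
#' `S(m) = Delta_np / m` in Gy/(MBq·h): the non-penetrating self-dose S value
#' scales inversely with the target mass, equivalently
#' `S(m) = S(m_ref) * m_ref / m`.
#'
#' @param mass_g Lesion mass in grams (> 0).
#' @param constants [isotope_constants()] providing `Delta_np`.
#' @return S value(s) in Gy/(MBq·h).
#' @examples
#' k <- isotope_constants("I131")
#' mass_adjusted_s_value(1, k)   # the reference Delta_np
#' mass_adjusted_s_value(2, k)   # exactly half
#' @export
mass_adjusted_s_value <- function(mass_g, constants) {
  stopifnot(inherits(constants, "isotope_constants"))
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("mass_g must be > 0", call. = FALSE)
  }
  constants$delta_np_Gy_g_per_MBq_h / mass_g
}

#' Lesion self-dose absorbed dose
#'
#' MIRD absorbed dose `D = A_tilde * S(rho * V)` with standard uncertainty
#' combining the cumulated-activity and mass uncertainties in quadrature (see
#' [propagate_dose_uncertainty()]).
#'
#' @param A_tilde_MBq_h Cumulated activity in MBq·h (>= 0).
#' @param volume_cm3 Lesion volume in cm^3 (> 0).
#' @param site Lesion site (used for density lookup).
#' @param massmodel A [mass_model()].
#' @param constants [isotope_constants()].
#' @param A_tilde_sd_MBq_h Standard uncertainty of the cumulated activity
#'   (default 0).
#' @param lesion_id Optional identifier carried through.
#' @return An object of class `dose_estimate`: `lesion_id`, `dose_Gy`,
#'   `sd_Gy`, and `components` (the shares of the relative variance due to
#'   the kinetic fit and the volume).
#' @export
absorbed_dose <- function(A_tilde_MBq_h, volume_cm3, site = "soft_tissue",
                          massmodel = mass_model(),
                          constants,
                          A_tilde_sd_MBq_h = 0,
                          lesion_id = NA_character_) {
  stopifnot(inherits(massmodel, "mass_model"), inherits(constants, "isotope_constants"))
  if (A_tilde_MBq_h < 0) stop("A_tilde_MBq_h must be >= 0", call. = FALSE)
  if (volume_cm3 <= 0) stop("volume_cm3 must be > 0", call. = FALSE)
  mass_g <- site_density(massmodel, site) * volume_cm3
  dose <- A_tilde_MBq_h * mass_adjusted_s_value(mass_g, constants)
  rel_fit <- if (A_tilde_MBq_h > 0) (A_tilde_sd_MBq_h / A_tilde_MBq_h)^2 else
    NA_real_
  rel_vol <- massmodel$volume_relative_sd^2
  if (A_tilde_MBq_h > 0) {
    rel_var <- rel_fit + rel_vol
    sd <- dose * sqrt(rel_var)
  } else {
    # Zero dose: only the additive cumulated-activity uncertainty survives.
    rel_fit <- NA_real_
    rel_var <- NA_real_
    sd <- A_tilde_sd_MBq_h * mass_adjusted_s_value(mass_g, constants)
  }
  structure(
    list(
      lesion_id = lesion_id,
      dose_Gy = dose,
      sd_Gy = sd,
      components = c(fit = rel_fit, volume = rel_vol)
    ),
    class = "dose_estimate"
  )
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("<dose_estimate> %s: %.4g Gy (sd %.3g Gy)\n",
              ifelse(is.na(x$lesion_id), "", x$lesion_id), x$dose_Gy, x$sd_Gy))
  invisible(x)
}

#' Propagate absorbed-dose uncertainty
#'
#' Combines the relative uncertainty of the cumulated activity (from the
#' time-activity fit covariance) with the relative mass uncertainty in
#' quadrature, following standard uncertainty-propagation guidance for
#' molecular radiotherapy dosimetry:
#' `(u(D)/D)^2 = (u(A_tilde)/A_tilde)^2 + (u(m)/m)^2`.
#'
#' @param fit A `tac_fit`.
#' @param massmodel A [mass_model()].
#' @param volume_cm3 Lesion volume in cm^3.
#' @param site Lesion site.
#' @param constants [isotope_constants()] matching the fit's isotope.
#' @return A list with `sd_Gy`, `rel_sd`, and `components` (relative
#'   variances `fit` and `volume`).
#' @export
propagate_dose_uncertainty <- function(fit, massmodel, volume_cm3,
                                       site = "soft_tissue",
                                       constants = isotope_constants(fit$isotope)) {
  stopifnot(inherits(fit, "tac_fit"), inherits(massmodel, "mass_model"))
  ca <- cumulated_activity(fit)
  rel_fit <- if (ca$A_tilde_MBq_h > 0) (ca$sd_MBq_h / ca$A_tilde_MBq_h)^2 else 0
  rel_vol <- massmodel$volume_relative_sd^2
  rel_sd <- sqrt(rel_fit + rel_vol)
  mass_g <- site_density(massmodel, site) * volume_cm3
  dose <- ca$A_tilde_MBq_h * mass_adjusted_s_value(mass_g, constants)
  list(
    sd_Gy = dose * rel_sd,
    rel_sd = rel_sd,
    components = c(fit = rel_fit, volume = rel_vol)
  )
}

#' Dose a table of fitted time-activity curves
#'
#' Computes per-lesion self-dose estimates for every row of a fit table
#' (output of [fit_tac_table()]), joining lesion volumes and sites.
#'
#' @param fits Fit table.
#' @param lesions Lesion table with `lesion_id`, `volume_cm3`, `site`.
#' @param massmodel A [mass_model()].
#' @param constants_by_isotope Named list of [isotope_constants()].
#' @return Data frame: `lesion_id`, `patient_id`, `phase`, `dose_Gy`,
#'   `sd_Gy`, `var_fraction_fit`, `var_fraction_volume`.
#' @export
dose_table <- function(fits, lesions, massmodel = mass_model(),
                       constants_by_isotope = list(I123 = isotope_constants("I123"),
                                                   I131 = isotope_constants("I131"))) {
  idx <- match(fits$lesion_id, lesions$lesion_id)
  if (any(is.na(idx))) stop("fit table contains lesions missing from the lesion table",
                            call. = FALSE)
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    fit <- fit_from_row(fits[i, ])
    les <- lesions[idx[i], ]
    ca <- cumulated_activity(fit)
    de <- absorbed_dose(ca$A_tilde_MBq_h, les$volume_cm3, les$site,
                        massmodel, constants_by_isotope[[fits$isotope[i]]],
                        A_tilde_sd_MBq_h = ca$sd_MBq_h,
                        lesion_id = fits$lesion_id[i])
    tot <- sum(de$components)
    data.frame(
      lesion_id = fits$lesion_id[i],
      patient_id = fits$patient_id[i],
      phase = fits$phase[i],
      dose_Gy = de$dose_Gy,
      sd_Gy = de$sd_Gy,
      var_fraction_fit = unname(de$components["fit"] / tot),
      var_fraction_volume = unname(de$components["volume"] / tot),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
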