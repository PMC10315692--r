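# Mono-exponential time-activity curve fitting and cumulated activity.
#
# The working model is A(t) = A0 * exp(-lambda_eff * t) with
# lambda_eff = lambda_phys + lambda_bio, fitted as a weighted linear
# regression of ln(activity) on time. When per-sample standard deviations are
# supplied the log-scale variances are treated as known and the parameter
# covariance is (X'WX)^-1; otherwise the usual residual-based covariance is
# used.

#' Fit a mono-exponential time-activity curve
#'
#' Fits `ln A = ln A0 - lambda_eff * t` by (weighted) least squares. With a
#' single sample the biological clearance cannot be estimated, so
#' `lambda_eff` falls back to the isotope's physical decay constant
#' (`lambda_bio = 0`) and `A0` is back-extrapolated. A fitted decay constant
#' of zero or below (apparent accumulation) is non-physical for a washout
#' integral; it is clamped to the physical decay constant with a warning and
#' the intercept re-estimated, so that slower-than-physical clearance is never
#' extrapolated to infinity.
#'
#' @param time_h Scan times in hours post administration (strictly
#'   increasing, > 0).
#' @param activity_MBq Measured activities in MBq (>= 0; zero-activity samples
#'   are dropped before the log-domain fit).
#' @param sd_MBq Optional per-sample standard deviations in MBq. When given,
#'   samples are weighted by the inverse known log-scale variance
#'   `log(1 + (sd/A)^2)` and the covariance does not rescale by the residual
#'   variance.
#' @param constants [isotope_constants()] of the measured isotope (used for
#'   the single-sample fallback and the non-physical clamp).
#'
#' @return An object of class `tac_fit`: `A0_MBq`, `lambda_eff_per_h`,
#'   `T_eff_h`, `cov` (2x2 covariance of `(ln A0, lambda_eff)`), `n_points`,
#'   `fallback_used`, `clamped` and `isotope`.
#'
#' @examples
#' k <- isotope_constants("I131")
#' fit <- fit_tac(c(1e-9, 24), c(100, 50), constants = k)
#' fit$lambda_eff_per_h # ln(2)/24
#' @export
fit_tac <- function(time_h, activity_MBq, sd_MBq = NULL, constants) {
  stopifnot(inherits(constants, "isotope_constants"))
  if (length(time_h) != length(activity_MBq)) {
    stop("time_h and activity_MBq must have equal length", call. = FALSE)
  }
  if (length(time_h) < 1L) stop("at least one sample is required", call. = FALSE)
  if (any(!is.finite(time_h)) || any(diff(time_h) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(activity_MBq < 0)) stop("activities must be >= 0", call. = FALSE)

  pos <- activity_MBq > 0
  if (!any(pos)) stop("all activities are zero: cannot fit a decay curve", call. = FALSE)
  t <- time_h[pos]
  a <- activity_MBq[pos]
  s <- if (!is.null(sd_MBq)) sd_MBq[pos] else NULL
  n <- length(t)
  lam_phys <- constants$lambda_phys_per_h

  known_var <- !is.null(s) && all(is.finite(s)) && all(s > 0)
  y <- log(a)
  v <- if (known_var) log(1 + (s / a)^2) else rep(1, n)
  w <- 1 / v

  new_fit <- function(lnA0, lambda, cov, fallback, clamped) {
    structure(
      list(
        A0_MBq = exp(lnA0),
        lambda_eff_per_h = lambda,
        T_eff_h = log(2) / lambda,
        cov = cov,
        n_points = n,
        fallback_used = fallback,
        clamped = clamped,
        isotope = constants$isotope
      ),
      class = "tac_fit"
    )
  }

  covnames <- list(c("lnA0", "lambda"), c("lnA0", "lambda"))
  if (n == 1L) {
    # Single scan: biological clearance unidentifiable, assume physical decay only.
    lnA0 <- y + lam_phys * t
    var_lnA0 <- if (known_var) v else 0
    cov <- matrix(c(var_lnA0, 0, 0, 0), 2, 2, dimnames = covnames)
    return(new_fit(lnA0, lam_phys, cov, fallback = TRUE, clamped = FALSE))
  }

  sw <- sum(w)
  tbar <- sum(w * t) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (t - tbar)^2)
  slope <- sum(w * (t - tbar) * (y - ybar)) / sxx
  lnA0 <- ybar - slope * tbar
  lambda <- -slope

  # Covariance of (intercept, slope) for the weighted straight line.
  cov_b <- matrix(
    c(1 / sw + tbar^2 / sxx, tbar / sxx,
      tbar / sxx, 1 / sxx),
    2, 2
  )
  if (!known_var) {
    rss <- sum(w * (y - (lnA0 + slope * t))^2)
    s2 <- if (n > 2) rss / (n - 2) else 0
    cov_b <- cov_b * s2
  }
  # (ln A0, lambda) = (intercept, -slope): negate the cross term.
  cov <- matrix(
    c(cov_b[1, 1], -cov_b[1, 2], -cov_b[2, 1], cov_b[2, 2]),
    2, 2, dimnames = covnames
  )

  if (lambda <= 0) {
    warning(sprintf(
      "fitted lambda_eff = %.4g /h is non-physical (accumulation); clamped to lambda_phys = %.4g /h",
      lambda, lam_phys
    ), call. = FALSE)
    lnA0 <- sum(w * (y + lam_phys * t)) / sw
    var_lnA0 <- if (known_var) 1 / sw else 0
    cov <- matrix(c(var_lnA0, 0, 0, 0), 2, 2, dimnames = covnames)
    return(new_fit(lnA0, lam_phys, cov, fallback = FALSE, clamped = TRUE))
  }
  new_fit(lnA0, lambda, cov, fallback = FALSE, clamped = FALSE)
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf(
    "<tac_fit> %s: A0 = %.4g MBq, lambda_eff = %.5g /h (T_eff = %.4g h), n = %d%s%s\n",
    x$isotope, x$A0_MBq, x$lambda_eff_per_h, x$T_eff_h, x$n_points,
    if (x$fallback_used) ", single-sample fallback" else "",
    if (x$clamped) ", clamped to physical decay" else ""
  ))
  invisible(x)
}

#' Cumulated activity of a fitted time-activity curve
#'
#' Integrates the fitted mono-exponential analytically over `[0, Inf)`:
#' `A_tilde = A0 / lambda_eff` (MBq·h). The standard uncertainty follows by
#' the delta method from the fit covariance of `(ln A0, lambda_eff)`:
#' `var(A_tilde) = A_tilde^2 * (var(lnA0) + var(lambda)/lambda^2
#'   - 2 cov(lnA0, lambda)/lambda)`.
#'
#' @param fit A `tac_fit`.
#' @return A list with `A_tilde_MBq_h` and `sd_MBq_h`.
#' @examples
#' k <- isotope_constants("I131")
#' fit <- fit_tac(c(1e-9, 24), c(100, 50), constants = k)
#' cumulated_activity(fit)$A_tilde_MBq_h # 2400 / ln(2)
#' @export
cumulated_activity <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  lam <- fit$lambda_eff_per_h
  if (lam <= 0) stop("lambda_eff <= 0: cumulated activity integral diverges", call. = FALSE)
  a_tilde <- fit$A0_MBq / lam
  v <- fit$cov
  rel_var <- v[1, 1] + v[2, 2] / lam^2 - 2 * v[1, 2] / lam
  rel_var <- max(rel_var, 0)
  list(A_tilde_MBq_h = a_tilde, sd_MBq_h = a_tilde * sqrt(rel_var))
}

#' Uptake concentration at a time point
#'
#' Activity concentration `A0 * exp(-lambda_eff * t) / V` in MBq/cm^3 at time
#' `t_h`, the quantity compared at the 24-h reference time.
#'
#' @param fit A `tac_fit`.
#' @param t_h Time in hours post administration.
#' @param volume_cm3 Lesion volume in cm^3 (> 0).
#' @return Concentration in MBq/cm^3.
#' @export
uptake_concentration <- function(fit, t_h, volume_cm3) {
  stopifnot(inherits(fit, "tac_fit"))
  if (!is.numeric(volume_cm3) || any(volume_cm3 <= 0)) {
    stop("volume_cm3 must be > 0", call. = FALSE)
  }
  fit$A0_MBq * exp(-fit$lambda_eff_per_h * t_h) / volume_cm3
}

#' Fit time-activity curves for every (lesion, phase) series in a table
#'
#' Applies [fit_tac()] to each `(lesion_id, phase)` group of a measurements
#' table (schema of [read_measurements()]).
#'
#' @param measurements Measurements data frame.
#' @param constants_by_isotope Named list of [isotope_constants()] keyed by
#'   isotope label; defaults to the packaged I-123/I-131 constants.
#' @return A data frame with one row per series: `lesion_id`, `patient_id`,
#'   `phase`, `isotope`, `A0_MBq`, `lambda_eff_per_h`, `T_eff_h`,
#'   `var_lnA0`, `var_lambda`, `cov_lnA0_lambda`, `n_points`,
#'   `fallback_used`, `clamped`.
#' @export
fit_tac_table <- function(measurements,
                          constants_by_isotope = list(I123 = isotope_constants("I123"),
                                                      I131 = isotope_constants("I131"))) {
  stopifnot(is.data.frame(measurements))
  key <- interaction(measurements$lesion_id, measurements$phase, drop = TRUE)
  rows <- lapply(split(measurements, key), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    sds <- d$activity_sd_MBq
    if (is.null(sds) || any(!is.finite(sds)) || any(sds <= 0)) sds <- NULL
    fit <- fit_tac(d$time_h, d$activity_MBq, sds,
                   constants_by_isotope[[d$isotope[1]]])
    data.frame(
      lesion_id = d$lesion_id[1],
      patient_id = d$patient_id[1],
      phase = d$phase[1],
      isotope = d$isotope[1],
      A0_MBq = fit$A0_MBq,
      lambda_eff_per_h = fit$lambda_eff_per_h,
      T_eff_h = fit$T_eff_h,
      var_lnA0 = fit$cov[1, 1],
      var_lambda = fit$cov[2, 2],
      cov_lnA0_lambda = fit$cov[1, 2],
      n_points = fit$n_points,
      fallback_used = fit$fallback_used,
      clamped = fit$clamped,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Rebuild a tac_fit object from one row of a fit table.
fit_from_row <- function(row) {
  structure(
    list(
      A0_MBq = row$A0_MBq,
      lambda_eff_per_h = row$lambda_eff_per_h,
      T_eff_h = row$T_eff_h,
      cov = matrix(c(row$var_lnA0, row$cov_lnA0_lambda,
                     row$cov_lnA0_lambda, row$var_lambda),
                   2, 2, dimnames = list(c("lnA0", "lambda"), c("lnA0", "lambda"))),
      n_points = row$n_points,
      fallback_used = row$fallback_used,
      clamped = row$clamped,
      isotope = row$isotope
    ),
    class = "tac_fit"
  )
}
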