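# Energy-to-dose conversion: MeV per decay -> Gy * g / (MBq * h).
# 1 MBq*h = 3.6e9 decays; 1 MeV = 1.602176634e-13 J; reference mass 1 g.
.MEV_TO_GY_G_PER_MBQ_H <- 1.602176634e-13 * 3.6e9 / 1e-3

# Standard decay data (ICRP Publication 107): physical half-life and the mean
# energy emitted per decay as non-penetrating radiation (beta, conversion and
# Auger electrons), which governs the self-dose of small lesions.
.ISOTOPE_DATA <- list(
  I123 = list(physical_halflife_h = 13.2235, e_np_MeV = 0.0280),
  I131 = list(physical_halflife_h = 8.0252 * 24, e_np_MeV = 0.1917)
)

#' Physical constants for a radioiodine isotope
#'
#' Returns the decay constants needed for lesion self-dosimetry: the physical
#' half-life and the non-penetrating dose constant \eqn{\Delta_{np}}, the mean
#' locally absorbed energy per unit cumulated activity. \eqn{\Delta_{np}} is
#' derived from the mean electron (beta + conversion + Auger) energy per decay
#' in standard decay data; photon emissions are excluded because lesion
#' self-dose at small volumes is dominated by locally deposited electron
#' energy.
#'
#' @param isotope `"I123"` or `"I131"`.
#' @param physical_halflife_h Optional override of the physical half-life in
#'   hours.
#' @param delta_np_Gy_g_per_MBq_h Optional override of the non-penetrating
#'   dose constant in Gy·g/(MBq·h).
#'
#' @return An object of class `isotope_constants`: a list with elements
#'   `isotope`, `physical_halflife_h`, `lambda_phys_per_h` and
#'   `delta_np_Gy_g_per_MBq_h`.
#'
#' @examples
#' isotope_constants("I131")
#' isotope_constants("I123")$physical_halflife_h
#' @export
isotope_constants <- function(isotope = c("I123", "I131"),
                              physical_halflife_h = NULL,
                              delta_np_Gy_g_per_MBq_h = NULL) {
  isotope <- match.arg(isotope)
  data <- .ISOTOPE_DATA[[isotope]]
  thalf <- physical_halflife_h %||% data$physical_halflife_h
  delta <- delta_np_Gy_g_per_MBq_h %||% (data$e_np_MeV * .MEV_TO_GY_G_PER_MBQ_H)
  if (!is.numeric(thalf) || length(thalf) != 1L || !is.finite(thalf) || thalf <= 0) {
    stop("'physical_halflife_h' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    stop("'delta_np_Gy_g_per_MBq_h' must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      isotope = isotope,
      physical_halflife_h = thalf,
      lambda_phys_per_h = log(2) / thalf,
      delta_np_Gy_g_per_MBq_h = delta
    ),
    class = "isotope_constants"
  )
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat(sprintf(
    "<isotope_constants> %s: T1/2 = %.4g h (lambda = %.5g /h), Delta_np = %.5g Gy*g/(MBq*h)\n",
    x$isotope, x$physical_halflife_h, x$lambda_phys_per_h,
    x$delta_np_Gy_g_per_MBq_h
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
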