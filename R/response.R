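# Per-lesion RECIST-style response classification on the CT longest axis.

#' Classify lesion response from longest-axis sizes
#'
#' Applies the per-lesion response rules: complete response (CR) when the
#' lesion has disappeared (follow-up size 0); progressive disease (PD) when
#' the longest axis increased by at least 20%; partial response (PR) when it
#' decreased by at least 30%; stable disease (SD) otherwise. Both thresholds
#' are inclusive ("at least"), and precedence is CR, PD, PR, SD.
#'
#' @param baseline_mm Baseline longest axis in mm (> 0). Vectorised.
#' @param followup_mm Follow-up longest axis in mm (>= 0; 0 = disappeared).
#' @return A data frame: `baseline_mm`, `followup_mm`, `category` (factor
#'   with levels CR, PR, SD, PD), `overall_response` (CR or PR) and
#'   `clinical_benefit` (CR, PR or SD).
#' @examples
#' classify_lesion(c(20, 20, 20, 20), c(14, 24, 0, 20))$category
#' @export
classify_lesion <- function(baseline_mm, followup_mm) {
  if (length(baseline_mm) != length(followup_mm)) {
    stop("baseline_mm and followup_mm must have equal length", call. = FALSE)
  }
  if (any(!is.finite(baseline_mm)) || any(baseline_mm <= 0)) {
    stop("baseline_mm must be > 0", call. = FALSE)
  }
  if (any(!is.finite(followup_mm)) || any(followup_mm < 0)) {
    stop("followup_mm must be >= 0", call. = FALSE)
  }
  change <- (followup_mm - baseline_mm) / baseline_mm
  category <- ifelse(followup_mm == 0, "CR",
              ifelse(change >= 0.20, "PD",
              ifelse(-change >= 0.30, "PR", "SD")))
  category <- factor(category, levels = c("CR", "PR", "SD", "PD"))
  data.frame(
    baseline_mm = baseline_mm,
    followup_mm = followup_mm,
    category = category,
    overall_response = category %in% c("CR", "PR"),
    clinical_benefit = category %in% c("CR", "PR", "SD")
  )
}

#' Overall response and clinical benefit rates
#'
#' `ORR = 100 * (#CR + #PR) / n` and `CBR = 100 * (#CR + #PR + #SD) / n`,
#' rounded to the nearest integer percent for reporting; raw fractions are
#' also returned.
#'
#' @param category Factor or character vector of lesion categories
#'   (CR/PR/SD/PD), e.g. the `category` column of [classify_lesion()].
#' @return A list: `orr_percent`, `cbr_percent` (integer percents),
#'   `orr_fraction`, `cbr_fraction`, `counts` (table over CR/PR/SD/PD) and
#'   `n`.
#' @examples
#' cats <- rep(c("PR", "SD", "PD"), c(3, 17, 4))
#' response_rates(cats) # ORR 13%, CBR 83%
#' @export
response_rates <- function(category) {
  if (length(category) < 1L) stop("at least one response record is required", call. = FALSE)
  category <- factor(as.character(category), levels = c("CR", "PR", "SD", "PD"))
  if (any(is.na(category))) stop("categories must be CR, PR, SD or PD", call. = FALSE)
  counts <- table(category)
  n <- length(category)
  orr <- unname(counts["CR"] + counts["PR"]) / n
  cbr <- unname(counts["CR"] + counts["PR"] + counts["SD"]) / n
  # Half-up rounding (12.5% reports as 13%), not banker's rounding.
  pct <- function(x) floor(100 * x + 0.5)
  list(
    orr_percent = pct(orr),
    cbr_percent = pct(cbr),
    orr_fraction = orr,
    cbr_fraction = cbr,
    counts = counts,
    n = n
  )
}
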