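# End-to-end pipeline: simulate (or load) -> size filter -> fit -> predict ->
# gate -> dose -> compare (-> response). All stage tables and a summary JSON
# are written when an output directory is given; a fixed seed reproduces the
# run byte for byte.

#' Pipeline configuration
#'
#' Bundles the inputs and tunables of [run_pipeline()]. Either a
#' [cohort_config()] (synthetic run) or paths to `measurements` and `lesions`
#' CSV tables must be supplied.
#'
#' @param cohort A [cohort_config()] for a synthetic run, or `NULL`.
#' @param measurements_csv,lesions_csv Paths to input tables when not
#'   simulating.
#' @param responses_csv Optional path to a baseline/follow-up lesion size
#'   table; the response stage is skipped when absent.
#' @param admin_123_MBq,admin_131_MBq Administered activities (taken from the
#'   cohort config when simulating).
#' @param eligibility_threshold Fractional uptake increase required for
#'   therapy (default 0.30).
#' @param size_threshold_mm Minimum measurable lesion axis (default 10 mm).
#' @param massmodel A [mass_model()].
#' @param constants_123,constants_131 Isotope constants overrides.
#' @param out_dir Output directory, or `NULL` to keep results in memory only.
#' @param seed Integer seed (overrides the cohort config seed when given).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL,
                            measurements_csv = NULL,
                            lesions_csv = NULL,
                            responses_csv = NULL,
                            admin_123_MBq = NULL,
                            admin_131_MBq = NULL,
                            eligibility_threshold = 0.30,
                            size_threshold_mm = 10,
                            massmodel = mass_model(),
                            constants_123 = isotope_constants("I123"),
                            constants_131 = isotope_constants("I131"),
                            out_dir = NULL,
                            seed = NULL) {
  if (is.null(cohort) && (is.null(measurements_csv) || is.null(lesions_csv))) {
    stop("supply either a cohort config or measurements_csv + lesions_csv",
         call. = FALSE)
  }
  for (p in c(measurements_csv, lesions_csv, responses_csv)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input file does not exist: %s", p), call. = FALSE)
    }
  }
  if (eligibility_threshold <= 0 || eligibility_threshold >= 10) {
    stop("eligibility_threshold must lie in (0, 10)", call. = FALSE)
  }
  if (!is.null(cohort)) {
    validate_cohort_config(cohort)
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
    admin_123_MBq <- admin_123_MBq %||% cohort$admin_123_MBq
    admin_131_MBq <- admin_131_MBq %||% cohort$admin_131_MBq
  }
  if (is.null(admin_123_MBq) || is.null(admin_131_MBq)) {
    stop("administered activities are required (admin_123_MBq, admin_131_MBq)",
         call. = FALSE)
  }
  structure(
    list(cohort = cohort,
         measurements_csv = measurements_csv,
         lesions_csv = lesions_csv,
         responses_csv = responses_csv,
         admin_123_MBq = admin_123_MBq,
         admin_131_MBq = admin_131_MBq,
         eligibility_threshold = eligibility_threshold,
         size_threshold_mm = size_threshold_mm,
         massmodel = massmodel,
         constants_123 = constants_123,
         constants_131 = constants_131,
         out_dir = out_dir,
         seed = seed),
    class = "pipeline_config"
  )
}

#' Run the lesion dosimetry pipeline end to end
#'
#' Executes, in order: cohort simulation (or table loading), the lesion size
#' filter, per-series time-activity fits, theranostic prediction of therapy
#' uptake from the pre- and post-drug diagnostic series, the patient
#' eligibility gate, absorbed-dose computation for predicted and (when
#' therapy series exist) measured doses, predicted-vs-measured agreement
#' statistics, and — when follow-up sizes are available — per-lesion response
#' classification. Stage failures abort with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `rai_run`: list with the stage tables
#'   (`lesions`, `measurements`, `fits`, `predictions`, `effects`,
#'   `eligibility`, `doses_predicted`, `doses_measured`, `pairs`), the
#'   `agreement` summary, optional `response` results, and a `summary` list
#'   (also written as `summary.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- NULL
  if (!is.null(config$cohort)) {
    cohort <- stage("simulate", generate_cohort(config$cohort))
    lesions <- cohort$lesions
    measurements <- cohort$measurements
  } else {
    lesions <- stage("load", read_lesions(config$lesions_csv))
    measurements <- stage("load", read_measurements(config$measurements_csv))
  }

  lesions <- stage("size_filter",
                   apply_size_filter(lesions, config$size_threshold_mm, quiet = TRUE))
  measurements <- measurements[measurements$lesion_id %in% lesions$lesion_id, ,
                               drop = FALSE]

  consts <- list(I123 = config$constants_123, I131 = config$constants_131)
  fits <- stage("fit", fit_tac_table(measurements, consts))

  vol <- lesions$volume_cm3[match(fits$lesion_id, lesions$lesion_id)]
  site <- lesions$site[match(fits$lesion_id, lesions$lesion_id)]

  predict_phase <- function(phase) {
    sel <- which(fits$phase == phase)
    rows <- lapply(sel, function(i) {
      pt <- predict_therapy(fit_from_row(fits[i, ]),
                            config$admin_123_MBq, config$admin_131_MBq,
                            config$constants_123, config$constants_131,
                            volume_cm3 = vol[i], site = site[i],
                            massmodel = config$massmodel,
                            lesion_id = fits$lesion_id[i])
      data.frame(
        lesion_id = fits$lesion_id[i],
        patient_id = fits$patient_id[i],
        phase = phase,
        A0_pred_MBq = pt$A0_pred_MBq,
        lambda_eff_pred_per_h = pt$lambda_eff_pred_per_h,
        lambda_bio_clamped = pt$lambda_bio_clamped,
        uptake24_pred_MBq_per_cm3 = pt$uptake24_pred_MBq_per_cm3,
        dose_Gy = pt$dose_pred$dose_Gy,
        sd_Gy = pt$dose_pred$sd_Gy,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame()
    out
  }

  pred_pre <- stage("predict", predict_phase("pre_selumetinib"))
  pred_post <- stage("predict", predict_phase("post_selumetinib"))
  predictions <- rbind(pred_pre, pred_post)

  effects <- stage("effects", {
    idx <- match(pred_post$lesion_id, pred_pre$lesion_id)
    keep <- !is.na(idx)
    up_pre <- pred_pre$uptake24_pred_MBq_per_cm3[idx[keep]]
    up_post <- pred_post$uptake24_pred_MBq_per_cm3[keep]
    data.frame(
      lesion_id = pred_post$lesion_id[keep],
      patient_id = pred_post$patient_id[keep],
      uptake_pre = up_pre,
      uptake_post = up_post,
      absolute_change = up_post - up_pre,
      relative_change = ifelse(up_pre > 0, up_post / up_pre, NA_real_),
      stringsAsFactors = FALSE
    )
  })

  eligibility <- stage("gate", eligibility_gate(effects, config$eligibility_threshold))

  doses_predicted <- pred_post[, c("lesion_id", "patient_id", "dose_Gy", "sd_Gy")]
  therapy_fits <- fits[fits$phase == "therapy", , drop = FALSE]
  doses_measured <- if (nrow(therapy_fits) > 0) {
    stage("dose", dose_table(therapy_fits, lesions, config$massmodel, consts))
  } else {
    data.frame()
  }

  eligible_patients <- eligibility$patient_id[eligibility$eligible]
  pairs <- data.frame()
  agreement <- NULL
  if (nrow(doses_measured) > 0) {
    pred_eligible <- doses_predicted[doses_predicted$patient_id %in% eligible_patients, ,
                                     drop = FALSE]
    pairs <- stage("compare", theranostic_pairs(pred_eligible, doses_measured))
    if (nrow(pairs) >= 3) {
      agreement <- stage("compare", {
        ba <- bland_altman(pairs$predicted_Gy, pairs$measured_Gy)
        cc <- centered_correlation(pairs$predicted_Gy, pairs$measured_Gy,
                                   pairs$patient_id, method = "pearson")
        list(bland_altman = ba, pearson_centered = cc)
      })
    }
  }

  response <- NULL
  if (!is.null(config$responses_csv)) {
    response <- stage("response", {
      resp <- read_responses(config$responses_csv)
      cls <- classify_lesion(resp$baseline_mm, resp$followup_mm)
      cls$lesion_id <- resp$lesion_id
      list(table = cls, rates = response_rates(cls$category))
    })
  }

  summary <- list(
    n_patients = length(unique(lesions$patient_id)),
    n_lesions = nrow(lesions),
    n_lesions_excluded_by_size = attr(lesions, "n_excluded") %||% 0L,
    n_eligible_patients = length(eligible_patients),
    eligibility_threshold = config$eligibility_threshold,
    median_uptake_pre = stats::median(effects$uptake_pre),
    median_uptake_post = stats::median(effects$uptake_post),
    median_absolute_change = stats::median(effects$absolute_change),
    median_relative_change = stats::median(effects$relative_change, na.rm = TRUE),
    seed = config$seed %||% (if (!is.null(config$cohort)) config$cohort$seed else NA)
  )
  if (!is.null(agreement)) {
    summary$bland_altman_bias_Gy <- agreement$bland_altman$bias
    summary$bland_altman_sd_Gy <- agreement$bland_altman$sd_diff
    summary$median_relative_diff_percent <-
      agreement$bland_altman$median_relative_diff_percent
    summary$pearson_r_centered <- agreement$pearson_centered$estimate
    summary$pearson_p_centered <- agreement$pearson_centered$p_value
  }
  if (nrow(effects) > 0 && length(unique(effects$patient_id)) >= 2) {
    kw <- kruskal_wallis(effects$relative_change[!is.na(effects$relative_change)],
                         effects$patient_id[!is.na(effects$relative_change)])
    summary$kruskal_wallis_H <- kw$H
    summary$kruskal_wallis_df <- kw$df
    summary$kruskal_wallis_p <- kw$p_value
    icc <- icc_patients(log(effects$uptake_post), effects$patient_id)
    summary$icc_patients_log_uptake <- icc$icc
  }
  if (!is.null(response)) {
    summary$orr_percent <- response$rates$orr_percent
    summary$cbr_percent <- response$rates$cbr_percent
  }

  run <- structure(
    list(lesions = lesions, measurements = measurements, fits = fits,
         predictions = predictions, effects = effects,
         eligibility = eligibility,
         doses_predicted = doses_predicted, doses_measured = doses_measured,
         pairs = pairs, agreement = agreement, response = response,
         summary = summary, config = config, cohort = cohort),
    class = "rai_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.rai_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<rai_run> %d patients / %d lesions; %d eligible patient(s)\n",
              s$n_patients, s$n_lesions, s$n_eligible_patients))
  cat(sprintf("  median relative uptake change: %.3g\n", s$median_relative_change))
  if (!is.null(s$pearson_r_centered)) {
    cat(sprintf("  predicted vs measured dose: centered r = %.3g, bias = %.4g Gy\n",
                s$pearson_r_centered, s$bland_altman_bias_Gy))
  }
  invisible(x)
}

#' Write all stage tables and the run summary to a directory
#'
#' Emits CSV tables per stage, `summary.json`, and `run_log.txt` (package
#' version, R version, seed, configuration hash).
#'
#' @param run An `rai_run`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "rai_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df) && nrow(df) > 0) {
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    }
  }
  wr(run$lesions, "lesions.csv")
  wr(run$measurements, "measurements.csv")
  wr(run$fits, "fits.csv")
  wr(run$predictions, "predictions.csv")
  wr(run$effects, "effects.csv")
  wr(run$eligibility, "eligibility.csv")
  wr(run$doses_predicted, "doses_predicted.csv")
  wr(run$doses_measured, "doses_measured.csv")
  wr(run$pairs, "pairs.csv")
  if (!is.null(run$response)) wr(run$response$table, "responses_classified.csv")
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  cfg_file <- file.path(dir, "config_echo.txt")
  writeLines(utils::capture.output(utils::str(run$config)), cfg_file)
  log_lines <- c(
    sprintf("raidose %s", as.character(utils::packageVersion("raidose"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %s", run$summary$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_file))),
    sprintf("generated: deterministic given config and seed")
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Load a cohort configuration from YAML or JSON
#'
#' Field names match the arguments of [cohort_config()]; unknown fields are
#' rejected.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A validated [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown cohort config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (f in c("site_probabilities", "volume_lognormal", "baseline_uptake_lognormal",
              "effect_lognormal", "biological_halflife_lognormal")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(cohort_config, raw)
}
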