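# Residue pipeline: censored per-AI wetland concentrations -> recovery-
# corrected totals, detection frequencies, and crop-by-season summary tables.
#
# A panel is a long-format table, one row per (wetland, season, matrix, AI):
#   wetland_id, qs_id, season, crop, crop_prev, matrix, ai,
#   measured, loq, recovery, units
# Water concentrations are ng/L; sediment concentrations ug/kg wet weight.
# The same logic applies to both matrices; no cross-matrix conversion exists.

PANEL_COLUMNS <- c("wetland_id", "qs_id", "season", "crop", "matrix",
                   "ai", "measured", "loq", "recovery")

#' Default limits of quantification
#'
#' Two LOQ sets are in circulation for the four active ingredients in water
#' (ng/L). The `"reported"` set (acetamiprid 0.25, clothianidin 0.6,
#' imidacloprid 0.55, thiamethoxam 0.9) is the default used for censoring in
#' summary tables; the `"method"` set is exactly double each value
#' (0.5 / 1.2 / 1.1 / 1.8) and corresponds to the analytical method's stated
#' quantification limits. Which of the two a reanalysis should use is a
#' judgement call; both are provided.
#'
#' @param set `"reported"` (default) or `"method"`.
#' @return Named numeric vector of LOQs (ng/L), one per active ingredient.
#' @export
loq_defaults <- function(set = c("reported", "method")) {
  set <- match.arg(set)
  base <- c(acetamiprid = 0.25, clothianidin = 0.6,
            imidacloprid = 0.55, thiamethoxam = 0.9)
  if (set == "method") base * 2 else base
}

#' Default assay recovery fractions
#'
#' Mean fractional recoveries of the extraction/LC-MS/MS assay, by matrix:
#' water (acetamiprid 0.896, clothianidin 0.789, imidacloprid 0.859,
#' thiamethoxam 0.888) and sediment (0.745, 0.723, 0.735, 0.736).
#'
#' @param matrix `"water"` or `"sediment"`.
#' @return Named numeric vector of recovery fractions in (0, 1].
#' @export
recovery_defaults <- function(matrix = c("water", "sediment")) {
  matrix <- match.arg(matrix)
  switch(matrix,
    water = c(acetamiprid = 0.896, clothianidin = 0.789,
              imidacloprid = 0.859, thiamethoxam = 0.888),
    sediment = c(acetamiprid = 0.745, clothianidin = 0.723,
                 imidacloprid = 0.735, thiamethoxam = 0.736))
}

#' Recovery-correct a measured concentration
#'
#' Divides the measured concentration by the assay's mean fractional
#' recovery: a clothianidin reading of 78.9 at recovery 0.789 corrects to
#' 100.
#'
#' @param measured Measured concentration (>= 0, vectorised).
#' @param recovery_fraction Recovery fraction in (0, 1] (vectorised).
#' @return Corrected concentration, same units as `measured`.
#' @export
apply_recovery_correction <- function(measured, recovery_fraction) {
  if (!is.numeric(measured) || any(!is.finite(measured)) || any(measured < 0)) {
    abort_measurement("`measured` must be finite and >= 0.")
  }
  if (!is.numeric(recovery_fraction) || any(!is.finite(recovery_fraction)) ||
      any(recovery_fraction <= 0) || any(recovery_fraction > 1)) {
    abort_invalid("`recovery_fraction` must lie in (0, 1].")
  }
  measured / recovery_fraction
}

#' Censor a measurement at its limit of quantification
#'
#' A value is censored ("ND") when it falls strictly below the LOQ; a value
#' exactly at the LOQ counts as detected. Censored values carry 0 so that
#' downstream sums and arithmetic means treat non-detects as zero.
#'
#' @param measured Measured concentration (>= 0, vectorised).
#' @param loq Limit of quantification (> 0, vectorised).
#' @return A tibble with columns `value` (0 when censored, else `measured`)
#'   and `censored` (logical).
#' @export
censor_at_loq <- function(measured, loq) {
  if (!is.numeric(measured) || any(!is.finite(measured)) || any(measured < 0)) {
    abort_measurement("`measured` must be finite and >= 0.")
  }
  if (!is.numeric(loq) || any(!is.finite(loq)) || any(loq <= 0)) {
    abort_invalid("`loq` must be finite and > 0.")
  }
  censored <- measured < loq
  tibble(value = ifelse(censored, 0, measured), censored = censored)
}

validate_panel <- function(panel) {
  panel <- as_tibble(panel)
  check_columns(panel, PANEL_COLUMNS, "residue sample table")
  if (!"crop_prev" %in% names(panel)) panel$crop_prev <- NA_character_
  if (!"units" %in% names(panel)) panel$units <- NA_character_
  key <- paste(panel$wetland_id, panel$season, panel$matrix, panel$ai)
  if (anyDuplicated(key)) {
    abort_sample(sprintf(
      "duplicate (wetland, season, matrix, ai) rows in panel: %s",
      paste(head(unique(key[duplicated(key)]), 3), collapse = "; ")))
  }
  panel
}

#' Censor and recovery-correct a residue panel
#'
#' Applies [censor_at_loq()] to each row's measured value, then
#' [apply_recovery_correction()] to the detects. Adds columns `censored`
#' (logical) and `value` (recovery-corrected concentration, 0 for
#' non-detects).
#'
#' @param panel Long-format sample table (see [read_samples()] for columns).
#' @return The panel tibble with `censored` and `value` columns appended.
#' @export
prepare_samples <- function(panel) {
  panel <- validate_panel(panel)
  cen <- censor_at_loq(panel$measured, panel$loq)
  corrected <- apply_recovery_correction(cen$value, panel$recovery)
  panel$censored <- cen$censored
  panel$value <- ifelse(cen$censored, 0, corrected)
  panel
}

#' Total neonicotinoid concentration of one sample
#'
#' Sums the recovery-corrected concentrations of the detected active
#' ingredients in a single sample (one wetland, one season, one matrix);
#' censored AIs contribute 0. Because the four neonicotinoids share the same
#' receptor target, their concentrations are treated as additive.
#'
#' @param sample Tibble of per-AI rows for one sample, with `measured`,
#'   `loq`, `recovery` and `matrix` columns (extra columns ignored).
#' @return Total concentration, in the matrix's units.
#' @export
total_neonic_concentration <- function(sample) {
  sample <- as_tibble(sample)
  check_columns(sample, c("matrix", "ai", "measured", "loq", "recovery"),
                "sample")
  if (length(unique(sample$matrix)) > 1) {
    abort_sample("a sample cannot mix matrices (water and sediment rows found).")
  }
  cen <- censor_at_loq(sample$measured, sample$loq)
  sum(ifelse(cen$censored, 0,
             apply_recovery_correction(cen$value, sample$recovery)))
}

#' Per-sample totals and detection flags
#'
#' Collapses a long panel to one row per (wetland, season): the total
#' neonicotinoid concentration (detected AIs summed, non-detects 0) and
#' whether any AI was detected.
#'
#' @param panel Long-format sample table.
#' @param matrix Which matrix to summarise (`"water"` or `"sediment"`).
#' @return Tibble with columns `wetland_id`, `qs_id`, `season`, `crop`,
#'   `crop_prev`, `matrix`, `n_ai`, `total`, `detected`.
#' @export
sample_totals <- function(panel, matrix = "water") {
  panel <- prepare_samples(panel)
  panel <- panel[panel$matrix == matrix, ]
  panel %>%
    group_by(.data$wetland_id, .data$qs_id, .data$season, .data$crop,
             .data$crop_prev, .data$matrix) %>%
    summarise(n_ai = dplyr::n(),
              total = sum(.data$value),
              detected = any(!.data$censored),
              .groups = "drop")
}

#' Detection frequency for one season
#'
#' At wetland level, a wetland counts as detected when at least one active
#' ingredient is at or above its LOQ in that season; at quarter-section
#' level, a quarter section counts when any of its sampled wetlands is
#' detected. Wetlands not sampled in a season (dry or flooded) are absent
#' from the panel and hence from the denominator. The percentage is rounded
#' half-up to an integer, the convention used for reporting (49 of 136 is
#' 36%; 37 of 49 is 76%).
#'
#' @param panel Long-format sample table.
#' @param season Season label to evaluate.
#' @param level `"wetland"` or `"quarter_section"`.
#' @param matrix `"water"` or `"sediment"`.
#' @return A list with `numerator`, `denominator` and `percent`.
#' @export
detection_frequency <- function(panel, season,
                                level = c("wetland", "quarter_section"),
                                matrix = "water") {
  level <- match.arg(level)
  st <- sample_totals(panel, matrix = matrix)
  st <- st[st$season == season, ]
  if (nrow(st) == 0) {
    abort_group(sprintf("no %s samples in season '%s'.", matrix, season))
  }
  if (level == "wetland") {
    num <- sum(st$detected)
    den <- nrow(st)
  } else {
    by_qs <- st %>%
      group_by(.data$qs_id) %>%
      summarise(detected = any(.data$detected), .groups = "drop")
    num <- sum(by_qs$detected)
    den <- nrow(by_qs)
  }
  list(numerator = as.integer(num), denominator = as.integer(den),
       percent = round_half_up(100 * num / den))
}

#' Crop-by-season summary of detections and concentrations
#'
#' For every (season, crop) stratum and every analyte (each active
#' ingredient plus the total), reports the sample count, number and
#' percentage of detections, the arithmetic mean and the maximum
#' concentration. By default censored values enter means as 0; the
#' `"detects_only"` mode averages over detected samples instead (and is `NA`
#' when nothing was detected).
#'
#' @param panel Long-format sample table.
#' @param matrix `"water"` or `"sediment"`.
#' @param mean_mode `"censored_zero"` (default) or `"detects_only"`.
#' @param crops Allowed crop labels; panel rows with other labels raise an
#'   invalid-category error. `NULL` accepts whatever the panel contains.
#' @return Tibble with columns `matrix`, `season`, `crop`, `analyte`, `n`,
#'   `n_detected`, `detection_pct` (unrounded), `mean`, `max`.
#' @export
crop_season_summary <- function(panel, matrix = "water",
                                mean_mode = c("censored_zero", "detects_only"),
                                crops = crop_levels()) {
  mean_mode <- match.arg(mean_mode)
  prepared <- prepare_samples(panel)
  prepared <- prepared[prepared$matrix == matrix, ]
  if (nrow(prepared) == 0) {
    abort_group(sprintf("panel contains no '%s' samples.", matrix))
  }
  if (!is.null(crops)) {
    unknown <- setdiff(unique(prepared$crop), crops)
    if (length(unknown)) {
      abort_category(sprintf("unknown crop label(s): %s",
                             paste(unknown, collapse = ", ")))
    }
  }
  mean_fun <- function(value, censored) {
    if (mean_mode == "censored_zero") {
      mean(value)
    } else if (any(!censored)) {
      mean(value[!censored])
    } else {
      NA_real_
    }
  }
  per_ai <- prepared %>%
    group_by(.data$season, .data$crop, analyte = .data$ai) %>%
    summarise(n = dplyr::n(),
              n_detected = sum(!.data$censored),
              mean = mean_fun(.data$value, .data$censored),
              max = max(.data$value),
              .groups = "drop")
  totals <- sample_totals(panel, matrix = matrix) %>%
    group_by(.data$season, .data$crop) %>%
    summarise(analyte = "total",
              n = dplyr::n(),
              n_detected = sum(.data$detected),
              mean = mean_fun(.data$total, !.data$detected),
              max = max(.data$total),
              .groups = "drop")
  bind_rows(totals, per_ai) %>%
    mutate(matrix = matrix,
           detection_pct = 100 * .data$n_detected / .data$n) %>%
    select("matrix", "season", "crop", "analyte", "n", "n_detected",
           "detection_pct", "mean", "max") %>%
    arrange(match(.data$season, season_levels()), .data$crop,
            match(.data$analyte, c("total", neonic_ais())))
}

#' Read and write residue sample tables
#'
#' Long-format CSV with header `wetland_id,qs_id,season,crop,crop_prev,`
#' `matrix,ai,measured,loq,recovery,units` — one active ingredient per row.
#'
#' @param path CSV file path.
#' @return `read_samples()` returns the validated panel tibble;
#'   `write_samples()` returns `path` invisibly.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("sample file not found: %s", path))
  validate_panel(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_samples
#' @param panel Long-format sample table.
#' @export
write_samples <- function(panel, path) {
  panel <- validate_panel(panel)
  write.csv(panel[, c("wetland_id", "qs_id", "season", "crop", "crop_prev",
                      "matrix", "ai", "measured", "loq", "recovery", "units")],
            path, row.names = FALSE)
  invisible(path)
}
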