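# Synthetic data: quarter-section-block crop landscapes and censored,
# repeated-measures wetland concentration panels with known ground truth.
# The generators write exactly the containers the pipeline consumes, so a
# full analysis can be exercised without any confidential input.

#' Landscape generator configuration
#'
#' Crops are planted one per quarter-section block: the landscape is a grid
#' of square blocks, each assigned a single crop code drawn from the
#' proportion vector. Defaults give 8 x 8-pixel (64-ha) blocks at 100-m
#' resolution.
#'
#' @param n_row,n_col Grid size in pixels.
#' @param resolution_m Pixel edge length in metres.
#' @param block_px Block edge in pixels (one quarter section per block).
#' @param crop_codes Named integer vector mapping crop names to codes.
#' @param proportions Numeric vector of planting proportions, same length
#'   and order as `crop_codes`; must be non-negative and sum to 1.
#' @param nodata_code Code for non-cropland (never drawn; reserved).
#' @param year Calendar year stamped on the grid.
#' @param seed Integer seed; a fixed seed gives a bit-identical landscape.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_row = 80, n_col = 80, resolution_m = 100,
                             block_px = 8,
                             crop_codes = c(canola = 1L, wheat = 2L,
                                            barley = 3L, oat = 4L, pea = 5L),
                             proportions = c(0.40, 0.24, 0.20, 0.11, 0.05),
                             nodata_code = 0L, year = 2012L, seed = NULL) {
  check_number(n_row, "n_row", min = 1)
  check_number(n_col, "n_col", min = 1)
  check_number(resolution_m, "resolution_m", min = 0, min_open = TRUE)
  check_number(block_px, "block_px", min = 1)
  if (length(crop_codes) != length(proportions)) {
    abort_invalid("`crop_codes` and `proportions` must have equal length.")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    abort_invalid("`proportions` must be non-negative and sum to 1.")
  }
  if (nodata_code %in% crop_codes) {
    abort_invalid("`nodata_code` must not collide with a crop code.")
  }
  structure(
    list(n_row = as.integer(n_row), n_col = as.integer(n_col),
         resolution_m = resolution_m, block_px = as.integer(block_px),
         crop_codes = crop_codes, proportions = proportions,
         nodata_code = as.integer(nodata_code), year = as.integer(year),
         seed = seed),
    class = "landscape_config"
  )
}

#' Generate a block-structured crop landscape
#'
#' @param cfg A [landscape_config()].
#' @return A [crop_grid()] whose quarter-section blocks each carry a single
#'   crop code.
#' @export
gen_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  if (cfg$block_px > min(cfg$n_row, cfg$n_col)) {
    abort_invalid("`block_px` exceeds the grid dimensions.")
  }
  with_seed_if(cfg$seed, {
    nbr <- ceiling(cfg$n_row / cfg$block_px)
    nbc <- ceiling(cfg$n_col / cfg$block_px)
    block_codes <- matrix(
      sample(as.integer(cfg$crop_codes), nbr * nbc, replace = TRUE,
             prob = cfg$proportions),
      nrow = nbr, ncol = nbc)
    ri <- ceiling(seq_len(cfg$n_row) / cfg$block_px)
    ci <- ceiling(seq_len(cfg$n_col) / cfg$block_px)
    crop_grid(block_codes[ri, ci, drop = FALSE], cfg$resolution_m,
              year = cfg$year, nodata_code = cfg$nodata_code)
  })
}

#' Default true cell means for the panel generator
#'
#' Log-scale (natural log of ng/L) mean total neonicotinoid concentration
#' per crop and season. The values are calibrated, given the default
#' variance components and AI mixing weights, so that the probability of a
#' sample exceeding its most sensitive censoring threshold reproduces the
#' field pattern of detection frequencies: low before seeding, peaking
#' during the growing season (highest in cereals and canola, lowest in
#' grassland), collapsing after harvest, and rebounding strongly with
#' snowmelt the following spring. Pre-seeding (spring 2012) rows are indexed
#' by the previous year's crop, since no current-year seed is in the ground
#' yet.
#'
#' @return Numeric matrix, crops x seasons.
#' @export
default_cell_means <- function() {
  m <- rbind(
    grassland = c(-2.3, -1.7, -1.1, -3.0),
    barley    = c(-0.7,  1.9, -2.1,  2.9),
    canola    = c( 0.3,  1.1, -1.2,  3.7),
    oat       = c( 0.1,  2.5, -0.5,  3.7),
    pea       = c(-0.9,  0.2, -0.2,  3.5),
    wheat     = c(-0.9,  0.8, -3.0,  2.3)
  )
  colnames(m) <- season_levels()
  m
}

#' Panel generator configuration
#'
#' Emulates the wetland sampling design: `n_qs` quarter sections, up to
#' three replicate wetlands each, sampled over four seasons, with fall
#' drawdown removing a fraction of fall samples. The log total
#' concentration of each sample is cell mean + quarter-section effect +
#' wetland effect + residual (all Gaussian); the back-transformed total is
#' split across active ingredients by fixed mixing weights, degraded by the
#' assay recovery, and left to be censored downstream at each AI's LOQ.
#'
#' @param n_qs Number of quarter sections.
#' @param wetlands_per_qs Wetlands per quarter section (1-3).
#' @param seasons Season labels, chronological.
#' @param crops Crop labels (rows of `cell_means`).
#' @param crop_proportions Probability that a quarter section carries each
#'   crop (crops are planted at quarter-section scale, so all wetlands in a
#'   parcel share the crop).
#' @param cell_means Crops x seasons matrix of true log-scale means; the
#'   column for `baseline_season` is indexed by `crop_prev`.
#' @param sigma_qs,sigma_wetland,sigma_resid Standard deviations of the
#'   quarter-section effect, the wetland-within-quarter-section effect and
#'   the residual (log scale, all >= 0).
#' @param mix_weights Named per-AI mixing weights (sum to 1); the default is
#'   clothianidin-dominant.
#' @param loqs,recoveries Named per-AI LOQs (ng/L) and recovery fractions.
#' @param drawdown_prob Probability that a wetland is dry (unsampled) in
#'   fall.
#' @param baseline_season Season whose mean is driven by the previous crop.
#' @param seed Integer seed; fixed seed gives an identical panel.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_qs = 50, wetlands_per_qs = 3,
                         seasons = season_levels(),
                         crops = crop_levels(),
                         crop_proportions = c(0.11, 0.19, 0.37, 0.11, 0.05, 0.17),
                         cell_means = default_cell_means(),
                         sigma_qs = 1.0, sigma_wetland = 1.1,
                         sigma_resid = 0.8,
                         mix_weights = c(acetamiprid = 0.02,
                                         clothianidin = 0.60,
                                         imidacloprid = 0.08,
                                         thiamethoxam = 0.30),
                         loqs = loq_defaults(),
                         recoveries = recovery_defaults("water"),
                         drawdown_prob = 0.4,
                         baseline_season = "spring2012",
                         seed = NULL) {
  check_number(n_qs, "n_qs", min = 1)
  check_number(wetlands_per_qs, "wetlands_per_qs", min = 1, max = 3)
  check_number(sigma_qs, "sigma_qs", min = 0)
  check_number(sigma_wetland, "sigma_wetland", min = 0)
  check_number(sigma_resid, "sigma_resid", min = 0)
  check_number(drawdown_prob, "drawdown_prob", min = 0, max = 1)
  if (length(crops) != length(crop_proportions) ||
      any(crop_proportions < 0) || abs(sum(crop_proportions) - 1) > 1e-8) {
    abort_invalid("`crop_proportions` must match `crops`, be >= 0 and sum to 1.")
  }
  if (!is.matrix(cell_means) ||
      !setequal(rownames(cell_means), crops) ||
      !setequal(colnames(cell_means), seasons)) {
    abort_invalid("`cell_means` must be a crops x seasons matrix with matching dimnames.")
  }
  ais <- names(mix_weights)
  if (is.null(ais) || any(mix_weights < 0) ||
      abs(sum(mix_weights) - 1) > 1e-8) {
    abort_invalid("`mix_weights` must be named, >= 0 and sum to 1.")
  }
  if (!all(ais %in% names(loqs)) || !all(ais %in% names(recoveries))) {
    abort_invalid("`loqs` and `recoveries` must cover every AI in `mix_weights`.")
  }
  if (any(loqs[ais] <= 0)) abort_invalid("LOQs must be > 0.")
  if (any(recoveries[ais] <= 0) || any(recoveries[ais] > 1)) {
    abort_invalid("recoveries must lie in (0, 1].")
  }
  if (!baseline_season %in% seasons) {
    abort_invalid("`baseline_season` must be one of `seasons`.")
  }
  structure(
    list(n_qs = as.integer(n_qs),
         wetlands_per_qs = as.integer(wetlands_per_qs),
         seasons = seasons, crops = crops,
         crop_proportions = crop_proportions,
         cell_means = cell_means[crops, seasons, drop = FALSE],
         sigma_qs = sigma_qs, sigma_wetland = sigma_wetland,
         sigma_resid = sigma_resid,
         mix_weights = mix_weights, loqs = loqs[ais],
         recoveries = recoveries[ais],
         drawdown_prob = drawdown_prob,
         baseline_season = baseline_season,
         seed = seed),
    class = "panel_config"
  )
}

#' Generate a censored wetland residue panel with known truth
#'
#' @param cfg A [panel_config()].
#' @return A list with `panel` (long-format sample table, one row per
#'   wetland/season/AI, carrying raw measured values, LOQs and recoveries)
#'   and `truth` (the generating quantities: per-quarter-section crop,
#'   previous crop and random effect; per-wetland random effect; per-sample
#'   true log totals; the cell-mean matrix and variance components).
#' @export
gen_residue_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed_if(cfg$seed, {
    qs <- tibble(
      qs_id = sprintf("QS%03d", seq_len(cfg$n_qs)),
      crop = sample(cfg$crops, cfg$n_qs, replace = TRUE,
                    prob = cfg$crop_proportions),
      crop_prev = sample(cfg$crops, cfg$n_qs, replace = TRUE,
                         prob = cfg$crop_proportions),
      b_qs = rnorm(cfg$n_qs, 0, cfg$sigma_qs)
    )
    wetlands <- tidyr::crossing(qs_id = qs$qs_id,
                                wetland = seq_len(cfg$wetlands_per_qs)) %>%
      mutate(wetland_id = sprintf("%s-W%d", .data$qs_id, .data$wetland),
             b_wetland = rnorm(dplyr::n(), 0, cfg$sigma_wetland)) %>%
      left_join(qs, by = "qs_id")

    samples <- tidyr::crossing(wetland_id = wetlands$wetland_id,
                               season = cfg$seasons) %>%
      left_join(wetlands, by = "wetland_id") %>%
      mutate(dry = .data$season == "fall2012" &
               runif(dplyr::n()) < cfg$drawdown_prob)
    samples <- samples[!samples$dry, ]
    mean_crop <- ifelse(samples$season == cfg$baseline_season,
                        samples$crop_prev, samples$crop)
    samples$cell_mean <- cfg$cell_means[cbind(mean_crop, samples$season)]
    samples$log_total <- samples$cell_mean + samples$b_qs +
      samples$b_wetland + rnorm(nrow(samples), 0, cfg$sigma_resid)
    samples$total_true <- exp(samples$log_total)

    ais <- names(cfg$mix_weights)
    panel <- samples[rep(seq_len(nrow(samples)), each = length(ais)), ]
    panel$ai <- rep(ais, times = nrow(samples))
    panel$measured <- panel$total_true * cfg$mix_weights[panel$ai] *
      cfg$recoveries[panel$ai]
    panel$loq <- unname(cfg$loqs[panel$ai])
    panel$recovery <- unname(cfg$recoveries[panel$ai])
    panel <- tibble(
      wetland_id = panel$wetland_id,
      qs_id = panel$qs_id,
      season = panel$season,
      crop = panel$crop,
      crop_prev = panel$crop_prev,
      matrix = "water",
      ai = panel$ai,
      measured = unname(panel$measured),
      loq = panel$loq,
      recovery = panel$recovery,
      units = "ng/L"
    )
    truth <- list(
      qs = qs,
      wetlands = wetlands[, c("wetland_id", "qs_id", "b_wetland")],
      samples = as_tibble(samples[, c("wetland_id", "qs_id", "season", "crop",
                                      "crop_prev", "cell_mean", "log_total")]),
      cell_means = cfg$cell_means,
      sigma = c(qs = cfg$sigma_qs, wetland = cfg$sigma_wetland,
                resid = cfg$sigma_resid),
      mix_weights = cfg$mix_weights
    )
    list(panel = panel, truth = truth)
  })
}

#' Reconstruct a panel from reported detection counts
#'
#' Builds a minimal single-season panel in which exactly `detected` of
#' `total` sampling units contain one active ingredient above its LOQ —
#' the shape needed to recompute a published detection frequency from its
#' printed numerator and denominator with [detection_frequency()].
#'
#' @param detected Number of detected units (0 <= detected <= total).
#' @param total Number of sampled units.
#' @param season Season label for all rows.
#' @param level `"wetland"` (each unit is a wetland on its own quarter
#'   section) or `"quarter_section"` (each unit is a quarter section holding
#'   `wetlands_per_unit` wetlands, one of which is detected).
#' @param wetlands_per_unit Wetlands per quarter section when
#'   `level = "quarter_section"`.
#' @param crop Crop label for all rows.
#' @param matrix Sample matrix label.
#' @return A long-format panel tibble.
#' @export
panel_from_counts <- function(detected, total, season = "spring2012",
                              level = c("wetland", "quarter_section"),
                              wetlands_per_unit = 2, crop = "canola",
                              matrix = "water") {
  level <- match.arg(level)
  check_number(detected, "detected", min = 0)
  check_number(total, "total", min = 1)
  if (detected > total) abort_invalid("`detected` cannot exceed `total`.")
  check_number(wetlands_per_unit, "wetlands_per_unit", min = 1, max = 3)
  loq <- loq_defaults()[["clothianidin"]]
  unit <- seq_len(total)
  if (level == "wetland") {
    units_tbl <- tibble(qs_id = sprintf("QS%04d", ceiling(unit / 3)),
                        wetland_id = sprintf("W%04d", unit),
                        hit = unit <= detected)
  } else {
    units_tbl <- tidyr::crossing(qs = unit,
                                 w = seq_len(as.integer(wetlands_per_unit))) %>%
      mutate(qs_id = sprintf("QS%04d", .data$qs),
             wetland_id = sprintf("QS%04d-W%d", .data$qs, .data$w),
             hit = .data$qs <= detected & .data$w == 1) %>%
      select("qs_id", "wetland_id", "hit")
  }
  units_label <- if (matrix == "water") "ng/L" else "ug/kg"
  matrix_label <- matrix
  tibble(
    wetland_id = units_tbl$wetland_id,
    qs_id = units_tbl$qs_id,
    season = season,
    crop = crop,
    crop_prev = crop,
    matrix = matrix_label,
    ai = "clothianidin",
    measured = ifelse(units_tbl$hit, 10 * loq, 0),
    loq = loq,
    recovery = 1,
    units = units_label
  )
}
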