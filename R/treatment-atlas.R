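# Treatment atlas: estimated neonicotinoid seed-treatment use from a crop
# grid and a treatment registry. The per-pixel expected application rate is
# resolved_rate (g AI/ha) x treated_fraction; per-AI rasters are merged by
# summation; parcels approximate 65-ha quarter sections; summaries roll up
# treated area (ha), active-ingredient mass (kg) and rate categories.

#' Seed-treatment application rate
#'
#' Converts a seed loading (g active ingredient per kg seed) and a seeding
#' rate (kg seed per ha) into an application rate in g AI/ha. For example a
#' canola loading of 4.2 g/kg sown at 5 kg/ha gives 21 g AI/ha.
#'
#' @param seed_loading Grams of active ingredient per kilogram of seed (>= 0).
#' @param seeding_rate Kilograms of seed sown per hectare (>= 0).
#' @return Application rate in g AI/ha (vectorised).
#' @export
application_rate <- function(seed_loading, seeding_rate) {
  check_numeric_vec(seed_loading, "seed_loading", min = 0)
  check_numeric_vec(seeding_rate, "seeding_rate", min = 0)
  seed_loading * seeding_rate
}

#' Pixel area in hectares
#'
#' Area of one square raster pixel, in hectares: `resolution_m^2 / 10000`.
#' A 56-m pixel is 0.3136 ha; a 100-m pixel is exactly 1 ha.
#'
#' @param resolution_m Pixel edge length in metres (> 0).
#' @return Hectares per pixel.
#' @export
pixel_area_ha <- function(resolution_m) {
  check_numeric_vec(resolution_m, "resolution_m")
  if (any(resolution_m <= 0)) {
    abort_invalid("`resolution_m` must be > 0.")
  }
  resolution_m^2 / 1e4
}

#' Treatment registry
#'
#' Validates a table of per-(crop, active ingredient) treatment entries.
#' `resolved_rate_g_per_ha` is computed as seed loading x seeding rate when
#' both are given and the resolved column is empty; when all three are given
#' they must agree. Where product labels allow several rates, the registry is
#' expected to hold one value per (crop, AI) — conventionally the median of
#' the recommended rates, resolved before entry.
#'
#' @param entries Data frame with columns `crop_code`, `ai`,
#'   `treated_fraction`, and either `resolved_rate_g_per_ha` or both
#'   `seed_loading_g_per_kg` and `seeding_rate_kg_per_ha`. An optional
#'   `crop_name` column is carried through.
#' @return A validated tibble of class `treatment_registry`.
#' @export
treatment_registry <- function(entries) {
  entries <- as_tibble(entries)
  check_columns(entries, c("crop_code", "ai", "treated_fraction"),
                "treatment registry")
  if (nrow(entries) == 0) {
    abort_invalid("treatment registry must contain at least one entry.")
  }
  for (col in c("seed_loading_g_per_kg", "seeding_rate_kg_per_ha",
                "resolved_rate_g_per_ha", "crop_name")) {
    if (!col %in% names(entries)) {
      entries[[col]] <- if (col == "crop_name") NA_character_ else NA_real_
    }
  }
  entries$crop_code <- as.integer(entries$crop_code)
  both <- !is.na(entries$seed_loading_g_per_kg) &
    !is.na(entries$seeding_rate_kg_per_ha)
  product <- ifelse(both,
                    entries$seed_loading_g_per_kg * entries$seeding_rate_kg_per_ha,
                    NA_real_)
  resolved <- entries$resolved_rate_g_per_ha
  conflict <- both & !is.na(resolved) &
    abs(resolved - product) > 1e-8 * pmax(1, abs(product))
  if (any(conflict)) {
    abort_invalid(sprintf(
      "registry rows %s: resolved_rate_g_per_ha contradicts seed loading x seeding rate.",
      paste(which(conflict), collapse = ", ")))
  }
  resolved[is.na(resolved)] <- product[is.na(resolved)]
  if (any(is.na(resolved))) {
    abort_invalid(sprintf(
      "registry rows %s: need resolved_rate_g_per_ha or both seed loading and seeding rate.",
      paste(which(is.na(resolved)), collapse = ", ")))
  }
  if (any(resolved < 0) || any(!is.finite(resolved))) {
    abort_invalid("resolved application rates must be finite and >= 0.")
  }
  if (any(is.na(entries$treated_fraction)) ||
      any(entries$treated_fraction < 0) || any(entries$treated_fraction > 1)) {
    abort_invalid("`treated_fraction` must lie in [0, 1].")
  }
  key <- paste(entries$crop_code, entries$ai)
  if (anyDuplicated(key)) {
    abort_invalid(sprintf("duplicate registry entries for (crop_code, ai): %s",
                          paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  entries$resolved_rate_g_per_ha <- resolved
  class(entries) <- c("treatment_registry", class(entries))
  entries
}

#' Read a treatment registry from CSV
#'
#' Expected header: `crop_code,crop_name,ai,seed_loading_g_per_kg,`
#' `seeding_rate_kg_per_ha,resolved_rate_g_per_ha,treated_fraction`.
#'
#' @param path CSV file path.
#' @return A [treatment_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("registry file not found: %s", path))
  treatment_registry(read.csv(path, stringsAsFactors = FALSE))
}

#' Build a per-pixel expected-use raster for one active ingredient
#'
#' Each pixel whose crop has a registry entry for `ai_name` receives the
#' expected rate `resolved_rate x treated_fraction` (g AI/ha) and the entry's
#' treated fraction; all other pixels (other crops, crops without an entry
#' for this AI, non-cropland) carry 0.
#'
#' @param grid A [crop_grid()].
#' @param registry A [treatment_registry()] (or data frame coercible to one).
#' @param ai_name Active ingredient to map; must occur in the registry.
#' @return A [use_raster()] labelled with `ai_name`.
#' @export
build_use_raster <- function(grid, registry, ai_name) {
  stopifnot(inherits(grid, "crop_grid"))
  if (!inherits(registry, "treatment_registry")) {
    registry <- treatment_registry(registry)
  }
  if (grid$nodata_code %in% registry$crop_code) {
    abort_config(sprintf(
      "registry uses crop code %d, which is the grid's nodata code.",
      grid$nodata_code))
  }
  if (!ai_name %in% registry$ai) {
    abort_invalid(sprintf("active ingredient '%s' has no registry entries.",
                          ai_name))
  }
  sub <- registry[registry$ai == ai_name, ]
  idx <- match(grid$codes, sub$crop_code)
  frac <- ifelse(is.na(idx), 0, sub$treated_fraction[idx])
  rate <- ifelse(is.na(idx), 0, sub$resolved_rate_g_per_ha[idx]) * frac
  dim(frac) <- dim(rate) <- dim(grid$codes)
  use_raster(rate, frac, grid$resolution_m, grid$year, ai_label = ai_name)
}

#' Merge per-AI use rasters into a total-use raster
#'
#' Per-pixel rates are summed across active ingredients. The merged treated
#' fraction is the per-pixel maximum of the component fractions: a pixel
#' counts as treated if any AI treats it.
#'
#' @param rasters List of [use_raster()] objects sharing shape, resolution
#'   and year.
#' @return A [use_raster()] with `ai_label = "total"`.
#' @export
merge_use_rasters <- function(rasters) {
  if (!is.list(rasters) || length(rasters) == 0 ||
      !all(vapply(rasters, inherits, logical(1), "use_raster"))) {
    abort_invalid("`rasters` must be a non-empty list of use_raster objects.")
  }
  ref <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!identical(dim(r$rates), dim(ref$rates)) ||
        r$resolution_m != ref$resolution_m ||
        !identical(r$year, ref$year)) {
      abort_incompatible(
        "use rasters must share shape, resolution and year to be merged.")
    }
  }
  rates <- Reduce(`+`, lapply(rasters, `[[`, "rates"))
  fracs <- Reduce(pmax, lapply(rasters, `[[`, "fractions"))
  use_raster(rates, fracs, ref$resolution_m, ref$year, ai_label = "total")
}

#' Aggregate a use raster to quarter-section parcels
#'
#' Tiles the raster into axis-aligned square blocks whose pixel count best
#' approximates the target parcel area (65 ha, a quarter section, by
#' default); at 100-m resolution this gives 8 x 8-pixel, 64-ha blocks. Edge
#' blocks are truncated and keep their true (smaller) area.
#'
#' @param raster A [use_raster()].
#' @param qs_target_ha Target parcel area in hectares (> 0).
#' @return A tibble with one row per parcel: `block_row`, `block_col`,
#'   `n_pixels`, `area_ha`, and `rate` (the area-weighted mean expected rate,
#'   g AI/ha).
#' @export
aggregate_quarter_sections <- function(raster, qs_target_ha = 65) {
  stopifnot(inherits(raster, "use_raster"))
  check_number(qs_target_ha, "qs_target_ha", min = 0, min_open = TRUE)
  px_ha <- pixel_area_ha(raster$resolution_m)
  if (qs_target_ha < px_ha) {
    abort_invalid(sprintf(
      "target parcel (%g ha) is smaller than one %g-m pixel (%g ha).",
      qs_target_ha, raster$resolution_m, px_ha))
  }
  block <- max(1L, as.integer(round(sqrt(qs_target_ha * 1e4) /
                                      raster$resolution_m)))
  nr <- nrow(raster$rates)
  nc <- ncol(raster$rates)
  row_starts <- seq(1L, nr, by = block)
  col_starts <- seq(1L, nc, by = block)
  out <- vector("list", length(row_starts) * length(col_starts))
  k <- 1L
  for (i in seq_along(row_starts)) {
    rows <- row_starts[i]:min(row_starts[i] + block - 1L, nr)
    for (j in seq_along(col_starts)) {
      cols <- col_starts[j]:min(col_starts[j] + block - 1L, nc)
      vals <- raster$rates[rows, cols]
      out[[k]] <- tibble(block_row = i, block_col = j,
                         n_pixels = length(vals),
                         area_ha = length(vals) * px_ha,
                         rate = mean(vals))
      k <- k + 1L
    }
  }
  bind_rows(out)
}

#' Application-rate categories
#'
#' Validates a set of rate bins. Bins are half-open upper-inclusive
#' intervals `(lower, upper]`; together they must partition `(min(lower),
#' max(upper)]` with no gaps or overlap.
#'
#' @param df Data frame with columns `name`, `lower` and `upper` (g AI/ha).
#' @return A tibble of class `rate_categories`, ordered by `lower`.
#' @export
rate_categories <- function(df) {
  df <- as_tibble(df)
  check_columns(df, c("name", "lower", "upper"), "rate categories")
  if (nrow(df) == 0) abort_invalid("at least one rate category is required.")
  df <- df[order(df$lower), ]
  if (any(df$upper <= df$lower)) {
    abort_invalid("each category must have upper > lower.")
  }
  if (df$lower[1] < 0) abort_invalid("category bounds must be >= 0.")
  if (nrow(df) > 1 && any(abs(df$lower[-1] - df$upper[-nrow(df)]) > 1e-12)) {
    abort_invalid("rate categories must partition the range: gaps or overlaps found.")
  }
  class(df) <- c("rate_categories", class(df))
  df
}

#' Default rate categories
#'
#' The five standard application-rate bins, in g AI/ha: Low (0, 1.25],
#' Low-Medium (1.25, 4], Medium (4, 10.5], Medium-High (10.5, 26] and
#' High (26, 70]. A boundary rate such as 4 g/ha falls in the lower-labelled
#' bin (Low-Medium), since bins are upper-inclusive.
#'
#' @return A [rate_categories()] tibble.
#' @export
default_rate_categories <- function() {
  rate_categories(tibble(
    name = c("Low", "Low-Medium", "Medium", "Medium-High", "High"),
    lower = c(0, 1.25, 4, 10.5, 26),
    upper = c(1.25, 4, 10.5, 26, 70)
  ))
}

#' Read rate categories from CSV
#'
#' Expected header: `name,lower_g_per_ha,upper_g_per_ha`.
#'
#' @param path CSV file path.
#' @return A [rate_categories()] tibble.
#' @export
read_rate_categories <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("categories file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("name", "lower_g_per_ha", "upper_g_per_ha"),
                "rate categories CSV")
  rate_categories(tibble(name = df$name, lower = df$lower_g_per_ha,
                         upper = df$upper_g_per_ha))
}

#' Assign treated units to rate categories
#'
#' Each unit (parcel or pixel) with rate > 0 falls in exactly one half-open
#' bin `(lower, upper]`; rate-0 units are untreated and excluded. Percentages
#' are of total treated area.
#'
#' @param units Data frame with numeric columns `rate` (g AI/ha) and
#'   `area_ha` (> 0), e.g. the output of [aggregate_quarter_sections()].
#' @param categories A [rate_categories()] tibble.
#' @return A tibble with one row per category: `name`, `lower`, `upper`,
#'   `area_ha` and `pct_within` (share of treated area, unrounded).
#' @export
categorize_rates <- function(units, categories = default_rate_categories()) {
  units <- as_tibble(units)
  check_columns(units, c("rate", "area_ha"), "rate units")
  if (!inherits(categories, "rate_categories")) {
    categories <- rate_categories(categories)
  }
  if (any(units$area_ha <= 0)) {
    abort_invalid("unit areas must be > 0.")
  }
  top <- max(categories$upper)
  if (any(units$rate > top)) {
    abort_range(sprintf(
      "rate %g g/ha exceeds the top category bound (%g g/ha).",
      max(units$rate), top))
  }
  treated <- units[units$rate > 0, ]
  breaks <- c(categories$lower[1], categories$upper)
  bin <- cut(treated$rate, breaks = breaks, labels = categories$name,
             right = TRUE, include.lowest = FALSE)
  area <- vapply(categories$name, function(nm) {
    sum(treated$area_ha[!is.na(bin) & bin == nm])
  }, numeric(1))
  total <- sum(area)
  tibble(name = categories$name,
         lower = categories$lower,
         upper = categories$upper,
         area_ha = unname(area),
         pct_within = if (total > 0) 100 * unname(area) / total else rep(0, length(area)))
}

#' Summarise a use raster
#'
#' Rolls a total-use raster up to the headline quantities: treated area
#' (fraction-weighted hectares over pixels with a positive expected rate),
#' total active-ingredient mass (kg), a per-category area breakdown, and the
#' treated percentage of total cropland. Mass equals the sum over treated
#' pixels of expected rate (g/ha) x pixel area (ha) / 1000; because the
#' expected rate already carries the treated fraction, this is the resolved
#' label rate applied to the fraction-weighted treated area.
#'
#' @param raster A [use_raster()] (typically the merged total).
#' @param categories A [rate_categories()] tibble.
#' @param total_cropland_ha Total cropland denominator in hectares (> 0),
#'   typically a survey-based estimate supplied by the user; non-cropland
#'   pixels never enter this denominator implicitly.
#' @return An object of class `use_summary`: a list with `categories`
#'   (per-category fraction-weighted treated area and percentages),
#'   `treated_area_ha`, `mass_kg`, `percent_of_cropland` (unrounded),
#'   `total_cropland_ha`, `ai_label` and `year`.
#' @export
summarize_use <- function(raster, categories = default_rate_categories(),
                          total_cropland_ha) {
  stopifnot(inherits(raster, "use_raster"))
  check_number(total_cropland_ha, "total_cropland_ha", min = 0, min_open = TRUE)
  px_ha <- pixel_area_ha(raster$resolution_m)
  mask <- raster$rates > 0
  treated_area <- sum(raster$fractions[mask]) * px_ha
  mass_kg <- sum(raster$rates[mask]) * px_ha / 1000
  units <- tibble(rate = as.numeric(raster$rates[mask]),
                  area_ha = as.numeric(raster$fractions[mask]) * px_ha)
  units <- units[units$area_ha > 0, ]
  cat_tbl <- categorize_rates(units, categories)
  structure(
    list(categories = cat_tbl,
         treated_area_ha = treated_area,
         mass_kg = mass_kg,
         percent_of_cropland = 100 * treated_area / total_cropland_ha,
         total_cropland_ha = total_cropland_ha,
         ai_label = raster$ai_label,
         year = raster$year),
    class = "use_summary"
  )
}

#' @export
print.use_summary <- function(x, ...) {
  cat(sprintf("<use_summary> %s (year %s)\n", x$ai_label,
              ifelse(is.na(x$year), "?", x$year)))
  cat(sprintf("  treated area: %.4g ha (%s%% of %.4g ha cropland)\n",
              x$treated_area_ha,
              round_half_up(x$percent_of_cropland),
              x$total_cropland_ha))
  cat(sprintf("  AI mass:      %.4g kg\n", x$mass_kg))
  print(as.data.frame(x$categories), row.names = FALSE)
  invisible(x)
}

#' Treated percentage of cropland
#'
#' Reporting convention: percentage of total cropland treated, rounded
#' half-up to an integer (10.993 Mha of 25 Mha cropland is 44%).
#'
#' @param treated_area_ha Treated area (ha or any unit shared with the denominator).
#' @param total_cropland_ha Total cropland in the same unit (> 0).
#' @return Integer-rounded percentage.
#' @export
treated_percent <- function(treated_area_ha, total_cropland_ha) {
  check_number(treated_area_ha, "treated_area_ha", min = 0)
  check_number(total_cropland_ha, "total_cropland_ha", min = 0, min_open = TRUE)
  round_half_up(100 * treated_area_ha / total_cropland_ha)
}
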