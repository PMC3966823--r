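# Shared fixtures and independent brute-force oracles. The oracles use plain
# per-pixel / per-pair loops so they stay independent of the implementation
# paths they check.

make_registry <- function() {
  treatment_registry(tibble::tibble(
    crop_code = c(1L, 1L, 2L, 3L),
    crop_name = c("canola", "canola", "barley", "bean"),
    ai = c("thiamethoxam", "clothianidin", "thiamethoxam", "imidacloprid"),
    resolved_rate_g_per_ha = c(21, 21, 13, 26),
    treated_fraction = c(0.5, 0.4, 1, 0.8)
  ))
}

uniform_grid <- function(code, n = 10, res = 100, nodata = 0L) {
  crop_grid(matrix(as.integer(code), n, n), resolution_m = res,
            year = 2012L, nodata_code = nodata)
}

random_grid <- function(nrow, ncol, codes = 0:3, res = 100) {
  crop_grid(matrix(sample(as.integer(codes), nrow * ncol, replace = TRUE),
                   nrow, ncol),
            resolution_m = res, year = 2012L, nodata_code = 0L)
}

# Per-pixel enumeration oracle for expected rate and fraction of one AI.
oracle_pixel_maps <- function(grid, registry, ai) {
  nr <- nrow(grid$codes)
  nc <- ncol(grid$codes)
  rate <- matrix(0, nr, nc)
  frac <- matrix(0, nr, nc)
  sub <- as.data.frame(registry[registry$ai == ai, ])
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      code <- grid$codes[i, j]
      hit <- which(sub$crop_code == code)
      if (length(hit) == 1) {
        frac[i, j] <- sub$treated_fraction[hit]
        rate[i, j] <- sub$resolved_rate_g_per_ha[hit] * frac[i, j]
      }
    }
  }
  list(rate = rate, frac = frac)
}

# Enumeration oracle for the merged-total summary quantities.
oracle_total_summary <- function(grid, registry, cropland_ha,
                                 categories = default_rate_categories()) {
  ais <- unique(registry$ai)
  maps <- lapply(ais, function(a) oracle_pixel_maps(grid, registry, a))
  nr <- nrow(grid$codes)
  nc <- ncol(grid$codes)
  px_ha <- grid$resolution_m^2 / 1e4
  treated_area <- 0
  mass_kg <- 0
  cat_area <- setNames(numeric(nrow(categories)), categories$name)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rate <- sum(vapply(maps, function(m) m$rate[i, j], numeric(1)))
      frac <- max(vapply(maps, function(m) m$frac[i, j], numeric(1)))
      if (rate > 0) {
        treated_area <- treated_area + frac * px_ha
        mass_kg <- mass_kg + rate * px_ha / 1000
        if (frac > 0) {
          for (b in seq_len(nrow(categories))) {
            if (rate > categories$lower[b] && rate <= categories$upper[b]) {
              cat_area[b] <- cat_area[b] + frac * px_ha
            }
          }
        }
      }
    }
  }
  list(treated_area_ha = treated_area, mass_kg = mass_kg,
       percent = 100 * treated_area / cropland_ha, cat_area = cat_area)
}

# Exhaustive pair-count Mann-Whitney oracle: U_a = #(a > b) + 0.5 #(a == b).
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Minimal one-sample panel: one row per AI with recovery 1 and default LOQs.
one_sample_panel <- function(measured, season = "summer2012", crop = "canola",
                             matrix = "water", wetland = "W1", qs = "QS1") {
  loqs <- loq_defaults()
  ais <- names(measured)
  units_label <- if (matrix == "water") "ng/L" else "ug/kg"
  tibble::tibble(
    wetland_id = wetland, qs_id = qs, season = season, crop = crop,
    crop_prev = crop, matrix = matrix, ai = ais,
    measured = unname(measured), loq = unname(loqs[ais]),
    recovery = 1, units = units_label
  )
}

# Cell-mean matrices used by the simulation studies (fixed truth values).
recovery_truth_cells <- function() {
  m <- rbind(
    grassland = c(2.5, 3.5, 2.5, 3.5),
    barley    = c(2.5, 5.5, 4.5, 5.5),
    canola    = c(2.5, 4.5, 3.5, 4.5),
    oat       = c(2.5, 4.5, 3.5, 4.5),
    pea       = c(2.5, 4.5, 3.5, 4.5),
    wheat     = c(2.5, 4.5, 3.5, 4.5)
  )
  colnames(m) <- season_levels()
  m
}

null_truth_cells <- function() {
  m <- matrix(3.5, nrow = 6, ncol = 4,
              dimnames = list(crop_levels(), season_levels()))
  m
}
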