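# Unit and property tests for the seed-treatment use atlas.

test_that("application_rate multiplies seed loading by seeding rate", {
  expect_identical(application_rate(0, 5.0), 0)
  expect_equal(application_rate(4.2, 5.0), 21.0)
  expect_equal(application_rate(2.6, 5.0), 13.0)
  expect_error(application_rate(-1, 5), class = "neonicr_invalid_parameter")
  expect_error(application_rate(1, Inf), class = "neonicr_invalid_parameter")
})

test_that("pixel_area_ha converts resolution to hectares", {
  expect_equal(pixel_area_ha(100), 1.0)
  expect_equal(pixel_area_ha(56), 0.3136)
  expect_equal(pixel_area_ha(30), 0.09)
  expect_error(pixel_area_ha(0), class = "neonicr_invalid_parameter")
  expect_error(pixel_area_ha(-30), class = "neonicr_invalid_parameter")
})

test_that("treatment_registry validates and resolves rates", {
  reg <- treatment_registry(tibble::tibble(
    crop_code = 1L, ai = "thiamethoxam",
    seed_loading_g_per_kg = 4.2, seeding_rate_kg_per_ha = 5,
    treated_fraction = 1))
  expect_equal(reg$resolved_rate_g_per_ha, 21)
  expect_error(
    treatment_registry(tibble::tibble(
      crop_code = 1L, ai = "thiamethoxam",
      seed_loading_g_per_kg = 4.2, seeding_rate_kg_per_ha = 5,
      resolved_rate_g_per_ha = 30, treated_fraction = 1)),
    class = "neonicr_invalid_parameter")
  expect_error(
    treatment_registry(tibble::tibble(
      crop_code = c(1L, 1L), ai = "thiamethoxam",
      resolved_rate_g_per_ha = c(21, 21), treated_fraction = 1)),
    class = "neonicr_invalid_parameter")
  expect_error(
    treatment_registry(tibble::tibble(
      crop_code = 1L, ai = "x", resolved_rate_g_per_ha = 21,
      treated_fraction = 1.2)),
    class = "neonicr_invalid_parameter")
})

test_that("build_use_raster fills expected rates and fractions", {
  reg <- make_registry()
  g <- uniform_grid(1L)  # all canola
  full <- build_use_raster(g, treatment_registry(tibble::tibble(
    crop_code = 1L, ai = "thiamethoxam", resolved_rate_g_per_ha = 21,
    treated_fraction = 1)), "thiamethoxam")
  expect_true(all(full$rates == 21))
  expect_true(all(full$fractions == 1))

  half <- build_use_raster(g, reg, "thiamethoxam")  # canola fraction 0.5
  oracle <- oracle_pixel_maps(g, reg, "thiamethoxam")
  expect_equal(half$rates, oracle$rate)    # 10.5 everywhere
  expect_equal(half$fractions, oracle$frac)
  expect_true(all(half$rates == 10.5))

  empty <- build_use_raster(uniform_grid(0L), reg, "thiamethoxam")
  expect_true(all(empty$rates == 0))
  expect_true(all(empty$fractions == 0))

  expect_error(build_use_raster(g, reg, "acetamiprid"),
               class = "neonicr_invalid_parameter")
  bad <- uniform_grid(1L, nodata = 2L)  # nodata code collides with barley
  expect_error(build_use_raster(bad, reg, "thiamethoxam"),
               class = "neonicr_configuration_error")
})

test_that("merge_use_rasters sums rates and maxes fractions, any order", {
  g <- uniform_grid(1L, n = 6)
  a <- use_raster(matrix(21, 6, 6), matrix(0.5, 6, 6), 100, 2012L, "thiamethoxam")
  b <- use_raster(matrix(13, 6, 6), matrix(0.8, 6, 6), 100, 2012L, "clothianidin")
  zero <- use_raster(matrix(0, 6, 6), matrix(0, 6, 6), 100, 2012L, "imidacloprid")

  expect_equal(merge_use_rasters(list(a, zero))$rates, a$rates)
  m <- merge_use_rasters(list(a, b))
  expect_true(all(m$rates == 34))
  expect_true(all(m$fractions == 0.8))
  expect_identical(m$ai_label, "total")

  withr::local_seed(11)
  rs <- lapply(1:3, function(i) {
    use_raster(matrix(runif(36, 0, 30), 6, 6), matrix(runif(36), 6, 6),
               100, 2012L, paste0("ai", i))
  })
  m1 <- merge_use_rasters(rs)
  m2 <- merge_use_rasters(rs[c(3, 1, 2)])
  expect_equal(m1$rates, m2$rates)
  expect_equal(m1$fractions, m2$fractions)

  small <- use_raster(matrix(1, 3, 3), matrix(1, 3, 3), 100, 2012L, "x")
  expect_error(merge_use_rasters(list(a, small)),
               class = "neonicr_incompatible_raster")
})

test_that("aggregate_quarter_sections tiles, truncates and averages", {
  u <- use_raster(matrix(21, 16, 16), matrix(1, 16, 16), 100, 2012L, "total")
  p <- aggregate_quarter_sections(u)
  expect_true(all(p$rate == 21))
  expect_true(all(p$n_pixels == 64))  # 8x8 blocks at 100 m

  # half the pixels in one 8x8 parcel at 20 g/ha, half untreated
  m <- matrix(0, 8, 8)
  m[, 1:4] <- 20
  u2 <- use_raster(m, (m > 0) * 1, 100, 2012L, "total")
  expect_equal(aggregate_quarter_sections(u2)$rate, 10)

  # 10x10 raster with 8-pixel blocks: parcel areas 64, 16, 16, 4 ha
  u3 <- use_raster(matrix(5, 10, 10), matrix(1, 10, 10), 100, 2012L, "total")
  p3 <- aggregate_quarter_sections(u3)
  expect_setequal(p3$area_ha, c(64, 16, 16, 4))
  expect_equal(sum(p3$area_ha), 100)

  expect_error(aggregate_quarter_sections(u, qs_target_ha = 0.5),
               class = "neonicr_invalid_parameter")
})

test_that("categorize_rates uses half-open upper-inclusive bins", {
  units <- tibble::tibble(rate = c(21, 0, 4), area_ha = c(10, 10, 10))
  out <- categorize_rates(units)
  expect_equal(out$area_ha[out$name == "Medium-High"], 10)  # 21 g/ha
  expect_equal(out$area_ha[out$name == "Low-Medium"], 10)   # boundary 4 g/ha
  expect_equal(sum(out$area_ha), 20)                        # rate 0 excluded
  expect_error(categorize_rates(tibble::tibble(rate = 80, area_ha = 1)),
               class = "neonicr_out_of_range")
})

test_that("every positive rate lands in exactly one category", {
  withr::local_seed(21)
  cats <- default_rate_categories()
  rates <- runif(500, 1e-9, 70)
  for (r in sample(rates, 50)) {
    hits <- sum(r > cats$lower & r <= cats$upper)
    expect_identical(hits, 1L)
  }
  out <- categorize_rates(tibble::tibble(rate = rates, area_ha = 1), cats)
  expect_equal(sum(out$area_ha), 500)
  expect_equal(sum(out$pct_within), 100)
})

test_that("summarize_use computes area, mass and conserves category areas", {
  u <- use_raster(matrix(21, 10, 10), matrix(1, 10, 10), 100, 2012L, "total")
  s <- summarize_use(u, total_cropland_ha = 200)
  expect_equal(s$treated_area_ha, 100)
  expect_equal(s$mass_kg, 2.1)
  expect_equal(s$percent_of_cropland, 50)
  expect_error(summarize_use(u, total_cropland_ha = 0),
               class = "neonicr_invalid_parameter")

  # area conservation on random rasters
  withr::local_seed(31)
  for (i in 1:5) {
    g <- random_grid(12, 9)
    tot <- merge_use_rasters(lapply(unique(make_registry()$ai),
                                    function(a) build_use_raster(g, make_registry(), a)))
    s <- summarize_use(tot, total_cropland_ha = 500)
    expect_equal(sum(s$categories$area_ha), s$treated_area_ha,
                 tolerance = 1e-6)
  }
})

test_that("mass is linear in rates and monotone in treated fractions", {
  withr::local_seed(41)
  g <- random_grid(15, 15)
  reg <- make_registry()
  build_total <- function(r) {
    merge_use_rasters(lapply(unique(r$ai), function(a) build_use_raster(g, r, a)))
  }
  s1 <- summarize_use(build_total(reg), total_cropland_ha = 500)

  reg2 <- reg
  reg2$resolved_rate_g_per_ha <- reg2$resolved_rate_g_per_ha * 2
  s2 <- summarize_use(build_total(treatment_registry(tibble::as_tibble(reg2))),
                      total_cropland_ha = 500)
  expect_equal(s2$mass_kg, 2 * s1$mass_kg)
  expect_equal(s2$treated_area_ha, s1$treated_area_ha)

  reg3 <- reg
  reg3$treated_fraction <- pmin(1, reg3$treated_fraction + 0.3)
  s3 <- summarize_use(build_total(treatment_registry(tibble::as_tibble(reg3))),
                      total_cropland_ha = 500)
  expect_gte(s3$treated_area_ha, s1$treated_area_ha)
  expect_gte(s3$mass_kg, s1$mass_kg)
})

test_that("treated_percent rounds half-up", {
  expect_identical(treated_percent(75.5, 100), 76)
  expect_identical(treated_percent(36, 100), 36)
})
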