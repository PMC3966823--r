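# Mixed model, AIC selection, interaction contrasts, Sidak correction and
# Mann-Whitney U.

test_that("sidak_adjust matches the closed form and its bounds", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.05, 10), 1 - 0.95^0.1)
  expect_equal(sidak_adjust(0.05, 10), 0.0051162, tolerance = 1e-5)
  withr::local_seed(8)
  for (i in 1:25) {
    alpha <- runif(1, 0.001, 0.2)
    k <- sample(1:50, 1)
    adj <- sidak_adjust(alpha, k)
    expect_gte(adj, alpha / k - 1e-12)
    expect_lte(adj, alpha + 1e-12)
  }
  expect_error(sidak_adjust(0.05, 0), class = "neonicr_invalid_parameter")
  expect_error(sidak_adjust(1, 3), class = "neonicr_invalid_parameter")
})

test_that("mann_whitney_u counts pairs and is symmetric", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)
  withr::local_seed(18)
  for (i in 1:200) {
    na <- sample(1:8, 1)
    nb <- sample(1:8, 1)
    a <- sample(1:6, na, replace = TRUE)  # integer values force ties
    b <- sample(1:6, nb, replace = TRUE)
    res <- mann_whitney_u(a, b)
    expect_equal(res$U, oracle_u(a, b))
    expect_equal(res$U + res$U_other, na * nb)
    expect_equal(mann_whitney_u(b, a)$U, res$U_other)
    expect_true(res$p >= 0 && res$p <= 1)
  }
  expect_error(mann_whitney_u(numeric(0), 1), class = "neonicr_empty_group")
})

test_that("with no random effects the fit matches the normal equations", {
  sim <- gen_residue_panel(panel_config(n_qs = 15, seed = 12,
                                        cell_means = recovery_truth_cells()))
  spec <- lmm_spec(re_structure = "none")
  md <- build_model_data(sim$panel, spec)
  fit <- fit_lmm(md, spec)
  X <- model.matrix(stats::as.formula(fit$formula), md)
  beta_hat <- solve(crossprod(X), crossprod(X, md$y))
  expect_equal(unname(fit$beta[colnames(X)]), unname(beta_hat[, 1]),
               tolerance = 1e-6)
})

test_that("a constant response yields zero effects and zero residual variance", {
  sim <- gen_residue_panel(panel_config(
    n_qs = 15, seed = 14, sigma_qs = 0, sigma_wetland = 0, sigma_resid = 0,
    cell_means = null_truth_cells(), drawdown_prob = 0))
  # a constant baseline covariate would be aliased with the intercept
  spec <- lmm_spec(re_structure = "none", use_baseline = FALSE,
                   use_prev_crop = FALSE)
  md <- build_model_data(sim$panel, spec)
  expect_lt(diff(range(md$y)), 1e-8)
  # lm warns about the (intended) perfect fit
  fit <- suppressWarnings(fit_lmm(md, spec))
  est <- fit$beta[!grepl("Intercept", names(fit$beta))]
  expect_true(all(abs(est) < 1e-6))
  expect_lt(fit$varcomp$variance[fit$varcomp$group == "Residual"], 1e-12)
})

test_that("degenerate structures and aliased designs raise classed errors", {
  sim <- gen_residue_panel(panel_config(n_qs = 25, seed = 19,
                                        cell_means = recovery_truth_cells()))
  spec <- lmm_spec(re_structure = "nested")
  md <- build_model_data(sim$panel, spec)

  one_qs <- md[md$qs_id == md$qs_id[1], ]
  expect_error(fit_lmm(one_qs, spec), class = "neonicr_degenerate_structure")

  aliased <- md
  aliased$crop_prev <- aliased$crop  # previous crop duplicates current crop
  err <- expect_error(fit_lmm(aliased, spec),
                      class = "neonicr_estimability_error")
  expect_match(conditionMessage(err), "crop_prev")
})

test_that("the mixed model recovers a known crop effect", {
  sim <- gen_residue_panel(panel_config(n_qs = 50, seed = 2024,
                                        cell_means = recovery_truth_cells()))
  spec <- lmm_spec(re_structure = "nested")
  md <- build_model_data(sim$panel, spec)
  fit <- fit_lmm(md, spec)
  expect_true(fit$converged)
  row <- fit$coefficients[fit$coefficients$term == "cropbarley", ]
  expect_lt(abs(row$estimate - 2.0), 3 * row$se)
  expect_true(all(fit$varcomp$variance >= 0))
})

test_that("season-specific structure reports one variance per season and level", {
  sim <- gen_residue_panel(panel_config(n_qs = 30, seed = 41,
                                        cell_means = recovery_truth_cells()))
  spec <- lmm_spec(re_structure = "season_specific")
  md <- build_model_data(sim$panel, spec)
  fit <- fit_lmm(md, spec)
  vc <- fit$varcomp[fit$varcomp$group != "Residual", ]
  expect_identical(nrow(vc), 6L)  # 3 seasons x (quarter section, wetland)
  expect_true(all(table(vc$term)[levels(md$season)] == 2))
  expect_true(all(vc$variance >= 0))
})

test_that("AIC tie-breaking prefers fewer parameters", {
  expect_identical(neonicr:::choose_by_aic(c(312.4, 308.1), c(5, 8)), 2L)
  expect_identical(neonicr:::choose_by_aic(c(100, 100 + 1e-9), c(8, 5)), 2L)
  expect_identical(neonicr:::choose_by_aic(c(100, 100 + 1e-9, 100), c(8, 5, 5)), 2L)
})

test_that("select_random_effects picks the lowest-AIC converged candidate", {
  sim <- gen_residue_panel(panel_config(n_qs = 30, seed = 47,
                                        cell_means = recovery_truth_cells()))
  spec0 <- lmm_spec(re_structure = "nested")
  md <- build_model_data(sim$panel, spec0)
  candidates <- list(
    nested = lmm_spec(re_structure = "nested"),
    season_specific = lmm_spec(re_structure = "season_specific"),
    nested_slope = lmm_spec(re_structure = "nested", random_slope = TRUE)
  )
  sel <- suppressWarnings(select_random_effects(md, candidates))
  ok <- sel$aic_table[sel$aic_table$converged, ]
  expect_equal(min(ok$AIC), ok$AIC[ok$label == sel$label])
  expect_identical(nrow(sel$aic_table), 3L)
  expect_true(sel$fit$converged)
})

test_that("a true random slope is detected by AIC in most replicates", {
  withr::local_seed(53)
  wins <- 0
  n_rep <- 15
  for (rep in seq_len(n_rep)) {
    # bespoke simulator: nested intercepts plus a real per-wetland time slope
    n_qs <- 40
    qs <- tibble::tibble(qs_id = sprintf("Q%02d", 1:n_qs),
                         crop = rep(c("grassland", "canola"), length.out = n_qs),
                         b_q = rnorm(n_qs, 0, 0.6))
    w <- tidyr::crossing(qs_id = qs$qs_id, w = 1:3) |>
      dplyr::mutate(wetland_id = paste0(qs_id, "-", w),
                    b_w = rnorm(dplyr::n(), 0, 0.6),
                    slope = rnorm(dplyr::n(), 0, 0.8)) |>
      dplyr::left_join(qs, by = "qs_id")
    md <- tidyr::crossing(wetland_id = w$wetland_id,
                          season = c("summer2012", "fall2012", "spring2013")) |>
      dplyr::left_join(w, by = "wetland_id") |>
      dplyr::mutate(
        time_num = match(season, season_levels()),
        season = factor(season,
                        levels = c("summer2012", "fall2012", "spring2013")),
        crop = factor(crop, levels = c("grassland", "canola")),
        y = 3 + b_q + b_w + slope * time_num + rnorm(dplyr::n(), 0, 0.5))
    specs <- list(
      nested = lmm_spec(re_structure = "nested", use_baseline = FALSE,
                        use_prev_crop = FALSE, ref_crop = "grassland"),
      slope = lmm_spec(re_structure = "nested", random_slope = TRUE,
                       use_baseline = FALSE, use_prev_crop = FALSE,
                       ref_crop = "grassland"))
    sel <- suppressWarnings(select_random_effects(md, specs))
    if (sel$label == "slope") wins <- wins + 1
  }
  expect_gt(wins, n_rep / 2)
})

test_that("interaction contrasts flag the built-in seasonal drop", {
  cells <- null_truth_cells()
  cells["barley", "fall2012"] <- cells["barley", "summer2012"] - 2.5
  withr::local_seed(61)
  hits <- 0
  n_rep <- 15
  for (rep in seq_len(n_rep)) {
    sim <- gen_residue_panel(panel_config(
      n_qs = 50, cell_means = cells,
      seed = sample.int(1e6, 1)))
    spec <- lmm_spec(re_structure = "nested")
    fit <- try(fit_lmm(build_model_data(sim$panel, spec), spec), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ic <- interaction_contrasts(fit)
    sf <- ic[ic$season_a == "summer2012" & ic$season_b == "fall2012", ]
    if (sf$crop[which.max(sf$chisq)] == "barley") hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.9 * n_rep) - 1)
})

test_that("a cell contrasted with itself gives chi-square zero", {
  sim <- gen_residue_panel(panel_config(n_qs = 20, seed = 67,
                                        cell_means = recovery_truth_cells()))
  spec <- lmm_spec(re_structure = "nested")
  fit <- fit_lmm(build_model_data(sim$panel, spec), spec)
  self <- interaction_contrasts(
    fit, family = data.frame(crop = "canola", season_a = "fall2012",
                             season_b = "fall2012"))
  expect_equal(self$chisq, 0)
  expect_equal(self$p_value, 1)
  expect_error(
    interaction_contrasts(fit, family = data.frame(
      crop = "canola", season_a = "spring2012", season_b = "fall2012")),
    class = "neonicr_invalid_parameter")
})
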