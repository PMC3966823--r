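# Statistical inference on wetland residue panels: a Gaussian linear mixed
# model of log total neonicotinoid concentration with crop x season fixed
# effects, AIC-guided random-effect selection, Wald chi-square interaction
# contrasts with Dunn-Sidak family-wise correction, and a Mann-Whitney check
# for drawdown sampling effects.

#' Mixed-model specification
#'
#' Describes the model fitted to per-sample log totals. The response is
#' `log(total + delta)`; by default `delta` is half the smallest configured
#' LOQ, so non-detect totals (0) remain finite on the log scale. Fixed
#' effects are season, crop and their interaction, optionally plus the
#' baseline (pre-seeding spring) log concentration and the previous year's
#' crop. Random effects come in three structures:
#'
#' * `"season_specific"` — independent season-specific intercept variances
#'   for quarter section and for wetland nested within quarter section (one
#'   variance per season per grouping, the default for data analysis);
#' * `"nested"` — a single intercept variance for quarter section and one
#'   for wetland within quarter section;
#' * `"none"` — no random effects (ordinary least squares; useful as the
#'   degenerate limit and for checking against closed-form regression).
#'
#' @param re_structure Random-effect structure (see above).
#' @param random_slope Add a random slope of sampling time (season index)
#'   per wetland.
#' @param use_baseline Include the baseline-season log concentration as a
#'   covariate.
#' @param use_prev_crop Include the previous year's crop as a covariate.
#' @param delta Offset added before the log transform; `NULL` means half the
#'   smallest LOQ in `loq_defaults()`.
#' @param ref_season Reference season for fixed effects (default summer 2012).
#' @param ref_crop Reference crop stratum (default grassland).
#' @param baseline_season Season providing the baseline covariate; its rows
#'   are removed from the response.
#' @param reml Fit the final model by REML (`TRUE`, default) or ML.
#' @return A list of class `lmm_spec`.
#' @export
lmm_spec <- function(re_structure = c("season_specific", "nested", "none"),
                     random_slope = FALSE,
                     use_baseline = TRUE,
                     use_prev_crop = TRUE,
                     delta = NULL,
                     ref_season = "summer2012",
                     ref_crop = "grassland",
                     baseline_season = "spring2012",
                     reml = TRUE) {
  re_structure <- match.arg(re_structure)
  if (!is.null(delta)) check_number(delta, "delta", min = 0, min_open = TRUE)
  structure(
    list(re_structure = re_structure,
         random_slope = isTRUE(random_slope),
         use_baseline = isTRUE(use_baseline),
         use_prev_crop = isTRUE(use_prev_crop),
         delta = delta,
         ref_season = ref_season,
         ref_crop = ref_crop,
         baseline_season = baseline_season,
         reml = isTRUE(reml)),
    class = "lmm_spec"
  )
}

#' Build the model data table from a residue panel
#'
#' Collapses the panel to per-sample totals, log-transforms them with the
#' spec's offset, attaches each wetland's baseline-season log concentration
#' as a covariate, and drops the baseline season from the response rows.
#' Season and crop become factors with the spec's reference levels; a
#' numeric season index (`time_num`) is added for the optional random slope.
#'
#' @param panel Long-format sample table.
#' @param spec An [lmm_spec()].
#' @param matrix `"water"` or `"sediment"`.
#' @param loqs LOQ set used to derive the default `delta`.
#' @return Tibble with columns `y`, `season`, `crop`, `crop_prev`,
#'   `baseline_log`, `time_num`, `qs_id`, `wetland_id`, `total`.
#' @export
build_model_data <- function(panel, spec = lmm_spec(), matrix = "water",
                             loqs = loq_defaults()) {
  stopifnot(inherits(spec, "lmm_spec"))
  st <- sample_totals(panel, matrix = matrix)
  delta <- spec$delta %||% (min(loqs) / 2)
  seasons_all <- intersect(season_levels(), unique(st$season))
  if (length(seasons_all) == 0) seasons_all <- unique(st$season)
  base <- st[st$season == spec$baseline_season, ]
  base <- tibble(wetland_id = base$wetland_id,
                 baseline_log = log(base$total + delta))
  md <- st[st$season != spec$baseline_season, ]
  md <- left_join(md, base, by = "wetland_id")
  seasons <- setdiff(seasons_all, spec$baseline_season)
  if (!spec$ref_season %in% md$season) {
    abort_invalid(sprintf("reference season '%s' not present in the data.",
                          spec$ref_season))
  }
  if (!spec$ref_crop %in% md$crop) {
    abort_invalid(sprintf("reference crop '%s' not present in the data.",
                          spec$ref_crop))
  }
  season_lv <- c(spec$ref_season, setdiff(seasons, spec$ref_season))
  crop_lv <- unique(c(spec$ref_crop, sort(unique(md$crop))))
  crop_lv <- intersect(crop_lv, unique(md$crop))
  md$y <- log(md$total + delta)
  md$season <- factor(md$season, levels = season_lv)
  md$crop <- factor(md$crop, levels = crop_lv)
  md$time_num <- match(as.character(md$season), seasons_all)
  if (spec$use_prev_crop) {
    prev_lv <- unique(c(spec$ref_crop, sort(unique(md$crop_prev))))
    prev_lv <- intersect(prev_lv, unique(md$crop_prev))
    md$crop_prev <- factor(md$crop_prev, levels = prev_lv)
  }
  if (spec$use_baseline) {
    n_missing <- sum(is.na(md$baseline_log))
    if (n_missing > 0) {
      message(sprintf(
        "dropping %d sample(s) from wetlands without a %s baseline.",
        n_missing, spec$baseline_season))
      md <- md[!is.na(md$baseline_log), ]
    }
  }
  droplevels(md)
}

fixed_formula_string <- function(spec) {
  rhs <- "season * crop"
  if (spec$use_baseline) rhs <- paste(rhs, "+ baseline_log")
  if (spec$use_prev_crop) rhs <- paste(rhs, "+ crop_prev")
  paste("y ~", rhs)
}

re_terms <- function(spec, season_lv) {
  if (spec$re_structure == "none") {
    terms <- character(0)
  } else if (spec$re_structure == "nested") {
    terms <- c("(1 | qs_id)", "(1 | qs_id:wetland_id)")
  } else {
    terms <- unlist(lapply(seq_along(season_lv), function(i) {
      c(sprintf("(0 + .season_ind_%d | qs_id)", i),
        sprintf("(0 + .season_ind_%d | qs_id:wetland_id)", i))
    }))
  }
  if (spec$random_slope) {
    terms <- c(terms, "(0 + time_num | qs_id:wetland_id)")
  }
  terms
}

n_re_params <- function(spec, n_seasons) {
  k <- switch(spec$re_structure,
              none = 0L,
              nested = 2L,
              season_specific = 2L * n_seasons)
  k + as.integer(spec$random_slope)
}

#' Fit the Gaussian linear mixed model
#'
#' Fits the model described by `spec` to a table from [build_model_data()].
#' Mixed structures are estimated by (RE)ML; season-specific intercept
#' variances are realised as independent per-season indicator random terms,
#' so the fit reports one variance per season for the quarter-section level
#' and one per season for wetlands nested within quarter sections.
#' Satterthwaite degrees of freedom are used for coefficient t statistics.
#' Non-convergence triggers up to three restarts from jittered parameters
#' and is flagged in the result — never silently ignored. A singular fit
#' (a variance estimated at exactly zero) is legitimate and reported via the
#' `singular` flag.
#'
#' @param data Model table from [build_model_data()] (columns `y`, `season`,
#'   `crop`, `qs_id`, `wetland_id`, plus covariates the spec uses).
#' @param spec An [lmm_spec()].
#' @return An object of class `lmm_fit`: coefficient table (estimate, SE,
#'   Satterthwaite df, t, p), fixed-effect covariance, variance components,
#'   log-likelihood, AIC, parameter count, convergence/singularity flags,
#'   and the underlying model object.
#' @export
fit_lmm <- function(data, spec = lmm_spec()) {
  stopifnot(inherits(spec, "lmm_spec"))
  data <- as_tibble(data)
  need <- c("y", "season", "crop", "qs_id", "wetland_id")
  if (spec$use_baseline) need <- c(need, "baseline_log")
  if (spec$use_prev_crop) need <- c(need, "crop_prev")
  if (spec$random_slope) need <- c(need, "time_num")
  check_columns(data, need, "model data")
  data$season <- droplevels(as.factor(data$season))
  data$crop <- droplevels(as.factor(data$crop))
  if (spec$use_prev_crop) data$crop_prev <- droplevels(as.factor(data$crop_prev))
  season_lv <- levels(data$season)
  if (length(season_lv) < 2) {
    abort_degenerate("need at least two seasons to fit the model.")
  }
  if (spec$re_structure != "none") {
    if (length(unique(data$qs_id)) < 2) {
      abort_degenerate("random quarter-section intercepts need >= 2 quarter sections.")
    }
    if (length(unique(paste(data$qs_id, data$wetland_id))) < 2) {
      abort_degenerate("random wetland intercepts need >= 2 wetlands.")
    }
  }

  fixed_str <- fixed_formula_string(spec)
  X <- model.matrix(as.formula(fixed_str), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_estimability(sprintf(
      "fixed-effect design is rank deficient; aliased term(s): %s",
      paste(aliased, collapse = ", ")))
  }

  md <- data
  for (i in seq_along(season_lv)) {
    md[[sprintf(".season_ind_%d", i)]] <- as.numeric(md$season == season_lv[i])
  }
  re <- re_terms(spec, season_lv)

  if (spec$re_structure == "none" && !spec$random_slope) {
    model <- stats::lm(as.formula(fixed_str), data = md)
    sm <- summary(model)$coefficients
    coef_tbl <- tibble(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                       df = model$df.residual, t = sm[, 3], p = sm[, 4])
    varcomp <- tibble(group = "Residual", term = NA_character_,
                      variance = summary(model)$sigma^2,
                      sd = summary(model)$sigma)
    converged <- TRUE
    singular <- FALSE
  } else {
    formula_all <- as.formula(paste(fixed_str, "+", paste(re, collapse = " + ")))
    fit_once <- function(start = NULL) {
      suppressMessages(lmerTest::lmer(
        formula_all, data = md, REML = spec$reml, start = start,
        control = lme4::lmerControl(calc.derivs = TRUE)))
    }
    model <- withCallingHandlers(
      fit_once(),
      warning = function(w) invokeRestart("muffleWarning"))
    conv_msgs <- function(m) unlist(m@optinfo$conv$lme4$messages)
    bad <- function(m) any(grepl("failed to converge", conv_msgs(m)))
    attempt <- 0
    while (bad(model) && attempt < 3) {
      attempt <- attempt + 1
      th <- lme4::getME(model, "theta")
      jitter <- th * exp(stats::rnorm(length(th), 0, 0.05)) + 1e-4
      model <- tryCatch(
        withCallingHandlers(fit_once(start = jitter),
                            warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) model)
    }
    converged <- !bad(model)
    if (!converged) {
      warning("mixed model did not converge after 3 jittered restarts; ",
              "estimates are reported but flagged.", call. = FALSE)
    }
    singular <- lme4::isSingular(model)
    sm <- suppressWarnings(summary(model)$coefficients)
    # lmerTest columns: Estimate, Std. Error, df, t value, Pr(>|t|)
    coef_tbl <- tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                       se = sm[, "Std. Error"], df = sm[, "df"],
                       t = sm[, "t value"], p = sm[, "Pr(>|t|)"])
    vc <- as.data.frame(lme4::VarCorr(model))
    season_of <- function(term) {
      idx <- suppressWarnings(as.integer(sub("^\\.season_ind_", "", term)))
      ifelse(is.na(idx), term, season_lv[idx])
    }
    varcomp <- tibble(group = vc$grp,
                      term = ifelse(is.na(vc$var1), NA_character_,
                                    season_of(vc$var1)),
                      variance = vc$vcov,
                      sd = vc$sdcor)
  }

  beta <- coef_tbl$estimate
  names(beta) <- coef_tbl$term
  V <- as.matrix(vcov(model))
  cells <- as_tibble(as.data.frame(table(crop = data$crop, season = data$season),
                                   stringsAsFactors = FALSE))
  names(cells) <- c("crop", "season", "n")

  xlev <- list(season = season_lv, crop = levels(data$crop))
  if (spec$use_prev_crop) xlev$crop_prev <- levels(data$crop_prev)

  structure(
    list(coefficients = coef_tbl,
         beta = beta,
         vcov_fixed = V,
         varcomp = varcomp,
         logLik = as.numeric(logLik(model)),
         AIC = AIC(model),
         n_par = attr(logLik(model), "df"),
         n_obs = nrow(data),
         converged = converged,
         singular = singular,
         spec = spec,
         formula = fixed_str,
         random_terms = re,
         xlev = xlev,
         cells = cells,
         model = model),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s%s\n", x$formula,
              if (length(x$random_terms))
                paste0(" + ", paste(x$random_terms, collapse = " + "))
              else " (no random effects)"))
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f, converged = %s%s\n",
              x$n_obs, x$logLik, x$AIC, x$converged,
              if (x$singular) " (singular)" else ""))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  invisible(x)
}

# Argmin with the tie rule: AICs within `tol` of the minimum are ties, and
# ties break toward the fewest parameters (then first listed).
choose_by_aic <- function(aic, n_par, tol = 1e-6) {
  stopifnot(length(aic) == length(n_par), length(aic) >= 1)
  tied <- which(aic <= min(aic) + tol)
  tied[which.min(n_par[tied])]
}

#' Select the random-effect structure by AIC
#'
#' Refits every candidate specification by maximum likelihood (not REML, so
#' the AICs are comparable across random-effect structures on the same
#' data), drops candidates that fail to converge (with a warning), and
#' returns the specification with the smallest AIC — ties within 1e-6 break
#' toward the model with fewer parameters. The winner is then refitted with
#' its own REML setting.
#'
#' @param data Model table from [build_model_data()].
#' @param specs Named list of [lmm_spec()] candidates.
#' @return List with `label` (winner's name), `spec`, `fit` (final refit),
#'   and `aic_table` (label, n_par, AIC, converged for every candidate).
#' @export
select_random_effects <- function(data, specs) {
  if (!is.list(specs) || length(specs) < 2) {
    abort_invalid("`specs` must be a list of at least two lmm_spec candidates.")
  }
  labels <- names(specs) %||% paste0("model", seq_along(specs))
  if (is.null(names(specs))) names(specs) <- labels
  rows <- vector("list", length(specs))
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    ml_spec <- specs[[i]]
    ml_spec$reml <- FALSE
    fit <- tryCatch(suppressWarnings(fit_lmm(data, ml_spec)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("candidate '%s' failed (%s); excluded from selection.",
                      labels[i], conditionMessage(fit)), call. = FALSE)
      rows[[i]] <- tibble(label = labels[i], n_par = NA_integer_,
                          AIC = NA_real_, converged = FALSE)
    } else {
      fits[[i]] <- fit
      if (!fit$converged) {
        warning(sprintf("candidate '%s' did not converge; excluded from selection.",
                        labels[i]), call. = FALSE)
      }
      rows[[i]] <- tibble(label = labels[i], n_par = fit$n_par,
                          AIC = fit$AIC, converged = fit$converged)
    }
  }
  aic_table <- bind_rows(rows)
  ok <- which(aic_table$converged)
  if (length(ok) == 0) {
    abort_selection("no candidate model converged; cannot select a structure.")
  }
  best <- ok[choose_by_aic(aic_table$AIC[ok], aic_table$n_par[ok])]
  final <- fit_lmm(data, specs[[best]])
  list(label = labels[best], spec = specs[[best]], fit = final,
       aic_table = aic_table)
}

#' Wald chi-square interaction contrasts
#'
#' Tests, for each requested (crop, season pair), whether the fixed-effect
#' cell means of that crop differ between the two seasons — the post-hoc
#' follow-up to a significant crop x season interaction. Each contrast is a
#' 1-df Wald chi-square on the difference of model cell means (covariates
#' held fixed, so they cancel). The family-wise level `alpha` is converted
#' to a per-test level with [sidak_adjust()] using k = number of contrasts
#' actually tested.
#'
#' @param fit An [fit_lmm()] result.
#' @param family Data frame with columns `crop`, `season_a`, `season_b`; by
#'   default every season pair within every crop with data in both cells.
#' @param alpha Family-wise significance level.
#' @return Tibble with `crop`, `season_a`, `season_b`, `estimate` (log-scale
#'   difference a - b), `chisq`, `df`, `p_value`, `alpha_adjusted`,
#'   `significant`.
#' @export
interaction_contrasts <- function(fit, family = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) {
    abort_invalid("cannot compute contrasts from a non-converged fit.")
  }
  seasons <- fit$xlev$season
  crops <- fit$xlev$crop
  cells <- fit$cells
  cell_n <- function(crop, season) {
    n <- cells$n[cells$crop == crop & cells$season == season]
    if (length(n) == 0) 0L else n
  }
  if (is.null(family)) {
    pairs <- utils::combn(seasons, 2)
    family <- do.call(rbind, lapply(crops, function(cr) {
      data.frame(crop = cr, season_a = pairs[1, ], season_b = pairs[2, ],
                 stringsAsFactors = FALSE)
    }))
    keep <- vapply(seq_len(nrow(family)), function(i) {
      cell_n(family$crop[i], family$season_a[i]) > 0 &&
        cell_n(family$crop[i], family$season_b[i]) > 0
    }, logical(1))
    family <- family[keep, ]
  }
  family <- as.data.frame(family)
  check_columns(family, c("crop", "season_a", "season_b"), "contrast family")
  if (nrow(family) == 0) abort_invalid("contrast family is empty.")

  k <- nrow(family)
  alpha_adj <- sidak_adjust(alpha, k)
  ref_prev <- if (!is.null(fit$xlev$crop_prev)) fit$xlev$crop_prev[1] else NULL

  cell_row <- function(crop, season) {
    nd <- data.frame(season = factor(season, levels = seasons),
                     crop = factor(crop, levels = crops))
    if (fit$spec$use_baseline) nd$baseline_log <- 0
    if (fit$spec$use_prev_crop) {
      nd$crop_prev <- factor(ref_prev, levels = fit$xlev$crop_prev)
    }
    ft <- delete.response(terms(as.formula(fit$formula)))
    model.matrix(ft, nd)[1, ]
  }

  res <- vector("list", k)
  for (i in seq_len(k)) {
    cr <- family$crop[i]
    sa <- family$season_a[i]
    sb <- family$season_b[i]
    for (s in unique(c(sa, sb))) {
      if (!s %in% seasons) {
        abort_invalid(sprintf("season '%s' is not in the fitted model.", s))
      }
    }
    if (!cr %in% crops) {
      abort_invalid(sprintf("crop '%s' is not in the fitted model.", cr))
    }
    missing_cells <- c(
      if (cell_n(cr, sa) == 0) sprintf("%s:%s", cr, sa),
      if (cell_n(cr, sb) == 0) sprintf("%s:%s", cr, sb))
    if (length(missing_cells)) {
      abort_estimability(sprintf(
        "contrast %s (%s vs %s) is not estimable; no observations in cell(s): %s",
        cr, sa, sb, paste(missing_cells, collapse = ", ")))
    }
    L <- cell_row(cr, sa) - cell_row(cr, sb)
    est <- sum(L * fit$beta)
    v <- as.numeric(t(L) %*% fit$vcov_fixed %*% L)
    if (all(abs(L) < 1e-12) || v <= 0) {
      chisq <- 0
      p <- 1
      est <- 0
    } else {
      chisq <- est^2 / v
      p <- pchisq(chisq, df = 1, lower.tail = FALSE)
    }
    res[[i]] <- tibble(crop = cr, season_a = sa, season_b = sb,
                       estimate = est, chisq = chisq, df = 1L,
                       p_value = p, alpha_adjusted = alpha_adj,
                       significant = p < alpha_adj)
  }
  bind_rows(res)
}

#' Dunn-Sidak per-test level
#'
#' Converts a family-wise significance level `alpha` across `k` tests into
#' the per-test level `1 - (1 - alpha)^(1/k)`. The result always lies
#' between the Bonferroni level `alpha / k` and `alpha`, which is why the
#' correction is (slightly) more powerful than Bonferroni.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param k Number of tests (integer >= 1).
#' @return Per-test significance level.
#' @export
sidak_adjust <- function(alpha, k) {
  check_number(alpha, "alpha", min = 0, max = 1, min_open = TRUE, max_open = TRUE)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 1 ||
      k != round(k)) {
    abort_invalid("`k` must be an integer >= 1.")
  }
  1 - (1 - alpha)^(1 / k)
}

#' Mann-Whitney U test
#'
#' U for group `a` is the number of (a, b) pairs with a > b plus half the
#' tied pairs, so `U_a + U_b = n_a * n_b`. The two-sided p-value is exact
#' when there are no ties and the smaller group has at most 8 observations;
#' otherwise a normal approximation with tie and continuity corrections is
#' used. Used here to compare total concentrations between wetlands that
#' later dried and those that stayed wet.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `U` (for group a), `U_other` (for group b), `p`
#'   (two-sided) and `exact` (logical).
#' @export
mann_whitney_u <- function(a, b) {
  if (!is.numeric(a) || length(a) == 0 || any(!is.finite(a))) {
    abort_group("group `a` must be a non-empty finite numeric vector.")
  }
  if (!is.numeric(b) || length(b) == 0 || any(!is.finite(b))) {
    abort_group("group `b` must be a non-empty finite numeric vector.")
  }
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  U_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  U_b <- na * nb - U_a
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(na, nb) <= 8
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  # degenerate case: every observation tied across both groups
  if (is.na(p)) p <- 1
  list(U = U_a, U_other = U_b, p = p, exact = exact)
}
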