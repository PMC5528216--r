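# Predictor sets of the standard seven-model battery. Models A-D combine
# predictors and are subject to backward LR selection; E-G are univariate
# forced-entry fits run for comparability on the complete-case subset
# (records with all three metrics), so their coefficients are directly
# comparable with model A's.
BATTERY_MODELS <- list(
  A = c("adipocyte_area_um2", "ai", "lipid_percent"),
  B = c("ai", "lipid_percent"),
  C = c("lipid_percent", "adipocyte_area_um2"),
  D = c("adipocyte_area_um2", "ai"),
  E = "adipocyte_area_um2",
  F = "ai",
  G = "lipid_percent"
)

#' Run the cohort-discrimination model battery
#'
#' Fits the seven standard binary logistic regressions of migration cohort
#' (early = 0, late = 1) on the adiposity metrics: A = area + AI + lipid,
#' B = AI + lipid, C = lipid + area, D = area + AI, and the univariate
#' models E = area, F = AI, G = lipid. Multi-predictor models A-D use
#' backward likelihood-ratio selection ([backward_lr_selection()]);
#' univariate models E-G are forced-entry fits evaluated on the
#' complete-case subset (all three metrics present) so that the three
#' measures are compared on identical samples. Every model uses listwise
#' deletion over its own variables, never imputation, so subset sizes
#' reflect each metric's coverage. Each fitted model carries its selection
#' trace and fit diagnostics (Nagelkerke R-squared, Hosmer-Lemeshow).
#'
#' @param records Metrics data frame with `cohort`, `adipocyte_area_um2`,
#'   `ai`, `lipid_percent`.
#' @param models Which models to run (subset of `LETTERS[1:7]`).
#' @param p_out Backward-LR removal threshold (default 0.10).
#' @param hl_groups Hosmer-Lemeshow bins (default 10).
#' @param min_per_class Minimum records per cohort for a model to run
#'   (default 10); smaller subsets are skipped with a warning.
#' @return An object of class `model_battery`: a named list of per-model
#'   results (`n`, `predictors`, `fit`, `trace`, `nagelkerke_r2`,
#'   `hosmer_lemeshow`), with skipped models set to `NULL`.
#' @export
run_model_battery <- function(records, models = names(BATTERY_MODELS),
                              p_out = 0.10, hl_groups = 10,
                              min_per_class = 10) {
  stopifnot(all(models %in% names(BATTERY_MODELS)))
  if (!is.factor(records$cohort)) {
    records$cohort <- factor(records$cohort, levels = c("early", "late"))
  }
  y_all <- as.integer(records$cohort) - 1L  # early = 0, late = 1
  complete3 <- complete.cases(
    records[c("adipocyte_area_um2", "ai", "lipid_percent")])
  out <- lapply(models, function(m) {
    vars <- BATTERY_MODELS[[m]]
    univariate <- length(vars) == 1L
    rows <- if (univariate) complete3 else complete.cases(records[vars])
    rows <- rows & !is.na(y_all)
    x <- records[rows, vars, drop = FALSE]
    y <- y_all[rows]
    if (sum(y == 0) < min_per_class || sum(y == 1) < min_per_class) {
      warning(sprintf(
        "model %s skipped: %d early / %d late below the %d-per-class minimum",
        m, sum(y == 0), sum(y == 1), min_per_class))
      return(NULL)
    }
    if (univariate) {
      fit <- fit_logistic(x, y)
      trace <- data.frame(step = 1L, predictor = vars,
                          p_remove = NA_real_, removed = FALSE)
    } else {
      sel <- backward_lr_selection(x, y, p_out = p_out)
      fit <- sel$fit
      trace <- sel$trace
    }
    # Near-separated fits can leave too few distinct fitted probabilities
    # to bin; the calibration test is then undefined, not a failure.
    hl <- tryCatch(hosmer_lemeshow(fit, groups = hl_groups),
                   error = function(e) {
                     list(chi_square = NA_real_, df = NA_integer_,
                          p_value = NA_real_, groups_used = NA_integer_,
                          table = NULL, note = conditionMessage(e))
                   })
    list(model = m, n = fit$n, predictors = fit$predictors,
         fit = fit, trace = trace,
         nagelkerke_r2 = nagelkerke_r2(fit),
         hosmer_lemeshow = hl)
  })
  names(out) <- models
  structure(out, class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat("<model_battery>\n")
  for (m in names(x)) {
    r <- x[[m]]
    if (is.null(r)) {
      cat(sprintf("  %s: skipped\n", m))
    } else {
      cat(sprintf("  %s: n = %d, final predictors: %s, Nagelkerke R2 = %.3f\n",
                  m, r$n,
                  if (length(r$predictors)) paste(r$predictors, collapse = " + ")
                  else "(intercept only)",
                  r$nagelkerke_r2))
    }
  }
  invisible(x)
}

#' Coefficient table of a model battery
#'
#' One row per (model, selection step, predictor) with coefficient,
#' standard error, Wald p, odds ratio and 95% CI. Steps before the final
#' model are re-fitted on the model's subset so every step's coefficients
#' are reported, mirroring how stepwise output is conventionally tabled.
#'
#' @param battery A [run_model_battery()] result.
#' @param records The metrics data frame the battery was run on.
#' @return Data frame.
#' @export
battery_coefficients <- function(battery, records) {
  if (!is.factor(records$cohort)) {
    records$cohort <- factor(records$cohort, levels = c("early", "late"))
  }
  y_all <- as.integer(records$cohort) - 1L
  complete3 <- complete.cases(
    records[c("adipocyte_area_um2", "ai", "lipid_percent")])
  rows <- lapply(names(battery), function(m) {
    r <- battery[[m]]
    if (is.null(r)) return(NULL)
    vars0 <- BATTERY_MODELS[[m]]
    subset_rows <- if (length(vars0) == 1L) complete3
                   else complete.cases(records[vars0])
    subset_rows <- subset_rows & !is.na(y_all)
    steps <- unique(r$trace$step)
    do.call(rbind, lapply(steps, function(s) {
      preds <- r$trace$predictor[r$trace$step == s]
      preds <- setdiff(preds, "(none)")
      fit <- if (identical(sort(preds), sort(r$predictors))) r$fit
             else fit_logistic(records[subset_rows, preds, drop = FALSE],
                               y_all[subset_rows])
      if (length(preds) == 0) return(NULL)
      data.frame(model = m, n = fit$n, step = s, predictor = preds,
                 b = fit$coefficients[preds], se = fit$se[preds],
                 p = fit$wald_p[preds],
                 odds_ratio = fit$odds_ratio[preds],
                 ci_lower = fit$ci_lower[preds],
                 ci_upper = fit$ci_upper[preds],
                 row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit-statistics table of a model battery
#'
#' One row per model: final predictors, Nagelkerke R-squared, and the
#' Hosmer-Lemeshow chi-square, df and p.
#'
#' @param battery A [run_model_battery()] result.
#' @return Data frame.
#' @export
battery_fit_stats <- function(battery) {
  rows <- lapply(names(battery), function(m) {
    r <- battery[[m]]
    if (is.null(r)) return(NULL)
    data.frame(model = m, n = r$n,
               predictors = if (length(r$predictors))
                 paste(r$predictors, collapse = "+") else "(intercept)",
               nagelkerke_r2 = r$nagelkerke_r2,
               hl_chi_square = r$hosmer_lemeshow$chi_square,
               hl_df = r$hosmer_lemeshow$df,
               hl_p = r$hosmer_lemeshow$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full statistical analysis of a metrics table
#'
#' Runs the whole analysis battery on a per-sample metrics table: the
#' distributional screens (Shapiro-Wilk per metric, with AI also screened
#' after log10; Levene across cohorts; the 2.2 x IQR outlier screen; VIF
#' over the three metrics), the cohort comparisons (pooled-variance t-tests
#' on area, log10 AI and lipid percent), the three pairwise Pearson
#' correlations, the per-cohort summary, and the seven-model logistic
#' battery. AI enters the logistic models untransformed; the log10 scale is
#' used only where normality matters (its t-test).
#'
#' @param records Metrics data frame (see [read_metrics_table()]).
#' @param p_out Backward-LR removal threshold.
#' @return An object of class `adiposity_report`: a list with `summary`,
#'   `screens`, `t_tests`, `correlations`, `battery`, `coefficients`,
#'   `fit_stats`.
#' @export
analyze_metrics_table <- function(records, p_out = 0.10) {
  metrics <- c("adipocyte_area_um2", "ai", "lipid_percent")
  area <- records$adipocyte_area_um2
  ai <- records$ai
  lipid <- records$lipid_percent
  coh <- records$cohort

  screens <- list(
    shapiro = list(
      adipocyte_area_um2 = try_or_na(test_normality(area)),
      ai = try_or_na(test_normality(ai)),
      ai_log10 = try_or_na(test_normality(log10(ai[!is.na(ai) & ai > 0]))),
      lipid_percent = try_or_na(test_normality(lipid))
    ),
    levene = lapply(setNames(metrics, metrics), function(m) {
      try_or_na(levene_test(records[[m]], coh))
    }),
    outliers = lapply(setNames(metrics, metrics), function(m) {
      sum(iqr_outliers(records[[m]], k = 2.2))
    }),
    vif = try_or_na(vif(records[stats::complete.cases(records[metrics]),
                                metrics]))
  )

  t_tests <- list(
    adipocyte_area_um2 = try_or_na(independent_t_test(
      area[coh == "early"], area[coh == "late"])),
    ai_log10 = try_or_na(independent_t_test(
      ai[coh == "early"], ai[coh == "late"], log10_first = TRUE)),
    lipid_percent = try_or_na(independent_t_test(
      lipid[coh == "early"], lipid[coh == "late"]))
  )

  correlations <- list(
    area_ai = try_or_na(pearson_cor(area, ai)),
    area_lipid = try_or_na(pearson_cor(area, lipid)),
    ai_lipid = try_or_na(pearson_cor(ai, lipid))
  )

  battery <- run_model_battery(records, p_out = p_out)

  structure(
    list(summary = cohort_summary(records),
         screens = screens, t_tests = t_tests,
         correlations = correlations, battery = battery,
         coefficients = battery_coefficients(battery, records),
         fit_stats = battery_fit_stats(battery)),
    class = "adiposity_report"
  )
}

try_or_na <- function(expr) {
  tryCatch(expr, error = function(e) {
    list(error = conditionMessage(e))
  })
}

#' @export
print.adiposity_report <- function(x, ...) {
  cat("<adiposity_report>\n\nCohort summary:\n")
  print(x$summary, digits = 5)
  cat("\nCorrelations:\n")
  for (nm in names(x$correlations)) {
    r <- x$correlations[[nm]]
    if (!is.null(r$r)) {
      cat(sprintf("  %s: r = %.3f (n = %d, p = %.3g)\n",
                  nm, r$r, r$n, r$p_value))
    }
  }
  cat("\n")
  print(x$battery)
  invisible(x)
}
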