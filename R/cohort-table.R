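#' Specification for a synthetic cohort metrics table
#'
#' Describes a two-cohort (early/late migration) table of per-sample
#' adiposity metrics with controlled marginals, cross-metric correlation
#' and missingness, generated by [generate_cohort_table()]. Metrics are
#' coupled through a Gaussian copula: a trivariate standard normal with the
#' target correlation matrix is transformed through each metric's marginal,
#' which controls Pearson/rank correlation without distorting the marginal
#' ranges.
#'
#' Marginals, per cohort:
#' \itemize{
#'   \item adipocyte area: normal, mean `area_mean`, SD `area_sd` (um2),
#'     floored at 1 um2;
#'   \item adipocyte index: log10-normal with mean `ai_log10_mean` and SD
#'     `ai_log10_sd` on the log10 scale, floored at its theoretical minimum
#'     of 1 (fully adipocyte-filled image);
#'   \item lipid percent: normal, mean `lipid_mean`, SD `lipid_sd`,
#'     clamped to (0.5, 100\].
#' }
#'
#' The defaults emulate the humpback-whale migration study conditions this
#' package targets: 98 early / 105 late samples; early cohort mean area
#' 792.10 um2 falling to 597.65 um2 after the fasting migration; AI
#' (higher = leaner) rising from a geometric mean of about 1.30 to 1.55,
#' overall about 1.42; lipid percent uninformative about cohort (equal
#' means, pooled geometric mean about 39); a strong negative area-AI
#' correlation (-0.784) and weak lipid correlations (0.388 with area,
#' -0.468 with AI); and the study's missingness pattern (see
#' [study_missingness()]).
#'
#' @param n_early,n_late Samples per cohort (either may be 0).
#' @param area_mean,area_sd Named or length-2 numeric `(early, late)`
#'   moments of adipocyte area (um2).
#' @param ai_log10_mean,ai_log10_sd Moments of log10 AI per cohort.
#' @param lipid_mean,lipid_sd Moments of lipid percent per cohort.
#' @param rho Length-3 numeric: target correlations
#'   `c(area_ai, area_lipid, ai_lipid)` of the underlying copula, applied
#'   within cohort. Must form a positive-definite matrix.
#' @param missingness `NULL` (fully observed) or a per-cohort list as
#'   returned by [study_missingness()]: counts of samples with area and
#'   lipid observed and the size of the area-and-lipid overlap (AI is
#'   always observed).
#' @param seed Integer RNG seed (mandatory).
#'
#' @return An object of class `cohort_table_spec`.
#' @export
cohort_table_spec <- function(n_early = 98L, n_late = 105L,
                              area_mean = c(early = 792.10, late = 597.65),
                              area_sd = c(early = 200, late = 126),
                              ai_log10_mean = c(early = log10(1.30),
                                                late = log10(1.55)),
                              ai_log10_sd = c(early = 0.05, late = 0.05),
                              lipid_mean = c(early = 42, late = 42),
                              lipid_sd = c(early = 16, late = 16),
                              rho = c(area_ai = -0.784, area_lipid = 0.388,
                                      ai_lipid = -0.468),
                              missingness = study_missingness(),
                              seed = NULL) {
  stopifnot(n_early >= 0, n_late >= 0, length(rho) == 3)
  if (is.null(seed)) stop("cohort_table_spec requires an explicit seed")
  R <- matrix(c(1, rho[1], rho[2],
                rho[1], 1, rho[3],
                rho[2], rho[3], 1), 3, 3,
              dimnames = list(c("area", "ai", "lipid"),
                              c("area", "ai", "lipid")))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("infeasible correlation matrix: target correlations (",
         paste(signif(rho, 3), collapse = ", "),
         ") are not jointly positive semi-definite")
  }
  spec <- list(n_early = as.integer(n_early), n_late = as.integer(n_late),
               area_mean = area_mean, area_sd = area_sd,
               ai_log10_mean = ai_log10_mean, ai_log10_sd = ai_log10_sd,
               lipid_mean = lipid_mean, lipid_sd = lipid_sd,
               rho = rho, R = R, missingness = missingness,
               seed = as.integer(seed))
  if (!is.null(missingness)) validate_missingness(spec)
  structure(spec, class = "cohort_table_spec")
}

#' Study missingness pattern
#'
#' The per-cohort observation pattern of the targeted field study: every
#' sample has an AI; 42/98 early and 41/105 late samples have an adipocyte
#' area; 38/98 early and 101/105 late have a lipid percent; and lipid
#' measurement is coupled to area measurement (36 early and all 41 late
#' area samples also have lipid). Listwise deletion then yields subset
#' sizes of 83 (area + AI), 139 (AI + lipid) and 77 (all three), the
#' subset structure the model battery is designed around.
#'
#' @return A list with `early` and `late` components, each holding counts
#'   `n_area`, `n_lipid`, `n_area_lipid`.
#' @export
study_missingness <- function() {
  list(early = list(n_area = 42L, n_lipid = 38L, n_area_lipid = 36L),
       late = list(n_area = 41L, n_lipid = 101L, n_area_lipid = 41L))
}

validate_missingness <- function(spec) {
  ns <- c(early = spec$n_early, late = spec$n_late)
  for (coh in c("early", "late")) {
    m <- spec$missingness[[coh]]
    stopifnot(!is.null(m$n_area), !is.null(m$n_lipid),
              !is.null(m$n_area_lipid))
    if (m$n_area > ns[[coh]] || m$n_lipid > ns[[coh]] ||
        m$n_area_lipid > min(m$n_area, m$n_lipid) ||
        m$n_lipid - m$n_area_lipid > ns[[coh]] - m$n_area) {
      stop("infeasible missingness pattern for cohort '", coh, "'")
    }
  }
  invisible(spec)
}

#' Generate a synthetic per-sample metrics table
#'
#' Draws one table of sample records according to a [cohort_table_spec()]:
#' correlated metrics per cohort via a Gaussian copula, then per-metric
#' missingness so listwise-deletion subset sizes are controlled exactly.
#'
#' @param spec A [cohort_table_spec()].
#' @return A data frame with columns `sample_id`, `cohort` (factor
#'   early/late), `adipocyte_area_um2`, `ai`, `lipid_percent`; missing
#'   values are `NA`.
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_table_spec"))
  withr::with_seed(spec$seed, {
    parts <- lapply(c("early", "late"), function(coh) {
      n <- if (coh == "early") spec$n_early else spec$n_late
      if (n == 0) return(NULL)
      z <- matrix(rnorm(n * 3), n, 3) %*% chol(spec$R)
      area <- pmax(spec$area_mean[[coh]] + spec$area_sd[[coh]] * z[, 1], 1)
      ai <- pmax(10^(spec$ai_log10_mean[[coh]] +
                       spec$ai_log10_sd[[coh]] * z[, 2]), 1)
      lipid <- pmin(pmax(spec$lipid_mean[[coh]] +
                           spec$lipid_sd[[coh]] * z[, 3], 0.5), 100)
      df <- data.frame(cohort = coh, adipocyte_area_um2 = area,
                       ai = ai, lipid_percent = lipid)
      if (!is.null(spec$missingness)) {
        m <- spec$missingness[[coh]]
        resample <- function(x, k) x[sample.int(length(x), k)]
        idx_area <- resample(seq_len(n), m$n_area)
        with_lip_in <- resample(idx_area, m$n_area_lipid)
        outside <- setdiff(seq_len(n), idx_area)
        with_lip_out <- resample(outside, m$n_lipid - m$n_area_lipid)
        keep_lip <- c(with_lip_in, with_lip_out)
        df$adipocyte_area_um2[setdiff(seq_len(n), idx_area)] <- NA_real_
        df$lipid_percent[setdiff(seq_len(n), keep_lip)] <- NA_real_
      }
      df
    })
    out <- do.call(rbind, parts)
    if (is.null(out)) {
      out <- data.frame(cohort = character(0),
                        adipocyte_area_um2 = numeric(0),
                        ai = numeric(0), lipid_percent = numeric(0))
    }
    out <- cbind(sample_id = sprintf("S%04d", seq_len(nrow(out))), out)
    out$cohort <- factor(out$cohort, levels = c("early", "late"))
    rownames(out) <- NULL
    out
  })
}
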