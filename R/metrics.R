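# Minimum image area for a valid adipocyte index, in um2. A smaller field
# of view makes the two-phase area ratio unstable to local tissue
# heterogeneity.
MIN_IMAGE_AREA_UM2 <- 167687.3336

#' Compute the adipocyte index of a segmented image
#'
#' The adipocyte index (AI) summarises adiposity from the two-phase
#' partition of a thresholded image. With adipocyte pixel fraction `a`:
#' \describe{
#'   \item{`total_over_adipocyte` (default)}{`AI = 1/a`, the total image
#'     area over the adipocyte area. Bounded below by 1, reached when the
#'     image is entirely adipocyte; higher AI means more intervacuolar
#'     matrix, i.e. leaner tissue.}
#'   \item{`intervacuolar_over_adipocyte`}{`AI = (1 - a)/a`, the strict
#'     intervacuolar-to-adipocyte ratio, bounded below by 0.}
#' }
#' The two definitions differ by exactly 1 for every mask. The default is
#' the total-over-adipocyte form, the only reading consistent with
#' reported field values that are bounded below by exactly 1; every result
#' records which definition produced it.
#'
#' @param mask A [binarize()] result.
#' @param definition `"total_over_adipocyte"` or
#'   `"intervacuolar_over_adipocyte"`.
#' @param min_image_area_um2 Minimum calibrated image area for a valid AI
#'   (default 167,687.3336 um2).
#' @param force Compute even when the image is below the area minimum.
#' @return An object of class `adipocyte_index` with fields `value`,
#'   `definition`, `adipocyte_fraction`, `image_area_um2`, `threshold`.
#' @export
compute_adipocyte_index <- function(mask,
                                    definition = c("total_over_adipocyte",
                                                   "intervacuolar_over_adipocyte"),
                                    min_image_area_um2 = MIN_IMAGE_AREA_UM2,
                                    force = FALSE) {
  definition <- match.arg(definition)
  stopifnot(inherits(mask, "binary_mask"))
  area <- length(mask$adipocyte) * mask$um_per_px^2
  if (area < min_image_area_um2 && !force) {
    stop(sprintf(
      "image area %.1f um2 below the %.4f um2 minimum for a valid AI (use force = TRUE to override)",
      area, min_image_area_um2))
  }
  a <- mean(mask$adipocyte)
  if (a == 0) {
    stop("undefined adipocyte index: no adipocyte pixels in mask")
  }
  # The strict ratio is computed as 1/a - 1 so the identity
  # AI(total) = 1 + AI(strict) holds exactly in floating point.
  value <- switch(definition,
                  total_over_adipocyte = 1 / a,
                  intervacuolar_over_adipocyte = 1 / a - 1)
  structure(
    list(value = value, definition = definition,
         adipocyte_fraction = a, image_area_um2 = area,
         threshold = mask$provenance$threshold_dark_high),
    class = "adipocyte_index"
  )
}

#' @export
print.adipocyte_index <- function(x, ...) {
  cat(sprintf("<adipocyte_index> %.4f (%s), adipocyte fraction %.3f\n",
              x$value, x$definition, x$adipocyte_fraction))
  invisible(x)
}

#' Spherical cell volume from cross-sectional area
#'
#' Treats the measured cross-section as the equatorial section of a
#' sphere: `r = sqrt(area / pi)`, `V = (4/3) pi r^3` in um3, converted to
#' nanolitres at 10^6 um3 per nl.
#'
#' @param area_um2 Positive cross-sectional area(s), um2.
#' @return Volume(s) in nanolitres.
#' @export
sphere_volume_from_area <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    stop("area_um2 must be positive and finite")
  }
  r <- sqrt(area_um2 / pi)
  (4 / 3) * pi * r^3 / UM3_PER_NL
}

#' Geometric mean
#'
#' `exp(mean(log(x)))` of strictly positive values.
#'
#' @param x Positive numeric vector.
#' @param na.rm Drop `NA` first.
#' @return The geometric mean.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (any(is.na(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive values")
  }
  exp(mean(log(x)))
}

#' Per-cohort summary of the adiposity metrics
#'
#' Summarises each metric (adipocyte area, AI, lipid percent) within each
#' cohort: n observed, geometric mean, arithmetic mean, min, max. Missing
#' values are excluded metric-wise, so each metric's n reflects its own
#' coverage.
#'
#' @param records Metrics data frame (see [read_metrics_table()] or
#'   [generate_cohort_table()]).
#' @return Data frame with one row per metric x cohort.
#' @export
cohort_summary <- function(records) {
  metrics <- c("adipocyte_area_um2", "ai", "lipid_percent")
  cohorts <- c("early", "late")
  rows <- lapply(metrics, function(m) {
    do.call(rbind, lapply(cohorts, function(coh) {
      v <- records[[m]][records$cohort == coh]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        data.frame(metric = m, cohort = coh, n = 0L,
                   geometric_mean = NA_real_, arithmetic_mean = NA_real_,
                   min = NA_real_, max = NA_real_)
      } else {
        data.frame(metric = m, cohort = coh, n = length(v),
                   geometric_mean = geometric_mean(v),
                   arithmetic_mean = mean(v),
                   min = min(v), max = max(v))
      }
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent reduction from an early to a late value
#'
#' `100 * (early - late) / early`; positive when the late value is
#' smaller. Reductions should be reported separately for arithmetic means,
#' geometric means and volumes — never as one blended "size" number, since
#' the three transforms do not commute.
#'
#' @param early_value Baseline (must be positive).
#' @param late_value Comparison value.
#' @return Percent reduction.
#' @export
percent_reduction <- function(early_value, late_value) {
  if (any(!is.finite(early_value)) || any(early_value <= 0)) {
    stop("early_value must be positive and finite")
  }
  100 * (early_value - late_value) / early_value
}
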