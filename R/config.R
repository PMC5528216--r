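#' Pipeline configuration
#'
#' Collects every tunable of the image-to-statistics pipeline in one
#' validated object. Defaults follow the field protocol this package
#' implements: segmentation threshold 65,527 (16-bit, dark-is-high; 255
#' for 8-bit), at least 100 complete cells per sample mean, minimum image
#' area 167,687.3336 um2 for a valid AI, total-over-adipocyte AI
#' definition, 20 px debris floor, watershed de-clustering off, and
#' backward-LR removal threshold 0.10. Every pipeline run writes the
#' resolved configuration beside its outputs so results are traceable.
#'
#' @param threshold Dark-is-high segmentation threshold; `NULL` resolves
#'   to [default_threshold()] for `bit_depth`.
#' @param bit_depth Image bit depth the threshold refers to.
#' @param um_per_px Calibration (mandatory for image work).
#' @param min_cells Minimum complete cells per sample (default 100).
#' @param min_image_area_um2 Minimum image area for a valid AI.
#' @param ai_definition AI definition (see [compute_adipocyte_index()]).
#' @param speck_floor_px Debris floor in pixels.
#' @param watershed Apply watershed de-clustering.
#' @param min_adipocyte_fraction QC floor for adipocyte-dominated images.
#' @param p_out Backward-LR removal threshold.
#' @param seed RNG seed for any stochastic stage (mandatory in pipelines).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = NULL, bit_depth = 16L,
                            um_per_px = NULL, min_cells = 100,
                            min_image_area_um2 = MIN_IMAGE_AREA_UM2,
                            ai_definition = "total_over_adipocyte",
                            speck_floor_px = 20, watershed = FALSE,
                            min_adipocyte_fraction = 0.5,
                            p_out = 0.10, seed = NULL) {
  if (is.null(threshold)) threshold <- default_threshold(bit_depth)
  stopifnot(min_cells >= 1, min_image_area_um2 > 0, speck_floor_px >= 0,
            p_out > 0, p_out < 1)
  ai_definition <- match.arg(ai_definition,
                             c("total_over_adipocyte",
                               "intervacuolar_over_adipocyte"))
  structure(
    list(threshold = threshold, bit_depth = as.integer(bit_depth),
         um_per_px = um_per_px, min_cells = min_cells,
         min_image_area_um2 = min_image_area_um2,
         ai_definition = ai_definition, speck_floor_px = speck_floor_px,
         watershed = isTRUE(watershed),
         min_adipocyte_fraction = min_adipocyte_fraction,
         p_out = p_out, seed = seed),
    class = "pipeline_config"
  )
}

#' Write the resolved configuration beside pipeline outputs
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory.
#' @return The path written, invisibly.
#' @export
write_resolved_config <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
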