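#' Default segmentation threshold for a bit depth
#'
#' The intervacuolar threshold is expressed on the dark-is-high scale
#' (0 = white, maximum = black): pixels at or beyond it are classed as
#' intervacuolar matrix. The 16-bit default is 65,527, the conservative
#' near-black cut used in the blubber study this package reimplements; the
#' 8-bit equivalent is derived by proportional scaling
#' (65,527/65,535 -> 254.97, rounded to 255, i.e. only pure black).
#' In practice the operator tunes the threshold per staining batch so that
#' darkened pixels cover the intervacuolar space without encroaching on
#' adipocyte area, then holds it constant across the whole sample set.
#'
#' @param bit_depth 8 or 16.
#' @return The default threshold intensity on the dark-is-high scale.
#' @export
default_threshold <- function(bit_depth) {
  switch(as.character(bit_depth),
         "16" = 65527,
         "8" = round(65527 / 65535 * 255),
         stop("bit_depth must be 8 or 16"))
}

#' Threshold an image into adipocyte and intervacuolar area
#'
#' Resolves the image's intensity convention to the dark-is-high scale and
#' classes every pixel at or beyond `threshold` on the dark side as
#' intervacuolar matrix, everything else as lipid-filled adipocyte area.
#' The threshold used (raw and on the dark-is-high scale), the convention
#' and the bit depth are recorded in the mask's provenance. When a sample
#' set is analyzed together the same threshold must be applied throughout;
#' [segment_image()] enforces this at the pipeline level.
#'
#' @param image A [raster_image()].
#' @param threshold Intensity cut on the dark-is-high scale, within
#'   `[0, 2^bit_depth - 1]`; defaults to [default_threshold()].
#' @return An object of class `binary_mask`: logical matrix `adipocyte`
#'   (`TRUE` = adipocyte), `um_per_px`, and `provenance`.
#' @export
binarize <- function(image, threshold = default_threshold(image$bit_depth)) {
  stopifnot(inherits(image, "raster_image"))
  mx <- 2^image$bit_depth - 1
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > mx) {
    stop("threshold ", threshold, " outside intensity range [0, ", mx, "]")
  }
  dark <- if (image$convention == "dark_high") image$pixels
          else mx - image$pixels
  structure(
    list(adipocyte = dark < threshold,
         um_per_px = image$um_per_px,
         provenance = list(threshold_dark_high = threshold,
                           threshold_file_scale = mx - threshold,
                           bit_depth = image$bit_depth,
                           source_convention = image$convention)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d px, adipocyte fraction %.3f, threshold %g (dark-is-high)\n",
    nrow(x$adipocyte), ncol(x$adipocyte), mean(x$adipocyte),
    x$provenance$threshold_dark_high))
  invisible(x)
}

#' Label adipocytes as connected components
#'
#' Labels 8-connected components of the adipocyte phase. With
#' `split = TRUE`, touching cells that merged into one component are
#' divided by seeded watershed on the Euclidean distance transform: seeds
#' are distance-transform maxima thinned to a minimum separation (default
#' half the median equivalent cell diameter), then grown through the mask.
#' This is the automated stand-in for the manual de-clustering step of
#' interactive morphometry tools; it is off by default.
#'
#' @param mask A [binarize()] result.
#' @param split Apply watershed de-clustering.
#' @param min_seed_separation_um Minimum distance between watershed seeds;
#'   `NULL` uses 0.5 x the median equivalent diameter of the unsplit
#'   labels.
#' @return Integer label matrix (0 = matrix, k >= 1 = cell), with
#'   attributes `um_per_px`.
#' @export
label_adipocytes <- function(mask, split = FALSE,
                             min_seed_separation_um = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components_8(mask$adipocyte)
  if (split && max(lab) > 0L) {
    upp <- mask$um_per_px
    if (is.null(min_seed_separation_um)) {
      px_counts <- tabulate(lab[lab > 0L])
      med_d <- stats::median(2 * sqrt(px_counts * upp^2 / pi))
      min_seed_separation_um <- 0.5 * med_d
    }
    d <- EBImage::distmap(mask$adipocyte * 1)
    seeds <- watershed_seeds(d, min_seed_separation_um / upp)
    if (max(seeds) > 0L) {
      lab <- EBImage::imageData(
        EBImage::propagate(d, seeds, mask = mask$adipocyte))
      storage.mode(lab) <- "integer"
    }
  }
  attr(lab, "um_per_px") <- mask$um_per_px
  lab
}

# Local maxima of the distance transform, greedily thinned so no two kept
# seeds are closer than min_sep_px (larger maxima win); returns an integer
# seed image labelled 1..k.
watershed_seeds <- function(d, min_sep_px) {
  d <- as.matrix(d)
  nr <- nrow(d); nc <- ncol(d)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- d
  is_max <- d > 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & d >= pad[2:(nr + 1) + di, 2:(nc + 1) + dj]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(0L, nr, nc))
  vals <- d[is_max]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- integer(0)
  for (k in seq_len(nrow(idx))) {
    if (length(keep) == 0 ||
        all((idx[keep, 1] - idx[k, 1])^2 +
              (idx[keep, 2] - idx[k, 2])^2 >= min_sep_px^2)) {
      keep <- c(keep, k)
    }
  }
  seeds <- matrix(0L, nr, nc)
  seeds[idx[keep, , drop = FALSE]] <- seq_along(keep)
  seeds
}

#' Keep only complete, non-debris cells
#'
#' Removes every label touching the image border (only complete cells are
#' measured) and every label smaller than `speck_floor_px` pixels, the
#' debris floor standing in for manual curation of specks and nuclei.
#' Counts of removed labels are attached as attributes and reported.
#'
#' @param labels Label matrix from [label_adipocytes()].
#' @param speck_floor_px Minimum pixel count for a real cell (default 20).
#' @param verbose Report removal counts with `message()`.
#' @return Filtered label matrix (original ids retained), with attributes
#'   `n_removed_border` and `n_removed_speck`.
#' @export
filter_complete_cells <- function(labels, speck_floor_px = 20,
                                  verbose = FALSE) {
  ids <- sort(unique(labels[labels > 0L]))
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  border <- border[border > 0L]
  counts <- tabulate(labels[labels > 0L], nbins = max(labels, 1L))
  specks <- setdiff(which(counts > 0L & counts < speck_floor_px), border)
  drop <- union(border, specks)
  out <- labels
  out[out %in% drop] <- 0L
  attr(out, "um_per_px") <- attr(labels, "um_per_px")
  attr(out, "n_removed_border") <- length(border)
  attr(out, "n_removed_speck") <- length(specks)
  if (verbose) {
    message(sprintf(
      "filter_complete_cells: %d labels in, %d removed at border, %d below %d px",
      length(ids), length(border), length(specks), speck_floor_px))
  }
  out
}

#' Measure labelled adipocytes
#'
#' Measures every label under the circular cell model: the equivalent
#' diameter is the diameter of the circle with the cell's pixel area,
#' `2 * sqrt(pixel_count * um_per_px^2 / pi)`, and the reported area is
#' the area of that circle, identically `pixel_count * um_per_px^2`. The
#' circular model is recorded so alternative diameter estimators (e.g.
#' Feret) can be swapped in without changing the measurement contract.
#' Per-sample summaries (`n_complete_cells`, `mean_area_um2`) cover only
#' cells that do not touch the border.
#'
#' @param labels Label matrix (filtered or not); border contact is
#'   determined from the matrix itself.
#' @param um_per_px Calibration; defaults to the matrix attribute.
#' @return An object of class `cell_measurements`: data frame `cells`
#'   (`cell_id`, `pixel_count`, `equivalent_diameter_um`, `area_um2`,
#'   `touches_border`), plus `n_complete_cells`, `mean_area_um2`,
#'   `diameter_model`.
#' @export
measure_cells <- function(labels, um_per_px = attr(labels, "um_per_px")) {
  if (is.null(um_per_px)) stop("um_per_px calibration is required")
  ids <- sort(unique(labels[labels > 0L]))
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  if (length(ids) == 0) {
    cells <- data.frame(cell_id = integer(0), pixel_count = integer(0),
                        equivalent_diameter_um = numeric(0),
                        area_um2 = numeric(0), touches_border = logical(0))
  } else {
    counts <- tabulate(labels[labels > 0L], nbins = max(ids))[ids]
    d <- 2 * sqrt(counts * um_per_px^2 / pi)
    cells <- data.frame(cell_id = ids, pixel_count = counts,
                        equivalent_diameter_um = d,
                        area_um2 = pi * (d / 2)^2,
                        touches_border = ids %in% border)
  }
  complete <- cells[!cells$touches_border, , drop = FALSE]
  structure(
    list(cells = cells,
         n_complete_cells = nrow(complete),
         mean_area_um2 = if (nrow(complete)) mean(complete$area_um2)
                         else NA_real_,
         diameter_model = "equivalent_circle"),
    class = "cell_measurements"
  )
}

#' @export
print.cell_measurements <- function(x, ...) {
  cat(sprintf(
    "<cell_measurements> %d cells (%d complete), mean complete-cell area %.2f um2\n",
    nrow(x$cells), x$n_complete_cells, x$mean_area_um2))
  invisible(x)
}

#' Mean adipocyte area of a sample
#'
#' Arithmetic mean area of the complete (non-border) cells, refusing to
#' report when fewer than `min_cells` were measured: sample-level means
#' are only comparable once at least 100 cells enter them, the count at
#' which adipocyte-area estimates stabilise.
#'
#' @param measurements A [measure_cells()] result.
#' @param min_cells Minimum complete-cell count (default 100).
#' @return Mean area in um2.
#' @export
mean_adipocyte_area <- function(measurements, min_cells = 100) {
  stopifnot(inherits(measurements, "cell_measurements"))
  n <- measurements$n_complete_cells
  if (n < min_cells) {
    stop(errorCondition(
      sprintf("insufficient complete cells: %d observed, %d required",
              n, min_cells),
      observed = n, required = min_cells,
      class = c("adipo_insufficient_cells", "error")))
  }
  measurements$mean_area_um2
}

#' Segment one image end to end
#'
#' Convenience pipeline: threshold, QC-gate, label, filter, measure, and
#' compute the adipocyte index for a single image. Images whose adipocyte
#' fraction falls below `min_adipocyte_fraction` are flagged as not
#' adipocyte-dominated (field selection normally discards such images) and
#' their AI is set to `NA` unless `force = TRUE`.
#'
#' @param image A [raster_image()].
#' @param threshold Dark-is-high threshold shared across the sample set.
#' @param split,speck_floor_px,min_cells Passed to the component steps.
#' @param min_adipocyte_fraction QC floor on the adipocyte fraction
#'   (default 0.5).
#' @param ai_definition Passed to [compute_adipocyte_index()].
#' @param min_image_area_um2 Passed to [compute_adipocyte_index()].
#' @param force Compute AI even for images failing the QC gate or the
#'   minimum-area requirement.
#' @return A list: `mask`, `labels`, `measurements`, `ai` (an
#'   `adipocyte_index` or `NA`), `qc_pass`.
#' @export
segment_image <- function(image,
                          threshold = default_threshold(image$bit_depth),
                          split = FALSE, speck_floor_px = 20,
                          min_cells = 100,
                          min_adipocyte_fraction = 0.5,
                          ai_definition = "total_over_adipocyte",
                          min_image_area_um2 = MIN_IMAGE_AREA_UM2,
                          force = FALSE) {
  mask <- binarize(image, threshold)
  qc_pass <- mean(mask$adipocyte) >= min_adipocyte_fraction
  labels <- label_adipocytes(mask, split = split)
  labels <- filter_complete_cells(labels, speck_floor_px = speck_floor_px)
  meas <- measure_cells(labels, um_per_px = image$um_per_px)
  ai <- if (qc_pass || force) {
    compute_adipocyte_index(mask, definition = ai_definition,
                            min_image_area_um2 = min_image_area_um2,
                            force = force)
  } else {
    NA
  }
  list(mask = mask, labels = labels, measurements = meas,
       ai = ai, qc_pass = qc_pass)
}
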