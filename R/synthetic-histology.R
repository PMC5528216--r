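#' Specification for a synthetic tissue image
#'
#' Describes the synthetic blubber section emulated by
#' [generate_tissue_image()]: lipid-filled adipocytes rendered as bright
#' non-overlapping discs in a darker-staining intervacuolar matrix, with
#' optional intensity noise and dark specks mimicking nuclei and debris.
#' Cell radii are lognormal; discs are placed by random sequential
#' adsorption (largest first) with a minimum matrix gap between cells.
#'
#' Defaults emulate an adipocyte-dominated field of outer blubber at 10x
#' magnification: 1024 x 1024 px at 0.65 um/px (a 443,000 um2 field, well
#' above the 167,687.3336 um2 floor required for a valid adipocyte index),
#' median cell radius 14.5 um (median cell area about 660 um2).
#'
#' @param width_px,height_px Image size in pixels.
#' @param um_per_px Micrometres per pixel.
#' @param bit_depth 8 or 16.
#' @param radius_log_mean,radius_log_sd Mean and SD of log cell radius
#'   (radius in micrometres). `radius_log_sd = 0` gives equal cells.
#' @param matrix_gap_um Minimum matrix thickness between cells (um).
#' @param noise_sd Gaussian intensity noise SD, in intensity units of the
#'   chosen bit depth; 0 disables noise.
#' @param speck_rate Dark specks (nuclei/debris mimic) per 1,000 um2.
#' @param target_fraction Adipocyte area fraction the packer aims for
#'   (analytic disc area; border clipping renders slightly less). Random
#'   sequential disc packing saturates well below the space-filling
#'   density of real adipose tissue, so feasible targets stop around 0.6
#'   at the default polydispersity; the default 0.58 renders an
#'   adipocyte-dominated field (fraction about 0.55, AI about 1.8).
#' @param n_cells Optional fixed number of cells; overrides
#'   `target_fraction` as the stopping rule.
#' @param max_attempts Placement attempts allowed per cell before the
#'   packer gives up.
#' @param elliptical If `TRUE`, each disc is perturbed into an ellipse of
#'   equal area (aspect drawn in \[1, 1.3\]); off by default, matching the
#'   circular cell model used for area measurement.
#' @param seed Integer RNG seed. Mandatory: identical seeds give
#'   bit-identical images and ground truth.
#'
#' @return An object of class `tissue_spec`.
#' @seealso [generate_tissue_image()]
#' @export
tissue_spec <- function(width_px = 1024L, height_px = 1024L,
                        um_per_px = 0.65, bit_depth = 8L,
                        radius_log_mean = log(14.5), radius_log_sd = 0.25,
                        matrix_gap_um = 2, noise_sd = 6, speck_rate = 0.3,
                        target_fraction = 0.58, n_cells = NULL,
                        max_attempts = 1e5L, elliptical = FALSE,
                        seed = NULL) {
  stopifnot(width_px >= 8, height_px >= 8, um_per_px > 0,
            bit_depth %in% c(8L, 16L), radius_log_sd >= 0,
            matrix_gap_um >= 0, noise_sd >= 0, speck_rate >= 0,
            target_fraction > 0, target_fraction < 1, max_attempts >= 1)
  if (is.null(seed)) stop("tissue_spec requires an explicit integer seed")
  # Enforce the >= 2 px diameter floor at this calibration: essentially all
  # of the radius distribution must clear one pixel.
  if (qlnorm(0.001, radius_log_mean, max(radius_log_sd, 1e-12)) < um_per_px) {
    stop("radius distribution yields cell diameters below 2 px at ",
         um_per_px, " um/px")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         um_per_px = um_per_px, bit_depth = as.integer(bit_depth),
         radius_log_mean = radius_log_mean, radius_log_sd = radius_log_sd,
         matrix_gap_um = matrix_gap_um, noise_sd = noise_sd,
         speck_rate = speck_rate, target_fraction = target_fraction,
         n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells),
         max_attempts = as.integer(max_attempts), elliptical = elliptical,
         seed = as.integer(seed)),
    class = "tissue_spec"
  )
}

# Intensity poles on the light-is-high scale, as fractions of the maximum:
# lipid-filled adipocyte area renders near-white, intervacuolar matrix
# dark, specks darker still.
ADIPOCYTE_LEVEL <- 0.90
MATRIX_LEVEL <- 0.12
SPECK_LEVEL <- 0.05

#' Generate a synthetic tissue image with ground truth
#'
#' Packs non-overlapping discs (cells) into the image by random sequential
#' adsorption, largest radius first, requiring centre-to-centre clearance
#' of at least the sum of radii plus `matrix_gap_um`. Cells are rendered at
#' the adipocyte (bright) pole and the matrix at the intervacuolar (dark)
#' pole of the light-is-high scale, then Gaussian noise and dark specks
#' are added, truncated to the bit-depth range. The returned ground truth
#' is derived from the noise-free rendered label mask, so `true_ai` is
#' exactly what [compute_adipocyte_index()] yields on that mask.
#'
#' @param spec A [tissue_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{a [raster_image()] (`light_high` convention)}
#'     \item{truth}{a `ground_truth` list: `label_mask` (0 = matrix,
#'       k >= 1 = cell k), `cell_areas_um2` (rasterized per-cell areas),
#'       `intervacuolar_fraction`, `true_ai`, and a `cells` data frame of
#'       centres and radii in micrometres}
#'   }
#' @export
generate_tissue_image <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  withr::with_seed(spec$seed, generate_tissue_image_impl(spec))
}

generate_tissue_image_impl <- function(spec) {
  w_um <- spec$width_px * spec$um_per_px
  h_um <- spec$height_px * spec$um_per_px
  total_um2 <- w_um * h_um

  cells <- pack_discs(spec, w_um, h_um, total_um2)

  lab <- rasterize_cells(cells, spec)
  npx <- length(lab)
  cell_px <- tabulate(lab[lab > 0L], nbins = nrow(cells))
  cell_areas <- cell_px * spec$um_per_px^2
  adip_frac <- sum(cell_px) / npx
  if (adip_frac == 0) stop("no cell pixels rendered")
  interv_frac <- 1 - adip_frac

  mx <- 2^spec$bit_depth - 1
  px <- matrix(MATRIX_LEVEL * mx, spec$height_px, spec$width_px)
  px[lab > 0L] <- ADIPOCYTE_LEVEL * mx

  if (spec$speck_rate > 0) {
    n_specks <- stats::rpois(1L, spec$speck_rate * total_um2 / 1000)
    if (n_specks > 0) {
      sx <- runif(n_specks, 0, spec$width_px)
      sy <- runif(n_specks, 0, spec$height_px)
      r_px <- pmax(1, round(runif(n_specks, 1, 2.5)))
      for (k in seq_len(n_specks)) {
        ii <- pmax(1L, pmin(spec$height_px,
                            as.integer(sy[k]) + seq(-r_px[k], r_px[k])))
        jj <- pmax(1L, pmin(spec$width_px,
                            as.integer(sx[k]) + seq(-r_px[k], r_px[k])))
        px[ii, jj] <- SPECK_LEVEL * mx
      }
    }
  }
  if (spec$noise_sd > 0) {
    px <- px + rnorm(length(px), sd = spec$noise_sd)
  }
  px <- round(pmin(pmax(px, 0), mx))

  image <- raster_image(px, bit_depth = spec$bit_depth,
                        um_per_px = spec$um_per_px,
                        convention = "light_high")
  truth <- structure(
    list(label_mask = lab, cell_areas_um2 = cell_areas,
         intervacuolar_fraction = interv_frac,
         true_ai = 1 / adip_frac, cells = cells),
    class = "ground_truth"
  )
  list(image = image, truth = truth)
}

# Random sequential adsorption of discs, largest first. Radii are drawn
# in batches from the lognormal (floored at one pixel radius) until the
# analytic disc area reaches the target, then placed in decreasing order
# so small cells can fill interstices.
pack_discs <- function(spec, w_um, h_um, total_um2) {
  draw_radii <- function(n) {
    r <- if (spec$radius_log_sd == 0) {
      rep(exp(spec$radius_log_mean), n)
    } else {
      rlnorm(n, spec$radius_log_mean, spec$radius_log_sd)
    }
    pmax(r, spec$um_per_px)
  }
  if (!is.null(spec$n_cells)) {
    radii <- draw_radii(spec$n_cells)
    target_um2 <- Inf
  } else {
    target_um2 <- spec$target_fraction * total_um2
    radii <- numeric(0)
    while (sum(pi * radii^2) < 1.3 * target_um2) {
      radii <- c(radii, draw_radii(64L))
    }
  }
  radii <- sort(radii, decreasing = TRUE)

  cx <- cy <- cr <- numeric(0)
  placed_um2 <- 0
  chunk <- 512L
  for (r in radii) {
    if (placed_um2 >= target_um2) break
    ok <- FALSE
    attempts_left <- spec$max_attempts
    while (attempts_left > 0L) {
      m <- min(chunk, attempts_left)
      attempts_left <- attempts_left - m
      x <- runif(m, 0, w_um); y <- runif(m, 0, h_um)
      if (length(cx) == 0) {
        x <- x[1]; y <- y[1]; ok <- TRUE; break
      }
      clear2 <- (cr + r + spec$matrix_gap_um)^2
      free <- colSums(outer(cx, x, "-")^2 + outer(cy, y, "-")^2 <
                        clear2) == 0L
      hit <- which(free)
      if (length(hit)) {
        x <- x[hit[1]]; y <- y[hit[1]]; ok <- TRUE; break
      }
    }
    if (ok) {
      cx <- c(cx, x); cy <- c(cy, y); cr <- c(cr, r)
      placed_um2 <- placed_um2 + pi * r^2
    } else if (!is.null(spec$n_cells)) {
      stop(sprintf(
        paste0("disc packing failed: could not place cell %d of %d ",
               "(radius %.2f um) after %d attempts; achieved adipocyte ",
               "fraction %.3f"),
        length(cx) + 1L, length(radii), r, spec$max_attempts,
        placed_um2 / total_um2))
    }
    # In target mode a failed radius is skipped; smaller radii may still fit.
  }
  if (is.finite(target_um2) && placed_um2 < target_um2) {
    stop(sprintf(
      paste0("disc packing failed: radii exhausted at adipocyte fraction ",
             "%.3f, below target %.3f"),
      placed_um2 / total_um2, spec$target_fraction))
  }
  if (length(cx) == 0) stop("disc packing produced no cells")
  asp <- rep(1, length(cx))
  ang <- rep(0, length(cx))
  if (isTRUE(spec$elliptical)) {
    asp <- runif(length(cx), 1, 1.3)
    ang <- runif(length(cx), 0, pi)
  }
  data.frame(x_um = cx, y_um = cy, radius_um = cr,
             aspect = asp, angle = ang)
}

# Pixel (i, j) has centre ((j - 0.5) upp, (i - 0.5) upp); a pixel belongs
# to cell k if its centre falls inside disc k (ellipse if perturbed).
# Clearance >= matrix gap guarantees membership is unique.
rasterize_cells <- function(cells, spec) {
  upp <- spec$um_per_px
  lab <- matrix(0L, spec$height_px, spec$width_px)
  for (k in seq_len(nrow(cells))) {
    r <- cells$radius_um[k]
    a <- r * sqrt(cells$aspect[k])  # semi-axes of equal-area ellipse
    b <- r / sqrt(cells$aspect[k])
    rmax <- max(a, b)
    j0 <- max(1L, floor((cells$x_um[k] - rmax) / upp))
    j1 <- min(spec$width_px, ceiling((cells$x_um[k] + rmax) / upp))
    i0 <- max(1L, floor((cells$y_um[k] - rmax) / upp))
    i1 <- min(spec$height_px, ceiling((cells$y_um[k] + rmax) / upp))
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    dx <- outer(rep(1, length(ii)), (jj - 0.5) * upp - cells$x_um[k])
    dy <- outer((ii - 0.5) * upp - cells$y_um[k], rep(1, length(jj)))
    if (cells$aspect[k] == 1) {
      inside <- dx^2 + dy^2 <= r^2
    } else {
      co <- cos(cells$angle[k]); si <- sin(cells$angle[k])
      u <- dx * co + dy * si
      v <- -dx * si + dy * co
      inside <- (u / a)^2 + (v / b)^2 <= 1
    }
    sub <- lab[ii, jj, drop = FALSE]
    sub[inside] <- k
    lab[ii, jj] <- sub
  }
  lab
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d cells, intervacuolar fraction %.3f, true AI %.4f\n",
    nrow(x$cells), x$intervacuolar_fraction, x$true_ai))
  invisible(x)
}
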