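# Independent oracles used by the test suite. These deliberately avoid the
# package's own fitting code paths.

# Bernoulli log-likelihood at coefficients beta for design matrix X
# (including the intercept column).
loglik_logistic <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Brute-force maximum-likelihood logistic coefficients by iterated
# grid refinement (coarse-to-fine zoom), independent of IRLS.
grid_logistic_oracle <- function(X, y, half_width = 8, points = 21,
                                 rounds = 8) {
  p <- ncol(X)
  centre <- rep(0, p)
  width <- rep(half_width, p)
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(centre[j] - width[j], centre[j] + width[j], length.out = points)
    })
    best <- -Inf
    best_beta <- centre
    # exhaustive scan of the p-dimensional grid
    idx <- rep(1L, p)
    repeat {
      beta <- vapply(seq_len(p), function(j) grids[[j]][idx[j]], 0)
      ll <- loglik_logistic(beta, X, y)
      if (ll > best) { best <- ll; best_beta <- beta }
      k <- 1L
      while (k <= p) {
        idx[k] <- idx[k] + 1L
        if (idx[k] <= points) break
        idx[k] <- 1L
        k <- k + 1L
      }
      if (k > p) break
    }
    centre <- best_beta
    width <- width * 2 / (points - 1)  # zoom in around the best point
  }
  centre
}

# Small helper: wrap a logical adipocyte matrix as a binary_mask the way
# binarize() would produce it, for metric tests that construct masks
# directly.
make_mask <- function(adipocyte, um_per_px = 1) {
  structure(
    list(adipocyte = adipocyte, um_per_px = um_per_px,
         provenance = list(threshold_dark_high = NA_real_,
                           threshold_file_scale = NA_real_,
                           bit_depth = 8L,
                           source_convention = "light_high")),
    class = "binary_mask")
}

# Render a light-is-high 8-bit raster image from a logical adipocyte mask.
mask_to_image <- function(adipocyte, um_per_px = 1) {
  px <- matrix(0, nrow(adipocyte), ncol(adipocyte))
  px[adipocyte] <- 255
  raster_image(px, bit_depth = 8L, um_per_px = um_per_px,
               convention = "light_high")
}

# Draw a filled disc into a logical matrix (pixel-centre membership).
draw_disc <- function(mat, cx, cy, r) {
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      if ((i - 0.5 - cy)^2 + (j - 0.5 - cx)^2 <= r^2) mat[i, j] <- TRUE
    }
  }
  mat
}
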