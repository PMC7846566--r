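#' Generate a synthetic H&E-style histology image
#'
#' Draws non-overlapping white ellipses (macrovesicular fat vacuoles) on a
#' noisy pink (eosin-stained tissue) background until the white-area fraction
#' is within 0.2 percentage points of the requested fat fraction. The
#' realized fraction and the exact vacuole mask are recorded as ground truth.
#'
#' @param fat_fraction_true target fat area fraction in percent (0-60).
#' @param vacuole_radius `c(mean, sd)` of the vacuole radius in micrometers;
#'   the mean must be at least 2 pixels.
#' @param image_size image size in pixels, `c(rows, cols)` or a scalar.
#' @param pixel_size pixel edge length in micrometers.
#' @param seed integer seed; identical seeds give identical images.
#' @param max_attempts placement attempts before giving up when the target
#'   fraction is unreachable without overlap.
#' @return object of class `histology_image`: `pixels` (rows x cols x 3 RGB
#'   in `[0, 1]`), `pixel_size`, `fat_fraction_true` (realized, percent),
#'   `fat_mask_true`, `n_vacuoles_true`.
#' @export
gen_histology <- function(fat_fraction_true, vacuole_radius = c(15, 4),
                          image_size = 256, pixel_size = 1, seed = 1,
                          max_attempts = 5000) {
  stopifnot(fat_fraction_true >= 0, fat_fraction_true <= 60,
            pixel_size > 0, length(vacuole_radius) == 2)
  if (vacuole_radius[1] / pixel_size < 2) {
    stop("mean vacuole radius must be at least 2 pixels")
  }
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  nr <- image_size[1]; nc <- image_size[2]
  npx <- nr * nc
  target <- fat_fraction_true / 100
  tol <- 0.2 / 100

  res <- with_seed_maybe(seed, {
    mask <- matrix(FALSE, nr, nc)
    n_vac <- 0L
    attempts <- 0L
    while (sum(mask) / npx < target - tol) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf("fat fraction %.1f%% unreachable without overlap after %d attempts (reached %.1f%%)",
                     fat_fraction_true, max_attempts, 100 * sum(mask) / npx))
      }
      r_um <- max(rnorm(1, vacuole_radius[1], vacuole_radius[2]),
                  2 * pixel_size)
      r_px <- r_um / pixel_size
      ecc <- runif(1, 0.8, 1.25)
      a <- r_px * ecc; b <- r_px / ecc
      th <- runif(1, 0, pi)
      # keep a 2 px border margin so vacuoles never touch the image edge
      # (a border-touching white vacuole would be indistinguishable from
      # slide background during segmentation)
      if (3 + a >= nr - 2 - a || 3 + a >= nc - 2 - a) next
      ctr <- c(runif(1, 3 + a, nr - 2 - a), runif(1, 3 + a, nc - 2 - a))
      rmax <- ceiling(max(a, b))
      rows <- max(1, floor(ctr[1] - rmax)):min(nr, ceiling(ctr[1] + rmax))
      cols <- max(1, floor(ctr[2] - rmax)):min(nc, ceiling(ctr[2] + rmax))
      dr <- outer(rows - ctr[1], rep(1, length(cols)))
      dc <- outer(rep(1, length(rows)), cols - ctr[2])
      ell <- ((dr * cos(th) + dc * sin(th)) / a)^2 +
        ((-dr * sin(th) + dc * cos(th)) / b)^2 <= 1
      if (any(mask[rows, cols] & ell)) next
      if ((sum(mask) + sum(ell)) / npx > target + tol) next
      sub <- mask[rows, cols]; sub[ell] <- TRUE
      mask[rows, cols] <- sub
      n_vac <- n_vac + 1L
    }
    # render: eosin-pink tissue, near-white vacuoles, light pixel noise
    px <- array(0, c(nr, nc, 3))
    tissue_rgb <- c(0.91, 0.62, 0.73)
    white_rgb <- c(0.97, 0.96, 0.97)
    for (ch in 1:3) {
      layer <- matrix(tissue_rgb[ch] + rnorm(npx, 0, 0.02), nr, nc)
      layer[mask] <- white_rgb[ch] + rnorm(sum(mask), 0, 0.008)
      px[, , ch] <- pmin(pmax(layer, 0), 1)
    }
    list(px = px, mask = mask, n_vac = n_vac)
  })

  structure(list(pixels = res$px, pixel_size = pixel_size,
                 fat_fraction_true = 100 * sum(res$mask) / npx,
                 fat_mask_true = res$mask,
                 n_vacuoles_true = res$n_vac,
                 seed = seed),
            class = "histology_image")
}

#' @export
print.histology_image <- function(x, ...) {
  cat(sprintf("<histology_image> %d x %d px @ %.2g um | true fat fraction %.2f%% (%d vacuoles)\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$pixel_size,
              x$fat_fraction_true, x$n_vacuoles_true))
  invisible(x)
}
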