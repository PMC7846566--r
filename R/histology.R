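#' Segment fat vacuoles and score the fat fraction
#'
#' Quantifies percent fat fraction from an H&E-style RGB image. Slide
#' background (near-white pixels connected to the image border) is excluded
#' from the tissue mask. Fat candidates are bright, low-saturation pixels
#' inside the tissue; the saturation threshold is Otsu's threshold computed
#' on tissue pixels, capped at `saturation_cap` so that a fat-free section
#' does not get split on noise. The candidate mask is cleaned by
#' morphological opening then closing with a disc, and components smaller
#' than `min_vacuole_area` are dropped. The fraction is fat area over tissue
#' area.
#'
#' @param image a `histology_image` (or any list with `pixels` rows x cols x
#'   3 RGB in `[0, 1]` and `pixel_size` in micrometers).
#' @param min_vacuole_area minimum vacuole area in square micrometers.
#' @param disc_radius structuring-element radius in pixels for the
#'   opening/closing.
#' @param brightness_min minimum HSV value channel for a fat candidate.
#' @param saturation_cap upper cap on the Otsu saturation threshold.
#' @return object of class `fat_fraction_result`: `fat_fraction` (percent),
#'   `fat_mask`, `tissue_mask`, `n_vacuoles`.
#' @export
segment_fat <- function(image, min_vacuole_area = 50, disc_radius = 3,
                        brightness_min = 0.75, saturation_cap = 0.15) {
  px <- image$pixels
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  pixel_size <- image$pixel_size %||% 1
  if (min_vacuole_area < pixel_size^2) {
    stop("min_vacuole_area must be at least one pixel")
  }
  nr <- dim(px)[1]; nc <- dim(px)[2]
  hsv <- rgb2hsv(r = as.vector(px[, , 1]), g = as.vector(px[, , 2]),
                 b = as.vector(px[, , 3]), maxColorValue = 1)
  s <- matrix(hsv["s", ], nr, nc)
  v <- matrix(hsv["v", ], nr, nc)

  near_white <- v > 0.92 & s < 0.08
  background <- border_connected(near_white)
  tissue <- !background
  if (!any(tissue)) stop("empty tissue mask: image contains no tissue")

  thr <- min(otsu_threshold(s[tissue]), saturation_cap)
  fat <- tissue & v > brightness_min & s < thr
  fat <- mask_close(mask_open(fat, disc_radius), disc_radius)
  fat <- fat & tissue

  n_vac <- 0L
  if (any(fat)) {
    lab <- label_components(fat)
    areas <- tabulate(lab[!is.na(lab)])
    keep <- which(areas * pixel_size^2 >= min_vacuole_area)
    fat <- !is.na(lab) & lab %in% keep
    n_vac <- length(keep)
  }
  structure(list(fat_fraction = 100 * sum(fat) / sum(tissue),
                 fat_mask = fat, tissue_mask = tissue,
                 n_vacuoles = n_vac),
            class = "fat_fraction_result")
}

#' @export
print.fat_fraction_result <- function(x, ...) {
  cat(sprintf("<fat_fraction_result> fat fraction %.2f%% | %d vacuoles | tissue %d px\n",
              x$fat_fraction, x$n_vacuoles, sum(x$tissue_mask)))
  invisible(x)
}
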