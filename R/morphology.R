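# Binary morphology on logical matrices, via vectorized shifts.
# Outside-image pixels are treated as FALSE (background).

disc_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

mask_dilate <- function(mask, radius = 3) {
  off <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(mask, off$dr[i], off$dc[i])
  }
  out
}

mask_erode <- function(mask, radius = 3) {
  !mask_dilate(!mask, radius)
}

mask_open <- function(mask, radius = 3) mask_dilate(mask_erode(mask, radius), radius)
mask_close <- function(mask, radius = 3) mask_erode(mask_dilate(mask, radius), radius)

# 4-connected component labelling by iterative minimum-label propagation.
# Fine for blob-like masks (converges in O(component diameter) passes).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  lab[!mask] <- NA_integer_
  repeat {
    nb <- pmin(shift_mat_int(lab, 1, 0), shift_mat_int(lab, -1, 0),
               shift_mat_int(lab, 0, 1), shift_mat_int(lab, 0, -1), na.rm = TRUE)
    new <- pmin(lab, nb, na.rm = TRUE)
    new[!mask] <- NA_integer_
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels to 1..n
  ids <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], ids)
  lab
}

shift_mat_int <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_integer_, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# region of `mask` 4-connected to the image border
border_connected <- function(mask) {
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- mask[1, ]; reach[nrow(mask), ] <- mask[nrow(mask), ]
  reach[, 1] <- reach[, 1] | mask[, 1]
  reach[, ncol(mask)] <- reach[, ncol(mask)] | mask[, ncol(mask)]
  repeat {
    grown <- (reach | shift_mat(reach, 1, 0) | shift_mat(reach, -1, 0) |
                shift_mat(reach, 0, 1) | shift_mat(reach, 0, -1)) & mask
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}
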