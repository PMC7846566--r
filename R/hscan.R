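#' Depth-gain attenuation correction
#'
#' Applies the bulk two-way gain `10^(coeff * fc[MHz] * 2 * z[cm] / 20)` to
#' every RF sample, with `fc` the frame's center frequency and `z` the sample
#' depth. The frame is flagged so the correction cannot be applied twice.
#'
#' @param frame an [rf_frame()].
#' @param coeff attenuation coefficient in dB/cm/MHz (>= 0). The study
#'   default for liver is 0.3 dB/cm/MHz.
#' @return the corrected [rf_frame()] (metadata flag set).
#' @export
attenuation_correct <- function(frame, coeff = 0.3) {
  stopifnot(inherits(frame, "rf_frame"))
  if (coeff < 0) stop("attenuation coefficient must be >= 0")
  if (isTRUE(frame$attenuation_corrected)) {
    stop("frame is already attenuation-corrected; refusing to apply twice")
  }
  z_cm <- rf_depth(frame) * 100
  gain <- 10^(coeff * (frame$center_frequency / 1e6) * 2 * z_cm / 20)
  frame$samples <- frame$samples * gain
  frame$attenuation_corrected <- TRUE
  frame$attenuation_coeff <- coeff
  frame
}

# physicists' Hermite polynomial H_n evaluated by recurrence
hermite_poly <- function(n, x) {
  if (n == 0) return(rep(1, length(x)))
  if (n == 1) return(2 * x)
  hm1 <- rep(1, length(x)); h <- 2 * x
  for (k in 2:n) {
    tmp <- 2 * x * h - 2 * (k - 1) * hm1
    hm1 <- h; h <- tmp
  }
  h
}

#' Gaussian-weighted Hermite matched-filter kernel
#'
#' Samples `GH_n(t) = H_n(t / sigma) * exp(-t^2 / (2 sigma^2))` (physicists'
#' Hermite polynomial) on a grid of at least +/- 6 sigma, and records the
#' kernel's signal energy `E_n = integral(GH_n^2 dt)` and spectral peak
#' frequency. Matched-filter outputs are normalized by `sqrt(E_n)` so that
#' the red/blue channel comparison is energy-fair across orders.
#'
#' @param order integer order n in 0..12.
#' @param time_scale Gaussian time scale sigma in seconds.
#' @param sampling_rate sampling rate in Hz; must resolve the kernel
#'   (at least 4 x its spectral peak frequency).
#' @return an object of class `gh_kernel` with fields `order`, `time_scale`,
#'   `taps`, `energy`, `peak_frequency`.
#' @export
make_gh_kernel <- function(order, time_scale, sampling_rate) {
  stopifnot(order %in% 0:12, time_scale > 0, sampling_rate > 0)
  half <- ceiling(6 * time_scale * sampling_rate)
  t <- (-half:half) / sampling_rate
  taps <- hermite_poly(order, t / time_scale) * exp(-t^2 / (2 * time_scale^2))
  energy <- sum(taps^2) / sampling_rate
  # spectral peak via zero-padded FFT and 3-point parabolic refinement
  nfft <- max(4096, nextn(length(taps), 2))
  spec <- Mod(fft(c(taps, rep(0, nfft - length(taps)))))[1:(nfft / 2)]
  i <- which.max(spec)
  if (i > 1 && i < length(spec)) {
    num <- spec[i - 1] - spec[i + 1]
    den <- spec[i - 1] - 2 * spec[i] + spec[i + 1]
    i <- i + ifelse(abs(den) > 0, 0.5 * num / den, 0)
  }
  peak_frequency <- (i - 1) * sampling_rate / nfft
  if (order > 0 && sampling_rate < 4 * peak_frequency) {
    stop(sprintf("kernel under-resolved: sampling_rate %.3g Hz < 4 x peak frequency %.3g Hz",
                 sampling_rate, peak_frequency))
  }
  structure(list(order = order, time_scale = time_scale, taps = taps,
                 energy = energy, peak_frequency = peak_frequency),
            class = "gh_kernel")
}

#' @export
print.gh_kernel <- function(x, ...) {
  cat(sprintf("<gh_kernel> GH_%d | sigma %.3g s | %d taps | E %.4g | peak %.3g Hz\n",
              x$order, x$time_scale, length(x$taps), x$energy, x$peak_frequency))
  invisible(x)
}

#' Matched pair of GH kernels for an analysis band
#'
#' Chooses a single shared time scale sigma for the low- and high-order
#' kernels. The spectral peak ratio of the two orders is fixed by the orders
#' themselves, so sigma only slides the pair along the frequency axis; it is
#' set so that the geometric mean of the two peaks equals
#' `min(center_frequency, target_cap * sqrt(band[1] * band[2]) ...)` -- in
#' practice the largest value that still keeps the high-order peak inside the
#' analysis band (with the transducer center frequency as an upper bound).
#' This keeps both matched filters inside the band-pass that follows them.
#'
#' @param center_frequency transducer center frequency in Hz.
#' @param band analysis band in Hz (default 5-18 MHz).
#' @param sampling_rate sampling rate in Hz.
#' @param orders the two GH orders, low then high (default 2 and 8).
#' @return list with elements `low` and `high` ([make_gh_kernel()] objects)
#'   and the chosen `sigma`.
#' @export
hscan_kernels <- function(center_frequency = 15e6, band = c(5e6, 18e6),
                          sampling_rate = 84e6, orders = c(2, 8)) {
  stopifnot(length(orders) == 2, orders[1] < orders[2])
  # peak frequencies scale as 1/sigma: measure them once at a reference sigma
  ref_sigma <- 10 / center_frequency
  p_lo <- make_gh_kernel(orders[1], ref_sigma, 1e3 * center_frequency)$peak_frequency
  p_hi <- make_gh_kernel(orders[2], ref_sigma, 1e3 * center_frequency)$peak_frequency
  ratio <- sqrt(p_hi / p_lo)            # peak_hi / geometric mean
  target <- min(center_frequency, 0.95 * band[2] / ratio)
  geo_ref <- sqrt(p_lo * p_hi)
  sigma <- ref_sigma * geo_ref / target
  list(low = make_gh_kernel(orders[1], sigma, sampling_rate),
       high = make_gh_kernel(orders[2], sigma, sampling_rate),
       sigma = sigma)
}

#' H-scan image reconstruction
#'
#' Runs the two parallel GH matched filters over every RF line, normalizes
#' each output by the kernel signal energy `sqrt(E_n)`, band-passes the
#' filtered channels (zero-phase), and takes Hilbert envelopes. The envelope
#' of the original, unfiltered data forms the B-scan channel. The H-scan
#' intensity map is the elementwise ratio `B / (R + B)` of the high-frequency
#' (blue) channel to the channel sum; samples within one kernel half-length
#' of the frame edges, or where `R + B` vanishes, are flagged `NA`.
#'
#' @param frame an attenuation-corrected [rf_frame()].
#' @param low_kernel,high_kernel GH kernels of distinct orders, low (red)
#'   first; see [hscan_kernels()].
#' @param band band-pass interval in Hz applied to the GH channels.
#' @return an object of class `hscan_image` with matrices `bscan_envelope`,
#'   `red_channel`, `blue_channel`, `intensity_map`.
#' @export
hscan_reconstruct <- function(frame, low_kernel, high_kernel,
                              band = c(5e6, 18e6)) {
  stopifnot(inherits(frame, "rf_frame"),
            inherits(low_kernel, "gh_kernel"), inherits(high_kernel, "gh_kernel"))
  if (!isTRUE(frame$attenuation_corrected)) {
    stop("frame must be attenuation-corrected first (see attenuation_correct(); use coeff = 0 for none)")
  }
  if (low_kernel$order == high_kernel$order) {
    stop("the two kernels must have distinct orders")
  }
  if (!(band[2] > band[1]) || band[2] > frame$sampling_rate / 2) {
    stop("band must be non-degenerate and within Nyquist")
  }
  x <- frame$samples
  fs <- frame$sampling_rate
  r <- conv_same_cols(x, low_kernel$taps) / sqrt(low_kernel$energy)
  b <- conv_same_cols(x, high_kernel$taps) / sqrt(high_kernel$energy)
  r <- envelope(bandpass_fft(r, fs, band))
  b <- envelope(bandpass_fft(b, fs, band))
  bscan <- envelope(x)

  margin <- max((length(low_kernel$taps) - 1) / 2,
                (length(high_kernel$taps) - 1) / 2)
  n <- nrow(x)
  bad_rows <- c(seq_len(min(margin, n)), seq.int(max(1, n - margin + 1), n))
  denom <- r + b
  intensity <- ifelse(denom > 0, b / denom, NA_real_)
  intensity[bad_rows, ] <- NA_real_

  structure(list(bscan_envelope = bscan, red_channel = r, blue_channel = b,
                 intensity_map = intensity,
                 band = band, edge_margin = margin,
                 depth = rf_depth(frame), line_pitch = frame$line_pitch),
            class = "hscan_image")
}

#' @export
print.hscan_image <- function(x, ...) {
  cat(sprintf("<hscan_image> %d x %d | band %.1f-%.1f MHz | median intensity %.3f\n",
              nrow(x$bscan_envelope), ncol(x$bscan_envelope),
              x$band[1] / 1e6, x$band[2] / 1e6,
              median(x$intensity_map, na.rm = TRUE)))
  invisible(x)
}

#' Region-of-interest intensity metrics
#'
#' @param image an `hscan_image` from [hscan_reconstruct()].
#' @param roi integer vector `c(row_min, row_max, col_min, col_max)` in image
#'   coordinates (axial rows, lateral columns); the ROI must contain at least
#'   100 pixels.
#' @return named numeric vector with `bscan_intensity` (mean B-scan envelope,
#'   a.u.) and `hscan_intensity` (mean of the `B/(R+B)` map over defined
#'   pixels, dimensionless in `[0, 1]`).
#' @export
roi_metrics <- function(image, roi) {
  stopifnot(inherits(image, "hscan_image"), length(roi) == 4)
  roi <- as.integer(roi)
  dm <- dim(image$bscan_envelope)
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > dm[1] || roi[4] > dm[2] ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("roi out of image bounds")
  }
  if ((roi[2] - roi[1] + 1) * (roi[4] - roi[3] + 1) < 100) {
    stop("roi must contain at least 100 pixels")
  }
  rows <- roi[1]:roi[2]; cols <- roi[3]:roi[4]
  hvals <- image$intensity_map[rows, cols]
  if (all(is.na(hvals))) stop("roi contains only undefined H-scan pixels")
  c(bscan_intensity = mean(image$bscan_envelope[rows, cols]),
    hscan_intensity = mean(hvals, na.rm = TRUE))
}
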