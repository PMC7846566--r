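`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tukey (tapered cosine) window
#'
#' @param n window length in samples.
#' @param alpha total fraction of the window inside the cosine ramps
#'   (`alpha/2` at each end). `alpha = 0` gives a rectangular window.
#' @param side `"both"` for the usual symmetric window, `"right"` for a
#'   window that is flat at the start and rolls off only at the far end
#'   (used on the lateral axis of the f-k analysis, where the shear wave
#'   source sits at the near edge).
#' @return numeric vector of length `n` in `[0, 1]`.
#' @export
tukey_window <- function(n, alpha = 0.25, side = c("both", "right")) {
  side <- match.arg(side)
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  w <- rep(1, n)
  edge <- floor(alpha * (n - 1) / 2)
  if (edge > 0) {
    i <- 0:edge
    ramp <- 0.5 * (1 + cos(pi * (2 * i / (alpha * (n - 1)) - 1)))
    if (side == "both") w[1:(edge + 1)] <- ramp
    w[n:(n - edge)] <- ramp
  }
  w
}

# DFT frequency axis in natural (wrapped) order: 0, 1/(n d), ..., negative.
fft_freq <- function(n, d = 1) {
  (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / (n * d)
}

#' Signal envelope via the analytic signal
#'
#' Computes `Mod(x + i H[x])` column-wise with the Hilbert transform realized
#' in the frequency domain.
#'
#' @param x numeric vector or matrix (columns are signals).
#' @return envelope with the shape of `x`.
#' @export
envelope <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- mvfft(mvfft(x) * h, inverse = TRUE) / n
  out <- Mod(a)
  if (vec) drop(out) else out
}

# Zero-phase band-pass along columns: FFT-domain mask with raised-cosine
# roll-off of width `roll * (hi - lo)` outside each band edge.
bandpass_fft <- function(x, fs, band, roll = 0.05) {
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1],
            band[2] <= fs / 2)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  f <- abs(fft_freq(n, 1 / fs))
  w <- roll * (band[2] - band[1])
  mask <- rep(0, n)
  inside <- f >= band[1] & f <= band[2]
  mask[inside] <- 1
  lo_ramp <- f > band[1] - w & f < band[1]
  mask[lo_ramp] <- 0.5 * (1 + cos(pi * (band[1] - f[lo_ramp]) / w))
  hi_ramp <- f > band[2] & f < band[2] + w
  mask[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - band[2]) / w))
  out <- Re(mvfft(mvfft(x) * mask, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

# "Same"-size linear convolution of each column of `x` with `taps`
# (odd-length, centered), via zero-padded FFT.
conv_same_cols <- function(x, taps) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  m <- length(taps)
  stopifnot(m %% 2 == 1)
  nfft <- nextn(n + m - 1, 2)
  H <- fft(c(taps, rep(0, nfft - m)))
  X <- mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(mvfft(X * H, inverse = TRUE)) / nfft
  half <- (m - 1) / 2
  out <- y[(half + 1):(half + n), , drop = FALSE]
  if (vec) drop(out) else out
}

# Otsu's threshold on a numeric vector (maximizes between-class variance).
otsu_threshold <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  stopifnot(length(v) > 1)
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(pmax(1L, as.integer((v - r[1]) / diff(r) * n_bins) + 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Deterministic 32-bit seed stream derived from a master seed and a
# character/integer path (subject id, timepoint, stage name, ...).
derive_seed <- function(master, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(p) else as.integer(p)
  }))
  h <- as.double(master) %% 2147483647
  for (p in parts) h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(h)
}

# run `expr` under a fixed seed when `seed` is non-NULL, leaving the caller's
# RNG state untouched; otherwise evaluate as-is.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
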