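#' Phase-based displacement estimation from IQ data
#'
#' Loupas-type lag-1 slow-time autocorrelation: for each lateral position and
#' frame pair, the displacement increment is
#' `d = c * angle(sum_z conj(s_t) s_{t+1}) / (4 pi f_demod)`, with the sum
#' running over an axial kernel. Increments are cumulatively summed over slow
#' time to give the displacement movie `u(x, t)`. When several whole axial
#' kernels fit in the ensemble, one displacement row is produced per kernel.
#'
#' A phase wrap (autocorrelation angle within 5% of +/- pi) flags the result
#' as aliased.
#'
#' @param iq an [iq_ensemble()].
#' @param axial_kernel axial kernel length in samples (>= 4).
#' @return a [displacement_field()] (meters), `aliased` flag set when phase
#'   wrapping was detected.
#' @export
estimate_displacement <- function(iq, axial_kernel = 8) {
  stopifnot(inherits(iq, "iq_ensemble"), axial_kernel >= 4)
  d <- dim(iq$data)
  if (d[3] < 2) stop("need at least 2 slow-time frames")
  n_blocks <- max(1L, d[1] %/% as.integer(axial_kernel))
  u <- array(0, c(n_blocks, d[2], d[3]))
  aliased <- FALSE
  scale <- iq$sound_speed / (4 * pi * iq$demod_frequency)
  prod_ <- Conj(iq$data[, , 1:(d[3] - 1), drop = FALSE]) *
    iq$data[, , 2:d[3], drop = FALSE]
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1) * axial_kernel + 1):min(b * axial_kernel, d[1])
    ac <- apply(prod_[rows, , , drop = FALSE], c(2, 3), sum)
    ang <- Arg(ac)
    if (any(abs(ang) >= 0.95 * pi)) aliased <- TRUE
    dd <- scale * ang                        # lateral x (nt - 1)
    cum <- apply(dd, 1, cumsum)              # (nt-1) x lateral, or a vector
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    u[b, , ] <- cbind(0, t(cum))
  }
  out <- displacement_field(u, dx = iq$lateral_pitch, dt = 1 / iq$prf,
                            aliased = aliased)
  if (aliased) warning("phase wrapping detected: displacement field flagged as aliased")
  out
}

#' 2D Fourier (f-k) spectrum of a displacement movie
#'
#' Transforms `u(x, t)` at one depth row into wavenumber-frequency space,
#' `F(k, f) = sum u(x, t) exp(-i k x + i 2 pi f t)`, after mean removal and
#' separable tapering. A wave travelling towards +x at speed c appears at
#' `k = 2 pi f / c` in the `f > 0` half-plane. The slow-time axis uses a
#' symmetric Tukey(0.25) taper; the lateral axis a one-sided Tukey that rolls
#' off only at the far edge, preserving the sharp wave onset at the push side
#' whose spectral tails encode the attenuation.
#'
#' @param field a [displacement_field()].
#' @param depth_row depth row index to analyze (default: middle row).
#' @return object of class `fk_spectrum`: complex matrix `S` (k x f, natural
#'   FFT order), axes `k` (rad/m) and `f` (Hz), the tapered field (for
#'   Parseval checks) and grid metadata.
#' @export
fk_transform <- function(field, depth_row = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(field$u)
  depth_row <- depth_row %||% ((d[1] + 1) %/% 2)
  stopifnot(depth_row >= 1, depth_row <= d[1])
  if (d[2] < 8) stop("need at least 8 lateral samples")
  if (d[3] < 16) stop("need at least 16 slow-time samples")
  M <- field$u[depth_row, , ]
  if (all(M == 0)) stop("degenerate input: displacement field is identically zero")
  M <- M - mean(M)
  M <- M * (tukey_window(d[2], side = "right") %o% tukey_window(d[3]))
  A <- mvfft(M)                          # over x, e^{-ikx}
  S <- t(mvfft(t(A), inverse = TRUE))    # over t, e^{+i 2 pi f t}
  structure(list(S = S,
                 k = 2 * pi * fft_freq(d[2], field$dx),
                 f = fft_freq(d[3], field$dt),
                 tapered = M, dx = field$dx, dt = field$dt),
            class = "fk_spectrum")
}

# least-squares Lorentzian fit of a squared-magnitude wavenumber profile:
# P(k) ~ p / ((k - k0)^2 + gamma^2). Returns sub-bin peak k0, half-width
# gamma, and fit R^2. Fit window: contiguous bins >= 2% of the peak.
fit_lorentzian <- function(k, P) {
  i0 <- which.max(P)
  lo <- i0; while (lo - 1 >= 1 && P[lo - 1] >= 0.02 * P[i0]) lo <- lo - 1
  hi <- i0; while (hi + 1 <= length(P) && P[hi + 1] >= 0.02 * P[i0]) hi <- hi + 1
  if (hi - lo < 6) { lo <- max(1, i0 - 5); hi <- min(length(P), i0 + 5) }
  if (hi - lo < 4) stop("unresolved wavenumber peak: too few bins to fit")
  kc <- k[i0]; ksc <- max(abs(k[hi] - k[lo]), 1e-12)
  ks <- (k[lo:hi] - kc) / ksc
  Ps <- P[lo:hi] / P[i0]
  # init: weighted quadratic regression on 1/P (exact for a Lorentzian)
  y <- 1 / Ps; w <- Ps^2
  X <- cbind(1, ks, ks^2)
  cf <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w))),
                 error = function(e) c(1, 0, 1))
  k0i <- if (cf[3] > 0) -cf[2] / (2 * cf[3]) else 0
  g2i <- max(if (cf[3] > 0) cf[1] / cf[3] - k0i^2 else 0.01, 1e-4)
  p0 <- if (cf[3] > 0) 1 / cf[3] else g2i   # 1/P ~ (k^2 ... ) / p
  obj <- function(th) {
    pred <- exp(th[3]) / ((ks - th[1])^2 + exp(th[2])^2)
    sum((Ps - pred)^2)
  }
  o <- optim(c(k0i, log(sqrt(g2i)), log(p0)), obj,
             method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  if (o$convergence != 0) {
    stop("Lorentzian fit did not converge; residual = ", signif(o$value, 4))
  }
  fitv <- exp(o$par[3]) / ((ks - o$par[1])^2 + exp(o$par[2])^2)
  r2 <- 1 - sum((Ps - fitv)^2) / sum((Ps - mean(Ps))^2)
  list(k0 = kc + o$par[1] * ksc, gamma = exp(o$par[2]) * ksc,
       r_squared = max(0, min(1, r2)), window = c(lo, hi))
}

# cached taper-broadening calibration: half-width (rad/m) that the analysis
# taper imprints on an undamped wave at (k0, f0) on the given grid.
.taper_cache <- new.env(parent = emptyenv())

taper_broadening <- function(nx, nt, dx, dt, k0, f0) {
  key <- paste(nx, nt, signif(dx, 6), signif(dt, 6), round(k0), round(f0),
               sep = "|")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  x <- (0:(nx - 1)) * dx
  t <- (0:(nt - 1)) * dt
  U0 <- sin(outer(-k0 * x, 2 * pi * f0 * t, "+"))
  sp0 <- fk_transform(displacement_field(array(U0, c(1, nx, nt)), dx, dt))
  P0 <- Mod(sp0$S)^2
  pos_k <- which(sp0$k > 0)
  fi <- which.min(abs(sp0$f - f0))
  fit0 <- fit_lorentzian(sp0$k[pos_k], P0[pos_k, fi])
  .taper_cache[[key]] <- fit0$gamma
  fit0$gamma
}

#' Shear wave speed and attenuation from an f-k spectrum
#'
#' Finds the global spectral maximum in the positive-frequency,
#' positive-wavenumber quadrant. The analysis frequency `f*` is its temporal
#' frequency; the wave speed is `2 pi f* / k_peak` with the wavenumber peak
#' localized to sub-bin precision. The attenuation is the half-width at
#' half-maximum of the squared-magnitude wavenumber profile at `f*`, from a
#' least-squares Lorentzian fit (exact for an exponentially damped
#' sinusoid), after subtracting the analytically measured broadening of the
#' analysis taper in quadrature.
#'
#' @param spectrum an `fk_spectrum` from [fk_transform()].
#' @return object of class `shear_wave_result`: `speed` (m/s), `attenuation`
#'   (Np/m), `analysis_frequency` (Hz), `r_squared` of the Lorentzian fit,
#'   and `resolution_floor` (Np/m), the taper half-width below which
#'   attenuation is not resolved.
#' @export
estimate_speed_attenuation <- function(spectrum) {
  stopifnot(inherits(spectrum, "fk_spectrum"))
  P <- Mod(spectrum$S)^2
  pos_k <- which(spectrum$k > 0)
  pos_f <- which(spectrum$f > 0)
  sub <- P[pos_k, pos_f, drop = FALSE]
  ij <- arrayInd(which.max(sub), dim(sub))
  ki <- pos_k[ij[1]]; fi <- pos_f[ij[2]]
  if (ij[1] %in% c(1L, length(pos_k))) {
    stop("wavenumber peak at spectrum edge: shear wave unresolved on this aperture")
  }
  f_star <- spectrum$f[fi]
  fit <- fit_lorentzian(spectrum$k[pos_k], P[pos_k, fi])
  speed <- 2 * pi * f_star / fit$k0
  floor_g <- taper_broadening(nrow(P), ncol(P), spectrum$dx, spectrum$dt,
                              fit$k0, f_star)
  attenuation <- sqrt(max(fit$gamma^2 - floor_g^2, 0))
  structure(list(speed = speed, attenuation = attenuation,
                 analysis_frequency = f_star, r_squared = fit$r_squared,
                 resolution_floor = floor_g),
            class = "shear_wave_result")
}

#' @export
print.shear_wave_result <- function(x, ...) {
  cat(sprintf("<shear_wave_result> SWS %.3f m/s | SWA %.1f Np/m | f* %.0f Hz | R2 %.3f\n",
              x$speed, x$attenuation, x$analysis_frequency, x$r_squared))
  invisible(x)
}

#' One-call shear wave measurement from IQ data
#'
#' Convenience wrapper: displacement estimation, restriction of the slow-time
#' axis to the trailing steady-state window (so every lateral position sees
#' the same effective observation time at the analysis frequency), f-k
#' transform, and speed/attenuation estimation. When the displacement field
#' carries several depth rows, up to `depth_rows` central rows are analyzed
#' and the median speed/attenuation reported.
#'
#' @param iq an [iq_ensemble()].
#' @param axial_kernel axial kernel for [estimate_displacement()].
#' @param n_analysis number of trailing slow-time frames analyzed.
#' @param depth_rows maximum number of central depth rows to aggregate
#'   (median), default 5.
#' @return a `shear_wave_result` (fields aggregated over rows).
#' @export
swe_measure <- function(iq, axial_kernel = 8, n_analysis = 128,
                        depth_rows = 5) {
  field <- estimate_displacement(iq, axial_kernel)
  d <- dim(field$u)
  n_an <- min(n_analysis, d[3])
  crop <- displacement_field(field$u[, , (d[3] - n_an + 1):d[3], drop = FALSE],
                             field$dx, field$dt, aliased = field$aliased)
  rows <- seq_len(d[1])
  if (length(rows) > depth_rows) {
    mid <- (d[1] + 1) %/% 2
    rows <- intersect(mid + seq(-(depth_rows %/% 2), depth_rows %/% 2), rows)
  }
  res <- lapply(rows, function(r) {
    estimate_speed_attenuation(fk_transform(crop, depth_row = r))
  })
  out <- res[[1]]
  out$speed <- median(vapply(res, `[[`, 0, "speed"))
  out$attenuation <- median(vapply(res, `[[`, 0, "attenuation"))
  out$r_squared <- median(vapply(res, `[[`, 0, "r_squared"))
  out
}
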