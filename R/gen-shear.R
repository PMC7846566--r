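#' Sampling grid for synthetic shear-wave movies
#'
#' @param dx lateral spacing in meters.
#' @param n_lateral number of lateral positions.
#' @param prf slow-time frame rate in Hz.
#' @param n_axial number of axial IQ samples carried per position.
#' @param duration total slow-time duration in seconds, or `NULL` to cover
#'   the wave's transit across the aperture plus a steady-state tail.
#' @param tail_periods steady-state tail length in shear periods used when
#'   `duration` is `NULL`.
#' @return a plain list consumed by [gen_shear_movie()].
#' @export
shear_grid <- function(dx = 0.625e-3, n_lateral = 384, prf = 1600,
                       n_axial = 12, duration = NULL, tail_periods = 16) {
  stopifnot(dx > 0, n_lateral >= 8, prf > 0, n_axial >= 4, tail_periods > 0)
  list(dx = dx, n_lateral = n_lateral, prf = prf, n_axial = n_axial,
       duration = duration, tail_periods = tail_periods)
}

#' Generate a damped plane shear wave embedded in IQ data
#'
#' Ground-truth displacement is the single-frequency, exponentially damped
#' travelling wave
#' `u(x, t) = A exp(-attenuation x) sin(2 pi f (t - x / speed))` for
#' `t >= x / speed` and zero before arrival. The wave is written into an IQ
#' ensemble as axial phase modulation `exp(i 4 pi f_demod u / c)` on a static
#' random-phase speckle pattern, plus complex white Gaussian noise at the
#' requested SNR.
#'
#' @param speed shear wave speed in m/s.
#' @param attenuation amplitude attenuation in Np/m (>= 0). When positive the
#'   lateral aperture must span at least `3 / attenuation`.
#' @param shear_frequency wave frequency in Hz; the grid must provide at
#'   least 8 slow-time samples per period.
#' @param grid a [shear_grid()].
#' @param demod_frequency IQ demodulation frequency in Hz.
#' @param snr_db IQ signal-to-noise ratio in dB (`Inf` for noiseless).
#' @param amplitude peak displacement A in meters. Displacements at or past
#'   the phase-wrapping limit `c / (4 f_demod)` are rejected.
#' @param sound_speed speed of sound in m/s.
#' @param seed integer seed (bit-reproducible output for a fixed seed).
#' @return list with `iq` (an [iq_ensemble()]) and `truth` (a
#'   [displacement_field()] plus the generating parameters as attributes).
#' @export
gen_shear_movie <- function(speed, attenuation, shear_frequency = 200,
                            grid = shear_grid(), demod_frequency = 5e6,
                            snr_db = 25, amplitude = 10e-6,
                            sound_speed = 1540, seed = 1) {
  stopifnot(speed > 0, attenuation >= 0, shear_frequency > 0, amplitude > 0)
  if (grid$prf < 8 * shear_frequency) {
    stop("grid does not resolve the shear frequency: need prf >= 8 * shear_frequency")
  }
  extent <- (grid$n_lateral - 1) * grid$dx
  if (attenuation > 0 && extent < 3 / attenuation) {
    stop(sprintf("lateral extent %.3g m too small: need >= 3/attenuation = %.3g m",
                 extent, 3 / attenuation))
  }
  alias_limit <- sound_speed / (4 * demod_frequency)
  if (amplitude >= alias_limit) {
    stop(sprintf("peak displacement %.3g m would wrap the IQ phase; aliasing limit is %.3g m",
                 amplitude, alias_limit))
  }
  x <- (0:(grid$n_lateral - 1)) * grid$dx
  dur <- grid$duration %||% (max(x) / speed + grid$tail_periods / shear_frequency)
  nt <- ceiling(dur * grid$prf)
  t <- (0:(nt - 1)) / grid$prf
  tau <- outer(-x / speed, t, "+")              # t - x/speed
  u <- amplitude * exp(-attenuation * x) * sin(2 * pi * shear_frequency * tau)
  u[tau < 0] <- 0

  na <- grid$n_axial
  nx <- grid$n_lateral
  data <- with_seed_maybe(seed, {
    base <- exp(1i * matrix(runif(na * nx, 0, 2 * pi), na, nx))
    ph <- 4 * pi * demod_frequency / sound_speed
    arr <- array(0i, c(na, nx, nt))
    noise_sd <- if (is.finite(snr_db)) 10^(-snr_db / 20) / sqrt(2) else 0
    for (k in seq_len(nt)) {
      fr <- base * matrix(exp(1i * ph * u[, k]), na, nx, byrow = TRUE)
      if (noise_sd > 0) {
        fr <- fr + complex(real = rnorm(na * nx, 0, noise_sd),
                           imaginary = rnorm(na * nx, 0, noise_sd))
      }
      arr[, , k] <- fr
    }
    arr
  })

  truth <- displacement_field(array(u, c(1, nx, nt)), dx = grid$dx,
                              dt = 1 / grid$prf)
  attr(truth, "params") <- list(speed = speed, attenuation = attenuation,
                                shear_frequency = shear_frequency,
                                amplitude = amplitude, snr_db = snr_db,
                                seed = seed)
  list(iq = iq_ensemble(data, demod_frequency, grid$prf, grid$dx,
                        sound_speed = sound_speed),
       truth = truth)
}
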