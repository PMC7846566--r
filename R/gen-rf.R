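#' Transducer pulse specification
#'
#' @param center_frequency pulse center frequency in Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth (dimensionless).
#' @param sampling_rate RF sampling rate in Hz; must be at least four times
#'   the center frequency.
#' @return an object of class `pulse_spec`.
#' @export
pulse_spec <- function(center_frequency = 15e6, fractional_bandwidth = 0.6,
                       sampling_rate = 84e6) {
  stopifnot(center_frequency > 0,
            fractional_bandwidth > 0, fractional_bandwidth < 2,
            sampling_rate >= 4 * center_frequency)
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_rate = sampling_rate),
            class = "pulse_spec")
}

#' Scatterer region specification
#'
#' Describes one depth band of an RF phantom. `echo_spectral_shift`
#' multiplies the pulse center frequency of echoes originating in the region:
#' values above 1 emulate finer scatterers (higher-frequency backscatter),
#' values below 1 coarser ones.
#'
#' @param depth_range ordered, non-negative depth interval in cm.
#' @param scatterer_density scatterers per mm^2 of imaging plane.
#' @param echo_spectral_shift positive spectral shift factor.
#' @param amplitude mean echo amplitude scale for the region (a.u.).
#' @return an object of class `scatterer_region`.
#' @export
scatterer_region <- function(depth_range, scatterer_density = 4,
                             echo_spectral_shift = 1, amplitude = 1) {
  stopifnot(length(depth_range) == 2, all(depth_range >= 0),
            depth_range[2] > depth_range[1],
            scatterer_density > 0, echo_spectral_shift > 0, amplitude > 0)
  structure(list(depth_range = as.numeric(depth_range),
                 scatterer_density = scatterer_density,
                 echo_spectral_shift = echo_spectral_shift,
                 amplitude = amplitude),
            class = "scatterer_region")
}

#' Generate a synthetic RF phantom frame
#'
#' Builds RF scan lines as sums of randomly positioned scatterer echoes. Each
#' echo is a Gaussian-enveloped sinusoid whose center frequency is the pulse
#' center frequency times the region's spectral shift; its amplitude carries a
#' two-way frequency-dependent depth attenuation
#' `10^(-coeff * f[MHz] * 2 * z[cm] / 20)`.
#'
#' @param pulse a [pulse_spec()].
#' @param regions list of [scatterer_region()]s that must tile a contiguous
#'   depth span with no gaps or overlaps.
#' @param attenuation_coeff attenuation in dB/cm/MHz (>= 0).
#' @param n_lines number of scan lines.
#' @param seed integer seed; the frame is reproducible given the seed.
#' @param line_pitch lateral line spacing in meters.
#' @param sound_speed speed of sound in m/s.
#' @return an [rf_frame()] with attribute-free known construction; the ground
#'   truth (regions, attenuation) travels in the `truth` field.
#' @export
gen_rf_phantom <- function(pulse, regions, attenuation_coeff = 0,
                           n_lines = 16, seed = 1,
                           line_pitch = 1e-4, sound_speed = 1540) {
  stopifnot(inherits(pulse, "pulse_spec"), length(regions) >= 1)
  if (attenuation_coeff < 0) {
    stop("attenuation_coeff must be >= 0 (got ", attenuation_coeff, ")")
  }
  regions <- regions[order(vapply(regions, function(r) r$depth_range[1], 0))]
  bounds <- vapply(regions, function(r) r$depth_range, numeric(2))
  if (length(regions) > 1) {
    gaps <- bounds[1, -1] - bounds[2, -ncol(bounds)]
    if (any(abs(gaps) > 1e-9)) {
      stop("regions must tile a contiguous depth span; found ",
           if (any(gaps > 1e-9)) "a gap" else "an overlap", " at depth ",
           signif(bounds[2, which(abs(gaps) > 1e-9)[1]], 4), " cm")
    }
  }
  z_max_cm <- bounds[2, ncol(bounds)]
  fs <- pulse$sampling_rate
  n_ax <- ceiling(2 * (z_max_cm / 100) / sound_speed * fs) + 1

  # Gaussian envelope sd from the -6 dB fractional bandwidth of the pulse
  b6 <- pulse$fractional_bandwidth * pulse$center_frequency
  sigma_t <- sqrt(2 * log(2)) / (pi * b6)
  half <- ceiling(4 * sigma_t * fs)

  samples <- with_seed_maybe(seed, {
    m <- matrix(0, n_ax, n_lines)
    for (rg in regions) {
      f_echo <- pulse$center_frequency * rg$echo_spectral_shift
      span_mm <- diff(rg$depth_range) * 10
      lam <- rg$scatterer_density * span_mm * (line_pitch * 1e3)
      for (ln in seq_len(n_lines)) {
        n_sc <- rpois(1, lam)
        if (n_sc == 0) next
        z_cm <- runif(n_sc, rg$depth_range[1], rg$depth_range[2])
        amp <- rg$amplitude * rnorm(n_sc) *
          10^(-attenuation_coeff * (f_echo / 1e6) * 2 * z_cm / 20)
        t0 <- 2 * (z_cm / 100) / sound_speed
        for (s in seq_len(n_sc)) {
          i0 <- round(t0[s] * fs) + 1
          idx <- max(1, i0 - half):min(n_ax, i0 + half)
          tt <- (idx - 1) / fs - t0[s]
          m[idx, ln] <- m[idx, ln] +
            amp[s] * exp(-tt^2 / (2 * sigma_t^2)) * cos(2 * pi * f_echo * tt)
        }
      }
    }
    m
  })

  frame <- rf_frame(samples, fs, pulse$center_frequency,
                    line_pitch = line_pitch, sound_speed = sound_speed)
  frame$truth <- list(regions = regions, attenuation_coeff = attenuation_coeff,
                      seed = seed)
  frame
}
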