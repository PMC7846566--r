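#' Beamformed radiofrequency frame
#'
#' Container for one frame of beamformed RF echo data. Rows are axial (fast
#' time) samples, columns are scan lines. Depth of axial sample `i` (0-based)
#' is `i * sound_speed / (2 * sampling_rate)`; sample 0 sits at depth 0.
#'
#' @param samples numeric matrix (axial x lateral), arbitrary units.
#' @param sampling_rate RF sampling rate in Hz.
#' @param center_frequency transducer center frequency in Hz.
#' @param line_pitch lateral spacing between scan lines in meters.
#' @param sound_speed speed of sound in m/s used for the depth axis.
#' @return an object of class `rf_frame`.
#' @export
rf_frame <- function(samples, sampling_rate, center_frequency,
                     line_pitch = 1e-4, sound_speed = 1540) {
  stopifnot(is.matrix(samples), all(is.finite(samples)),
            sampling_rate > 0, center_frequency > 0,
            line_pitch > 0, sound_speed > 0)
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 center_frequency = center_frequency,
                 line_pitch = line_pitch,
                 sound_speed = sound_speed,
                 attenuation_corrected = FALSE),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d axial x %d lines | fs %.1f MHz | fc %.1f MHz | depth %.2f cm%s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate / 1e6,
              x$center_frequency / 1e6, max(rf_depth(x)) * 100,
              if (isTRUE(x$attenuation_corrected)) " | attenuation-corrected" else ""))
  invisible(x)
}

# depth (meters) of each axial sample
rf_depth <- function(frame) {
  (seq_len(nrow(frame$samples)) - 1) * frame$sound_speed / (2 * frame$sampling_rate)
}

#' Complex baseband (IQ) ensemble
#'
#' Demodulated echo data organized as axial x lateral x slow-time, as used for
#' phase-based displacement tracking during shear wave elastography.
#'
#' @param data complex array, axial x lateral x slow-time.
#' @param demod_frequency demodulation (carrier) frequency in Hz.
#' @param prf slow-time frame rate in Hz.
#' @param lateral_pitch lateral sample spacing in meters.
#' @param axial_sampling axial sampling rate in Hz.
#' @param sound_speed speed of sound in m/s.
#' @return an object of class `iq_ensemble`.
#' @export
iq_ensemble <- function(data, demod_frequency, prf, lateral_pitch,
                        axial_sampling = 4 * demod_frequency,
                        sound_speed = 1540) {
  stopifnot(is.array(data), length(dim(data)) == 3, is.complex(data),
            all(is.finite(Re(data))), all(is.finite(Im(data))),
            demod_frequency > 0, prf > 0, lateral_pitch > 0, sound_speed > 0)
  structure(list(data = data,
                 demod_frequency = demod_frequency,
                 prf = prf,
                 lateral_pitch = lateral_pitch,
                 axial_sampling = axial_sampling,
                 sound_speed = sound_speed),
            class = "iq_ensemble")
}

#' @export
print.iq_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<iq_ensemble> %d axial x %d lateral x %d frames | PRF %.0f Hz | f_demod %.2f MHz\n",
              d[1], d[2], d[3], x$prf, x$demod_frequency / 1e6))
  invisible(x)
}

#' Axial displacement movie
#'
#' Tracked (or ground-truth) axial tissue displacement `u(x, t)` in meters,
#' stored as depth-row x lateral x slow-time.
#'
#' @param u numeric array (depth rows x lateral x slow-time), meters.
#' @param dx lateral spacing in meters.
#' @param dt slow-time frame interval in seconds.
#' @param aliased logical; `TRUE` when phase wrapping was detected while the
#'   field was estimated.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u, dx, dt, aliased = FALSE) {
  if (length(dim(u)) == 2) u <- array(u, c(1, dim(u)))
  stopifnot(length(dim(u)) == 3, all(is.finite(u)), dx > 0, dt > 0)
  structure(list(u = u, dx = dx, dt = dt, aliased = isTRUE(aliased)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<displacement_field> %d rows x %d lateral x %d frames | dx %.3g mm | dt %.3g ms | peak |u| %.2f um%s\n",
              d[1], d[2], d[3], x$dx * 1e3, x$dt * 1e3, max(abs(x$u)) * 1e6,
              if (x$aliased) " | ALIASING FLAGGED" else ""))
  invisible(x)
}
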