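# HDF5 container and image I/O. These are optional conveniences and only
# touch rhdf5/png when actually called.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this I/O helper")
  }
}

#' Write / read an RF frame or IQ ensemble as an HDF5 container
#'
#' Layout: datasets under `/data` (complex data as `real` + `imag`), scalar
#' acquisition metadata under `/meta`.
#'
#' @param x an [rf_frame()] or [iq_ensemble()].
#' @param path file path (`.h5`).
#' @return `write_mpus_h5` returns `path` invisibly; `read_mpus_h5` the
#'   restored object.
#' @export
write_mpus_h5 <- function(x, path) {
  need_pkg("rhdf5")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "data")
  rhdf5::h5createGroup(path, "meta")
  if (inherits(x, "rf_frame")) {
    rhdf5::h5write(x$samples, path, "data/samples")
    meta <- x[c("sampling_rate", "center_frequency", "line_pitch",
                "sound_speed")]
    meta$type <- "rf_frame"
    meta$attenuation_corrected <- as.integer(isTRUE(x$attenuation_corrected))
  } else if (inherits(x, "iq_ensemble")) {
    rhdf5::h5write(Re(x$data), path, "data/real")
    rhdf5::h5write(Im(x$data), path, "data/imag")
    meta <- x[c("demod_frequency", "prf", "lateral_pitch", "axial_sampling",
                "sound_speed")]
    meta$type <- "iq_ensemble"
  } else {
    stop("unsupported object of class ", paste(class(x), collapse = "/"))
  }
  for (nm in names(meta)) rhdf5::h5write(meta[[nm]], path, paste0("meta/", nm))
  rhdf5::H5close()
  invisible(path)
}

#' @rdname write_mpus_h5
#' @export
read_mpus_h5 <- function(path) {
  need_pkg("rhdf5")
  meta <- lapply(rhdf5::h5read(path, "meta"),
                 function(v) if (is.array(v)) as.vector(v) else v)
  out <- if (identical(as.character(meta$type), "rf_frame")) {
    fr <- rf_frame(rhdf5::h5read(path, "data/samples"),
                   sampling_rate = meta$sampling_rate,
                   center_frequency = meta$center_frequency,
                   line_pitch = meta$line_pitch,
                   sound_speed = meta$sound_speed)
    fr$attenuation_corrected <- isTRUE(meta$attenuation_corrected == 1)
    fr
  } else if (identical(as.character(meta$type), "iq_ensemble")) {
    re <- rhdf5::h5read(path, "data/real")
    im <- rhdf5::h5read(path, "data/imag")
    iq_ensemble(array(complex(real = re, imaginary = im), dim(re)),
                demod_frequency = meta$demod_frequency, prf = meta$prf,
                lateral_pitch = meta$lateral_pitch,
                axial_sampling = meta$axial_sampling,
                sound_speed = meta$sound_speed)
  } else {
    stop("unrecognized container type")
  }
  rhdf5::H5close()
  out
}

#' Write a histology image (or any RGB array in `[0,1]`) as PNG
#'
#' @param image a `histology_image` or rows x cols x 3 array.
#' @param path file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_histology_png <- function(image, path) {
  need_pkg("png")
  px <- if (inherits(image, "histology_image")) image$pixels else image
  png::writePNG(px, path)
  invisible(path)
}
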