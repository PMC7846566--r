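# ---- lognormal bolus model ------------------------------------------------
#
# I(t) = scale / tau * exp(-(log(tau) - mu)^2 / (2 sigma^2)),  tau = t - t0 > 0
#
# Closed forms used throughout (s = sigma^2):
#   peak time      tau* = exp(mu - s);      PE  = scale * exp(s/2 - mu)
#   max wash-in slope at L* = -s (1 + v),  v = (1 + sqrt(1 + 4/s)) / 2
#                  WIR = scale * exp(-2 mu) * v * exp(-2 L* - L*^2 / (2 s))

bolus_curve <- function(t, t0, mu, sigma, scale) {
  tau <- t - t0
  out <- numeric(length(t))
  pos <- tau > 0
  out[pos] <- scale / tau[pos] *
    exp(-(log(tau[pos]) - mu)^2 / (2 * sigma^2))
  out
}

bolus_peak <- function(t0, mu, sigma, scale) {
  s <- sigma^2
  list(t_peak = t0 + exp(mu - s), pe = scale * exp(s / 2 - mu))
}

bolus_wir <- function(mu, sigma, scale) {
  s <- sigma^2
  v <- (1 + sqrt(1 + 4 / s)) / 2
  L <- -s * (1 + v)
  scale * exp(-2 * mu) * v * exp(-2 * L - L^2 / (2 * s))
}

# invert (PE, WIR) -> (mu, scale) for fixed shape sigma and onset t0
bolus_params_from_pe_wir <- function(pe, wir, sigma, t0) {
  s <- sigma^2
  v <- (1 + sqrt(1 + 4 / s)) / 2
  L <- -s * (1 + v)
  w <- v * exp(-2 * L - L^2 / (2 * s))          # WIR = scale exp(-2 mu) w
  mu <- log(pe * w / wir) - s / 2
  scale <- pe * exp(mu - s / 2)
  list(t0 = t0, mu = mu, sigma = sigma, scale = scale)
}

# ---- synthetic CEUS series ------------------------------------------------

#' Generate a synthetic contrast-enhanced ultrasound series
#'
#' Builds a frame stack with named liver and inferior-vena-cava (IVC) regions
#' whose mean intensities follow lognormal bolus time courses with exactly the
#' requested analytic peak enhancement (PE) and maximum wash-in rate (WIR).
#' IVC enhancement always precedes the liver parenchyma (the bolus arrives
#' through the vein); the liver onset is delayed if necessary to preserve the
#' peak-time ordering. Additive white Gaussian noise is scaled to the liver
#' PE.
#'
#' @param liver_truth numeric `c(pe, wir)` for the liver ROI (a.u., a.u./s).
#' @param ivc_truth numeric `c(pe, wir)` for the IVC ROI.
#' @param frame_rate frames per second.
#' @param duration series length in seconds; must contain the full wash-in of
#'   both ROIs.
#' @param snr_db SNR in dB relative to the liver PE (`Inf` = noiseless).
#' @param seed integer seed.
#' @param dims frame size `c(rows, cols)` in pixels.
#' @param shape lognormal shape parameter sigma.
#' @param t0_ivc,t0_liver bolus onset times in seconds.
#' @param baseline pre-contrast intensity level (a.u.).
#' @return object of class `ceus_series`: `frames` (rows x cols x time),
#'   `frame_times`, named logical `rois`, `baseline`, and `truth` (per-ROI
#'   bolus parameters, PE/WIR and noiseless curves).
#' @export
gen_ceus_series <- function(liver_truth = c(pe = 15, wir = 6),
                            ivc_truth = c(pe = 40, wir = 25),
                            frame_rate = 10, duration = 30, snr_db = 25,
                            seed = 1, dims = c(48, 48), shape = 0.35,
                            t0_ivc = 2, t0_liver = 4, baseline = 2) {
  if (any(c(liver_truth, ivc_truth) <= 0)) {
    stop("PE and WIR ground-truth values must be positive")
  }
  p_ivc <- bolus_params_from_pe_wir(ivc_truth[1], ivc_truth[2], shape, t0_ivc)
  p_liv <- bolus_params_from_pe_wir(liver_truth[1], liver_truth[2], shape, t0_liver)
  pk_i <- bolus_peak(p_ivc$t0, p_ivc$mu, p_ivc$sigma, p_ivc$scale)
  pk_l <- bolus_peak(p_liv$t0, p_liv$mu, p_liv$sigma, p_liv$scale)
  if (pk_l$t_peak <= pk_i$t_peak) {          # enforce IVC-first arrival
    p_liv$t0 <- p_liv$t0 + (pk_i$t_peak - pk_l$t_peak) + 0.5
    pk_l <- bolus_peak(p_liv$t0, p_liv$mu, p_liv$sigma, p_liv$scale)
  }
  if (pk_l$t_peak + 2 / frame_rate >= duration) {
    stop("duration too short to contain the liver wash-in phase")
  }
  times <- seq(0, duration, by = 1 / frame_rate)
  curve_l <- bolus_curve(times, p_liv$t0, p_liv$mu, p_liv$sigma, p_liv$scale)
  curve_i <- bolus_curve(times, p_ivc$t0, p_ivc$mu, p_ivc$sigma, p_ivc$scale)

  nr <- dims[1]; nc <- dims[2]
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  liver_mask <- cc <= floor(nc * 0.55)
  ctr <- c(0.3 * nr, 0.8 * nc); rad <- 0.12 * min(nr, nc)
  ivc_mask <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
  noise_sd <- if (is.finite(snr_db)) liver_truth[1] * 10^(-snr_db / 20) else 0

  frames <- with_seed_maybe(seed, {
    arr <- array(baseline, c(nr, nc, length(times)))
    for (k in seq_along(times)) {
      fr <- arr[, , k]
      fr[liver_mask] <- fr[liver_mask] + curve_l[k]
      fr[ivc_mask] <- fr[ivc_mask] + curve_i[k]
      if (noise_sd > 0) fr <- fr + rnorm(nr * nc, 0, noise_sd)
      arr[, , k] <- fr
    }
    arr
  })

  structure(list(frames = frames, frame_times = times,
                 rois = list(liver = liver_mask, ivc = ivc_mask),
                 baseline = baseline,
                 truth = list(
                   liver = c(p_liv, list(pe = unname(liver_truth[1]),
                                         wir = unname(liver_truth[2]),
                                         t_peak = pk_l$t_peak, curve = curve_l)),
                   ivc = c(p_ivc, list(pe = unname(ivc_truth[1]),
                                       wir = unname(ivc_truth[2]),
                                       t_peak = pk_i$t_peak, curve = curve_i)),
                   snr_db = snr_db, noise_sd = noise_sd, seed = seed)),
            class = "ceus_series")
}

#' @export
print.ceus_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ceus_series> %d x %d px, %d frames over %.1f s | ROIs: %s\n",
              d[1], d[2], d[3], max(x$frame_times),
              paste(names(x$rois), collapse = ", ")))
  invisible(x)
}

# ---- TIC extraction and fitting -------------------------------------------

#' Extract a time-intensity curve from a CEUS series
#'
#' Averages frame pixels under the named ROI mask, estimates the baseline
#' from the pre-arrival frames (arrival = first frame whose intensity exceeds
#' the mean + 3 SD of a leading pre-injection window), and returns the
#' baseline-subtracted curve.
#'
#' @param series a `ceus_series`.
#' @param roi_name name of the ROI mask to use.
#' @param pre_window length in seconds of the leading window used for the
#'   arrival threshold (default 1 s).
#' @return object of class `tic` with `times`, `intensities`
#'   (baseline-subtracted), `roi_name`, `baseline` and `arrival_index`.
#' @export
extract_tic <- function(series, roi_name, pre_window = 1) {
  stopifnot(inherits(series, "ceus_series"))
  if (!roi_name %in% names(series$rois)) {
    stop("unknown ROI '", roi_name, "'; available: ",
         paste(names(series$rois), collapse = ", "))
  }
  mask <- series$rois[[roi_name]]
  if (!any(mask)) stop("ROI '", roi_name, "' is empty")
  nt <- dim(series$frames)[3]
  raw <- vapply(seq_len(nt), function(k) mean(series$frames[, , k][mask]), 0)
  pre <- which(series$frame_times <= pre_window)
  if (length(pre) < 2) stop("no pre-arrival frames before the bolus")
  thr <- mean(raw[pre]) + 3 * max(sd(raw[pre]), 1e-12)
  arrival <- which(raw > thr)[1]
  if (is.na(arrival)) arrival <- nt + 1L
  pre_all <- seq_len(max(arrival - 1, length(pre)))
  baseline <- mean(raw[seq_len(min(arrival - 1, nt))])
  if (arrival <= 1) stop("no pre-arrival frames before the bolus")
  structure(list(times = series$frame_times, intensities = raw - baseline,
                 roi_name = roi_name, baseline = baseline,
                 arrival_index = min(arrival, nt)),
            class = "tic")
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("<tic> '%s' | %d samples | baseline %.3g | peak %.3g a.u.\n",
              x$roi_name, length(x$times), x$baseline, max(x$intensities)))
  invisible(x)
}

#' Fit a wash-in bolus model to a time-intensity curve
#'
#' Fits the lognormal bolus model by nonlinear least squares to the samples
#' from arrival through the first post-peak sample only (the wash-in
#' restriction, which insulates the parameters from recirculation). Peak
#' enhancement is the fitted curve's analytic maximum and the wash-in rate
#' the analytic maximum of its first derivative.
#'
#' Degenerate shapes are handled explicitly: a curve that is still rising at
#' the end of the record is an error; a curve that plateaus without a
#' post-peak decline, or a fit that fails to converge, falls back to
#' model-free estimates (maximum of the median-smoothed curve; maximum
#' finite-difference slope) flagged with `fallback = TRUE`.
#'
#' @param tic a `tic` (baseline-subtracted).
#' @param shape_init initial value for the lognormal shape sigma.
#' @return object of class `perfusion_params`: `pe`, `wir`, `t_peak`,
#'   `pe_nlp`/`wir_nlp` (`NA` until [normalize_perfusion()]), `fit_rmse`,
#'   `fallback`, `roi_name`.
#' @export
fit_tic <- function(tic, shape_init = 0.35) {
  stopifnot(inherits(tic, "tic"))
  y <- tic$intensities
  t <- tic$times
  n <- length(y)
  sm <- runmed(y, 5)
  pk <- which.max(sm)
  if (sum(y > 0.05 * max(y)) < 5) {
    stop("TIC has fewer than 5 samples above baseline; cannot fit a wash-in")
  }
  if (pk >= n - 1 && all(diff(sm[max(1, n - 5):n]) >= -1e-12)) {
    stop("TIC is still rising at the end of the record: no peak to fit")
  }
  arrival <- tic$arrival_index %||% which(y > 0.05 * max(sm))[1]
  plateau <- min(sm[pk:n]) > 0.95 * sm[pk]

  mk <- function(pe, wir, t_peak, rmse, fallback) {
    structure(list(pe = pe, wir = wir, t_peak = t_peak,
                   pe_nlp = NA_real_, wir_nlp = NA_real_,
                   fit_rmse = rmse, fallback = fallback,
                   roi_name = tic$roi_name),
              class = "perfusion_params")
  }
  fallback_est <- function() {
    slopes <- diff(sm) / diff(t)
    mk(max(sm), max(slopes[seq_len(pk - 1)]), t[pk], NA_real_, TRUE)
  }
  if (plateau) return(fallback_est())

  idx <- arrival:min(pk + 1, n)
  ts <- t[idx]; ys <- y[idx]
  t_arr <- t[arrival]
  tau0 <- max(t[pk] - t_arr, 2 * (t[2] - t[1]))
  th0 <- c(t0 = max(t_arr - tau0 / 4, 0),
           mu = log(tau0) + shape_init^2,
           lsig = log(shape_init),
           lsc = 0)
  th0["lsc"] <- log(max(max(ys), 1e-9)) - shape_init^2 / 2 + th0["mu"]
  obj <- function(th) {
    pred <- bolus_curve(ts, th[1], th[2], exp(th[3]), exp(th[4]))
    sum((ys - pred)^2)
  }
  o <- tryCatch(
    optim(th0, obj, method = "L-BFGS-B",
          lower = c(-2, -10, log(0.05), -20),
          upper = c(t[pk], 10, log(2), 30),
          control = list(maxit = 500, factr = 1e4)),
    error = function(e) list(convergence = 99))
  if (o$convergence != 0) return(fallback_est())
  par <- unname(o$par)
  t0 <- par[1]; mu <- par[2]
  sig <- exp(par[3]); sc <- exp(par[4])
  pkfit <- bolus_peak(t0, mu, sig, sc)
  rmse <- sqrt(o$value / length(ys))
  mk(pkfit$pe, bolus_wir(mu, sig, sc), pkfit$t_peak, rmse, FALSE)
}

#' @export
print.perfusion_params <- function(x, ...) {
  cat(sprintf("<perfusion_params> '%s' | PE %.3g | WIR %.3g /s | t_peak %.2f s%s%s\n",
              x$roi_name %||% "?", x$pe, x$wir, x$t_peak,
              if (!is.na(x$pe_nlp)) sprintf(" | PE-nLP %.3g WIR-nLP %.3g", x$pe_nlp, x$wir_nlp) else "",
              if (isTRUE(x$fallback)) " | model-free fallback" else ""))
  invisible(x)
}

#' Normalize liver perfusion parameters by the IVC reference
#'
#' Expresses liver peak enhancement and wash-in rate as dimensionless ratios
#' to the inferior vena cava, removing system gain and injection-dose
#' dependence: `pe_nlp = pe_liver / pe_ivc`, `wir_nlp = wir_liver / wir_ivc`.
#'
#' @param liver,ivc `perfusion_params` objects.
#' @return the liver `perfusion_params` with `pe_nlp` and `wir_nlp` filled.
#' @export
normalize_perfusion <- function(liver, ivc) {
  stopifnot(inherits(liver, "perfusion_params"),
            inherits(ivc, "perfusion_params"))
  if (!(ivc$pe > 0) || !(ivc$wir > 0)) {
    stop("invalid IVC reference: PE and WIR must be positive")
  }
  liver$pe_nlp <- liver$pe / ivc$pe
  liver$wir_nlp <- liver$wir / ivc$wir
  liver
}

#' Maximum intensity projection of a CEUS series
#'
#' Per-pixel maximum over time of the baseline-subtracted frames; bright
#' where contrast passed at any time, highlighting vascular structure.
#'
#' @param series a `ceus_series`.
#' @return numeric matrix (rows x cols).
#' @export
max_intensity_projection <- function(series) {
  stopifnot(inherits(series, "ceus_series"))
  d <- dim(series$frames)
  if (d[3] < 2) stop("need at least 2 frames")
  pre <- which(series$frame_times <= 1)
  base <- apply(series$frames[, , pre, drop = FALSE], c(1, 2), mean)
  apply(series$frames, c(1, 2), max) - base
}
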