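# Shared fixture builders. Everything is generated in code at test time.

# Two cohorts (39 normal / 12 high-fat rows, mirroring the study's normal vs
# high-fat arms) separated by 3 pooled SDs in every feature. Scales are
# arbitrary (Z-scoring removes them); the hscan column keeps its (0, 1)
# intensity units.
two_cohort_sep3 <- function() {
  sds <- c(sws = 1, swa = 1, bscan = 1, hscan = 0.05, pe_nlp = 1, wir_nlp = 1)
  m0 <- c(sws = 10, swa = 100, bscan = 5, hscan = 0.40, pe_nlp = 4, wir_nlp = 6)
  m1 <- m0 + 3 * sds * c(-1, 1, 1, 1, -1, -1)   # direction per feature trend
  list(cohort_spec("normal", 39, m0, sds),
       cohort_spec("high_fat", 12, m1, sds))
}

# Three cohorts (39/12/12) in which the hscan feature carries the dominant
# standardized separation: successive cohort shifts of 6 pooled SDs on hscan
# vs 1.5 on each other feature, unit within-cohort SDs (hscan scaled into its
# (0, 1) units; Z-scoring makes that equivalent).
three_cohort_hscan_dominant <- function() {
  sds <- c(sws = 1, swa = 1, bscan = 1, hscan = 0.05, pe_nlp = 1, wir_nlp = 1)
  mk <- function(lab, n, step) {
    m <- c(sws = 10 + step * 1.5, swa = 100 + step * 1.5, bscan = 5 + step * 1.5,
           hscan = 0.2 + step * 6 * 0.05,
           pe_nlp = 10 - step * 1.5, wir_nlp = 10 - step * 1.5)
    cohort_spec(lab, n, m, sds)
  }
  list(mk("normal", 39, 0), mk("low_fat", 12, 1), mk("high_fat", 12, 2))
}

# Compact shear-wave grid for tests that only need a working wave, not the
# full-resolution attenuation recovery.
test_shear_grid <- function() shear_grid(n_lateral = 256)

# Single-echo RF frame: one Gaussian-enveloped echo at frequency f0 placed
# mid-depth in every line. Returned attenuation-corrected (coeff 0).
single_echo_frame <- function(f0, amp = 1, n_lines = 12, n_ax = 1200,
                              fs = 84e6, frac_bw = 0.6) {
  t <- (0:(n_ax - 1)) / fs
  t0 <- t[n_ax / 2]
  sig <- sqrt(2 * log(2)) / (pi * frac_bw * f0)
  line <- amp * exp(-(t - t0)^2 / (2 * sig^2)) * cos(2 * pi * f0 * (t - t0))
  attenuation_correct(rf_frame(matrix(line, n_ax, n_lines), fs, 15e6), 0)
}

# depth-resolved mean log-envelope slope (dB/cm) of an RF frame, by linear fit
log_envelope_slope <- function(frame, skip_frac = 0.1) {
  env <- envelope(frame$samples)
  depth_cm <- (seq_len(nrow(env)) - 1) * frame$sound_speed /
    (2 * frame$sampling_rate) * 100
  keep <- seq(floor(nrow(env) * skip_frac), ceiling(nrow(env) * (1 - skip_frac)))
  prof <- 20 * log10(rowMeans(env)[keep] + 1e-300)
  unname(coef(lm(prof ~ depth_cm[keep]))[2])
}

# spectral centroid (Hz) of a set of RF segments (columns)
spectral_centroid <- function(segments, fs) {
  n <- nrow(segments)
  spec <- rowMeans(Mod(mvfft(segments))^2)[1:(n %/% 2)]
  f <- (0:(n %/% 2 - 1)) * fs / n
  sum(f * spec) / sum(spec)
}

# brute-force two-sided Mann-Whitney p by enumerating all C(nx+ny, nx)
# labelings (no ties assumed)
mwu_p_enumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) {
    ux <- sum(r[idx]) - nx * (nx + 1) / 2
    min(ux, nx * ny - ux)
  })
  u_obs <- {
    ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    min(ux, nx * ny - ux)
  }
  mean(us <= u_obs)  # both tails already folded by the min()
}
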