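test_that("attenuation correction applies the right gain and refuses re-application", {
  fs <- 77e6  # depth step is exactly 1e-3 cm at this rate
  n <- 1101   # spans 1.1 cm so the 1 cm sample exists
  fr <- rf_frame(matrix(1, n, 4), fs, 15e6)
  cor <- attenuation_correct(fr, 0.3)
  z <- (seq_len(n) - 1) * 1540 / (2 * fs) * 100       # cm
  i1cm <- which.min(abs(z - 1))
  # 0.3 dB/cm/MHz x 15 MHz x 2 x 1 cm = 9 dB = x2.818
  expect_equal(cor$samples[i1cm, 1], 10^(9 / 20) * 1,
               tolerance = 1e-3)
  expect_equal(cor$samples[1, 1], 1)                   # z = 0 untouched
  expect_error(attenuation_correct(cor, 0.3), "already")
  expect_error(attenuation_correct(fr, -1), ">= 0")
})

test_that("correcting a phantom generated with the same coefficient flattens the depth profile", {
  p <- pulse_spec(15e6, 0.6, 84e6)
  fr <- gen_rf_phantom(p, list(scatterer_region(c(0.1, 2.1),
                                                scatterer_density = 128)),
                       attenuation_coeff = 0.3, n_lines = 256, seed = 21)
  slope <- log_envelope_slope(attenuation_correct(fr, 0.3))
  expect_lt(abs(slope), 0.5)   # residual dB/cm
})

test_that("GH kernel energy matches the closed-form Hermite integral", {
  # E_2 = integral H_2(t)^2 exp(-t^2) dt = 2^2 * 2! * sqrt(pi)
  k2 <- make_gh_kernel(2, time_scale = 1, sampling_rate = 50)
  expect_equal(k2$energy, 2^2 * factorial(2) * sqrt(pi), tolerance = 1e-6)
  # general-order spot check at order 4: 2^4 * 4! * sqrt(pi)
  k4 <- make_gh_kernel(4, time_scale = 1, sampling_rate = 50)
  expect_equal(k4$energy, 2^4 * factorial(4) * sqrt(pi), tolerance = 1e-6)
})

test_that("GH kernel shapes and spectra behave with order", {
  k0 <- make_gh_kernel(0, 1, 50)
  expect_true(all(k0$taps >= 0))                       # order 0 is a Gaussian
  expect_equal(k0$peak_frequency, 0, tolerance = 1e-6)
  peaks <- vapply(c(2, 4, 8), function(n) {
    make_gh_kernel(n, 1, 50)$peak_frequency
  }, 0)
  expect_true(all(diff(peaks) > 0))                    # increasing with order
  k2 <- make_gh_kernel(2, 1, 50)
  expect_equal(k2$taps, rev(k2$taps))                  # even order symmetric
  k3 <- make_gh_kernel(3, 1, 50)
  expect_equal(k3$taps, -rev(k3$taps))                 # odd order antisymmetric
  expect_error(make_gh_kernel(8, 1e-7, 4e6), "under-resolved")
})

test_that("kernel pair tuned for the analysis band keeps both peaks inside it", {
  ks <- hscan_kernels(15e6, c(5e6, 18e6), 84e6)
  expect_gt(ks$low$peak_frequency, 5e6)
  expect_lt(ks$high$peak_frequency, 18e6)
  expect_gt(ks$high$peak_frequency, ks$low$peak_frequency)
})

test_that("matched-filter identity: a GH2-shaped echo lands red", {
  ks <- hscan_kernels()
  n <- 1024
  line <- numeric(n)
  taps <- ks$low$taps
  mid <- n / 2 - floor(length(taps) / 2)
  line[mid:(mid + length(taps) - 1)] <- taps
  fr <- attenuation_correct(rf_frame(matrix(line, n, 12), 84e6, 15e6), 0)
  img <- hscan_reconstruct(fr, ks$low, ks$high)
  at_echo <- n / 2
  expect_gt(img$red_channel[at_echo, 1], img$blue_channel[at_echo, 1])
  expect_lt(img$intensity_map[at_echo, 1], 0.5)
})

test_that("H-scan intensity is non-decreasing in echo center frequency across the band", {
  ks <- hscan_kernels()
  freqs <- seq(5e6, 18e6, length.out = 12)
  vals <- vapply(freqs, function(f0) {
    img <- hscan_reconstruct(single_echo_frame(f0), ks$low, ks$high)
    roi_metrics(img, c(500, 700, 1, 12))[["hscan_intensity"]]
  }, 0)
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("intensity map is invariant to RF gain while channels scale linearly", {
  ks <- hscan_kernels()
  fr <- single_echo_frame(10e6)
  img1 <- hscan_reconstruct(fr, ks$low, ks$high)
  fr10 <- fr
  fr10$samples <- fr10$samples * 10
  img10 <- hscan_reconstruct(fr10, ks$low, ks$high)
  expect_equal(img10$red_channel, 10 * img1$red_channel, tolerance = 1e-9)
  expect_equal(img10$blue_channel, 10 * img1$blue_channel, tolerance = 1e-9)
  expect_equal(img10$intensity_map, img1$intensity_map, tolerance = 1e-9)
})

test_that("two-region phantom shows the expected red-to-blue depth ordering", {
  p <- pulse_spec(15e6, 0.6, 84e6)
  fr <- gen_rf_phantom(p, list(
    scatterer_region(c(0.1, 0.6), echo_spectral_shift = 0.6),
    scatterer_region(c(0.6, 1.1), echo_spectral_shift = 0.9)),
    attenuation_coeff = 0, n_lines = 16, seed = 22)
  fr <- attenuation_correct(fr, 0)
  ks <- hscan_kernels()
  img <- hscan_reconstruct(fr, ks$low, ks$high)
  depth <- img$depth * 100
  roi_shallow <- c(which(depth > 0.15)[1], max(which(depth < 0.55)), 1, 16)
  roi_deep <- c(which(depth > 0.65)[1], max(which(depth < 1.05)), 1, 16)
  m_shallow <- roi_metrics(img, roi_shallow)
  m_deep <- roi_metrics(img, roi_deep)
  expect_gt(m_deep[["hscan_intensity"]], m_shallow[["hscan_intensity"]])
})

test_that("reconstruction preconditions are enforced", {
  ks <- hscan_kernels()
  fr <- rf_frame(matrix(rnorm(512 * 4), 512, 4), 84e6, 15e6)
  expect_error(hscan_reconstruct(fr, ks$low, ks$high), "attenuation-corrected")
  frc <- attenuation_correct(fr, 0)
  expect_error(hscan_reconstruct(frc, ks$low, ks$low), "distinct orders")
  expect_error(hscan_reconstruct(frc, ks$low, ks$high, band = c(5e6, 60e6)),
               "Nyquist")
})

test_that("ROI metrics average correctly and validate the ROI", {
  ks <- hscan_kernels()
  img <- hscan_reconstruct(single_echo_frame(10e6), ks$low, ks$high)
  # constant-envelope check via a synthetic image object
  fake <- img
  fake$bscan_envelope[] <- 3.5
  expect_equal(roi_metrics(fake, c(400, 800, 1, 12))[["bscan_intensity"]], 3.5)
  fake$intensity_map[] <- 0.5
  expect_equal(roi_metrics(fake, c(400, 800, 1, 12))[["hscan_intensity"]], 0.5)
  # checkerboard of 0.2 / 0.8 averages to exactly 0.5
  chk <- matrix(c(0.2, 0.8), nrow(fake$intensity_map), ncol(fake$intensity_map))
  fake$intensity_map <- chk
  expect_equal(roi_metrics(fake, c(401, 800, 1, 12))[["hscan_intensity"]], 0.5)
  expect_error(roi_metrics(img, c(1, 5, 1, 5)), "100 pixels")
  expect_error(roi_metrics(img, c(0, 600, 1, 12)), "bounds")
  fake$intensity_map[] <- NA_real_
  expect_error(roi_metrics(fake, c(400, 800, 1, 12)), "undefined")
})
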