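test_that("identical consecutive frames give zero displacement", {
  base <- array(complex(real = rnorm(8 * 32), imaginary = rnorm(8 * 32)),
                c(8, 32, 1))
  iq <- iq_ensemble(array(rep(base, 5), c(8, 32, 5)), 5e6, 1000, 5e-4)
  u <- estimate_displacement(iq)
  expect_equal(max(abs(u$u)), 0)
  expect_false(u$aliased)
})

test_that("a uniform lambda/20 phase shift is recovered within 2%", {
  lambda <- 1540 / 5e6
  d <- lambda / 20
  set.seed(31)
  f1 <- matrix(complex(real = rnorm(8 * 32), imaginary = rnorm(8 * 32)), 8, 32)
  f2 <- f1 * exp(1i * 4 * pi * 5e6 * d / 1540)
  iq <- iq_ensemble(array(c(f1, f2), c(8, 32, 2)), 5e6, 1000, 5e-4)
  u <- estimate_displacement(iq)
  expect_equal(unique(round(u$u[1, , 2], 12)), d, tolerance = 0.02)
})

test_that("a lambda/4 shift is flagged as aliasing", {
  lambda <- 1540 / 5e6
  set.seed(32)
  f1 <- matrix(complex(real = rnorm(8 * 32), imaginary = rnorm(8 * 32)), 8, 32)
  f2 <- f1 * exp(1i * 4 * pi * 5e6 * (lambda / 4) / 1540 * 0.999)
  iq <- iq_ensemble(array(c(f1, f2), c(8, 32, 2)), 5e6, 1000, 5e-4)
  expect_warning(u <- estimate_displacement(iq), "aliased")
  expect_true(u$aliased)
})

test_that("f-k transform places a complex plane wave at (k0, f0)", {
  nx <- 64; nt <- 64
  dx <- 1e-3; dt <- 1e-3
  k0 <- 2 * pi * 8 / (nx * dx)          # on-bin
  f0 <- 10 / (nt * dt)
  x <- (0:(nx - 1)) * dx; t <- (0:(nt - 1)) * dt
  u <- exp(1i * (outer(k0 * x, 2 * pi * f0 * t, "-")))
  sp <- fk_transform(displacement_field(array(u, c(1, nx, nt)), dx, dt))
  ij <- arrayInd(which.max(Mod(sp$S)), dim(sp$S))
  expect_equal(sp$k[ij[1]], k0, tolerance = 1e-9)
  expect_equal(sp$f[ij[2]], f0, tolerance = 1e-9)
})

test_that("a real sinusoid shows conjugate-symmetric peaks", {
  nx <- 64; nt <- 64; dx <- 1e-3; dt <- 1e-3
  k0 <- 2 * pi * 8 / (nx * dx); f0 <- 10 / (nt * dt)
  x <- (0:(nx - 1)) * dx; t <- (0:(nt - 1)) * dt
  u <- sin(outer(-k0 * x, 2 * pi * f0 * t, "+"))
  sp <- fk_transform(displacement_field(array(u, c(1, nx, nt)), dx, dt))
  P <- Mod(sp$S)^2
  i1 <- c(which(abs(sp$k - k0) < 1e-9), which(abs(sp$f - f0) < 1e-9))
  i2 <- c(which(abs(sp$k + k0) < 1e-9), which(abs(sp$f + f0) < 1e-9))
  expect_equal(P[i1[1], i1[2]], P[i2[1], i2[2]], tolerance = 1e-9)
  top2 <- sort(P, decreasing = TRUE)[1:2]
  expect_equal(P[i1[1], i1[2]], top2[1], tolerance = 1e-6)
})

test_that("Parseval holds between the tapered field and its spectrum", {
  mv <- gen_shear_movie(1.5, 80, grid = test_shear_grid(), seed = 41)
  fld <- estimate_displacement(mv$iq)
  sp <- fk_transform(fld)
  lhs <- sum(Mod(sp$tapered)^2)
  rhs <- sum(Mod(sp$S)^2) / prod(dim(sp$S))
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("damped wave energy follows the dispersion ridge f = c k / (2 pi)", {
  mv <- gen_shear_movie(1.5, 80, grid = test_shear_grid(), snr_db = Inf,
                        seed = 42)
  d <- dim(mv$truth$u)
  crop <- displacement_field(mv$truth$u[, , (d[3] - 127):d[3], drop = FALSE],
                             mv$truth$dx, mv$truth$dt)
  sp <- fk_transform(crop)
  P <- Mod(sp$S)^2
  pos_k <- which(sp$k > 0)
  f0 <- 200
  for (mult in c(1)) {                   # single-frequency wave: ridge at f0
    fi <- which.min(abs(sp$f - mult * f0))
    k_at <- sp$k[pos_k[which.max(P[pos_k, fi])]]
    expect_equal(2 * pi * mult * f0 / k_at, 1.5, tolerance = 0.05)
  }
})

test_that("fk transform validates degenerate input", {
  expect_error(fk_transform(displacement_field(array(0, c(1, 32, 32)),
                                               1e-3, 1e-3)),
               "zero")
  expect_error(fk_transform(displacement_field(array(1, c(1, 4, 32)),
                                               1e-3, 1e-3)),
               "lateral")
})

test_that("undamped wave reports attenuation at or below the taper floor", {
  mv <- gen_shear_movie(1.5, 0, grid = test_shear_grid(), snr_db = Inf,
                        seed = 43)
  res <- swe_measure(mv$iq)
  expect_lte(res$attenuation, res$resolution_floor)
  expect_gt(res$resolution_floor, 0)
})

test_that("halving the speed doubles the wavenumber peak at fixed frequency", {
  est_k <- function(speed) {
    mv <- gen_shear_movie(speed, 60, grid = test_shear_grid(), snr_db = Inf,
                          seed = 44)
    r <- swe_measure(mv$iq)
    2 * pi * r$analysis_frequency / r$speed
  }
  expect_equal(est_k(0.8) / est_k(1.6), 2, tolerance = 0.02)
})

test_that("speed and attenuation estimates are invariant to displacement scaling", {
  mv <- gen_shear_movie(1.4, 90, grid = test_shear_grid(), seed = 45)
  fld <- estimate_displacement(mv$iq)
  d <- dim(fld$u)
  crop <- function(s) {
    displacement_field(s * fld$u[, , (d[3] - 127):d[3], drop = FALSE],
                       fld$dx, fld$dt)
  }
  r1 <- estimate_speed_attenuation(fk_transform(crop(1)))
  r2 <- estimate_speed_attenuation(fk_transform(crop(37.5)))
  expect_equal(r1$speed, r2$speed, tolerance = 1e-9)
  expect_equal(r1$attenuation, r2$attenuation, tolerance = 1e-9)
})

test_that("the published control / steatotic example pair is recovered through the full chain", {
  ctrl <- gen_shear_movie(1.52, 94.8, snr_db = 25, seed = 46)
  mcd <- gen_shear_movie(1.36, 113.9, snr_db = 25, seed = 46)
  r_ctrl <- swe_measure(ctrl$iq)
  r_mcd <- swe_measure(mcd$iq)
  expect_lt(abs(r_ctrl$speed - 1.52) / 1.52, 0.05)
  expect_lt(abs(r_ctrl$attenuation - 94.8) / 94.8, 0.10)
  expect_lt(abs(r_mcd$speed - 1.36) / 1.36, 0.05)
  expect_lt(abs(r_mcd$attenuation - 113.9) / 113.9, 0.10)
  # steatotic liver: slower and more attenuated
  expect_lt(r_mcd$speed, r_ctrl$speed)
  expect_gt(r_mcd$attenuation, r_ctrl$attenuation)
})
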