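test_that("flow curve sums ROI velocities with the cm/s x mm^2 -> uL/s scale", {
  f <- structure(list(velocity = array(1, c(5, 5, 8)),
                      pixel_spacing_mm = c(1, 1), period_s = 1,
                      n_phases = 8L),
                 class = "velocity_field")
  m <- matrix(FALSE, 5, 5); m[1:2, 1:5] <- TRUE  # 10 voxels of 1 mm^2
  roi <- roi_mask(m, "aqu", pixel_area_mm2 = 1)
  q <- compute_flow_curve(f, roi)$q
  expect_equal(q, rep(100, 8))  # 10 vox * 1 cm/s * 1 mm^2 = 100 uL/s

  f$velocity[] <- 0
  expect_equal(compute_flow_curve(f, roi)$q, rep(0, 8))
})

test_that("phantom flow curve tracks the analytic waveform through the true mask", {
  sp <- sine_phantom(profile = "poiseuille")
  sim <- generate_cine_series(sp)
  field <- phase_to_velocity(sim$series)
  roi <- roi_mask(sim$truth$lumen_mask_true, "aqu",
                  prod(sp$pixel_spacing_mm))
  q <- compute_flow_curve(field, roi)$q
  expect_lt(max(abs(q - sim$truth$flow_curve_true)) /
              max(abs(sim$truth$flow_curve_true)), 0.02)
})

test_that("phase resampling preserves waveforms and their integrals", {
  q <- sin(2 * pi * (0:63) / 64) * 70.7
  c64 <- flow_curve(q, period_s = 1)
  expect_identical(resample_phases(c64, 64L), c64)

  const <- flow_curve(rep(5, 16), period_s = 1)
  expect_equal(resample_phases(const, 32L)$q, rep(5, 32))

  c32 <- resample_phases(c64, 32L)
  sv64 <- stroke_volume(c64)$sv_ul_per_cc
  sv32 <- stroke_volume(c32)$sv_ul_per_cc
  expect_lt(abs(sv32 - sv64) / sv64, 0.01)
})

test_that("stroke volume integrates directional volumes as (V+ + V-)/2", {
  # sinusoid: SV = Q0 T / pi, net 0
  q0 <- 70.7
  curve <- flow_curve(q0 * sin(2 * pi * (0:31) / 32), period_s = 1)
  res <- stroke_volume(curve)
  expect_equal(res$sv_ul_per_cc, q0 / pi, tolerance = 5e-3)
  expect_equal(res$net_volume_ul, 0, tolerance = 1e-10)

  z <- stroke_volume(flow_curve(rep(0, 32), period_s = 1))
  expect_equal(z$sv_ul_per_cc, 0)
  expect_equal(z$net_volume_ul, 0)

  # unidirectional convention: constant +10 uL/s over 1 s
  u <- stroke_volume(flow_curve(rep(10, 32), period_s = 1))
  expect_equal(u$v_plus_ul, 10)
  expect_equal(u$sv_ul_per_cc, 5)
  expect_equal(u$net_volume_ul, 10)
})

test_that("stroke volume is homogeneous, direction-symmetric and shift-invariant", {
  set.seed(4)
  for (rep_i in 1:5) {
    amp <- runif(3, 0.2, 2); ph <- runif(3, 0, 2 * pi)
    t <- (0:31) / 32
    q <- 100 * (amp[1] * sin(2 * pi * t + ph[1]) +
                amp[2] * sin(4 * pi * t + ph[2]) +
                amp[3] * sin(6 * pi * t + ph[3]))
    sv <- function(qq) stroke_volume(flow_curve(qq, period_s = 1))$sv_ul_per_cc
    expect_equal(sv(3 * q), 3 * sv(q), tolerance = 1e-10)
    expect_equal(sv(-q), sv(q), tolerance = 1e-10)
    k <- sample(31, 1)
    expect_equal(sv(c(q[-(1:k)], q[1:k])), sv(q), tolerance = 1e-10)
  }
})

test_that("32-sample trapezoid with crossing subdivision matches fine quadrature", {
  set.seed(11)
  t32 <- (0:31) / 32
  t_fine <- seq(0, 1, length.out = 1e6 + 1)
  for (rep_i in 1:8) {
    # fundamental-dominated spectra, as in physiological CSF flow; the
    # interpolation error of a 32-sample grid grows as the square of the
    # harmonic index, so a dominant high harmonic would exceed this bound
    amp <- c(runif(1, 0.5, 1), runif(1, 0.05, 0.2), runif(1, 0.02, 0.08))
    ph <- runif(3, 0, 2 * pi)
    wave <- function(t) 100 * (amp[1] * sin(2 * pi * t + ph[1]) +
                               amp[2] * sin(4 * pi * t + ph[2]) +
                               amp[3] * sin(6 * pi * t + ph[3]))
    sv32 <- stroke_volume(flow_curve(wave(t32), period_s = 1))$sv_ul_per_cc
    qf <- wave(t_fine)
    sv_ref <- (pracma::trapz(t_fine, pmax(qf, 0)) +
               pracma::trapz(t_fine, pmax(-qf, 0))) / 2
    expect_lt(abs(sv32 - sv_ref) / sv_ref, 0.005)
  }
})

test_that("end-to-end quantification recovers phantom stroke volume", {
  # noise-free laminar phantom: within 5 %
  sp <- sine_phantom(profile = "poiseuille")
  sim <- generate_cine_series(sp)
  res <- quantify_site(sim$series, seed = center_seed(sp), site = "aqu")
  expect_lt(abs(res$sv_ul_per_cc - sim$truth$sv_true_ul) /
              sim$truth$sv_true_ul, 0.05)
  expect_equal(res$site, "aqu")
  flags <- attr(res, "artifacts")$flags
  expect_true(flags$aliasing_corrected && flags$background_corrected)

  # zero-flow phantom at noise 0: SV is numerically zero
  sp0 <- sine_phantom(); sp0$waveform$amplitude_cms <- 0
  sim0 <- generate_cine_series(sp0)
  f0 <- phase_to_velocity(sim0$series)
  sv0 <- stroke_volume(compute_flow_curve(
    f0, roi_mask(sim0$truth$lumen_mask_true, "aqu", 0.25^2)))
  expect_equal(sv0$sv_ul_per_cc, 0)
})

test_that("plug-flow result does not depend on where in the lumen the seed lands", {
  sp <- sine_phantom(profile = "plug")
  sim <- generate_cine_series(sp)
  ref <- quantify_site(sim$series, seed = center_seed(sp))$sv_ul_per_cc
  inside <- which(sim$truth$lumen_mask_true, arr.ind = TRUE) - 1L
  set.seed(2)
  for (i in sample(nrow(inside), 5)) {
    alt <- quantify_site(sim$series, seed = inside[i, ])$sv_ul_per_cc
    expect_equal(alt, ref)
  }
})

test_that("stroke volume scales with waveform amplitude and lumen area", {
  base <- sine_phantom(profile = "plug")
  sv_of <- function(sp) {
    sim <- generate_cine_series(sp)
    quantify_site(sim$series, seed = center_seed(sp))$sv_ul_per_cc
  }
  sv1 <- sv_of(base)
  sv2 <- sv_of(sine_phantom(profile = "plug", amplitude = 2))
  expect_equal(sv2 / sv1, 2, tolerance = 1e-6)
  # doubling the lumen area (radius * sqrt(2))
  big <- phantom_spec(radius_mm = 1.5 * sqrt(2), profile = "plug",
                      waveform = list(amplitude_cms = 1, harmonic = 1,
                                      phase_rad = 0),
                      pixel_spacing_mm = 0.25, grid_shape = c(64L, 64L))
  expect_equal(sv_of(big) / sv1, 2, tolerance = 0.02)
})

test_that("stroke volume is invariant under a time-origin shift", {
  sv_of <- function(phase_rad) {
    sp <- sine_phantom(profile = "plug", phase_rad = phase_rad)
    sim <- generate_cine_series(sp)
    quantify_site(sim$series, seed = center_seed(sp))$sv_ul_per_cc
  }
  expect_equal(sv_of(pi / 3), sv_of(0), tolerance = 1e-3)
})

test_that("noisy end-to-end recovery stays within 10 % on average", {
  sp_base <- sine_phantom(profile = "poiseuille", noise = 0.05)
  errs <- vapply(1:20, function(s) {
    sp <- sp_base; sp$seed <- 1000L + s
    sim <- generate_cine_series(sp)
    res <- quantify_site(sim$series, seed = center_seed(sp))
    abs(res$sv_ul_per_cc - sim$truth$sv_true_ul) / sim$truth$sv_true_ul
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})
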