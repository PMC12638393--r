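# Shared phantom builders for the test suite.

# 1.5 mm circular lumen, single-harmonic 1 cm/s waveform, venc 10, 0.25 mm
# grid: analytic SV = pi * 1.5^2 * 10 * 1 / pi = 22.5 uL per cycle.
sine_phantom <- function(profile = "plug", amplitude = 1, noise = 0,
                         offset = 0, n_phases = 32L, venc = 10,
                         spacing = 0.25, grid = c(64L, 64L),
                         phase_rad = 0, seed = NULL) {
  phantom_spec(geometry = "circle", center_mm = c(8, 8), radius_mm = 1.5,
               profile = profile,
               waveform = list(amplitude_cms = amplitude, harmonic = 1,
                               phase_rad = phase_rad),
               period_s = 1, n_phases = n_phases, venc_cms = venc,
               pixel_spacing_mm = spacing, grid_shape = grid,
               noise_sd_rad = noise, background_offset_rad = offset,
               seed = seed)
}

# seed voxel at the lumen centre for the phantom above
center_seed <- function(spec) round(spec$center_mm / spec$pixel_spacing_mm)

# expectation of a normal(mu, sigma) truncated below at 0 (the law the
# cohort generator draws from)
trunc_mean <- function(mu, sigma) {
  if (sigma == 0) return(max(mu, 0))
  mu + sigma * dnorm(mu / sigma) / pnorm(mu / sigma)
}

# brute-force two-sided Mann-Whitney p by exhaustive reassignment of the
# pooled sample into all C(n1+n2, n1) group splits (no ties assumed)
mw_enumerate_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">"))
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pool), n1)
  u_all <- apply(splits, 2, function(idx) u_of(pool[idx], pool[-idx]))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}
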