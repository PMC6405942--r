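# Shared fixtures for the test suite. All images are generated in code at
# test time; sizes are kept small so the default run stays fast.

# small simulation config with an isotropic ~1.3 px PSF (FWHM 199 nm at a
# 65 nm pixel) unless overridden
small_config <- function(size = 96, snr = 5, seed = 1, ...) {
  sim_config(width_px = size, height_px = size, pixel_size_nm = 65,
             psf_fwhm_nm = 199, target_snr = snr, rng_seed = seed, ...)
}

# default-physics config: 156 nm pixels, 199 nm FWHM (sigma ~0.54 px)
tirf_config <- function(size = 160, snr = 5, seed = 1, ...) {
  sim_config(width_px = size, height_px = size, pixel_size_nm = 156,
             psf_fwhm_nm = 199, target_snr = snr, rng_seed = seed, ...)
}

# endpoint error of a detected seed against its ground-truth filament,
# order-insensitive; returns c(err_start, err_end) after orienting
seed_endpoint_errors <- function(seed, fil) {
  d1 <- sum((seed$start - fil$start)^2) + sum((seed$end - fil$end)^2)
  d2 <- sum((seed$start - fil$end)^2) + sum((seed$end - fil$start)^2)
  if (d2 < d1) {
    c(sqrt(sum((seed$start - fil$end)^2)), sqrt(sum((seed$end - fil$start)^2)))
  } else {
    c(sqrt(sum((seed$start - fil$start)^2)), sqrt(sum((seed$end - fil$end)^2)))
  }
}

# model-generated image: the SoG model itself rendered on a grid (so the
# model can represent the image exactly; used for solver fixed-point tests)
model_image <- function(theta, size, sigma, kind = "line") {
  grid <- pixel_grid(0, size - 1, 0, size - 1)
  matrix(MTdyn:::sog_model_eval(theta, grid, sigma, sog_chain(theta, kind)),
         nrow = size)
}

# telegraph track with Gaussian localization noise
noisy_track <- function(n_frames, dt, vg, vs, fc, fr, noise_nm, seed) {
  tr <- simulate_trajectory(n_frames, dt, vg, vs, fc, fr, rng_seed = seed)
  n <- length(tr$times)
  lengths <- withr::with_seed(seed + 1, tr$lengths + rnorm(n, 0, noise_nm))
  list(track = data.frame(time_s = tr$times, length_nm = lengths,
                          frame = seq_len(n)),
       truth = tr)
}
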