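# Image and trajectory simulator: rendering geometry, Poisson/SNR
# calibration, and the two-state length process.

test_that("rendered ridge reaches the configured amplitude and decays off-axis", {
  cfg <- small_config(size = 64, background = 0, amplitude = 120)
  fil <- filament_line(12, 32, 52, 32)
  img <- render_filament(cfg, fil)
  # ridge midpoint vs 5 sigma away
  mid <- img[33, 33]
  expect_equal(mid, 120, tolerance = 0.02)
  off <- img[33 + round(5 * cfg$psf_sigma_px[2]) + 1, 33]
  expect_lt(off, 120 * 1e-3)
  # zero-length filament renders a single Gaussian spot
  spot <- render_filament(small_config(size = 32, background = 0),
                          filament_line(16, 16, 16, 16))
  expect_equal(which(spot == max(spot)), which(outer(0:31, 0:31,
    function(y, x) x == 16 & y == 16)))
})

test_that("rendering rejects paths outside the image unless clipping", {
  cfg <- small_config(size = 32)
  fil <- filament_line(-10, 5, 20, 5)
  expect_error(render_filament(cfg, fil), "bounds")
  expect_silent(render_filament(cfg, fil, clip = TRUE))
})

test_that("cubic-path render deposits constant intensity per unit arc length", {
  cfg <- small_config(size = 96, background = 0, amplitude = 100)
  # gentle cubic 3e-5 (x - 45)^3 + 48, expanded to plain coefficients
  fil <- filament_cubic(3e-5 * c(1, -135, 6075, -91125) + c(0, 0, 0, 48),
                        10, 80)
  img <- render_filament(cfg, fil)
  # intensity integrated across the ridge, per unit arc length, at sample
  # points along the known path (integration removes pixel-phase effects)
  ss <- seq(8, fil$length_px - 8, length.out = 25)
  pts <- filament_point(fil, ss)
  tg <- MTdyn:::filament_tangent(fil, ss)
  vals <- vapply(seq_along(ss), function(k) {
    nrm <- c(-tg[k, 2], tg[k, 1])
    u <- seq(-5 * 1.3, 5 * 1.3, by = 0.1)
    sum(MTdyn:::interp_bilinear(img, pts[k, 1] + u * nrm[1],
                                pts[k, 2] + u * nrm[2])) * 0.1
  }, 0)
  expect_lt(max(vals) / min(vals), 1.02)
})

test_that("noiseless rendering is deterministic and translation-equivariant", {
  cfg <- small_config(size = 64, background = 2)
  fil <- filament_line(10.3, 20.7, 40.3, 35.7)
  img1 <- render_filament(cfg, fil)
  expect_identical(img1, render_filament(cfg, fil))
  fil2 <- filament_line(10.3 + 7, 20.7 + 5, 40.3 + 7, 35.7 + 5)
  img2 <- render_filament(cfg, fil2)
  expect_equal(img2[(5 + 1):64, (7 + 1):64], img1[1:(64 - 5), 1:(64 - 7)],
               tolerance = 1e-12)
})

test_that("Poisson noise is calibrated to the target SNR and reproducible", {
  # scaling rule on zero background: ridge mean = snr^2
  expect_equal(MTdyn:::snr_to_ridge_mean(5, 0), 25)
  # with background the ridge mean solves lambda/sqrt(lambda+bg) = snr
  lam <- MTdyn:::snr_to_ridge_mean(5, 10)
  expect_equal(lam / sqrt(lam + 10), 5, tolerance = 1e-12)

  cfg <- small_config(size = 72, background = 4, amplitude = 90)
  fil <- filament_line(8, 36, 64, 36)
  img <- render_filament(cfg, fil)
  n1 <- apply_poisson_noise(img, 5, rng_seed = 7, background = 4, amplitude = 90)
  n2 <- apply_poisson_noise(img, 5, rng_seed = 7, background = 4, amplitude = 90)
  expect_identical(n1, n2)
  expect_error(apply_poisson_noise(img - 100, 5, 1), "non-negative")

  # measured SNR over independent realizations within 10% of the target
  for (snr in c(3, 5, 10)) {
    got <- vapply(1:10, function(k) {
      nz <- apply_poisson_noise(img, snr, rng_seed = 100 + k,
                                background = 4, amplitude = 90)
      measure_snr(nz - 4, filament_scan(fil, n = 50))
    }, 0)
    expect_equal(mean(got), snr, tolerance = 0.1)
  }
})

test_that("measure_snr is mean over sd, with Inf for a constant scan", {
  img <- matrix(10, 20, 20)
  scan <- cbind(seq(2, 17, length.out = 12), rep(10, 12))
  expect_identical(measure_snr(img, scan), Inf)
  img2 <- matrix(rep(c(8, 12), each = 20), nrow = 20, ncol = 20)  # columns alternate
  scan2 <- cbind(seq(0, 19, by = 1), rep(5, 20))
  v <- img2[cbind(rep(6, 20), 1:20)]
  expect_equal(measure_snr(img2, scan2), mean(v) / sd(v))
  expect_equal(measure_snr(img2, scan2), 5, tolerance = 0.03)
  expect_error(measure_snr(img, scan[1:5, ]), "at least 10")
})

test_that("trajectory generator obeys rates, clamping and determinism", {
  # no switching: exact linear growth at vg
  tr <- simulate_trajectory(50, 2, vg = 10, vs = 100, fc = 0, fr = 0,
                            rng_seed = 1)
  expect_equal(diff(tr$lengths), rep(20, 49), tolerance = 1e-12)
  expect_true(all(tr$phases == "growth"))

  # lengths never negative; catastrophe count matches the rate
  n_cat <- 0; t_growth <- 0
  for (k in 1:30) {
    tr <- simulate_trajectory(400, 1, vg = 20, vs = 100, fc = 0.05,
                              fr = 0.05, rng_seed = 100 + k)
    expect_true(all(tr$lengths >= 0))
    segs <- tr$segments
    n_cat <- n_cat + sum(tr$events$type %in% c("catastrophe"))
    t_growth <- t_growth + sum(segs$t1[segs$phase == "growth"] -
                               segs$t0[segs$phase == "growth"])
  }
  expect_gt(n_cat, 50)
  rate <- n_cat / t_growth
  expect_equal(rate, 0.05, tolerance = 3 / sqrt(n_cat))

  tr1 <- simulate_trajectory(100, 1, 10, 100, 0.02, 0.05, rng_seed = 5)
  tr2 <- simulate_trajectory(100, 1, 10, 100, 0.02, 0.05, rng_seed = 5)
  expect_identical(tr1$lengths, tr2$lengths)
  expect_error(simulate_trajectory(10, 0, 1, 1), "frame_interval")
})

test_that("simulated movies carry consistent ground truth", {
  cfg <- tirf_config(size = 128, snr = 10, seed = 3)
  mov <- simulate_movie(cfg, n_frames = 6, frame_interval = 2,
                        dynamics = list(vg = 30, vs = 300, fc = 0, fr = 0,
                                        l0 = 400), n_filaments = 2)
  expect_length(mov$frames, 6)
  expect_equal(nrow(mov$truth), 12)
  # truth tips lie on the filament paths at the recorded contour length
  for (r in seq_len(nrow(mov$truth))) {
    row <- mov$truth[r, ]
    f <- mov$filaments[[row$filament]]
    p <- filament_point(f, f$length_px + row$length_nm / cfg$pixel_size_nm)
    expect_equal(unname(c(row$tip_x, row$tip_y)), unname(p[1, ]),
                 tolerance = 1e-6)
  }
  # monotone growth: lengths increase at vg * dt
  l1 <- mov$truth$length_nm[mov$truth$filament == 1]
  expect_equal(diff(l1), rep(60, 5), tolerance = 1e-9)
})

test_that("random seed fields respect the pairwise separation constraint", {
  cfg <- sim_config(width_px = 256, height_px = 256, rng_seed = 9)
  seeds <- with(cfg, NULL)
  seeds <- MTdyn:::with_seed(9, random_seed_field(cfg, 12, min_separation_px = 5))
  expect_length(seeds, 12)
  for (i in 1:11) for (j in (i + 1):12) {
    d <- MTdyn:::segment_distance(seeds[[i]]$start, seeds[[i]]$end,
                                  seeds[[j]]$start, seeds[[j]]$end)
    expect_gt(d, 5)
  }
})
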