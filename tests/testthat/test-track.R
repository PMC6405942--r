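# Frame-to-frame tracking: initialization geometry, step validation,
# collision resolution, and end-to-end accuracy on simulated movies.

test_that("end guess lies at the far region boundary along the growth direction", {
  cfg <- tirf_config(size = 128, snr = 10, seed = 31)
  seed_fil <- filament_line(30, 64, 50, 64)
  mov <- simulate_movie(cfg, n_frames = 1, frame_interval = 2,
                        dynamics = list(vg = 50, vs = 500, l0 = 1560),
                        paths = list(seed_fil))
  img <- mov$frames[[1]]
  regs <- detect_mser_regions(img)
  lab <- MTdyn:::region_label_image(regs, dim(img))
  g <- initialize_guess(img, regs, lab, c(50, 64), c(1, 0))
  expect_length(g, 1)
  truth_tip <- mov$truth$tip_x[1]
  expect_lt(abs(g[[1]]$guess[1] - truth_tip), 2)
  # a dim region (all intensity below the 50% threshold) yields no guess
  g2 <- initialize_guess(img, regs, lab, c(50, 64), c(1, 0),
                         intensity_frac = 2)
  expect_length(g2, 0)
})

test_that("step validation enforces the angular and coefficient rules", {
  expect_true(validate_step(c(1, 0), c(1, 0)))
  d25 <- c(cos(25 * pi / 180), sin(25 * pi / 180))
  expect_false(validate_step(c(1, 0), d25))                # > 20 degrees
  d15 <- c(cos(15 * pi / 180), sin(15 * pi / 180))
  expect_true(validate_step(c(1, 0), d15))
  hist <- data.frame(b = rnorm(10, 0, 1e-3), I = rnorm(10, 0, 1e-5))
  expect_true(validate_step(c(1, 0), c(1, 0),
                            new_coef = list(b = 2e-3, I = 0), history = hist))
  expect_false(validate_step(c(1, 0), c(1, 0),
                             new_coef = list(b = 0.5, I = 0), history = hist))
  # the floor forgives jumps below a pixel of tip deflection
  expect_true(validate_step(c(1, 0), c(1, 0),
                            new_coef = list(b = 0.5, I = 0), history = hist,
                            coef_floor = c(b = 0.1, I = 0)))
})

test_that("collision resolution picks the fit nearest the last tip", {
  fits <- list(list(tip = c(10, 10)), list(tip = c(23, 10)))
  expect_equal(resolve_multi_region(fits, c(11, 10))$tip, c(10, 10))
  expect_equal(resolve_multi_region(fits, c(22, 10))$tip, c(23, 10))
  expect_null(resolve_multi_region(list(), c(0, 0)))
})

test_that("a static movie gives constant length within localization noise", {
  cfg <- tirf_config(size = 128, snr = 10, seed = 32)
  mov <- simulate_movie(cfg, n_frames = 8, frame_interval = 2,
                        dynamics = list(vg = 1e-9, vs = 1, l0 = 1560),
                        n_filaments = 1)
  tc <- track_config(sigma = cfg$psf_sigma_px, pixel_size_nm = 156,
                     frame_interval_s = 2)
  tk <- track_movie(mov$frames, mov$filaments, tc)
  expect_gte(nrow(tk), 6)
  expect_lt(sd(tk$length_nm), 0.5 * 156)   # < half a pixel of scatter
})

test_that("straight growth is tracked at pixel resolution (SNR 5)", {
  errs <- c(); n_expected <- 0
  for (s in 1:2) {
    cfg <- tirf_config(size = 160, snr = 5, seed = 40 + s)
    mov <- simulate_movie(cfg, n_frames = 15, frame_interval = 2,
                          dynamics = list(vg = 40, vs = 400, l0 = 500),
                          n_filaments = 1)
    tc <- track_config(sigma = cfg$psf_sigma_px, pixel_size_nm = 156,
                       frame_interval_s = 2)
    tk <- track_movie(mov$frames, mov$filaments, tc)
    mm <- merge(tk, mov$truth[mov$truth$filament == 1, ], by = "frame")
    errs <- c(errs, sqrt((mm$x - mm$tip_x)^2 + (mm$y - mm$tip_y)^2))
    n_expected <- n_expected + 15
  }
  expect_gt(length(errs), 0.7 * n_expected)
  expect_lt(median(errs), 1)
})

test_that("bending growth along a cubic is tracked like the straight case", {
  cfg <- tirf_config(size = 160, snr = 10, seed = 51)
  mov <- simulate_movie(cfg, n_frames = 15, frame_interval = 2,
                        dynamics = list(vg = 40, vs = 400, l0 = 500),
                        n_filaments = 1, path_kind = "cubic")
  tc <- track_config(sigma = cfg$psf_sigma_px, pixel_size_nm = 156,
                     frame_interval_s = 2)
  tk <- track_movie(mov$frames, mov$filaments, tc)
  mm <- merge(tk, mov$truth[mov$truth$filament == 1, ], by = "frame")
  expect_gte(nrow(mm), 11)
  errs <- sqrt((mm$x - mm$tip_x)^2 + (mm$y - mm$tip_y)^2)
  expect_lt(median(errs), 1)
})

test_that("tracks recover after gaps: deleting frames barely changes lengths", {
  cfg <- tirf_config(size = 160, snr = 10, seed = 52)
  mov <- simulate_movie(cfg, n_frames = 16, frame_interval = 2,
                        dynamics = list(vg = 40, vs = 400, l0 = 600),
                        n_filaments = 1)
  tc <- track_config(sigma = cfg$psf_sigma_px, pixel_size_nm = 156,
                     frame_interval_s = 2)
  tk_full <- track_movie(mov$frames, mov$filaments, tc)
  # blank frames 8-10: nothing to detect, the track must bridge the gap
  frames_gap <- mov$frames
  for (k in 8:10) frames_gap[[k]] <- matrix(rpois(160 * 160, cfg$background), 160)
  tk_gap <- track_movie(frames_gap, mov$filaments, tc)
  post_full <- tk_full[tk_full$frame > 10, c("frame", "length_nm")]
  post_gap <- tk_gap[tk_gap$frame > 10, c("frame", "length_nm")]
  mm <- merge(post_full, post_gap, by = "frame")
  expect_gte(nrow(mm), 4)
  expect_lt(max(abs(mm$length_nm.x - mm$length_nm.y)), 156)  # < 1 px
})

test_that("line-model tracking matches the polynomial model on straight filaments", {
  cfg <- tirf_config(size = 160, snr = 10, seed = 53)
  mov <- simulate_movie(cfg, n_frames = 10, frame_interval = 2,
                        dynamics = list(vg = 40, vs = 400, l0 = 600),
                        n_filaments = 1)
  tc_poly <- track_config(sigma = cfg$psf_sigma_px, pixel_size_nm = 156,
                          frame_interval_s = 2, model = "poly")
  tc_line <- track_config(sigma = cfg$psf_sigma_px, pixel_size_nm = 156,
                          frame_interval_s = 2, model = "line")
  tk_p <- track_movie(mov$frames, mov$filaments, tc_poly)
  tk_l <- track_movie(mov$frames, mov$filaments, tc_line)
  mm <- merge(tk_p, tk_l, by = "frame")
  expect_gte(nrow(mm), 8)
  d <- sqrt((mm$x.x - mm$x.y)^2 + (mm$y.x - mm$y.y)^2)
  expect_lt(median(d), 0.15)   # the mask refinement aligns both models
})

test_that("two crossing filaments keep their identities", {
  cfg <- tirf_config(size = 160, snr = 10, seed = 54)
  # seeds aimed at a crossing point, ~60 degrees apart
  f1 <- filament_line(40, 60, 60, 70)
  f2 <- filament_line(50, 110, 62, 94)
  mov <- simulate_movie(cfg, n_frames = 14, frame_interval = 2,
                        dynamics = list(vg = 50, vs = 500, l0 = 300),
                        paths = list(f1, f2))
  tc <- track_config(sigma = cfg$psf_sigma_px, pixel_size_nm = 156,
                     frame_interval_s = 2)
  tk <- track_movie(mov$frames, mov$filaments, tc)
  for (i in 1:2) {
    tr <- tk[tk$seed_id == i, ]
    truth <- mov$truth[mov$truth$filament == i, ]
    mm <- merge(tr, truth, by = "frame")
    expect_gt(nrow(mm), 7)
    errs <- sqrt((mm$x - mm$tip_x)^2 + (mm$y - mm$tip_y)^2)
    # no identity swap: every accepted tip stays on its own filament
    expect_lt(max(errs), 5)
    expect_lt(median(errs), 1.5)
  }
})
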