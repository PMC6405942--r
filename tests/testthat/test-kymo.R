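# Kymograph analysis: RANSAC event segmentation, frequencies, transition
# classification, polarity and the two-state length distribution.

test_that("a perfectly linear track yields exactly one growth event", {
  tr <- data.frame(time_s = seq(0, 100, by = 2))
  tr$length_nm <- 12 * tr$time_s
  tr$frame <- seq_len(nrow(tr))
  ev <- find_growth_events(tr, ransac_config(epsilon = 5, rng_seed = 1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$slope_nm_per_s, 12, tolerance = 1e-9)
  expect_equal(ev$n_inliers, nrow(tr))
  # and no shrink events on monotone growth
  sh <- find_shrink_events(tr, ev, ransac_config(epsilon = 5, rng_seed = 1))
  expect_equal(nrow(sh), 0)
})

test_that("piecewise growth slopes are recovered within 5%", {
  set.seed(11)
  t1 <- seq(0, 120, by = 2); t2 <- seq(122, 240, by = 2)
  eps <- 9
  l1 <- 5 * t1 + rnorm(length(t1), 0, eps / 3)
  # drop, then second growth at a different slope
  l2 <- 8 * (t2 - 122) + 40 + rnorm(length(t2), 0, eps / 3)
  tr <- data.frame(time_s = c(t1, t2), length_nm = c(l1, l2),
                   frame = seq_len(length(t1) + length(t2)))
  ev <- find_growth_events(tr, ransac_config(epsilon = eps, rng_seed = 2))
  expect_equal(nrow(ev), 2)
  slopes <- sort(ev$slope_nm_per_s)
  expect_equal(slopes[1], 5, tolerance = 0.05 * 5)
  expect_equal(slopes[2], 8, tolerance = 0.05 * 8)
})

test_that("sawtooth shrink phases are found with slopes within 10%", {
  # vg = 10, vs = 100 nm/s; period: 60 s growth + 6 s shrink, dt = 1 s
  dt <- 1
  times <- seq(0, 330, by = dt)
  len <- numeric(length(times)); l <- 0; phase_up <- TRUE; t_sw <- 60
  for (i in seq_along(times)) {
    len[i] <- l
    l <- l + if (phase_up) 10 * dt else -100 * dt
    if (phase_up && times[i] >= t_sw) { phase_up <- FALSE; t_sw <- times[i] + 6 }
    else if (!phase_up && l <= 0) { l <- 0; phase_up <- TRUE; t_sw <- times[i] + 60 }
  }
  set.seed(3)
  tr <- data.frame(time_s = times, length_nm = pmax(len, 0) + rnorm(length(times), 0, 3),
                   frame = seq_along(times))
  cfg <- ransac_config(epsilon = 10, rng_seed = 3)
  g <- find_growth_events(tr, cfg)
  s <- find_shrink_events(tr, g, cfg, vg_track = 10)
  expect_gte(nrow(s), 3)
  expect_true(all(s$slope_nm_per_s < 0))
  expect_equal(mean(abs(s$slope_nm_per_s)), 100, tolerance = 0.1 * 100)
  # shallow decline slower than the threshold is not called shrinkage
  tr2 <- data.frame(time_s = times, length_nm = 4000 - 5 * times,
                    frame = seq_along(times))
  s2 <- find_shrink_events(tr2, g[0, ], cfg, vg_track = 10)  # threshold -20
  expect_equal(nrow(s2), 0)
})

test_that("event inlier sets are disjoint, consecutive, and sampling shrinks", {
  set.seed(4)
  tr <- noisy_track(300, 2, 8, 50, 0.008, 0.02, noise_nm = 10, seed = 77)$track
  a <- analyze_track(tr, ransac_config(rng_seed = 7))
  inl <- a$events$inliers
  all_idx <- unlist(inl)
  expect_equal(anyDuplicated(all_idx), 0)
  for (k in seq_along(inl)) {
    fr <- sort(tr$frame[inl[[k]]])
    expect_true(all(diff(fr) >= 1))
    # consecutive run: no measured frame inside the span is excluded
    span <- tr$frame >= min(fr) & tr$frame <= max(fr)
    expect_equal(sum(span), length(fr))
  }
})

test_that("RANSAC segmentation is reproducible under a fixed seed", {
  tr <- noisy_track(200, 2, 8, 50, 0.01, 0.02, noise_nm = 10, seed = 5)$track
  a1 <- analyze_track(tr, ransac_config(rng_seed = 42))
  a2 <- analyze_track(tr, ransac_config(rng_seed = 42))
  expect_identical(a1$events, a2$events)
})

test_that("frequency arithmetic follows events/time with dead-time correction", {
  ev <- data.frame(
    kind = c("growth", "shrink", "growth", "shrink", "growth", "shrink", "growth"),
    t_start = c(0, 31, 41, 71, 81, 111, 121),
    t_end = c(30, 40, 70, 80, 110, 120, 150),
    slope_nm_per_s = c(10, -100, 10, -100, 10, -100, 10),
    intercept_nm = c(0, 3400, -410, 7500, -810, 11600, -1210),
    n_inliers = rep(10, 7))
  fr0 <- compute_frequencies(ev, baseline_nm = 0, epsilon = 5)
  # 3 complete growth events (30 + 29 + 29 s; the last is unbounded)
  expect_equal(fr0$n_catastrophes, 3)
  expect_equal(fr0$fc, 3 / 88)
  fr1 <- compute_frequencies(ev, baseline_nm = 0, epsilon = 5, dead_time_s = 6)
  expect_equal(fr1$fc, 3 / (88 - 18))
  # no shrink events: fc = 0 and fr = 0 by the zero-shrink rule
  g_only <- ev[ev$kind == "growth", ][1, ]
  fr2 <- compute_frequencies(g_only)
  expect_true(is.na(fr2$fc))           # no complete growth: undefined
  expect_identical(fr2$fr, 0)
})

test_that("transitions split into total catastrophes and rescues by baseline", {
  ev <- data.frame(
    kind = c("growth", "shrink", "growth", "shrink", "growth"),
    t_start = c(0, 51, 61, 121, 129),
    t_end = c(50, 60, 120, 128, 160),
    slope_nm_per_s = c(10, -50, 10, -30, 10),
    intercept_nm = c(0, 3050, -610, 3850, 1000 - 10 * 129),
    n_inliers = rep(8, 5))
  # first shrink ends at 0 (3050 - 50*60 = 50 ~ baseline), regrowth from ~0
  tc <- classify_transitions(ev, baseline_nm = 0, epsilon = 60)
  expect_equal(tc$transition, c("total_catastrophe", "rescued"))
  # a shrink not followed by growth is incomplete
  ev2 <- ev[1:2, ]
  tc2 <- classify_transitions(ev2, baseline_nm = 0, epsilon = 60)
  expect_equal(tc2$transition, "incomplete")
})

test_that("plus end is the faster-growing end, ties broken by length gained", {
  a <- list(vg_nm_per_s = 2, total_gain_nm = 100)
  b <- list(vg_nm_per_s = 0.5, total_gain_nm = 500)
  expect_equal(assign_polarity(a, b), c(A = "plus", B = "minus"))
  a2 <- list(vg_nm_per_s = 1, total_gain_nm = 50)
  b2 <- list(vg_nm_per_s = 1, total_gain_nm = 80)
  expect_equal(assign_polarity(a2, b2), c(A = "minus", B = "plus"))
  expect_true(all(is.na(assign_polarity(list(vg_nm_per_s = NA), b))))
})

test_that("telegraph parameter recovery is within sampling error (pooled)", {
  res <- lapply(1:12, function(i) {
    tr <- noisy_track(300, 2, 8, 50, 0.008, 0.02, noise_nm = 10,
                      seed = 3000 + i)
    analyze_track(tr$track, ransac_config(rng_seed = i))$summary
  })
  f <- function(n) vapply(res, function(x) x[[n]] %||% NA_real_, 0)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  vg_hat <- mean(f("vg_nm_per_s"), na.rm = TRUE)
  expect_equal(vg_hat, 8, tolerance = 0.08)
  ncat <- sum(f("n_catastrophes"))
  fc_hat <- ncat / sum(f("growth_time_s"))
  expect_gt(ncat, 15)
  expect_lt(abs(fc_hat - 0.008), 3 * fc_hat / sqrt(ncat))
})

test_that("length distribution is exponential in the bounded regime", {
  # bounded: vg * fr < vs * fc
  d <- length_distribution(vg = 8, vs = 50, fc = 0.01, fr = 0.01)
  expect_equal(sum(d$density) * diff(d$length_nm[1:2]), 1, tolerance = 1e-6)
  # decay constant fc/vg - fr/vs from a log-linear fit over the body
  sel <- d$density > max(d$density) / 200 & d$length_nm > 100
  fit <- lm(log(d$density[sel]) ~ d$length_nm[sel])
  expect_equal(unname(-coef(fit)[2]), 0.01 / 8 - 0.01 / 50, tolerance = 0.05)
  # vs -> large limit: decay approaches fc/vg
  d2 <- length_distribution(vg = 8, vs = 5000, fc = 0.01, fr = 0)
  sel2 <- d2$density > max(d2$density) / 200 & d2$length_nm > 100
  fit2 <- lm(log(d2$density[sel2]) ~ d2$length_nm[sel2])
  expect_equal(unname(-coef(fit2)[2]), 0.01 / 8, tolerance = 0.07)
  # unbounded regime signals non-stationarity for the time average
  expect_error(length_distribution(8, 50, fc = 0, fr = 0.01),
               class = "mtdyn_nonstationary")
  expect_error(length_distribution(8, 50, fc = 0.001, fr = 0.05),
               class = "mtdyn_nonstationary")
  # but a finite-time distribution is still available
  dt <- length_distribution(8, 50, fc = 0.001, fr = 0.05, t = 100)
  expect_true(all(is.finite(dt$density)))
})
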