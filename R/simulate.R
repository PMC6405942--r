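# Synthetic TIRF image and trajectory generator.
#
# Filaments are rendered as dense chains of 2D Gaussians of PSF width along
# a line or third-order polynomial path, on a constant background, and
# per-pixel Poisson noise is calibrated so the measured filament SNR
# (mean / sd along a background-subtracted line scan) matches a target.

#' Simulation image configuration
#'
#' Holds the image geometry and optics used by the simulator. The PSF sigma
#' can be given directly in pixels or derived from a FWHM in nm.
#'
#' @param width_px,height_px image size in pixels (at least 16)
#' @param pixel_size_nm pixel size, nm per pixel
#' @param psf_sigma_px Gaussian PSF sigma, length-2 `(sx, sy)` in pixels; if
#'   `NULL`, derived from `psf_fwhm_nm`
#' @param psf_fwhm_nm PSF full width at half maximum in nm (default 199 nm,
#'   a typical value for a 100x TIRF objective in the red channel)
#' @param background constant background intensity, counts
#' @param amplitude filament ridge intensity above background, counts (the
#'   rendered ridge peaks at `background + amplitude`)
#' @param target_snr target signal-to-noise ratio for [apply_poisson_noise()]
#' @param rng_seed integer seed controlling all stochastic draws
#' @return an object of class `sim_config`
#' @export
sim_config <- function(width_px = 512L, height_px = 512L,
                       pixel_size_nm = 156, psf_sigma_px = NULL,
                       psf_fwhm_nm = 199, background = 5,
                       amplitude = 100, target_snr = 5, rng_seed = 1L) {
  if (width_px < 16 || height_px < 16) stop("image must be at least 16x16 pixels")
  if (is.null(psf_sigma_px)) {
    s <- fwhm_to_sigma_px(psf_fwhm_nm, pixel_size_nm)
    psf_sigma_px <- c(s, s)
  }
  psf_sigma_px <- rep_len(as.numeric(psf_sigma_px), 2L)
  if (any(psf_sigma_px <= 0)) stop("psf_sigma_px must be > 0")
  if (target_snr <= 0) stop("target_snr must be > 0")
  if (background < 0) stop("background must be >= 0")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 pixel_size_nm = pixel_size_nm, psf_sigma_px = psf_sigma_px,
                 psf_fwhm_nm = psf_fwhm_nm, background = background,
                 amplitude = amplitude, target_snr = target_snr,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}

## ---- filament geometry -----------------------------------------------------

#' Ground-truth filaments
#'
#' A filament is a segment of a path, either a straight line or a cubic
#' polynomial `y = I x^3 + b x^2 + m x + c`, in 0-based pixel coordinates.
#' `filament_line()` builds it from its two endpoints, `filament_cubic()`
#' from the polynomial coefficients and an x range. The object records the
#' exact endpoints and true contour length; [filament_point()] maps arc
#' length (from the start endpoint) to subpixel path coordinates, with
#' negative arc lengths extrapolating behind the start point.
#'
#' @param x0,y0,x1,y1 endpoints in pixels
#' @param coef numeric `(I, b, m, c)`: inflection, curvature, slope, intercept
#' @param start_x,end_x x range of the segment in pixels
#' @return an object of class `mt_filament` with fields `path_kind`,
#'   `coefficients`, `start`, `end`, `length_px`
#' @export
filament_line <- function(x0, y0, x1, y1) {
  x0 <- unname(x0); y0 <- unname(y0); x1 <- unname(x1); y1 <- unname(y1)
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  m <- if (dx == 0) Inf else dy / dx
  c0 <- if (is.finite(m)) y0 - m * x0 else NA_real_
  structure(list(path_kind = "line", coefficients = c(m = m, c = c0),
                 start = c(x0, y0), end = c(x1, y1), length_px = len),
            class = "mt_filament")
}

#' @rdname filament_line
#' @export
filament_cubic <- function(coef, start_x, end_x) {
  coef <- setNames(as.numeric(coef), c("I", "b", "m", "c"))
  start_x <- unname(start_x); end_x <- unname(end_x)
  f <- function(x) coef[["I"]] * x^3 + coef[["b"]] * x^2 + coef[["m"]] * x + coef[["c"]]
  fp <- function(x) 3 * coef[["I"]] * x^2 + 2 * coef[["b"]] * x + coef[["m"]]
  len <- integrate(function(x) sqrt(1 + fp(x)^2), start_x, end_x,
                   rel.tol = 1e-10)$value
  structure(list(path_kind = "cubic", coefficients = coef,
                 start = c(start_x, f(start_x)), end = c(end_x, f(end_x)),
                 length_px = abs(len)),
            class = "mt_filament")
}

# derivative of the cubic path
cubic_slope <- function(coef, x) 3 * coef[["I"]] * x^2 + 2 * coef[["b"]] * x + coef[["m"]]

#' Points along a filament path at given arc lengths
#'
#' @param filament an `mt_filament`
#' @param s arc lengths in pixels measured from the start endpoint (may
#'   exceed the filament length or be negative: the path is extrapolated)
#' @param step integration step for the cubic arc-length inversion (px)
#' @return matrix with columns `x`, `y`
#' @export
filament_point <- function(filament, s, step = 0.02) {
  if (filament$path_kind == "line") {
    u <- if (filament$length_px > 0)
      (filament$end - filament$start) / filament$length_px else c(0, 0)
    out <- cbind(filament$start[1] + s * u[1], filament$start[2] + s * u[2])
  } else {
    coef <- filament$coefficients
    out <- t(vapply(s, function(si) {
      x <- filament$start[1]
      remaining <- si
      h <- if (si >= 0) step else -step
      n <- floor(abs(si) / step)
      if (n > 0) {
        for (k in seq_len(n)) {
          # midpoint rule on dx/ds = 1 / sqrt(1 + y'(x)^2)
          xm <- x + 0.5 * h / sqrt(1 + cubic_slope(coef, x)^2)
          x <- x + h / sqrt(1 + cubic_slope(coef, xm)^2)
        }
        remaining <- si - n * h
      }
      x <- x + remaining / sqrt(1 + cubic_slope(coef, x)^2)
      c(x, coef[["I"]] * x^3 + coef[["b"]] * x^2 + coef[["m"]] * x + coef[["c"]])
    }, numeric(2)))
  }
  colnames(out) <- c("x", "y")
  out
}

# unit tangent of the path at arc length s (pointing towards increasing s)
filament_tangent <- function(filament, s) {
  if (filament$path_kind == "line") {
    u <- (filament$end - filament$start) / filament$length_px
    matrix(u, nrow = length(s), ncol = 2, byrow = TRUE)
  } else {
    p <- filament_point(filament, s)
    sl <- cubic_slope(filament$coefficients, p[, 1])
    cbind(1, sl) / sqrt(1 + sl^2)
  }
}

## ---- rendering -------------------------------------------------------------

# on-axis ridge intensity of an infinite Gaussian chain with spacing ds,
# unit per-Gaussian amplitude
ridge_factor <- function(ds, sigma) {
  k <- seq(-ceiling(6 * sigma / ds), ceiling(6 * sigma / ds))
  sum(exp(-(k * ds)^2 / (2 * sigma^2)))
}

#' Render a filament as a noiseless image
#'
#' The filament appears as a chain of 2D Gaussians of PSF width placed at
#' spacing `sigma/3` along the path (dense enough to be continuous), scaled
#' so the ridge intensity equals `config$amplitude`, on the constant
#' `config$background`.
#'
#' @param config a [sim_config()]
#' @param filament an `mt_filament`
#' @param image optional existing image matrix to add the filament to
#'   (background is only added when a new image is created)
#' @param s_range arc-length range to render, default the whole filament
#' @param clip if `TRUE`, chain points outside the image are silently
#'   dropped instead of raising an error
#' @return numeric matrix `height_px x width_px`
#' @export
render_filament <- function(config, filament, image = NULL, s_range = NULL,
                            clip = FALSE) {
  sx <- config$psf_sigma_px[1]; sy <- config$psf_sigma_px[2]
  ds <- min(sx, sy) / 3
  if (is.null(s_range)) s_range <- c(0, filament$length_px)
  if (is.null(image)) {
    image <- matrix(config$background, nrow = config$height_px,
                    ncol = config$width_px)
  }
  span <- s_range[2] - s_range[1]
  # equal spacing <= ds with both endpoints exactly on the chain
  s <- if (span <= 0) s_range[1] else
    seq(s_range[1], s_range[2], length.out = ceiling(span / ds) + 1)
  pts <- filament_point(filament, s)
  inside <- pts[, 1] >= 0 & pts[, 1] <= config$width_px - 1 &
            pts[, 2] >= 0 & pts[, 2] <= config$height_px - 1
  if (!all(inside)) {
    if (!clip) stop("filament path lies outside the image bounds")
    pts <- pts[inside, , drop = FALSE]
    if (nrow(pts) == 0) return(image)
  }
  amp <- config$amplitude / ridge_factor(ds, sx)
  # evaluate only in the dilated bounding box of the chain
  x0 <- max(0, floor(min(pts[, 1]) - 5 * sx)); x1 <- min(config$width_px - 1, ceiling(max(pts[, 1]) + 5 * sx))
  y0 <- max(0, floor(min(pts[, 2]) - 5 * sy)); y1 <- min(config$height_px - 1, ceiling(max(pts[, 2]) + 5 * sy))
  gx <- x0:x1; gy <- y0:y1
  px <- rep(gx, each = length(gy)); py <- rep(gy, times = length(gx))
  vals <- .sog_render_cpp(px, py, pts[, 1], pts[, 2], amp, sx, sy)
  image[gy + 1, gx + 1] <- image[gy + 1, gx + 1] + matrix(vals, nrow = length(gy))
  image
}

# mean ridge intensity solving lambda / sqrt(lambda + bg) = snr
snr_to_ridge_mean <- function(snr, background = 0) {
  (snr^2 + snr * sqrt(snr^2 + 4 * background)) / 2
}

#' Apply calibrated Poisson noise to a noiseless image
#'
#' Pixel values are rescaled so that the filament ridge has Poisson mean
#' `lambda` solving `lambda / sqrt(lambda + background) = target_snr`
#' (for zero background the familiar identity `SNR = sqrt(lambda)`), the
#' background is kept at its configured level, and each pixel is drawn from
#' a Poisson law with that mean. Deterministic given `rng_seed`.
#'
#' @param image noiseless image (counts, all pixels `>= 0`)
#' @param target_snr desired SNR measured along a background-subtracted
#'   ridge line scan
#' @param rng_seed integer seed
#' @param background background level of `image` (counts)
#' @param amplitude ridge intensity of `image` above background; default the
#'   image maximum minus background
#' @return integer-valued noisy image matrix
#' @export
apply_poisson_noise <- function(image, target_snr, rng_seed,
                                background = 0,
                                amplitude = max(image) - background) {
  if (any(image < 0)) stop("image must be non-negative")
  if (amplitude <= 0) stop("image has no signal above background")
  lambda <- snr_to_ridge_mean(target_snr, background)
  mean_img <- pmax(0, image - background) * (lambda / amplitude) + background
  with_seed(rng_seed, {
    noisy <- matrix(rpois(length(mean_img), as.vector(mean_img)),
                    nrow = nrow(image))
  })
  noisy
}

#' Measure the SNR along a line scan
#'
#' Returns `I_MT / sigma_MT`: the mean over the standard deviation of the
#' (background-subtracted) pixel intensities along the scan. Each scan
#' point reads the nearest pixel (interpolation would smooth the noise and
#' inflate the SNR). A scan with zero variance yields `Inf`
#' (infinite/undefined SNR), distinct from a failure.
#'
#' @param image image matrix with the background already subtracted
#' @param line_scan matrix of ordered `(x, y)` 0-based coordinates, at least
#'   10 samples
#' @return the SNR (possibly `Inf`)
#' @export
measure_snr <- function(image, line_scan) {
  line_scan <- as.matrix(line_scan)
  if (nrow(line_scan) < 10) stop("line scan must have at least 10 samples")
  ix <- pmin(pmax(round(line_scan[, 1]), 0), ncol(image) - 1)
  iy <- pmin(pmax(round(line_scan[, 2]), 0), nrow(image) - 1)
  v <- image[cbind(iy + 1, ix + 1)]
  s <- sd(v)
  if (s == 0) return(Inf)
  mean(v) / s
}

# bilinear interpolation at 0-based subpixel coordinates
interp_bilinear <- function(image, x, y) {
  nx <- ncol(image); ny <- nrow(image)
  x <- pmin(pmax(x, 0), nx - 1); y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]; i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]; i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Line-scan coordinates along a filament ridge
#'
#' @param filament an `mt_filament`
#' @param n number of samples
#' @param s_range arc range, default the filament extent trimmed by 2 px at
#'   each end so the scan stays on the ridge plateau
#' @return matrix of `(x, y)` coordinates
#' @export
filament_scan <- function(filament, n = 50, s_range = NULL) {
  if (is.null(s_range)) {
    trim <- min(2, filament$length_px / 4)
    s_range <- c(trim, filament$length_px - trim)
  }
  filament_point(filament, seq(s_range[1], s_range[2], length.out = n))
}

## ---- trajectories ----------------------------------------------------------

#' Simulate a two-state (telegraph) length trajectory
#'
#' Microtubule length grows at `vg` and shrinks at `vs`; switching follows
#' exponential waiting times with catastrophe rate `fc` (growth to
#' shrinkage) and rescue rate `fr` (shrinkage to growth). When the length
#' shrinks back to the seed (length 0) a total catastrophe is recorded and
#' growth restarts immediately. Length is sampled at the frame times.
#'
#' @param n_frames number of frames
#' @param frame_interval frame interval in s (must be > 0)
#' @param vg,vs growth and shrinkage velocity, nm/s (> 0)
#' @param fc,fr catastrophe and rescue frequency, 1/s (>= 0)
#' @param l0 initial length in nm
#' @param rng_seed optional integer seed
#' @return list with `times` (s), `lengths` (nm), `phases` (per frame,
#'   "growth"/"shrink"), `events` (data frame `time`, `type`), `segments`
#'   (data frame of constant-velocity pieces) and the true parameters
#' @export
simulate_trajectory <- function(n_frames, frame_interval, vg, vs,
                                fc = 0, fr = 0, l0 = 0, rng_seed = NULL) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (vg <= 0 || vs <= 0) stop("vg and vs must be > 0")
  if (fc < 0 || fr < 0) stop("fc and fr must be >= 0")
  t_end <- (n_frames - 1) * frame_interval
  with_seed(rng_seed, {
    t <- 0; l <- l0; phase <- "growth"
    seg <- list(); ev <- list()
    while (t < t_end) {
      if (phase == "growth") {
        dt <- if (fc > 0) rexp(1, fc) else Inf
        dt <- min(dt, t_end - t)
        seg[[length(seg) + 1]] <- data.frame(t0 = t, t1 = t + dt, l0 = l,
                                             v = vg, phase = "growth")
        t <- t + dt; l <- l + vg * dt
        if (t < t_end) {
          ev[[length(ev) + 1]] <- data.frame(time = t, type = "catastrophe")
          phase <- "shrink"
        }
      } else {
        dt_resc <- if (fr > 0) rexp(1, fr) else Inf
        dt_base <- l / vs
        dt <- min(dt_resc, dt_base, t_end - t)
        seg[[length(seg) + 1]] <- data.frame(t0 = t, t1 = t + dt, l0 = l,
                                             v = -vs, phase = "shrink")
        t <- t + dt; l <- max(0, l - vs * dt)
        if (t < t_end) {
          if (dt == dt_base) {
            ev[[length(ev) + 1]] <- data.frame(time = t, type = "total_catastrophe")
          } else {
            ev[[length(ev) + 1]] <- data.frame(time = t, type = "rescue")
          }
          phase <- "growth"
        }
      }
    }
    segments <- if (length(seg)) do.call(rbind, seg) else
      data.frame(t0 = 0, t1 = 0, l0 = l0, v = vg, phase = "growth")
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(time = numeric(0), type = character(0))
  })
  times <- seq(0, t_end, by = frame_interval)
  idx <- findInterval(times, segments$t0, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  lengths <- segments$l0[idx] + segments$v[idx] * (times - segments$t0[idx])
  lengths <- pmax(0, lengths)
  list(times = times, lengths = lengths, phases = segments$phase[idx],
       events = events, segments = segments,
       true_vg = vg, true_vs = vs, true_fc = fc, true_fr = fr)
}

## ---- fields of seeds and movies -------------------------------------------

# minimum distance between two segments p1-p2 and q1-q2
segment_distance <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  ccw <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  inter <- ccw(p1, p2, q1) * ccw(p1, p2, q2) < 0 && ccw(q1, q2, p1) * ccw(q1, q2, p2) < 0
  if (inter) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2), pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

#' Generate a random field of straight seeds
#'
#' Seeds are placed with uniformly random orientation and position by
#' rejection sampling until every pairwise segment-to-segment distance
#' exceeds `min_separation_px`.
#'
#' @param config a [sim_config()]
#' @param n_seeds number of seeds
#' @param length_px length range in pixels, drawn uniformly
#' @param min_separation_px minimum pairwise distance between seed segments
#' @param margin_px margin kept free at the image border
#' @return list of `mt_filament` objects
#' @export
random_seed_field <- function(config, n_seeds, length_px = c(20, 60),
                              min_separation_px = 5, margin_px = 15) {
  w <- config$width_px; h <- config$height_px
  seeds <- list()
  tries <- 0
  while (length(seeds) < n_seeds) {
    tries <- tries + 1
    if (tries > 2000 * n_seeds) stop("could not place seeds at the requested separation")
    len <- runif(1, length_px[1], length_px[2])
    th <- runif(1, 0, pi)
    u <- c(cos(th), sin(th))
    cx <- runif(1, margin_px + len / 2, w - 1 - margin_px - len / 2)
    cy <- runif(1, margin_px + len / 2, h - 1 - margin_px - len / 2)
    a <- c(cx, cy) - u * len / 2; b <- c(cx, cy) + u * len / 2
    ok <- TRUE
    for (s in seeds) {
      if (segment_distance(a, b, s$start, s$end) <= min_separation_px) { ok <- FALSE; break }
    }
    if (ok) seeds[[length(seeds) + 1]] <- filament_line(a[1], a[2], b[1], b[2])
  }
  seeds
}

#' Simulate a seed-channel image
#'
#' @param config a [sim_config()]
#' @param n_seeds number of seeds
#' @param ... passed to [random_seed_field()]
#' @return list with `image` (noisy), `noiseless`, `filaments`
#' @export
simulate_seed_image <- function(config, n_seeds, ...) {
  filaments <- with_seed(config$rng_seed, random_seed_field(config, n_seeds, ...))
  img <- matrix(config$background, config$height_px, config$width_px)
  for (f in filaments) img <- render_filament(config, f, image = img)
  noisy <- apply_poisson_noise(img, config$target_snr, config$rng_seed + 1L,
                               background = config$background,
                               amplitude = config$amplitude)
  list(image = noisy, noiseless = img, filaments = filaments)
}

#' Simulate a dynamic-microtubule movie with ground truth
#'
#' Each filament consists of a stabilized seed segment on a line or cubic
#' path and a dynamic extension growing from the seed end along the same
#' path. Lengths follow the two-state telegraph process of
#' [simulate_trajectory()]. The seed channel contains only the seeds; the
#' dynamic channel contains only the dynamic extensions.
#'
#' @param config a [sim_config()]
#' @param n_frames number of dynamic frames
#' @param frame_interval frame interval, s
#' @param dynamics list with `vg`, `vs` (nm/s), `fc`, `fr` (1/s) and
#'   optionally `l0`, the initial dynamic length in nm
#' @param n_filaments number of filaments (ignored when `paths` given)
#' @param paths optional list of `mt_filament` seed objects (the dynamic
#'   extension continues past each seed's end point)
#' @param path_kind `"line"` or `"cubic"` for randomly generated paths
#' @param seed_length_px seed length range, px
#' @param curvature,inflection ranges of the cubic coefficients `b` and `I`
#'   (only for `path_kind = "cubic"`)
#' @param margin_px border margin for random placement
#' @return list with `seed_image`, `frames` (list of noisy matrices),
#'   `noiseless` (list), `filaments`, `trajectories`, and `truth`, a data
#'   frame with per frame and filament the exact tip position (px), contour
#'   length (nm) and phase
#' @export
simulate_movie <- function(config, n_frames, frame_interval, dynamics,
                           n_filaments = 1, paths = NULL,
                           path_kind = c("line", "cubic"),
                           seed_length_px = c(15, 30),
                           curvature = c(-2e-3, 2e-3),
                           inflection = c(-2e-5, 2e-5),
                           margin_px = 12) {
  path_kind <- match.arg(path_kind)
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  with_seed(config$rng_seed, {
    n_fil <- if (is.null(paths)) n_filaments else length(paths)
    trajs <- lapply(seq_len(n_fil), function(i)
      simulate_trajectory(n_frames, frame_interval, dynamics$vg, dynamics$vs,
                          dynamics$fc %||% 0, dynamics$fr %||% 0,
                          l0 = dynamics$l0 %||% 0))
    max_len_px <- vapply(trajs, function(tr) max(tr$lengths), 0) / config$pixel_size_nm
    if (is.null(paths)) {
      paths <- place_paths(config, n_fil, path_kind, seed_length_px,
                           max_len_px, curvature, inflection, margin_px)
    }
    noise_seeds <- config$rng_seed + seq_len(n_frames + 1)
  })

  seed_noiseless <- matrix(config$background, config$height_px, config$width_px)
  for (f in paths) seed_noiseless <- render_filament(config, f, image = seed_noiseless)
  seed_image <- apply_poisson_noise(seed_noiseless, config$target_snr, noise_seeds[1],
                                    background = config$background,
                                    amplitude = config$amplitude)

  frames <- vector("list", n_frames)
  noiseless <- vector("list", n_frames)
  truth <- list()
  for (k in seq_len(n_frames)) {
    img <- matrix(config$background, config$height_px, config$width_px)
    for (i in seq_len(length(paths))) {
      f <- paths[[i]]; tr <- trajs[[i]]
      l_px <- tr$lengths[k] / config$pixel_size_nm
      if (l_px > 1e-9) {
        img <- render_filament(config, f, image = img,
                               s_range = c(f$length_px, f$length_px + l_px),
                               clip = TRUE)
      }
      tip <- filament_point(f, f$length_px + l_px)
      truth[[length(truth) + 1]] <- data.frame(
        frame = k, filament = i, time_s = tr$times[k],
        tip_x = tip[1, 1], tip_y = tip[1, 2],
        length_nm = tr$lengths[k], phase = tr$phases[k])
    }
    noiseless[[k]] <- img
    frames[[k]] <- apply_poisson_noise(img, config$target_snr, noise_seeds[k + 1],
                                       background = config$background,
                                       amplitude = config$amplitude)
  }
  list(seed_image = seed_image, seed_noiseless = seed_noiseless,
       frames = frames, noiseless = noiseless, filaments = paths,
       trajectories = trajs, truth = do.call(rbind, truth),
       frame_interval = frame_interval, config = config, dynamics = dynamics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# place seed paths so that seed plus maximal growth stays inside the image
place_paths <- function(config, n_fil, path_kind, seed_length_px, max_len_px,
                        curvature, inflection, margin_px) {
  w <- config$width_px; h <- config$height_px
  paths <- list()
  for (i in seq_len(n_fil)) {
    for (try in 1:500) {
      seed_len <- runif(1, seed_length_px[1], seed_length_px[2])
      total <- seed_len + max_len_px[i] + 2
      if (path_kind == "line") {
        th <- runif(1, 0, 2 * pi)
        u <- c(cos(th), sin(th))
        x0 <- runif(1, margin_px, w - 1 - margin_px)
        y0 <- runif(1, margin_px, h - 1 - margin_px)
        p1 <- c(x0, y0) + u * total
        if (p1[1] < margin_px || p1[1] > w - 1 - margin_px ||
            p1[2] < margin_px || p1[2] > h - 1 - margin_px) next
        full <- filament_line(x0, y0, p1[1], p1[2])
        cand <- filament_line(x0, y0,
                              filament_point(full, seed_len)[1, 1],
                              filament_point(full, seed_len)[1, 2])
      } else {
        b <- runif(1, curvature[1], curvature[2])
        If <- runif(1, inflection[1], inflection[2])
        m <- runif(1, -0.5, 0.5)
        x0 <- runif(1, margin_px, w - 1 - margin_px)
        y0 <- runif(1, margin_px, h - 1 - margin_px)
        # re-center the cubic around the seed start so coefficients stay mild
        cc <- y0 - If * x0^3 - b * x0^2 - m * x0
        # x extent needed for the total arc length (upper bound: arc >= dx)
        cand_full <- filament_cubic(c(If, b, m, cc), x0, x0 + total)
        pts <- filament_point(cand_full, seq(0, total, length.out = 64))
        if (any(pts[, 1] < margin_px | pts[, 1] > w - 1 - margin_px |
                pts[, 2] < margin_px | pts[, 2] > h - 1 - margin_px)) next
        send <- filament_point(cand_full, seed_len)
        cand <- filament_cubic(c(If, b, m, cc), x0, send[1, 1])
      }
      ok <- TRUE
      for (s in paths) {
        if (segment_distance(cand$start, cand$end, s$start, s$end) <= 8) { ok <- FALSE; break }
      }
      if (ok) { paths[[i]] <- cand; break }
    }
    if (length(paths) < i) stop("could not place filament paths inside the image")
  }
  paths
}
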