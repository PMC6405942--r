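# Seed detection: MSER segmentation, line initialization from the region
# ellipse, SoG line-model fit and Gaussian-mask end-point refinement.

#' MSER detector configuration
#'
#' The stability delta is expressed in gray levels of the 8-bit-normalized
#' image; the default of 25 corresponds to roughly two to three Poisson
#' counts at typical TIRF intensities, so single-count noise structure is
#' not reported as stable. Images are smoothed with a small Gaussian
#' (matched filter) before the component tree is built; all fits run on
#' the raw image, so localization is unaffected.
#'
#' @param delta stability delta in gray levels of the 8-bit-normalized image
#' @param min_area minimum region area, px
#' @param max_area maximum region area, px; default 10% of the image
#' @param max_variation maximum relative area growth over `delta` levels
#' @param min_diversity minimum relative area difference for two nested
#'   detections to be reported separately; the default `Inf` keeps only
#'   the most stable node of every nested chain
#' @param smooth_sigma Gaussian presmoothing sigma in px (0 disables)
#' @return list of settings
#' @export
mser_config <- function(delta = 25L, min_area = 10L, max_area = NULL,
                        max_variation = 0.5, min_diversity = Inf,
                        smooth_sigma = 1.0) {
  list(delta = as.integer(delta), min_area = as.integer(min_area),
       max_area = max_area, max_variation = max_variation,
       min_diversity = min_diversity, smooth_sigma = smooth_sigma)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], r), v, rep(v[length(v)], r))
  conv1 <- function(v) stats::filter(pad(v), k, sides = 2)[(r + 1):(r + length(v))]
  t(apply(t(apply(img, 2, conv1)), 2, conv1))
}

#' Detect maximally stable extremal regions (bright on dark)
#'
#' Builds the component tree of the image's upper level sets and returns
#' the maximally stable nodes: components whose relative area growth over
#' `delta` normalized gray levels is a local minimum along their branch and
#' below `max_variation`. Each region carries the centroid and second
#' central moments of its pixel set; nested overlapping detections are
#' reduced to the most stable one.
#'
#' @param image numeric image matrix
#' @param config an [mser_config()]
#' @return list of regions of class `mt_region`, each with `pixels`
#'   (matrix of 0-based `(x, y)`), `area`, `centroid`, second moments
#'   `p`, `q`, `r`, the quantized `level` and the stability `variation`;
#'   an empty list when no stable region exists
#' @export
detect_mser_regions <- function(image, config = mser_config()) {
  image <- gaussian_blur(image, config$smooth_sigma %||% 0)
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(list())
  q <- matrix(as.integer(round((image - rng[1]) / diff(rng) * 255)),
              nrow = nrow(image))
  max_area <- config$max_area %||% floor(0.1 * length(image))
  raw <- .mser_cpp(q, config$delta, config$min_area, as.integer(max_area),
                   config$max_variation, config$min_diversity)
  lapply(raw, function(reg) {
    structure(list(pixels = reg$pixels, area = reg$area,
                   centroid = c(reg$cx, reg$cy),
                   p = reg$p, q = reg$q, r = reg$r,
                   dr = sqrt(max(reg$p^2 + 4 * reg$q^2 - 2 * reg$p * reg$r + reg$r^2, 0)),
                   level = reg$level, variation = reg$variation),
              class = "mt_region")
  })
}

#' Major-axis line of an MSER region ellipse
#'
#' From the second central moments `p = sx^2`, `r = sy^2`, `q = rho_xy` of
#' the region pixel set, with `dr = sqrt(p^2 + 4 q^2 - 2 p r + r^2)`, the
#' major axis has slope `m = (r - p + dr) / (2 q)` and intercept
#' `c = y_c - m x_c`, so the line passes through the centroid. For `q = 0`
#' the ellipse is axis-aligned and the eigen decomposition is used
#' directly: `m = 0` when `p > r`, a vertical axis (`m = Inf`, `c = NA`,
#' with `x = x_c` recorded in `x0`) otherwise.
#'
#' @param region an `mt_region` (or any list with `p`, `q`, `r`, `centroid`)
#' @return list with `m`, `c`, `direction` (unit vector along the axis) and
#'   `x0` (the vertical-line abscissa, `NA` otherwise)
#' @export
line_from_ellipse <- function(region) {
  p <- region$p; q <- region$q; r <- region$r
  cen <- region$centroid
  dr <- sqrt(max(p^2 + 4 * q^2 - 2 * p * r + r^2, 0))
  if (q != 0) {
    m <- (r - p + dr) / (2 * q)
    v <- c(2 * q, r - p + dr)
    v <- v / sqrt(sum(v^2))
    return(list(m = m, c = cen[2] - cen[1] * m, direction = v, x0 = NA_real_))
  }
  if (p >= r) {
    list(m = 0, c = cen[2], direction = c(1, 0), x0 = NA_real_)
  } else {
    list(m = Inf, c = NA_real_, direction = c(0, 1), x0 = cen[1])
  }
}

# initial endpoints: extreme projections of the region pixels on the axis
region_axis_endpoints <- function(region, direction) {
  cen <- region$centroid
  proj <- (region$pixels[, 1] - cen[1]) * direction[1] +
          (region$pixels[, 2] - cen[2]) * direction[2]
  list(start = cen + min(proj) * direction,
       end = cen + max(proj) * direction)
}

#' Detect microtubule seeds in a seed-channel image
#'
#' Pipeline: MSER segmentation, line initialization from each region's
#' ellipse major axis, Levenberg-Marquardt fit of the line SoG model, and
#' Gaussian-mask refinement of both end points. Regions whose fit fails
#' are dropped (with a message), not fatal.
#'
#' @param image seed-channel image matrix
#' @param sigma PSF sigma `(sx, sy)` in px
#' @param mser an [mser_config()]
#' @param lm an [lm_config()]
#' @param min_length_px discard fitted seeds shorter than this (px)
#' @return list of seeds; each seed is a list with `theta` (fitted line SoG
#'   parameters), `start`, `end` (refined subpixel end points), `refined`
#'   (logical, per end), `m`, `c` (line parameters), `chisq`, `snr`,
#'   `region` (the originating `mt_region`)
#' @export
detect_seeds <- function(image, sigma, mser = mser_config(),
                         lm = lm_config(), min_length_px = 3) {
  regions <- detect_mser_regions(image, mser)
  seeds <- list()
  for (reg in regions) {
    seed <- tryCatch(
      fit_seed_region(image, reg, sigma, lm),
      error = function(e) {
        message("seed region dropped: ", conditionMessage(e))
        NULL
      })
    if (is.null(seed)) next
    len <- sqrt(sum((seed$end - seed$start)^2))
    if (len < min_length_px) next
    seeds[[length(seeds) + 1]] <- seed
  }
  seeds
}

fit_seed_region <- function(image, region, sigma, lm = lm_config()) {
  axis <- line_from_ellipse(region)
  ends <- region_axis_endpoints(region, axis$direction)
  window <- fit_window(region$pixels, sigma, dim(image))
  wimg <- image[window$y0:window$y1 + 1, window$x0:window$x1 + 1]
  bg0 <- median(wimg)
  theta0 <- c(xs = ends$start[1], ys = ends$start[2],
              xe = ends$end[1], ye = ends$end[2],
              ds = sigma[1], A = max(wimg) - bg0, Bg = bg0)
  fit <- fit_filament(image, theta0, "line", sigma, window, config = lm)
  th <- fit$theta
  u <- c(th[["xe"]] - th[["xs"]], th[["ye"]] - th[["ys"]])
  nu <- sqrt(sum(u^2))
  if (nu < 1e-6 || !is.finite(fit$chisq)) stop("degenerate line fit")
  u <- u / nu
  rs <- gaussian_mask_refine(image, c(th[["xs"]], th[["ys"]]), inward = u,
                             ds = th[["ds"]], sigma = sigma,
                             background = th[["Bg"]])
  re <- gaussian_mask_refine(image, c(th[["xe"]], th[["ye"]]), inward = -u,
                             ds = th[["ds"]], sigma = sigma,
                             background = th[["Bg"]])
  m <- if (u[1] != 0) u[2] / u[1] else Inf
  cc <- if (is.finite(m)) rs$endpoint[2] - m * rs$endpoint[1] else NA_real_
  snr <- tryCatch({
    fil <- filament_line(rs$endpoint[1], rs$endpoint[2],
                         re$endpoint[1], re$endpoint[2])
    if (fil$length_px > 6)
      measure_snr(image - th[["Bg"]], filament_scan(fil))
    else NA_real_
  }, error = function(e) NA_real_)
  list(theta = th, start = rs$endpoint, end = re$endpoint,
       refined = c(start = rs$refined, end = re$refined),
       m = m, c = cc, chisq = fit$chisq, converged = fit$converged,
       snr = snr, region = region)
}

#' Match detected seeds to ground-truth filaments one-to-one
#'
#' Greedy assignment by increasing distance between detected and true
#' center points; a pair matches when both endpoint sets agree within
#' `tol_px` (endpoint order-insensitive).
#'
#' @param seeds list of detections from [detect_seeds()]
#' @param filaments list of `mt_filament` ground-truth objects
#' @param tol_px maximum endpoint distance for a match
#' @return list with `matched` (data frame `seed`, `filament`, `err_start`,
#'   `err_end`) and `accuracy` (percent of filaments matched to exactly one
#'   detection)
#' @export
match_seeds <- function(seeds, filaments, tol_px = 5) {
  if (length(seeds) == 0 || length(filaments) == 0) {
    return(list(matched = data.frame(), accuracy = 0))
  }
  pair_err <- function(seed, fil) {
    d1 <- max(sqrt(sum((seed$start - fil$start)^2)),
              sqrt(sum((seed$end - fil$end)^2)))
    d2 <- max(sqrt(sum((seed$start - fil$end)^2)),
              sqrt(sum((seed$end - fil$start)^2)))
    min(d1, d2)
  }
  err <- outer(seq_along(seeds), seq_along(filaments),
               Vectorize(function(i, j) pair_err(seeds[[i]], filaments[[j]])))
  matched <- data.frame(seed = integer(0), filament = integer(0), err = numeric(0))
  while (TRUE) {
    i <- which(err == min(err), arr.ind = TRUE)[1, ]
    if (!is.finite(err[i[1], i[2]]) || err[i[1], i[2]] > tol_px) break
    matched <- rbind(matched, data.frame(seed = i[1], filament = i[2],
                                         err = err[i[1], i[2]]))
    err[i[1], ] <- Inf
    err[, i[2]] <- Inf
    if (all(!is.finite(err))) break
  }
  list(matched = matched,
       accuracy = 100 * nrow(matched) / length(filaments))
}
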