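# Frame-by-frame tracking of dynamic microtubules growing from detected
# seed ends. Per frame: MSER regions are detected in the dynamic channel,
# each track projects its previous growth direction from the seed end to
# find its region and an end-point guess, the polynomial SoG model is
# fitted with the start point held fixed at the seed end, implausible
# steps (sharp direction or polynomial-parameter changes) are rejected as
# gaps, collisions are resolved by proximity to the last known tip, and
# the growing end is refined with the Gaussian-mask fit.

#' Tracking configuration
#'
#' @param sigma PSF sigma `(sx, sy)` of the dynamic channel, px
#' @param pixel_size_nm nm per pixel
#' @param frame_interval_s frame interval, s
#' @param mser an [mser_config()] for the dynamic channel
#' @param lm an [lm_config()]
#' @param model `"poly"` (third-order path, default) or `"line"`
#' @param angular_threshold_deg reject a step when the tip direction turns
#'   by more than this (degrees)
#' @param coef_jump_sd reject a step when `b` or `I` jumps by more than
#'   this many running standard deviations
#' @param max_gap close a track after this many consecutive gaps
#' @param intensity_frac fraction of the region maximum an end-point guess
#'   must exceed along the projection ray
#' @param both_ends track both seed ends
#' @return list of settings
#' @export
track_config <- function(sigma, pixel_size_nm = 156, frame_interval_s = 1,
                         mser = mser_config(), lm = lm_config(),
                         model = c("poly", "line"),
                         angular_threshold_deg = 20, coef_jump_sd = 10,
                         max_gap = 5L, intensity_frac = 0.5,
                         both_ends = FALSE) {
  list(sigma = sigma, pixel_size_nm = pixel_size_nm,
       frame_interval_s = frame_interval_s, mser = mser, lm = lm,
       model = match.arg(model),
       angular_threshold_deg = angular_threshold_deg,
       coef_jump_sd = coef_jump_sd, max_gap = as.integer(max_gap),
       intensity_frac = intensity_frac, both_ends = both_ends)
}

# pixel subset within r of the segment a-b (extended by ext at both ends),
# shaped like a pixel_grid so fits accept it directly
tube_window <- function(a, b, sigma, dim_img, r = NULL, ext = NULL) {
  if (is.null(r)) r <- 3 * max(sigma) + 2
  if (is.null(ext)) ext <- 4 * max(sigma)
  ab <- b - a
  len <- sqrt(sum(ab^2))
  u <- if (len > 1e-9) ab / len else c(1, 0)
  a2 <- a - ext * u; b2 <- b + ext * u
  x0 <- max(0, floor(min(a2[1], b2[1]) - r))
  x1 <- min(dim_img[2] - 1, ceiling(max(a2[1], b2[1]) + r))
  y0 <- max(0, floor(min(a2[2], b2[2]) - r))
  y1 <- min(dim_img[1] - 1, ceiling(max(a2[2], b2[2]) + r))
  gx <- x0:x1; gy <- y0:y1
  px <- rep(gx, each = length(gy)); py <- rep(gy, times = length(gx))
  seg <- b2 - a2
  seg_len2 <- max(sum(seg^2), 1e-12)
  t <- ((px - a2[1]) * seg[1] + (py - a2[2]) * seg[2]) / seg_len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (a2[1] + t * seg[1] - px)^2 + (a2[2] + t * seg[2] - py)^2
  keep <- d2 <= r^2
  list(px = px[keep], py = py[keep],
       x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

# region id per pixel (smaller regions take precedence within overlaps)
region_label_image <- function(regions, dim_img) {
  lab <- matrix(0L, dim_img[1], dim_img[2])
  ord <- order(vapply(regions, function(r) r$area, 0), decreasing = TRUE)
  for (i in ord) {
    px <- regions[[i]]$pixels
    lab[cbind(px[, 2] + 1, px[, 1] + 1)] <- i
  }
  lab
}

#' End-point guess from the projected growth direction
#'
#' Samples the ray from the seed end along the previous growth direction;
#' candidate regions are those the ray crosses. Within a region the guess
#' is the last ray point before the filament intensity falls away for
#' good: walking outward from the first above-threshold point, the scan
#' tolerates brief sub-threshold dips (up to `gap_px`) but stops at the
#' first sustained exit, so a crossing filament farther along the ray is
#' not mistaken for the tip. The threshold is `intensity_frac` of the
#' region's robust ridge intensity (90th percentile of its pixels; the
#' literal maximum would sit on a crossing hotspot). A region with no
#' above-threshold ray point yields no guess (a gap for this track).
#'
#' @param image current frame
#' @param regions regions from [detect_mser_regions()]
#' @param label label image from the same regions
#' @param seed_end `(x, y)` fixed start point
#' @param direction unit projection direction
#' @param intensity_frac intensity threshold fraction
#' @param step ray sampling step, px
#' @param gap_px sub-threshold run length tolerated within a filament, px
#' @return list of candidates, each `list(region = index, guess = c(x, y))`
#' @export
initialize_guess <- function(image, regions, label, seed_end, direction,
                             intensity_frac = 0.5, step = 0.5, gap_px = 2) {
  h <- nrow(image); w <- ncol(image)
  # distance to the image border along the ray
  tmax <- sqrt(w^2 + h^2)
  tt <- seq(0, tmax, by = step)
  rx <- seed_end[1] + tt * direction[1]
  ry <- seed_end[2] + tt * direction[2]
  keep <- rx >= 0 & rx <= w - 1 & ry >= 0 & ry <= h - 1
  rx <- rx[keep]; ry <- ry[keep]; tt <- tt[keep]
  if (length(rx) == 0) return(list())
  ix <- round(rx); iy <- round(ry)
  ids <- label[cbind(iy + 1, ix + 1)]
  vals <- image[cbind(iy + 1, ix + 1)]
  out <- list()
  for (rid in setdiff(unique(ids), 0L)) {
    rmax <- quantile(image[cbind(regions[[rid]]$pixels[, 2] + 1,
                                 regions[[rid]]$pixels[, 1] + 1)], 0.9)
    ok <- ids == rid & vals >= intensity_frac * rmax
    if (!any(ok)) next
    first <- which(ok)[1]
    last <- first; run <- 0L
    for (k in first:length(ok)) {
      if (ok[k]) { last <- k; run <- 0L }
      else { run <- run + 1L; if (run * step > gap_px) break }
    }
    out[[length(out) + 1]] <- list(region = rid,
                                   guess = c(rx[last], ry[last]),
                                   t = tt[last])
  }
  out
}

#' Validate a tracking step against the previous accepted point
#'
#' A new fit is rejected (becomes a gap) when the tip direction changes by
#' more than the angular threshold, or when the polynomial coefficients
#' `b`, `I` jump by more than `coef_jump_sd` running standard deviations.
#'
#' @param prev_dir previous unit tip direction
#' @param new_dir new unit tip direction
#' @param new_coef named `(b, I)` of the new fit (optional)
#' @param history data frame of previous accepted `(b, I)` (optional)
#' @param angular_threshold_deg angular threshold, degrees
#' @param coef_jump_sd coefficient jump threshold, in running SDs
#' @param coef_floor named `(b, I)` lower bounds on the running SD used in
#'   the jump test; the tracker passes the coefficient change that deflects
#'   the tip by one pixel (`1/L^2` and `1/L^3` for a filament of length `L`
#'   px), so fluctuations below a pixel of deflection are never rejected
#' @return `TRUE` to accept, `FALSE` to reject
#' @export
validate_step <- function(prev_dir, new_dir, new_coef = NULL, history = NULL,
                          angular_threshold_deg = 20, coef_jump_sd = 10,
                          coef_floor = c(b = 0, I = 0)) {
  cosang <- sum(prev_dir * new_dir) /
    (sqrt(sum(prev_dir^2)) * sqrt(sum(new_dir^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (ang > angular_threshold_deg) return(FALSE)
  if (!is.null(new_coef) && !is.null(history) && nrow(history) >= 5) {
    for (p in c("b", "I")) {
      s <- max(sd(history[[p]]), coef_floor[[p]])
      if (s > 0 && abs(new_coef[[p]] - mean(history[[p]])) > coef_jump_sd * s)
        return(FALSE)
    }
  }
  TRUE
}

#' Choose among candidate fits the one nearest the last known tip
#'
#' @param fits list of fit results, each with a `tip` field `(x, y)`
#' @param last_tip `(x, y)` last accepted tip position
#' @return the chosen fit (or `NULL` when `fits` is empty)
#' @export
resolve_multi_region <- function(fits, last_tip) {
  if (length(fits) == 0) return(NULL)
  d <- vapply(fits, function(f) sqrt(sum((f$tip - last_tip)^2)), 0)
  fits[[which.min(d)]]
}

# fit one candidate region for a track; works in the x<->y swapped frame
# when the growth direction is more vertical than horizontal
fit_track_candidate <- function(image, region, seed_end, guess, state, cfg) {
  seed_end <- unname(seed_end); guess <- unname(guess)
  swap <- abs(state$dir[2]) > abs(state$dir[1])
  if (swap) {
    img <- t(image)
    se <- seed_end[2:1]; gu <- guess[2:1]
    sig <- cfg$sigma[2:1]
  } else {
    img <- image
    se <- seed_end; gu <- guess
    sig <- cfg$sigma
  }
  if (abs(gu[1] - se[1]) < 0.5) gu[1] <- se[1] + sign(gu[1] - se[1] + 1e-9) * 0.5
  # fit within a tube around the initialization line rather than the full
  # region bounding box: when a crossing merges two filaments into one
  # region, the box would contain the other filament and the optimizer
  # could latch onto it
  window <- tube_window(se, gu, sig, dim(img))
  wvals <- img[cbind(window$py + 1, window$px + 1)]
  bg0 <- median(wvals)
  # fit in coordinates centred on the window: the cubic path in absolute
  # image coordinates (x^3 ~ 1e6) makes b and I catastrophically
  # ill-conditioned against m and c
  off <- c(window$x0, window$y0)
  sub <- img[window$y0:window$y1 + 1, window$x0:window$x1 + 1, drop = FALSE]
  window_s <- list(px = window$px - off[1], py = window$py - off[2],
                   x0 = 0, x1 = window$x1 - window$x0,
                   y0 = 0, y1 = window$y1 - window$y0)
  se_s <- se - off; gu_s <- gu - off
  theta0 <- c(xs = se_s[1], ys = se_s[2], xe = gu_s[1], ye = gu_s[2],
              ds = state$ds, A = max(wvals) - bg0, Bg = bg0,
              b = state$b, I = state$I)
  if (cfg$model == "line") {
    fit <- fit_filament(sub, theta0[1:7], "line", sig, window_s,
                        free = c("xe", "ye", "ds", "A", "Bg"), config = cfg$lm)
    th <- c(fit$theta, b = 0, I = 0)
  } else {
    fit <- fit_filament(sub, theta0, "poly", sig, window_s, config = cfg$lm)
    th <- fit$theta
  }
  m <- (th[["ye"]] - th[["ys"]]) / (th[["xe"]] - th[["xs"]]) -
    th[["b"]] * (th[["xe"]] + th[["xs"]]) -
    th[["I"]] * (th[["xs"]]^2 + th[["xe"]]^2 + th[["xs"]] * th[["xe"]])
  S <- 3 * th[["I"]] * th[["xe"]]^2 + 2 * th[["b"]] * th[["xe"]] + m
  dir_fit <- sign(th[["xe"]] - th[["xs"]]) * c(1, S) / sqrt(1 + S^2)
  ref <- gaussian_mask_refine(sub, c(th[["xe"]], th[["ye"]]),
                              inward = -dir_fit, ds = th[["ds"]], sigma = sig,
                              background = th[["Bg"]])
  tip <- ref$endpoint
  len_px <- contour_length(c(th[c("xs", "ys")],
                             xe = unname(tip[1]), ye = unname(tip[2]),
                             b = th[["b"]], I = th[["I"]]),
                           if (cfg$model == "line") "line" else "poly")
  tip <- tip + off
  if (swap) {
    tip <- tip[2:1]
    dir_fit <- dir_fit[2:1]
  }
  list(theta = th, tip = tip, dir = dir_fit, refined = ref$refined,
       length_px = len_px, chisq = fit$chisq, swap = swap,
       b = th[["b"]], I = th[["I"]], m = m)
}

#' Track dynamic microtubules through a movie
#'
#' @param frames list of dynamic-channel image matrices (time-ordered)
#' @param seeds seed detections from [detect_seeds()] (or a list of
#'   `mt_filament` objects used as exact seed geometry)
#' @param cfg a [track_config()]
#' @return data frame of track points: `track_id`, `seed_id`, `end`
#'   (`"A"`/`"B"`), `frame`, `time_s`, `x`, `y`, `length_nm`, `ok`
#'   (refined), `b`, `I`, `angle_deg`; gaps are absent rows. The attribute
#'   `"status"` records per track whether it survived to the last frame.
#' @export
track_movie <- function(frames, seeds, cfg) {
  tracks <- list()
  for (s in seq_along(seeds)) {
    sd_ <- seeds[[s]]
    u <- (sd_$end - sd_$start) / sqrt(sum((sd_$end - sd_$start)^2))
    tracks[[length(tracks) + 1]] <- list(
      seed_id = s, end = "A", seed_end = unname(sd_$end), dir = u)
    if (isTRUE(cfg$both_ends)) {
      tracks[[length(tracks) + 1]] <- list(
        seed_id = s, end = "B", seed_end = unname(sd_$start), dir = -u)
    }
  }
  states <- lapply(tracks, function(tr) {
    list(dir = tr$dir, tip = tr$seed_end, ds = cfg$sigma[1],
         b = 0, I = 0, gap_run = 0L, open = TRUE,
         history = data.frame(b = numeric(0), I = numeric(0)))
  })
  rows <- list()
  status <- rep("open", length(tracks))
  for (k in seq_along(frames)) {
    img <- frames[[k]]
    regions <- detect_mser_regions(img, cfg$mser)
    label <- if (length(regions)) region_label_image(regions, dim(img)) else
      matrix(0L, nrow(img), ncol(img))
    for (ti in seq_along(tracks)) {
      st <- states[[ti]]
      if (!st$open) next
      tr <- tracks[[ti]]
      cands <- if (length(regions))
        initialize_guess(img, regions, label, tr$seed_end, st$dir,
                         cfg$intensity_frac) else list()
      fits <- list()
      for (cand in cands) {
        f <- tryCatch(
          fit_track_candidate(img, regions[[cand$region]], tr$seed_end,
                              cand$guess, st, cfg),
          error = function(e) NULL)
        if (is.null(f) || !is.finite(f$chisq)) next
        # direction of the microtubule = chord from the seed end to the
        # tip; undefined for near-zero-length filaments, so the
        # plausibility rules apply only once the tip clears the seed end
        chord <- f$tip - tr$seed_end
        chord_n <- sqrt(sum(chord^2))
        f$chord_dir <- if (chord_n > 1e-9) chord / chord_n else st$dir
        short <- f$length_px < 5
        L <- max(f$length_px, 5)
        if (!short &&
            !validate_step(st$dir, f$chord_dir, new_coef = f,
                           history = st$history,
                           angular_threshold_deg = cfg$angular_threshold_deg,
                           coef_jump_sd = cfg$coef_jump_sd,
                           coef_floor = c(b = 1 / L^2, I = 1 / L^3))) next
        fits[[length(fits) + 1]] <- f
      }
      best <- resolve_multi_region(fits, st$tip)
      if (is.null(best)) {
        # frames before the first accepted point do not count towards the
        # gap limit (the microtubule may not have nucleated yet)
        if (isTRUE(st$started)) {
          st$gap_run <- st$gap_run + 1L
          if (st$gap_run > cfg$max_gap) { st$open <- FALSE; status[ti] <- "closed" }
        }
        states[[ti]] <- st
        next
      }
      st$started <- TRUE
      st$gap_run <- 0L
      # the chord of a stub filament is dominated by localization noise:
      # keep the seed direction until the tip clears the seed end
      if (best$length_px > 5) st$dir <- best$chord_dir
      st$tip <- best$tip
      st$ds <- best$theta[["ds"]]
      st$b <- best$b; st$I <- best$I
      st$history <- rbind(st$history, data.frame(b = best$b, I = best$I))
      states[[ti]] <- st
      rows[[length(rows) + 1]] <- data.frame(
        track_id = ti, seed_id = tr$seed_id, end = tr$end, frame = k,
        time_s = (k - 1) * cfg$frame_interval_s,
        x = best$tip[1], y = best$tip[2],
        length_nm = best$length_px * cfg$pixel_size_nm,
        ok = best$refined, b = best$b, I = best$I,
        angle_deg = atan2(best$dir[2], best$dir[1]) * 180 / pi)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), seed_id = integer(0),
               end = character(0), frame = integer(0), time_s = numeric(0),
               x = numeric(0), y = numeric(0), length_nm = numeric(0),
               ok = logical(0), b = numeric(0), I = numeric(0),
               angle_deg = numeric(0))
  attr(out, "status") <- status
  out
}
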