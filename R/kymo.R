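# Kymograph analysis: iterative RANSAC segmentation of length-versus-time
# tracks into growth and shrinkage events, and derivation of the dynamic
# instability parameters vg, vs, fc, fr with polarity and population
# statistics.
#
# Growth is assumed near-linear: RANSAC samples minimal point sets, fits a
# third-order polynomial ridge-regularized towards a line, counts inliers
# within the error tolerance epsilon among consecutive time points, keeps
# the largest event, removes its inliers from the sampling set and repeats
# until no further event is found. Every reported slope comes from a plain
# linear refit to the event inliers. Shrinkage uses a linear model
# restricted to fast decline on the remaining points.

#' RANSAC configuration for event segmentation
#'
#' @param epsilon inlier tolerance in nm; `NULL` (default) estimates it per
#'   track as 3x the median per-frame localization noise from the track's
#'   high-frequency differences
#' @param min_inliers minimum points per event (also the minimum event
#'   length; events shorter than 3 points are always discarded as noise)
#' @param max_iter RANSAC iterations per event
#' @param model_order polynomial order of the growth model (2 or 3)
#' @param lambda_reg ridge penalty on the order-2 and order-3 coefficients
#'   in normalized time/length units (large = near-linear)
#' @param shrink_slope_factor shrinkage must be faster than
#'   `-shrink_slope_factor * vg` of the same track (nm/s); used when
#'   `shrink_slope` is `NULL`
#' @param shrink_slope absolute shrinkage slope threshold (nm/s, negative)
#' @param max_frame_gap inliers must form a run with at most this many
#'   missing frames between consecutive members
#' @param rng_seed seed making the sampling reproducible
#' @return list of settings
#' @export
ransac_config <- function(epsilon = NULL, min_inliers = 3L, max_iter = 500L,
                          model_order = 3L, lambda_reg = 1e3,
                          shrink_slope_factor = 2, shrink_slope = NULL,
                          max_frame_gap = 2L, rng_seed = 42L) {
  stopifnot(model_order %in% c(2L, 3L))
  list(epsilon = epsilon, min_inliers = max(3L, as.integer(min_inliers)),
       max_iter = as.integer(max_iter), model_order = as.integer(model_order),
       lambda_reg = lambda_reg, shrink_slope_factor = shrink_slope_factor,
       shrink_slope = shrink_slope, max_frame_gap = as.integer(max_frame_gap),
       rng_seed = as.integer(rng_seed))
}

# epsilon estimate: 3 x per-frame localization noise from first differences
estimate_epsilon <- function(lengths) {
  d <- diff(lengths)
  max(3 * 1.4826 * median(abs(d - median(d))) / sqrt(2), 1e-6)
}

# ridge-regularized polynomial fit in normalized units; returns predictions
ransac_poly_fit <- function(t, l, t_all, order, lambda_reg) {
  t0 <- mean(t); ts <- max(diff(range(t)), 1e-9)
  ls <- max(diff(range(l)), 1e-9)
  tn <- (t - t0) / ts
  X <- outer(tn, 0:order, `^`)
  pen <- diag(c(0, 0, rep(lambda_reg, order - 1)), order + 1)
  beta <- tryCatch(solve(crossprod(X) + pen, crossprod(X, l / ls)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  drop(outer((t_all - t0) / ts, 0:order, `^`) %*% beta) * ls
}

# largest run of inlier indices consecutive in frame order. A run may
# bridge up to max_frame_gap frames that are absent from the track
# entirely (dropouts), but never a frame that was measured and fell
# outside the tolerance: a present-but-outlier point is evidence of a
# different phase and breaks the run.
largest_consecutive_run <- function(inlier_idx, frames, max_frame_gap,
                                    frames_all = frames) {
  if (length(inlier_idx) == 0) return(integer(0))
  fr <- frames[inlier_idx]
  o <- order(fr)
  inlier_idx <- inlier_idx[o]; fr <- fr[o]
  cut <- logical(length(fr) - 1)
  if (length(fr) > 1) {
    for (k in seq_len(length(fr) - 1)) {
      between <- frames_all > fr[k] & frames_all < fr[k + 1]
      n_present <- sum(between)
      n_absent <- (fr[k + 1] - fr[k] - 1) - n_present
      cut[k] <- n_present > 0 || n_absent > max_frame_gap
    }
  }
  breaks <- c(0, which(cut), length(fr))
  best <- integer(0)
  for (k in seq_len(length(breaks) - 1)) {
    run <- inlier_idx[(breaks[k] + 1):breaks[k + 1]]
    if (length(run) > length(best)) best <- run
  }
  best
}

# one RANSAC pass: best event among `avail` indices, or NULL
ransac_best_event <- function(time, length_nm, frames, avail, cfg, epsilon,
                              kind, slope_limit = NULL) {
  n_min <- if (kind == "growth") cfg$model_order + 1L else 2L
  if (length(avail) < n_min) return(NULL)
  best <- NULL
  for (it in seq_len(cfg$max_iter)) {
    smp <- sample(avail, n_min)
    if (kind == "growth") {
      # minimal samples must span enough frames to constrain the fit
      if (diff(range(frames[smp])) < 5 && length(avail) > n_min) next
      pred <- ransac_poly_fit(time[smp], length_nm[smp], time,
                              cfg$model_order, cfg$lambda_reg)
      if (is.null(pred)) next
    } else {
      if (frames[smp[1]] == frames[smp[2]]) next
      sl <- diff(length_nm[smp]) / diff(time[smp])
      if (!is.finite(sl) || sl >= slope_limit) next
      pred <- length_nm[smp[1]] + sl * (time - time[smp[1]])
    }
    ok <- avail[abs(length_nm[avail] - pred[avail]) < epsilon]
    run <- largest_consecutive_run(ok, frames, cfg$max_frame_gap,
                                   frames_all = frames)
    if (length(run) < max(cfg$min_inliers, 3L)) next
    # final slope always from the plain linear refit to the inliers
    fit <- lm(length_nm[run] ~ time[run])
    slope <- unname(coef(fit)[2])
    if (kind == "growth" && !(slope > 0)) next
    if (kind == "shrink" && !(slope < slope_limit)) next
    if (is.null(best) || length(run) > length(best$inliers)) {
      best <- list(inliers = run, slope = slope,
                   intercept = unname(coef(fit)[1]))
    }
  }
  best
}

#' Find growth events in a length-versus-time track by iterative RANSAC
#'
#' @param track data frame with columns `time_s` and `length_nm` (a
#'   `frame` column is used for consecutiveness when present)
#' @param cfg a [ransac_config()]
#' @return data frame of events: `kind`, `t_start`, `t_end`, `slope_nm_per_s`,
#'   `intercept_nm`, `n_inliers`, with the inlier row indices in the
#'   list-column `inliers`
#' @export
find_growth_events <- function(track, cfg = ransac_config()) {
  find_events(track, cfg, kind = "growth")
}

#' Find shrinkage events among the points not claimed by growth events
#'
#' @param track data frame with `time_s`, `length_nm`
#' @param growth_events result of [find_growth_events()]
#' @param cfg a [ransac_config()]
#' @param vg_track growth velocity of the track (nm/s), used for the
#'   default fast-decline threshold `-shrink_slope_factor * vg`
#' @return data frame of events (see [find_growth_events()])
#' @export
find_shrink_events <- function(track, growth_events, cfg = ransac_config(),
                               vg_track = NULL) {
  used <- unlist(growth_events$inliers)
  slope_limit <- cfg$shrink_slope
  if (is.null(slope_limit)) {
    vg <- vg_track %||% (if (nrow(growth_events)) mean(growth_events$slope_nm_per_s) else 0)
    slope_limit <- -cfg$shrink_slope_factor * max(vg, 1e-9)
  }
  find_events(track, cfg, kind = "shrink", exclude = used,
              slope_limit = slope_limit)
}

find_events <- function(track, cfg, kind, exclude = integer(0),
                        slope_limit = NULL) {
  time <- track$time_s; length_nm <- track$length_nm
  frames <- if (!is.null(track$frame)) track$frame else seq_along(time)
  epsilon <- cfg$epsilon %||% estimate_epsilon(length_nm)
  avail <- setdiff(seq_along(time), exclude)
  events <- list()
  with_seed(cfg$rng_seed, {
    while (length(avail) >= max(cfg$min_inliers, 3L)) {
      ev <- ransac_best_event(time, length_nm, frames, avail, cfg, epsilon,
                              kind, slope_limit)
      if (is.null(ev)) break
      events[[length(events) + 1]] <- ev
      avail <- setdiff(avail, ev$inliers)   # strictly shrinking sampling set
    }
  })
  if (length(events) == 0) {
    return(data.frame(kind = character(0), t_start = numeric(0),
                      t_end = numeric(0), slope_nm_per_s = numeric(0),
                      intercept_nm = numeric(0), n_inliers = integer(0),
                      inliers = I(list())))
  }
  out <- data.frame(
    kind = kind,
    t_start = vapply(events, function(e) min(time[e$inliers]), 0),
    t_end = vapply(events, function(e) max(time[e$inliers]), 0),
    slope_nm_per_s = vapply(events, function(e) e$slope, 0),
    intercept_nm = vapply(events, function(e) e$intercept, 0),
    n_inliers = vapply(events, function(e) length(e$inliers), 0L))
  out$inliers <- I(lapply(events, function(e) sort(e$inliers)))
  out[order(out$t_start), , drop = FALSE]
}

#' Classify shrink-to-growth transitions as total catastrophes or rescues
#'
#' A shrinkage event followed by a growth event starting at or below the
#' seed baseline (within `epsilon`) is a total catastrophe (the microtubule
#' shrank all the way back to the seed); a growth event starting above the
#' baseline marks a rescue. A shrinkage not followed by growth (track ends
#' mid-shrink) is incomplete.
#'
#' @param events combined event data frame (growth and shrink), time-ordered
#' @param baseline_nm seed baseline length (0 = seed end)
#' @param epsilon tolerance in nm for "at the baseline"
#' @return the shrink events with added columns `followed_by_growth`,
#'   `next_growth_start_nm`, `transition` (`"total_catastrophe"`,
#'   `"rescued"` or `"incomplete"`)
#' @export
classify_transitions <- function(events, baseline_nm = 0, epsilon = 0) {
  events <- events[order(events$t_start), , drop = FALSE]
  shr <- which(events$kind == "shrink")
  out <- events[shr, , drop = FALSE]
  out$followed_by_growth <- logical(length(shr))
  out$next_growth_start_nm <- rep(NA_real_, length(shr))
  out$transition <- rep("incomplete", length(shr))
  for (i in seq_along(shr)) {
    later <- events[events$kind == "growth" &
                    events$t_start >= events$t_end[shr[i]], , drop = FALSE]
    if (nrow(later) == 0) next
    nxt <- later[which.min(later$t_start), ]
    # length at the transition: intersection of the shrink and growth
    # lines (the kink), rather than the growth line at its first inlier,
    # which sits a frame or two after the true valley and would push
    # total catastrophes above the baseline
    sh <- events[shr[i], ]
    denom <- sh$slope_nm_per_s - nxt$slope_nm_per_s
    start_len <- NA_real_
    if (is.finite(denom) && abs(denom) > 1e-12) {
      t_star <- (nxt$intercept_nm - sh$intercept_nm) / denom
      if (t_star >= sh$t_start && t_star <= nxt$t_end) {
        start_len <- nxt$intercept_nm + nxt$slope_nm_per_s * t_star
      }
    }
    if (!is.finite(start_len)) {
      start_len <- nxt$intercept_nm + nxt$slope_nm_per_s * nxt$t_start
    }
    out$followed_by_growth[i] <- TRUE
    out$next_growth_start_nm[i] <- start_len
    out$transition[i] <- if (start_len <= baseline_nm + epsilon)
      "total_catastrophe" else "rescued"
  }
  out
}

#' Catastrophe and rescue frequencies from segmented events
#'
#' The catastrophe frequency is the number of observed catastrophes
#' (complete growth events, i.e. growth bounded at the start by the seed
#' baseline or a preceding shrinkage and whose immediately following event
#' is a shrinkage) divided by the total time spent in those growth events.
#' The rescue frequency is the number of rescues (shrinkage followed by
#' growth resuming above the baseline) divided by the total time spent in
#' complete shrinkage events.
#'
#' Because events shorter than the minimum detectable span (three frames)
#' are censored, counted durations are reduced by the detection dead time
#' `dead_time_s`: for a memoryless switching process, an event known to
#' have survived the dead time contributes no switching risk during it, so
#' subtracting it from each counted duration keeps the events/time
#' estimator consistent.
#'
#' @param events combined event data frame (growth and shrink)
#' @param baseline_nm seed baseline, nm
#' @param epsilon baseline tolerance, nm
#' @param dead_time_s detection dead time subtracted from each counted
#'   event duration, s (typically `(min event frames - 1) *` frame interval)
#' @return list with `fc`, `fr` (1/s; `NA` with `undefined` flags when a
#'   denominator is zero), event counts and the total growth/shrink times
#' @export
compute_frequencies <- function(events, baseline_nm = 0, epsilon = 0,
                                dead_time_s = 0) {
  events <- events[order(events$t_start), , drop = FALSE]
  growth <- events[events$kind == "growth", , drop = FALSE]
  shrink <- classify_transitions(events, baseline_nm, epsilon)
  # growth is complete when bounded at the start (baseline or a preceding
  # shrink) and its immediately following event is a shrink (an observed
  # catastrophe); an intervening growth event means the transition was lost
  complete_growth <- logical(nrow(growth))
  for (i in seq_len(nrow(growth))) {
    start_len <- growth$intercept_nm[i] + growth$slope_nm_per_s[i] * growth$t_start[i]
    preceded <- any(events$kind == "shrink" & events$t_end <= growth$t_start[i])
    start_ok <- preceded || start_len <= baseline_nm + epsilon
    later <- events[events$t_start >= growth$t_end[i] &
                    events$t_start > growth$t_start[i], , drop = FALSE]
    end_ok <- nrow(later) > 0 && later$kind[which.min(later$t_start)] == "shrink"
    complete_growth[i] <- start_ok && end_ok
  }
  # events whose span does not exceed the dead time contribute neither
  # observation time nor transition counts: keeping their transitions
  # while zeroing their time would bias the rate upward
  dur_g <- growth$t_end - growth$t_start
  counted_g <- complete_growth & dur_g > dead_time_s
  growth_time <- sum(dur_g[counted_g] - dead_time_s)
  complete_shrink <- shrink$followed_by_growth
  dur_s <- shrink$t_end - shrink$t_start
  counted_s <- complete_shrink & dur_s > dead_time_s
  shrink_time <- sum(dur_s[counted_s] - dead_time_s)
  n_cat <- sum(counted_g)
  n_shrink <- nrow(shrink)
  n_rescue <- sum(shrink$transition == "rescued" & counted_s)
  n_total_cat <- sum(shrink$transition == "total_catastrophe")
  fc <- if (growth_time > 0) n_cat / growth_time else NA_real_
  fr <- if (shrink_time > 0) n_rescue / shrink_time else
    (if (n_shrink == 0) 0 else NA_real_)
  structure(
    list(fc = fc, fr = fr,
         n_growth = nrow(growth), n_shrink = n_shrink,
         n_catastrophes = n_cat,
         n_rescues = n_rescue, n_total_catastrophes = n_total_cat,
         growth_time_s = growth_time, shrink_time_s = shrink_time,
         undefined = c(fc = growth_time <= 0,
                       fr = shrink_time <= 0 && n_shrink > 0)),
    complete_growth = complete_growth,
    complete_shrink = complete_shrink)
}

#' Segment one track and summarize its dynamics
#'
#' Runs the growth and shrinkage RANSAC passes and computes velocities and
#' frequencies.
#'
#' @param track data frame with `time_s`, `length_nm` (optionally `frame`)
#' @param cfg a [ransac_config()]
#' @param baseline_nm seed baseline, nm
#' @return list with `events` (time-ordered data frame), `summary` (vg, vs
#'   means and SDs, fc, fr, counts)
#' @export
analyze_track <- function(track, cfg = ransac_config(), baseline_nm = 0) {
  growth <- find_growth_events(track, cfg)
  vg_track <- if (nrow(growth)) mean(growth$slope_nm_per_s) else NA_real_
  shrink <- find_shrink_events(track, growth, cfg, vg_track = vg_track)
  events <- rbind(growth, shrink)
  events <- events[order(events$t_start), , drop = FALSE]
  eps <- cfg$epsilon %||% estimate_epsilon(track$length_nm)
  # events need >= min_inliers present frames plus edge frames lost to the
  # adjacent phase: use min_inliers frame intervals as the detection dead
  # time
  dead <- cfg$min_inliers * median(diff(track$time_s))
  freq <- compute_frequencies(events, baseline_nm, epsilon = eps,
                              dead_time_s = dead)
  # velocities over cleanly bounded events where available: an event whose
  # bounding transition went undetected may straddle a phase corner and
  # bias its slope; completeness is independent of the event's own slope
  cg <- attr(freq, "complete_growth")
  g_slopes <- growth$slope_nm_per_s
  if (!is.null(cg) && any(cg)) g_slopes <- g_slopes[cg]
  cs <- attr(freq, "complete_shrink")
  s_slopes <- abs(shrink$slope_nm_per_s)
  if (!is.null(cs) && any(cs)) s_slopes <- s_slopes[cs]
  summary <- list(
    vg_nm_per_s = if (length(g_slopes)) mean(g_slopes) else NA_real_,
    vg_sd = if (length(g_slopes) > 1) sd(g_slopes) else NA_real_,
    vs_nm_per_s = if (length(s_slopes)) mean(s_slopes) else NA_real_,
    vs_sd = if (length(s_slopes) > 1) sd(s_slopes) else NA_real_,
    fc = freq$fc, fr = freq$fr,
    n_growth = freq$n_growth, n_shrink = freq$n_shrink,
    n_catastrophes = freq$n_catastrophes, n_rescues = freq$n_rescues,
    n_total_catastrophes = freq$n_total_catastrophes,
    growth_time_s = freq$growth_time_s, shrink_time_s = freq$shrink_time_s)
  list(events = events, summary = summary, epsilon = eps)
}

#' Assign plus/minus polarity to the two tracked ends of a seed
#'
#' The faster-growing end (larger mean growth-event slope) is the plus
#' end; ties are broken by the total length gained over the track.
#'
#' @param summary_A,summary_B summaries from [analyze_track()] for the two
#'   ends; each may carry `total_gain_nm` for the tie-break
#' @return named character vector `c(A = , B = )` with values `"plus"`
#'   / `"minus"`, or `NA` when only one end has growth data
#' @export
assign_polarity <- function(summary_A, summary_B) {
  va <- summary_A$vg_nm_per_s; vb <- summary_B$vg_nm_per_s
  if (is.null(va) || is.null(vb) || is.na(va) || is.na(vb)) {
    return(c(A = NA_character_, B = NA_character_))
  }
  if (va == vb) {
    ga <- summary_A$total_gain_nm %||% 0
    gb <- summary_B$total_gain_nm %||% 0
    va <- ga; vb <- gb
  }
  if (va >= vb) c(A = "plus", B = "minus") else c(A = "minus", B = "plus")
}

#' Steady-state / time-dependent microtubule length distribution
#'
#' Forward-integrates the two-state advection equations for the density of
#' growing and shrinking microtubules,
#' \deqn{\partial_t p_g = -v_g \partial_x p_g - f_c p_g + f_r p_s,}
#' \deqn{\partial_t p_s = +v_s \partial_x p_s + f_c p_g - f_r p_s,}
#' with shrinking mass reaching the seed re-entering the growing state at
#' length zero, on a length grid (first-order upwind, `deSolve`). In the
#' bounded regime (`vg * fr < vs * fc`) the time-averaged distribution is
#' exponential with decay constant `fc/vg - fr/vs` per nm.
#'
#' @param vg,vs velocities, nm/s (> 0)
#' @param fc,fr frequencies, 1/s
#' @param t time at which to report the distribution, s; `NULL` (default)
#'   reports the time-averaged (stationary) distribution, which requires
#'   the bounded regime
#' @param x_max length-grid upper end, nm; default several mean lengths
#' @param nx number of grid cells
#' @return data frame with `length_nm`, `p_growing`, `p_shrinking`,
#'   `density` (total, normalized to integrate to 1)
#' @export
length_distribution <- function(vg, vs, fc, fr, t = NULL,
                                x_max = NULL, nx = 400L) {
  if (vg <= 0 || vs <= 0 || fc < 0 || fr < 0) stop("invalid parameters")
  bounded <- fc > 0 && (vg * fr < vs * fc)
  if (is.null(t) && !bounded) {
    stop(structure(class = c("mtdyn_nonstationary", "error", "condition"),
                   list(message = paste("unbounded regime (vg*fr >= vs*fc or",
                                        "fc = 0): no stationary length",
                                        "distribution; request a finite t"),
                        call = sys.call(-1))))
  }
  if (is.null(x_max)) {
    decay <- if (bounded) fc / vg - fr / vs else fc / max(vg, 1e-9)
    x_max <- if (bounded) 8 / decay else max(vg * (t %||% 1) * 2, 10 * vg)
  }
  dx <- x_max / nx
  x <- (seq_len(nx) - 0.5) * dx
  deriv <- function(tt, y, parms) {
    pg <- y[1:nx]; ps <- y[nx + 1:nx]
    # upwind advection: growth moves mass to larger x, shrink to smaller x
    adv_g <- -vg * (pg - c(0, pg[-nx])) / dx
    adv_s <- vs * (c(ps[-1], 0) - ps) / dx
    dpg <- adv_g - fc * pg + fr * ps
    dps <- adv_s + fc * pg - fr * ps
    # shrinking flux through x = 0 (already an outflux in the upwind
    # advection of cell 1) re-enters the growing state at the seed
    dpg[1] <- dpg[1] + vs * ps[1] / dx
    list(c(dpg, dps))
  }
  y0 <- c(rep(0, nx), rep(0, nx))
  y0[1] <- 1 / dx   # all mass starts as a fresh nucleus at the seed
  t_relax <- if (bounded) 20 / min(fc + fr, fc) else 0
  t_out <- if (is.null(t)) seq(0, t_relax, length.out = 60) else c(0, t)
  sol <- deSolve::ode(y0, t_out, deriv, parms = NULL, method = "lsoda")
  if (is.null(t)) {
    # average the second half (after relaxation) as the stationary state
    rows <- sol[sol[, 1] >= t_relax / 2, -1, drop = FALSE]
    y <- colMeans(rows)
  } else {
    y <- sol[nrow(sol), -1]
  }
  pg <- pmax(y[1:nx], 0); ps <- pmax(y[nx + 1:nx], 0)
  tot <- (pg + ps)
  z <- sum(tot) * dx
  data.frame(length_nm = x, p_growing = pg / z, p_shrinking = ps / z,
             density = tot / z)
}
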