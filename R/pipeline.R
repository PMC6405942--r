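# End-to-end pipeline: seed detection -> tracking -> kymograph analysis,
# with every stage's outputs written as standalone CSV files.

#' Run the full analysis pipeline
#'
#' Detects seeds in the seed channel, tracks dynamic microtubules through
#' the movie, segments every track into growth/shrinkage events and pools
#' the dynamic-instability statistics. All stage outputs are written under
#' `out_dir` (`seeds.csv`, `tracks.csv`, `events.csv`, `summary.json`) and
#' also returned. A stage failure keeps the outputs produced so far and
#' signals an error.
#'
#' @param seed_image seed-channel image matrix (or a TIFF path)
#' @param movie list of dynamic-channel matrices (or a TIFF path)
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory (`NULL` = no files written)
#' @param quiet suppress progress messages
#' @return list with `seeds`, `tracks`, `events`, `track_summaries`,
#'   `pooled` (pooled vg, vs, fc, fr and counts)
#' @export
run_pipeline <- function(seed_image, movie, cfg = pipeline_config(),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.character(seed_image)) seed_image <- read_stack(seed_image)[[1]]
  if (is.character(movie)) movie <- read_stack(movie)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sigma_seed <- config_sigma_seed(cfg)
  seeds <- detect_seeds(seed_image, sigma_seed, mser = config_mser(cfg),
                        lm = lm_config(lambda0 = cfg$lm_lambda0,
                                       max_iter = cfg$lm_max_iter))
  say(sprintf("detected %d seeds", length(seeds)))
  seeds_df <- seeds_to_df(seeds)
  if (!is.null(out_dir))
    write_schema_csv(seeds_df, file.path(out_dir, "seeds.csv"), "seeds")
  if (length(seeds) == 0) {
    say("no seeds: writing empty outputs")
    empty <- data.frame()
    if (!is.null(out_dir)) {
      write_schema_csv(empty, file.path(out_dir, "tracks.csv"), "tracks")
      write_schema_csv(empty, file.path(out_dir, "events.csv"), "events")
    }
    return(invisible(list(seeds = seeds, tracks = empty, events = empty,
                          track_summaries = list(), pooled = NULL)))
  }

  tracks <- track_movie(movie, seeds, config_track(cfg))
  say(sprintf("tracked %d track(s), %d points",
              length(unique(tracks$track_id)), nrow(tracks)))
  if (!is.null(out_dir))
    write_schema_csv(tracks, file.path(out_dir, "tracks.csv"), "tracks")

  rcfg <- config_ransac(cfg)
  track_ids <- unique(tracks$track_id)
  analyses <- lapply(track_ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) < 2 * rcfg$min_inliers) return(NULL)
    analyze_track(tr, rcfg)
  })
  names(analyses) <- as.character(track_ids)
  keep <- !vapply(analyses, is.null, TRUE)
  events <- do.call(rbind, lapply(track_ids[keep], function(id) {
    ev <- analyses[[as.character(id)]]$events
    if (nrow(ev) == 0) return(NULL)
    cbind(data.frame(track_id = id), ev[setdiff(names(ev), "inliers")])
  }))
  if (is.null(events)) events <- data.frame()
  if (!is.null(out_dir))
    write_schema_csv(events, file.path(out_dir, "events.csv"), "events")

  pooled <- pool_dynamics(analyses[keep])
  say(sprintf("pooled: vg = %.2f nm/s, vs = %.2f nm/s, fc = %.4g 1/s, fr = %.4g 1/s",
              pooled$vg_nm_per_s %||% NA, pooled$vs_nm_per_s %||% NA,
              pooled$fc %||% NA, pooled$fr %||% NA))
  if (!is.null(out_dir)) {
    jsonlite::write_json(pooled, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(seeds = seeds, tracks = tracks, events = events,
                 track_summaries = lapply(analyses[keep], `[[`, "summary"),
                 pooled = pooled))
}

#' Pool dynamics statistics over tracks
#'
#' Velocities are averaged over events pooled across tracks; frequencies
#' are recomputed from the pooled event counts and phase durations
#' (events/time), which weights tracks by observation time.
#'
#' @param analyses list of [analyze_track()] results
#' @return list of pooled statistics
#' @export
pool_dynamics <- function(analyses) {
  if (length(analyses) == 0) return(NULL)
  evs <- do.call(rbind, lapply(analyses, `[[`, "events"))
  sums <- lapply(analyses, `[[`, "summary")
  g <- evs[evs$kind == "growth", , drop = FALSE]
  s <- evs[evs$kind == "shrink", , drop = FALSE]
  tot <- function(field) sum(vapply(sums, function(x) x[[field]] %||% 0, 0), na.rm = TRUE)
  n_shrink <- tot("n_shrink"); growth_time <- tot("growth_time_s")
  n_cat <- tot("n_catastrophes")
  n_rescue <- tot("n_rescues"); shrink_time <- tot("shrink_time_s")
  list(n_tracks = length(analyses),
       vg_nm_per_s = if (nrow(g)) mean(g$slope_nm_per_s) else NA_real_,
       vg_sd = if (nrow(g) > 1) sd(g$slope_nm_per_s) else NA_real_,
       vs_nm_per_s = if (nrow(s)) mean(abs(s$slope_nm_per_s)) else NA_real_,
       vs_sd = if (nrow(s) > 1) sd(abs(s$slope_nm_per_s)) else NA_real_,
       fc = if (growth_time > 0) n_cat / growth_time else NA_real_,
       fr = if (shrink_time > 0) n_rescue / shrink_time else
         (if (n_shrink == 0) 0 else NA_real_),
       n_growth = tot("n_growth"), n_shrink = n_shrink,
       n_catastrophes = n_cat, n_rescues = n_rescue,
       n_total_catastrophes = tot("n_total_catastrophes"),
       growth_time_s = growth_time, shrink_time_s = shrink_time)
}
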