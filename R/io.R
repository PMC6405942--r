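# TIFF stack and tabular I/O, and the flat configuration file.
#
# All CSV outputs start with a schema comment line `# MTdyn <table> v1` and
# use the package-wide units: lengths nm, times s, angles degrees,
# coordinates 0-based pixels.

#' Read a TIFF stack
#'
#' Reads a single- or multi-frame TIFF (8/16-bit or float) as a list of
#' numeric matrices. Intensities are returned on the native integer scale
#' (the `tiff` package's [0, 1] scaling is undone using the sample depth).
#' RGB frames are converted to a single channel by averaging, with a
#' warning.
#'
#' @param path TIFF file path
#' @return list of image matrices (class `mt_stack`), frame order preserved
#' @export
read_stack <- function(path) {
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                     error = function(e)
                       stop("cannot read TIFF '", path, "': ",
                            conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  out <- lapply(frames, function(fr) {
    bps <- attr(fr, "bits.per.sample")
    fmt <- attr(fr, "sample.format")
    if (length(dim(fr)) == 3) {
      warning("RGB TIFF converted to a single channel by averaging")
      fr2 <- apply(fr, c(1, 2), mean)
      attr(fr2, "bits.per.sample") <- bps
      attr(fr2, "sample.format") <- fmt
      fr <- fr2
    }
    scale <- if (!is.null(fmt) && identical(fmt, "float")) 1
             else if (!is.null(bps)) 2^bps - 1 else 1
    m <- fr * scale
    attributes(m) <- list(dim = dim(fr))
    m
  })
  dims <- vapply(out, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("ragged TIFF stack '", path, "': frames differ in size")
  }
  structure(out, class = "mt_stack")
}

#' Write a list of image matrices as a multi-frame TIFF
#'
#' Integer-valued images (e.g. Poisson counts) are stored as 16-bit,
#' other images as 32-bit float; both round-trip through [read_stack()]
#' exactly (16-bit) or to single precision (float).
#'
#' @param frames image matrix or list of matrices
#' @param path output file
#' @return `path`, invisibly
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  ints <- all(vapply(frames, function(f)
    max(abs(f - round(f))) < 1e-9 && max(f) < 65536 && min(f) >= 0, TRUE))
  if (ints) {
    tiff::writeTIFF(lapply(frames, function(f) f / 65535),
                    path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(lapply(frames, function(f) {
      storage.mode(f) <- "double"; f
    }), path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

write_schema_csv <- function(df, path, table) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# MTdyn %s v1", table), con)
  drop <- vapply(df, is.list, TRUE)
  write.table(df[!drop], con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_schema_csv <- function(path) {
  read.table(path, header = TRUE, sep = ",", comment.char = "#")
}

#' Pipeline configuration
#'
#' Collects the acquisition calibration and the per-stage settings; the
#' object round-trips losslessly through a flat YAML file via
#' [write_config()] / [read_config()].
#'
#' @param pixel_size_nm pixel size, nm/px
#' @param frame_interval_s frame interval, s
#' @param psf_fwhm_seed_nm,psf_fwhm_dynamic_nm PSF FWHM per channel, nm
#' @param mser_delta,mser_min_area,mser_max_variation MSER settings
#' @param lm_lambda0,lm_max_iter Levenberg-Marquardt settings
#' @param angular_threshold_deg tracking step rejection angle, degrees
#' @param max_gap tracking gap limit, frames
#' @param ransac_epsilon_nm RANSAC inlier tolerance (`NA` = per-track
#'   estimate)
#' @param ransac_iter RANSAC iterations per event
#' @param both_ends track both seed ends; the default `TRUE` suits the
#'   automated pipeline, where the orientation of a detected seed is
#'   arbitrary and the growing end is not known in advance (an end with
#'   nothing growing simply produces no track)
#' @param rng_seed integer seed
#' @return list of class `mt_config`
#' @export
pipeline_config <- function(pixel_size_nm = 156, frame_interval_s = 1,
                            psf_fwhm_seed_nm = 199,
                            psf_fwhm_dynamic_nm = 205,
                            mser_delta = 25, mser_min_area = 10,
                            mser_max_variation = 0.5,
                            lm_lambda0 = 1e-3, lm_max_iter = 100,
                            angular_threshold_deg = 20, max_gap = 5,
                            ransac_epsilon_nm = NA, ransac_iter = 500,
                            both_ends = TRUE, rng_seed = 1) {
  cfg <- list(pixel_size_nm = pixel_size_nm,
              frame_interval_s = frame_interval_s,
              psf_fwhm_seed_nm = psf_fwhm_seed_nm,
              psf_fwhm_dynamic_nm = psf_fwhm_dynamic_nm,
              mser_delta = mser_delta, mser_min_area = mser_min_area,
              mser_max_variation = mser_max_variation,
              lm_lambda0 = lm_lambda0, lm_max_iter = lm_max_iter,
              angular_threshold_deg = angular_threshold_deg,
              max_gap = max_gap, ransac_epsilon_nm = ransac_epsilon_nm,
              ransac_iter = ransac_iter, both_ends = both_ends,
              rng_seed = rng_seed)
  stopifnot(pixel_size_nm > 0, frame_interval_s > 0,
            psf_fwhm_seed_nm > 0, psf_fwhm_dynamic_nm > 0)
  structure(cfg, class = "mt_config")
}

#' @rdname pipeline_config
#' @param cfg an `mt_config`
#' @param path file path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# derived per-stage settings
config_sigma_seed <- function(cfg)
  rep(fwhm_to_sigma_px(cfg$psf_fwhm_seed_nm, cfg$pixel_size_nm), 2)
config_sigma_dynamic <- function(cfg)
  rep(fwhm_to_sigma_px(cfg$psf_fwhm_dynamic_nm, cfg$pixel_size_nm), 2)
config_mser <- function(cfg)
  mser_config(delta = cfg$mser_delta, min_area = cfg$mser_min_area,
              max_variation = cfg$mser_max_variation)
config_track <- function(cfg)
  track_config(sigma = config_sigma_dynamic(cfg),
               pixel_size_nm = cfg$pixel_size_nm,
               frame_interval_s = cfg$frame_interval_s,
               mser = config_mser(cfg),
               lm = lm_config(lambda0 = cfg$lm_lambda0,
                              max_iter = cfg$lm_max_iter),
               angular_threshold_deg = cfg$angular_threshold_deg,
               max_gap = cfg$max_gap, both_ends = cfg$both_ends)
config_ransac <- function(cfg)
  ransac_config(epsilon = if (is.na(cfg$ransac_epsilon_nm)) NULL
                          else cfg$ransac_epsilon_nm,
                max_iter = cfg$ransac_iter,
                rng_seed = cfg$rng_seed + 41L)

#' Seeds as a data frame (for CSV export)
#'
#' @param seeds detections from [detect_seeds()]
#' @return data frame `seed_id, x_start, y_start, x_end, y_end, m, c, A,
#'   Bg, ds, snr`
#' @export
seeds_to_df <- function(seeds) {
  if (length(seeds) == 0) {
    return(data.frame(seed_id = integer(0), x_start = numeric(0),
                      y_start = numeric(0), x_end = numeric(0),
                      y_end = numeric(0), m = numeric(0), c = numeric(0),
                      A = numeric(0), Bg = numeric(0), ds = numeric(0),
                      snr = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(seeds), function(i) {
    s <- seeds[[i]]
    data.frame(seed_id = i, x_start = s$start[1], y_start = s$start[2],
               x_end = s$end[1], y_end = s$end[2], m = s$m, c = s$c,
               A = s$theta[["A"]], Bg = s$theta[["Bg"]],
               ds = s$theta[["ds"]], snr = s$snr)
  }))
}

df_to_seeds <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    list(start = c(df$x_start[i], df$y_start[i]),
         end = c(df$x_end[i], df$y_end[i])))
}
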