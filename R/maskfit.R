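# Iterative Gaussian-mask refinement of filament end points.
#
# The weight mask is the sum of two Gaussians: one at the current end-point
# estimate and one at +/- ds along the filament towards its interior, so
# the mask covers the tip the way the filament model does. The update moves
# the estimate by the difference between the mask-weighted centroid of the
# (background-subtracted) image and the mask-weighted centroid of the model
# tip profile (a dense Gaussian chain ending at the current estimate);
# its fixed point is therefore exactly the true tip when the image follows
# the model, and the scheme inherits no inward pull from the filament
# continuing under the mask.

#' Refine a filament end point with an iterative Gaussian-mask fit
#'
#' @param image image matrix
#' @param endpoint numeric `(x, y)` start estimate, 0-based px
#' @param inward unit vector pointing from the end point towards the
#'   filament interior
#' @param ds Gaussian spacing of the fitted model (px); sets the offset of
#'   the second mask Gaussian
#' @param sigma PSF sigma `(sx, sy)` in px
#' @param background background level subtracted before the centroids are
#'   taken (typically the fitted `Bg`)
#' @param chain_spacing spacing of the model tip profile used as centroid
#'   reference; defaults to `min(sigma)/3`, the renderer's chain spacing
#' @param tol convergence tolerance on the update displacement (px)
#' @param max_iter maximum number of iterations
#' @param max_walk abandon (and flag) the refinement when the estimate
#'   drifts more than this from the start (px); default `3 * max(sigma)`
#' @return list with `endpoint` (refined `(x, y)`), `refined` (logical),
#'   `iterations`
#' @export
gaussian_mask_refine <- function(image, endpoint, inward, ds, sigma,
                                 background = 0,
                                 chain_spacing = min(sigma) / 3,
                                 tol = 1e-3, max_iter = 50L,
                                 max_walk = 3 * max(sigma)) {
  inward <- inward / sqrt(sum(inward^2))
  sx <- sigma[1]; sy <- sigma[2]
  r <- ceiling(3 * max(sigma) + ds)
  start <- endpoint
  cur <- endpoint
  h <- nrow(image); w <- ncol(image)
  n_chain <- ceiling((r + 4 * max(sigma)) / chain_spacing)
  it <- 0L
  repeat {
    it <- it + 1L
    x0 <- max(0, floor(cur[1] - r)); x1 <- min(w - 1, ceiling(cur[1] + r))
    y0 <- max(0, floor(cur[2] - r)); y1 <- min(h - 1, ceiling(cur[2] + r))
    if (x1 - x0 < 2 || y1 - y0 < 2) {
      return(list(endpoint = start, refined = FALSE, iterations = it))
    }
    g <- pixel_grid(x0, x1, y0, y1)
    obs <- as.vector(image[y0:y1 + 1, x0:x1 + 1]) - background
    # two-Gaussian weight mask at the current estimate
    wgt <- exp(-((g$px - cur[1])^2 / (2 * sx^2) + (g$py - cur[2])^2 / (2 * sy^2))) +
           exp(-((g$px - (cur[1] + ds * inward[1]))^2 / (2 * sx^2) +
                 (g$py - (cur[2] + ds * inward[2]))^2 / (2 * sy^2)))
    # model tip profile: dense chain from the current estimate inward
    kk <- seq(0, n_chain) * chain_spacing
    prof <- .sog_render_cpp(g$px, g$py,
                            cur[1] + kk * inward[1], cur[2] + kk * inward[2],
                            1, sx, sy)
    wi <- wgt * obs
    wm <- wgt * prof
    swi <- sum(wi); swm <- sum(wm)
    if (swi <= 0 || swm <= 0) {
      return(list(endpoint = start, refined = FALSE, iterations = it))
    }
    ci <- c(sum(wi * g$px), sum(wi * g$py)) / swi
    cm <- c(sum(wm * g$px), sum(wm * g$py)) / swm
    step <- ci - cm
    cur <- cur + step
    if (sqrt(sum((cur - start)^2)) > max_walk) {
      return(list(endpoint = start, refined = FALSE, iterations = it))
    }
    if (sqrt(sum(step^2)) < tol || it >= max_iter) break
  }
  list(endpoint = cur, refined = TRUE, iterations = it)
}
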