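# Sum-of-Gaussians (SoG) filament intensity models.
#
# A filament is modelled as F_i = A (G_start,i + sum_j G_j,i + G_end,i) + Bg
# where the interior Gaussians are placed at constant arc spacing ds along a
# line (seed channel) or a third-order polynomial y = I x^3 + b x^2 + m x + c
# (dynamic channel; m is eliminated through the endpoints so the path always
# passes through both). The PSF widths (sigma_x, sigma_y) are user input,
# not fit parameters.
#
# The chain geometry (interior Gaussian positions and the per-Gaussian
# direction fields used by the analytic derivatives) is explicit model
# state, built from a parameter vector by `sog_chain()` and refreshed
# between solver iterations. Within one geometry the model responds to the
# parameters as follows: the terminal Gaussians sit exactly at the endpoint
# parameters; interior Gaussian j is displaced linearly by
# j * [(ds - ds0) B_j + (b - b0) Jv_j + (I - I0) Lv_j]. The analytic
# gradients below are exact derivatives of that model, which is also what
# the finite-difference checks differentiate.

# parameter vector layout (named numeric):
#   xs, ys, xe, ye : endpoints (px)
#   ds             : Gaussian spacing (px)
#   A, Bg          : amplitude and background
#   b, I           : curvature and inflection (poly model only)

#' Build the Gaussian chain geometry for a SoG model
#'
#' @param theta named parameter vector with `xs, ys, xe, ye, ds, A, Bg` and,
#'   for `kind = "poly"`, `b` and `I`
#' @param kind `"line"` or `"poly"`
#' @return an object of class `sog_chain`: Gaussian centres `mux`, `muy`
#'   (terminals included), derivative index `jidx` (0 at the terminals),
#'   direction fields `B`, `Jv`, `Lv`, and the reference parameters
#' @export
sog_chain <- function(theta, kind = c("line", "poly")) {
  kind <- match.arg(kind)
  xs <- theta[["xs"]]; ys <- theta[["ys"]]
  xe <- theta[["xe"]]; ye <- theta[["ye"]]
  ds <- theta[["ds"]]
  if (ds <= 0) stop("ds must be > 0")
  d <- sqrt((xe - xs)^2 + (ye - ys)^2)

  if (kind == "line") {
    u <- if (d > 0) c(xe - xs, ye - ys) / d else c(1, 0)
    K <- max(0L, as.integer(ceiling(d / ds)) - 1L)
    jj <- seq_len(K)
    mux <- c(xs, xs + jj * ds * u[1], xe)
    muy <- c(ys, ys + jj * ds * u[2], ye)
    ng <- K + 2L
    B <- rbind(c(0, 0), matrix(rep(u, each = K), nrow = K, ncol = 2),
               c(0, 0))
    Jv <- Lv <- matrix(0, ng, 2)
    jidx <- c(0, jj, 0)
    m <- if (xe != xs) (ye - ys) / (xe - xs) else Inf
  } else {
    b <- theta[["b"]]; I <- theta[["I"]]
    if (xe == xs) stop("poly model requires distinct endpoint x coordinates")
    # slope from the endpoints and the higher-order coefficients, so the
    # path passes through both endpoints for any (b, I)
    m <- (ye - ys) / (xe - xs) - b * (xe + xs) - I * (xs^2 + xe^2 + xs * xe)
    cc <- ys - I * xs^3 - b * xs^2 - m * xs
    sgn <- sign(xe - xs)
    # step along the arc with the local tangent
    xj <- numeric(0)
    x <- xs
    for (k in seq_len(5000L)) {
      S <- 3 * I * x^2 + 2 * b * x + m
      x <- x + sgn * ds / sqrt(1 + S^2)
      if (sgn * (xe - x) <= 1e-9) break
      xj <- c(xj, x)
    }
    K <- length(xj)
    Sj <- 3 * I * xj^2 + 2 * b * xj + m
    yj <- I * xj^3 + b * xj^2 + m * xj + cc
    mux <- c(xs, xj, xe)
    muy <- c(ys, yj, ye)
    ng <- K + 2L
    root <- sqrt(1 + Sj^2)
    B <- rbind(0, cbind(sgn / root, sgn * Sj / root), 0)
    dsn <- sgn * ds
    dm <- 1 / sqrt(1 + m^2)
    hb <- 2 * xj - (xs + xe)
    H <- -Sj * dsn * hb / root^3
    Jv <- rbind(0, cbind(H, Sj * H + hb * dsn * dm), 0)
    hi <- 3 * xj^2 - (xs^2 + xe^2 + xs * xe)
    Kk <- -Sj * dsn * hi / root^3
    Lv <- rbind(0, cbind(Kk, Sj * Kk + hi * dsn * dm), 0)
    jidx <- c(0, seq_len(K), 0)
  }
  structure(list(mux = mux, muy = muy, jidx = jidx, B = B, Jv = Jv, Lv = Lv,
                 kind = kind, m = m, ref = theta),
            class = "sog_chain")
}

# Gaussian centres for parameters theta under a given chain geometry
chain_positions <- function(chain, theta) {
  ref <- chain$ref
  mux <- chain$mux; muy <- chain$muy
  j <- chain$jidx
  dds <- theta[["ds"]] - ref[["ds"]]
  mux <- mux + j * dds * chain$B[, 1]
  muy <- muy + j * dds * chain$B[, 2]
  if (chain$kind == "poly") {
    db <- theta[["b"]] - ref[["b"]]; dI <- theta[["I"]] - ref[["I"]]
    mux <- mux + j * (db * chain$Jv[, 1] + dI * chain$Lv[, 1])
    muy <- muy + j * (db * chain$Jv[, 2] + dI * chain$Lv[, 2])
  }
  ng <- length(mux)
  mux[1] <- theta[["xs"]]; muy[1] <- theta[["ys"]]
  mux[ng] <- theta[["xe"]]; muy[ng] <- theta[["ye"]]
  list(mux = mux, muy = muy)
}

#' Rectangular pixel grid
#'
#' @param x0,x1,y0,y1 inclusive 0-based pixel coordinate bounds
#' @return list with vectors `px`, `py` (column-major order) and the bounds
#' @export
pixel_grid <- function(x0, x1, y0, y1) {
  gx <- x0:x1; gy <- y0:y1
  list(px = rep(gx, each = length(gy)), py = rep(gy, times = length(gx)),
       x0 = x0, x1 = x1, y0 = y0, y1 = y1, nx = length(gx), ny = length(gy))
}

#' Evaluate a SoG filament model on a pixel grid
#'
#' `model_line_sog()` and `model_poly_sog()` evaluate
#' \eqn{F_i = A (G_{start,i} + \sum_j G_{j,i} + G_{end,i}) + Bg}
#' with Gaussians of widths `sigma` placed along the line / cubic path
#' defined by `theta` (see [sog_chain()]).
#'
#' @param theta named parameter vector (see [sog_chain()])
#' @param grid a [pixel_grid()]
#' @param sigma PSF sigma, length-2 `(sx, sy)` in px
#' @param chain optional chain geometry; defaults to `sog_chain(theta)`.
#'   Passing the chain built at a reference parameter vector evaluates the
#'   model within that frozen geometry.
#' @return vector of model intensities, one per grid pixel
#' @export
model_line_sog <- function(theta, grid, sigma, chain = sog_chain(theta, "line")) {
  sog_model_eval(theta, grid, sigma, chain)
}

#' @rdname model_line_sog
#' @export
model_poly_sog <- function(theta, grid, sigma, chain = sog_chain(theta, "poly")) {
  sog_model_eval(theta, grid, sigma, chain)
}

sog_model_eval <- function(theta, grid, sigma, chain) {
  pos <- chain_positions(chain, theta)
  .sog_render_cpp(grid$px, grid$py, pos$mux, pos$muy,
                  theta[["A"]], sigma[1], sigma[2]) + theta[["Bg"]]
}

#' Analytic gradient of a SoG filament model
#'
#' Returns the model values and the matrix of partial derivatives of the
#' model intensities with respect to the requested parameters, evaluated
#' with the analytic expressions (terminal-Gaussian derivatives for the
#' endpoints, the chain-index-weighted direction sums for `ds`, `b`, `I`,
#' the amplitude-free model for `A` and unity for `Bg`).
#'
#' @inheritParams model_line_sog
#' @param free character vector of parameter names to differentiate
#' @return list with `F` (model values) and `D` (matrix, one column per
#'   entry of `free`)
#' @export
line_gradient <- function(theta, grid, sigma,
                          free = c("xs", "ys", "xe", "ye", "ds", "A", "Bg"),
                          chain = sog_chain(theta, "line")) {
  sog_gradient(theta, grid, sigma, free, chain)
}

#' @rdname line_gradient
#' @export
poly_gradient <- function(theta, grid, sigma,
                          free = c("xe", "ye", "ds", "A", "Bg", "b", "I"),
                          chain = sog_chain(theta, "poly")) {
  sog_gradient(theta, grid, sigma, free, chain)
}

sog_gradient <- function(theta, grid, sigma, free, chain) {
  pos <- chain_positions(chain, theta)
  fields <- .sog_fields_cpp(grid$px, grid$py, pos$mux, pos$muy,
                            chain$jidx, chain$B[, 1], chain$B[, 2],
                            chain$Jv[, 1], chain$Jv[, 2],
                            chain$Lv[, 1], chain$Lv[, 2],
                            sigma[1], sigma[2])
  A <- theta[["A"]]
  sx2 <- sigma[1]^2; sy2 <- sigma[2]^2
  ng <- length(pos$mux)
  D <- matrix(0, nrow = length(grid$px), ncol = length(free),
              dimnames = list(NULL, free))
  for (p in free) {
    D[, p] <- switch(p,
      xs = A * (grid$px - pos$mux[1]) / sx2 * fields[, 2],
      ys = A * (grid$py - pos$muy[1]) / sy2 * fields[, 2],
      xe = A * (grid$px - pos$mux[ng]) / sx2 * fields[, 3],
      ye = A * (grid$py - pos$muy[ng]) / sy2 * fields[, 3],
      ds = A * fields[, 4],
      b  = A * fields[, 5],
      I  = A * fields[, 6],
      A  = fields[, 1],
      Bg = rep(1, length(grid$px)),
      stop("unknown parameter: ", p))
  }
  list(F = A * fields[, 1] + theta[["Bg"]], D = D)
}

#' Contour length of a fitted filament path
#'
#' Arc length of the model path between the endpoint x coordinates:
#' Euclidean endpoint distance for the line model, adaptive quadrature of
#' \eqn{\sqrt{1 + (3 I x^2 + 2 b x + m)^2}} for the cubic.
#'
#' @param theta named parameter vector (line: `xs, ys, xe, ye`; poly
#'   additionally `b`, `I`)
#' @param kind `"line"` or `"poly"`
#' @param pixel_size_nm nm per pixel (use 1 for a length in pixels)
#' @return length in nm
#' @export
contour_length <- function(theta, kind = c("line", "poly"), pixel_size_nm = 1) {
  kind <- match.arg(kind)
  xs <- theta[["xs"]]; ys <- theta[["ys"]]
  xe <- theta[["xe"]]; ye <- theta[["ye"]]
  if (kind == "line" || (theta[["b"]] == 0 && theta[["I"]] == 0) || xe == xs) {
    return(sqrt((xe - xs)^2 + (ye - ys)^2) * pixel_size_nm)
  }
  b <- theta[["b"]]; I <- theta[["I"]]
  m <- (ye - ys) / (xe - xs) - b * (xe + xs) - I * (xs^2 + xe^2 + xs * xe)
  len <- integrate(function(x) sqrt(1 + (3 * I * x^2 + 2 * b * x + m)^2),
                   min(xs, xe), max(xs, xe), rel.tol = 1e-9,
                   subdivisions = 500L)$value
  len * pixel_size_nm
}
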