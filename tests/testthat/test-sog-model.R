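# Sum-of-Gaussians models: evaluation, analytic gradients against a
# central finite-difference oracle, and contour length.

sigma <- c(1.2, 1.2)
grid <- pixel_grid(0, 30, 0, 30)

random_line_theta <- function() {
  c(xs = runif(1, 5, 10), ys = runif(1, 5, 25),
    xe = runif(1, 20, 28), ye = runif(1, 5, 25),
    ds = runif(1, 0.8, 2), A = runif(1, 50, 200), Bg = runif(1, 0, 10))
}

fd_check <- function(theta, kind, steps) {
  chain <- sog_chain(theta, kind)
  g <- if (kind == "line") line_gradient(theta, grid, sigma, chain = chain)
       else poly_gradient(theta, grid, sigma, chain = chain)
  model <- if (kind == "line") model_line_sog else model_poly_sog
  worst <- 0
  for (p in colnames(g$D)) {
    h <- steps[[p]] %||% (1e-5 * max(1, abs(theta[[p]])))
    tp <- theta; tp[[p]] <- theta[[p]] + h
    tm <- theta; tm[[p]] <- theta[[p]] - h
    fd <- (model(tp, grid, sigma, chain) - model(tm, grid, sigma, chain)) / (2 * h)
    worst <- max(worst, max(abs(g$D[, p] - fd)) / max(abs(fd), 1e-8))
  }
  worst
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("line model degenerates correctly and is mirror-symmetric", {
  th <- c(xs = 8, ys = 15, xe = 24, ye = 15, ds = 1.2, A = 0, Bg = 3.5)
  expect_equal(model_line_sog(th, grid, sigma), rep(3.5, length(grid$px)))
  # single Gaussian when start = end
  th2 <- c(xs = 15, ys = 15, xe = 15, ye = 15, ds = 1.2, A = 10, Bg = 0)
  v <- model_line_sog(th2, grid, sigma)
  direct <- 2 * 10 * exp(-((grid$px - 15)^2 + (grid$py - 15)^2) /
                         (2 * 1.2^2))
  expect_lt(max(abs(v - direct)), 1e-9)  # start and end Gaussian coincide
  # symmetry about the chain midpoint for a horizontal filament
  th3 <- c(xs = 9, ys = 15, xe = 21, ye = 15, ds = 1, A = 50, Bg = 0)
  img <- matrix(model_line_sog(th3, grid, sigma), nrow = grid$ny)
  expect_lt(max(abs(img[, (15 - 4):(15 - 0) + 1] -
                    img[, (15 + 4):(15 + 0) + 1])), 1e-9)
})

test_that("analytic line-model gradients match central finite differences", {
  set.seed(42)
  worst <- 0
  for (k in 1:100) worst <- max(worst, fd_check(random_line_theta(), "line",
                                                list()))
  expect_lt(worst, 1e-4)
  # background derivative is unity at every pixel
  th <- random_line_theta()
  g <- line_gradient(th, grid, sigma)
  expect_equal(unname(g$D[, "Bg"]), rep(1, length(grid$px)))
  # chain direction field has unit norm
  ch <- sog_chain(th, "line")
  inner <- ch$jidx > 0
  if (any(inner)) {
    norms <- sqrt(rowSums(ch$B[inner, , drop = FALSE]^2))
    expect_equal(norms, rep(1, sum(inner)), tolerance = 1e-12)
  }
})

test_that("analytic polynomial-model gradients match finite differences", {
  set.seed(43)
  worst <- 0
  for (k in 1:100) {
    th <- c(random_line_theta(), b = runif(1, -0.02, 0.02),
            I = runif(1, -2e-4, 2e-4))
    worst <- max(worst, fd_check(th, "poly",
                                 list(b = 1e-7, I = 1e-8)))
  }
  expect_lt(worst, 1e-4)
})

test_that("polynomial model reduces to the line model at b = I = 0", {
  th <- c(xs = 7, ys = 12, xe = 25, ye = 20, ds = 1.1, A = 80, Bg = 2,
          b = 0, I = 0)
  expect_lt(max(abs(model_poly_sog(th, grid, sigma) -
                    model_line_sog(th[1:7], grid, sigma))), 1e-9)
})

test_that("the polynomial path passes through both endpoints for any b, I", {
  set.seed(44)
  for (k in 1:25) {
    th <- c(random_line_theta(), b = runif(1, -0.05, 0.05),
            I = runif(1, -5e-4, 5e-4))
    m <- (th[["ye"]] - th[["ys"]]) / (th[["xe"]] - th[["xs"]]) -
      th[["b"]] * (th[["xe"]] + th[["xs"]]) -
      th[["I"]] * (th[["xs"]]^2 + th[["xe"]]^2 + th[["xs"]] * th[["xe"]])
    cc <- th[["ys"]] - th[["I"]] * th[["xs"]]^3 - th[["b"]] * th[["xs"]]^2 -
      m * th[["xs"]]
    y_end <- th[["I"]] * th[["xe"]]^3 + th[["b"]] * th[["xe"]]^2 +
      m * th[["xe"]] + cc
    expect_equal(y_end, th[["ye"]], tolerance = 1e-9)
  }
})

test_that("contour length: Euclidean for lines, polyline oracle for cubics", {
  # 3-4-5 triangle
  th <- c(xs = 0, ys = 0, xe = 3, ye = 4)
  expect_equal(contour_length(th, "line", pixel_size_nm = 1), 5)
  # b = I = 0 equals the endpoint distance exactly
  th2 <- c(xs = 2, ys = 3, xe = 10, ye = 9, b = 0, I = 0)
  expect_identical(contour_length(th2, "poly"),
                   sqrt(8^2 + 6^2))
  # cubic y = x^3/300 over [0, 30] against a dense polyline
  b <- 0; I <- 1 / 300
  xs <- 0; xe <- 30
  ys <- 0; ye <- I * 30^3
  th3 <- c(xs = xs, ys = ys, xe = xe, ye = ye, b = b, I = I)
  xg <- seq(0, 30, length.out = 1e5 + 1)
  yg <- I * xg^3
  oracle <- sum(sqrt(diff(xg)^2 + diff(yg)^2))
  expect_equal(contour_length(th3, "poly"), oracle, tolerance = 1e-3)
})
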