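# Levenberg-Marquardt minimization of the SoG chi-squared with analytic
# derivatives. The approximate Hessian keeps only the first-order
# (Jacobian) term; the damping factor is divided by 10 after an accepted
# step and multiplied by 10 after a rejected one.

#' Levenberg-Marquardt configuration
#'
#' @param lambda0 initial damping factor
#' @param max_iter maximum number of iterations
#' @param tol_chisq stop when the relative chi-squared change of an
#'   accepted step falls below this
#' @param tol_step stop when the step norm falls below this (px)
#' @return list of settings
#' @export
lm_config <- function(lambda0 = 1e-3, max_iter = 100L,
                      tol_chisq = 1e-10, tol_step = 1e-4) {
  list(lambda0 = lambda0, max_iter = as.integer(max_iter),
       tol_chisq = tol_chisq, tol_step = tol_step)
}

#' Minimize a least-squares objective by Levenberg-Marquardt
#'
#' Generic solver for objectives of the form
#' \eqn{\chi^2(\theta) = \sum_i (I_i - F_i(\theta))^2}. `objective(theta)`
#' must return `list(F = model values, D = Jacobian of F over the free
#' parameters)`; `value(theta)` must return the model values alone (used to
#' evaluate trial steps; when omitted, `objective` is used). The step is
#' \eqn{\delta = -(H + \lambda_d I)^{-1} g} with \eqn{H = 2 D^T D},
#' \eqn{g = -2 D^T (I - F)}; accepted steps never increase chi-squared.
#'
#' @param theta0 named numeric start vector
#' @param observed observed intensities
#' @param objective function returning model values and Jacobian
#' @param value optional cheaper function returning model values only
#' @param free names of free parameters (columns of the Jacobian)
#' @param lower,upper optional named bounds; trial steps are clamped
#' @param config an [lm_config()]
#' @return list with `theta`, `chisq`, `converged`, `iterations`
#' @export
lm_minimize <- function(theta0, observed, objective, value = NULL,
                        free = names(theta0), lower = NULL, upper = NULL,
                        config = lm_config()) {
  if (is.null(value)) value <- function(th) objective(th)$F
  clamp <- function(th) {
    for (p in names(lower)) th[[p]] <- max(th[[p]], lower[[p]])
    for (p in names(upper)) th[[p]] <- min(th[[p]], upper[[p]])
    th
  }
  theta <- clamp(theta0)
  ob <- objective(theta)
  chisq <- sum((observed - ob$F)^2)
  lambda_d <- config$lambda0
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    f <- observed - ob$F
    D <- ob$D[, free, drop = FALSE]
    g <- -2 * crossprod(D, f)
    H <- 2 * crossprod(D)
    dH <- pmax(diag(H), 1e-12)   # Marquardt scaling of the damping term
    delta <- tryCatch(
      solve(H + lambda_d * diag(dH, ncol(H)), -g),
      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      lambda_d <- lambda_d * 10
      if (lambda_d > 1e12) break
      next
    }
    trial <- theta
    trial[free] <- theta[free] + as.vector(delta)
    trial <- clamp(trial)
    chisq_trial <- tryCatch(sum((observed - value(trial))^2),
                            error = function(e) Inf)
    if (is.finite(chisq_trial) && chisq_trial <= chisq) {
      step <- sqrt(sum((trial[free] - theta[free])^2))
      dchi <- chisq - chisq_trial
      theta <- trial
      chisq <- chisq_trial
      ob <- objective(theta)
      lambda_d <- max(lambda_d / 10, 1e-12)
      if (dchi / max(chisq, .Machine$double.eps) < config$tol_chisq ||
          step < config$tol_step) {
        converged <- TRUE
        break
      }
    } else {
      lambda_d <- lambda_d * 10
      if (lambda_d > 1e12) break
    }
  }
  list(theta = theta, chisq = chisq, converged = converged, iterations = iter)
}

# Gauss-Newton polish of the exact (rebuilt-geometry) objective with a
# central finite-difference Jacobian. The analytic-derivative LM treats the
# chain geometry as frozen within an iteration, whose stationary point can
# sit a few hundredths of a pixel from the exact optimum; a handful of
# damped Gauss-Newton steps on the exact objective removes that offset.
fd_polish <- function(theta, observed, value, free, lower, upper,
                      max_iter = 30L, h = 1e-4, tol_step = 1e-6) {
  clamp <- function(th) {
    for (p in names(lower)) th[[p]] <- max(th[[p]], lower[[p]])
    for (p in names(upper)) th[[p]] <- min(th[[p]], upper[[p]])
    th
  }
  chisq <- sum((observed - value(theta))^2)
  lam <- 1e-3
  for (it in seq_len(max_iter)) {
    D <- matrix(0, length(observed), length(free))
    for (k in seq_along(free)) {
      hp <- h * max(1, abs(theta[[free[k]]]))
      tp <- theta; tp[[free[k]]] <- theta[[free[k]]] + hp
      tm <- theta; tm[[free[k]]] <- theta[[free[k]]] - hp
      D[, k] <- (value(tp) - value(tm)) / (2 * hp)
    }
    f <- observed - value(theta)
    g <- -2 * crossprod(D, f)
    H <- 2 * crossprod(D)
    dH <- pmax(diag(H), 1e-12)
    improved <- FALSE
    for (sub in 1:8) {
      delta <- tryCatch(solve(H + lam * diag(dH, ncol(H)), -g),
                        error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) { lam <- lam * 10; next }
      trial <- theta
      trial[free] <- theta[free] + as.vector(delta)
      trial <- clamp(trial)
      ct <- tryCatch(sum((observed - value(trial))^2), error = function(e) Inf)
      if (is.finite(ct) && ct < chisq) {
        step <- sqrt(sum((trial[free] - theta[free])^2))
        theta <- trial; chisq <- ct
        lam <- max(lam / 10, 1e-12)
        improved <- TRUE
        if (step < tol_step) return(list(theta = theta, chisq = chisq))
        break
      }
      lam <- lam * 10
    }
    if (!improved) break
  }
  list(theta = theta, chisq = chisq)
}

#' Fit a SoG filament model to an image window
#'
#' Minimizes the chi-squared between the observed window intensities and
#' the line or polynomial SoG model, rebuilding the chain geometry from the
#' current parameters at every solver iteration.
#'
#' @param image image matrix
#' @param theta0 named start vector (see [sog_chain()])
#' @param kind `"line"` or `"poly"`
#' @param sigma PSF sigma `(sx, sy)` in px
#' @param window a [pixel_grid()] defining the fit region
#' @param free free parameter names; by default all parameters for the line
#'   model and all but the fixed start point for the polynomial model
#' @param config an [lm_config()]
#' @param polish after the analytic-derivative LM, run a short Gauss-Newton
#'   polish of the exact objective (finite-difference Jacobian). `TRUE`
#'   polishes within the current Gaussian-count branch of the chain;
#'   `"branches"` additionally starts from the best of a coarse grid of
#'   endpoint offsets and probes the neighbouring Gaussian-count branches
#'   (chi-squared is discontinuous in the count), which is slower but
#'   recovers exact optima on noiseless data even from starts well outside
#'   the PSF-wide basin; `FALSE` disables polishing
#' @return list with `theta`, `chisq`, `converged`, `iterations`, `kind`
#' @export
fit_filament <- function(image, theta0, kind = c("line", "poly"), sigma,
                         window, free = NULL, config = lm_config(),
                         polish = TRUE) {
  kind <- match.arg(kind)
  if (is.null(free)) {
    free <- if (kind == "line") c("xs", "ys", "xe", "ye", "ds", "A", "Bg")
            else c("xe", "ye", "ds", "A", "Bg", "b", "I")
  }
  # the window may be a full rectangle or any pixel subset (e.g. a tube
  # around the initialization line); observed follows the grid order
  observed <- image[cbind(window$py + 1, window$px + 1)]
  smin <- min(sigma)
  # curvature/inflection bounds: microtubule rigidity keeps paths gentle;
  # beyond these the cubic can snake onto neighbouring structures
  lower <- c(ds = smin / 3, A = 1e-9,
             xs = window$x0 - 2, ys = window$y0 - 2,
             xe = window$x0 - 2, ye = window$y0 - 2,
             b = -0.1, I = -0.01)
  upper <- c(ds = 5 * max(sigma),
             xs = window$x1 + 2, ys = window$y1 + 2,
             xe = window$x1 + 2, ye = window$y1 + 2,
             b = 0.1, I = 0.01)
  lower <- lower[intersect(names(lower), free)]
  upper <- upper[intersect(names(upper), free)]
  objective <- function(th) sog_gradient(th, window, sigma, free,
                                         chain = sog_chain(th, kind))
  value <- function(th) sog_model_eval(th, window, sigma, sog_chain(th, kind))
  if (identical(polish, "branches")) {
    # coarse grid over endpoint offsets: the chi-squared basin is only a
    # few PSF widths wide, so a start more than ~1 sigma off the ridge can
    # land in a secondary minimum; pick the best 1-px-grid start first
    ends <- intersect(c("xs", "ys", "xe", "ye"), free)
    if (length(ends) > 0) {
      offs <- expand.grid(rep(list(-2:2), length(ends)))
      best <- list(theta = theta0,
                   chisq = tryCatch(sum((observed - value(theta0))^2),
                                    error = function(e) Inf))
      for (r in seq_len(nrow(offs))) {
        trial <- theta0
        trial[ends] <- theta0[ends] + as.numeric(offs[r, ])
        cs <- tryCatch(sum((observed - value(trial))^2),
                       error = function(e) Inf)
        if (cs < best$chisq) best <- list(theta = trial, chisq = cs)
      }
      theta0 <- best$theta
    }
  }
  fit <- lm_minimize(theta0, observed, objective, value = value, free = free,
                     lower = lower, upper = upper, config = config)
  if (!identical(polish, FALSE)) {
    pol <- fd_polish(fit$theta, observed, value, free, lower, upper)
    if (identical(polish, "branches") && "ds" %in% free) {
      # chi-squared is discontinuous across Gaussian-count branches of the
      # chain (J = ceil(d/ds) + 1); probe the neighbouring branches and
      # keep the best polished fit
      th <- pol$theta
      d <- sqrt((th[["xe"]] - th[["xs"]])^2 + (th[["ye"]] - th[["ys"]])^2)
      K <- max(1L, as.integer(ceiling(d / th[["ds"]])))
      for (k in setdiff(seq(max(2L, K - 2L), K + 2L), K)) {
        tp <- th
        tp[["ds"]] <- min(max(d / (k - 0.5), lower[["ds"]]), upper[["ds"]])
        cand <- fd_polish(tp, observed, value, free, lower, upper,
                          max_iter = 10L)
        if (cand$chisq < pol$chisq) pol <- cand
      }
    }
    fit$theta <- pol$theta
    fit$chisq <- pol$chisq
  }
  fit$kind <- kind
  fit
}

# fit window: bounding box of a pixel set dilated by 3 sigma, clipped
fit_window <- function(pixels, sigma, dim_img, extra = 0) {
  r <- ceiling(3 * max(sigma)) + extra
  x0 <- max(0, min(pixels[, 1]) - r); x1 <- min(dim_img[2] - 1, max(pixels[, 1]) + r)
  y0 <- max(0, min(pixels[, 2]) - r); y1 <- min(dim_img[1] - 1, max(pixels[, 2]) + r)
  pixel_grid(x0, x1, y0, y1)
}
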