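## Least-squares fitting of floating model surfaces to point clouds.

#' Best-fit sphere
#'
#' Least-squares sphere through a point cloud.  The algebraic linear
#' system `x^2 + y^2 + z^2 = 2 a x + 2 b y + 2 c z + d` is solved for the
#' centre `(a, b, c)` and `R = sqrt(d + a^2 + b^2 + c^2)`, then refined by
#' a short geometric Gauss-Newton pass on the radial residuals
#' `||p_i - centre|| - R` (the algebraic solution alone amplifies height
#' noise considerably on a shallow corneal cap).  Deterministic, and exact
#' for noiseless spherical data.  The apex is reported assuming the
#' surface opens toward +z (posterior-positive sag), i.e. apex
#' z = centre z - R.
#'
#' @param points data frame or matrix with columns `x`, `y`, `z` in mm.
#' @return A list with `R`, `X0`, `Y0`, `Z0` (apex position).
#' @export
best_fit_sphere <- function(points) {
  pts <- as.data.frame(points)
  if (nrow(pts) < 4L) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * pts$x, 2 * pts$y, 2 * pts$z, 1)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate point cloud: points are coplanar or otherwise rank-deficient")
  beta <- qr.coef(qrA, pts$x^2 + pts$y^2 + pts$z^2)
  R2 <- beta[4L] + sum(beta[1:3]^2)
  if (!is.finite(R2) || R2 <= 0) stop("sphere fit failed: non-positive radius")
  ctr <- unname(beta[1:3])
  out <- nls.lm(par = c(ctr, sqrt(R2)),
                fn = function(p) sqrt((pts$x - p[1])^2 + (pts$y - p[2])^2 +
                                        (pts$z - p[3])^2) - p[4],
                control = nls.lm.control(maxiter = 50))
  p <- out$par
  if (!all(is.finite(p)) || p[4] <= 0)
    stop("sphere fit failed: non-positive radius")
  list(R = p[4], X0 = p[1], Y0 = p[2], Z0 = p[3] - p[4])
}

#' Options controlling a surface fit
#'
#' Parameter bounds, convergence tolerances and the iteration cap for
#' [fit_surface()].  Defaults: radii in \[3, 15\] mm, asphericities in
#' \[-3, 2\], |X0|, |Y0| <= 1.5 mm, Z0 in \[-2, 2\] mm; cost tolerance
#' 1e-12 mm^2, parameter tolerance 1e-9, at most 500 iterations.
#' Initialisation is deterministic (no random restarts).
#'
#' @param model surface model the options apply to.
#' @param r_bounds,q_bounds,xy_bound,z_bounds parameter box constraints.
#' @param ftol relative tolerance on the sum-of-squares cost.
#' @param ptol relative tolerance on parameter change.
#' @param max_iter maximum number of optimiser iterations.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(model = "Biconic",
                        r_bounds = c(3, 15), q_bounds = c(-3, 2),
                        xy_bound = 1.5, z_bounds = c(-2, 2),
                        ftol = 1e-12, ptol = 1e-9, max_iter = 500L) {
  model <- match.arg(model, SURFACE_MODELS)
  stopifnot(r_bounds[1] > 0, diff(r_bounds) > 0, diff(q_bounds) > 0,
            xy_bound > 0, diff(z_bounds) > 0, ftol > 0, ptol > 0,
            max_iter >= 1)
  structure(list(model = model, r_bounds = r_bounds, q_bounds = q_bounds,
                 xy_bound = xy_bound, z_bounds = z_bounds, ftol = ftol,
                 ptol = ptol, max_iter = as.integer(max_iter)),
            class = "fit_options")
}

## parameter vector layout per model
par_names <- function(model) {
  switch(model,
         SphCyl    = c("R1", "R2", "A1", "X0", "Y0", "Z0"),
         CylConoid = c("R1", "R2", "A1", "Q", "X0", "Y0", "Z0"),
         Biconic   = c("R1", "R2", "A1", "Q1", "Q2", "X0", "Y0", "Z0"))
}

par_to_params <- function(p, model) {
  q1 <- switch(model, SphCyl = 0, CylConoid = p[["Q"]], Biconic = p[["Q1"]])
  q2 <- switch(model, SphCyl = 0, CylConoid = p[["Q"]], Biconic = p[["Q2"]])
  list(model = model, R1 = p[["R1"]], R2 = p[["R2"]], A1 = p[["A1"]],
       Q1 = q1, Q2 = q2, X0 = p[["X0"]], Y0 = p[["Y0"]], Z0 = p[["Z0"]])
}

fit_bounds <- function(model, opts, a_centre) {
  nm <- par_names(model)
  lower <- setNames(numeric(length(nm)), nm)
  upper <- lower
  lower[c("R1", "R2")] <- opts$r_bounds[1]; upper[c("R1", "R2")] <- opts$r_bounds[2]
  # the axis is periodic: allow a half-turn either side of the initial guess
  lower["A1"] <- a_centre - 90; upper["A1"] <- a_centre + 90
  for (q in intersect(c("Q", "Q1", "Q2"), nm)) {
    lower[q] <- opts$q_bounds[1]; upper[q] <- opts$q_bounds[2]
  }
  lower[c("X0", "Y0")] <- -opts$xy_bound; upper[c("X0", "Y0")] <- opts$xy_bound
  lower["Z0"] <- opts$z_bounds[1]; upper["Z0"] <- opts$z_bounds[2]
  list(lower = lower, upper = upper)
}

## Deterministic initial guess: algebraic sphere for radius/apex, then the
## principal directions of the quadratic form fitted to the heights give the
## flat axis and the meridional curvature split.
fit_initial_guess <- function(pts, model, opts) {
  sph <- best_fit_sphere(pts)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  r0 <- clamp(sph$R, opts$r_bounds[1] * 1.05, opts$r_bounds[2] * 0.95)
  x0 <- clamp(sph$X0, -opts$xy_bound * 0.9, opts$xy_bound * 0.9)
  y0 <- clamp(sph$Y0, -opts$xy_bound * 0.9, opts$xy_bound * 0.9)
  z0 <- clamp(sph$Z0, opts$z_bounds[1] * 0.95, opts$z_bounds[2] * 0.95)

  dx <- pts$x - x0
  dy <- pts$y - y0
  qfit <- tryCatch(
    lm.fit(cbind(1, dx, dy, dx^2, dy^2, dx * dy), pts$z)$coefficients,
    error = function(e) rep(NA_real_, 6))
  a1 <- 0
  r1 <- r2 <- r0
  if (all(is.finite(qfit))) {
    H <- matrix(c(2 * qfit[4L], qfit[6L], qfit[6L], 2 * qfit[5L]), 2L)
    eg <- eigen(H, symmetric = TRUE)
    lam <- sort(eg$values)               # curvature estimates (1/mm)
    rmax <- max(sqrt(pts$x^2 + pts$y^2))
    astig_sag <- abs(diff(lam)) * rmax^2 / 2   # astigmatic height signal, mm
    if (astig_sag >= 1e-6) {
      i_flat <- which.min(eg$values)
      a1 <- wrap_axis(atan2(eg$vectors[2L, i_flat], eg$vectors[1L, i_flat]) * 180 / pi)
      if (all(lam > 1 / opts$r_bounds[2] & lam < 1 / opts$r_bounds[1])) {
        r1 <- 1 / lam[1L]
        r2 <- 1 / lam[2L]
      }
    }
  }
  init <- c(R1 = r1, R2 = r2, A1 = a1, Q = 0, Q1 = 0, Q2 = 0,
            X0 = x0, Y0 = y0, Z0 = z0)
  init[par_names(model)]
}

#' Fit a floating model surface to a point cloud
#'
#' Minimises the RMS height residual
#' `sqrt(mean((z_i - sag(params, x_i, y_i))^2))` over the model's
#' parameters within box bounds, using bounded Levenberg-Marquardt least
#' squares started from a deterministic initial guess (algebraic best-fit
#' sphere; flat axis and meridional curvature split from the principal
#' directions of a quadratic height fit).  A negative sag radicand during
#' the search is clamped to zero; the returned result reports whether the
#' solution itself sits on that clamp.
#'
#' When the fitted astigmatism is below resolution (`R1 - R2 < 1e-6` mm)
#' the axis is not identifiable; it is reported as 0 by convention and
#' flagged via `axis_identifiable = FALSE`.
#'
#' @param points data frame with columns `x`, `y`, `z` (mm), e.g. from
#'   [to_cartesian_points()].
#' @param model surface model to fit (ignored if `options` is supplied).
#' @param options a [fit_options()].
#' @return An object of class `corneal_fit`: `params` (canonicalised
#'   [surface_params()]), `rms_error` (mm), `n_points`, `converged`,
#'   `n_iterations`, `axis_identifiable`, `clipped`, plus the ROI/surface
#'   tags of the input cloud when present.
#' @export
fit_surface <- function(points, model = "Biconic", options = NULL) {
  if (is.null(options)) options <- fit_options(model)
  model <- options$model
  pts <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(pts)))
    stop("'points' must have columns x, y, z")
  if (nrow(pts) < 3L * dof(model))
    stop(sprintf("too few points (%d) to fit %s (needs >= %d)",
                 nrow(pts), model, 3L * dof(model)))

  init <- fit_initial_guess(pts, model, options)
  b <- fit_bounds(model, options, a_centre = init[["A1"]])

  resid_fn <- function(p) {
    pr <- par_to_params(setNames(p, names(init)), model)
    pts$z - sag_kernel(pr, pts$x, pts$y, clip = TRUE)
  }
  out <- nls.lm(par = init, lower = b$lower, upper = b$upper, fn = resid_fn,
                control = nls.lm.control(
                  ftol = options$ftol, ptol = options$ptol,
                  maxiter = options$max_iter,
                  maxfev = 100L * (length(init) + 1L) * options$max_iter))

  pr <- par_to_params(out$par, model)
  params <- canonicalize(do.call(surface_params, pr))
  axis_identifiable <- (params$R1 - params$R2) >= 1e-6
  if (!axis_identifiable) params$A1 <- 0

  aa <- params$A1 * pi / 180
  du <- cos(aa) * (pts$x - params$X0) + sin(aa) * (pts$y - params$Y0)
  dv <- -sin(aa) * (pts$x - params$X0) + cos(aa) * (pts$y - params$Y0)
  rad <- 1 - (1 + params$Q1) * (du / params$R1)^2 -
    (1 + params$Q2) * (dv / params$R2)^2
  res <- pts$z - sag_kernel(params, pts$x, pts$y, clip = TRUE)
  structure(list(
    params = params,
    rms_error = sqrt(mean(res^2)),
    n_points = nrow(pts),
    converged = out$info %in% 1:4,
    n_iterations = out$niter,
    info = out$info,
    message = out$message,
    axis_identifiable = axis_identifiable,
    clipped = any(rad < 0),
    roi_diameter = attr(points, "roi_diameter"),
    surface = attr(points, "surface")
  ), class = "corneal_fit")
}

#' @export
print.corneal_fit <- function(x, ...) {
  cat(sprintf("Surface fit (%s%s): rms %.3g mm over %d points, %s in %d iterations\n",
              x$params$model,
              if (!is.null(x$roi_diameter)) sprintf(", ROI %g mm", x$roi_diameter) else "",
              x$rms_error, x$n_points,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  print(x$params)
  invisible(x)
}

#' Fit one model to all three surfaces of a measurement
#'
#' @param record a [measurement_record()].
#' @param roi_diameter ROI diameter in mm (typically 3 or 6).
#' @param model surface model.
#' @param options optional [fit_options()].
#' @return A named list of [fit_surface()] results for `epithelium`,
#'   `stroma` and `endothelium`, with attributes `roi_diameter` and `model`.
#' @export
fit_measurement <- function(record, roi_diameter, model = "Biconic",
                            options = NULL) {
  stopifnot(inherits(record, "measurement_record"))
  fits <- lapply(MAP_SURFACES, function(s) {
    m <- record$maps[[s]]
    attr(m, "surface") <- s
    tryCatch({
      cloud <- to_cartesian_points(m, roi_diameter)
      fit_surface(cloud, model = model, options = options)
    }, error = function(e) {
      stop("fit failed for surface '", s, "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  names(fits) <- MAP_SURFACES
  attr(fits, "roi_diameter") <- roi_diameter
  attr(fits, "model") <- if (is.null(options)) model else options$model
  fits
}
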