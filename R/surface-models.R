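## Closed-form sag of the three floating model surfaces.

SURFACE_MODELS <- c("SphCyl", "CylConoid", "Biconic")

#' Parameters of a floating model surface
#'
#' Three nested astigmatic models are supported, all with orthogonal
#' principal meridians and a floating apex:
#'
#' * `SphCyl` — spherocylinder: radii `R1` (flat meridian, at axis `A1`)
#'   and `R2` (steep meridian), no asphericity (6 degrees of freedom);
#' * `CylConoid` — cylindrical conoid: adds a common asphericity
#'   `Q1 == Q2` in all meridians (7 degrees of freedom);
#' * `Biconic` — separate asphericities `Q1` (flat) and `Q2` (steep)
#'   (8 degrees of freedom).
#'
#' The canonical labelling has `R1 >= R2` (flat meridian is the flatter
#' one) and `A1` in \[0, 180) degrees; use [canonicalize()] to enforce it.
#'
#' @param model one of `"SphCyl"`, `"CylConoid"`, `"Biconic"`.
#' @param R1,R2 apical radii of curvature in mm (flat / steep meridian).
#' @param A1 axis of the flat meridian in degrees.
#' @param Q1,Q2 asphericities (dimensionless); `Q = 0` is a sphere,
#'   `Q < 0` prolate (typical cornea), `Q > 0` oblate.
#' @param X0,Y0,Z0 apex position in mm.
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(model, R1, R2, A1 = 0, Q1 = 0, Q2 = 0,
                           X0 = 0, Y0 = 0, Z0 = 0) {
  model <- match.arg(model, SURFACE_MODELS)
  for (nm in c("R1", "R2", "A1", "Q1", "Q2", "X0", "Y0", "Z0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar")
  }
  if (R1 <= 0 || R2 <= 0) stop("apical radii must be positive")
  if (model == "SphCyl" && (Q1 != 0 || Q2 != 0))
    stop("SphCyl has no asphericity: Q1 and Q2 must be 0")
  if (model == "CylConoid" && Q1 != Q2)
    stop("CylConoid carries one common asphericity: Q1 must equal Q2")
  structure(list(model = model, R1 = R1, R2 = R2, A1 = A1,
                 Q1 = Q1, Q2 = Q2, X0 = X0, Y0 = Y0, Z0 = Z0),
            class = "surface_params")
}

#' @export
print.surface_params <- function(x, ...) {
  cat(sprintf("%s surface: R1 = %.4f mm @ %.1f deg, R2 = %.4f mm", x$model,
              x$R1, x$A1, x$R2))
  if (x$model == "CylConoid") cat(sprintf(", Q = %.4f", x$Q1))
  if (x$model == "Biconic") cat(sprintf(", Q1 = %.4f, Q2 = %.4f", x$Q1, x$Q2))
  cat(sprintf("\n  apex (%.4f, %.4f, %.4f) mm\n", x$X0, x$Y0, x$Z0))
  invisible(x)
}

#' Degrees of freedom of a surface model
#'
#' @param model `"SphCyl"`, `"CylConoid"` or `"Biconic"`.
#' @return 6, 7 or 8 respectively.
#' @export
dof <- function(model) {
  model <- match.arg(model, SURFACE_MODELS)
  c(SphCyl = 6L, CylConoid = 7L, Biconic = 8L)[[model]]
}

## Core sag kernel.  With (u, v) the lateral offsets from the apex rotated
## by -A1 (u along the flat meridian), cx = 1/R1, cy = 1/R2:
##   s(u, v) = (cx u^2 + cy v^2) / (1 + sqrt(1 - (1+Q1) cx^2 u^2 - (1+Q2) cy^2 v^2))
## The (1+Q) factor multiplies c^2 u^2 directly, i.e. Q is the asphericity
## (conic constant) with Q = 0 the sphere.  `clip = TRUE` clamps a negative
## radicand to 0 (used only inside optimisation).
sag_kernel <- function(p, x, y, clip = FALSE) {
  a <- p$A1 * pi / 180
  dx <- x - p$X0
  dy <- y - p$Y0
  u <- cos(a) * dx + sin(a) * dy
  v <- -sin(a) * dx + cos(a) * dy
  cx <- 1 / p$R1
  cy <- 1 / p$R2
  num <- cx * u^2 + cy * v^2
  rad <- 1 - (1 + p$Q1) * (cx * u)^2 - (1 + p$Q2) * (cy * v)^2
  if (clip) {
    rad <- pmax(rad, 0)
  } else if (any(rad < 0)) {
    i <- which(rad < 0)[1L]
    stop(sprintf(
      "sag undefined (negative radicand) at (x, y) = (%.4f, %.4f) mm",
      x[i], y[i]))
  }
  p$Z0 + num / (1 + sqrt(rad))
}

#' Surface sag (height) at lateral positions
#'
#' Evaluates the closed-form sag of a model surface: positive z posterior,
#' `sag(X0, Y0) = Z0` at the apex.  Points outside the surface's domain of
#' definition (negative radicand) raise a domain error identifying the
#' offending point.
#'
#' @param params a [surface_params()].
#' @param x,y lateral coordinates in mm (vectorised).
#' @return Heights z in mm.
#' @export
sag <- function(params, x, y) {
  stopifnot(inherits(params, "surface_params"))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  sag_kernel(params, x, y, clip = FALSE)
}

wrap_axis <- function(a) ((a %% 180) + 180) %% 180

#' Canonicalise surface parameters
#'
#' Enforces the flat/steep labelling: if `R1 < R2` the meridians are
#' swapped (`(R1, Q1) <-> (R2, Q2)`, `A1 <- A1 + 90`), and `A1` is wrapped
#' into \[0, 180).  The surface itself (its sag) is unchanged.
#'
#' @param params a [surface_params()].
#' @return A canonical `surface_params` describing the same surface.
#' @export
canonicalize <- function(params) {
  stopifnot(inherits(params, "surface_params"))
  if (params$R1 <= 0 || params$R2 <= 0) stop("apical radii must be positive")
  p <- params
  if (p$R1 < p$R2) {
    p[c("R1", "R2", "Q1", "Q2")] <- p[c("R2", "R1", "Q2", "Q1")]
    p$A1 <- p$A1 + 90
  }
  p$A1 <- wrap_axis(p$A1)
  p
}
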