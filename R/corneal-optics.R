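## Dioptric power vectors and layer thicknesses from fitted geometry.

#' Refractive index chain of the three-surface cornea
#'
#' Literature refractive indices for the media bounding the three fitted
#' surfaces: air 1.0, epithelium 1.41, stroma 1.376, aqueous humour 1.336.
#' The epithelial surface refracts air -> epithelium, the epithelium-stroma
#' interface epithelium -> stroma, and the endothelium stroma -> aqueous.
#'
#' @param n_air,n_epithelium,n_stroma,n_aqueous refractive indices.
#' @return An object of class `index_chain`.
#' @export
refractive_index_chain <- function(n_air = 1.0, n_epithelium = 1.41,
                                   n_stroma = 1.376, n_aqueous = 1.336) {
  ns <- c(air = n_air, epithelium = n_epithelium, stroma = n_stroma,
          aqueous = n_aqueous)
  if (!all(is.finite(ns)) || any(ns <= 0))
    stop("refractive indices must be positive and finite")
  structure(as.list(ns), class = "index_chain")
}

index_step <- function(chain, surface) {
  switch(surface,
         epithelium = c(chain$air, chain$epithelium),
         stroma = c(chain$epithelium, chain$stroma),
         endothelium = c(chain$stroma, chain$aqueous),
         stop("unknown surface '", surface, "'"))
}

#' Paraxial power of a single refracting surface
#'
#' `F = (n_after - n_before) / R` with `R` converted from mm to metres.
#'
#' @param R radius of curvature in mm (> 0).
#' @param n_before,n_after refractive indices before/after the surface.
#' @return Power in dioptres (vectorised over `R`).
#' @export
surface_power <- function(R, n_before, n_after) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("'R' must be positive and finite")
  (n_after - n_before) / (R / 1000)
}

#' Decompose principal powers into a power vector
#'
#' `SEQ = (F_flat + F_steep) / 2`, and the full cylinder
#' `C = F_steep - F_flat` is projected onto the 0/90 and 45/135 degree
#' meridians: `C0 = C cos(2 A1)`, `C45 = C sin(2 A1)`.  Note the full
#' cylinder magnitude is used (not the half-magnitude J0/J45 convention).
#'
#' @param F_flat,F_steep powers of the flat/steep meridian in dioptres.
#' @param A1 axis of the flat meridian in degrees.
#' @return Named numeric vector `c(SEQ, C0, C45)` in dioptres.
#' @export
to_power_vector <- function(F_flat, F_steep, A1) {
  stopifnot(is.finite(F_flat), is.finite(F_steep), is.finite(A1))
  C <- F_steep - F_flat
  c(SEQ = (F_flat + F_steep) / 2,
    C0 = C * cos(2 * A1 * pi / 180),
    C45 = C * sin(2 * A1 * pi / 180))
}

#' Recover principal powers from a power vector
#'
#' Inverse of [to_power_vector()] on its canonical domain (`C >= 0`):
#' `C = sqrt(C0^2 + C45^2)`, `A1 = atan2(C45, C0) / 2` wrapped to
#' \[0, 180), `F_flat = SEQ - C/2`, `F_steep = SEQ + C/2`.  A zero cylinder
#' returns `A1 = 0` by convention.
#'
#' @param pv named numeric vector (or list) with `SEQ`, `C0`, `C45`.
#' @return Named numeric vector `c(F_flat, F_steep, A1)`.
#' @export
from_power_vector <- function(pv) {
  pv <- unlist(pv)[c("SEQ", "C0", "C45")]
  stopifnot(all(is.finite(pv)))
  C <- sqrt(pv[["C0"]]^2 + pv[["C45"]]^2)
  A1 <- if (C == 0) 0 else wrap_axis(atan2(pv[["C45"]], pv[["C0"]]) * 90 / pi)
  c(F_flat = pv[["SEQ"]] - C / 2, F_steep = pv[["SEQ"]] + C / 2, A1 = A1)
}

## Map a power vector back to apical radii and the geometric flat axis for
## a surface with index step dn.  The flat meridian (larger radius R1) has
## power dn/R1: for dn > 0 that is the lower of the two principal powers,
## for dn < 0 (stroma interface, endothelium) the higher one, in which case
## the geometric flat axis sits 90 degrees from the lower-power meridian.
radii_from_power_vector <- function(pv, dn) {
  if (dn == 0) stop("cannot recover radii for a zero index step")
  fp <- from_power_vector(pv)
  if (dn > 0) {
    R1 <- 1000 * dn / fp[["F_flat"]]
    R2 <- 1000 * dn / fp[["F_steep"]]
    A1 <- fp[["A1"]]
  } else {
    R1 <- 1000 * dn / fp[["F_steep"]]
    R2 <- 1000 * dn / fp[["F_flat"]]
    A1 <- wrap_axis(fp[["A1"]] + 90)
  }
  if (R1 <= 0 || R2 <= 0) stop("power vector inconsistent with index step sign")
  c(R1 = R1, R2 = R2, A1 = A1)
}

#' Power vector of one fitted surface
#'
#' @param fit a [fit_surface()] result.
#' @param n_before,n_after bounding refractive indices.
#' @return Named numeric vector `c(SEQ, C0, C45)` in dioptres.
#' @export
fit_power_vector <- function(fit, n_before, n_after) {
  stopifnot(inherits(fit, "corneal_fit"))
  p <- fit$params
  to_power_vector(surface_power(p$R1, n_before, n_after),
                  surface_power(p$R2, n_before, n_after), p$A1)
}

#' Power vectors of all three surfaces of a measurement
#'
#' @param fits result of [fit_measurement()] (canonical fits for
#'   epithelium, stroma, endothelium).
#' @param chain a [refractive_index_chain()].
#' @return Named list of power vectors per surface.
#' @export
measurement_powers <- function(fits, chain = refractive_index_chain()) {
  stopifnot(all(MAP_SURFACES %in% names(fits)))
  out <- lapply(MAP_SURFACES, function(s) {
    ns <- index_step(chain, s)
    fit_power_vector(fits[[s]], ns[1L], ns[2L])
  })
  names(out) <- MAP_SURFACES
  out
}

#' Layer thicknesses from the apex positions of three surface fits
#'
#' Apical layer thicknesses are differences of the fitted apex Z positions:
#' epithelium = Z0(stroma) - Z0(epithelium), stroma = Z0(endothelium) -
#' Z0(stroma), total = Z0(endothelium) - Z0(epithelium).
#'
#' @param epi,stroma,endo [fit_surface()] results sharing model and ROI.
#' @return A list with `epithelium`, `stroma` and `total` thickness in mm
#'   (class `layer_thicknesses`); `total == epithelium + stroma` exactly.
#' @export
layer_thicknesses <- function(epi, stroma, endo) {
  fits <- list(epi, stroma, endo)
  stopifnot(all(vapply(fits, inherits, logical(1), "corneal_fit")))
  models <- vapply(fits, function(f) f$params$model, character(1))
  if (length(unique(models)) != 1L)
    stop("consistency error: fits use different models (",
         paste(models, collapse = ", "), ")")
  rois <- vapply(fits, function(f) f$roi_diameter %||% NA_real_, numeric(1))
  if (!all(is.na(rois)) && length(unique(rois[!is.na(rois)])) != 1L)
    stop("consistency error: fits use different ROI diameters")
  t_epi <- stroma$params$Z0 - epi$params$Z0
  t_str <- endo$params$Z0 - stroma$params$Z0
  structure(list(epithelium = t_epi, stroma = t_str, total = t_epi + t_str),
            class = "layer_thicknesses")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
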