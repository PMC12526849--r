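# Fixtures are built in code: model surfaces rendered on the standard
# 256 x 31 polar grid, with optional height noise and sentinel handling
# for cells outside a steep surface's domain of definition.

render_map <- function(params, grid = polar_grid(), sigma = 0) {
  th <- grid$meridian_angles * pi / 180
  xg <- outer(cos(th), grid$ring_radii)
  yg <- outer(sin(th), grid$ring_radii)
  aa <- params$A1 * pi / 180
  du <- cos(aa) * (xg - params$X0) + sin(aa) * (yg - params$Y0)
  dv <- -sin(aa) * (xg - params$X0) + cos(aa) * (yg - params$Y0)
  rad <- 1 - (1 + params$Q1) * (du / params$R1)^2 -
    (1 + params$Q2) * (dv / params$R2)^2
  h <- matrix(MS39_SENTINEL, grid$n_meridians, length(grid$ring_radii))
  ok <- rad > 1e-9
  h[ok] <- sag(params, xg[ok], yg[ok])
  if (sigma > 0) {
    noise <- matrix(rnorm(length(h), 0, sigma), nrow(h))
    noise[, 1L] <- noise[1L, 1L]
    h[ok] <- h[ok] + noise[ok]
  }
  h[, 1L] <- h[1L, 1L]
  polar_height_map(h, grid)
}

render_cloud <- function(params, roi = 6, sigma = 0, grid = polar_grid()) {
  to_cartesian_points(render_map(params, grid, sigma), roi)
}

make_record <- function(epi, stroma, endo, patient_id = "P001",
                        laterality = "OD",
                        exam_datetime = "2024-03-01T09:00:00", sigma = 0) {
  measurement_record(
    patient_id, "1957-06-01", "female", laterality, exam_datetime,
    list(epithelium = render_map(epi, sigma = sigma),
         stroma = render_map(stroma, sigma = sigma),
         endothelium = render_map(endo, sigma = sigma)))
}

# a plausible three-surface eye used by several suites
demo_eye_params <- function(a1 = 20) {
  list(
    epi = surface_params("Biconic", R1 = 7.80, R2 = 7.55, A1 = a1,
                         Q1 = -0.15, Q2 = -0.22, X0 = 0.05, Y0 = -0.03,
                         Z0 = 0.01),
    stroma = surface_params("Biconic", R1 = 7.70, R2 = 7.46, A1 = a1,
                            Q1 = -0.18, Q2 = -0.30, X0 = 0.05, Y0 = -0.03,
                            Z0 = 0.0647),
    endo = surface_params("Biconic", R1 = 6.55, R2 = 6.23, A1 = a1,
                          Q1 = -0.28, Q2 = -0.33, X0 = 0.05, Y0 = -0.03,
                          Z0 = 0.5507))
}

# triple of repeat entries from parameter lists + an index step
make_triple <- function(params_list, dn, eye = "E1", surface = "epithelium") {
  reps <- lapply(params_list, function(p) {
    list(params = p,
         pv = to_power_vector(surface_power(p$R1, 1, 1 + dn),
                              surface_power(p$R2, 1, 1 + dn), p$A1))
  })
  repeat_triple(reps, eye = eye, surface = surface, index_step = dn)
}
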