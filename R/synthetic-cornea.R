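## Synthetic three-surface cornea cohorts with known ground truth.

#' Population specification for synthetic corneal cohorts
#'
#' Defines the statistical structure of a generated cohort: per-surface
#' population means/SDs of the biconic truth parameters (apical radii in
#' mm, asphericities), a wrapped-normal flat-axis distribution shared by
#' the three surfaces of an eye, layer thickness distributions, per-repeat
#' within-subject jitter SDs, pointwise height noise, and the
#' invalid-point dropout rate.  Defaults describe a cataract-age adult
#' population: epithelium R1 ~ 7.79 +/- 0.35 mm, endothelium R1 ~ 6.54 mm,
#' epithelial thickness 54.7 +/- 4.4 um, stromal thickness 485.6 +/-
#' 38.8 um, and within-subject radius repeat SDs of roughly 11 um
#' (epithelium) to 30 um (endothelium).
#'
#' @param ... named overrides of the default fields (nested lists are
#'   merged with [utils::modifyList()]).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(...) {
  spec <- list(
    surfaces = list(
      epithelium = list(
        R1_mean = 7.79, R1_sd = 0.35, R2_mean = 7.56, R2_sd = 0.34,
        Q1_mean = -0.16, Q1_sd = 0.20, Q2_mean = -0.21, Q2_sd = 0.21,
        repeat_sd = list(R1 = 0.0108, R2 = 0.0106, Q1 = 0.0281,
                         Q2 = 0.0312, A1 = 2, Z0 = 0.0005)),
      stroma = list(
        R1_mean = 7.72, R1_sd = 0.40, R2_mean = 7.45, R2_sd = 0.38,
        Q1_mean = -0.16, Q1_sd = 0.24, Q2_mean = -0.33, Q2_sd = 0.26,
        repeat_sd = list(R1 = 0.0244, R2 = 0.0250, Q1 = 0.0507,
                         Q2 = 0.0493, A1 = 2, Z0 = 0.0005)),
      endothelium = list(
        R1_mean = 6.54, R1_sd = 0.33, R2_mean = 6.21, R2_sd = 0.34,
        Q1_mean = -0.30, Q1_sd = 0.26, Q2_mean = -0.34, Q2_sd = 0.24,
        repeat_sd = list(R1 = 0.0302, R2 = 0.0226, Q1 = 0.0378,
                         Q2 = 0.0348, A1 = 2, Z0 = 0.0005))),
    r12_correlation = 0.9,
    q12_correlation = 0.7,
    surface_correlation = 0.8,
    axis_mean = 0, axis_sd = 25,
    apex_xy_sd = 0.15, apex_z_sd = 0.02,
    align_xy_sd = 0.02,
    thickness = list(epithelium_mean = 0.0547, epithelium_sd = 0.0044,
                     stroma_mean = 0.4856, stroma_sd = 0.0388),
    noise_sd_um = 2, dropout = 0.02, mirror_os = TRUE,
    sex_female_prob = 0.57, age_mean = 67.2, age_sd = 9.7,
    grid = polar_grid())
  spec <- modifyList(spec, list(...))
  for (s in MAP_SURFACES) {
    su <- spec$surfaces[[s]]
    if (su$R1_mean <= 0 || su$R2_mean <= 0)
      stop("population radius means must be positive")
    sds <- c(su$R1_sd, su$R2_sd, su$Q1_sd, su$Q2_sd,
             unlist(su$repeat_sd))
    if (any(sds < 0)) stop("all SDs must be >= 0")
  }
  if (spec$dropout < 0 || spec$dropout > 0.5)
    stop("'dropout' must be in [0, 0.5]")
  for (f in c("r12_correlation", "q12_correlation", "surface_correlation"))
    if (abs(spec[[f]]) > 1) stop("'", f, "' must be in [-1, 1]")
  structure(spec, class = "population_spec")
}

## Correlated standard-normal pair (shared within-eye structure).
z2_cor <- function(rho) {
  z <- rnorm(2L)
  c(z[1L], rho * z[1L] + sqrt(1 - rho^2) * z[2L])
}

#' Draw eye-level ground-truth parameters
#'
#' Samples one eye from the population.  The three corneal surfaces of an
#' eye are nearly parallel, so their radii and asphericities are drawn
#' from a shared latent structure: eye-level standard-normal factors for
#' the flat/steep meridians (correlated by `r12_correlation` for radii and
#' `q12_correlation` for asphericities) are mixed with per-surface
#' residuals with loading `surface_correlation`, preserving every
#' surface's marginal mean/SD while correlating the layers.  Radii are
#' sorted so `R1 >= R2` holds by construction.  One wrapped-normal flat
#' axis is shared by the three surfaces (mirrored `A1 -> 180 - A1` for OS
#' eyes when `mirror_os` is set), as is one lateral apex position; layer
#' thickness draws space the apex Z positions.  Draws are taken from the
#' current RNG stream.
#'
#' @param spec a [population_spec()].
#' @param laterality `"OD"` or `"OS"`.
#' @param eye_id identifying label.
#' @return A list of class `eye_truth` with the shared geometry and a
#'   per-surface list of true biconic parameters ([surface_params()]).
#' @export
sample_eye <- function(spec, laterality = c("OD", "OS"), eye_id = "eye") {
  stopifnot(inherits(spec, "population_spec"))
  laterality <- match.arg(laterality)
  a1 <- wrap_axis(rnorm(1L, spec$axis_mean, spec$axis_sd))
  if (laterality == "OS" && isTRUE(spec$mirror_os))
    a1 <- wrap_axis(180 - a1)
  x0 <- rnorm(1L, 0, spec$apex_xy_sd)
  y0 <- rnorm(1L, 0, spec$apex_xy_sd)
  z0 <- rnorm(1L, 0, spec$apex_z_sd)
  t_epi <- rnorm(1L, spec$thickness$epithelium_mean, spec$thickness$epithelium_sd)
  t_str <- rnorm(1L, spec$thickness$stroma_mean, spec$thickness$stroma_sd)
  z0s <- c(epithelium = z0, stroma = z0 + t_epi, endothelium = z0 + t_epi + t_str)

  lam <- spec$surface_correlation
  res <- sqrt(1 - lam^2)
  u_r <- z2_cor(spec$r12_correlation)   # eye-level meridian factors, radii
  u_q <- z2_cor(spec$q12_correlation)   # eye-level factors, asphericities
  surfaces <- lapply(MAP_SURFACES, function(s) {
    su <- spec$surfaces[[s]]
    e_r <- z2_cor(spec$r12_correlation)
    e_q <- z2_cor(spec$q12_correlation)
    z_r <- lam * u_r + res * e_r
    z_q <- lam * u_q + res * e_q
    r <- c(su$R1_mean + su$R1_sd * z_r[1L], su$R2_mean + su$R2_sd * z_r[2L])
    if (r[1L] < r[2L]) r <- rev(r)
    surface_params("Biconic",
                   R1 = r[1L], R2 = r[2L], A1 = a1,
                   Q1 = su$Q1_mean + su$Q1_sd * z_q[1L],
                   Q2 = su$Q2_mean + su$Q2_sd * z_q[2L],
                   X0 = x0, Y0 = y0, Z0 = z0s[[s]])
  })
  names(surfaces) <- MAP_SURFACES
  structure(list(eye_id = eye_id, laterality = laterality, A1 = a1,
                 thickness = c(epithelium = t_epi, stroma = t_str),
                 surfaces = surfaces),
            class = "eye_truth")
}

jitter_params <- function(p, rs, align_xy) {
  q <- p
  q$R1 <- p$R1 + rnorm(1L, 0, rs$R1)
  q$R2 <- p$R2 + rnorm(1L, 0, rs$R2)
  q$Q1 <- p$Q1 + rnorm(1L, 0, rs$Q1)
  q$Q2 <- p$Q2 + rnorm(1L, 0, rs$Q2)
  q$A1 <- p$A1 + rnorm(1L, 0, rs$A1)
  q$X0 <- p$X0 + align_xy[1L]
  q$Y0 <- p$Y0 + align_xy[2L]
  q$Z0 <- p$Z0 + rnorm(1L, 0, rs$Z0)
  canonicalize(do.call(surface_params, q))
}

#' Render one repeat measurement of an eye
#'
#' Applies within-subject jitter to the eye-level truth (radius,
#' asphericity, axis and apex-Z jitter per surface, plus one common
#' lateral alignment shift per repeat), evaluates the jittered biconic
#' surfaces on the full polar grid, adds i.i.d. Gaussian height noise, and
#' marks a Bernoulli subset of cells invalid.  The radius-0 ring is a
#' single physical point: it receives one noise draw and one dropout draw,
#' and is never dropped on all three surfaces simultaneously.
#'
#' A steep surface (e.g. the endothelium, apical radius near 6.2 mm) can
#' be undefined at the outermost grid rings; such out-of-domain cells are
#' coded with the sentinel, exactly as an instrument marks unreliable
#' peripheral points.  If the surface is undefined anywhere in the central
#' zone (lateral radius <= 3.2 mm, covering both fitting ROIs) the spec is
#' considered pathological and a generation error naming the surface is
#' raised.
#'
#' @param truth an [sample_eye()] result.
#' @param repeat_index 1, 2 or 3.
#' @param spec the [population_spec()].
#' @param patient_id,dob,sex,exam_datetime metadata for the record.
#' @return A list with `record` (the [measurement_record()]) and
#'   `params` (the per-surface repeat-level true parameters).
#' @export
render_measurement <- function(truth, repeat_index, spec,
                               patient_id = "P000", dob = "1957-01-01",
                               sex = "female",
                               exam_datetime = "2024-03-01T09:00:00") {
  stopifnot(inherits(truth, "eye_truth"), inherits(spec, "population_spec"))
  g <- spec$grid
  nm <- g$n_meridians
  nr <- length(g$ring_radii)
  th <- g$meridian_angles * pi / 180
  xg <- outer(cos(th), g$ring_radii)
  yg <- outer(sin(th), g$ring_radii)
  sigma <- spec$noise_sd_um / 1000

  align_xy <- rnorm(2L, 0, spec$align_xy_sd)
  rep_params <- list()
  maps <- list()
  centre_drop <- logical(3L)
  drop_masks <- list()
  rg <- sqrt(xg^2 + yg^2)
  for (s in MAP_SURFACES) {
    p <- jitter_params(truth$surfaces[[s]], spec$surfaces[[s]]$repeat_sd,
                       align_xy)
    rep_params[[s]] <- p
    aa <- p$A1 * pi / 180
    du <- cos(aa) * (xg - p$X0) + sin(aa) * (yg - p$Y0)
    dv <- -sin(aa) * (xg - p$X0) + cos(aa) * (yg - p$Y0)
    rad <- 1 - (1 + p$Q1) * (du / p$R1)^2 - (1 + p$Q2) * (dv / p$R2)^2
    domain <- rad > 1e-9
    if (any(!domain & rg <= 3.2))
      stop("generation error for surface '", s,
           "': sag undefined inside the central zone", call. = FALSE)
    h <- matrix(NA_real_, nm, nr)
    h[domain] <- sag_kernel(p, xg[domain], yg[domain], clip = TRUE)
    if (sigma > 0) {
      noise <- matrix(rnorm(nm * nr, 0, sigma), nm, nr)
      noise[, 1L] <- noise[1L, 1L]  # one physical centre point
      h <- h + noise
    }
    h[, 1L] <- h[1L, 1L]
    mask <- !domain
    if (spec$dropout > 0) {
      mask[, -1L] <- mask[, -1L] | rbinom(nm * (nr - 1L), 1L, spec$dropout) == 1L
      mask[, 1L] <- mask[, 1L] | rbinom(1L, 1L, spec$dropout) == 1L
    }
    centre_drop[match(s, MAP_SURFACES)] <- mask[1L, 1L]
    drop_masks[[s]] <- mask
    maps[[s]] <- h
  }
  if (all(centre_drop)) drop_masks$epithelium[, 1L] <- FALSE
  for (s in MAP_SURFACES) {
    h <- maps[[s]]
    h[drop_masks[[s]]] <- MS39_SENTINEL
    maps[[s]] <- polar_height_map(h, g)
  }
  record <- measurement_record(patient_id, dob, sex, truth$laterality,
                               exam_datetime, maps)
  list(record = record, params = rep_params, repeat_index = repeat_index)
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces `6 * n_patients` measurement records: two eyes (OD, OS) per
#' patient, three repeat measurements per eye, emulating the structure of
#' a bilateral repeatability study.  Deterministic under `seed`.  When
#' `dir` is given, every record is written as a map CSV via
#' [write_map_csv()] and the truth registry as `truth.json`.
#'
#' @param spec a [population_spec()].
#' @param n_patients number of patients (>= 1).
#' @param seed integer RNG seed.
#' @param dir optional output directory for CSV files + truth registry.
#' @return A list of class `synthetic_cohort`: `records` (list of
#'   [measurement_record()]s), `truth` (per-eye truth including per-repeat
#'   parameters), `manifest` (data frame mapping records to eyes/repeats)
#'   and `files` (paths, when written).
#' @export
generate_cohort <- function(spec = population_spec(), n_patients, seed,
                            dir = NULL) {
  stopifnot(inherits(spec, "population_spec"), n_patients >= 1)
  set.seed(as.integer(seed))
  records <- list()
  truth <- list()
  manifest <- NULL
  files <- character(0)
  base_date <- as.Date("2024-03-01")
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d", i)
    sex <- if (runif(1L) < spec$sex_female_prob) "female" else "male"
    age <- rnorm(1L, spec$age_mean, spec$age_sd)
    exam_date <- base_date + (i - 1L) %% 365L
    dob <- format(exam_date - round(age * 365.25), "%Y-%m-%d")
    for (lat in c("OD", "OS")) {
      eye_id <- paste0(pid, "_", lat)
      eye <- sample_eye(spec, lat, eye_id = eye_id)
      reps <- list()
      for (m in 1:3) {
        exam_dt <- sprintf("%sT%02d:%02d:00", format(exam_date, "%Y-%m-%d"),
                           9L + (m - 1L), sample.int(59L, 1L))
        r <- render_measurement(eye, m, spec, patient_id = pid, dob = dob,
                                sex = sex, exam_datetime = exam_dt)
        key <- sprintf("%s_m%d", eye_id, m)
        records[[key]] <- r$record
        reps[[m]] <- r$params
        manifest <- rbind(manifest, data.frame(
          key = key, patient_id = pid, eye_id = eye_id, laterality = lat,
          repeat_index = m, stringsAsFactors = FALSE))
      }
      eye$repeats <- reps
      truth[[eye_id]] <- eye
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(names(records), function(key) {
      path <- file.path(dir, paste0(key, ".csv"))
      write_map_csv(records[[key]], path)
      path
    }, character(1))
    jsonlite::write_json(
      lapply(truth, truth_to_json),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(records = records, truth = truth, manifest = manifest,
                 files = files, spec = spec, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

truth_to_json <- function(eye) {
  list(eye_id = eye$eye_id, laterality = eye$laterality, A1 = eye$A1,
       thickness = as.list(eye$thickness),
       surfaces = lapply(eye$surfaces, unclass),
       repeats = lapply(eye$repeats, function(r) lapply(r, unclass)))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d records (%d eyes x 3 repeats), seed %d\n",
    length(x$records), length(x$truth), x$seed))
  invisible(x)
}
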