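## End-to-end study driver: ingest or generate a cohort, fit, aggregate.

#' Configuration of a full repeatability study
#'
#' @param input_dir directory of map CSV files; `NULL` for synthetic mode.
#' @param spec [population_spec()] used in synthetic mode.
#' @param n_patients number of synthetic patients (synthetic mode).
#' @param seed RNG seed; required in synthetic mode.
#' @param models surface models to fit (default all three).
#' @param rois ROI diameters in mm (default 3 and 6).
#' @param chain a [refractive_index_chain()].
#' @param mirror mirror OS eyes when pooling astigmatism samples.
#' @param radii how per-eye mean radii are derived, see [mean_of_repeats()].
#' @param alpha,coverage normality branch threshold and region coverage.
#' @param out_dir output directory for CSV tables, the JSON report and
#'   figures; `NULL` suppresses all file output.
#' @param write_plots write PNG figures (double-angle plots, SEQ
#'   rainclouds, axis-SD envelope) under `out_dir`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(input_dir = NULL, spec = population_spec(),
                         n_patients = 100L, seed = NULL,
                         models = SURFACE_MODELS, rois = c(3, 6),
                         chain = refractive_index_chain(), mirror = TRUE,
                         radii = "power", alpha = 0.05, coverage = 0.95,
                         out_dir = NULL, write_plots = !is.null(out_dir)) {
  models <- match.arg(models, SURFACE_MODELS, several.ok = TRUE)
  if (!length(rois) || any(rois <= 0 | rois > 12))
    stop("need at least one ROI diameter in (0, 12] mm")
  if (is.null(input_dir) && is.null(seed))
    stop("synthetic mode requires a seed")
  structure(list(input_dir = input_dir, spec = spec,
                 n_patients = as.integer(n_patients), seed = seed,
                 models = models, rois = rois, chain = chain,
                 mirror = isTRUE(mirror), radii = radii, alpha = alpha,
                 coverage = coverage, out_dir = out_dir,
                 write_plots = isTRUE(write_plots)),
            class = "study_config")
}

#' Scan a directory of map CSVs and group them into eyes
#'
#' Reads every `*.csv` file, groups readable records by patient and
#' laterality, and accepts eyes with exactly three repeat measurements.
#' Unreadable files and incomplete groups are listed with reasons, never
#' silently dropped.
#'
#' @param dir directory containing map CSV files.
#' @return A list of class `cohort_manifest`: `eyes` (data frame with
#'   `eye_id`, `n_repeats`, `accepted`, `reason`), `files` (per-file
#'   status) and `records` (the parsed records of accepted eyes, ordered
#'   by exam time).
#' @export
validate_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("not a readable directory: ", dir)
  paths <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(paths)) stop("no CSV files found in ", dir)
  parsed <- lapply(paths, function(p)
    tryCatch(read_map_csv(p), error = function(e) conditionMessage(e)))
  ok <- vapply(parsed, inherits, logical(1), "measurement_record")
  files <- data.frame(path = paths, ok = ok,
                      error = ifelse(ok, "", unlist(lapply(parsed, function(x)
                        if (is.character(x)) x else ""))),
                      stringsAsFactors = FALSE)
  recs <- parsed[ok]
  eye_of <- vapply(recs, function(r) paste0(r$patient_id, "_", r$laterality),
                   character(1))
  groups <- split(recs, eye_of)
  eyes <- data.frame(
    eye_id = names(groups),
    n_repeats = vapply(groups, length, integer(1)),
    stringsAsFactors = FALSE)
  eyes$accepted <- eyes$n_repeats == 3L
  eyes$reason <- ifelse(eyes$accepted, "",
                        paste0("expected 3 repeats, found ", eyes$n_repeats))
  accepted <- lapply(groups[eyes$accepted[match(names(groups), eyes$eye_id)]],
                     function(g) g[order(vapply(g, function(r) r$exam_datetime,
                                                character(1)))])
  structure(list(eyes = eyes, files = files, records = accepted),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("Cohort manifest: %d files (%d unreadable), %d eyes (%d accepted)\n",
              nrow(x$files), sum(!x$files$ok), nrow(x$eyes),
              sum(x$eyes$accepted)))
  invisible(x)
}

table_params <- function(model) {
  switch(model, SphCyl = c("R1", "R2"), CylConoid = c("R1", "R2", "Q1"),
         Biconic = c("R1", "R2", "Q1", "Q2"))
}

descriptive_block <- function(df, params, keys) {
  out <- NULL
  for (p in params) {
    row <- cbind(keys, parameter = p, descriptive_table(df[[p]]))
    out <- rbind(out, row)
  }
  out
}

#' Run the full three-surface repeatability study
#'
#' For every eye (three repeat measurements), ROI and surface model, fits
#' the three corneal surfaces, converts to power vectors and layer
#' thicknesses, aggregates means of repeats and deviations from the mean,
#' and produces: descriptive tables of per-eye means and of deviations
#' (radii/asphericities), thickness tables, per-surface SEQ summaries and
#' double-angle astigmatism summaries (normality-branched location +
#' 95% region), and the axis-SD versus radius-difference envelope merged
#' over models.  All numbers are returned (and written as JSON when
#' `out_dir` is set); CSV tables and figures are derived views.
#'
#' @param config a [study_config()].
#' @return An object of class `study_report`; see Details.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(config$input_dir)) {
    cohort <- generate_cohort(config$spec, config$n_patients, config$seed)
    man <- cohort$manifest
    eyes <- split(seq_len(nrow(man)), man$eye_id)
    records <- lapply(eyes, function(i)
      cohort$records[man$key[i][order(man$repeat_index[i])]])
    excluded <- data.frame(eye_id = character(0), reason = character(0))
  } else {
    manifest <- validate_cohort(config$input_dir)
    records <- manifest$records
    excluded <- manifest$eyes[!manifest$eyes$accepted,
                              c("eye_id", "reason"), drop = FALSE]
  }
  if (!length(records)) stop("no valid eyes with 3 repeat measurements")

  means <- devs <- tmeans <- tdevs <- NULL
  fit_failures <- NULL
  n_fits <- 0L
  for (roi in config$rois) {
    for (model in config$models) {
      for (eye_id in names(records)) {
        recs <- records[[eye_id]]
        lat <- recs[[1L]]$laterality
        fms <- tryCatch(
          lapply(recs, fit_measurement, roi_diameter = roi, model = model),
          error = function(e) conditionMessage(e))
        if (is.character(fms)) {
          fit_failures <- rbind(fit_failures, data.frame(
            roi = roi, model = model, eye_id = eye_id, error = fms,
            stringsAsFactors = FALSE))
          next
        }
        n_fits <- n_fits + 9L
        pvs <- lapply(fms, measurement_powers, chain = config$chain)
        for (s in MAP_SURFACES) {
          triple <- repeat_triple(
            lapply(1:3, function(m)
              list(params = fms[[m]][[s]]$params, pv = pvs[[m]][[s]])),
            eye = eye_id, surface = s,
            index_step = diff(index_step(config$chain, s)))
          mr <- mean_of_repeats(triple, radii = config$radii)
          axes <- vapply(triple$repeats, function(r) r$params$A1, numeric(1))
          ident <- vapply(1:3, function(m) fms[[m]][[s]]$axis_identifiable,
                          logical(1))
          asd <- if (all(ident)) as.numeric(axis_sd(axes)) else NA_real_
          means <- rbind(means, data.frame(
            roi = roi, model = model, surface = s, eye_id = eye_id,
            laterality = lat, R1 = mr$R1, R2 = mr$R2, A1 = mr$A1,
            Q1 = mr$Q1, Q2 = mr$Q2, SEQ = mr$SEQ, C0 = mr$C0,
            C45 = mr$C45, dR = mr$R1 - mr$R2, axis_sd = asd,
            stringsAsFactors = FALSE))
          dv <- deviations_from_mean(triple)
          devs <- rbind(devs, cbind(
            data.frame(roi = roi, model = model, surface = s,
                       eye_id = eye_id, repeat_index = 1:3,
                       stringsAsFactors = FALSE),
            dv[, c("R1", "R2", "Q1", "Q2", "SEQ", "C0", "C45")]))
        }
        th <- vapply(1:3, function(m) {
          lt <- layer_thicknesses(fms[[m]]$epithelium, fms[[m]]$stroma,
                                  fms[[m]]$endothelium)
          c(lt$epithelium, lt$stroma, lt$total)
        }, numeric(3))
        tm <- rowMeans(th)
        tmeans <- rbind(tmeans, data.frame(
          roi = roi, model = model, eye_id = eye_id,
          epithelium = tm[1L], stroma = tm[2L], total = tm[3L],
          stringsAsFactors = FALSE))
        tdevs <- rbind(tdevs, data.frame(
          roi = roi, model = model, eye_id = eye_id, repeat_index = 1:3,
          epithelium = th[1L, ] - tm[1L], stroma = th[2L, ] - tm[2L],
          total = th[3L, ] - tm[3L], stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(means)) stop("no valid eyes could be fitted")

  ## Descriptive tables over eyes (means) and measurements (deviations)
  table_means <- table_devs <- NULL
  astig <- list()
  seq_summary <- NULL
  for (roi in config$rois) for (model in config$models) {
    params <- table_params(model)
    for (s in MAP_SURFACES) {
      mm <- means[means$roi == roi & means$model == model & means$surface == s, ]
      dd <- devs[devs$roi == roi & devs$model == model & devs$surface == s, ]
      if (nrow(mm) < 2L) next  # descriptive rows need at least two eyes
      keys <- data.frame(roi = roi, model = model, surface = s,
                         stringsAsFactors = FALSE)
      table_means <- rbind(table_means, descriptive_block(mm, params, keys))
      table_devs <- rbind(table_devs, descriptive_block(dd, params, keys))
      seq_summary <- rbind(seq_summary,
                           cbind(keys, parameter = "SEQ",
                                 descriptive_table(mm$SEQ)))
      samp <- data.frame(C0 = mm$C0, C45 = mm$C45,
                         laterality = mm$laterality)
      pop <- tryCatch(
        summarize_population(samp, alpha = config$alpha,
                             coverage = config$coverage,
                             mirror = config$mirror),
        error = function(e) NULL)
      if (!is.null(pop))
        astig[[paste(roi, model, s, sep = "_")]] <- list(
          roi = roi, model = model, surface = s, branch = pop$branch,
          hz_p = pop$test$p.value, location = pop$location,
          area = pop$region$area, retained = pop$region$retained,
          region = pop$region)
    }
  }

  ## Thickness tables
  table_thick <- table_thick_dev <- NULL
  for (roi in config$rois) for (model in config$models) {
    tm <- tmeans[tmeans$roi == roi & tmeans$model == model, ]
    td <- tdevs[tdevs$roi == roi & tdevs$model == model, ]
    if (nrow(tm) < 2L) next
    keys <- data.frame(roi = roi, model = model, stringsAsFactors = FALSE)
    layer_cols <- c("epithelium", "stroma", "total")
    table_thick <- rbind(table_thick, descriptive_block(tm, layer_cols, keys))
    table_thick_dev <- rbind(table_thick_dev,
                             descriptive_block(td, layer_cols, keys))
  }

  ## Axis-SD vs dR envelope, merged over the surface models, per ROI/surface
  envelopes <- list()
  for (roi in config$rois) for (s in MAP_SURFACES) {
    mm <- means[means$roi == roi & means$surface == s & is.finite(means$axis_sd), ]
    env <- tryCatch(axis_sd_vs_dR_envelope(mm$axis_sd, mm$dR),
                    error = function(e) NULL)
    if (!is.null(env)) envelopes[[paste(roi, s, sep = "_")]] <- env
  }

  report <- structure(list(
    config = config,
    n_eyes = length(records), n_fits = n_fits,
    excluded = excluded, fit_failures = fit_failures,
    means = means, deviations = devs,
    thickness_means = tmeans, thickness_deviations = tdevs,
    table_means = table_means, table_deviations = table_devs,
    table_thickness = table_thick, table_thickness_deviations = table_thick_dev,
    seq_summary = seq_summary, astig = astig, envelopes = envelopes
  ), class = "study_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "Study report: %d eyes, %d surface fits (%d eye-level failures), %d excluded eye groups\n",
    x$n_eyes, x$n_fits,
    if (is.null(x$fit_failures)) 0L else nrow(x$fit_failures),
    nrow(x$excluded)))
  cat("  models:", paste(x$config$models, collapse = ", "),
      "| ROIs:", paste(x$config$rois, collapse = ", "), "mm\n")
  invisible(x)
}

report_json <- function(report) {
  astig <- lapply(report$astig, function(a)
    a[c("roi", "model", "surface", "branch", "hz_p", "location", "area",
        "retained")])
  envelopes <- lapply(report$envelopes, function(e)
    list(coefficients = as.list(e$coefficients), bins = e$bins, n = e$n))
  list(n_eyes = report$n_eyes, n_fits = report$n_fits,
       excluded = report$excluded, fit_failures = report$fit_failures,
       table_means = report$table_means,
       table_deviations = report$table_deviations,
       table_thickness = report$table_thickness,
       table_thickness_deviations = report$table_thickness_deviations,
       seq_summary = report$seq_summary,
       astigmatism = astig, envelopes = envelopes,
       per_eye_means = report$means,
       thickness_means = report$thickness_means)
}

#' Write a study report bundle to disk
#'
#' Writes the machine-readable JSON report (the complete record: every
#' number in the tables and plots), the CSV tables, and optionally the
#' figures.
#'
#' @param report a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  tabs <- list(means = report$table_means,
               deviations = report$table_deviations,
               thickness = report$table_thickness,
               thickness_deviations = report$table_thickness_deviations,
               seq_summary = report$seq_summary)
  for (nm in names(tabs))
    if (!is.null(tabs[[nm]]))
      utils::write.csv(tabs[[nm]],
                       file.path(out_dir, paste0("table_", nm, ".csv")),
                       row.names = FALSE)
  if (report$config$write_plots) write_report_figures(report, out_dir)
  invisible(out_dir)
}
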