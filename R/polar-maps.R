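## Polar height-map containers and the CSV map-file dialect.

#' Sentinel value marking invalid map cells
#'
#' Height-map exports code invalid or unreliable data points with the
#' literal value -1000; the sentinel is preserved through read/write
#' round trips and excluded from all geometry.
#'
#' @export
MS39_SENTINEL <- -1000

#' Cylindrical sampling grid of an anterior-segment height map
#'
#' The standard export grid has 256 equally spaced meridians and 31
#' concentric rings from 0.0 to 6.0 mm radius in 0.2 mm steps.  Meridian
#' angle 0 lies along +x in the examiner's view and angles increase
#' counterclockwise; the convention is identical for right and left eyes at
#' the file level (left-eye mirroring is applied only in population
#' statistics, see [mirror_left_eyes()]).
#'
#' @param n_meridians number of equally spaced meridians.
#' @param ring_radii radial distances of the concentric rings in mm;
#'   strictly increasing, starting at 0.
#' @return An object of class `polar_grid` with fields `n_meridians`,
#'   `ring_radii` and `meridian_angles` (degrees).
#' @export
polar_grid <- function(n_meridians = 256L, ring_radii = seq(0, 6, by = 0.2)) {
  n_meridians <- as.integer(n_meridians)
  if (is.na(n_meridians) || n_meridians < 4L)
    stop("'n_meridians' must be an integer >= 4")
  ring_radii <- as.numeric(ring_radii)
  if (length(ring_radii) < 2L || abs(ring_radii[1L]) > 1e-12 ||
      any(diff(ring_radii) <= 0))
    stop("'ring_radii' must be strictly increasing, starting at 0.0")
  ring_radii[1L] <- 0
  structure(list(
    n_meridians = n_meridians,
    ring_radii = ring_radii,
    meridian_angles = seq(0, 360, length.out = n_meridians + 1L)[seq_len(n_meridians)]
  ), class = "polar_grid")
}

grids_identical <- function(a, b) {
  a$n_meridians == b$n_meridians &&
    length(a$ring_radii) == length(b$ring_radii) &&
    all(abs(a$ring_radii - b$ring_radii) < 1e-12)
}

#' One surface's heights on a cylindrical grid
#'
#' @param heights numeric matrix, rows = meridians, columns = rings, in mm.
#'   Positive z points posterior (into the eye).  Invalid cells carry the
#'   sentinel [MS39_SENTINEL].
#' @param grid a [polar_grid()].
#' @return An object of class `polar_height_map`.
#' @details Every cell must either be finite with |z| < 10 mm or exactly the
#'   sentinel.  The ring at radius 0 represents a single physical point, so
#'   all its meridian entries must be equal (or all sentinel).
#' @export
polar_height_map <- function(heights, grid = polar_grid()) {
  if (!inherits(grid, "polar_grid")) stop("'grid' must be a polar_grid")
  heights <- as.matrix(heights)
  nr <- length(grid$ring_radii)
  if (nrow(heights) != grid$n_meridians || ncol(heights) != nr)
    stop(sprintf(
      "shape error: heights must be %d meridians x %d rings, got %d x %d",
      grid$n_meridians, nr, nrow(heights), ncol(heights)))
  sentinel <- heights == MS39_SENTINEL
  ok <- sentinel | (is.finite(heights) & abs(heights) < 10)
  if (!all(ok))
    stop("height cells must be finite with |z| < 10 mm or exactly the sentinel")
  centre <- heights[, 1L]
  if (length(unique(centre)) > 1L)
    stop("the radius-0 ring is a single physical point: all meridian entries must agree")
  structure(list(grid = grid, heights = heights), class = "polar_height_map")
}

MAP_SURFACES <- c("epithelium", "stroma", "endothelium")

#' One tomographer measurement: metadata plus three surface height maps
#'
#' @param patient_id character scalar.
#' @param dob date of birth, `Date` or ISO-8601 string.
#' @param sex `"male"` or `"female"`.
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param exam_datetime examination timestamp, `POSIXct` or ISO-8601 string
#'   (`YYYY-MM-DDTHH:MM:SS`).
#' @param maps named list with elements `epithelium`, `stroma` and
#'   `endothelium`, each a [polar_height_map()] on one shared grid.
#' @return An object of class `measurement_record`.
#' @export
measurement_record <- function(patient_id, dob, sex, laterality,
                               exam_datetime, maps) {
  patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L || is.na(patient_id) || !nzchar(patient_id))
    stop("format error in field 'PatientID': must be a non-empty string")
  dob <- tryCatch(as.Date(dob), error = function(e) NA)
  if (length(dob) != 1L || is.na(dob))
    stop("format error in field 'DOB': not an ISO-8601 date")
  if (!(length(sex) == 1L && sex %in% c("male", "female")))
    stop("format error in field 'Sex': must be 'male' or 'female'")
  if (!(length(laterality) == 1L && laterality %in% c("OD", "OS")))
    stop("format error in field 'Eye': must be 'OD' or 'OS'")
  exam_chr <- format_exam_datetime(exam_datetime)
  if (is.na(exam_chr))
    stop("format error in field 'ExamDateTime': not an ISO-8601 timestamp")
  if (!is.list(maps) || !setequal(names(maps), MAP_SURFACES))
    stop("'maps' must be a named list with surfaces: ",
         paste(MAP_SURFACES, collapse = ", "))
  maps <- maps[MAP_SURFACES]
  for (s in MAP_SURFACES)
    if (!inherits(maps[[s]], "polar_height_map"))
      stop("map '", s, "' is not a polar_height_map")
  g <- maps$epithelium$grid
  for (s in MAP_SURFACES[-1L])
    if (!grids_identical(g, maps[[s]]$grid))
      stop("all three maps must share one grid")
  structure(list(
    patient_id = patient_id, dob = dob, sex = sex, laterality = laterality,
    exam_datetime = exam_chr, maps = maps
  ), class = "measurement_record")
}

format_exam_datetime <- function(x) {
  if (inherits(x, "POSIXt")) return(format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  x <- as.character(x)
  if (length(x) != 1L) return(NA_character_)
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(t)) return(NA_character_)
  format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Patient age in years at examination time
#'
#' @param record a [measurement_record()].
#' @return Age in (fractional) years.
#' @export
patient_age <- function(record) {
  stopifnot(inherits(record, "measurement_record"))
  exam <- as.Date(substr(record$exam_datetime, 1, 10))
  as.numeric(exam - record$dob) / 365.25
}

#' @export
print.measurement_record <- function(x, ...) {
  cat("Measurement record: patient", x$patient_id, x$laterality,
      "at", x$exam_datetime, "\n")
  for (s in MAP_SURFACES) {
    h <- x$maps[[s]]$heights
    cat(sprintf("  %-11s %d x %d cells, %d invalid\n", s,
                nrow(h), ncol(h), sum(h == MS39_SENTINEL)))
  }
  invisible(x)
}

format_height <- function(x) {
  out <- sprintf("%.9f", x)
  out[x == MS39_SENTINEL] <- "-1000"
  out
}

#' Write a measurement to a map CSV file
#'
#' The file dialect is UTF-8 text: five `key;value` metadata lines
#' (`PatientID`, `DOB`, `Sex`, `Eye`, `ExamDateTime`), then for each surface
#' a `#SURFACE;<name>` line followed by one row per meridian of
#' semicolon-separated heights in mm (one column per ring).  Sentinel cells
#' are written as the literal `-1000`.  Heights round-trip to better than
#' 1e-9 mm.
#'
#' @param record a [measurement_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(record, path) {
  stopifnot(inherits(record, "measurement_record"))
  lines <- c(
    paste0("PatientID;", record$patient_id),
    paste0("DOB;", format(record$dob, "%Y-%m-%d")),
    paste0("Sex;", record$sex),
    paste0("Eye;", record$laterality),
    paste0("ExamDateTime;", record$exam_datetime))
  for (s in MAP_SURFACES) {
    h <- record$maps[[s]]$heights
    body <- apply(matrix(format_height(h), nrow = nrow(h)), 1L,
                  paste, collapse = ";")
    lines <- c(lines, paste0("#SURFACE;", s), body)
  }
  ok <- tryCatch({
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error writing '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read a map CSV file
#'
#' Parses the dialect documented in [write_map_csv()] and validates the
#' grid shape (default 256 meridians x 31 rings).  Anything that does not
#' match the dialect is rejected with an error naming the offending field.
#'
#' @param path path to a map CSV file.
#' @param grid the [polar_grid()] the file is expected to be sampled on.
#' @return A [measurement_record()]; sentinel cells are preserved.
#' @export
read_map_csv <- function(path, grid = polar_grid()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta_keys <- c("PatientID", "DOB", "Sex", "Eye", "ExamDateTime")
  if (length(lines) < 5L)
    stop("format error: file too short for metadata header")
  meta <- list()
  for (i in 1:5) {
    kv <- strsplit(lines[i], ";", fixed = TRUE)[[1L]]
    if (length(kv) != 2L || !(kv[1L] %in% meta_keys))
      stop("format error in metadata line ", i, ": expected 'key;value' with key in ",
           paste(meta_keys, collapse = "/"))
    meta[[kv[1L]]] <- kv[2L]
  }
  missing <- setdiff(meta_keys, names(meta))
  if (length(missing))
    stop("format error: missing metadata field '", missing[1L], "'")

  body <- lines[-(1:5)]
  headers <- grep("^#SURFACE;", body)
  if (length(headers) != 3L)
    stop("format error: expected 3 '#SURFACE;' blocks, found ", length(headers))
  surf_names <- sub("^#SURFACE;", "", body[headers])
  if (!setequal(surf_names, MAP_SURFACES))
    stop("format error: surface blocks must be ",
         paste(MAP_SURFACES, collapse = ", "), "; got ",
         paste(surf_names, collapse = ", "))
  ends <- c(headers[-1L] - 1L, length(body))
  maps <- list()
  nr <- length(grid$ring_radii)
  for (k in seq_along(headers)) {
    rows <- body[(headers[k] + 1L):ends[k]]
    rows <- rows[nzchar(rows)]
    if (length(rows) != grid$n_meridians)
      stop(sprintf("shape error in surface '%s': expected %d meridian rows, got %d",
                   surf_names[k], grid$n_meridians, length(rows)))
    parts <- strsplit(rows, ";", fixed = TRUE)
    ncols <- lengths(parts)
    if (any(ncols != nr))
      stop(sprintf("shape error in surface '%s': expected %d ring columns, got %d",
                   surf_names[k], nr, ncols[which(ncols != nr)[1L]]))
    h <- suppressWarnings(
      matrix(as.numeric(unlist(parts)), nrow = grid$n_meridians,
             ncol = nr, byrow = TRUE))
    if (anyNA(h))
      stop("format error in surface '", surf_names[k],
           "': non-numeric height value")
    maps[[surf_names[k]]] <- polar_height_map(h, grid)
  }
  measurement_record(meta$PatientID, meta$DOB, meta$Sex, meta$Eye,
                     meta$ExamDateTime, maps)
}

#' Unpack a polar height map to a Cartesian point cloud
#'
#' Converts valid cells inside the region of interest to (x, y, z) points
#' with `x = r cos(theta)`, `y = r sin(theta)`.  The radius-0 ring is a
#' single physical point and contributes exactly one point (none if it is
#' sentinel), so the apex is not weighted once per meridian in the fit.
#' ROI inclusion is the closed condition `r <= roi_diameter / 2`.
#'
#' @param map a [polar_height_map()].
#' @param roi_diameter diameter of the circular region of interest in mm,
#'   in (0, 12].
#' @return A data frame with columns `x`, `y`, `z` (mm) and attributes
#'   `roi_diameter` and `surface` (if tagged on the map).
#' @export
to_cartesian_points <- function(map, roi_diameter) {
  stopifnot(inherits(map, "polar_height_map"))
  if (!is.numeric(roi_diameter) || length(roi_diameter) != 1L ||
      roi_diameter <= 0 || roi_diameter > 12)
    stop("'roi_diameter' must be in (0, 12] mm")
  g <- map$grid
  h <- map$heights
  keep_ring <- g$ring_radii <= roi_diameter / 2 + 1e-9
  th <- g$meridian_angles * pi / 180

  xs <- ys <- zs <- numeric(0)
  # centre point once
  if (keep_ring[1L] && h[1L, 1L] != MS39_SENTINEL) {
    xs <- 0; ys <- 0; zs <- h[1L, 1L]
  }
  rings <- which(keep_ring)[-1L]
  if (length(rings)) {
    r <- rep(g$ring_radii[rings], each = g$n_meridians)
    ang <- rep(th, times = length(rings))
    z <- as.vector(h[, rings, drop = FALSE])
    valid <- z != MS39_SENTINEL
    xs <- c(xs, (r * cos(ang))[valid])
    ys <- c(ys, (r * sin(ang))[valid])
    zs <- c(zs, z[valid])
  }
  if (!length(zs))
    stop("empty cloud: all cells inside the ", roi_diameter, " mm ROI are invalid")
  out <- data.frame(x = xs, y = ys, z = zs)
  attr(out, "roi_diameter") <- roi_diameter
  attr(out, "surface") <- attr(map, "surface")
  out
}
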