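test_that("map CSV round trip is lossless for heights, metadata and sentinels", {
  set.seed(41)
  p <- demo_eye_params()
  rec <- make_record(p$epi, p$stroma, p$endo, sigma = 0.002)
  # plant some sentinels
  h <- rec$maps$stroma$heights
  h[10, 5] <- MS39_SENTINEL
  h[, 12] <- MS39_SENTINEL
  rec$maps$stroma <- polar_height_map(h, rec$maps$stroma$grid)

  path <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(rec, path)

  txt <- readLines(path)
  expect_length(grep("^#SURFACE;", txt), 3L)
  row10 <- strsplit(txt[grep("^#SURFACE;stroma", txt) + 10L], ";")[[1L]]
  expect_identical(row10[5L], "-1000")

  back <- read_map_csv(path)
  expect_identical(back$patient_id, rec$patient_id)
  expect_identical(back$dob, rec$dob)
  expect_identical(back$sex, rec$sex)
  expect_identical(back$laterality, rec$laterality)
  expect_identical(back$exam_datetime, rec$exam_datetime)
  for (s in c("epithelium", "stroma", "endothelium")) {
    a <- rec$maps[[s]]$heights
    b <- back$maps[[s]]$heights
    expect_identical(b == MS39_SENTINEL, a == MS39_SENTINEL)
    expect_lt(max(abs(b - a)), 1e-9)
  }
})

test_that("malformed files are rejected loudly", {
  p <- demo_eye_params()
  rec <- make_record(p$epi, p$stroma, p$endo)
  path <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(rec, path)
  lines <- readLines(path)

  # drop one ring column from an epithelium row -> shape error with dims
  i <- grep("^#SURFACE;epithelium", lines) + 3L
  bad <- lines
  bad[i] <- sub(";[^;]*$", "", bad[i])
  f1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, f1)
  expect_error(read_map_csv(f1), "shape error.*epithelium.*30", ignore.case = TRUE)

  # drop a whole meridian row
  bad2 <- lines[-i]
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad2, f2)
  expect_error(read_map_csv(f2), "shape error")

  # mangle a metadata key
  bad3 <- lines
  bad3[3] <- "Gender;female"
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad3, f3)
  expect_error(read_map_csv(f3), "format error")

  expect_error(read_map_csv(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("record and map invariants are enforced", {
  g <- polar_grid()
  h <- matrix(0.5, 256, 31)
  expect_s3_class(polar_height_map(h, g), "polar_height_map")
  expect_error(polar_height_map(h[, 1:30], g), "shape error")
  h2 <- h; h2[3, 7] <- 11
  expect_error(polar_height_map(h2, g), "10 mm")
  h3 <- h; h3[5, 1] <- 0.4   # centre ring must be one physical point
  expect_error(polar_height_map(h3, g), "single physical point")
  p <- demo_eye_params()
  expect_error(
    measurement_record("P1", "1950-01-01", "unknown", "OD",
                       "2024-01-01T10:00:00",
                       list(epithelium = render_map(p$epi),
                            stroma = render_map(p$stroma),
                            endothelium = render_map(p$endo))),
    "Sex")
})

test_that("ROI point counts follow the grid geometry and sentinel mask", {
  m <- render_map(surface_params("SphCyl", 7.8, 7.8))
  expect_identical(nrow(to_cartesian_points(m, 3)), 1L + 7L * 256L)   # 1793
  expect_identical(nrow(to_cartesian_points(m, 6)), 1L + 15L * 256L)  # 3841
  # knock out the entire 1.0 mm ring
  h <- m$heights
  h[, which.min(abs(m$grid$ring_radii - 1.0))] <- MS39_SENTINEL
  m2 <- polar_height_map(h, m$grid)
  expect_identical(nrow(to_cartesian_points(m2, 3)), 1793L - 256L)
  # sentinel centre: contributes no point
  h[, 1] <- MS39_SENTINEL
  m3 <- polar_height_map(h, m$grid)
  expect_identical(nrow(to_cartesian_points(m3, 3)), 1792L - 256L)
  # all-invalid ROI
  h[] <- MS39_SENTINEL
  expect_error(to_cartesian_points(polar_height_map(h, m$grid), 3),
               "empty cloud")
  expect_error(to_cartesian_points(m, 0), "roi_diameter")
  expect_false(anyNA(to_cartesian_points(m, 6)))
})

test_that("rotating the map by k meridian steps rotates the point cloud", {
  set.seed(7)
  m <- render_map(surface_params("Biconic", 7.9, 7.5, A1 = 37,
                                 Q1 = -0.2, Q2 = -0.1, X0 = 0.1, Y0 = 0.05),
                  sigma = 0.001)
  cloud <- to_cartesian_points(m, 6)
  for (k in c(1L, 32L, 100L)) {
    # meridian i of the rotated map holds the heights of meridian i - k
    idx <- ((seq_len(256L) - 1L - k) %% 256L) + 1L
    mk <- polar_height_map(m$heights[idx, ], m$grid)
    ck <- to_cartesian_points(mk, 6)
    phi <- k * 2 * pi / 256
    rx <- cos(phi) * cloud$x - sin(phi) * cloud$y
    ry <- sin(phi) * cloud$x + cos(phi) * cloud$y
    ord <- function(x, y, z) order(round(x, 9), round(y, 9), round(z, 9))
    o1 <- ord(rx, ry, cloud$z); o2 <- ord(ck$x, ck$y, ck$z)
    expect_lt(max(abs(rx[o1] - ck$x[o2])), 1e-9)
    expect_lt(max(abs(ry[o1] - ck$y[o2])), 1e-9)
    expect_lt(max(abs(cloud$z[o1] - ck$z[o2])), 1e-12)
  }
})
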