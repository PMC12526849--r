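test_that("cohort generation is deterministic under a seed", {
  spec <- population_spec()
  a <- generate_cohort(spec, n_patients = 1, seed = 99)
  b <- generate_cohort(spec, n_patients = 1, seed = 99)
  expect_identical(length(a$records), 6L)
  expect_identical(length(a$truth), 2L)
  expect_identical(
    jsonlite::toJSON(lapply(a$truth, cornfit:::truth_to_json), digits = NA),
    jsonlite::toJSON(lapply(b$truth, cornfit:::truth_to_json), digits = NA))
  expect_identical(a$records[[1]]$maps$epithelium$heights,
                   b$records[[1]]$maps$epithelium$heights)
  c2 <- generate_cohort(spec, n_patients = 1, seed = 100)
  expect_false(identical(a$records[[1]]$maps$epithelium$heights,
                         c2$records[[1]]$maps$epithelium$heights))
})

test_that("eye-level draws match the population distributions", {
  spec <- population_spec()
  set.seed(61)
  n <- 3000
  r1 <- q1 <- numeric(n)
  sin2a <- cos2a <- numeric(n)
  for (i in seq_len(n)) {
    lat <- if (i %% 2 == 0) "OD" else "OS"
    e <- sample_eye(spec, lat)
    r1[i] <- e$surfaces$epithelium$R1
    q1[i] <- e$surfaces$epithelium$Q1
    sin2a[i] <- sin(2 * e$A1 * pi / 180)
    cos2a[i] <- cos(2 * e$A1 * pi / 180)
  }
  # R1 >= R2 sorting inflates the R1 mean by E[(R2-R1)^+], about 0.004 mm
  se <- spec$surfaces$epithelium$R1_sd / sqrt(n)
  expect_lt(abs(mean(r1) - spec$surfaces$epithelium$R1_mean) - 0.005, 3 * se)
  expect_lt(abs(mean(q1) - spec$surfaces$epithelium$Q1_mean),
            3 * spec$surfaces$epithelium$Q1_sd / sqrt(n))
  # mirrored pooling symmetric about axis 0: mean doubled-angle sine ~ 0
  expect_lt(abs(mean(sin2a)), 3 / sqrt(n) + 0.02)
  expect_gt(mean(cos2a), 0.2)  # concentrated near 0/180 (with-the-rule flat axis)
})

test_that("rendered repeats share eye truth but differ by jitter", {
  spec <- population_spec()
  set.seed(62)
  eye <- sample_eye(spec, "OD")
  m1 <- render_measurement(eye, 1, spec)
  m2 <- render_measurement(eye, 2, spec)
  expect_false(identical(m1$params$epithelium$R1, m2$params$epithelium$R1))
  expect_lt(abs(m1$params$epithelium$R1 - eye$surfaces$epithelium$R1), 0.1)
  expect_false(identical(m1$record$maps$epithelium$heights,
                         m2$record$maps$epithelium$heights))
})

test_that("dropout marks a binomial share of cells invalid", {
  spec <- population_spec(dropout = 0.1)
  set.seed(63)
  eye <- sample_eye(spec, "OD")
  m <- render_measurement(eye, 1, spec)
  h <- m$record$maps$epithelium$heights
  # one centre point + 256 x 30 ring cells; epithelium is defined on the
  # whole grid so sentinels come from dropout alone
  n_cells <- 1 + 256 * 30
  n_sent <- sum(h[, -1] == MS39_SENTINEL) + (h[1, 1] == MS39_SENTINEL)
  expect_lt(abs(n_sent - 0.1 * n_cells), 4 * sqrt(n_cells * 0.1 * 0.9) + 5)
  # the centre is never invalid on all three surfaces at once
  centre_all <- all(vapply(m$record$maps, function(mp)
    mp$heights[1, 1] == MS39_SENTINEL, logical(1)))
  expect_false(centre_all)
})

test_that("a noise-free, jitter-free render is recovered to 1e-4 end to end", {
  spec <- population_spec(
    noise_sd_um = 0, dropout = 0, align_xy_sd = 0,
    surfaces = local({
      s <- population_spec()$surfaces
      for (nm in names(s))
        s[[nm]]$repeat_sd <- list(R1 = 0, R2 = 0, Q1 = 0, Q2 = 0,
                                  A1 = 0, Z0 = 0)
      s
    }))
  set.seed(64)
  eye <- sample_eye(spec, "OD")
  m <- render_measurement(eye, 1, spec)
  fits <- fit_measurement(m$record, 6, "Biconic")
  for (s in c("epithelium", "stroma", "endothelium")) {
    got <- fits[[s]]$params
    want <- eye$surfaces[[s]]
    for (nm in c("R1", "R2", "Q1", "Q2", "X0", "Y0", "Z0"))
      expect_lt(abs(got[[nm]] - want[[nm]]), 1e-4)
    expect_lt(abs(((got$A1 - want$A1 + 90) %% 180) - 90), 1e-3)
  }
  lt <- layer_thicknesses(fits$epithelium, fits$stroma, fits$endothelium)
  expect_lt(abs(lt$epithelium - eye$thickness[["epithelium"]]), 1e-4)
  expect_lt(abs(lt$stroma - eye$thickness[["stroma"]]), 1e-4)
})

test_that("layers are ordered front to back across the fitting zone", {
  # conic truths of adjacent layers may cross in the far periphery (the
  # apex gap is only ~55 um); within the r <= 3 mm zone used by both
  # fitting ROIs the ordering is guaranteed with ~8 SD of slack
  spec <- population_spec()
  zone <- matrix(rep(spec$grid$ring_radii <= 3 + 1e-9, each = 256), 256)
  set.seed(65)
  for (i in 1:6) {
    eye <- sample_eye(spec, "OD")
    m <- render_measurement(eye, 1, spec)
    he <- m$record$maps$epithelium$heights
    hs <- m$record$maps$stroma$heights
    hn <- m$record$maps$endothelium$heights
    v <- he != MS39_SENTINEL & hs != MS39_SENTINEL & zone
    expect_true(all(he[v] < hs[v]))
    v2 <- hs != MS39_SENTINEL & hn != MS39_SENTINEL & zone
    expect_true(all(hs[v2] < hn[v2]))
  }
})

test_that("written cohorts round-trip through the CSV dialect", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(population_spec(), n_patients = 1, seed = 66,
                         dir = dir)
  expect_length(coh$files, 6L)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_map_csv(coh$files[[1]])
  orig <- coh$records[[1]]
  expect_identical(back$patient_id, orig$patient_id)
  expect_lt(max(abs(back$maps$stroma$heights - orig$maps$stroma$heights)),
            1e-9)
})

test_that("pathological specs raise a generation error naming the surface", {
  spec <- population_spec()
  spec$surfaces$endothelium$R1_mean <- 3.1
  spec$surfaces$endothelium$R2_mean <- 3.0
  spec$surfaces$endothelium$Q1_mean <- 1.5
  spec$surfaces$endothelium$Q2_mean <- 1.5
  spec$surfaces$endothelium$R1_sd <- 0
  spec$surfaces$endothelium$R2_sd <- 0
  spec$surfaces$endothelium$Q1_sd <- 0
  spec$surfaces$endothelium$Q2_sd <- 0
  set.seed(67)
  eye <- sample_eye(spec, "OD")
  expect_error(render_measurement(eye, 1, spec),
               "generation error.*endothelium")
})
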