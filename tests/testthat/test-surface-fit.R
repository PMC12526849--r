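test_that("algebraic sphere fit recovers exact and noisy spheres", {
  p <- surface_params("SphCyl", 7.7, 7.7)
  cloud <- render_cloud(p, roi = 6)
  s <- best_fit_sphere(cloud)
  expect_lt(abs(s$R - 7.7), 1e-9)
  expect_lt(max(abs(c(s$X0, s$Y0, s$Z0))), 1e-9)

  p2 <- surface_params("SphCyl", 7.7, 7.7, X0 = 0.2, Y0 = -0.1, Z0 = 0.05)
  s2 <- best_fit_sphere(render_cloud(p2, roi = 6))
  expect_lt(abs(s2$R - 7.7), 1e-9)
  expect_lt(max(abs(c(s2$X0 - 0.2, s2$Y0 + 0.1, s2$Z0 - 0.05))), 1e-9)

  # radius errors on a shallow cap are noise-limited: the height
  # sensitivity to R is ~rho^2/(2 R^2), so sigma = 5 um admits errors of
  # a few microns times the ~60x amplification
  set.seed(21)
  errs <- replicate(10, {
    cl <- render_cloud(p, roi = 6, sigma = 0.005)
    abs(best_fit_sphere(cl)$R - 7.7)
  })
  expect_lt(max(errs), 0.01)

  flat <- data.frame(x = runif(20), y = runif(20), z = 0)
  expect_error(best_fit_sphere(flat), "coplanar|degenerate")
})

test_that("noiseless parameter recovery is exact to 1e-4 for all models", {
  cases <- list(
    list(model = "SphCyl",
         p = surface_params("SphCyl", 7.80, 7.55, A1 = 10,
                            X0 = 0.1, Y0 = -0.05, Z0 = 0.02)),
    list(model = "CylConoid",
         p = surface_params("CylConoid", 7.9, 7.5, A1 = 121, Q1 = -0.3,
                            Q2 = -0.3, X0 = -0.15, Y0 = 0.1, Z0 = -0.04)),
    list(model = "Biconic",
         p = surface_params("Biconic", 7.79, 7.55, A1 = 170, Q1 = -0.15,
                            Q2 = -0.23, X0 = 0.08, Y0 = 0.02, Z0 = 0.01)))
  for (cs in cases) {
    fit <- fit_surface(render_cloud(cs$p, roi = 6), model = cs$model)
    expect_true(fit$converged)
    got <- fit$params
    want <- cs$p
    for (nm in c("R1", "R2", "Q1", "Q2", "X0", "Y0", "Z0"))
      expect_lt(abs(got[[nm]] - want[[nm]]), 1e-4)
    expect_lt(abs(((got$A1 - want$A1 + 90) %% 180) - 90), 1e-4)
    expect_lt(fit$rms_error, 1e-9)
  }
})

test_that("a pure sphere fitted with SphCyl degenerates cleanly", {
  p <- surface_params("SphCyl", 7.8, 7.8, X0 = 0.05)
  fit <- fit_surface(render_cloud(p, roi = 6), model = "SphCyl")
  expect_lt(fit$params$R1 - fit$params$R2, 1e-6)
  expect_lt(fit$rms_error, 1e-9)
  expect_false(fit$axis_identifiable)
  expect_identical(fit$params$A1, 0)
})

test_that("model fits never beat the data less than the best-fit sphere", {
  set.seed(31)
  p <- surface_params("CylConoid", 7.8, 7.5, A1 = 40, Q1 = -0.3, Q2 = -0.3)
  cloud <- render_cloud(p, roi = 6, sigma = 0.003)
  s <- best_fit_sphere(cloud)
  sphere_params <- surface_params("SphCyl", s$R, s$R, X0 = s$X0, Y0 = s$Y0,
                                  Z0 = s$Z0)
  rms_sphere <- sqrt(mean((cloud$z - sag(sphere_params, cloud$x, cloud$y))^2))
  for (model in c("SphCyl", "CylConoid", "Biconic")) {
    fit <- fit_surface(cloud, model = model)
    expect_lte(fit$rms_error, rms_sphere + 1e-12)
  }
})

test_that("the objective is invariant under point order", {
  set.seed(5)
  p <- surface_params("Biconic", 7.7, 7.4, A1 = 65, Q1 = -0.2, Q2 = -0.1)
  cloud <- render_cloud(p, roi = 6, sigma = 0.002)
  f1 <- fit_surface(cloud, "Biconic")
  shuffled <- cloud[sample(nrow(cloud)), ]
  f2 <- fit_surface(shuffled, "Biconic")
  # the minimiser is identical up to floating-point summation order
  for (nm in c("R1", "R2", "A1", "Q1", "Q2", "X0", "Y0", "Z0"))
    expect_lt(abs(f1$params[[nm]] - f2$params[[nm]]), 1e-5)
  expect_equal(f1$rms_error, f2$rms_error, tolerance = 1e-8)
})

test_that("a prolate conoid fitted by SphCyl looks flatter in the larger ROI", {
  p <- surface_params("CylConoid", 7.7, 7.5, A1 = 15, Q1 = -0.3, Q2 = -0.3)
  m <- render_map(p)
  f3 <- fit_surface(to_cartesian_points(m, 3), "SphCyl")
  f6 <- fit_surface(to_cartesian_points(m, 6), "SphCyl")
  expect_gt(f6$params$R1, f3$params$R1)
  expect_gt(f6$params$R2, f3$params$R2)
})

test_that("fit_measurement fits all three surfaces and survives dropout", {
  set.seed(77)
  p <- demo_eye_params()
  rec <- make_record(p$epi, p$stroma, p$endo, sigma = 0.002)
  fits <- fit_measurement(rec, 6, "Biconic")
  expect_named(fits, c("epithelium", "stroma", "endothelium"))
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  expect_lt(abs(fits$epithelium$params$R1 - p$epi$R1), 0.02)

  # 50% dropout on the endothelium: still converges, n_points reported
  h <- rec$maps$endothelium$heights
  drop <- matrix(runif(length(h)) < 0.5, nrow(h)); drop[, 1] <- FALSE
  h[drop] <- MS39_SENTINEL
  rec$maps$endothelium <- polar_height_map(h, rec$maps$endothelium$grid)
  fits2 <- fit_measurement(rec, 6, "Biconic")
  expect_true(fits2$endothelium$converged)
  expect_lt(fits2$endothelium$n_points, 0.6 * 3841)
  expect_lt(abs(fits2$endothelium$params$R1 - p$endo$R1), 0.05)

  # per-surface failure is named
  h[] <- MS39_SENTINEL
  rec$maps$endothelium <- polar_height_map(h, rec$maps$endothelium$grid)
  expect_error(fit_measurement(rec, 6, "Biconic"), "endothelium")
})

test_that("too-small clouds are rejected", {
  p <- surface_params("SphCyl", 7.8, 7.6, A1 = 5)
  cloud <- render_cloud(p, roi = 6)
  expect_error(fit_surface(cloud[1:10, ], "Biconic"), "too few points")
})
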