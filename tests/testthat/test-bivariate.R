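test_that("left-eye mirroring flips C45 only and is an involution", {
  s <- data.frame(C0 = c(0.5, -0.2, 0.1), C45 = c(0.3, 0.4, -0.6),
                  laterality = c("OS", "OD", "OS"))
  m <- mirror_left_eyes(s)
  expect_equal(m$C0, s$C0)
  expect_equal(m$C45, c(-0.3, 0.4, 0.6))
  expect_equal(mirror_left_eyes(m), s)
  s$laterality[2] <- "left"
  expect_error(mirror_left_eyes(s), "laterality")
})

test_that("Henze-Zirkler matches the reference implementation on frozen fixtures", {
  # expected values computed independently with pingouin.multivariate_normality
  # on byte-identical samples
  set.seed(42)
  x <- cbind(rnorm(50), rnorm(50) * 0.5 + 0.2)
  h <- henze_zirkler(x)
  expect_equal(unname(h$statistic), 0.5673992838, tolerance = 1e-9)
  expect_equal(h$p.value, 0.3174150581, tolerance = 1e-8)

  set.seed(7)
  y <- cbind(exp(rnorm(80)), rnorm(80))
  h2 <- henze_zirkler(y)
  expect_equal(unname(h2$statistic), 4.7209410183, tolerance = 1e-9)
  expect_equal(h2$p.value, 3.072983171e-10, tolerance = 1e-6)
})

test_that("Henze-Zirkler is affine invariant and validates its input", {
  set.seed(5)
  x <- matrix(rnorm(200), 100, 2)
  A <- matrix(c(2, 0.7, -0.3, 1.4), 2)
  y <- sweep(x %*% t(A), 2, c(1, -2), "+")
  expect_lt(abs(henze_zirkler(x)$statistic - henze_zirkler(y)$statistic),
            1e-10)
  expect_error(henze_zirkler(x[1:5, ]), "at least 8")
  sing <- cbind(1:20, 2 * (1:20))
  expect_error(henze_zirkler(sing), "singular|degenerate")
})

test_that("Henze-Zirkler type-I error is calibrated and detects non-normality", {
  set.seed(123)
  rej <- 0L
  for (i in 1:400) {
    x <- matrix(rnorm(400), 200, 2)
    if (henze_zirkler(x)$p.value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 400, 0.02)
  expect_lt(rej / 400, 0.09)

  set.seed(9)
  hits <- 0L
  for (i in 1:50) {
    z <- rbind(matrix(rnorm(200, -3), 100, 2), matrix(rnorm(200, 3), 100, 2))
    if (henze_zirkler(z)$p.value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("the medoid is a sample point minimising total distance", {
  expect_equal(medoid(cbind(0.3, -0.2)), c(C0 = 0.3, C45 = -0.2))
  coll <- cbind(c(0, 1, 10), c(0, 0, 0))
  expect_equal(unname(medoid(coll)), c(1, 0))

  brute <- function(x) {
    d <- as.matrix(dist(x))
    x[which.min(rowSums(d)), ]
  }
  set.seed(37)
  for (i in 1:5) {
    x <- cbind(rnorm(200), rnorm(200))
    expect_equal(unname(medoid(x)), unname(brute(x)))
  }
  # translation and rotation equivariance; membership
  x <- cbind(rnorm(50), rnorm(50))
  m0 <- medoid(x)
  expect_true(any(x[, 1] == m0[1] & x[, 2] == m0[2]))
  mt <- medoid(sweep(x, 2, c(3, -1), "+"))
  expect_equal(unname(mt), unname(m0) + c(3, -1), tolerance = 1e-12)
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mr <- medoid(x %*% t(Rm))
  expect_equal(unname(mr), as.vector(Rm %*% m0), tolerance = 1e-12)
})

test_that("the parametric error ellipse has the chi-square area", {
  set.seed(41)
  x <- matrix(rnorm(8000), 4000, 2)
  e <- centroid_and_ellipse(x, 0.95)
  expect_equal(e$area, pi * qchisq(0.95, 2) * sqrt(det(cov(x))),
               tolerance = 1e-12)
  expect_lt(abs(e$area - pi * qchisq(0.95, 2)) / (pi * qchisq(0.95, 2)), 0.1)
  # doubling one coordinate doubles the area; rotation preserves it
  x2 <- x; x2[, 1] <- 2 * x2[, 1]
  expect_equal(centroid_and_ellipse(x2)$area, 2 * e$area, tolerance = 1e-9)
  th <- 0.6; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(centroid_and_ellipse(x %*% t(Rm))$area, e$area,
               tolerance = 1e-9)
  expect_error(centroid_and_ellipse(cbind(1:20, 2 * (1:20))), "singular")
})

test_that("convex hull stripping retains at least the target fraction", {
  # four corners plus a tight interior cluster; stripping the corner layer
  # would drop below 97 of 100 points, so the region is the unit square
  grid <- as.matrix(expand.grid(seq(0.4, 0.6, length.out = 10),
                                seq(0.4, 0.6, length.out = 10)))[1:96, ]
  x <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), grid)
  r <- convex_hull_strip(x, coverage = 0.97)
  expect_equal(r$area, 1.0, tolerance = 1e-12)
  expect_identical(r$layers_stripped, 0L)

  set.seed(43)
  for (i in 1:5) {
    th <- runif(1000, 0, 2 * pi); rad <- sqrt(runif(1000))
    disc <- cbind(rad * cos(th), rad * sin(th))
    full_area <- cornfit:::shoelace_area(disc[chull(disc), ])
    r <- convex_hull_strip(disc, 0.95)
    expect_gte(r$retained, 0.95)
    expect_lte(r$retained, 1)
    expect_lt(r$area, full_area)
    # central 95% of a uniform disc is a disc of area 0.95 * pi
    expect_lt(abs(r$area - 0.95 * pi) / (0.95 * pi), 0.12)
  }
  expect_error(convex_hull_strip(cbind(rnorm(5), rnorm(5))), "at least 10")
})

test_that("population summaries branch on the normality test", {
  set.seed(47)
  normal <- data.frame(C0 = rnorm(200, 0.7, 0.3), C45 = rnorm(200, 0, 0.3))
  s1 <- summarize_population(normal)
  expect_identical(s1$branch, "ellipse")
  expect_s3_class(s1$test, "htest")

  heavy <- data.frame(C0 = rt(200, df = 1.5), C45 = rt(200, df = 1.5))
  s2 <- summarize_population(heavy)
  expect_identical(s2$branch, "hull")
  expect_true(all(c("C0", "C45") %in% names(s2$location)))
  expect_gt(s2$region$area, 0)
  expect_true(is.numeric(s2$test$p.value))
})
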