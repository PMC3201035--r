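# Ellipsoid geometry, MVEE computation, and uniform interior sampling.

test_that("unit-ball volumes follow the dimension recursion", {
  expect_equal(unit_ball_volume(0), 1)
  expect_equal(unit_ball_volume(1), 2)
  expect_equal(unit_ball_volume(2), pi)
  expect_equal(unit_ball_volume(3), 4 * pi / 3)
  expect_equal(ellipsoid_volume(ellipsoid(c(0, 0), diag(2))), pi)
  expect_equal(ellipsoid_volume(ellipsoid(rep(0, 3), diag(3))), 4 * pi / 3)
  # axis-aligned semi-axes (2, 3): volume 6 pi
  expect_equal(ellipsoid_volume(ellipsoid(c(0, 0), diag(c(1 / 4, 1 / 9)))),
               6 * pi)
})

test_that("mvee handles canonical and degenerate inputs", {
  # interval hull in 1-D
  e1 <- mvee(matrix(c(0, 1), ncol = 1))
  expect_equal(e1$center, 0.5, tolerance = 1e-9)
  expect_equal(ellipsoid_volume(e1), 1, tolerance = 1e-6)
  # square corners: circle of radius sqrt(2), volume 2 pi
  e2 <- mvee(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  expect_equal(e2$center, c(0, 0), tolerance = 1e-9)
  expect_equal(ellipsoid_volume(e2), 2 * pi, tolerance = 1e-5)
  # collinear points: regularized, still contains everything
  P <- rbind(c(0, 0), c(1, 0), c(2, 0))
  e3 <- mvee(P)
  expect_true(all(in_ellipsoid(e3, P, tol = 1e-6)))
  expect_lt(ellipsoid_volume(e3), 1e-4)  # thin regularized sliver
  # fewer than 2 points errors
  expect_error(mvee(matrix(1, ncol = 2)), "at least 2")
})

test_that("mvee contains its input and is nearly minimal on random clouds", {
  set.seed(10)
  for (d in c(2, 3, 6)) {
    P <- matrix(stats::rnorm(60 * d), ncol = d)
    e <- mvee(P)
    expect_true(all(in_ellipsoid(e, P, tol = 1e-6)))
    # upper oracle: the ball at the centroid with radius max distance
    centroid <- colMeans(P)
    r <- sqrt(max(rowSums(sweep(P, 2, centroid)^2)))
    expect_lte(ellipsoid_volume(e), unit_ball_volume(d) * r^d * (1 + 1e-6))
  }
})

test_that("mvee is affine-equivariant", {
  set.seed(12)
  P <- matrix(stats::rnorm(80 * 3), ncol = 3)
  A <- matrix(stats::rnorm(9), 3) + diag(3) * 2
  b <- c(1, -2, 0.5)
  e <- mvee(P)
  eT <- mvee(sweep(P %*% t(A), 2, b, `+`))
  expect_equal(eT$center, as.numeric(A %*% e$center + b), tolerance = 1e-3)
  expect_equal(ellipsoid_volume(eT), abs(det(A)) * ellipsoid_volume(e),
               tolerance = 1e-3)
})

test_that("scaling multiplies axes by g and volume by g^d", {
  e <- mvee(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  expect_equal(scale_ellipsoid(e, 1)$shape, e$shape)
  expect_equal(ellipsoid_volume(scale_ellipsoid(e, 2)),
               2^2 * ellipsoid_volume(e))
  back <- scale_ellipsoid(scale_ellipsoid(e, 0.5), 2)
  expect_equal(back$shape, e$shape, tolerance = 1e-10)
  expect_error(scale_ellipsoid(e, 0), "positive")
})

test_that("interior sampling is uniform", {
  set.seed(21)
  # membership contract in a skewed ellipsoid
  S <- crossprod(matrix(stats::rnorm(9), 3)) + diag(3)
  e <- ellipsoid(c(1, 2, 3), S)
  X <- sample_in_ellipsoid(e, 5000)
  expect_true(all(ellipsoid_membership(e, X) <= 1 + 1e-12))
  # unit ball d = 3: sample mean near the center (3 sigma CLT bound)
  b3 <- ellipsoid(rep(0, 3), diag(3))
  Y <- sample_in_ellipsoid(b3, 1e5)
  expect_true(all(abs(colMeans(Y)) < 0.02))
  # unit ball d = 2: radius <= 0.5 has probability 0.25 (area ratio r^2)
  b2 <- ellipsoid(c(0, 0), diag(2))
  Z <- sample_in_ellipsoid(b2, 1e5)
  expect_lt(abs(mean(rowSums(Z^2) <= 0.25) - 0.25), 0.005)
  # radial CDF is r^d: Kolmogorov-Smirnov at alpha = 0.001
  r3 <- sqrt(rowSums(sample_in_ellipsoid(b3, 1e5)^2))
  ks <- stats::ks.test(r3^3, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("ellipsoids survive a JSON round trip", {
  e <- mvee(rbind(c(0, 1), c(2, 3), c(-1, 0.5), c(1, -2)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(ellipsoid_to_list(e), path, digits = NA)
  back <- ellipsoid_from_list(jsonlite::read_json(path,
                                                  simplifyVector = TRUE))
  expect_equal(back$center, e$center, tolerance = 1e-12)
  expect_equal(back$shape, e$shape, tolerance = 1e-12)
})
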