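# Cover construction and overlap-once stratified volume estimation.

test_that("build_cover picks one blob vs two by total volume", {
  set.seed(80)
  blob <- sample_in_ellipsoid(ellipsoid(c(0, 0), diag(2)), 500)
  cov1 <- build_cover(blob, k_max = 4)
  expect_identical(cov1$k, 1L)
  two <- rbind(blob, sweep(blob, 2, c(9, 0), `+`))
  cov2 <- build_cover(two, k_max = 4)
  expect_identical(cov2$k, 2L)
  expect_lt(sum(cov2$volumes), ellipsoid_volume(mvee(two)))
  # every input point is inside the union
  expect_true(all(cover_contains(cov2, two)))
  expect_error(build_cover(matrix(0, 2, 5)), "d \\+ 1")
})

test_that("the overlap-once integrand credits each region exactly once", {
  pb <- all_viable_problem(2, bound = 10)
  e_big <- ellipsoid(c(0, 0), diag(2) / 4)   # radius 2
  e_small <- ellipsoid(c(1, 0), diag(2))     # radius 1, inside overlap
  cover <- structure(list(ellipsoids = list(e_big, e_small),
                          volumes = c(ellipsoid_volume(e_big),
                                      ellipsoid_volume(e_small)),
                          k = 2L, inflation = 1),
                     class = "ellipsoid_cover")
  # drawn from ellipsoid 2 but inside ellipsoid 1: claimed already -> 0
  expect_identical(overlap_once_indicator(cover, 2, c(1, 0), pb), 0)
  # drawn from ellipsoid 1, viable -> 1
  expect_identical(overlap_once_indicator(cover, 1, c(1, 0), pb), 1)
  # outside the box -> 0 even if inside an ellipsoid
  e_edge <- ellipsoid(c(10, 0), diag(2) / 4)
  cov_edge <- structure(list(ellipsoids = list(e_edge),
                             volumes = ellipsoid_volume(e_edge), k = 1L,
                             inflation = 1), class = "ellipsoid_cover")
  expect_identical(overlap_once_indicator(cov_edge, 1, c(10.5, 0), pb), 0)
})

test_that("an ellipsoid wholly inside the viable region is estimated
           exactly with zero stderr", {
  pb <- ball_problem(2, r = 5)
  e <- ellipsoid(c(0, 0), diag(2))  # unit disk, well inside the viable ball
  cover <- structure(list(ellipsoids = list(e), volumes = ellipsoid_volume(e),
                          k = 1L, inflation = 1), class = "ellipsoid_cover")
  est <- estimate_volume(cover, pb, N = 1000, seed = 81)
  expect_equal(est$volume, pi, tolerance = 1e-12)
  expect_identical(est$stderr, 0)
  expect_identical(sum(est$m_i), 1000L)
})

test_that("a duplicated ellipsoid adds nothing to the expected estimate", {
  pb <- shell_problem(2)
  set.seed(82)
  pts <- sample_shell_point(attr(pb, "shell_spec"), 1, 2000)
  e <- mvee(pts)
  cov1 <- structure(list(ellipsoids = list(e), volumes = ellipsoid_volume(e),
                         k = 1L, inflation = 1), class = "ellipsoid_cover")
  cov2 <- structure(list(ellipsoids = list(e, e),
                         volumes = rep(ellipsoid_volume(e), 2), k = 2L,
                         inflation = 1), class = "ellipsoid_cover")
  est1 <- replicate(20, estimate_volume(cov1, pb, N = 5000)$volume)
  est2 <- replicate(20, estimate_volume(cov2, pb, N = 5000)$volume)
  # same expectation: difference within combined Monte Carlo error
  se <- sqrt(stats::var(est1) / 20 + stats::var(est2) / 20)
  expect_lt(abs(mean(est1) - mean(est2)), 4 * se)
})

test_that("the estimator is unbiased on the 2-D shell and its stderr
           covers the analytic value", {
  pb <- shell_problem(2)
  analytic <- shell_volume_analytic(2)
  # a generous cover that contains the whole shell, so the only error is
  # the Monte Carlo noise the estimator is supposed to quantify
  ball <- ellipsoid(c(0, 0), diag(2) / 0.5^2)
  cover <- structure(list(ellipsoids = list(scale_ellipsoid(ball, 1.05)),
                          volumes = ellipsoid_volume(ball) * 1.05^2,
                          k = 1L, inflation = 1),
                     class = "ellipsoid_cover")
  set.seed(83)
  ests <- replicate(100, {
    e <- estimate_volume(cover, pb, N = 20000)
    c(e$volume, e$stderr)
  })
  # replicate mean within 3 standard errors of the mean
  sem <- stats::sd(ests[1, ]) / sqrt(100)
  expect_lt(abs(mean(ests[1, ]) - analytic), 3 * sem)
  # 3-sigma coverage of the analytic value in at least 95% of replicates
  covered <- abs(ests[1, ] - analytic) <= 3 * ests[2, ]
  expect_gte(mean(covered), 0.95)
  # the estimate never exceeds the summed ellipsoid volumes
  expect_true(all(ests[1, ] <= sum(cover$volumes) + 1e-12))
})

test_that("permuting the ellipsoid order leaves the expectation unchanged", {
  pb <- ball_problem(2, r = 2)
  e1 <- ellipsoid(c(-0.5, 0), diag(2))
  e2 <- ellipsoid(c(0.5, 0), diag(2))
  mk <- function(ells) structure(
    list(ellipsoids = ells,
         volumes = vapply(ells, ellipsoid_volume, numeric(1)), k = 2L,
         inflation = 1), class = "ellipsoid_cover")
  set.seed(84)
  a <- replicate(30, estimate_volume(mk(list(e1, e2)), pb, N = 4000)$volume)
  b <- replicate(30, estimate_volume(mk(list(e2, e1)), pb, N = 4000)$volume)
  se <- sqrt(stats::var(a) / 30 + stats::var(b) / 30)
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
})

test_that("the viable sample is uniform over the viable region", {
  pb <- shell_problem(2)
  set.seed(85)
  pts <- sample_shell_point(attr(pb, "shell_spec"), 1, 3000)
  cover <- build_cover(pts, k_max = 3)
  est <- estimate_volume(cover, pb, N = 2e5)
  smp <- est$viable_points$points
  # chi-squared over 8 angular sectors (each has equal viable area)
  ang <- atan2(smp[, 2], smp[, 1])
  counts <- table(cut(ang, breaks = seq(-pi, pi, length.out = 9)))
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("brute force matches a Bernoulli oracle and flags degeneracy", {
  # viable region = half the box in 1-D
  pb <- box_region_problem(lo = -10, hi = 0)
  est <- brute_force_volume(pb, N = 1e5, seed = 86)
  expect_lt(abs(est$volume - 10), 3 * est$stderr + 1e-12)
  # no viable points: degenerate zero estimate, flagged
  none <- ball_problem(2, r = 1e-8)
  est0 <- brute_force_volume(none, N = 1000, seed = 87)
  expect_identical(est0$volume, 0)
  expect_identical(est0$stderr, 0)
  expect_true(attr(est0, "degenerate"))
})

test_that("stratified estimation beats brute force at equal N on the
           2-D shell", {
  pb <- shell_problem(2)
  analytic <- shell_volume_analytic(2)
  set.seed(88)
  pts <- sample_shell_point(attr(pb, "shell_spec"), 1, 2000)
  cover <- build_cover(pts, k_max = 3)
  est_s <- estimate_volume(cover, pb, N = 1e5)
  est_b <- brute_force_volume(pb, N = 1e5)
  expect_lt(abs(est_s$volume - analytic), 3 * est_s$stderr + 1e-3)
  expect_lt(abs(est_b$volume - analytic), 3 * est_b$stderr + 1e-3)
  expect_lt(est_s$stderr * 5, est_b$stderr)
})
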