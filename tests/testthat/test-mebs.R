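# Local ellipsoid-based exploration: boundary bracketing, scaling updates,
# expansions, start selection.

test_that("scaling updates follow the offset rule exactly", {
  cfg <- mebs_config(2, g0 = 0.9, g1 = 1.05, p = 0.5, b_l = 0.05, b_u = 0.5,
                     n = 100)
  expect_identical(update_scaling(1.23, 10, cfg, i = 0), 0.9)
  expect_identical(update_scaling(0.9, 10, cfg, i = 1), 1.05)
  # growth: offset (g - 1) multiplied by (1 + p)
  expect_equal(update_scaling(1.5, 60, cfg, i = 2), 1.75)
  # shrink: offset multiplied by (1 - p)
  expect_equal(update_scaling(1.5, 2, cfg, i = 2), 1.25)
  # in-band: unchanged
  expect_identical(update_scaling(1.5, 20, cfg, i = 2), 1.5)
})

test_that("the g-sequence converges to one under persistent shrink and
           diverges under persistent growth", {
  cfg <- mebs_config(2, p = 0.5, n = 100)
  g <- 1.8
  gs <- numeric(20)
  for (i in seq_len(20)) {
    g <- update_scaling(g, 0, cfg, i + 1)  # always below n * b_l
    gs[i] <- g
  }
  expect_true(all(diff(gs) < 0))
  expect_lt(abs(gs[20] - 1), 1e-5)
  g <- 1.1
  hs <- numeric(10)
  for (i in seq_len(10)) {
    g <- update_scaling(g, 100, cfg, i + 1)  # always above n * b_u
    hs[i] <- g
  }
  expect_true(all(diff(hs) > 0))
  expect_gt(hs[10], 1.1 * 1.5^9 - 1.5^9 + 1 - 1e-9)
})

test_that("boundary points bracket the viability boundary along the axes", {
  # 1-D viable interval (-1, 1): boundary points within 2e-3 of +/-1
  pb <- quad_problem(E0 = 1)
  bp <- find_boundary_points(pb, 0)
  ends <- sort(bp$points[, 1])
  expect_equal(ends, c(-1, 1), tolerance = 2e-3)
  expect_true(all(is_viable(pb, bp$points)))
  expect_error(find_boundary_points(pb, 5), "viable")

  # 2-D shell from a mid-sphere point: 4 viable points near radius 0.4-0.5
  pbs <- shell_problem(2)
  bps <- find_boundary_points(pbs, c(0.4, 0))
  expect_equal(n_points(bps), 4)
  expect_true(all(is_viable(pbs, bps$points)))
  radii <- sqrt(rowSums(bps$points^2))
  expect_true(all(abs(radii - 0.4) <= 0.1 + 1e-9))

  # whole box viable: the rays clip at the box faces
  pba <- all_viable_problem(2, bound = 10)
  bpa <- find_boundary_points(pba, c(0, 0))
  expect_true(all(apply(abs(bpa$points), 1, max) == 10))
})

test_that("an expansion stays inside the viable region and spans it", {
  pb <- shell_problem(2)
  set.seed(70)
  vs <- ellipsoid_expansion(pb, c(0.4, 0), mebs_config(2), seed = 71)
  radii <- sqrt(rowSums(vs$points^2))
  expect_true(all(radii >= 0.3 - 1e-9 & radii <= 0.5 + 1e-9))
  expect_true(all(is_viable(pb, vs$points)))
  g_traj <- attr(vs, "g_trajectory")
  expect_identical(g_traj[1], 0.9)
  expect_identical(g_traj[2], 1.05)

  # box-shaped viable region from the center: the final MVEE is at least
  # as large as the inscribed ellipsoid of the box
  pbx <- box_region_problem(c(-1, -2), c(1, 2))
  vb <- ellipsoid_expansion(pbx, c(0, 0), mebs_config(2), seed = 72)
  L <- attr(vb, "ellipsoid")
  expect_gte(ellipsoid_volume(L), pi * 1 * 2 * (1 - 0.05))
})

test_that("start selection is far from previous starts", {
  # single candidate: returned as is
  expect_equal(select_next_start(matrix(c(3, 4), nrow = 1), NULL), c(3, 4))
  # candidates at 0 and 10 in 1-D with previous mean at 0: picks 10
  cands <- matrix(c(0, 10), ncol = 1)
  expect_equal(select_next_start(cands, matrix(0), seed = 73)[1], 10)
  expect_error(select_next_start(matrix(numeric(), ncol = 2), NULL),
               "no candidates")
  # two clusters, all previous starts in cluster 1: far cluster is reachable
  set.seed(74)
  c1 <- matrix(stats::rnorm(100, 0, 0.1), ncol = 2)
  c2 <- matrix(stats::rnorm(100, 8, 0.1), ncol = 2)
  picks <- replicate(50, select_next_start(rbind(c1, c2),
                                           matrix(c(0, 0), 1))[1])
  expect_true(all(picks > 4))  # the top decile by distance is cluster 2
})

test_that("run_mebs pools viable points and reaches shell coverage", {
  pb <- shell_problem(5)
  spec <- attr(pb, "shell_spec")
  seeds <- sample_shell_point(spec, 1, 3, seed = 75)
  cfg <- mebs_config(5, max_expansions = 12)
  vt <- run_mebs(pb, seeds, cfg, seed = 76)
  expect_true(all(is_viable(pb, vt$points)))
  vol <- as.numeric(clustered_cover_volume(vt))
  expect_gt(vol, 0.5 * shell_volume_analytic(5))
  tr <- attr(vt, "trace")
  expect_true(nrow(tr) >= 1)
})
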