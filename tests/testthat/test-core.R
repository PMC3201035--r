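# Viability problem abstraction: box, cost counting, viability predicate.

test_that("viability predicate matches the shell benchmark by hand", {
  pb <- shell_problem(3)  # r_e = 0.5, r_i = 0.3, center at origin
  # a point on the mid-sphere (distance 0.4) attains the cost minimum 0
  p_mid <- c(0.4, 0, 0)
  expect_equal(eval_cost(pb, p_mid), 0)
  expect_true(is_viable(pb, p_mid))
  # distance 0.5: cost (0.5 - 0.4)^2 = 0.01, exactly the printed bound;
  # the threshold sits infinitesimally above it, so the point is viable
  p_edge <- c(0.5, 0, 0)
  expect_equal(eval_cost(pb, p_edge), 0.01, tolerance = 1e-14)
  expect_true(is_viable(pb, p_edge))
  # just beyond the bound: nonviable
  expect_false(is_viable(pb, c(0.5 + 1e-6, 0, 0)))
  # outside the box: nonviable by definition, without evaluating the cost
  n0 <- evaluations(pb)
  expect_false(is_viable(pb, c(10.5, 0, 0)))
  expect_identical(evaluations(pb), n0)
  # dimension mismatch errors
  expect_error(is_viable(pb, c(0, 0)), "dimension")
})

test_that("cost evaluations are counted exactly once per in-box point", {
  pb <- quad_problem()
  reset_evaluations(pb)
  eval_cost(pb, 0.5)
  eval_cost(pb, matrix(c(0, 1, 2, 100), ncol = 1))  # 100 is outside [-10,10]
  expect_identical(evaluations(pb), 4)  # 1 + 3 in-box rows
  reset_evaluations(pb)
  expect_identical(evaluations(pb), 0)
})

test_that("parameter space invariants are enforced and volume is exact", {
  expect_error(parameter_space(c(0, 1), c(1, 1)), "lower < upper")
  expect_error(parameter_space(numeric(), numeric()), "non-empty")
  sp <- parameter_space(c(-10, -10), c(10, 10))
  expect_equal(space_volume(sp), 400)
  expect_equal(space_volume(osc_space()), 6^10 * 9^2)
})

test_that("seeded runs are reproducible and uniform draws behave", {
  set.seed(42); a <- stats::runif(100)
  set.seed(42); b <- stats::runif(100)
  expect_identical(a, b)
  set.seed(1); c1 <- stats::runif(100)
  set.seed(2); c2 <- stats::runif(100)
  expect_false(identical(c1, c2))
  set.seed(7)
  expect_lt(abs(mean(stats::runif(1e5)) - 0.5), 0.01)
})

test_that("every stored viable point re-checks as viable", {
  pb <- shell_problem(4)
  set.seed(11)
  spec <- attr(pb, "shell_spec")
  pts <- sample_shell_point(spec, 1, 200)
  vs <- viable_set(pts, eval_cost(pb, pts), "oeamc")
  expect_true(all(is_viable(pb, vs$points)))
  expect_equal(n_points(vs), 200)
})

test_that("viable sets serialize round-trip at full precision", {
  set.seed(3)
  pts <- matrix(stats::rnorm(15) * exp(stats::rnorm(15) * 5), ncol = 3)
  vs <- viable_set(pts, stats::runif(5), c("oeamc", "mebs-boundary",
                                           "mebs-expansion", "integration",
                                           "oeamc"), 1:5)
  path <- tempfile(fileext = ".csv")
  write_viable_set(vs, path)
  back <- read_viable_set(path)
  expect_identical(unname(unclass(back$points))[TRUE], vs$points[TRUE])
  expect_equal(dim(back$points), dim(vs$points))
  expect_identical(back$cost, vs$cost)
  expect_identical(back$stage, vs$stage)
  # header row present
  expect_match(readLines(path, n = 1), "cost")
})

test_that("vs_bind pools sets and drops exact duplicates, keeping provenance", {
  a <- viable_set(rbind(c(0, 0), c(1, 1)), c(0, 0), "oeamc")
  b <- viable_set(rbind(c(1, 1), c(2, 2)), c(0, 0), "mebs-expansion")
  pooled <- vs_bind(a, b)
  expect_equal(n_points(pooled), 3)
  expect_identical(pooled$stage[2], "oeamc")  # first occurrence wins
})

test_that("the seed finder reaches a viable point on smooth problems", {
  pb <- shell_problem(8)
  theta0 <- find_viable_seed(pb, seed = 5)
  expect_true(is_viable(pb, theta0))
  # the budget is respected on an impossible problem
  impossible <- viability_problem(parameter_space(-1, 1),
                                  function(theta) 1e6, threshold = 1e-3)
  expect_error(find_viable_seed(impossible, budget = 300, seed = 1),
               "budget")
  expect_lte(evaluations(impossible), 301)
})
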