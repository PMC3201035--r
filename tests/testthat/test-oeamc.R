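# Global adaptive Metropolis exploration: acceptance rule, adaptation
# branches, stopping statistic, and the full sampler.

test_that("acceptance probabilities match the Metropolis rule exactly", {
  expect_identical(acceptance_probability(-3.7, 2.5), 1)
  expect_identical(acceptance_probability(0, 1), 1)
  expect_equal(acceptance_probability(log(2), 1), 0.5)
  expect_identical(acceptance_probability(Inf, 1), 0)
  expect_equal(acceptance_probability(c(-1, log(4), Inf), 0.5),
               c(1, 0.5, 0))
})

test_that("adaptation applies the published branch structure exactly", {
  cfg <- oeamc_config(2, sigma0 = diag(2), b = 2, s = 2,
                      f0 = 0.2, f_l = 0.2, f_u = 0.5)
  # beta branches
  expect_equal(adapt(1, diag(2), f_v = 0, f_a = 0.3, cfg)$beta, 2)
  expect_equal(adapt(1, diag(2), f_v = 0.1, f_a = 0.3, cfg)$beta, 1)
  expect_equal(adapt(1, diag(2), f_v = 0.2, f_a = 0.3, cfg)$beta, 1)
  expect_equal(adapt(1, diag(2), f_v = 0.3, f_a = 0.3, cfg)$beta, 0.5)
  # sigma branches (scalar multiplication of the whole matrix)
  expect_equal(adapt(1, diag(2), f_v = 0.1, f_a = 0.9, cfg)$sigma,
               2 * diag(2))
  expect_equal(adapt(1, diag(2), f_v = 0.1, f_a = 0.3, cfg)$sigma, diag(2))
  expect_equal(adapt(1, diag(2), f_v = 0.1, f_a = 0.1, cfg)$sigma,
               diag(2) / 2)
  # both applied independently in the same block; twice with f_v = 0
  # multiplies beta by b^2 exactly
  st <- adapt(1, diag(2), 0, 0.9, cfg)
  st <- adapt(st$beta, st$sigma, 0, 0.9, cfg)
  expect_identical(st$beta, 4)
  expect_equal(st$sigma, 4 * diag(2))
})

test_that("config invariants are enforced", {
  expect_error(oeamc_config(2, sigma0 = diag(2), b = 0.5), "b > 1")
  expect_error(oeamc_config(2, sigma0 = diag(2), f_l = 0.6, f_u = 0.5))
  expect_error(oeamc_config(2, sigma0 = diag(2), n = 5))
})

test_that("proposals are Gaussian with the requested covariance", {
  set.seed(31)
  Z <- propose(c(5, -5), diag(2), n = 1e5)
  v <- apply(sweep(Z, 2, c(5, -5)), 2, stats::var)
  expect_true(all(abs(v - 1) < 0.02))
  expect_error(propose(c(0, 0), matrix(c(1, 2, 2, 1), 2)), "positive")
})

test_that("clustered cover volume prefers separated clusters and flags
           insufficient input", {
  set.seed(32)
  # two well-separated balls: k = 2 beats k = 1
  b1 <- sample_in_ellipsoid(ellipsoid(c(0, 0), diag(2)), 300)
  b2 <- sample_in_ellipsoid(ellipsoid(c(8, 0), diag(2)), 300)
  v2 <- clustered_cover_volume(rbind(b1, b2), k_max = 4)
  e_single <- mvee(rbind(b1, b2))
  expect_lt(v2, ellipsoid_volume(e_single))
  # one dense ball, k forced to 1: approaches the ball volume from below
  v1 <- clustered_cover_volume(b1, k_max = 1)
  expect_gt(v1, pi * (1 - 0.1))
  # insufficient points: flagged zero, not an error
  v0 <- clustered_cover_volume(matrix(0, nrow = 2, ncol = 5))
  expect_identical(as.numeric(v0), 0)
  expect_true(attr(v0, "insufficient"))
  # identical points: regularized near-zero volume
  vid <- clustered_cover_volume(matrix(1, nrow = 10, ncol = 2))
  expect_lt(as.numeric(vid), 1e-10)
})

test_that("the fixed-temperature kernel samples exp(-beta E) correctly", {
  # on E = theta^2 the stationary variance is 1/(2 beta)
  pb <- quad_problem(E0 = 1e-300)  # no viable region to speak of
  for (beta in c(0.5, 2)) {
    chain <- metropolis_sample(pb, 0, beta = beta, sigma = matrix(4 / beta),
                               n_iter = 1e6, seed = 40 + beta)
    expect_equal(stats::var(chain[, 1]), 1 / (2 * beta), tolerance = 0.05)
  }
})

test_that("run_oeamc returns viable points only and honest counters", {
  pb <- quad_problem(E0 = 1)  # viable interval (-1, 1) in [-10, 10]
  cfg <- oeamc_config(1, -10, 10, n = 200, max_blocks = 30)
  vs <- run_oeamc(pb, theta0 = 0, cfg, seed = 50)
  expect_gt(n_points(vs), 0)
  expect_true(all(vs$points >= -1 & vs$points <= 1))
  expect_true(all(is_viable(pb, vs$points)))
  tr <- attr(vs, "trace")
  expect_true(all(c("beta", "f_v", "f_a", "cover_volume") %in% names(tr)))
  # nonviable start errors
  expect_error(run_oeamc(pb, theta0 = 5, cfg), "viable starting point")
})

test_that("oeamc recovers the single-shell volume within a factor of two", {
  pb <- shell_problem(5)
  theta0 <- find_viable_seed(pb, seed = 60)
  cfg <- oeamc_config(5, pb$space$lower, pb$space$upper, n = 500,
                      max_blocks = 120)
  vs <- run_oeamc(pb, theta0, cfg, seed = 61)
  vol <- as.numeric(clustered_cover_volume(vs))
  analytic <- shell_volume_analytic(5)
  expect_gt(vol, analytic / 2)
  expect_lt(vol, analytic * 2)
})
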