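# Two-feedback-loop oscillator: ODE right-hand side, integration, period
# detection, cost arithmetic, loop classification, robustness, connectivity.

test_that("the right-hand side matches the model structure", {
  k <- c(0.5, 0, 0, 1, 0.5, 1, 0.5, 1, 0.5, -2, -1, 1)
  kt <- 10^k
  # all-zero state: only the production term of R is active
  r0 <- oscillator_rhs(rep(0, 5), k)
  expect_equal(r0, c(kt[1], 0, 0, 0, 0))
  # Zp = 0 switches the positive loop off: p = k2 exactly
  st <- c(2, 1, 0.3, 0.4, 0)
  r <- oscillator_rhs(st, k)
  expect_equal(r[1], kt[1] - kt[2] * 2)
  # Xp = 1 exhausts the substrate of the first Michaelis-Menten step
  st2 <- c(1, 1, 1, 0, 0)
  r2 <- oscillator_rhs(st2, k)
  expect_equal(r2[3], -kt[5] * 1 / (kt[10] + 1))
})

test_that("period detection handles known signals", {
  t <- seq(0, 50, by = 0.001)
  expect_equal(detect_period(sin(2 * pi * t), t), 1, tolerance = 1e-3)
  expect_equal(detect_period(sin(2 * pi * t / 1.1), t), 1.1,
               tolerance = 1e-3)
  # decaying signal: no sustained oscillation
  expect_true(is.na(detect_period(exp(-t), t)))
  # flat signal: below the amplitude floor
  expect_true(is.na(detect_period(rep(1, length(t)), t)))
  # drifting inter-peak intervals fail the CV test
  chirp <- sin(2 * pi * t * (1 + 0.2 * t / 50))
  expect_true(is.na(detect_period(chirp, t)))
})

test_that("period cost arithmetic is exact on the viability boundary", {
  expect_identical(period_cost(1), 0)
  expect_equal(period_cost(1.1), 1)
  expect_equal(period_cost(0.9), 1)
  expect_identical(period_cost(NA_real_), Inf)
  expect_equal(period_cost(1.05), 0.25)
})

test_that("the reference parameter point oscillates with unit period", {
  k <- osc_reference_params()
  expect_true(all(k >= osc_space()$lower & k <= osc_space()$upper))
  cost <- oscillator_cost(k)
  expect_lt(cost, 1)
  res <- viaspace:::osc_period(k)
  expect_equal(res$period, 1, tolerance = 0.01)
})

test_that("trajectories respect concentration bounds and solver-grid
           invariance", {
  set.seed(100)
  sp <- osc_space()
  K <- sample_box(sp, 30)
  for (i in seq_len(nrow(K))) {
    out <- osc_integrate(K[i, ], t_end = 30, t_record = 0, dt_out = 0.05)
    if (!out$success) next
    expect_true(all(out$y[, c("Xp", "Yp", "Zp")] <= 1 + 1e-6))
    expect_true(all(out$y >= -1e-6))
  }
  # halving the output grid changes the detected period by < 0.1%
  k <- osc_reference_params()
  p1 <- detect_period(osc_integrate(k, dt_out = 0.01)$y[, "Rp"], dt = 0.01,
                      transient_frac = 0)
  p2 <- detect_period(osc_integrate(k, dt_out = 0.02)$y[, "Rp"], dt = 0.02,
                      transient_frac = 0)
  expect_lt(abs(p1 - p2) / p1, 1e-3)
})

test_that("the stiff fallback integrator agrees with the explicit one", {
  k <- osc_reference_params()
  kt <- 10^as.numeric(k)
  a <- viaspace:::.osc_integrate_cpp(kt, 60, 50, 0.01, 1e-8, 1e-10, 100000L,
                                     0L, 0, 0L, 0, rep(0, 5))
  b <- viaspace:::.osc_integrate_sdirk_cpp(kt, 60, 50, 0.01, 1e-8, 1e-10,
                                           200000L, 0L, 0, 0L, 0, rep(0, 5))
  expect_true(a$success && b$success)
  expect_lt(max(abs(a$y[, 2] - b$y[, 2])), 1e-3)
})

test_that("loop classification is deterministic and respects negligible
           feedback strengths", {
  k <- osc_reference_params()
  lab1 <- classify_loops(k)
  lab2 <- classify_loops(k)
  expect_identical(as.character(lab1), as.character(lab2))
  expect_true(as.character(lab1) %in%
                c("negative-essential", "positive-essential",
                  "both-essential", "neither-essential"))
  # a viable point with k11 at the lower bound has a numerically inactive
  # positive loop: removing it is a no-op, so the positive loop is
  # dispensable and the label cannot be positive- or both-essential
  k_neg <- k
  k_neg["k11"] <- -7
  if (oscillator_cost(k_neg) < 1) {
    lab <- classify_loops(k_neg)
    expect_true(as.character(lab) %in% c("negative-essential",
                                         "neither-essential"))
    expect_true(attr(lab, "detail")$pos_removed)
  }
  expect_error(classify_loops(rep(0, 12)), "viable")
})

test_that("random-walk escape times reflect the viable region size", {
  # synthetic oracle: balls of radius 10 sigma vs 3 sigma around the start
  sigma <- 0.01
  d <- 12
  big <- ball_problem(d, r = 10 * sigma)
  small <- ball_problem(d, r = 3 * sigma)
  m_big <- vapply(1:20, function(s)
    as.numeric(random_walk_robustness(big, rep(0, d), sigma = sigma,
                                      walks = 5, seed = s)), numeric(1))
  m_small <- vapply(1:20, function(s)
    as.numeric(random_walk_robustness(small, rep(0, d), sigma = sigma,
                                      walks = 5, seed = 100 + s)),
    numeric(1))
  expect_gt(mean(m_big), mean(m_small))
  # immediate exit: a start whose entire neighborhood is nonviable
  tiny <- ball_problem(2, r = 1e-9)
  expect_equal(as.numeric(random_walk_robustness(tiny, c(0, 0), sigma = 1,
                                                 walks = 10, seed = 1)), 1)
  expect_error(random_walk_robustness(tiny, c(5, 5), walks = 2), "viable")
})

test_that("connectivity edges require viable interior points", {
  # common convex viable region: edge present
  pb <- ball_problem(2, r = 2)
  g <- connectivity_graph(rbind(c(-1, 0), c(1, 0)), pb, segments = 4)
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$largest_component_fraction, 1)
  # opposite tangent shells: the straight line crosses nonviable interior
  pbs <- shell_problem(3, n_shells = 2)
  spec <- attr(pbs, "shell_spec")
  a <- c(-0.4, 0, 0)            # shell 1, opposite side
  b <- spec$centers[2, ] + c(0.4, 0, 0)  # shell 2, far side
  expect_true(is_viable(pbs, a) && is_viable(pbs, b))
  g2 <- connectivity_graph(rbind(a, b), pbs, segments = 4)
  expect_identical(nrow(g2$edges), 0L)
  expect_equal(g2$largest_component_fraction, 0.5)
  # single node: trivially one component
  g1 <- connectivity_graph(matrix(c(0, 0), 1), pb)
  expect_equal(g1$largest_component_fraction, 1)
})
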