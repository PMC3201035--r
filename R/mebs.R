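#' Configuration for the local multiple ellipsoid-based exploration
#'
#' An expansion starts from a viable point, brackets the viability boundary
#' along every coordinate axis, wraps the resulting `2d` boundary points in
#' their minimum-volume enclosing ellipsoid, and then iterates: sample `n`
#' points uniformly inside the current ellipsoid scaled by `g_i`, keep the
#' viable ones, refit the MVEE, and update `g_i`. The scaling starts below 1
#' (`g0`) to concentrate early samples inside the viable region, jumps above
#' 1 (`g1`) to grow, and afterwards the offset `g - 1` is multiplied by
#' `(1 + p)` when more than `n * b_u` new viable points arrived and by
#' `(1 - p)` when fewer than `n * b_l` did, so that persistent scarcity
#' drives `g` to 1 geometrically and ends the expansion.
#'
#' @param d Dimension (sets the default `n`).
#' @param g0 Initial scaling, in (0, 1).
#' @param g1 Second-iteration scaling, > 1.
#' @param p Offset multiplier, in (0, 1).
#' @param b_l,b_u Viable-yield bounds, `0 < b_l < b_u < 1`.
#' @param n Points sampled per iteration (default `max(100, 20 d)`).
#' @param max_iter Iteration cap per expansion.
#' @param g_tol Convergence tolerance on `|g - 1|`.
#' @param max_expansions Cap on the number of expansions per run.
#' @param k_max,conv_tol,conv_window Stopping-statistic settings shared with
#'   the global stage.
#' @param mvee_tol,mvee_max_points Tolerance and (strided) input-size cap for
#'   the MVEE refit inside an expansion. The refit only *guides* the next
#'   sampling ellipsoid, so a looser fit than [mvee()]'s default changes
#'   nothing statistically while keeping high-dimensional expansions fast.
#' @return An `mebs_config` list.
#' @export
mebs_config <- function(d, g0 = 0.9, g1 = 1.05, p = 0.5,
                        b_l = 0.05, b_u = 0.5,
                        n = max(100L, 20L * d), max_iter = 50,
                        g_tol = 1e-3, max_expansions = 100,
                        k_max = 10, conv_tol = 0.01, conv_window = 3,
                        mvee_tol = 3e-3, mvee_max_points = 800) {
  cfg <- list(g0 = g0, g1 = g1, p = p, b_l = b_l, b_u = b_u,
              n = as.integer(n), max_iter = as.integer(max_iter),
              g_tol = g_tol, max_expansions = as.integer(max_expansions),
              k_max = as.integer(k_max), conv_tol = conv_tol,
              conv_window = as.integer(conv_window),
              mvee_tol = mvee_tol,
              mvee_max_points = as.integer(mvee_max_points))
  validate_mebs_config(cfg)
  structure(cfg, class = "mebs_config")
}

validate_mebs_config <- function(cfg) {
  stopifnot(cfg$g0 > 0, cfg$g0 < 1, cfg$g1 > 1,
            cfg$p > 0, cfg$p < 1,
            cfg$b_l > 0, cfg$b_l < cfg$b_u, cfg$b_u < 1,
            cfg$n >= 1, cfg$max_iter >= 1, cfg$g_tol > 0,
            cfg$max_expansions >= 1, cfg$conv_tol > 0, cfg$conv_window >= 1)
  invisible(cfg)
}

#' Axis scaling update for an ellipsoid expansion
#'
#' @param g_prev Scaling used in the previous iteration.
#' @param new_viable Number of new viable points found in that iteration.
#' @param cfg An [mebs_config()].
#' @param i Iteration index (0-based): `i = 0` returns `g0`, `i = 1`
#'   returns `g1`, afterwards the offset rule applies.
#' @return The scaling factor for iteration `i`.
#' @export
update_scaling <- function(g_prev, new_viable, cfg, i) {
  stopifnot(i >= 0, g_prev > 0)
  if (i == 0) return(cfg$g0)
  if (i == 1) return(cfg$g1)
  if (new_viable > cfg$n * cfg$b_u) {
    g_prev + (g_prev - 1) * cfg$p
  } else if (new_viable < cfg$n * cfg$b_l) {
    g_prev - (g_prev - 1) * cfg$p
  } else {
    g_prev
  }
}

# viability test + cost for a single point, without matrix ceremony
viable_cost1 <- function(problem, x) {
  cost <- eval_cost(problem, x)
  list(viable = cost < problem$threshold, cost = cost)
}

#' Viable points near the viability boundary along the coordinate axes
#'
#' From a viable point, walks along every axis in both directions: doubling
#' steps (initial step 1% of the axis width, clipped at the box edge)
#' bracket the exit from the viable region, then bisection tightens the
#' (viable, nonviable) bracket to a small fraction of the axis width and
#' the viable end is returned. A ray that stays viable all the way to the box edge
#' returns the edge-clipped viable point.
#'
#' @param problem A [viability_problem()].
#' @param theta_v A viable point.
#' @param tol_frac Bisection tolerance as a fraction of the axis width.
#' @return A [viable_set()] of `2d` points (stage `"mebs-boundary"`).
#' @export
find_boundary_points <- function(problem, theta_v, tol_frac = 1e-4) {
  theta_v <- as.numeric(theta_v)
  sp <- problem$space
  v0 <- viable_cost1(problem, theta_v)
  if (!v0$viable) stop("find_boundary_points requires a viable starting point")
  pts <- matrix(NA_real_, nrow = 2 * sp$d, ncol = sp$d)
  costs <- numeric(2 * sp$d)
  row <- 0L
  for (j in seq_len(sp$d)) {
    width <- sp$upper[j] - sp$lower[j]
    for (dir in c(-1, 1)) {
      edge <- if (dir > 0) sp$upper[j] - theta_v[j] else
        theta_v[j] - sp$lower[j]
      step <- min(0.01 * width, edge)
      lo <- 0            # last viable offset along the ray
      lo_cost <- v0$cost
      hi <- NA_real_     # first nonviable offset
      repeat {
        if (step >= edge) step <- edge
        x <- theta_v
        x[j] <- theta_v[j] + dir * step
        vc <- viable_cost1(problem, x)
        if (vc$viable) {
          lo <- step
          lo_cost <- vc$cost
          if (step >= edge) break  # viable through the box edge: clip
          step <- min(2 * step, edge)
        } else {
          hi <- step
          break
        }
      }
      if (!is.na(hi)) {
        while (hi - lo > tol_frac * width) {
          mid <- (lo + hi) / 2
          x <- theta_v
          x[j] <- theta_v[j] + dir * mid
          vc <- viable_cost1(problem, x)
          if (vc$viable) {
            lo <- mid
            lo_cost <- vc$cost
          } else {
            hi <- mid
          }
        }
      }
      x <- theta_v
      x[j] <- theta_v[j] + dir * lo
      row <- row + 1L
      pts[row, ] <- x
      costs[row] <- lo_cost
    }
  }
  viable_set(pts, costs, "mebs-boundary")
}

#' One ellipsoid expansion around a viable point
#'
#' Boundary points seed the first MVEE; each iteration samples `cfg$n`
#' points uniformly inside the scaled ellipsoid, adds those that are viable
#' (and inside the box) to the running set, refits the MVEE of all points
#' found, and updates the scaling. Stops when `|g - 1| < cfg$g_tol` or after
#' `cfg$max_iter` iterations.
#'
#' @param problem A [viability_problem()].
#' @param theta_v Viable starting point.
#' @param cfg An [mebs_config()].
#' @param seed Optional RNG seed.
#' @return A [viable_set()] (boundary + expansion points) with attributes
#'   `g_trajectory`, `new_viable` (per iteration) and `ellipsoid` (the final
#'   MVEE).
#' @export
ellipsoid_expansion <- function(problem, theta_v, cfg = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- problem$space
  if (is.null(cfg)) cfg <- mebs_config(sp$d)
  validate_mebs_config(cfg)
  bp <- find_boundary_points(problem, theta_v)
  vset <- vs_bind(bp, viable_set(theta_v, eval_cost(problem, theta_v),
                                 "mebs-expansion", 0L))
  fit_L <- function(pts) {
    n <- nrow(pts)
    if (n > cfg$mvee_max_points) {
      idx <- unique(round(seq(1, n, length.out = cfg$mvee_max_points)))
      pts <- pts[idx, , drop = FALSE]
    }
    mvee(pts, tolerance = cfg$mvee_tol, max_iter = 3e4)
  }
  L <- fit_L(vset$points)
  g <- cfg$g0
  g_traj <- numeric(0)
  nv_traj <- integer(0)
  i <- 0L
  repeat {
    g_traj <- c(g_traj, g)
    S <- scale_ellipsoid(L, g)
    X <- sample_in_ellipsoid(S, cfg$n)
    costs <- eval_cost(problem, X)       # out-of-box rows get +Inf uncounted
    viable <- costs < problem$threshold
    nv <- sum(viable)
    nv_traj <- c(nv_traj, nv)
    if (nv > 0) {
      vset <- vs_bind(vset, viable_set(X[viable, , drop = FALSE],
                                       costs[viable], "mebs-expansion",
                                       i + 1L))
      L <- fit_L(vset$points)
    }
    i <- i + 1L
    g <- update_scaling(g, nv, cfg, i)
    if (abs(g - 1) < cfg$g_tol || i >= cfg$max_iter) break
  }
  attr(vset, "g_trajectory") <- g_traj
  attr(vset, "new_viable") <- nv_traj
  attr(vset, "ellipsoid") <- L
  vset
}

#' Select the next expansion start far from previous starts
#'
#' Computes the mean of the previous starting points (or of the candidates
#' themselves if there are none) and draws uniformly among the top decile of
#' candidates by Euclidean distance from that mean. Randomizing within the
#' top decile avoids re-selecting the same extreme point over and over.
#'
#' @param candidates A [viable_set()] or matrix of candidate points.
#' @param previous_starts Matrix (possibly 0-row) of earlier start points.
#' @param seed Optional RNG seed.
#' @return A length-`d` point.
#' @export
select_next_start <- function(candidates, previous_starts = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(candidates, "viable_set")) candidates <- candidates$points
  candidates <- as.matrix(candidates)
  if (nrow(candidates) == 0L) stop("select_next_start: no candidates")
  ref <- if (is.null(previous_starts) || NROW(previous_starts) == 0L) {
    colMeans(candidates)
  } else {
    colMeans(as_point_matrix(previous_starts, ncol(candidates)))
  }
  dist <- sqrt(rowSums(sweep(candidates, 2, ref)^2))
  n_top <- max(1L, ceiling(nrow(candidates) / 10))
  top <- order(dist, decreasing = TRUE)[seq_len(n_top)]
  candidates[top[sample.int(n_top, 1L)], ]
}

#' Local exploration by repeated ellipsoid expansions
#'
#' Alternates [select_next_start()] and [ellipsoid_expansion()], pooling all
#' viable points (seeds included). Stops when the clustered-cover volume of
#' the pooled set changes by less than `cfg$conv_tol` for `cfg$conv_window`
#' consecutive expansions, or at `cfg$max_expansions`.
#'
#' @param problem A [viability_problem()].
#' @param seeds A non-empty [viable_set()] or matrix of viable points
#'   (typically the output of [run_oeamc()]).
#' @param cfg An [mebs_config()].
#' @param seed Optional RNG seed.
#' @param verbose Print per-expansion progress lines.
#' @param stop_when Optional predicate `function(pooled_viable_set)`;
#'   when it returns `TRUE` after an expansion, the run stops immediately.
#'   Discovery studies (has a second region been found yet?) use this to
#'   avoid paying for full volume convergence once the answer is fixed.
#' @return The pooled [viable_set()] with attributes `trace` (per-expansion
#'   data frame) and `converged`.
#' @export
run_mebs <- function(problem, seeds, cfg = NULL, seed = NULL,
                     verbose = FALSE, stop_when = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- problem$space
  if (is.null(cfg)) cfg <- mebs_config(sp$d)
  validate_mebs_config(cfg)
  if (!inherits(seeds, "viable_set")) {
    seeds <- as_point_matrix(seeds, sp$d)
    seeds <- viable_set(seeds, eval_cost(problem, seeds), "oeamc")
  }
  if (n_points(seeds) == 0L) stop("run_mebs needs at least one seed point")

  pooled <- seeds
  starts <- matrix(numeric(), nrow = 0, ncol = sp$d)
  prev_vol <- NA_real_
  prev_k <- NULL
  streak <- 0L
  converged <- FALSE
  trace <- vector("list", cfg$max_expansions)

  for (j in seq_len(cfg$max_expansions)) {
    start <- select_next_start(pooled, starts)
    starts <- rbind(starts, start)
    exp_j <- ellipsoid_expansion(problem, start, cfg)
    exp_j$block <- rep(j, n_points(exp_j))
    pooled <- vs_bind(pooled, exp_j)
    k_set <- if (is.null(prev_k)) NULL else (prev_k - 1L):(prev_k + 1L)
    vol <- clustered_cover_volume(pooled, k_max = cfg$k_max, k_set = k_set)
    prev_k <- attr(vol, "k")
    if (!isTRUE(attr(vol, "insufficient")) && vol > 0 &&
        is.finite(prev_vol) && prev_vol > 0 &&
        abs(vol - prev_vol) / prev_vol < cfg$conv_tol) {
      streak <- streak + 1L
    } else {
      streak <- 0L
    }
    prev_vol <- as.numeric(vol)
    trace[[j]] <- data.frame(
      expansion = j, iterations = length(attr(exp_j, "g_trajectory")),
      g_final = utils::tail(attr(exp_j, "g_trajectory"), 1),
      new_points = n_points(exp_j), pooled_points = n_points(pooled),
      cover_volume = as.numeric(vol), evaluations = evaluations(problem))
    if (verbose) {
      message(sprintf("expansion %d: +%d points, pooled=%d, cover=%.4g",
                      j, n_points(exp_j), n_points(pooled), as.numeric(vol)))
    }
    if (streak >= cfg$conv_window) {
      converged <- TRUE
      break
    }
    if (!is.null(stop_when) && isTRUE(stop_when(pooled))) break
  }
  attr(pooled, "trace") <- do.call(rbind, Filter(Negate(is.null), trace))
  attr(pooled, "converged") <- converged
  attr(pooled, "starts") <- starts
  pooled
}
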