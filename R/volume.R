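#' Overlap-once integrand over an ellipsoid cover
#'
#' For a point drawn uniformly from ellipsoid `i` of the cover, the
#' integrand credits the point to the *first* ellipsoid (in the cover's
#' fixed, descending-volume order) that contains it: it returns 0 if the
#' point lies in any earlier ellipsoid or outside the box, and the viability
#' indicator otherwise. Summing per-ellipsoid integrals of this integrand
#' counts every region of the union exactly once.
#'
#' @param cover An `ellipsoid_cover` from [build_cover()].
#' @param i Index of the ellipsoid the point was drawn from.
#' @param point A single point (vector) or matrix of points.
#' @param problem A [viability_problem()].
#' @return Numeric 0/1 value(s) of the integrand.
#' @export
overlap_once_indicator <- function(cover, i, point, problem) {
  x <- as_point_matrix(point, problem$space$d)
  f <- numeric(nrow(x))
  fresh <- rep(TRUE, nrow(x))
  if (i > 1) {
    for (j in seq_len(i - 1)) {
      todo <- which(fresh)
      if (!length(todo)) break
      fresh[todo] <- !in_ellipsoid(cover$ellipsoids[[j]],
                                   x[todo, , drop = FALSE])
    }
  }
  fresh <- fresh & in_space(problem$space, x)
  idx <- which(fresh)
  if (length(idx)) {
    f[idx] <- as.numeric(is_viable(problem, x[idx, , drop = FALSE]))
  }
  f
}

#' Stratified Monte Carlo estimate of the viable volume over a cover
#'
#' Allocates `m_i` of the `N` samples to ellipsoid `i` proportionally to its
#' volume (largest-remainder rounding, at least 1 each), samples uniformly
#' inside each ellipsoid, and evaluates the overlap-once integrand. The
#' estimate is `sum_i Vol(W_i) * <f_i>`; the standard error combines the
#' per-ellipsoid (stratified) variance terms in quadrature:
#' `sqrt(sum_i Vol(W_i)^2 (<f_i^2> - <f_i>^2) / m_i)`. Points with
#' `f_i = 1` form a uniform sample of the viable region covered by the
#' union, returned as a [viable_set()].
#'
#' @param cover An `ellipsoid_cover` from [build_cover()].
#' @param problem A [viability_problem()].
#' @param N Total number of samples (`>= 10 * k`).
#' @param seed Optional RNG seed.
#' @param keep_costs Store cost values of the viable sample (they are known
#'   from the integrand evaluation at no extra cost).
#' @return An object of class `volume_estimate`: `volume`, `stderr`, `N`,
#'   `m_i`, `viable_points` (uniform viable sample), `domain_volume` (Monte
#'   Carlo estimate of the union's volume) and `box_ratio`
#'   (box volume / domain volume).
#' @export
estimate_volume <- function(cover, problem, N, seed = NULL,
                            keep_costs = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(cover$ellipsoids)
  if (N < 10 * k) stop("N must be at least 10 * k")
  vols <- cover$volumes
  m <- largest_remainder_alloc(N, vols)

  volume <- 0
  var_sum <- 0
  union_vol <- 0
  viable_list <- vector("list", k)
  cost_list <- vector("list", k)
  for (i in seq_len(k)) {
    e <- cover$ellipsoids[[i]]
    X <- sample_in_ellipsoid(e, m[i])
    # fresh = not claimed by an earlier ellipsoid, and inside the box
    fresh <- in_space(problem$space, X)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        todo <- which(fresh)
        if (!length(todo)) break
        fresh[todo] <- !in_ellipsoid(cover$ellipsoids[[j]],
                                     X[todo, , drop = FALSE])
      }
    }
    f <- numeric(m[i])
    idx <- which(fresh)
    costs <- NULL
    if (length(idx)) {
      costs <- eval_cost(problem, X[idx, , drop = FALSE])
      f[idx] <- as.numeric(costs < problem$threshold)
    }
    fbar <- mean(f)
    # f is an indicator, so <f^2> = <f>
    volume <- volume + vols[i] * fbar
    var_sum <- var_sum + vols[i]^2 * (fbar - fbar^2) / m[i]
    union_vol <- union_vol + vols[i] * mean(fresh)
    vi <- which(f == 1)
    if (length(vi)) {
      viable_list[[i]] <- X[vi, , drop = FALSE]
      if (keep_costs && !is.null(costs)) {
        cost_list[[i]] <- costs[match(vi, idx)]
      }
    }
  }
  pts <- Filter(Negate(is.null), viable_list)
  vset <- if (length(pts)) {
    viable_set(do.call(rbind, pts),
               unlist(cost_list, use.names = FALSE), "integration")
  } else {
    viable_set()
  }
  box_vol <- space_volume(problem$space)
  structure(
    list(volume = volume, stderr = sqrt(var_sum), N = N, m_i = m,
         viable_points = vset, domain_volume = union_vol,
         box_ratio = box_vol / union_vol,
         cover_volume = sum(vols)),
    class = "volume_estimate"
  )
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat("volume_estimate:", format(x$volume), "+/-", format(x$stderr),
      " (N =", x$N, ",", length(x$m_i), "ellipsoids)\n")
  cat("  domain volume:", format(x$domain_volume),
      "; box / domain ratio:", format(x$box_ratio), "\n")
  cat("  uniform viable sample:", n_points(x$viable_points), "points\n")
  invisible(x)
}

# m_i proportional to weights, summing exactly to N, each at least 1
largest_remainder_alloc <- function(N, weights) {
  k <- length(weights)
  if (N < k) stop("cannot allocate fewer samples than strata")
  w <- weights / sum(weights)
  raw <- w * (N - k)           # reserve the floor of 1 per stratum
  m <- floor(raw)
  rem <- N - k - sum(m)
  if (rem > 0) {
    frac <- raw - m
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    m[add] <- m[add] + 1
  }
  as.integer(m + 1)
}

#' Brute-force Monte Carlo estimate of the viable volume
#'
#' Samples `N` points uniformly over the whole box and applies the plain
#' Monte Carlo integration estimator with its standard error. This is the
#' baseline every efficiency comparison is made against; in high dimension
#' its viable-hit probability collapses with the viable fraction of the box.
#'
#' @param problem A [viability_problem()].
#' @param N Number of uniform samples.
#' @param seed Optional RNG seed.
#' @param chunk Evaluate in chunks of this size to bound memory.
#' @return A `volume_estimate` (with `domain_volume` = box volume). When no
#'   viable point is sampled the estimate and stderr are both 0 and the
#'   result carries attribute `degenerate = TRUE`.
#' @export
brute_force_volume <- function(problem, N, seed = NULL, chunk = 200000L) {
  if (!is.null(seed)) set.seed(seed)
  box_vol <- space_volume(problem$space)
  n_hit <- 0
  pts <- list()
  costs <- list()
  done <- 0L
  while (done < N) {
    nn <- min(chunk, N - done)
    X <- sample_box(problem$space, nn)
    cst <- eval_cost(problem, X)
    v <- cst < problem$threshold
    n_hit <- n_hit + sum(v)
    if (any(v)) {
      pts[[length(pts) + 1L]] <- X[v, , drop = FALSE]
      costs[[length(costs) + 1L]] <- cst[v]
    }
    done <- done + nn
  }
  fbar <- n_hit / N
  est <- box_vol * fbar
  se <- box_vol * sqrt((fbar - fbar^2) / N)
  vset <- if (length(pts)) {
    viable_set(do.call(rbind, pts), unlist(costs), "integration")
  } else {
    viable_set()
  }
  structure(
    list(volume = est, stderr = se, N = N, m_i = N,
         viable_points = vset, domain_volume = box_vol, box_ratio = 1,
         cover_volume = box_vol),
    class = "volume_estimate",
    degenerate = n_hit == 0
  )
}
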