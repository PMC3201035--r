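#' Configuration for the global adaptive Metropolis exploration
#'
#' The global stage runs blocks of `n` Metropolis iterations with Gaussian
#' proposals of covariance `Sigma` and acceptance inverse temperature
#' `beta`. After every block it multiplies or divides `beta` by `b`
#' depending on the block's viable-hit fraction `f_v` (target: small but
#' nonzero, at most `f0`) and `Sigma` by `s` depending on the acceptance
#' fraction `f_a` (target: inside `(f_l, f_u]`). The published update rule
#' fixes the branch structure but no numeric values; the defaults below
#' bracket the classical ~0.23 Metropolis acceptance optimum and use
#' symmetric powers of two for the up/down moves.
#'
#' @param d Dimension of the parameter space.
#' @param lower,upper Box bounds (used for the default proposal scale).
#' @param beta0 Initial inverse temperature (> 0).
#' @param sigma0 Initial proposal covariance; default
#'   `diag((0.05 * (upper - lower))^2)`.
#' @param b Multiplier for `beta` (> 1).
#' @param s Multiplier for `Sigma` (> 1).
#' @param f0 Maximum tolerated viable-hit frequency, in (0, 1).
#' @param f_l,f_u Acceptance-rate band, `0 < f_l < f_u < 1`.
#' @param n Iterations per adaptation block (>= 10).
#' @param max_blocks Hard cap on the number of blocks.
#' @param k_max Cluster scan limit for the stopping statistic.
#' @param conv_tol Relative tolerance on the cover-volume statistic.
#' @param conv_window Consecutive converged blocks required to stop.
#' @return An `oeamc_config` list.
#' @export
oeamc_config <- function(d, lower = NULL, upper = NULL,
                         beta0 = 1,
                         sigma0 = NULL,
                         b = 2, s = 2,
                         f0 = 0.2, f_l = 0.2, f_u = 0.5,
                         n = 1000, max_blocks = 200,
                         k_max = 10, conv_tol = 0.01, conv_window = 3) {
  if (is.null(sigma0)) {
    if (is.null(lower) || is.null(upper))
      stop("either sigma0 or box bounds must be given")
    sigma0 <- diag((0.05 * (upper - lower))^2, d)
  }
  cfg <- list(beta0 = beta0, sigma0 = sigma0, b = b, s = s, f0 = f0,
              f_l = f_l, f_u = f_u, n = as.integer(n),
              max_blocks = as.integer(max_blocks), k_max = as.integer(k_max),
              conv_tol = conv_tol, conv_window = as.integer(conv_window))
  validate_oeamc_config(cfg, d)
  structure(cfg, class = "oeamc_config")
}

validate_oeamc_config <- function(cfg, d) {
  stopifnot(cfg$beta0 > 0, cfg$b > 1, cfg$s > 1,
            cfg$f0 > 0, cfg$f0 < 1,
            cfg$f_l > 0, cfg$f_l < cfg$f_u, cfg$f_u < 1,
            cfg$n >= 10, cfg$max_blocks >= 1,
            cfg$conv_tol > 0, cfg$conv_window >= 1)
  if (!all(dim(as.matrix(cfg$sigma0)) == d))
    stop("sigma0 must be a ", d, " x ", d, " matrix")
  invisible(cfg)
}

#' Gaussian random-walk proposal
#'
#' @param current Current point (length-`d`).
#' @param sigma Positive-definite proposal covariance.
#' @param n Number of proposals to draw.
#' @return An `n x d` matrix `current + z`, `z ~ N(0, sigma)`. The proposal
#'   density is symmetric in its two arguments, as Metropolis requires.
#' @export
propose <- function(current, sigma, n = 1) {
  sigma <- as.matrix(sigma)
  R <- tryCatch(chol(sigma), error = function(e)
    stop("proposal covariance must be positive definite"))
  d <- length(current)
  z <- matrix(stats::rnorm(n * d), nrow = n) %*% R
  sweep(z, 2, current, `+`)
}

#' Metropolis acceptance probability
#'
#' @param delta_E Cost increment `E(proposal) - E(current)`; may be `+Inf`
#'   (e.g. the proposal does not oscillate at all).
#' @param beta Inverse temperature (> 0).
#' @return `1` if `delta_E <= 0`, else `exp(-beta * delta_E)` (so `0` at
#'   `+Inf`). Vectorized over `delta_E`.
#' @export
acceptance_probability <- function(delta_E, beta) {
  stopifnot(beta > 0)
  p <- ifelse(delta_E <= 0, 1, exp(-beta * delta_E))
  p[is.infinite(delta_E) & delta_E > 0] <- 0
  p
}

#' Joint adaptation of inverse temperature and proposal covariance
#'
#' Applies the two multiplicative updates independently in the same block:
#' `beta` is multiplied by `b` when the block found no viable point, kept
#' when `0 < f_v <= f0`, divided by `b` when `f_v > f0`; `Sigma` is
#' multiplied by `s` when `f_a > f_u`, kept when `f_l < f_a <= f_u`, divided
#' by `s` when `f_a < f_l` (scalar multiplication of the whole matrix).
#'
#' @param beta Current inverse temperature.
#' @param sigma Current proposal covariance.
#' @param f_v Fraction of the block's proposals that were viable.
#' @param f_a Fraction of accepted transitions in the block.
#' @param cfg An [oeamc_config()].
#' @return List with updated `beta` and `sigma`.
#' @export
adapt <- function(beta, sigma, f_v, f_a, cfg) {
  stopifnot(f_v >= 0, f_v <= 1, f_a >= 0, f_a <= 1)
  beta2 <- if (f_v == 0) cfg$b * beta else if (f_v <= cfg$f0) beta else
    beta / cfg$b
  sigma2 <- if (f_a > cfg$f_u) cfg$s * sigma else
    if (f_a > cfg$f_l) sigma else sigma / cfg$s
  list(beta = beta2, sigma = sigma2)
}

# One block of n Metropolis iterations. Proposals falling outside the box
# are rejected without a cost evaluation (and count as nonviable, rejected
# transitions). Every viable *proposed* point is recorded, accepted or not.
metropolis_block <- function(problem, current, current_cost, n, sigma, beta) {
  sp <- problem$space
  d <- sp$d
  lower <- sp$lower
  upper <- sp$upper
  cost_fn <- problem$cost
  R <- chol(as.matrix(sigma))
  Z <- matrix(stats::rnorm(n * d), nrow = n) %*% R
  U <- stats::runif(n)
  E0 <- problem$threshold
  viable_pts <- matrix(NA_real_, nrow = n, ncol = d)
  viable_costs <- numeric(n)
  nv <- 0L
  n_acc <- 0L
  n_out <- 0L
  n_eval <- 0L
  for (i in seq_len(n)) {
    prop <- current + Z[i, ]
    if (any(prop < lower) || any(prop > upper)) {
      n_out <- n_out + 1L
      next
    }
    cost <- cost_fn(prop)
    n_eval <- n_eval + 1L
    if (is.na(cost)) cost <- Inf
    if (cost < E0) {
      nv <- nv + 1L
      viable_pts[nv, ] <- prop
      viable_costs[nv] <- cost
    }
    delta <- cost - current_cost
    if (delta <= 0 || U[i] < exp(-beta * delta)) {
      current <- prop
      current_cost <- cost
      n_acc <- n_acc + 1L
    }
  }
  problem$counter$n <- problem$counter$n + n_eval
  pts <- if (nv) viable_pts[seq_len(nv), , drop = FALSE] else NULL
  list(current = current, current_cost = current_cost,
       viable_points = pts, viable_costs = viable_costs[seq_len(nv)],
       f_v = nv / n, f_a = n_acc / n, n_out = n_out)
}

#' Plain fixed-temperature Metropolis sampler
#'
#' The chain the adaptive explorer reduces to when both adaptations are
#' switched off: a standard Metropolis sampler of `exp(-beta * E)` on the
#' box. Exposed mainly so the sampling kernel can be validated against
#' closed-form stationary distributions.
#'
#' @param problem A [viability_problem()] (only its box and cost are used).
#' @param theta0 Starting point.
#' @param beta Fixed inverse temperature.
#' @param sigma Fixed proposal covariance.
#' @param n_iter Number of iterations.
#' @param seed Optional RNG seed.
#' @param thin Keep every `thin`-th state.
#' @return Matrix of sampled chain states.
#' @export
metropolis_sample <- function(problem, theta0, beta, sigma, n_iter,
                              seed = NULL, thin = 1L) {
  if (!is.null(seed)) set.seed(seed)
  sp <- problem$space
  d <- sp$d
  R <- chol(as.matrix(sigma))
  Z <- matrix(stats::rnorm(n_iter * d), ncol = d) %*% R
  U <- stats::runif(n_iter)
  cur <- as.numeric(theta0)
  cur_cost <- eval_cost(problem, cur)
  keep <- matrix(NA_real_, nrow = floor(n_iter / thin), ncol = d)
  ki <- 0L
  for (i in seq_len(n_iter)) {
    prop <- cur + Z[i, ]
    if (!(any(prop < sp$lower) || any(prop > sp$upper))) {
      cost <- eval_cost(problem, prop)
      delta <- cost - cur_cost
      if (delta <= 0 || U[i] < exp(-beta * delta)) {
        cur <- prop
        cur_cost <- cost
      }
    }
    if (i %% thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- cur
    }
  }
  keep[seq_len(ki), , drop = FALSE]
}

#' Global exploration by out-of-equilibrium adaptive Metropolis sampling
#'
#' Runs adaptation blocks of `cfg$n` Metropolis iterations from a viable
#' starting point, recording every viable point proposed (accepted or not).
#' After each block the viable-hit and acceptance fractions drive the joint
#' `beta`/`Sigma` adaptation, and the clustered-cover volume of all viable
#' points found so far serves as the stopping statistic: the run ends when
#' its relative change stays below `cfg$conv_tol` for `cfg$conv_window`
#' consecutive blocks, or at `cfg$max_blocks`.
#'
#' The chain deliberately stays out of equilibrium: it continually re-tunes
#' the temperature so that viable hits stay rare but nonzero, which lets it
#' traverse moderately costly nonviable territory between poorly connected
#' viable regions.
#'
#' @param problem A [viability_problem()].
#' @param theta0 Viable starting point; if `NULL`, [find_viable_seed()] is
#'   invoked first.
#' @param cfg An [oeamc_config()]; defaults built from the problem if `NULL`.
#' @param seed Optional RNG seed.
#' @param verbose Print per-block progress lines.
#' @return A [viable_set()] (stage `"oeamc"`, block index per point) with
#'   attributes `trace` (per-block data frame: beta, mean proposal sd, f_v,
#'   f_a, cover volume, evaluations) and `converged`.
#' @export
run_oeamc <- function(problem, theta0 = NULL, cfg = NULL, seed = NULL,
                      verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sp <- problem$space
  if (is.null(cfg)) cfg <- oeamc_config(sp$d, sp$lower, sp$upper)
  validate_oeamc_config(cfg, sp$d)
  if (is.null(theta0)) theta0 <- find_viable_seed(problem)
  theta0 <- as.numeric(theta0)
  cost0 <- eval_cost(problem, theta0)
  if (!(cost0 < problem$threshold))
    stop("run_oeamc requires a viable starting point")

  beta <- cfg$beta0
  sigma <- as.matrix(cfg$sigma0)
  cur <- theta0
  cur_cost <- cost0
  found <- viable_set(theta0, cost0, "oeamc", 0L)
  prev_vol <- NA_real_
  prev_k <- NULL
  streak <- 0L
  converged <- FALSE
  trace <- vector("list", cfg$max_blocks)

  for (blk in seq_len(cfg$max_blocks)) {
    res <- metropolis_block(problem, cur, cur_cost, cfg$n, sigma, beta)
    cur <- res$current
    cur_cost <- res$current_cost
    if (!is.null(res$viable_points)) {
      found <- vs_bind(found, viable_set(res$viable_points, res$viable_costs,
                                         "oeamc", blk))
    }
    if (!is.null(res$viable_points) || is.null(prev_k)) {
      k_set <- if (is.null(prev_k)) NULL else (prev_k - 1L):(prev_k + 1L)
      vol <- clustered_cover_volume(found, k_max = cfg$k_max, k_set = k_set)
      prev_k <- attr(vol, "k")
    }  # else: the viable set did not grow, so the statistic is unchanged
    if (!isTRUE(attr(vol, "insufficient")) && vol > 0 &&
        is.finite(prev_vol) && prev_vol > 0) {
      if (abs(vol - prev_vol) / prev_vol < cfg$conv_tol) {
        streak <- streak + 1L
      } else {
        streak <- 0L
      }
    } else {
      streak <- 0L
    }
    prev_vol <- as.numeric(vol)
    trace[[blk]] <- data.frame(
      block = blk, beta = beta, sigma_scale = sqrt(mean(diag(sigma))),
      f_v = res$f_v, f_a = res$f_a, cover_volume = as.numeric(vol),
      n_viable = n_points(found), evaluations = evaluations(problem))
    if (verbose) {
      message(sprintf(
        "block %d: beta=%.3g f_v=%.3f f_a=%.3f cover=%.4g viable=%d",
        blk, beta, res$f_v, res$f_a, as.numeric(vol), n_points(found)))
    }
    if (streak >= cfg$conv_window) {
      converged <- TRUE
      break
    }
    upd <- adapt(beta, sigma, res$f_v, res$f_a, cfg)
    beta <- upd$beta
    sigma <- upd$sigma
  }

  attr(found, "trace") <- do.call(rbind, Filter(Negate(is.null), trace))
  attr(found, "converged") <- converged
  attr(found, "beta") <- beta
  found
}
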