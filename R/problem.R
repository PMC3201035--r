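#' Box-bounded parameter space
#'
#' Defines the search domain as a product of closed intervals, one per model
#' parameter. All exploration, sampling and volume estimation in this package
#' happens inside such a box; points outside it are nonviable by definition.
#'
#' @param lower,upper Numeric vectors of equal length `d` with
#'   `lower < upper` componentwise. Units are whatever the cost function
#'   expects (often log10 of rate constants).
#' @param names Optional parameter names (default `theta1..thetad`).
#' @return An object of class `parameter_space` with elements `lower`,
#'   `upper`, `d`, `names`.
#' @export
parameter_space <- function(lower, upper, names = NULL) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L)
    stop("lower and upper must be non-empty vectors of equal length")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper))
    stop("every dimension needs lower < upper")
  if (is.null(names)) names <- paste0("theta", seq_along(lower))
  structure(
    list(lower = lower, upper = upper, d = length(lower), names = names),
    class = "parameter_space"
  )
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("parameter_space: d =", x$d, "\n")
  cat("  total volume:", format(space_volume(x)), "\n")
  invisible(x)
}

#' Total volume of a parameter space
#'
#' @param space A [parameter_space()].
#' @return `prod(upper - lower)`, strictly positive and finite.
#' @export
space_volume <- function(space) {
  prod(space$upper - space$lower)
}

#' Test whether points lie inside the box
#'
#' @param space A [parameter_space()].
#' @param x A length-`d` vector or an `n x d` matrix of points.
#' @return Logical scalar or length-`n` vector.
#' @export
in_space <- function(space, x) {
  x <- as_point_matrix(x, space$d)
  ok <- rep(TRUE, nrow(x))
  for (j in seq_len(space$d)) {
    ok <- ok & x[, j] >= space$lower[j] & x[, j] <= space$upper[j]
  }
  ok
}

as_point_matrix <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d) stop("point has dimension ", length(x),
                             ", expected ", d)
    x <- matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != d) stop("points have dimension ", ncol(x),
                           ", expected ", d)
  }
  storage.mode(x) <- "double"
  x
}

#' Viability problem
#'
#' Bundles a box-bounded parameter space, a non-negative cost function
#' `E(theta)` and a positive viability threshold `E0`. A point is viable iff
#' it lies inside the box and `E(theta) < E0` (strict inequality; benchmark
#' problems whose published viability condition is `<=` place `E0`
#' infinitesimally above the printed bound, which leaves every volume
#' unchanged). Cost evaluations are counted, and the counter is the common
#' currency for all efficiency comparisons between methods.
#'
#' @param space A [parameter_space()].
#' @param cost Function mapping a length-`d` vector to a value in
#'   `[0, Inf]`; `+Inf` encodes qualitative failure (e.g. no oscillation).
#' @param threshold Positive viability threshold `E0`.
#' @param cost_matrix Optional vectorized form: function mapping an `n x d`
#'   matrix to a length-`n` cost vector. Used as a fast path by samplers;
#'   must agree with `cost` row by row.
#' @param name Label used in serialized outputs.
#' @return An object of class `viability_problem`.
#' @export
viability_problem <- function(space, cost, threshold, cost_matrix = NULL,
                              name = "custom") {
  stopifnot(inherits(space, "parameter_space"), is.function(cost))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold E0 must be a positive scalar")
  counter <- new.env(parent = emptyenv())
  counter$n <- 0
  structure(
    list(space = space, cost = cost, threshold = threshold,
         cost_matrix = cost_matrix, name = name, counter = counter),
    class = "viability_problem"
  )
}

#' @export
print.viability_problem <- function(x, ...) {
  cat("viability_problem '", x$name, "': d = ", x$space$d,
      ", E0 = ", format(x$threshold),
      ", evaluations = ", x$counter$n, "\n", sep = "")
  invisible(x)
}

#' Number of cost evaluations performed so far
#' @param problem A [viability_problem()].
#' @return Non-negative integer count.
#' @export
evaluations <- function(problem) problem$counter$n

#' Reset the evaluation counter to zero
#' @param problem A [viability_problem()].
#' @return The problem, invisibly.
#' @export
reset_evaluations <- function(problem) {
  problem$counter$n <- 0
  invisible(problem)
}

#' Evaluate the cost function (counted)
#'
#' Rows outside the box get `+Inf` without an evaluation (a point outside
#' the domain is nonviable by definition, so its cost is never needed and
#' expensive model solves are saved).
#'
#' @param problem A [viability_problem()].
#' @param x A length-`d` vector or `n x d` matrix.
#' @return Numeric vector of costs, `+Inf` for out-of-box rows.
#' @export
eval_cost <- function(problem, x) {
  x <- as_point_matrix(x, problem$space$d)
  inside <- in_space(problem$space, x)
  out <- rep(Inf, nrow(x))
  idx <- which(inside)
  if (length(idx)) {
    xi <- x[idx, , drop = FALSE]
    if (!is.null(problem$cost_matrix)) {
      v <- problem$cost_matrix(xi)
    } else {
      v <- vapply(seq_len(nrow(xi)), function(i) problem$cost(xi[i, ]),
                  numeric(1))
    }
    if (any(v < 0, na.rm = TRUE)) stop("cost function returned a negative value")
    v[is.na(v)] <- Inf
    out[idx] <- v
    problem$counter$n <- problem$counter$n + length(idx)
  }
  out
}

#' Viability predicate
#'
#' @param problem A [viability_problem()].
#' @param x A length-`d` vector or `n x d` matrix of points.
#' @return Logical scalar/vector: inside the box and `cost < E0`.
#' @export
is_viable <- function(problem, x) {
  eval_cost(problem, x) < problem$threshold
}

#' Search for an initial viable point
#'
#' Uniform random multi-starts over the box followed by derivative-free
#' downhill simplex (Nelder-Mead) descent on the cost from the best starts,
#' until a point with `E < E0` is found or the evaluation budget is spent.
#' Out-of-box trial points during the descent are scored `+Inf` (uncounted).
#'
#' @param problem A [viability_problem()].
#' @param budget Maximum number of cost evaluations to spend.
#' @param n_uniform Number of uniform probe points drawn first.
#' @param seed Optional RNG seed.
#' @return A viable length-`d` point.
#' @export
find_viable_seed <- function(problem, budget = 1e4, n_uniform = 200,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- problem$space
  start_evals <- evaluations(problem)
  n_uniform <- min(n_uniform, budget)
  probes <- sample_box(sp, n_uniform)
  costs <- eval_cost(problem, probes)
  best <- order(costs)
  if (costs[best[1]] < problem$threshold)
    return(probes[best[1], ])

  found <- NULL
  fn <- function(th) {
    if (!all(th >= sp$lower & th <= sp$upper)) return(.Machine$double.xmax)
    v <- eval_cost(problem, th)
    if (v < problem$threshold) {
      found <<- th
      stop(structure(class = c("viaspace_seed_found", "condition"),
                     list(message = "", call = NULL)))
    }
    min(v, .Machine$double.xmax)
  }
  for (i in best[seq_len(min(8L, length(best)))]) {
    if (!is.finite(costs[i])) next
    par <- probes[i, ]
    val <- costs[i]
    repeat {  # restart the simplex until viable, stuck, or out of budget
      spent <- evaluations(problem) - start_evals
      if (spent >= budget) break
      res <- tryCatch(
        suppressWarnings(  # d = 1 triggers optim's Nelder-Mead advisory
          stats::optim(par, fn, method = "Nelder-Mead",
                       control = list(maxit = 1000,
                                      reltol = 1e-12))),
        viaspace_seed_found = function(e) NULL
      )
      if (!is.null(found)) return(found)
      if (res$value >= val * (1 - 1e-6)) break  # no further progress
      par <- res$par
      val <- res$value
      if (val < problem$threshold) return(par)
    }
    if (evaluations(problem) - start_evals >= budget) break
  }
  stop("find_viable_seed: no viable point found within the evaluation budget")
}

#' Uniform sample from the box
#'
#' @param space A [parameter_space()].
#' @param n Number of points.
#' @return An `n x d` matrix.
#' @export
sample_box <- function(space, n) {
  d <- space$d
  m <- matrix(stats::runif(n * d), nrow = n)
  sweep(sweep(m, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
}
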