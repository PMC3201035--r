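#' Ellipsoid in d dimensions
#'
#' The set `{theta : (theta - center)' A (theta - center) <= 1}` with `A`
#' symmetric positive definite. Ellipsoids are the geometric unit of the
#' whole package: local sampling grows them around viable points, and the
#' integration domain is a union of them.
#'
#' @param center Numeric length-`d` center.
#' @param shape `d x d` symmetric positive-definite matrix `A`.
#' @return An object of class `ellipsoid`.
#' @export
ellipsoid <- function(center, shape) {
  center <- as.numeric(center)
  shape <- as.matrix(shape)
  d <- length(center)
  if (!all(dim(shape) == d)) stop("shape must be d x d")
  if (max(abs(shape - t(shape))) > 1e-10 * max(1, max(abs(shape))))
    stop("shape matrix must be symmetric (tolerance 1e-10)")
  shape <- (shape + t(shape)) / 2
  # Cholesky is the positive-definiteness test (and is reused for volume
  # and sampling); eigen can misreport tiny negatives on the extremely
  # ill-conditioned shapes that regularized degenerate fits produce
  ok <- tryCatch({ chol(shape); TRUE }, error = function(e) FALSE)
  if (!ok) stop("shape matrix must be positive definite")
  structure(list(center = center, shape = shape, d = d), class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat("ellipsoid: d =", x$d, ", volume =", format(ellipsoid_volume(x)), "\n")
  invisible(x)
}

#' Volume of the d-dimensional unit ball
#'
#' Computed by the recursion `C_0 = 1`, `C_1 = 2`,
#' `C_d = (2 * pi / d) * C_{d-2}`.
#'
#' @param d Non-negative integer dimension.
#' @return Unit-ball volume `C_d`.
#' @export
unit_ball_volume <- function(d) {
  stopifnot(length(d) == 1L, d >= 0, d == round(d))
  if (d == 0) return(1)
  if (d == 1) return(2)
  (2 * pi / d) * unit_ball_volume(d - 2)
}

#' Volume of an ellipsoid
#'
#' `C_d / sqrt(det A)` where `C_d` is the unit-ball volume.
#'
#' @param e An [ellipsoid()].
#' @return Positive volume.
#' @export
ellipsoid_volume <- function(e) {
  R <- tryCatch(chol(e$shape), error = function(err)
    stop("shape matrix is not positive definite"))
  # det(A) = prod(diag(R))^2 ; volume = C_d * prod(1/diag(R))
  unit_ball_volume(e$d) * prod(1 / diag(R))
}

#' Scale an ellipsoid about its center
#'
#' Keeps the center and axis directions; multiplies every semi-axis length
#' by `g`, hence the volume by `g^d`.
#'
#' @param e An [ellipsoid()].
#' @param g Positive scaling factor.
#' @return The scaled [ellipsoid()].
#' @export
scale_ellipsoid <- function(e, g) {
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop("scaling factor g must be a positive scalar")
  ellipsoid(e$center, e$shape / g^2)
}

#' Membership value of points relative to an ellipsoid
#'
#' @param e An [ellipsoid()].
#' @param x Length-`d` vector or `n x d` matrix.
#' @return The quadratic form `(x - c)' A (x - c)` per point; values
#'   `<= 1` lie inside.
#' @export
ellipsoid_membership <- function(e, x) {
  x <- as_point_matrix(x, e$d)
  as.numeric(.ellipsoid_membership_cpp(x, e$center, e$shape))
}

#' Test membership of points in an ellipsoid
#' @param e An [ellipsoid()].
#' @param x Points as vector or matrix.
#' @param tol Slack on the quadratic form (membership `<= 1 + tol`).
#' @return Logical vector.
#' @export
in_ellipsoid <- function(e, x, tol = 0) {
  ellipsoid_membership(e, x) <= 1 + tol
}

#' Minimum-volume enclosing ellipsoid (MVEE)
#'
#' Computes the Lowner-John ellipsoid of a point set by Khachiyan-type
#' barycentric ascent (with away steps and an active-set outer loop for
#' speed). The returned ellipsoid contains every input point, and its volume
#' is within the usual `(1 + tolerance * d)` factor of the optimum.
#'
#' Affinely degenerate point sets (fewer than `d + 1` independent points,
#' e.g. collinear clouds) do not error: the ellipsoid is solved in the
#' affine span and the null directions get a regularizing semi-axis
#' `eps_reg = 1e-6 *` (mean pairwise distance, or `1e-6` if that is zero).
#' Local expansions routinely produce near-coplanar sets early on, so this
#' robustness is load-bearing, not cosmetic.
#'
#' @param points An `n x d` matrix with `n >= 2`.
#' @param tolerance Khachiyan optimality tolerance.
#' @param max_iter Iteration cap for the ascent.
#' @return An [ellipsoid()].
#' @export
mvee <- function(points, tolerance = 1e-7, max_iter = 1e5) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("mvee needs at least 2 points")
  storage.mode(points) <- "double"
  fit <- .mvee_cpp(points, tolerance, as.integer(max_iter))
  ellipsoid(fit$center, fit$shape)
}

#' Uniform sample from the interior of an ellipsoid
#'
#' Draws uniformly in the unit ball (isotropic Gaussian direction, radius
#' `U^(1/d)`) and maps affinely onto the ellipsoid.
#'
#' @param e An [ellipsoid()].
#' @param n Number of points (`>= 1`).
#' @param seed Optional RNG seed.
#' @return An `n x d` matrix of points with membership `<= 1`.
#' @export
sample_in_ellipsoid <- function(e, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  d <- e$d
  z <- matrix(stats::rnorm(n * d), nrow = n)
  norms <- sqrt(rowSums(z^2))
  norms[norms == 0] <- 1
  radii <- stats::runif(n)^(1 / d)
  y <- z * (radii / norms)
  # membership (x-c)'A(x-c) = ||R (x-c)||^2 with A = R'R  =>  x = c + R^{-1} y
  R <- chol(e$shape)
  x <- t(backsolve(R, t(y)))
  sweep(x, 2, e$center, `+`)
}

#' Serialize an ellipsoid to a plain list (for JSON covers)
#' @param e An [ellipsoid()].
#' @return List with `center` and `shape`.
#' @export
ellipsoid_to_list <- function(e) {
  list(center = e$center, shape = unname(as.matrix(e$shape)))
}

#' Rebuild an ellipsoid from its serialized list form
#' @param x List with `center` and `shape` (as written by
#'   [ellipsoid_to_list()]).
#' @return An [ellipsoid()].
#' @export
ellipsoid_from_list <- function(x) {
  sh <- x$shape
  if (!is.matrix(sh)) sh <- do.call(rbind, lapply(sh, as.numeric))
  ellipsoid(as.numeric(x$center), sh)
}
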