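# Clustered ellipsoid covers: the shared stopping statistic of both
# exploration stages and the construction of the integration domain.

# k-means partition of (whitened) points plus per-cluster MVEEs, scanned
# over k = 1..k_max; returns the k minimizing the total enclosed volume.
# Singleton clusters get a tiny regularized ball so every point stays
# covered without dominating the volume sum.
cover_scan <- function(points, k_max = 10, nstart = 10, tolerance = 1e-7,
                       max_iter = 1e5, k_set = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  sds <- apply(points, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  white <- sweep(points, 2, sds, `/`)
  eps_ball <- function(p) {
    ellipsoid(p, diag(1 / 1e-12, d))  # radius 1e-6 ball
  }
  cluster_ellipsoids <- function(assign, k) {
    lapply(seq_len(k), function(j) {
      pts <- points[assign == j, , drop = FALSE]
      if (nrow(pts) == 0L) return(NULL)
      if (nrow(pts) == 1L) return(eps_ball(pts[1, ]))
      mvee(pts, tolerance = tolerance, max_iter = max_iter)
    })
  }
  best <- NULL
  k_hi <- max(1L, min(k_max, n - 1L))
  ks <- if (is.null(k_set)) seq_len(k_hi) else
    sort(unique(pmin(pmax(as.integer(k_set), 1L), k_hi)))
  for (k in ks) {
    assign <- if (k == 1L) rep(1L, n) else {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(white, centers = k, nstart = nstart,
                                       iter.max = 50)),
        error = function(e) NULL)  # fewer distinct points than centers
      if (is.null(km)) next
      km$cluster
    }
    ells <- Filter(Negate(is.null), cluster_ellipsoids(assign, k))
    vols <- vapply(ells, ellipsoid_volume, numeric(1))
    total <- sum(vols)
    if (is.null(best) || total < best$total) {
      ord <- order(vols, decreasing = TRUE)
      best <- list(ellipsoids = ells[ord], volumes = vols[ord], k = k,
                   total = total)
    }
  }
  best
}

#' Total volume of a clustered ellipsoid cover of a point set
#'
#' The convergence statistic used by both exploration stages: points are
#' partitioned into k clusters (k chosen over `1..k_max` to minimize the
#' total), each cluster is wrapped in its minimum-volume enclosing
#' ellipsoid, and the ellipsoid volumes are summed. The statistic plateaus
#' once further sampling stops discovering new viable territory.
#'
#' @param points `n x d` matrix or [viable_set()] of viable points.
#' @param k_max Largest cluster count scanned.
#' @param nstart k-means restarts per k.
#' @param max_points Point sets larger than this are thinned by a
#'   deterministic stride before the scan (the statistic is a convergence
#'   heuristic; thinning leaves its trajectory essentially unchanged while
#'   keeping per-block cost bounded).
#' @param tolerance MVEE tolerance for the statistic. The default is looser
#'   than [mvee()]'s because only the *relative change* of the statistic
#'   matters for convergence, and the looser fit is several-fold cheaper.
#' @param k_set Optional subset of cluster counts to scan (callers that
#'   evaluate the statistic repeatedly warm-start the scan around the
#'   previously selected k); `NULL` scans `1..k_max`. The selected k is
#'   attached as attribute `k`.
#' @return Total cover volume (numeric). With fewer than `d + 1` points the
#'   statistic is undefined; 0 is returned with attribute
#'   `insufficient = TRUE` rather than an error.
#' @export
clustered_cover_volume <- function(points, k_max = 10, nstart = 2,
                                   max_points = 4000, tolerance = 1e-4,
                                   k_set = NULL) {
  if (inherits(points, "viable_set")) points <- points$points
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  if (n < d + 1) return(structure(0, insufficient = TRUE))
  if (n > max_points) {
    idx <- unique(round(seq(1, n, length.out = max_points)))
    points <- points[idx, , drop = FALSE]
  }
  # the statistic must be a deterministic function of the point set: random
  # k-means restarts would jitter it between blocks and mask convergence,
  # and it must not consume draws from the caller's seeded RNG stream
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed)
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(141421L)
  sc <- cover_scan(points, k_max = k_max, nstart = nstart,
                   tolerance = tolerance, max_iter = 3e4, k_set = k_set)
  structure(sc$total, k = sc$k)
}

#' Build the multi-ellipsoid integration domain
#'
#' Groups the pooled viable points into k clusters (k-means on whitened
#' coordinates, best of `nstart` restarts, k scanned over `1..k_max` keeping
#' the k with the smallest total ellipsoid volume) and wraps each cluster in
#' its minimum-volume enclosing ellipsoid. The resulting union is the
#' integration subspace; ellipsoids are ordered by descending volume, which
#' is also the fixed processing order of the overlap-once integrand.
#'
#' @param points `n x d` matrix or [viable_set()]; needs at least `d + 1`
#'   points.
#' @param k_max Largest cluster count scanned.
#' @param nstart k-means restarts per k.
#' @param inflation Optional factor applied to every ellipsoid's axes after
#'   construction (default 1 = faithful MVEE cover). An inflation slightly
#'   above 1 counters the systematic undercoverage of an MVEE fitted to a
#'   finite sample; it is never applied silently.
#' @param select_points Cluster-count selection runs on at most this many
#'   (deterministically strided) points; the final per-cluster ellipsoids
#'   are then fitted to *all* points, so the containment invariant always
#'   holds on the full input.
#' @return An object of class `ellipsoid_cover`: list of [ellipsoid()]s,
#'   their volumes, and the selected `k`.
#' @export
build_cover <- function(points, k_max = 10, nstart = 10, inflation = 1,
                        select_points = 10000) {
  if (inherits(points, "viable_set")) points <- points$points
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  if (n < d + 1)
    stop("build_cover needs at least d + 1 viable points; explore more first")
  sds <- apply(points, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  white <- sweep(points, 2, sds, `/`)

  sel <- seq_len(n)
  if (n > select_points)
    sel <- unique(round(seq(1, n, length.out = select_points)))

  # phase 1: choose k by the min-total-MVEE-volume scan on the subset
  best <- NULL
  k_hi <- max(1L, min(k_max, length(sel) - 1L))
  for (k in seq_len(k_hi)) {
    km <- NULL
    assign_sel <- if (k == 1L) rep(1L, length(sel)) else {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(white[sel, , drop = FALSE],
                                       centers = k, nstart = nstart,
                                       iter.max = 50)),
        error = function(e) NULL)
      if (is.null(km)) next
      km$cluster
    }
    total <- 0
    ok <- TRUE
    for (j in seq_len(k)) {
      pts <- points[sel[assign_sel == j], , drop = FALSE]
      if (nrow(pts) < 2L) next
      total <- total + ellipsoid_volume(
        mvee(pts, tolerance = 1e-4, max_iter = 3e4))
    }
    if (ok && (is.null(best) || total < best$total)) {
      best <- list(k = k, total = total, centers = if (!is.null(km))
        km$centers else matrix(colMeans(white[sel, , drop = FALSE]),
                               nrow = 1))
    }
  }

  # phase 2: assign every point to its nearest selected center and fit the
  # final tight ellipsoid per cluster
  k <- best$k
  assign_all <- if (k == 1L) rep(1L, n) else {
    dist2 <- sapply(seq_len(k), function(j)
      rowSums(sweep(white, 2, best$centers[j, ])^2))
    max.col(-matrix(dist2, ncol = k))
  }
  ells <- lapply(seq_len(k), function(j) {
    pts <- points[assign_all == j, , drop = FALSE]
    if (nrow(pts) == 0L) return(NULL)
    if (nrow(pts) == 1L) return(ellipsoid(pts[1, ], diag(1e12, d)))
    mvee(pts)
  })
  ells <- Filter(Negate(is.null), ells)
  if (inflation != 1) {
    ells <- lapply(ells, scale_ellipsoid, g = inflation)
  }
  vols <- vapply(ells, ellipsoid_volume, numeric(1))
  ord <- order(vols, decreasing = TRUE)
  structure(list(ellipsoids = ells[ord], volumes = vols[ord],
                 k = length(ells), inflation = inflation),
            class = "ellipsoid_cover")
}

#' @export
print.ellipsoid_cover <- function(x, ...) {
  cat("ellipsoid_cover: k =", x$k, "ellipsoids, total volume",
      format(sum(x$volumes)), "\n")
  invisible(x)
}

#' Check that a cover contains a point set
#' @param cover An [ellipsoid_cover()][build_cover].
#' @param points Matrix or [viable_set()].
#' @param tol Membership slack.
#' @return Logical vector: point lies in at least one ellipsoid.
#' @export
cover_contains <- function(cover, points, tol = 1e-6) {
  if (inherits(points, "viable_set")) points <- points$points
  points <- as.matrix(points)
  inside <- rep(FALSE, nrow(points))
  for (e in cover$ellipsoids) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- in_ellipsoid(e, points[todo, , drop = FALSE], tol = tol)
  }
  inside
}
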