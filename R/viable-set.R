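#' Ordered collection of viable parameter points
#'
#' Stores viable points together with their cost values and a provenance
#' label recording which stage of the pipeline found them (`"oeamc"`,
#' `"mebs-boundary"`, `"mebs-expansion"`, `"integration"`). Points are unique
#' up to exact coordinate equality.
#'
#' @param points An `n x d` matrix (or single vector) of viable points.
#' @param cost Numeric vector of their cost values.
#' @param stage Character vector (recycled) of provenance labels.
#' @param block Optional integer vector (recycled) tagging the sampler block
#'   or expansion index that produced each point.
#' @return An object of class `viable_set`.
#' @export
viable_set <- function(points = NULL, cost = numeric(), stage = character(),
                       block = NA_integer_) {
  if (is.null(points)) {
    points <- matrix(numeric(), nrow = 0, ncol = 0)
  } else if (is.null(dim(points))) {
    points <- matrix(points, nrow = 1L)
  } else {
    points <- as.matrix(points)
  }
  n <- nrow(points)
  stage <- rep_len(as.character(stage), if (n) n else 0)
  block <- rep_len(as.integer(block), if (n) n else 0)
  cost <- rep_len(as.numeric(cost), if (n) n else 0)
  structure(list(points = points, cost = cost, stage = stage, block = block),
            class = "viable_set")
}

#' @export
print.viable_set <- function(x, ...) {
  cat("viable_set:", n_points(x), "points in", ncol(x$points),
      "dimensions\n")
  if (n_points(x)) {
    tab <- table(x$stage)
    cat("  stages:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of points in a viable set
#' @param vs A [viable_set()].
#' @return Integer count.
#' @export
n_points <- function(vs) nrow(vs$points)

#' Concatenate viable sets, dropping exact duplicate coordinates
#'
#' The first occurrence of a coordinate vector wins, so provenance reflects
#' the stage that discovered the point.
#'
#' @param ... [viable_set()] objects.
#' @return A combined [viable_set()].
#' @export
vs_bind <- function(...) {
  sets <- Filter(function(s) n_points(s) > 0, list(...))
  if (!length(sets)) return(viable_set())
  pts <- do.call(rbind, lapply(sets, `[[`, "points"))
  cost <- unlist(lapply(sets, `[[`, "cost"), use.names = FALSE)
  stage <- unlist(lapply(sets, `[[`, "stage"), use.names = FALSE)
  block <- unlist(lapply(sets, `[[`, "block"), use.names = FALSE)
  keep <- !duplicated(pts)
  viable_set(pts[keep, , drop = FALSE], cost[keep], stage[keep], block[keep])
}

#' @export
as.data.frame.viable_set <- function(x, ...,
                                     names = NULL) {
  d <- ncol(x$points)
  if (is.null(names)) names <- paste0("theta", seq_len(d))
  df <- as.data.frame(x$points)
  colnames(df) <- names
  df$cost <- x$cost
  df$stage <- x$stage
  df$block <- x$block
  df
}

#' Write a viable set as delimiter-separated values
#'
#' One row per point, one column per parameter plus `cost`, `stage` and
#' `block`; header row mandatory; full double precision (17 significant
#' digits) so a re-read reproduces the coordinates bit for bit.
#'
#' @param vs A [viable_set()].
#' @param path Output file path.
#' @param names Optional parameter names for the header.
#' @return `path`, invisibly.
#' @export
write_viable_set <- function(vs, path, names = NULL) {
  df <- as.data.frame(vs, names = names)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a viable set written by [write_viable_set()]
#'
#' @param path CSV file path.
#' @return A [viable_set()].
#' @export
read_viable_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("cost", "stage", "block")
  par_cols <- setdiff(colnames(df), meta)
  viable_set(as.matrix(df[par_cols]), df$cost, df$stage,
             if ("block" %in% colnames(df)) df$block else NA_integer_)
}
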