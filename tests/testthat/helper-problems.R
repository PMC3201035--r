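# Small viability problems used across the suite (all built in code).

# 1-D quadratic: viable interval is (-sqrt(E0), sqrt(E0)) inside [-10, 10]
quad_problem <- function(E0 = 1, bound = 10) {
  viability_problem(
    parameter_space(-bound, bound),
    cost = function(theta) theta^2,
    threshold = E0,
    cost_matrix = function(x) x[, 1]^2,
    name = "quad-1d"
  )
}

# d-dimensional ball of radius r: viable iff ||theta - center|| < r
ball_problem <- function(d, r = 1, center = rep(0, d), bound = 10) {
  viability_problem(
    parameter_space(rep(-bound, d), rep(bound, d)),
    cost = function(theta) sum((theta - center)^2),
    threshold = r^2,
    cost_matrix = function(x) rowSums(sweep(x, 2, center)^2),
    name = "ball"
  )
}

# axis-aligned box viable region [lo, hi] in each coordinate
box_region_problem <- function(lo, hi, bound = 10) {
  d <- length(lo)
  viability_problem(
    parameter_space(rep(-bound, d), rep(bound, d)),
    cost = function(theta) as.numeric(any(theta < lo | theta > hi)),
    threshold = 0.5,
    cost_matrix = function(x) {
      bad <- rep(FALSE, nrow(x))
      for (j in seq_len(d)) bad <- bad | x[, j] < lo[j] | x[, j] > hi[j]
      as.numeric(bad)
    },
    name = "box-region"
  )
}

# whole box viable (cost identically zero)
all_viable_problem <- function(d, bound = 10) {
  viability_problem(
    parameter_space(rep(-bound, d), rep(bound, d)),
    cost = function(theta) 0,
    threshold = 1,
    cost_matrix = function(x) numeric(nrow(x)),
    name = "all-viable"
  )
}
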