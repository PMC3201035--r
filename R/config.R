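#' Build a validated pipeline run configuration
#'
#' Bundles a builtin problem id (or a user-supplied [viability_problem()]),
#' the settings of both exploration stages, the volume-estimation settings,
#' and the RNG seed. Every field is validated against its stage's
#' invariants before any computation starts, and the serialized
#' configuration hash travels with all outputs.
#'
#' Builtin problem ids: `"shell-d<D>"` (single shell), `"shell-d<D>-tangent"`
#' (two tangent shells), `"oscillator"`.
#'
#' @param problem Builtin id string, or a [viability_problem()].
#' @param oeamc Named list of [oeamc_config()] overrides.
#' @param mebs Named list of [mebs_config()] overrides.
#' @param volume Named list: `N` (samples), `k_max`, `inflation`.
#' @param seed Integer RNG seed.
#' @param out Optional output directory.
#' @return A `run_config` object.
#' @export
run_config <- function(problem = "shell-d5", oeamc = list(), mebs = list(),
                       volume = list(), seed = 1, out = NULL) {
  vol_defaults <- list(N = 1e5, k_max = 10, inflation = 1)
  unknown <- setdiff(names(volume), names(vol_defaults))
  if (length(unknown)) stop("unknown volume settings: ",
                            paste(unknown, collapse = ", "))
  volume <- utils::modifyList(vol_defaults, volume)
  stopifnot(volume$N >= 10, volume$k_max >= 1, volume$inflation > 0,
            length(seed) == 1, is.finite(seed))

  pb <- if (inherits(problem, "viability_problem")) problem else
    builtin_problem(problem)
  d <- pb$space$d
  ocfg <- do.call(oeamc_config,
                  c(list(d = d, lower = pb$space$lower,
                         upper = pb$space$upper), oeamc))
  mcfg <- do.call(mebs_config, c(list(d = d), mebs))

  structure(
    list(problem_id = if (is.character(problem)) problem else pb$name,
         problem = pb, oeamc = ocfg, mebs = mcfg, volume = volume,
         seed = as.integer(seed), out = out),
    class = "run_config"
  )
}

#' Instantiate a builtin viability problem from its id
#' @param id `"shell-d<D>"`, `"shell-d<D>-tangent"`, or `"oscillator"`.
#' @return A [viability_problem()].
#' @export
builtin_problem <- function(id) {
  if (identical(id, "oscillator")) return(oscillator_problem())
  m <- regmatches(id, regexec("^shell-d([0-9]+)(-tangent)?$", id))[[1]]
  if (length(m)) {
    return(shell_problem(as.integer(m[2]),
                         n_shells = if (nzchar(m[3])) 2L else 1L))
  }
  stop("unknown builtin problem id: ", id)
}

config_to_list <- function(cfg) {
  list(problem = cfg$problem_id,
       oeamc = lapply(unclass(cfg$oeamc), function(x)
         if (is.matrix(x)) unname(x) else x),
       mebs = unclass(cfg$mebs),
       volume = cfg$volume,
       seed = cfg$seed)
}

#' Save a run configuration as JSON
#' @param cfg A [run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(config_to_list(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate a run configuration from JSON
#'
#' Unknown keys raise an error (no silently ignored typos); omitted keys
#' take the documented defaults.
#'
#' @param path JSON file written by [save_config()] or by hand.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("problem", "oeamc", "mebs", "volume", "seed", "out")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  oeamc <- as.list(x$oeamc %||% list())
  if (!is.null(oeamc$sigma0)) oeamc$sigma0 <- as.matrix(oeamc$sigma0)
  ok_oeamc <- c("beta0", "sigma0", "b", "s", "f0", "f_l", "f_u", "n",
                "max_blocks", "k_max", "conv_tol", "conv_window")
  bad <- setdiff(names(oeamc), ok_oeamc)
  if (length(bad)) stop("unknown oeamc settings: ", paste(bad, collapse = ", "))
  mebs <- as.list(x$mebs %||% list())
  ok_mebs <- c("g0", "g1", "p", "b_l", "b_u", "n", "max_iter", "g_tol",
               "max_expansions", "k_max", "conv_tol", "conv_window",
               "mvee_tol", "mvee_max_points")
  bad <- setdiff(names(mebs), ok_mebs)
  if (length(bad)) stop("unknown mebs settings: ", paste(bad, collapse = ", "))
  run_config(problem = x$problem %||% "shell-d5",
             oeamc = oeamc, mebs = mebs,
             volume = as.list(x$volume %||% list()),
             seed = x$seed %||% 1,
             out = x$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Short stable hash of a run configuration
#'
#' Polynomial rolling hash over the canonical JSON serialization; recorded
#' beside every output so runs can be matched to the exact settings that
#' produced them. (No cryptographic strength claimed or needed.)
#'
#' @param cfg A [run_config()].
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(config_to_list(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
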