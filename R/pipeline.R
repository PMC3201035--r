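#' Run the full exploration and volume-estimation pipeline
#'
#' Executes, in order: seed finding (unless the problem is the oscillator,
#' which starts from its bundled reference point), the global adaptive
#' Metropolis exploration, the local ellipsoid-based exploration, cover
#' construction, and stratified Monte Carlo volume estimation. Each stage's
#' outputs (point files, JSON traces) are written under `cfg$out` when that
#' is set, together with a JSON summary carrying the seed, the
#' configuration hash and per-stage evaluation counts.
#'
#' @param cfg A [run_config()].
#' @param resume If `TRUE` and `cfg$out` contains a previously written
#'   pooled point file (`v_t.csv`), exploration is skipped and only the
#'   cover/volume stage is recomputed from it.
#' @param verbose Print stage progress.
#' @return A list with `v_mc`, `v_t` ([viable_set()]s), `cover`,
#'   `estimate` ([estimate_volume()] result), `evaluations` (named
#'   per-stage counts) and `summary` (the list written as JSON).
#' @export
run_pipeline <- function(cfg, resume = FALSE, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  problem <- cfg$problem
  reset_evaluations(problem)
  set.seed(cfg$seed)
  out_dir <- cfg$out
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  names <- problem$space$names

  v_mc <- NULL
  v_t <- NULL
  evals <- c(seed = 0, oeamc = 0, mebs = 0, volume = 0)

  pooled_path <- if (!is.null(out_dir)) file.path(out_dir, "v_t.csv")
  if (resume && !is.null(pooled_path) && file.exists(pooled_path)) {
    v_t <- read_viable_set(pooled_path)
    if (verbose) message("resumed from ", pooled_path, ": ",
                         n_points(v_t), " points")
  } else {
    if (identical(problem$name, "oscillator")) {
      theta0 <- unname(osc_reference_params())
    } else {
      theta0 <- find_viable_seed(problem)
    }
    evals["seed"] <- evaluations(problem)
    if (verbose) message("seed point found after ", evals["seed"],
                         " evaluations")
    v_mc <- run_oeamc(problem, theta0, cfg$oeamc, verbose = verbose)
    evals["oeamc"] <- evaluations(problem) - sum(evals)
    v_t <- run_mebs(problem, v_mc, cfg$mebs, verbose = verbose)
    evals["mebs"] <- evaluations(problem) - sum(evals)
    if (!is.null(out_dir)) {
      write_viable_set(v_mc, file.path(out_dir, "v_mc.csv"), names = names)
      write_viable_set(v_t, pooled_path, names = names)
      jsonlite::write_json(
        list(oeamc = attr(v_mc, "trace"), mebs = attr(v_t, "trace")),
        file.path(out_dir, "exploration_trace.json"),
        dataframe = "columns", digits = NA)
    }
  }

  cover <- build_cover(v_t, k_max = cfg$volume$k_max,
                       inflation = cfg$volume$inflation)
  estimate <- estimate_volume(cover, problem, N = cfg$volume$N)
  evals["volume"] <- evaluations(problem) - sum(evals)

  summary <- list(
    problem = cfg$problem_id,
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("viaspace")),
    volume = estimate$volume,
    stderr = estimate$stderr,
    domain_volume = estimate$domain_volume,
    box_ratio = estimate$box_ratio,
    k = cover$k,
    n_viable_uniform = n_points(estimate$viable_points),
    evaluations = as.list(evals),
    total_evaluations = sum(evals))

  if (!is.null(out_dir)) {
    write_viable_set(estimate$viable_points,
                     file.path(out_dir, "viable_uniform.csv"), names = names)
    jsonlite::write_json(lapply(cover$ellipsoids, ellipsoid_to_list),
                         file.path(out_dir, "cover.json"), digits = NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    save_config(cfg, file.path(out_dir, "config.json"))
  }
  if (verbose) {
    message(sprintf("volume = %.6g +/- %.3g (%d evaluations)",
                    estimate$volume, estimate$stderr, sum(evals)))
  }
  list(v_mc = v_mc, v_t = v_t, cover = cover, estimate = estimate,
       evaluations = evals, summary = summary)
}
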