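#' Full split-network pipeline: ordering search, weighting, filtering
#'
#' Runs the whole method on a distance matrix: find a circular ordering by
#' greedy initialization plus simulated annealing (optionally several
#' restarts with distinct seeds, keeping the lowest-energy ordering), extract
#' the ordering's circular splits, weight them by non-negative least squares,
#' and drop near-zero splits.
#'
#' @param d a [distance_matrix()].
#' @param schedule an [anneal_schedule()].
#' @param init initialization for the ordering search (see
#'   [run_mcnet_ordering()]).
#' @param given_sigma starting ordering when `init = "given"`.
#' @param threshold weight threshold for [filter_splits()].
#' @param restarts number of independent annealing runs (seeds
#'   `seed, seed+1, ...`); the best ordering wins. Default 1.
#' @return an `mcnet_result` list: `system` (filtered `mcnet_splits`),
#'   `anneal` (the winning `mcnet_anneal` result), `energy`, `n_splits`,
#'   `norm`, `restarts`.
#' @examples
#' gen <- random_tree_metric(6, seed = 42)
#' res <- mcnet(gen$d)
#' res$n_splits   # 2n - 3 splits for a treelike input
#' res$norm       # ~0: the fit is exact
#' @export
mcnet <- function(d, schedule = anneal_schedule(),
                  init = c("greedy", "random", "given"), given_sigma = NULL,
                  threshold = 1e-8, restarts = 1L) {
  check_dist(d)
  init <- match.arg(init)
  if (restarts < 1L) stop("`restarts` must be >= 1", call. = FALSE)
  best <- NULL
  for (r in seq_len(restarts)) {
    sch <- schedule
    sch$seed <- schedule$seed + (r - 1L)
    ar <- run_mcnet_ordering(d, init = init, given_sigma = given_sigma,
                             schedule = sch)
    if (is.null(best) || ar$energy < best$energy) best <- ar
  }
  system <- filter_splits(weight_splits(d, best$ordering, method = "nnls"),
                          threshold = threshold)
  structure(list(system = system, anneal = best,
                 energy = best$energy,
                 n_splits = length(system$splits),
                 norm = fit_norm(system),
                 restarts = as.integer(restarts)),
            class = "mcnet_result")
}

#' @export
print.mcnet_result <- function(x, ...) {
  cat("Split network result\n")
  cat("  taxa:", length(x$system$labels), "\n")
  cat("  tour energy:", format(x$energy), "\n")
  cat("  splits retained:", x$n_splits, "\n")
  cat("  fit norm ||Aw - d||:", format(x$norm), "\n")
  invisible(x)
}

#' Run the pipeline on files: distance matrix in, NEXUS + JSON summary out
#'
#' Thin file-level wrapper over [mcnet()]: reads a PHYLIP or NEXUS distance
#' matrix, runs the pipeline, writes the weighted split system as a
#' SplitsTree-readable NEXUS file, and returns (and optionally writes) a
#' JSON-ready summary. On failure no partial output file is left behind.
#'
#' @param in_path input distance-matrix file.
#' @param out_path output NEXUS path.
#' @param format input format (see [read_distance_matrix()]).
#' @param summary_path optional path for a JSON summary.
#' @param seed RNG seed for the annealer.
#' @param t0,cooling,tlow,reps schedule parameters (see [anneal_schedule()]).
#' @param init,threshold,restarts see [mcnet()].
#' @param verbose print stage messages to stderr.
#' @return the summary list, invisibly: `n`, `energy`, `n_splits`, `norm`,
#'   `seed`, `schedule`, `restarts`, `cycle`.
#' @export
mcnet_run <- function(in_path, out_path, format = "auto",
                      summary_path = NULL, seed = 1L,
                      t0 = NULL, cooling = 0.9, tlow = 1e-4, reps = NULL,
                      init = "greedy", threshold = 1e-8, restarts = 1L,
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("reading ", in_path)
  d <- read_distance_matrix(in_path, format = format)
  say("n = ", n_taxa(d), " taxa; searching for a circular ordering")
  schedule <- anneal_schedule(t_initial = t0, cooling = cooling,
                              reps_per_temp = reps, t_low = tlow, seed = seed)
  res <- mcnet(d, schedule = schedule, init = init,
               threshold = threshold, restarts = restarts)
  say("energy ", format(res$energy), "; ", res$n_splits,
      " splits retained; fit norm ", format(res$norm))
  tmp <- paste0(out_path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  write_splits_nexus(res$system, tmp)
  file.rename(tmp, out_path)
  say("wrote ", out_path)
  summary <- list(
    n = n_taxa(d),
    energy = res$energy,
    n_splits = res$n_splits,
    norm = res$norm,
    seed = as.integer(seed),
    schedule = list(t_initial = schedule$t_initial, cooling = cooling,
                    reps_per_temp = schedule$reps_per_temp, t_low = tlow),
    restarts = as.integer(restarts),
    cycle = res$system$cycle
  )
  if (!is.null(summary_path)) {
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    say("wrote ", summary_path)
  }
  invisible(summary)
}

#' Cooling-schedule sweep
#'
#' Full-factorial sweep over cooling coefficients, stopping temperatures and
#' seeds on one input, reporting the achieved tour energy and the number of
#' proposals per cell. The proposal count, not wall-clock time, is the
#' effort measure, so results are hardware-independent.
#'
#' @param d a [distance_matrix()] (or a file path, read with
#'   [read_distance_matrix()]).
#' @param cooling_values numeric vector of cooling coefficients.
#' @param tlow_values numeric vector of stopping temperatures.
#' @param seeds integer vector of seeds.
#' @param init initialization mode.
#' @param t0,reps optional fixed initial temperature and proposals per
#'   temperature, shared by every cell (defaults as in [anneal_schedule()]).
#' @param out_csv optional path: write the sweep table as CSV.
#' @return data frame with one row per (cooling, tlow, seed): `cooling`,
#'   `t_low`, `seed`, `energy`, `iterations`.
#' @export
mcnet_sweep <- function(d, cooling_values = c(0.5, 0.7, 0.9),
                        tlow_values = c(1e-2, 1e-4), seeds = 1:3,
                        init = "greedy", t0 = NULL, reps = NULL,
                        out_csv = NULL) {
  if (is.character(d)) d <- read_distance_matrix(d)
  check_dist(d)
  grid <- expand.grid(cooling = cooling_values, t_low = tlow_values,
                      seed = as.integer(seeds),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$energy <- NA_real_
  grid$iterations <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    sch <- anneal_schedule(t_initial = t0, cooling = grid$cooling[i],
                           reps_per_temp = reps, t_low = grid$t_low[i],
                           seed = grid$seed[i])
    ar <- run_mcnet_ordering(d, init = init, schedule = sch)
    grid$energy[i] <- ar$energy
    grid$iterations[i] <- ar$iterations
  }
  if (!is.null(out_csv)) {
    utils::write.csv(grid, out_csv, row.names = FALSE, quote = FALSE)
  }
  grid
}

#' Export an annealing trace as CSV
#'
#' @param result an `mcnet_anneal` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_anneal_trace <- function(result, path) {
  stopifnot(inherits(result, "mcnet_anneal"))
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
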