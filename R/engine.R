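#' @useDynLib eaesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Execute a single simulation run
#'
#' Initializes the world from the configuration (naive T-cell pools in the
#' lymphoid compartments and circulation, the MBP + adjuvant immunization
#' bolus, the CNS neuron/microglia pools, resident dendritic cells) and
#' steps it for the configured duration. A run is fully reproducible: the
#' same configuration and seed give bit-identical records.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a `sim_run` object: list with
#'   \describe{
#'     \item{counts}{integer array `[time, lineage, state, compartment]`
#'       of population counts at the recording cadence (removed agents are
#'       excluded from counts).}
#'     \item{record_times}{hours corresponding to the first array margin.}
#'     \item{priming}{data.frame of priming events (time, lineage,
#'       compartment, DC id), one per effector transition.}
#'     \item{licensing}{data.frame of DC licensing events with the DC's
#'       creation and licensing times.}
#'     \item{kills}{data.frame of CD8Treg kill events with compartment.}
#'     \item{dc_census}{data.frame, one row per DC at its apoptosis:
#'       presented-kind flags and the T-cell neighbour census.}
#'     \item{th1_apoptosis_total}{total CD4Th1 apoptosis events (AICD and
#'       CTL killing).}
#'     \item{created, removed, conservation_ok}{conservation ledger.}
#'   }
#' @export
run_simulation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- validate_config(config)
  set.seed(as.integer(config$seed))
  cfg <- unclass(config)
  cfg$qa1_delay_hours <- ifelse(is.na(cfg$qa1_delay_hours), -1,
                                cfg$qa1_delay_hours)
  cfg$cd8_cap <- ifelse(is.na(cfg$cd8_cap), -1L, as.integer(cfg$cd8_cap))
  out <- sim_run_cpp(cfg)
  out$seed <- as.integer(config$seed)
  out$config <- config
  out$config_digest <- config_digest(config)
  dimnames(out$counts) <- list(NULL, LINEAGES, MATURITY_STATES, COMPARTMENTS)
  class(out) <- "sim_run"
  out
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> seed %d, digest %s, %d recording steps\n",
              x$seed, x$config_digest, length(x$record_times)))
  cat(sprintf("  events: %d priming, %d licensing, %d kills, %d DC censuses\n",
              nrow(x$priming), nrow(x$licensing), nrow(x$kills),
              nrow(x$dc_census)))
  invisible(x)
}

#' Execute an ensemble of simulation runs
#'
#' Runs `n_runs` independent replicates with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n_runs - 1`. Each run owns
#' its seed, so results are identical whether executed serially or in
#' parallel, and are always ordered by seed.
#'
#' @param config a [sim_config()].
#' @param n_runs number of replicates (the desk-scale default used by the
#'   experiment registry is 100).
#' @param base_seed integer seed of the first run.
#' @param parallel if TRUE, run across `cores` local processes.
#' @param cores worker count when `parallel`.
#' @return an `ensemble_result`: list with `runs` (list of `sim_run`),
#'   `n_runs`, `base_seed`, `config`, `config_digest`.
#' @export
run_batch <- function(config, n_runs = 100, base_seed = 1L,
                      parallel = FALSE, cores = 2L) {
  stopifnot(inherits(config, "sim_config"), n_runs >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  worker <- function(s) run_simulation(config, seed = s)
  runs <- if (parallel && .Platform$OS.type == "unix") {
    parallel::mclapply(seeds, worker, mc.cores = cores)
  } else {
    lapply(seeds, worker)
  }
  structure(
    list(runs = runs, n_runs = n_runs, base_seed = as.integer(base_seed),
         config = config, config_digest = config_digest(config)),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d runs, base seed %d, digest %s\n",
              x$n_runs, x$base_seed, x$config_digest))
  invisible(x)
}

#' Write a run's population time series as tidy CSV
#'
#' One row per recording step x lineage x state x compartment with a
#' nonzero count (zeros omitted to keep files small); a header comment
#' carries the config digest and seed.
#'
#' @param run a `sim_run`.
#' @param path output file.
#' @export
write_timeseries <- function(run, path) {
  stopifnot(inherits(run, "sim_run"))
  df <- as.data.frame.table(run$counts, responseName = "count",
                            stringsAsFactors = FALSE)
  names(df) <- c("step", "lineage", "state", "compartment", "count")
  df$time_hours <- run$record_times[as.integer(factor(df$step,
                                                      levels = unique(df$step)))]
  df <- df[df$count > 0, c("time_hours", "lineage", "state", "compartment",
                           "count")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eaesim timeseries digest=%s seed=%d",
                     run$config_digest, run$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#' @param path file path.
#' @return data.frame with attributes `digest` and `seed`.
#' @export
read_timeseries <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#")
  m <- regmatches(header, regexec("digest=([0-9a-f]+) seed=([0-9-]+)", header))[[1]]
  if (length(m) == 3L) {
    attr(df, "digest") <- m[2]
    attr(df, "seed") <- as.integer(m[3])
  }
  df
}

#' Write a run's event logs as line-delimited JSON
#'
#' Each line is one JSON record with a `record` field naming the log
#' (priming, licensing, kill, dc_census) plus that log's columns.
#'
#' @param run a `sim_run`.
#' @param path output file.
#' @export
write_events <- function(run, path) {
  stopifnot(inherits(run, "sim_run"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(record = "header",
                                   digest = run$config_digest,
                                   seed = run$seed), auto_unbox = TRUE), con)
  emit <- function(df, what) {
    if (nrow(df) == 0) return(invisible())
    df$record <- what
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  emit(run$priming, "priming")
  emit(run$licensing, "licensing")
  emit(run$kills, "kill")
  emit(run$dc_census, "dc_census")
  invisible(path)
}
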