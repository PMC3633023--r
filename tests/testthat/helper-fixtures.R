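# Fixture builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk.

# a small, fast world for engine-level tests: same mechanisms, ~1/4 the
# populations and a 25-day horizon
tiny_config <- function(...) {
  small <- list(
    duration_days = 25,
    n_cd4th_naive = 120L, n_cd4treg_naive = 30L, n_cd8treg_naive = 60L,
    naive_influx_cd4th = 0.05, naive_influx_cd4treg = 0.02,
    naive_influx_cd8treg = 0.03,
    n_neurons = 120L, n_microglia = 20L,
    n_dc_init_spleen = 15L, n_dc_init_cln = 10L, n_dc_init_cns = 5L,
    dc_influx_spleen = 0.25, dc_influx_cln = 0.2, dc_influx_cns = 0.2,
    p_mbp_uptake = 0.004)
  do.call(control_config, utils::modifyList(small, list(...)))
}

# hand-built sim_run skeleton: a counts array plus event logs, enough for
# the stats/experiments extractors
make_run <- function(counts_by_time = NULL, record_times = NULL,
                     lineage = "CD8Treg", state = "effector",
                     compartment = "Spleen",
                     priming = NULL, licensing = NULL, kills = NULL,
                     dc_census = NULL, th1_apoptosis_total = 0) {
  if (is.null(record_times)) {
    record_times <- if (is.null(counts_by_time)) numeric(0) else
      seq(0, by = 6, length.out = length(counts_by_time))
  }
  counts <- array(
    0L, dim = c(length(record_times), length(LINEAGES),
                length(MATURITY_STATES), length(COMPARTMENTS)),
    dimnames = list(NULL, LINEAGES, MATURITY_STATES, COMPARTMENTS))
  if (!is.null(counts_by_time)) {
    counts[, lineage, state, compartment] <- as.integer(counts_by_time)
  }
  empty <- function(...) {
    df <- data.frame(...)
    df[0, , drop = FALSE]
  }
  structure(list(
    counts = counts, record_times = record_times,
    priming = if (is.null(priming))
      empty(time = 0, lineage = "", compartment = "", dc_id = 0L) else priming,
    licensing = if (is.null(licensing))
      empty(dc_id = 0L, creation_time = 0, licensing_time = 0) else licensing,
    kills = if (is.null(kills)) empty(time = 0, compartment = "") else kills,
    dc_census = if (is.null(dc_census))
      empty(time = 0, compartment = "", presented_mbp = 0L,
            presented_tcr = 0L, nb_cd4th_naive = 0L, nb_cd4th1 = 0L,
            nb_cd4th2 = 0L, nb_cd4treg = 0L, nb_cd8treg = 0L) else dc_census,
    th1_apoptosis_total = th1_apoptosis_total,
    seed = 0L, config_digest = "fixture"), class = "sim_run")
}

make_ensemble <- function(runs) {
  structure(list(runs = runs, n_runs = length(runs), base_seed = 0L,
                 config = NULL, config_digest = "fixture"),
            class = "ensemble_result")
}

# brute-force pair-enumeration oracle for the Vargha-Delaney A statistic
a_test_bruteforce <- function(x, y) {
  wins <- 0
  for (xi in x) for (yj in y) {
    wins <- wins + (xi > yj) + 0.5 * (xi == yj)
  }
  wins / (length(x) * length(y))
}
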