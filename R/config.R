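# Simulation configuration: one flat, documented parameter list. The
# mechanisms of the regulatory circuit are fixed; every numeric rate lives
# here, and the shipped defaults are the frozen control configuration
# produced by the calibration harness (see the methods vignette and
# `calibration_targets()`).

.default_config <- function() {
  list(
    # -- time ------------------------------------------------------------
    duration_days = 100,        # simulated days per run
    dt_hours = 1,               # scheduler step; all delays are multiples
    record_every_hours = 6,     # population-count cadence (events exact)
    seed = 1L,
    # -- initial populations and influx (cells, cells/hour) --------------
    n_cd4th_naive = 450L,       # naive unpolarized, MBP-specific
    n_cd4treg_naive = 70L,      # naive Fr3-specific
    n_cd8treg_naive = 260L,      # naive CDR1/2-specific
    naive_influx_cd4th = 0.12,
    naive_influx_cd4treg = 0.05,
    naive_influx_cd8treg = 0.1,
    n_neurons = 350L,           # CNS neuron pool (aggregate)
    n_microglia = 40L,
    n_dc_init_spleen = 35L,
    n_dc_init_cln = 25L,
    n_dc_init_cns = 10L,
    dc_influx_spleen = 0.5,     # new immature DCs per hour
    dc_influx_cln = 0.35,
    dc_influx_cns = 0.45,
    # -- dendritic cells -------------------------------------------------
    dc_lifespan_mean = 105,     # hours; uniform jitter below
    dc_lifespan_jitter = 15,
    dc_binding_sites = 3L,      # simultaneous bound T cells per DC
    processing_delay_hours = 13, # engulfment -> presentable peptide
    processing_delay_debris_hours = 30,  # slower processing of myelin debris
                                # (no adjuvant activation in the CNS route)
    processing_delay_bolus_hours = 36,  # immunization depot releases MBP to
                                # the DC surface over the first days
    display_mbp_hours = 48,     # surface lifetime of the MHCII-MBP display
    display_tcr_hours = 72,     # surface lifetime of the Fr3 / CDR1-2 display
    p_present_mbp = 0.10,       # per-hour chance processed MBP reaches MHCII
    p_present_tcr = 0.2,       # per-hour chance processed TCR peptide shown
    p_efferocytose = 0.3,       # per-hour clearance of a co-located corpse
    p_process_tcr = 0.09,       # chance an engulfed T-cell corpse yields
                                # presentable TCR peptide (cross-presentation
                                # bottleneck)
    p_eff_neuron = 0.004,        # per-hour CNS DC pickup of neuron debris
    mbp_bolus_hours = 96,       # immunization bolus persistence
    p_mbp_uptake = 0.001,      # per-hour bolus pickup by a lymphoid DC
    p_dc_migrate_cns = 0.02,     # per-hour mature CNS DC -> CLN
    # -- world geometry --------------------------------------------------
    grid_spleen_nx = 6L, grid_spleen_ny = 6L,
    grid_cln_nx = 5L, grid_cln_ny = 5L,
    grid_cns_nx = 4L, grid_cns_ny = 4L,
    capacity_lymphoid = 5L,     # T cells per lymphoid grid space
    capacity_cns = 8L,
    # -- T-cell activation and proliferation -----------------------------
    contact_duration_hours = 5, # length of one priming contact
    n_priming_contacts = 2L,    # naive -> partial -> effector
    n_priming_contacts_cd4treg = 2L,  # CD4Treg mature slowly (~2 days
                                # from first Fr3 contact) before licensing
    n_priming_contacts_cd8treg = 3L,  # cross-priming needs sustained
                                # contact, so short Qa-1 windows fail
    p_bind = 0.4,               # per-hour binding to an eligible DC
    p_license = 0.5,           # per-hour licensing by adjacent eff CD4Treg
    cd40l_delay_hours = 35,     # effector CD4Treg upregulate CD40L (and can
                                # license) only this long after maturing
    p_th1 = 0.9,                # Th1 polarization under a type1 milieu
    burst_cd4th = 5L,           # clonal burst on reaching effector
    burst_cd4treg = 5L,
    burst_cd8treg = 4L,
    eff_lifespan_th1 = 100,      # hours to activation-induced cell death
    eff_lifespan_th2 = 70,
    eff_lifespan_cd4treg = 130,
    eff_lifespan_cd8treg = 110,
    eff_lifespan_jitter_frac = 0.2,
    # -- motility and migration (per-hour probabilities) -----------------
    p_relocate = 0.4,           # move to another space in the compartment
    p_exit_lymphoid = 0.03,     # recirculation: lymphoid -> Circulation
    p_treg4eff_exit_lymphoid = 0.35,  # effector CD4Treg patrol: they leave
                                # the lymphoid grid soon after maturing
    p_circ_to_lymphoid = 0.3,
    frac_to_spleen = 0.35,       # Circulation exit split Spleen vs CLN
    drain_frac_spleen = 0.7,    # apoptotic CD4Th1 drain split Spleen vs CLN
    p_th1_exit_lymphoid = 0.03, # effector CD4Th1 leave for Circulation
    p_circ_to_cns = 0.15,       # effector CD4Th1 Circulation -> CNS
    p_apop_drain_cns = 0.72,     # apoptotic CD4Th1 CNS -> CLN/Spleen
    # -- effector function -----------------------------------------------
    p_kill = 0.28,              # per-hour CD8Treg kill of co-located CD4Th1
    p_mg_activate = 0.001,       # per eff CD4Th1 per microglia per hour
    p_neuron_kill = 0.000085,  # per-neuron per-active-microglia hazard
    apop_removal_window = 24,   # hours a corpse stays efferocytosable
    # -- experiment switches ----------------------------------------------
    mutex_mode = FALSE,
    qa1_mode = "licensing_required",  # or "constitutive_after_delay"
    qa1_delay_hours = NA_real_,
    abrogate_cd4treg = FALSE,
    occupancy_mode = "standard",      # or "relaxed_cd8"
    cd8_cap = NA_integer_,
    debug_conservation = FALSE
  )
}

#' Build a simulation configuration
#'
#' Returns the frozen control configuration, with any named overrides
#' applied and validated. All rate parameters are per-hour probabilities,
#' all durations are hours unless named `_days`. See the methods vignette
#' for the meaning and provenance of each default.
#'
#' @param ... named overrides of the default parameters.
#' @return a validated `sim_config` object (named list).
#' @examples
#' cfg <- sim_config(duration_days = 10, seed = 42L)
#' @export
sim_config <- function(...) {
  overrides <- list(...)
  base <- .default_config()
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(base, overrides)
  structure(validate_config(cfg), class = "sim_config")
}

#' Validate a simulation configuration
#'
#' Checks types, ranges, and cross-field constraints (e.g. the Qa-1 delay
#' must be a non-negative multiple of the time step in constitutive mode,
#' relaxed occupancy requires a CD8 cap, CD4Treg abrogation zeroes the
#' CD4Treg pools). Reports every failing field, not just the first.
#'
#' @param cfg a config list.
#' @return the (possibly adjusted) config, invisibly usable.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  num_fields <- setdiff(names(.default_config()),
                        c("mutex_mode", "qa1_mode", "qa1_delay_hours",
                          "abrogate_cd4treg", "occupancy_mode", "cd8_cap",
                          "debug_conservation"))
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      errs <- c(errs, paste0(f, ": must be a single non-negative number"))
    }
  }
  probs <- grep("^p_|^frac_", names(cfg), value = TRUE)
  for (f in probs) {
    if (is.numeric(cfg[[f]]) && !is.na(cfg[[f]]) && cfg[[f]] > 1) {
      errs <- c(errs, paste0(f, ": probability must be <= 1"))
    }
  }
  if (!cfg$qa1_mode %in% c("licensing_required", "constitutive_after_delay")) {
    errs <- c(errs, "qa1_mode: unknown mode")
  }
  if (cfg$qa1_mode == "constitutive_after_delay") {
    if (is.na(cfg$qa1_delay_hours) || cfg$qa1_delay_hours < 0) {
      errs <- c(errs, "qa1_delay_hours: required in constitutive mode")
    } else if (cfg$qa1_delay_hours %% cfg$dt_hours != 0) {
      errs <- c(errs, "qa1_delay_hours: must be a multiple of dt_hours")
    }
  }
  if (!cfg$occupancy_mode %in% c("standard", "relaxed_cd8")) {
    errs <- c(errs, "occupancy_mode: unknown mode")
  }
  if (cfg$occupancy_mode == "relaxed_cd8" &&
      (is.na(cfg$cd8_cap) || cfg$cd8_cap < 1)) {
    errs <- c(errs, "cd8_cap: relaxed_cd8 occupancy requires cd8_cap >= 1")
  }
  if (isTRUE(cfg$abrogate_cd4treg)) {
    cfg$n_cd4treg_naive <- 0L
    cfg$naive_influx_cd4treg <- 0
  }
  if (length(errs)) {
    stop("invalid simulation config:\n  ", paste(errs, collapse = "\n  "))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", "digest:", config_digest(x), "\n")
  cat(sprintf("  %d days, dt %g h, seed %d\n", x$duration_days, x$dt_hours,
              as.integer(x$seed)))
  cat(sprintf("  mutex=%s qa1=%s delay=%s abrogate_cd4treg=%s occupancy=%s\n",
              x$mutex_mode, x$qa1_mode, x$qa1_delay_hours,
              x$abrogate_cd4treg, x$occupancy_mode))
  invisible(x)
}

#' Configuration digest
#'
#' A short stable FNV-1a hash of the canonical serialized configuration,
#' stamped on every output file so runs and analyses can be matched to the
#' exact parameter set that produced them. The seed is excluded: runs of
#' one ensemble share a digest.
#'
#' @param cfg a [sim_config()].
#' @return 8-character hex string.
#' @export
config_digest <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$seed <- NULL
  keys <- sort(names(cfg))
  txt <- paste(keys, vapply(cfg[keys], function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";")
  bytes <- as.integer(charToRaw(txt))
  # 31-bit polynomial rolling hash (exact in double precision)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read a configuration as YAML
#'
#' Round-trips exactly: `read_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a validated `sim_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  # restore NA sentinels that YAML writes as ~ / .na
  do.call(sim_config, raw[!vapply(raw, is.null, logical(1))])
}
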