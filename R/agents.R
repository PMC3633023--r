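# Agent-level rules of the regulatory circuit. These functions are the
# documented, directly testable form of the pairwise interaction rules; the
# batch engine (src/engine.cpp) applies the same rules inside its compiled
# scheduler.

#' Create a T-cell agent
#'
#' @param lineage one of the T-cell lineages (see [LINEAGES]).
#' @param state maturity state, default `"naive"`.
#' @param location compartment name.
#' @param age hours since creation.
#' @param effector_clock hours remaining in the effector phase (NA until
#'   the cell becomes an effector).
#' @param has_CD40L CD40L display; only lawful on effector CD4Treg, which
#'   use it to deliver the licensing signal to DCs.
#' @param bound_dc identifier of the DC the cell is bound to, or NA.
#' @return a `t_cell` object.
#' @export
t_cell <- function(lineage, state = "naive", location = "Spleen", age = 0,
                   effector_clock = NA_real_, has_CD40L = FALSE,
                   bound_dc = NA_integer_) {
  lineage <- match.arg(lineage, LINEAGES[1:5])
  state <- match.arg(state, MATURITY_STATES)
  location <- match.arg(location, COMPARTMENTS)
  if (has_CD40L && !(lineage == "CD4Treg" && state == "effector")) {
    stop("has_CD40L requires an effector CD4Treg")
  }
  structure(
    list(lineage = lineage, state = state,
         specificity = lineage_specificity(lineage), location = location,
         age = age, effector_clock = effector_clock, has_CD40L = has_CD40L,
         bound_dc = bound_dc),
    class = "t_cell"
  )
}

#' Create a dendritic-cell state record
#'
#' @param maturity `"immature"` or `"mature"`.
#' @param polarization cytokine polarization perceived at maturation:
#'   `"type1"` (adjuvant-driven), `"type2"` or `"none"`.
#' @param inventory named counts of engulfed antigen sources
#'   (`MBP_source`, `TCR_source`).
#' @param mutex_lock in mutually-exclusive presentation mode, the first
#'   source kind processed; NA when unset or when the mode is off.
#' @param presented character vector of displayed complexes.
#' @param licensed whether a CD4Treg has delivered the CD40-CD40L licensing
#'   signal.
#' @param qa1_expressed whether Qa-1 is expressed (gates `QA1_CDR12`
#'   display and hence CD8Treg cross-priming).
#' @param creation_time,licensing_time,lifespan hours.
#' @param binding_sites number of T cells that can be bound simultaneously.
#' @param location compartment name.
#' @return a `dc_state` object.
#' @export
dc_state <- function(maturity = "immature", polarization = "none",
                     inventory = c(MBP_source = 0L, TCR_source = 0L),
                     mutex_lock = NA_character_, presented = character(0),
                     licensed = FALSE, qa1_expressed = FALSE,
                     creation_time = 0, licensing_time = NA_real_,
                     lifespan = 120, binding_sites = 6L,
                     location = "Spleen") {
  maturity <- match.arg(maturity, c("immature", "mature"))
  polarization <- match.arg(polarization, c("type1", "type2", "none"))
  stopifnot(all(SOURCE_KINDS %in% names(inventory)))
  if (!all(presented %in% PRESENTED_COMPLEXES)) stop("unknown complex")
  dc <- structure(
    list(maturity = maturity, polarization = polarization,
         inventory = inventory[SOURCE_KINDS], mutex_lock = mutex_lock,
         presented = presented, licensed = licensed,
         qa1_expressed = qa1_expressed, creation_time = creation_time,
         licensing_time = licensing_time, lifespan = lifespan,
         binding_sites = as.integer(binding_sites),
         location = match.arg(location, COMPARTMENTS)),
    class = "dc_state"
  )
  validate_dc(dc)
  dc
}

validate_dc <- function(dc) {
  if ("QA1_CDR12" %in% dc$presented && !dc$qa1_expressed) {
    stop("QA1_CDR12 can only be displayed while Qa-1 is expressed")
  }
  if (!is.na(dc$licensing_time) && dc$licensing_time < dc$creation_time) {
    stop("licensing_time precedes creation_time")
  }
  invisible(dc)
}

#' Qa-1 expression policy
#'
#' In the control circuit (`licensing_required`) Qa-1 appears only after a
#' CD4Treg licenses the DC. The constitutive policy replaces licensing with
#' a fixed delay from DC creation (used with CD4Treg abrogation to probe the
#' timing of Qa-1 expression; the delays studied are the 60 h and 82 h
#' licensing-age medians measured under control conditions).
#'
#' @param mode `"licensing_required"` or `"constitutive_after_delay"`.
#' @param delay hours; required in constitutive mode.
#' @export
qa1_policy <- function(mode = c("licensing_required",
                                "constitutive_after_delay"),
                       delay = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "constitutive_after_delay" && (is.na(delay) || delay < 0)) {
    stop("constitutive_after_delay requires a non-negative delay in hours")
  }
  structure(list(mode = mode, delay = delay), class = "qa1_policy")
}

#' Probabilistic CD4Th polarization at activation
#'
#' A naive CD4Th cell being primed commits irreversibly to Th1 or Th2. The
#' probability of Th1 is the type1 weight of the local cytokine milieu:
#' under immunization the adjuvant polarizes perceiving DCs to type1, whose
#' cytokines drive the majority of CD4Th activations to Th1.
#'
#' @param agent an unpolarized CD4Th [t_cell()].
#' @param milieu named numeric weights `c(type1 = , type2 = )`; must be
#'   non-negative and not both zero.
#' @return `"CD4Th1"` or `"CD4Th2"`.
#' @export
polarize_cd4th <- function(agent, milieu) {
  stopifnot(inherits(agent, "t_cell"))
  if (agent$lineage != "CD4Th_naive_unpolarized") {
    stop("polarize_cd4th: agent is already polarized")
  }
  w <- milieu[c("type1", "type2")]
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop("milieu must supply non-negative type1/type2 weights, not both 0")
  }
  p1 <- w[["type1"]] / sum(w)
  if (stats::runif(1) < p1) "CD4Th1" else "CD4Th2"
}

#' Efferocytosis: a DC engulfs an apoptotic corpse
#'
#' The corpse transitions to `removed`. Apoptotic T cells contribute
#' TCR-derived antigen (`TCR_source`: Fr3 and CDR1/2 peptides); neuron
#' debris contributes myelin antigen (`MBP_source`). In mutually-exclusive
#' mode the DC locks onto the kind of the first corpse processed; later
#' corpses of the other kind are still engulfed but never processed into
#' presentable peptide (their inventory increment is discarded).
#'
#' @param dc a [dc_state()].
#' @param corpse an apoptotic agent: a `t_cell` or the string `"Neuron"`
#'   for neuron debris.
#' @param mutex_mode enforce mutually exclusive presentation.
#' @return list with elements `dc` (updated) and `corpse` (removed), or
#'   just `dc` when the corpse was neuron debris.
#' @export
efferocytose <- function(dc, corpse, mutex_mode = FALSE) {
  stopifnot(inherits(dc, "dc_state"))
  if (identical(corpse, "Neuron")) {
    kind <- "MBP_source"
    corpse <- NULL
  } else {
    stopifnot(inherits(corpse, "t_cell"))
    if (corpse$state != "apoptotic") {
      stop("efferocytose: corpse must be apoptotic (is ", corpse$state, ")")
    }
    kind <- "TCR_source"
    corpse$state <- "removed"
  }
  if (mutex_mode) {
    if (is.na(dc$mutex_lock)) dc$mutex_lock <- kind
    if (dc$mutex_lock == kind) {
      dc$inventory[kind] <- dc$inventory[kind] + 1L
    } # else: engulfed but never processed to peptide
  } else {
    dc$inventory[kind] <- dc$inventory[kind] + 1L
  }
  if (is.null(corpse)) list(dc = dc) else list(dc = dc, corpse = corpse)
}

#' Probabilistic peptide presentation by a mature DC
#'
#' Each processed inventory kind has a per-step chance of reaching the cell
#' surface: `MBP_source` yields `MHCII_MBP`; `TCR_source` yields
#' `MHCII_Fr3` and, while Qa-1 is expressed, the cross-presented
#' `QA1_CDR12` complex. Displayed complexes persist (the display duration
#' is the remainder of the DC's life). `QA1_CDR12` is re-derived whenever
#' Qa-1 expression begins on a DC already presenting Fr3.
#'
#' @param dc a mature [dc_state()].
#' @param p_mbp,p_tcr per-step presentation probabilities.
#' @return updated `dc_state`.
#' @export
derive_presentation <- function(dc, p_mbp = 0.5, p_tcr = 0.5) {
  stopifnot(inherits(dc, "dc_state"))
  if (dc$maturity != "mature") stop("derive_presentation: DC must be mature")
  if (dc$inventory[["MBP_source"]] > 0 &&
      !("MHCII_MBP" %in% dc$presented) && stats::runif(1) < p_mbp) {
    dc$presented <- union(dc$presented, "MHCII_MBP")
  }
  if (dc$inventory[["TCR_source"]] > 0 &&
      !("MHCII_Fr3" %in% dc$presented) && stats::runif(1) < p_tcr) {
    dc$presented <- union(dc$presented, "MHCII_Fr3")
  }
  if ("MHCII_Fr3" %in% dc$presented && dc$qa1_expressed) {
    dc$presented <- union(dc$presented, "QA1_CDR12")
  }
  validate_dc(dc)
}

#' CD4Treg licensing of a dendritic cell
#'
#' Signal 1 is the Fr3-MHCII complex that activated the CD4Treg; signal 2
#' is the CD40-CD40L bind formed by the effector CD4Treg, which licenses
#' the DC to express Qa-1. Only the first licensing contact is recorded.
#'
#' @param dc a [dc_state()] presenting `MHCII_Fr3`.
#' @param treg an effector CD4Treg [t_cell()] with `has_CD40L`.
#' @param t current simulation time in hours.
#' @return updated `dc_state` with `licensed`, `qa1_expressed` set and
#'   `licensing_time` recorded at the first licensing only.
#' @export
license_dc <- function(dc, treg, t) {
  stopifnot(inherits(dc, "dc_state"), inherits(treg, "t_cell"))
  if (treg$lineage != "CD4Treg" || treg$state != "effector" ||
      !treg$has_CD40L) {
    stop("license_dc: licensing requires an effector CD4Treg with CD40L")
  }
  if (!("MHCII_Fr3" %in% dc$presented)) {
    stop("license_dc: DC does not present MHCII-Fr3")
  }
  if (!dc$licensed) {
    dc$licensed <- TRUE
    dc$qa1_expressed <- TRUE
    dc$licensing_time <- t
    if ("MHCII_Fr3" %in% dc$presented) {
      dc$presented <- union(dc$presented, "QA1_CDR12")
    }
  }
  validate_dc(dc)
}

#' Constitutive Qa-1 expression after a fixed delay
#'
#' Used with CD4Treg abrogation: Qa-1 appears once DC age reaches the
#' policy delay (closed lower bound, age >= delay), with no licensing.
#'
#' @param dc a [dc_state()].
#' @param policy a [qa1_policy()] in `constitutive_after_delay` mode.
#' @param t current simulation time in hours.
#' @return updated `dc_state`.
#' @export
constitutive_qa1_update <- function(dc, policy, t) {
  stopifnot(inherits(dc, "dc_state"), inherits(policy, "qa1_policy"))
  if (policy$mode != "constitutive_after_delay") {
    stop("constitutive_qa1_update: policy mode is licensing_required")
  }
  dc$qa1_expressed <- (t - dc$creation_time) >= policy$delay
  if (dc$qa1_expressed && "MHCII_Fr3" %in% dc$presented) {
    dc$presented <- union(dc$presented, "QA1_CDR12")
  } else if (!dc$qa1_expressed) {
    dc$presented <- setdiff(dc$presented, "QA1_CDR12")
  }
  validate_dc(dc)
}

#' One priming contact between a T cell and a DC
#'
#' A T cell bound to a DC that displays its cognate complex advances one
#' maturity stage per completed contact
#' (naive -> partially_activated -> effector). An unpolarized CD4Th commits
#' to Th1 or Th2 (via [polarize_cd4th()]) when it reaches effector. A
#' mismatch between specificity and the displayed complexes is a no-op, not
#' an error: the cell simply fails to engage.
#'
#' @param tcell a [t_cell()] in state naive or partially_activated.
#' @param dc the [dc_state()] it is bound to.
#' @param milieu polarization milieu passed to [polarize_cd4th()] when an
#'   unpolarized CD4Th activates.
#' @param effector_lifespan hours assigned to `effector_clock` on
#'   activation.
#' @return updated `t_cell`.
#' @export
prime_t_cell <- function(tcell, dc, milieu = c(type1 = 0.9, type2 = 0.1),
                         effector_lifespan = 96) {
  stopifnot(inherits(tcell, "t_cell"), inherits(dc, "dc_state"))
  if (!(tcell$state %in% c("naive", "partially_activated"))) return(tcell)
  cognate <- .COGNATE[[tcell$specificity]]
  if (!(cognate %in% dc$presented)) return(tcell)  # mismatch: no-op
  if (tcell$state == "naive") {
    tcell$state <- "partially_activated"
  } else {
    tcell$state <- "effector"
    tcell$effector_clock <- effector_lifespan
    if (tcell$lineage == "CD4Th_naive_unpolarized") {
      tcell$lineage <- polarize_cd4th(tcell, milieu)
      tcell$specificity <- lineage_specificity(tcell$lineage)
    }
    if (tcell$lineage == "CD4Treg") tcell$has_CD40L <- TRUE
  }
  tcell
}

#' CD8Treg killing of an encephalitogenic CD4Th1 cell
#'
#' An effector CD8Treg induces apoptosis in a co-located activated/effector
#' CD4Th1. Selectivity is absolute: any other target lineage is a contract
#' error.
#'
#' @param killer effector CD8Treg [t_cell()].
#' @param target activated or effector CD4Th1 [t_cell()].
#' @return the target, now apoptotic.
#' @export
cd8treg_kill <- function(killer, target) {
  stopifnot(inherits(killer, "t_cell"), inherits(target, "t_cell"))
  if (killer$lineage != "CD8Treg" || killer$state != "effector") {
    stop("cd8treg_kill: killer must be an effector CD8Treg")
  }
  if (target$lineage != "CD4Th1") {
    stop("cd8treg_kill: CD8Treg killing is selective for CD4Th1 targets")
  }
  if (!(target$state %in% c("partially_activated", "effector"))) {
    stop("cd8treg_kill: target must be activated or effector")
  }
  target$state <- "apoptotic"
  target
}

#' Advance an agent's clocks by one time step
#'
#' Effector CD4Th1 whose effector clock expires undergo activation-induced
#' cell death (deterministic at expiry); other effector lineages likewise
#' become apoptotic at clock expiry.
#'
#' @param agent a [t_cell()].
#' @param dt hours.
#' @return updated agent.
#' @export
step_lifecycle <- function(agent, dt = 1) {
  stopifnot(inherits(agent, "t_cell"))
  if (agent$state == "removed") stop("step_lifecycle: agent is removed")
  agent$age <- agent$age + dt
  if (agent$state == "effector" && !is.na(agent$effector_clock)) {
    agent$effector_clock <- agent$effector_clock - dt
    if (agent$effector_clock <= 0) {
      agent$state <- "apoptotic"
      agent$has_CD40L <- FALSE
    }
  }
  agent
}
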