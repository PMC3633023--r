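# Compartments, grid occupancy and migration rules. The compiled engine
# holds its own grid state; these functions define and test the rules it
# applies, and build the grid geometry passed to it.

#' Grid-space occupancy policy
#'
#' Under the `standard` rule every space holds at most `capacity` T cells.
#' The `relaxed_cd8` rule removes CD8Treg cells from that competition:
#' a CD8Treg may enter a space whenever the space holds fewer than
#' `cd8_cap` CD8Treg, irrespective of how many CD4Treg (or other) cells
#' already reside there; all other lineages still obey the standard rule.
#' `cd8_cap` is set empirically from the median CD8Treg neighbour count of
#' apoptotic DCs in a preliminary CD4Treg-abrogated ensemble
#' (see [cd8_neighbour_cap()]).
#'
#' @param mode `"standard"` or `"relaxed_cd8"`.
#' @param cd8_cap integer >= 1; required in relaxed mode.
#' @export
occupancy_policy <- function(mode = c("standard", "relaxed_cd8"),
                             cd8_cap = NA_integer_) {
  mode <- match.arg(mode)
  if (mode == "relaxed_cd8" &&
      (is.na(cd8_cap) || cd8_cap < 1)) {
    stop("relaxed_cd8 requires cd8_cap >= 1 (run the neighbour census first)")
  }
  structure(list(mode = mode, cd8_cap = as.integer(cd8_cap)),
            class = "occupancy_policy")
}

#' May a cell enter a grid space?
#'
#' @param occupants character vector of the lineages currently in the
#'   space.
#' @param capacity the space's standard capacity.
#' @param lineage lineage of the entering cell.
#' @param policy an [occupancy_policy()].
#' @return logical.
#' @export
occupancy_allowed <- function(occupants, capacity, lineage,
                              policy = occupancy_policy()) {
  stopifnot(inherits(policy, "occupancy_policy"))
  if (policy$mode == "relaxed_cd8" && lineage == "CD8Treg") {
    return(sum(occupants == "CD8Treg") < policy$cd8_cap)
  }
  length(occupants) < capacity
}

# migration edges: from, to, lineage restriction ("" = any), state
# restriction ("" = any)
.MIGRATION_EDGES <- data.frame(
  from = c("Circulation", "Circulation", "CLN", "Spleen",
           "Circulation", "CNS", "CNS", "CNS"),
  to = c("CLN", "Spleen", "Circulation", "Circulation",
         "CNS", "CLN", "Spleen", "CLN"),
  lineage = c("", "", "", "", "CD4Th1", "CD4Th1", "CD4Th1",
              "DendriticCell"),
  state = c("", "", "", "", "effector", "apoptotic", "apoptotic",
            ""),
  stringsAsFactors = FALSE
)

#' Is a compartment move a permitted migration edge?
#'
#' The permitted edges are: any T cell recirculates between Circulation and
#' the lymphoid compartments (CLN, Spleen); effector CD4Th1 enter the CNS
#' from Circulation; apoptotic CD4Th1 drain from the CNS to the CLN or
#' Spleen; mature DCs migrate from the CNS to the CLN.
#'
#' @param lineage,state the migrating agent's lineage and maturity state.
#' @param from,to compartment names.
#' @return logical.
#' @export
migration_allowed <- function(lineage, state, from, to) {
  e <- .MIGRATION_EDGES
  any(e$from == from & e$to == to &
        (e$lineage == "" | e$lineage == lineage) &
        (e$state == "" | e$state == state))
}

#' Census of T-cell neighbours around a DC
#'
#' Counts neighbours by lineage. The engine records this census, over the
#' DC's own grid space plus its Moore-adjacent spaces, whenever a DC enters
#' apoptosis; the median CD8Treg count of those records parameterizes the
#' relaxed occupancy rule.
#'
#' @param lineages character vector of neighbour lineages.
#' @return named integer vector of counts over the five T-cell lineages.
#' @export
neighbour_census <- function(lineages) {
  tc <- LINEAGES[1:5]
  if (!all(lineages %in% tc)) {
    stop("neighbour_census: unknown T-cell lineage in input")
  }
  counts <- vapply(tc, function(l) sum(lineages == l), integer(1))
  names(counts) <- tc
  counts
}

#' Grid geometry of the lean default world
#'
#' Builds the per-compartment grid dimensions and Moore adjacency used by
#' the engine. Spleen and CLN grids are small and genuinely contested at
#' default population sizes, since contestedness around priming DCs is the
#' object of the spatial-relaxation experiment; Circulation is a single
#' uncontested transit space.
#'
#' @param config a [sim_config()].
#' @return list with per-compartment `nx`, `ny`, `capacity`.
#' @keywords internal
grid_geometry <- function(config) {
  list(
    CNS = list(nx = config$grid_cns_nx, ny = config$grid_cns_ny,
               capacity = config$capacity_cns),
    CLN = list(nx = config$grid_cln_nx, ny = config$grid_cln_ny,
               capacity = config$capacity_lymphoid),
    Spleen = list(nx = config$grid_spleen_nx, ny = config$grid_spleen_ny,
                  capacity = config$capacity_lymphoid),
    Circulation = list(nx = 1L, ny = 1L, capacity = 1000000L)
  )
}
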