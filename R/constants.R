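#' Cell lineages modelled by the simulator
#'
#' Naive CD4Th cells are unpolarized; polarization to Th1 or Th2 happens
#' once, at activation, and is irreversible.
#' @export
LINEAGES <- c("CD4Th_naive_unpolarized", "CD4Th1", "CD4Th2",
              "CD4Treg", "CD8Treg", "DendriticCell", "Microglia", "Neuron")

#' Maturity states, in their only permitted order
#'
#' Transitions move strictly forward; `removed` agents take part in no
#' further interactions and are excluded from population counts.
#' @export
MATURITY_STATES <- c("naive", "partially_activated", "effector",
                     "apoptotic", "removed")

#' Spatial compartments
#' @export
COMPARTMENTS <- c("CNS", "CLN", "Spleen", "Circulation")

#' Peptide-MHC complexes a dendritic cell can display
#'
#' `MHCII_MBP` derives from engulfed myelin debris (neurons, immunization
#' bolus); `MHCII_Fr3` and `QA1_CDR12` derive from the TCR of efferocytosed
#' apoptotic CD4Th1 cells. `QA1_CDR12` is only displayed while the DC's
#' Qa-1 expression flag is set.
#' @export
PRESENTED_COMPLEXES <- c("MHCII_MBP", "MHCII_Fr3", "QA1_CDR12")

#' Antigen source kinds in a DC's engulfed inventory
#' @export
SOURCE_KINDS <- c("MBP_source", "TCR_source")

# specificity implied by lineage (clonal repertoires are out of scope)
.SPECIFICITY <- c(CD4Th_naive_unpolarized = "MBP", CD4Th1 = "MBP",
                  CD4Th2 = "MBP", CD4Treg = "Fr3", CD8Treg = "CDR1_2")

# complex recognised by each T-cell specificity
.COGNATE <- c(MBP = "MHCII_MBP", Fr3 = "MHCII_Fr3", CDR1_2 = "QA1_CDR12")

#' Specificity of a T-cell lineage
#'
#' MBP for the encephalitogenic CD4Th lineages, TCR framework region 3
#' (Fr3) for CD4Treg, TCR CDR1/2 for CD8Treg.
#' @param lineage lineage name(s).
#' @return character vector of specificities.
#' @export
lineage_specificity <- function(lineage) {
  out <- .SPECIFICITY[lineage]
  if (anyNA(out)) stop("no T-cell specificity for lineage: ",
                       paste(lineage[is.na(out)], collapse = ", "))
  unname(out)
}
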