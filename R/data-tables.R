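# Shipped reference assessment tables (published per-ensemble deviations)
# and group summaries over them.

#' Load the shipped ensemble assessment table
#'
#' Per-ensemble deviations between ensemble-model predictions and measured
#' observables for the IDP8 reference set: SAXS chi, chemical-shift RMSDs
#' per atom type (ppm) and CD RMSD (kMRE), for the published reference
#' ensembles (groups A-C) and the unrefined initial MD ensembles
#' (group 0).
#'
#' @return Data frame with columns `group`, `ensemble`, `saxs_chi`,
#'   `cs_ca`, `cs_cb`, `cs_co`, `cd_rmsd`.
#' @export
idp8_model_assessment <- function() {
  utils::read.table(system.file("extdata", "idp8_model_assessment.tsv",
                                package = "bmecd"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c("character", "character",
                                   rep("numeric", 5)))
}

#' Load the shipped CD prediction accuracy table
#'
#' Per-ensemble RMSDs (kMRE) between measured CD spectra and predictions
#' from the reference ensemble models, for four basis-set variants and two
#' external prediction methods; `refined_basis` marks the basis set used
#' during CD-aware refinement of the group B ensembles.
#'
#' @return Data frame with columns `group`, `ensemble`, one column per
#'   method, and `refined_basis`.
#' @export
idp8_cd_prediction_rmsd <- function() {
  utils::read.table(system.file("extdata", "idp8_cd_prediction_rmsd.tsv",
                                package = "bmecd"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, na.strings = "NA")
}

#' Group summaries of the shipped assessment tables
#'
#' Recomputes, via [summarize_metrics()], the per-group mean and standard
#' error of every assessment column: SAXS chi, per-atom-type
#' chemical-shift RMSD and CD RMSD by group (A, B, C and the unrefined
#' group 0), plus the CD-prediction summaries (group B and C over all four
#' basis sets, and group B restricted to the basis set used in its
#' refinement).
#'
#' @return Named list of `group_summary` objects.
#' @export
idp8_group_summaries <- function() {
  ma <- idp8_model_assessment()
  cd <- idp8_cd_prediction_rmsd()
  out <- list()
  for (g in c("A", "B", "C", "0")) {
    sub <- ma[ma$group == g, ]
    for (col in c("saxs_chi", "cs_ca", "cs_cb", "cs_co", "cd_rmsd"))
      out[[paste0(col, "_group", g)]] <- summarize_metrics(sub[[col]])
  }
  basis_cols <- c("DS-dTSC3", "DSSP-1SC3", "HBSS-3SC1", "DS5-4SC1")
  for (g in c("B", "C")) {
    v <- unlist(cd[cd$group == g, basis_cols], use.names = FALSE)
    out[[paste0("cd_allbasis_group", g)]] <- summarize_metrics(v)
  }
  bb <- cd[cd$group == "B", ]
  out$cd_refined_basis_groupB <- summarize_metrics(
    vapply(seq_len(nrow(bb)), function(i) bb[[bb$refined_basis[i]]][i],
           numeric(1)))
  out
}
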