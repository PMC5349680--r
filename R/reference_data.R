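# Packaged reference datasets (plain-text, under inst/extdata).

#' Published reference candidate list
#'
#' The transcribed candidate list from a carp photoreceptor
#' membrane-fractionation experiment: 48 membrane proteins with their emPAI
#' values in the COS-rich and CIS-rich fractions (for 5e4 cones), the printed
#' COS/(COS+CIS) share, and the localization annotation (8 known
#' COS-specific, 16 known to reside elsewhere, 24 unassigned). Shares in the
#' `share_printed` column were originally computed from unrounded emPAI
#' values, so recomputing them from the rounded emPAI columns reproduces most
#' but not all rows at three decimals.
#'
#' @return a data.frame with columns `protein_id`, `mass_kda`, `empai_cos`,
#'   `empai_cis`, `share_printed`, `annotation_class`.
#' @export
cos_reference_candidates <- function() {
  path <- system.file("extdata", "cos_candidate_reference.tsv",
                      package = "cosfrac", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published reference marker recoveries
#'
#' Marker-protein recoveries (percent of the initial membranes, with SEM)
#' in the upper and lower gradient fractions of rod and cone preparations:
#' visual pigment for OS membranes, F1 ATPase beta subunit and TOM20 for
#' mitochondrial inner/outer membranes, Na+/K+ ATPase alpha subunit for IS
#' plasma membranes and calnexin for ER membranes. `percent` is `NA` where
#' the signal was not detected.
#'
#' @return a data.frame with columns `marker`, `compartment`, `cell_type`,
#'   `fraction`, `percent`, `sem`.
#' @export
reference_marker_recoveries <- function() {
  path <- system.file("extdata", "marker_recovery_reference.tsv",
                      package = "cosfrac", mustWork = TRUE)
  read_marker_table(path)
}
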