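# Loaders for the packaged reference tables: the published CaMBD codon
# grid, replicate ipTM scores and ddG estimates that drive the golden
# tests. These are static fixtures, separate from the random generators.

.extdata <- function(file) {
  system.file("extdata", file, package = "cambdscan", mustWork = TRUE)
}

#' Published CaMBD codon table
#'
#' The 18-codon windows of the 11 human PMCA isoform/variant CaMBDs,
#' positions T01-T18.
#'
#' @return Character matrix of lower-case codons, rows named by isoform
#'   (with an `accession` attribute), columns `T1...T18`.
#' @export
cambd_codon_table <- function() {
  df <- utils::read.delim(.extdata("table1_codons.tsv"),
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, grep("^t\\d+$", names(df))])
  dimnames(m) <- list(df$isoform, paste0("T", 1:18))
  attr(m, "accession") <- stats::setNames(df$accession, df$isoform)
  m
}

#' Published nucleotide-conservation star profile
#'
#' @return Integer vector of 18 star counts (0-3), one per window
#'   position.
#' @export
cambd_star_profile <- function() {
  df <- utils::read.delim(.extdata("conservation_stars.tsv"))
  stats::setNames(as.integer(df$stars), paste0("T", df$position))
}

#' Published replicate ipTM table
#'
#' Five-model ipTM replicates for every wild-type, literature-reported
#' and evaluated-substitution CaM-CaMBD complex, together with the
#' published 95% interval bounds (`printed_lo`, `printed_hi`).
#'
#' @return Data frame with `group`, `variant`, `model_0...model_4`,
#'   `printed_lo`, `printed_hi`.
#' @export
cambd_iptm_table <- function() {
  utils::read.delim(.extdata("table2_iptm.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published ddG estimate grid
#'
#' The 70 binding free-energy changes for the evaluated substitutions:
#' 7 window groups x 5 substitution classes x 2 methods.
#'
#' @return Long data frame with `group`, `substitution`, `method`, `ddg`.
#' @export
cambd_ddg_table <- function() {
  utils::read.delim(.extdata("table3_ddg.tsv"), stringsAsFactors = FALSE)
}

#' Published literature-mutation energies
#'
#' FoldX and MutaBind2 ddG for the three literature-reported CaMBD
#' mutations, with the underlying FoldX binding energies. The published
#' FoldX ddG for the PMCA3b G1107D row (9.29) does not equal
#' `dg_mut - dg_wt` from the printed energies (11.27); both are carried
#' and the discrepancy is noted rather than silently corrected.
#'
#' @return Data frame with `complex`, `mutation`, `foldx_ddg`,
#'   `mutabind2_ddg`, `dg_mut`, `dg_wt`.
#' @export
cambd_literature_ddg <- function() {
  utils::read.delim(.extdata("literature_ddg.tsv"),
                    stringsAsFactors = FALSE)
}

#' Build CaMBD windows from a codon table
#'
#' Translates each isoform's 18 codons into a window object; useful for
#' driving the substitution workflow directly from the packaged codon
#' grid when full-length proteins are not at hand.
#'
#' @param codon_matrix Matrix from [cambd_codon_table()] (isoforms x 18).
#' @param reference_offset Reference numbering offset (default 1092).
#' @return List of [cambd_window()] objects, one per row.
#' @export
windows_from_codon_table <- function(codon_matrix,
                                     reference_offset = 1092L) {
  lapply(rownames(codon_matrix), function(iso) {
    codons <- as.character(codon_matrix[iso, ])
    cambd_window(member_isoforms = iso,
                 residues = translate_cds(paste(codons, collapse = "")),
                 codons = codons,
                 reference_numbering_offset = reference_offset)
  })
}
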