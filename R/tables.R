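# Bundled reference tables: RI-MP2/def2-TZVP interaction energies and
# QTAIM/NCI densities of the small bimolecular model complexes, and the
# intramolecular backbone tetrel-bond records of the ATSP, p53 and pDIQ
# peptide clusters plus the 4N5T crystal structure. These are transcribed
# literature values consumed as calibration input; the package never
# recomputes them quantum-mechanically.

#' Model-complex calibration table
#'
#' Ten bimolecular complexes of a cyclic amide (and its urea-bound,
#' hydrogen-bond-reinforced analogue) with small Lewis bases. Columns:
#' `complex` (id; 2-6 are the plain tetrel-bond complexes, 8-12 the
#' HB-reinforced ones), `dE` (counterpoise-corrected interaction energy,
#' kcal/mol), `d` (equilibrium O...C distance, A), `rho100` (electron
#' density at the tetrel-bond critical point, a.u. x 100) and
#' `rho100_ancillary` (density at the co-occurring secondary-contact
#' critical point, a.u. x 100).
#'
#' @param subset optional integer vector of complex ids to keep.
#' @return data.frame.
#' @examples
#' ttb_model_complexes(subset = 2:6)
#' @export
ttb_model_complexes <- function(subset = NULL) {
  path <- system.file("extdata", "model_complexes.tsv", package = "ttbscan",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(subset)) df <- df[df$complex %in% subset, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Intramolecular peptide tetrel-bond records
#'
#' Backbone C=O...C=O contacts of the ATSP, p53 and pDIQ simulation-ensemble
#' clusters and the ATSP crystal structure (PDB 4N5T), with NCI-isosurface
#' densities (`rho100`, a.u. x 100), interaction energies (`dE`, kcal/mol)
#' and O...C distances (`d`, A). Residue names are NA for the crystal
#' records, whose table prints ids only.
#'
#' @param structures optional character vector, e.g. `c("ATSP", "pDIQ")`;
#'   `"4N5T"` selects the crystal-structure block.
#' @return data.frame with columns `structure, contact_id, res_i, res_j,
#'   rho100, dE, d`.
#' @export
ttb_peptide_contacts <- function(structures = NULL) {
  path <- system.file("extdata", "peptide_ttbs.tsv", package = "ttbscan",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA",
                          colClasses = c(structure = "character",
                                         contact_id = "character"))
  if (!is.null(structures)) df <- df[df$structure %in% structures, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Default density-to-energy calibration
#'
#' The least-squares line of interaction energy on `rho100` fitted to model
#' complexes 2-6 (the HB-reinforced complexes 8-12 are withheld as an
#' out-of-sample check, and complex 12 — the one case where tetrel and
#' ancillary densities diverge strongly — is excluded from fitting
#' altogether).
#'
#' @param ancillary_fraction share of the predicted energy assigned to the
#'   tetrel bond itself (default 0.5).
#' @return a `ttb_calibration` model.
#' @export
default_calibration <- function(ancillary_fraction = 0.5) {
  fit_calibration(ttb_model_complexes(subset = 2:6),
                  ancillary_fraction = ancillary_fraction)
}

#' Default distance-to-density surrogate
#'
#' Exponential decay model fitted to the 21 paired (d, rho100) records of
#' the ATSP/p53/pDIQ ensemble clusters, used to estimate a density when
#' only geometry is available.
#'
#' @return a `ttb_distance_density` model.
#' @export
default_distance_density <- function() {
  df <- ttb_peptide_contacts(structures = c("ATSP", "p53", "pDIQ"))
  fit_distance_density(data.frame(label = df$contact_id,
                                  rho100 = df$rho100, d_OC = df$d))
}
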