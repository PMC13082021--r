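# Atomic coordinate input: Calpha extraction from PDB/mmCIF via bio3d,
# producing the (protein, residue) -> coordinate lookup used for
# distance-restraint mapping.

#' Read a coordinate model into a structure map
#'
#' Extracts one Calpha per (chain, author residue number) from a PDB or
#' mmCIF file. Alternate locations resolve to the highest-occupancy copy;
#' residues with insertion codes are rejected (renumber upstream). Chains
#' are mapped to protein identifiers through `chain_map`; chains absent
#' from the map are skipped with a warning. Coordinates stay in Angstrom.
#'
#' @param path PDB or mmCIF file.
#' @param chain_map named character vector `chain -> protein id`; `NULL`
#'   uses the chain id as the protein id.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a [structure_map()].
#' @export
read_structure <- function(path, chain_map = NULL,
                           format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("read_structure: no such file: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
  else bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0) stopf("read_structure: no Calpha atoms in %s", path)
  ins <- !is.na(ca$insert) & nzchar(as.character(ca$insert))
  if (any(ins))
    stopf("read_structure: %d residue(s) carry insertion codes; renumber the model first",
          sum(ins))
  # altloc: keep the highest-occupancy copy per (chain, residue)
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  ca <- ca[order(ca$chain, ca$resno, -occ), , drop = FALSE]
  ca <- ca[!duplicated(ca[, c("chain", "resno")]), , drop = FALSE]
  if (is.null(chain_map)) {
    chain_map <- stats::setNames(unique(ca$chain), unique(ca$chain))
  }
  known <- ca$chain %in% names(chain_map)
  if (!all(known)) {
    skipped <- unique(ca$chain[!known])
    warning(sprintf("read_structure: skipped %d atom(s) on unmapped chain(s): %s",
                    sum(!known), paste(skipped, collapse = ", ")))
    ca <- ca[known, , drop = FALSE]
  }
  if (nrow(ca) == 0) stopf("read_structure: no mapped chains remain")
  structure_map(data.frame(
    protein = unname(chain_map[ca$chain]),
    chain = ca$chain,
    residue = as.integer(ca$resno),
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE))
}
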