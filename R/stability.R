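# Atom and molecule stability: an atom is stable iff its summed inferred
# bond orders hit a permitted valence for its element (and charge, where
# tabled); a molecule is stable iff all of its atoms are.

atom_stability_flags <- function(mol, table = default_bond_table()) {
  B <- infer_bonds(mol, table)
  val <- rowSums(B)
  vapply(seq_along(mol$elements), function(i) {
    allowed <- allowed_valences_for(table, mol$elements[i], mol$charges[i])
    if (is.null(allowed)) return(FALSE)
    val[i] %in% allowed
  }, logical(1))
}

#' Atom and molecule stability of a molecule set
#'
#' @param mols non-empty list of [molecule_record()]s.
#' @param table a [default_bond_table()].
#' @return tibble with one row: `n_molecules`, `n_atoms`,
#'   `atom_stable_frac`, `mol_stable_frac` (fractions in `[0, 1]`).
#' @export
atom_and_molecule_stability <- function(mols, table = default_bond_table()) {
  if (length(mols) == 0L) stop("empty molecule set.", call. = FALSE)
  flags <- lapply(mols, atom_stability_flags, table = table)
  tibble::tibble(
    n_molecules = length(mols),
    n_atoms = sum(lengths(flags)),
    atom_stable_frac = mean(unlist(flags)),
    mol_stable_frac = mean(vapply(flags, all, logical(1)))
  )
}

#' Full molecule-quality report for a generated set
#'
#' Aggregates atom/molecule stability, validity, valid-and-unique, and
#' (when a reference is supplied) novelty into one row. Uniqueness is the
#' number of distinct canonical SMILES among valid molecules divided by the
#' total sampled; novelty the fraction of valid-and-unique canonical SMILES
#' absent from the reference set.
#'
#' @param mols list of [molecule_record()]s.
#' @param reference_smiles optional character vector of canonical SMILES.
#' @param table a [default_bond_table()].
#' @return tibble of class `stability_report` with percentage columns.
#' @export
evaluate_molecules <- function(mols, reference_smiles = NULL,
                               table = default_bond_table()) {
  st <- atom_and_molecule_stability(mols, table)
  vu <- validity_uniqueness(mols, table)
  out <- tibble::tibble(
    n_molecules = st$n_molecules,
    atom_stable_pct = 100 * st$atom_stable_frac,
    mol_stable_pct = 100 * st$mol_stable_frac,
    valid_pct = vu$valid_pct,
    valid_unique_pct = vu$valid_unique_pct
  )
  if (!is.null(reference_smiles)) {
    out$novel_pct <- novelty(vu$unique_smiles, reference_smiles)
  }
  class(out) <- c("stability_report", class(out))
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  NextMethod()
  invisible(x)
}
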