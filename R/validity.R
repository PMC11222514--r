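# Validity, uniqueness, and novelty. A molecule is valid iff the bonds
# inferred from its geometry assemble into a sanitizable molecular graph
# under standard valence rules: no atom's total bond order may exceed the
# maximum permitted valence for its element and formal charge (radicals,
# i.e. under-bonded atoms, sanitize fine, mirroring the usual cheminformatics
# sanitizer semantics). Canonical SMILES come from the Open Babel CLI.

max_valence_for <- function(table, element, charge) {
  v <- allowed_valences_for(table, element, charge)
  if (is.null(v)) return(NA_real_)
  max(v)
}

#' Sanitize a molecule's inferred bond graph
#'
#' @param mol a [molecule_record()].
#' @param table a [default_bond_table()].
#' @param bonds optional precomputed bond-order matrix.
#' @return `TRUE` if every atom's summed bond order is within its maximum
#'   permitted valence and coordinates are finite.
#' @export
sanitize_molecule <- function(mol, table = default_bond_table(), bonds = NULL) {
  if (!all(is.finite(mol$coords))) return(FALSE)
  if (is.null(bonds)) bonds <- infer_bonds(mol, table)
  val <- rowSums(bonds)
  ok <- vapply(seq_along(mol$elements), function(i) {
    mx <- max_valence_for(table, mol$elements[i], mol$charges[i])
    !is.na(mx) && val[i] <= mx
  }, logical(1))
  all(ok)
}

ob_available <- function() {
  nzchar(Sys.which("obabel"))
}

require_openbabel <- function() {
  if (!ob_available()) {
    stop("the `obabel` command-line tool is required for canonical SMILES ",
         "and energy computations but was not found on PATH.", call. = FALSE)
  }
}

#' Canonical SMILES of a molecule set
#'
#' Writes the molecules (with their inferred bond blocks) to SDF and runs
#' them through Open Babel's canonical SMILES writer in a single batch
#' call. Molecules Open Babel cannot convert yield `NA`.
#'
#' @param mols list of [molecule_record()]s.
#' @param table bond table used to infer the bond blocks.
#' @return character vector of canonical SMILES (length of `mols`).
#' @export
canonical_smiles <- function(mols, table = default_bond_table()) {
  require_openbabel()
  if (length(mols) == 0L) return(character(0))
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  write_sdf(mols, tmp, bonds = lapply(mols, infer_bonds, table = table))
  out <- suppressWarnings(
    system2("obabel", c(shQuote(tmp), "-ocan"), stdout = TRUE, stderr = FALSE)
  )
  smi <- trimws(vapply(strsplit(out, "\t"), `[`, character(1), 1L))
  smi <- smi[nzchar(smi)]
  if (length(smi) != length(mols)) {
    # align by reconverting one-by-one so failures map to NA
    smi <- vapply(mols, function(m) {
      t1 <- tempfile(fileext = ".sdf")
      on.exit(unlink(t1), add = TRUE)
      write_sdf(list(m), t1, bonds = list(infer_bonds(m, table)))
      o <- suppressWarnings(system2("obabel", c(shQuote(t1), "-ocan"),
                                    stdout = TRUE, stderr = FALSE))
      if (length(o) == 0L) return(NA_character_)
      trimws(strsplit(o[1], "\t")[[1]][1])
    }, character(1))
  }
  smi
}

#' Validity and uniqueness of a molecule set
#'
#' @param mols list of [molecule_record()]s.
#' @param table a [default_bond_table()].
#' @return tibble with `valid_pct`, `valid_unique_pct`, plus the distinct
#'   canonical SMILES of the valid molecules in `unique_smiles`
#'   (list-column).
#' @export
validity_uniqueness <- function(mols, table = default_bond_table()) {
  bonds <- lapply(mols, infer_bonds, table = table)
  valid <- mapply(sanitize_molecule, mols, bonds,
                  MoreArgs = list(table = table))
  n <- length(mols)
  uniq <- character(0)
  if (any(valid)) {
    smi <- canonical_smiles(mols[valid], table)
    uniq <- unique(smi[!is.na(smi)])
  }
  tibble::tibble(
    valid_pct = 100 * mean(valid),
    valid_unique_pct = 100 * length(uniq) / max(n, 1L),
    unique_smiles = list(uniq)
  )
}

#' Novelty of generated molecules against a reference set
#'
#' @param generated_smiles canonical SMILES of the valid-and-unique
#'   generated molecules.
#' @param reference_smiles canonical SMILES of the reference dataset.
#' @return percentage of generated strings absent from the reference.
#' @export
novelty <- function(generated_smiles, reference_smiles) {
  if (is.list(generated_smiles)) generated_smiles <- unlist(generated_smiles)
  if (length(generated_smiles) == 0L) {
    stop("novelty is undefined for an empty generated set.", call. = FALSE)
  }
  100 * mean(!(generated_smiles %in% reference_smiles))
}

#' Embed SMILES strings in 3D via Open Babel
#'
#' Convenience used to turn literature SMILES into [molecule_record()]s:
#' each string is parsed, embedded with `--gen3d`, and read back from SDF.
#'
#' @param smiles character vector.
#' @return list of [molecule_record()]s (failed embeddings dropped with a
#'   warning).
#' @export
embed_smiles <- function(smiles) {
  require_openbabel()
  out <- list()
  for (s in smiles) {
    tmp <- tempfile(fileext = ".sdf")
    status <- suppressWarnings(
      system2("obabel", c(paste0("-:", shQuote(s)), "-osdf", "--gen3d",
                          "-O", shQuote(tmp)),
              stdout = FALSE, stderr = FALSE)
    )
    mols <- if (file.exists(tmp) && file.size(tmp) > 0) read_sdf(tmp) else list()
    unlink(tmp)
    if (length(mols) == 0L) {
      warning(sprintf("could not embed SMILES '%s'", s))
    } else {
      out <- c(out, mols[1])
    }
  }
  out
}
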