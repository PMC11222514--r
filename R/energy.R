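# Conformer energy-ratio statistic: the universal-force-field (UFF) energy
# of a given conformer divided by the mean UFF energy of a reference
# ensemble of conformers re-embedded from the same molecular graph. Ratios
# above 7 flag highly unlikely 3D conformations. Energies and conformers
# come from the Open Babel CLI: the reference ensemble is built by
# canonicalizing the graph to SMILES, re-embedding with gen3d, and running
# a weighted rotor conformer search.

smiles_of_graph <- function(mol, bonds) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  write_sdf(list(mol), tmp, bonds = list(bonds))
  out <- suppressWarnings(system2("obabel", c(shQuote(tmp), "-ocan"),
                                  stdout = TRUE, stderr = FALSE))
  if (length(out) == 0L) return(NA_character_)
  trimws(strsplit(out[1], "\t")[[1]][1])
}

obenergy_uff <- function(sdf_path) {
  out <- suppressWarnings(
    system2("obenergy", c("-ff", "UFF", shQuote(sdf_path)),
            stdout = TRUE, stderr = FALSE)
  )
  hits <- grep("^TOTAL ENERGY", out, value = TRUE)
  as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", hits))
}

#' Energy ratio of a molecule's conformation
#'
#' Numerator: the UFF energy of the molecule as given (bonds inferred from
#' its geometry). Denominator: the mean UFF energy over `n_conformers`
#' conformers generated from the molecule's canonical graph by 3D
#' re-embedding plus a knowledge-based rotor search. Rigid molecules yield
#' a single reference conformer. Embedding failures or a non-positive
#' reference mean give an unavailable result (excluded from aggregates but
#' counted).
#'
#' @param mol a [molecule_record()].
#' @param n_conformers reference ensemble size (default 50).
#' @param table bond table for graph inference.
#' @param bonds optional explicit bond-order matrix defining the molecular
#'   graph (defaults to [infer_bonds()] on the given geometry); supply the
#'   undistorted graph when scoring deliberately distorted conformers.
#' @return list of class `energy_ratio_result`: `ratio`,
#'   `n_reference_conformers`, `flag_unlikely` (`ratio > 7`), `available`.
#' @export
energy_ratio <- function(mol, n_conformers = 50L, table = default_bond_table(),
                         bonds = NULL) {
  if (is.null(bonds)) bonds <- infer_bonds(mol, table)
  require_openbabel()
  unavailable <- structure(
    list(ratio = NA_real_, n_reference_conformers = 0L,
         flag_unlikely = NA, available = FALSE),
    class = "energy_ratio_result")

  tmp_in <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in)), add = TRUE)
  write_sdf(list(mol), tmp_in, bonds = list(bonds))
  e_mol <- obenergy_uff(tmp_in)
  if (length(e_mol) != 1L || !is.finite(e_mol)) return(unavailable)

  smi <- smiles_of_graph(mol, bonds)
  if (is.na(smi)) return(unavailable)
  emb <- tempfile(fileext = ".sdf")
  confs <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(emb, confs)), add = TRUE)
  suppressWarnings(system2("obabel", c(paste0("-:", shQuote(smi)), "-osdf",
                                       "--gen3d", "-O", shQuote(emb)),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(emb) || file.size(emb) == 0) return(unavailable)
  suppressWarnings(system2("obabel", c(shQuote(emb), "-O", shQuote(confs),
                                       "--conformer", "--nconf", n_conformers,
                                       "--writeconformers"),
                           stdout = FALSE, stderr = FALSE))
  ref_path <- if (file.exists(confs) && file.size(confs) > 0) confs else emb
  e_ref <- obenergy_uff(ref_path)
  e_ref <- e_ref[is.finite(e_ref)]
  if (length(e_ref) == 0L || mean(e_ref) <= 0) return(unavailable)

  ratio <- e_mol / mean(e_ref)
  structure(
    list(ratio = ratio, n_reference_conformers = length(e_ref),
         flag_unlikely = ratio > 7, available = TRUE),
    class = "energy_ratio_result")
}

#' @export
print.energy_ratio_result <- function(x, ...) {
  if (!x$available) {
    cat("<energy_ratio_result> unavailable (embedding failed)\n")
  } else {
    cat(sprintf("<energy_ratio_result> ratio = %.3f over %d reference conformers%s\n",
                x$ratio, x$n_reference_conformers,
                if (isTRUE(x$flag_unlikely)) "  [UNLIKELY conformation: ratio > 7]" else ""))
  }
  invisible(x)
}

#' Energy-ratio summary of a molecule set
#'
#' Mean energy ratio with a Student's t 95% confidence interval over the
#' available molecules.
#'
#' @param mols list of [molecule_record()]s.
#' @param n_conformers reference ensemble size per molecule.
#' @param table bond table.
#' @return tibble: `n`, `n_unavailable`, `mean_ratio`, `ci_low`, `ci_high`,
#'   `frac_unlikely`, plus a `ratios` list-column.
#' @export
energy_ratio_summary <- function(mols, n_conformers = 50L,
                                 table = default_bond_table()) {
  res <- lapply(mols, energy_ratio, n_conformers = n_conformers, table = table)
  ratios <- vapply(res, `[[`, numeric(1), "ratio")
  ok <- !is.na(ratios)
  r <- ratios[ok]
  ci <- c(NA_real_, NA_real_)
  if (length(r) >= 2L) {
    tt <- stats::t.test(r)
    ci <- as.numeric(tt$conf.int)
  }
  tibble::tibble(
    n = length(mols),
    n_unavailable = sum(!ok),
    mean_ratio = if (length(r)) mean(r) else NA_real_,
    ci_low = ci[1], ci_high = ci[2],
    frac_unlikely = if (length(r)) mean(r > 7) else NA_real_,
    ratios = list(ratios)
  )
}
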