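# Molecule <-> latent conversions. Atom types are one-hot encoded and
# scaled by 0.25, integer formal charges occupy one slot scaled by 0.1
# (EDM-lineage scalings); coordinates are centred on input.

#' Construct a molecule record
#'
#' The decoded object the model generates: element symbols, integer formal
#' charges, and Cartesian coordinates in Angstrom.
#'
#' @param elements character vector of element symbols.
#' @param coords N x 3 numeric matrix (Angstrom).
#' @param charges integer formal charges (default all zero).
#' @param property optional named scalar property (e.g. polarizability).
#' @return object of class `molecule_record`.
#' @export
molecule_record <- function(elements, coords, charges = NULL, property = NULL) {
  coords <- as.matrix(coords)
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom.", call. = FALSE)
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop("`coords` must be N x 3 with N = length(elements).", call. = FALSE)
  }
  if (is.null(charges)) charges <- integer(n)
  if (length(charges) != n) stop("`charges` must match N.", call. = FALSE)
  structure(list(elements = as.character(elements),
                 charges = as.integer(charges),
                 coords = unname(coords),
                 property = property),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s%s\n",
              paste0(x$elements, collapse = ""),
              if (is.null(x$property)) "" else
                sprintf("  [%s = %.4f]", names(x$property)[1], x$property[[1]])))
  invisible(x)
}

#' Default latent scalings for types and charges
#' @return list with `one_hot` (0.25) and `charge` (0.1).
#' @export
default_scaling <- function() list(one_hot = 0.25, charge = 0.1)

#' Encode a molecule as a clean latent state
#'
#' One-hot atom types and integer charges are packed into the feature
#' channel with per-block scaling; coordinates are centred onto the
#' zero-CoG subspace. Also returns the fully-connected directed edge list.
#'
#' @param mol a [molecule_record()].
#' @param alphabet character vector of allowed element symbols (column
#'   order of the one-hot block).
#' @param scaling list from [default_scaling()].
#' @return list with `z0` ([latent_state()] at t = 0) and `edges`.
#' @export
featurize <- function(mol, alphabet, scaling = default_scaling()) {
  stopifnot(inherits(mol, "molecule_record"))
  idx <- match(mol$elements, alphabet)
  if (anyNA(idx)) {
    stop(sprintf("element(s) outside alphabet: %s",
                 paste(unique(mol$elements[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  n <- length(idx)
  onehot <- matrix(0, n, length(alphabet))
  onehot[cbind(seq_len(n), idx)] <- 1
  zh <- cbind(onehot * scaling$one_hot, mol$charges * scaling$charge)
  z0 <- latent_state(project_zero_cog(mol$coords), zh, t = 0L)
  list(z0 = z0, edges = full_edges(n))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Decode a latent state back into a molecule
#'
#' Element = argmax over the unscaled one-hot block; charge = nearest
#' integer (ties rounded half away from zero) of the unscaled charge slot;
#' coordinates pass through. Always decodes.
#'
#' @param z0 a [latent_state()].
#' @param alphabet element alphabet used at encoding time.
#' @param scaling list from [default_scaling()].
#' @return a [molecule_record()].
#' @export
decode_latent <- function(z0, alphabet, scaling = default_scaling()) {
  stopifnot(inherits(z0, "latent_state"))
  K <- length(alphabet)
  onehot <- z0$zh[, seq_len(K), drop = FALSE] / scaling$one_hot
  onehot[!is.finite(onehot)] <- -Inf
  charges <- round_half_away(z0$zh[, K + 1L] / scaling$charge)
  # guard degenerate (diverged) latents: clamp into integer range
  charges[!is.finite(charges)] <- 0
  charges <- pmax(pmin(charges, 2^31 - 1), -(2^31 - 1))
  molecule_record(alphabet[max.col(onehot, ties.method = "first")],
                  z0$zx, as.integer(charges))
}

#' Empirical molecule-size distribution
#'
#' The categorical prior p(N) over atom counts, estimated from a training
#' set; its log-probability enters the likelihood log p(x, h, N).
#'
#' @param sizes integer vector of observed atom counts.
#' @return object of class `size_distribution` with `support` and `probs`.
#' @export
size_distribution <- function(sizes) {
  if (length(sizes) == 0L) stop("empty size sample.", call. = FALSE)
  tab <- table(factor(sizes))
  structure(list(support = as.integer(names(tab)),
                 probs = as.numeric(tab) / sum(tab)),
            class = "size_distribution")
}

#' Draw an atom count from a size distribution
#' @param dist a [size_distribution()].
#' @return single integer from the support.
#' @export
sample_num_atoms <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  if (length(dist$support) == 0L) stop("empty support.", call. = FALSE)
  dist$support[sample.int(length(dist$support), 1L, prob = dist$probs)]
}

log_prob_size <- function(dist, n) {
  i <- match(n, dist$support)
  if (is.na(i) || dist$probs[i] <= 0) {
    stop(sprintf("molecule size %d has zero probability under p(N).", n),
         call. = FALSE)
  }
  log(dist$probs[i])
}
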