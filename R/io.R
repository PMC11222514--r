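# Molecular file formats: XYZ and SDF V2000, lossless at the declared
# precision (XYZ is written with 6 decimals; formal charges travel in SDF
# `M  CHG` lines), plus SMILES line lists.

#' Read molecules from an XYZ file
#'
#' Standard multi-block XYZ: count line, comment line, then `element x y z`
#' rows. An empty file yields an empty list; malformed counts or
#' non-numeric coordinates raise a parse error naming the line.
#'
#' @param path file path.
#' @return list of [molecule_record()]s.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]),
           call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("line %d: count %d exceeds remaining rows", i, n),
           call. = FALSE)
    }
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad)) {
      stop(sprintf("line %d: malformed atom row", i + 1L + bad[1]), call. = FALSE)
    }
    el <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                    numeric(3)))
    if (anyNA(xyz)) {
      stop(sprintf("non-numeric coordinate near line %d", i + 2L), call. = FALSE)
    }
    mols[[length(mols) + 1L]] <- molecule_record(el, xyz)
    i <- i + 2L + n
  }
  mols
}

#' Write molecules to an XYZ file
#'
#' @param mols list of [molecule_record()]s.
#' @param path output path.
#' @param comment comment-line text (recycled).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mols, path, comment = "") {
  comment <- rep_len(comment, length(mols))
  out <- character(0)
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    out <- c(out, as.character(length(m$elements)), comment[k],
             sprintf("%s %.6f %.6f %.6f", m$elements,
                     m$coords[, 1], m$coords[, 2], m$coords[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read molecules from an SDF (V2000) file
#'
#' Parses elements, coordinates, and formal charges (from `M  CHG` lines;
#' old-style atom-block charge codes are also honoured). The bond block, if
#' present, is attached to each record as the `"bonds"` attribute (an
#' N x N order matrix). V3000 input raises an explicit unsupported-dialect
#' error.
#'
#' @param path file path.
#' @return list of [molecule_record()]s.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(c(TRUE, utils::head(lines, -1) == "$$$$")))
  mols <- list()
  for (bl in blocks) {
    bl <- bl[bl != "$$$$"]
    if (all(!nzchar(trimws(bl)))) next
    if (length(bl) < 4L) stop("truncated SDF block.", call. = FALSE)
    counts <- bl[4]
    if (grepl("V3000", counts)) {
      stop("SDF V3000 is not supported; supply V2000.", call. = FALSE)
    }
    n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(n_atoms) || is.na(n_bonds)) {
      stop("malformed SDF counts line.", call. = FALSE)
    }
    if (length(bl) < 4L + n_atoms) stop("SDF atom block truncated.", call. = FALSE)
    at <- bl[5:(4 + n_atoms)]
    xyz <- cbind(as.numeric(substr(at, 1, 10)),
                 as.numeric(substr(at, 11, 20)),
                 as.numeric(substr(at, 21, 30)))
    if (anyNA(xyz)) stop("non-numeric coordinate in SDF atom block.", call. = FALSE)
    el <- trimws(substr(at, 32, 34))
    # old-style charge codes: 1..7 encode +3..-3 (4 = unused)
    oldchg <- suppressWarnings(as.integer(substr(at, 37, 39)))
    charges <- ifelse(!is.na(oldchg) & oldchg >= 1 & oldchg <= 7 & oldchg != 4,
                      4L - oldchg, 0L)
    for (ln in grep("^M  CHG", bl, value = TRUE)) {
      toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- toks[1]
      for (q in seq_len(k)) charges[toks[2 * q]] <- toks[2 * q + 1]
    }
    rec <- molecule_record(el, xyz, charges)
    if (n_bonds > 0L && length(bl) >= 4L + n_atoms + n_bonds) {
      bd <- bl[(5L + n_atoms):(4L + n_atoms + n_bonds)]
      B <- matrix(0L, n_atoms, n_atoms)
      bi <- as.integer(substr(bd, 1, 3))
      bj <- as.integer(substr(bd, 4, 6))
      bo <- as.integer(substr(bd, 7, 9))
      bo[bo == 4L] <- 1L  # aromatic flag: count as order 1 plus ring context
      B[cbind(bi, bj)] <- bo
      B[cbind(bj, bi)] <- bo
      attr(rec, "bonds") <- B
    }
    mols[[length(mols) + 1L]] <- rec
  }
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols list of [molecule_record()]s.
#' @param path output path.
#' @param bonds optional list of bond-order matrices (e.g. from
#'   [infer_bonds()]) to emit as bond blocks.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, bonds = NULL) {
  out <- character(0)
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    n <- length(m$elements)
    B <- if (is.null(bonds)) matrix(0L, n, n) else bonds[[k]]
    bl <- which(upper.tri(B) & B > 0, arr.ind = TRUE)
    out <- c(out,
             sprintf("mol_%d", k), "  moldiff", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bl)),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     m$coords[, 1], m$coords[, 2], m$coords[, 3], m$elements))
    if (nrow(bl)) {
      out <- c(out, sprintf("%3d%3d%3d  0", bl[, 1], bl[, 2], B[bl]))
    }
    chg <- which(m$charges != 0L)
    while (length(chg)) {
      take <- utils::head(chg, 8L)
      chg <- chg[-seq_along(take)]
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(take)),
                           paste0(sprintf("%4d%4d", take, m$charges[take]),
                                  collapse = "")))
    }
    out <- c(out, "M  END", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write SMILES line lists
#'
#' One SMILES per line; blank lines ignored.
#'
#' @param path file path.
#' @return `read_smiles` a character vector; `write_smiles` the path,
#'   invisibly.
#' @export
read_smiles <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_smiles
#' @param smiles character vector of SMILES strings.
#' @export
write_smiles <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
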