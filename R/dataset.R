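# Dataset bundles: the synthetic toy generator that stands in for the
# external small-molecule corpora in every offline run, and the loader for
# pre-processed external datasets laid out under a manifest.

#' Rigid toy molecule templates
#'
#' Three chemically plausible templates (every one has atom and molecule
#' stability 1.0 under the bundled bond table at zero jitter):
#' a bent water-like triatomic (O-H 0.9572 A, 104.52 deg), a methane-like
#' tetrahedron (C-H 1.09 A), and a linear acetylene-like chain (C-C triple
#' bond, exercises degenerate colinear frames).
#'
#' @return named list of [molecule_record()]s.
#' @export
toy_templates <- function() {
  water <- molecule_record(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(0.9572, 0, 0),
          c(0.9572 * cos(104.52 * pi / 180), 0.9572 * sin(104.52 * pi / 180), 0)))
  s <- 1.09 / sqrt(3)
  methane <- molecule_record(
    c("C", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s)))
  acetylene <- molecule_record(
    c("H", "C", "C", "H"),
    cbind(c(0, 1.06, 2.26, 3.32), 0, 0))
  list(water = water, methane = methane, acetylene = acetylene)
}

#' Specify a synthetic toy dataset
#'
#' Molecules are generated by picking templates, applying uniformly random
#' rigid rotations, optional global scaling, and Gaussian coordinate jitter,
#' and attaching a scalar property computed from the resulting geometry.
#' Every template must be stable (atom stability 1) under the bond table at
#' zero jitter and unit scale — this is what makes the toy distribution a
#' meaningful stand-in for real small molecules.
#'
#' @param templates list of [molecule_record()]s (default [toy_templates()]
#'   water entry).
#' @param n number of molecules.
#' @param jitter_sd per-coordinate Gaussian jitter, Angstrom.
#' @param property_rule `NULL`, or a function `molecule -> scalar`, or the
#'   name `"mean_pairwise_distance"`.
#' @param property_name name under which the property is stored.
#' @param scale_range length-2 range of uniform global scale factors
#'   (`c(1, 1)` for rigid templates).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return object of class `toy_spec`.
#' @export
toy_spec <- function(templates = toy_templates()["water"],
                     n = 200L, jitter_sd = 0.02,
                     property_rule = NULL,
                     property_name = "property",
                     scale_range = c(1, 1),
                     seed = 1L) {
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0.", call. = FALSE)
  if (is.character(property_rule)) {
    property_rule <- switch(property_rule,
      mean_pairwise_distance = mean_pairwise_distance,
      stop(sprintf("unknown property rule '%s'.", property_rule), call. = FALSE))
  }
  tbl <- default_bond_table()
  for (tm in templates) {
    st <- atom_and_molecule_stability(list(tm), tbl)
    if (st$mol_stable_frac < 1) {
      stop("template fails the stability plausibility check (AS < 1 at zero jitter).",
           call. = FALSE)
    }
  }
  structure(list(templates = templates, n = as.integer(n),
                 jitter_sd = jitter_sd, property_rule = property_rule,
                 property_name = property_name,
                 scale_range = as.numeric(scale_range), seed = as.integer(seed)),
            class = "toy_spec")
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  Q <- Q %*% diag(sign(diag(qr.R(qr_res))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a synthetic toy dataset
#'
#' @param spec a [toy_spec()].
#' @return object of class `dataset_bundle`: `molecules`, named `splits`
#'   (train/valid/test index vectors, 80/10/10), `size_dist` and
#'   `property_stats` computed from the training split.
#' @export
make_toy_dataset <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  mols <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    tm <- spec$templates[[sample.int(length(spec$templates), 1L)]]
    sc <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
    X <- project_zero_cog(tm$coords * sc) %*% random_rotation()
    if (spec$jitter_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = spec$jitter_sd), nrow(X), 3L)
    }
    m <- molecule_record(tm$elements, X, tm$charges)
    if (!is.null(spec$property_rule)) {
      p <- list(spec$property_rule(m))
      names(p) <- spec$property_name
      m$property <- p
    }
    mols[[i]] <- m
  }
  dataset_bundle(mols, property_name = if (is.null(spec$property_rule)) NULL
                 else spec$property_name)
}

dataset_bundle <- function(mols, property_name = NULL, splits = NULL) {
  n <- length(mols)
  if (is.null(splits)) {
    n_train <- max(1L, floor(0.8 * n))
    n_valid <- max(0L, floor(0.1 * n))
    splits <- list(train = seq_len(n_train),
                   valid = seq.int(n_train + 1L, length.out = n_valid),
                   test = if (n_train + n_valid < n)
                     seq.int(n_train + n_valid + 1L, n) else integer(0))
  }
  sizes <- vapply(mols[splits$train], function(m) length(m$elements), integer(1))
  prop_stats <- NULL
  if (!is.null(property_name)) {
    vals <- vapply(mols[splits$train], function(m) m$property[[property_name]],
                   numeric(1))
    prop_stats <- list(name = property_name, center = mean(vals),
                       scale = max(stats::mad(vals), 1e-8))
  }
  structure(list(molecules = mols, splits = splits,
                 size_dist = size_distribution(sizes),
                 property_stats = prop_stats),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %d molecules (train %d / valid %d / test %d)\n",
              length(x$molecules), length(x$splits$train),
              length(x$splits$valid), length(x$splits$test)))
  invisible(x)
}

#' Load a pre-processed external dataset
#'
#' Expects `root/<which>/` to contain a `manifest.yaml` naming the split
#' files (`train`, `valid`, `test`, each an XYZ or SDF file relative to the
#' directory). The size distribution and property statistics are computed
#' from the training split. Downloading the archives is out of scope; the
#' loader validates the manifest rather than guessing a layout.
#'
#' @param root directory holding the processed datasets.
#' @param which `"qm9"` or `"geom_drugs"`.
#' @return a `dataset_bundle`.
#' @export
load_processed_dataset <- function(root, which = c("qm9", "geom_drugs")) {
  which <- match.arg(which)
  dir <- file.path(root, which)
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) {
    stop(sprintf(paste0(
      "processed dataset not found: expected %s with a manifest.yaml of the ",
      "form\n  train: train.xyz\n  valid: valid.xyz\n  test: test.xyz\n",
      "with the split files (XYZ or SDF) alongside it."), dir), call. = FALSE)
  }
  man <- yaml::read_yaml(mf)
  for (sp in c("train", "valid", "test")) {
    if (is.null(man[[sp]])) {
      stop(sprintf("manifest.yaml lacks the '%s' entry.", sp), call. = FALSE)
    }
  }
  read_any <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("split file missing: %s", p), call. = FALSE)
    if (grepl("\\.sdf$", p, ignore.case = TRUE)) read_sdf(p) else read_xyz(p)
  }
  tr <- read_any(man$train); va <- read_any(man$valid); te <- read_any(man$test)
  mols <- c(tr, va, te)
  splits <- list(train = seq_along(tr),
                 valid = seq_along(va) + length(tr),
                 test = seq_along(te) + length(tr) + length(va))
  dataset_bundle(mols, splits = splits)
}
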