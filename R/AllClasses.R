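#' Fingerprint configuration
#'
#' Settings for the package-standard circular fingerprint: a Morgan-style
#' (extended-connectivity) fingerprint of the given bond radius, folded to
#' `fpBits` bits. The default radius 2 / 1024 bits corresponds to the
#' widely used ECFP4, 1024-bit setting.
#'
#' @param radius non-negative integer bond radius (radius 2 = diameter 4).
#' @param fpBits positive power of two; folded fingerprint length.
#' @return A `FingerprintConfig` object.
#' @examples
#' fingerprintConfig()
#' @export
fingerprintConfig <- function(radius = 2L, fpBits = 1024L) {
  new("FingerprintConfig", radius = as.integer(radius),
      fpBits = as.integer(fpBits))
}

#' @rdname fingerprintConfig
#' @export
setClass("FingerprintConfig",
         representation(radius = "integer", fpBits = "integer"),
         prototype(radius = 2L, fpBits = 1024L))

setValidity("FingerprintConfig", function(object) {
  msg <- character(0)
  if (length(object@radius) != 1L || object@radius < 0L)
    msg <- c(msg, "radius must be a single non-negative integer")
  fb <- object@fpBits
  if (length(fb) != 1L || fb <= 0L || bitwAnd(fb, fb - 1L) != 0L)
    msg <- c(msg, "fpBits must be a positive power of two")
  if (length(msg)) msg else TRUE
})

#' A set of screening molecules
#'
#' The central small-molecule container: canonical SMILES, the
#' package-standard circular fingerprint for each molecule, and computed
#' physico-chemical descriptors. Constructed with [moleculeSet()].
#'
#' @slot ids character vector of unique molecule identifiers.
#' @slot smiles canonical SMILES, parallel to `ids`.
#' @slot fingerprints logical matrix, one row per molecule.
#' @slot descriptors data.frame of descriptors (mw, clogp, hbd, hba,
#'   rotatable_bonds, tpsa), parallel to `ids`.
#' @slot fpConfig the [fingerprintConfig()] used.
#' @export
setClass("MoleculeSet",
         representation(ids = "character", smiles = "character",
                        fingerprints = "matrix", descriptors = "data.frame",
                        fpConfig = "FingerprintConfig"))

setValidity("MoleculeSet", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (anyDuplicated(object@ids)) msg <- c(msg, "molecule ids must be unique")
  if (length(object@smiles) != n) msg <- c(msg, "smiles length mismatch")
  if (nrow(object@fingerprints) != n)
    msg <- c(msg, "fingerprint rows must match number of molecules")
  if (n > 0 && ncol(object@fingerprints) != object@fpConfig@fpBits)
    msg <- c(msg, "fingerprint length must equal configured fpBits")
  if (nrow(object@descriptors) != n)
    msg <- c(msg, "descriptor rows must match number of molecules")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet with", length(object@ids), "molecules\n")
  cat("  fingerprint: radius", object@fpConfig@radius, "/",
      object@fpConfig@fpBits, "bits\n")
  if (length(object@ids)) {
    k <- min(3L, length(object@ids))
    for (i in seq_len(k))
      cat("  ", object@ids[i], " ", object@smiles[i], "\n", sep = "")
    if (length(object@ids) > k) cat("  ...\n")
  }
})

#' @describeIn moleculeSet number of molecules in the set
#' @param x a `MoleculeSet`.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@ids))

#' A protein-ligand pose
#'
#' Atoms of one docked ligand pose together with the (already truncated)
#' receptor atoms that form its binding pocket. Atom tables carry columns
#' `element`, `sybyl`, `x`, `y`, `z`.
#'
#' @slot ligandAtoms data.frame of ligand atoms.
#' @slot receptorAtoms data.frame of receptor atoms.
#' @slot poseId,targetId,ligandId identifiers.
#' @export
setClass("ComplexPose",
         representation(ligandAtoms = "data.frame",
                        receptorAtoms = "data.frame",
                        poseId = "character", targetId = "character",
                        ligandId = "character"))

.atom_cols <- c("element", "sybyl", "x", "y", "z")

setValidity("ComplexPose", function(object) {
  msg <- character(0)
  if (nrow(object@ligandAtoms) < 1L)
    msg <- c(msg, "a pose needs at least one ligand atom")
  for (nm in list(object@ligandAtoms, object@receptorAtoms)) {
    if (!all(.atom_cols %in% names(nm)))
      msg <- c(msg, "atom tables need columns element, sybyl, x, y, z")
    else if (!all(is.finite(as.matrix(nm[, c("x", "y", "z")]))) && nrow(nm))
      msg <- c(msg, "atom coordinates must be finite")
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "ComplexPose", function(object) {
  cat("ComplexPose", object@poseId, "(ligand", object@ligandId,
      "/ target", object@targetId, "):",
      nrow(object@ligandAtoms), "ligand +",
      nrow(object@receptorAtoms), "receptor atoms\n")
})

#' A featurized protein-ligand graph
#'
#' Graph representation consumed by the scoring network: one-hot Sybyl-type
#' node features plus a ligand/receptor role bit, and per-cutoff symmetric
#' distance-annotated edge lists.
#'
#' @slot nodeFeatures numeric matrix (atoms x feature dim).
#' @slot edgeSets named list (one per cutoff, names like "5", "7") of
#'   data.frames with columns `i`, `j`, `d`.
#' @slot ligandMask logical vector marking ligand atoms.
#' @slot cutoffs numeric vector of edge cutoffs in Angstrom.
#' @slot poseId,targetId,ligandId identifiers carried through scoring.
#' @export
setClass("ComplexGraph",
         representation(nodeFeatures = "matrix", edgeSets = "list",
                        ligandMask = "logical", cutoffs = "numeric",
                        poseId = "character", targetId = "character",
                        ligandId = "character"))

setValidity("ComplexGraph", function(object) {
  msg <- character(0)
  n <- nrow(object@nodeFeatures)
  if (length(object@ligandMask) != n)
    msg <- c(msg, "ligandMask length must equal number of atoms")
  if (length(object@edgeSets) != length(object@cutoffs))
    msg <- c(msg, "one edge set per cutoff required")
  for (k in seq_along(object@edgeSets)) {
    e <- object@edgeSets[[k]]
    if (!nrow(e)) next
    if (any(e$i == e$j)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$d > object@cutoffs[k] + 1e-9))
      msg <- c(msg, "edge distance exceeds its cutoff")
    key <- paste(e$i, e$j)
    rev <- paste(e$j, e$i)
    if (!all(rev %in% key)) msg <- c(msg, "edge lists must be symmetric")
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "ComplexGraph", function(object) {
  cat("ComplexGraph", object@poseId, ":", nrow(object@nodeFeatures),
      "atoms (", sum(object@ligandMask), "ligand );",
      paste(vapply(seq_along(object@cutoffs), function(k)
        paste0(object@cutoffs[k], "A:", nrow(object@edgeSets[[k]]), "e"),
        character(1)), collapse = " "), "\n")
})

#' An ensemble of trained scoring networks
#'
#' Six (by default) sets of graph-convolutional network parameters, each
#' trained with a different held-out sequence-identity fold, plus the fold
#' map and training log.
#'
#' @slot members list of parameter sets.
#' @slot foldMap named integer vector, target id -> fold.
#' @slot config the training/network configuration snapshot.
#' @slot trainingLog data.frame of per-member, per-epoch mean losses.
#' @export
setClass("GNNEnsemble",
         representation(members = "list", foldMap = "integer",
                        config = "list", trainingLog = "data.frame"))

setValidity("GNNEnsemble", function(object) {
  folds <- vapply(object@members, function(m) m$held_out_fold, integer(1))
  if (anyDuplicated(folds))
    return("ensemble members must hold out distinct folds")
  TRUE
})

setMethod("show", "GNNEnsemble", function(object) {
  cat("GNNEnsemble:", length(object@members), "members,",
      length(unique(object@foldMap)), "folds over",
      length(object@foldMap), "targets\n")
  cat("  head:", object@config$gnn$head, "| blocks:",
      paste(vapply(object@config$gnn$blocks, function(b)
        paste0(b$cutoff, "A/", b$filters, if (b$scope == "ligand") "L" else ""),
        character(1)), collapse = " "), "\n")
})

#' Accessors for atomscreen containers
#'
#' @param x a [MoleculeSet].
#' @return `fingerprints()` the logical fingerprint matrix (rows named by
#'   molecule id); `moleculeIds()` the id vector; `smilesOf()` the canonical
#'   SMILES named by id; `descriptors()` the descriptor data.frame.
#' @examples
#' \donttest{
#' ms <- moleculeSet(c("CCO", "c1ccccc1"), ids = c("a", "b"))
#' fingerprints(ms)[, 1:4]
#' }
#' @export
fingerprints <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  fp <- x@fingerprints
  rownames(fp) <- x@ids
  fp
}

#' @rdname fingerprints
#' @export
moleculeIds <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  x@ids
}

#' @rdname fingerprints
#' @export
smilesOf <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  setNames(x@smiles, x@ids)
}

#' @rdname fingerprints
#' @export
descriptors <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  d <- x@descriptors
  rownames(d) <- x@ids
  d
}
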