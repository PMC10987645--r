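#' Canonicalize SMILES strings
#'
#' Converts SMILES to the package-standard canonical form (Open Babel
#' canonical SMILES). Canonicalization is idempotent and maps structurally
#' identical inputs (differing only in atom order or aromatic notation) to
#' the same string.
#'
#' @param smiles character vector of SMILES.
#' @param standardize strip salts (keep the largest covalent fragment) and
#'   neutralize charges before canonicalizing. Default `TRUE`; see the
#'   methods vignette for why fingerprints are computed on standardized
#'   structures.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \donttest{
#' canonicalizeSmiles(c("C1=CC=CC=C1", "c1ccccc1"))
#' }
#' @export
canonicalizeSmiles <- function(smiles, standardize = TRUE) {
  stopifnot(is.character(smiles))
  if (standardize) .ob_standardize(smiles) else .ob_canonical(smiles)
}

#' Compute circular fingerprints
#'
#' The package-standard fingerprint: Open Babel's extended-connectivity
#' (Morgan-style) circular fingerprint of bond radius `cfg@radius`, folded
#' to `cfg@fpBits` bits by modular OR. Deterministic: the same molecule
#' always yields the same bits.
#'
#' @param smiles character vector of (preferably canonical) SMILES.
#' @param cfg a [fingerprintConfig()].
#' @return logical matrix with one row per molecule and `fpBits` columns.
#' @export
computeFingerprints <- function(smiles, cfg = fingerprintConfig()) {
  stopifnot(is(cfg, "FingerprintConfig"))
  validObject(cfg)
  .ob_fingerprints(smiles, radius = cfg@radius, fp_bits = cfg@fpBits)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are all-zero so
#' that exclusion logic stays total.
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' All-pairs Tanimoto similarity matrix
#'
#' Computes similarities between the rows of `a` and the rows of `b` by
#' bit-count algebra. Rows that are all-zero have similarity 0 to
#' everything (including each other).
#'
#' @param a,b logical matrices with the same number of columns. `b`
#'   defaults to `a`.
#' @return numeric matrix of dimension `nrow(a)` x `nrow(b)`.
#' @export
tanimotoMatrix <- function(a, b = a) {
  if (ncol(a) != ncol(b))
    stop("fingerprint length mismatch: ", ncol(a), " vs ", ncol(b),
         call. = FALSE)
  am <- matrix(as.integer(a), nrow = nrow(a))
  bm <- matrix(as.integer(b), nrow = nrow(b))
  inter <- tcrossprod(am, bm)
  ca <- rowSums(am)
  cb <- rowSums(bm)
  un <- outer(ca, cb, "+") - inter
  sim <- ifelse(un == 0, 0, inter / pmax(un, 1))
  dimnames(sim) <- list(rownames(a), rownames(b))
  sim
}

#' Compute physico-chemical descriptors
#'
#' Standard drug-likeness descriptors, as implemented by Open Babel:
#' molecular weight (`mw`, g/mol), `clogp`, hydrogen-bond donors (`hbd`)
#' and acceptors (`hba`, N+O Lipinski counting), `rotatable_bonds`
#' (non-ring single bonds between non-terminal heavy atoms) and topological
#' polar surface area (`tpsa`, Angstrom^2).
#'
#' @param smiles character vector of SMILES (parsed as-is; canonicalize
#'   first if you need standardized structures).
#' @return data.frame with columns mw, clogp, hbd, hba, rotatable_bonds,
#'   tpsa.
#' @export
computeDescriptors <- function(smiles) {
  n <- length(smiles)
  empty <- data.frame(mw = numeric(0), clogp = numeric(0), hbd = integer(0),
                      hba = integer(0), rotatable_bonds = integer(0),
                      tpsa = numeric(0))
  if (n == 0L) return(empty)
  rot_smarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
  inp <- paste(paste(smiles, sprintf("m%07d", seq_len(n))), collapse = "\n")
  res <- ChemmineOB::forEachMol("SMILES", paste0(inp, "\n"), function(m) {
    p <- ChemmineOB::prop_OB(list(m))
    r <- ChemmineOB::smartsSearch_OB(list(m), rot_smarts, uniqueMatches = TRUE)
    c(mw = p$MW, clogp = p$logP, hbd = p$HBD, hba = p$HBA1,
      rotatable_bonds = as.numeric(r), tpsa = p$TPSA)
  })
  m <- do.call(rbind, res)
  if (nrow(m) != n)
    stop("descriptor computation failed for ", n - nrow(m), " molecule(s)",
         call. = FALSE)
  data.frame(mw = m[, "mw"], clogp = m[, "clogp"],
             hbd = as.integer(m[, "hbd"]), hba = as.integer(m[, "hba"]),
             rotatable_bonds = as.integer(m[, "rotatable_bonds"]),
             tpsa = m[, "tpsa"], row.names = NULL)
}

#' Build a MoleculeSet
#'
#' Canonicalizes the input SMILES (optionally standardizing salts and
#' charges), computes fingerprints and descriptors, and bundles everything
#' into a [MoleculeSet-class].
#'
#' @param smiles character vector of SMILES.
#' @param ids unique identifiers; defaults to `mol00001`-style ids.
#' @param cfg a [fingerprintConfig()].
#' @param standardize passed to [canonicalizeSmiles()].
#' @return a [MoleculeSet-class].
#' @export
moleculeSet <- function(smiles, ids = NULL, cfg = fingerprintConfig(),
                        standardize = TRUE) {
  n <- length(smiles)
  if (is.null(ids)) ids <- sprintf("mol%05d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids must match smiles in length", call. = FALSE)
  can <- canonicalizeSmiles(smiles, standardize = standardize)
  fps <- computeFingerprints(can, cfg)
  desc <- computeDescriptors(can)
  new("MoleculeSet", ids = ids, smiles = can, fingerprints = fps,
      descriptors = desc, fpConfig = cfg)
}

#' Subset a MoleculeSet by id or index
#'
#' @param x a [MoleculeSet-class].
#' @param i character ids or integer/logical indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@ids)
    if (anyNA(idx)) stop("unknown molecule id: ", i[which(is.na(idx))[1]],
                         call. = FALSE)
  } else idx <- seq_along(x@ids)[i]
  new("MoleculeSet", ids = x@ids[idx], smiles = x@smiles[idx],
      fingerprints = x@fingerprints[idx, , drop = FALSE],
      descriptors = x@descriptors[idx, , drop = FALSE],
      fpConfig = x@fpConfig)
})

#' Read and write SMILES files
#'
#' SMILES files carry one record per line: a SMILES string, whitespace,
#' then an identifier. `readSmilesFile` also accepts SDF input (detected by
#' the `.sdf` extension), taking structures and titles from the SD records.
#'
#' @param path file to read or write.
#' @param ... passed on to [moleculeSet()].
#' @return `readSmilesFile`: a [MoleculeSet-class]. `writeSmilesFile`:
#'   the path, invisibly.
#' @export
readSmilesFile <- function(path, ...) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    ids <- ChemmineR::sdfid(sdf)
    return(moleculeSet(smi, ids = ids, ...))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smi <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(k)
    if (length(parts[[k]]) > 1) parts[[k]][2] else sprintf("mol%05d", k),
    character(1))
  moleculeSet(smi, ids = ids, ...)
}

#' @param x a [MoleculeSet-class] to write.
#' @rdname readSmilesFile
#' @export
writeSmilesFile <- function(x, path) {
  stopifnot(is(x, "MoleculeSet"))
  writeLines(paste(x@smiles, x@ids), path)
  invisible(path)
}
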