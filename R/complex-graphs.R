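## Receptor/ligand loading, Sybyl atom typing and graph featurization.

.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                     P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                     B = 0.84, Si = 1.11, Se = 1.20)

#' The packaged Sybyl atom-type vocabulary
#'
#' Returns the ordered vocabulary of Sybyl/MOL2 atom types over which node
#' features are one-hot encoded. Types not in the table (assigned as
#' `<element>.generic`) are encoded on the shared `generic` slot.
#'
#' @return data.frame with columns `type` and `description`.
#' @export
sybylVocabulary <- function() {
  utils::read.csv(system.file("extdata", "sybyl_types.csv",
                              package = "atomscreen", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Load receptor atoms from a PDB file
#'
#' Parses ATOM/HETATM records. Waters (and any additionally named hetero
#' residues) are dropped, as are hydrogens by default. Malformed coordinate
#' fields or unknown elements raise a record-level error naming the line.
#'
#' @param path PDB file.
#' @param dropWaters drop HOH/WAT/DOD residues (default TRUE).
#' @param dropHetero character vector of additional residue names to drop.
#' @param dropHydrogens drop hydrogen atoms (default TRUE).
#' @return data.frame with columns element, x, y, z, resid, resno, atom,
#'   line (source line number).
#' @export
loadReceptorPdb <- function(path, dropWaters = TRUE,
                            dropHetero = character(0),
                            dropHydrogens = TRUE) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  parse_num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v))
      stop("malformed ", what, " in PDB record at line ", ln, call. = FALSE)
    v
  }
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("truncated PDB record at line ", ln, call. = FALSE)
    atom_name <- trimws(substr(l, 13, 16))
    resid <- trimws(substr(l, 18, 20))
    resno <- suppressWarnings(as.integer(trimws(substr(l, 23, 26))))
    x <- parse_num(substr(l, 31, 38), ln, "x coordinate")
    y <- parse_num(substr(l, 39, 46), ln, "y coordinate")
    z <- parse_num(substr(l, 47, 54), ln, "z coordinate")
    el <- if (nchar(l) >= 78) trimws(substr(l, 77, 78)) else ""
    if (!nzchar(el)) {
      ## fall back to the first letter(s) of the atom name
      el <- sub("^[0-9]*", "", atom_name)
      el <- sub("([A-Za-z]).*", "\\1", el)
    }
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
    if (!el %in% c(names(.covalent_radii), "Na", "K", "Ca", "Mg", "Zn",
                   "Fe", "Mn", "Cu", "Co", "Ni"))
      stop("unknown element '", el, "' in PDB record at line ", ln,
           call. = FALSE)
    out[[k]] <- data.frame(element = el, x = x, y = y, z = z,
                           resid = resid, resno = resno, atom = atom_name,
                           line = ln)
  }
  df <- do.call(rbind, out)
  if (dropWaters) df <- df[!df$resid %in% c("HOH", "WAT", "DOD"), ]
  if (length(dropHetero)) df <- df[!df$resid %in% dropHetero, ]
  if (dropHydrogens) df <- df[df$element != "H", ]
  rownames(df) <- NULL
  df
}

#' Perceive covalent bonds from interatomic distances
#'
#' Distance-based connectivity for atom tables that carry no bond block:
#' two atoms are bonded when their distance is at most the sum of their
#' covalent radii plus 0.4 Angstrom tolerance.
#'
#' @param atoms data.frame with columns element, x, y, z.
#' @return data.frame of bonds (i, j, order) with `order = 1`.
#' @export
perceiveBonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0),
                               order = integer(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  r <- .covalent_radii[atoms$element]
  r[is.na(r)] <- 1.4
  thr <- outer(r, r, "+") + 0.4
  hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
             order = rep(1L, nrow(hit)))
}

## ring membership + crude aromaticity from a kekulized bond table
.ring_info <- function(n, bonds) {
  in_ring <- rep(FALSE, n)
  aromatic <- rep(FALSE, n)
  if (!nrow(bonds)) return(list(in_ring = in_ring, aromatic = aromatic))
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$i, to = bonds$j),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  bc <- igraph::biconnected_components(g)
  for (comp in bc$components) {
    v <- as.integer(igraph::as_ids(comp))
    if (length(v) < 3) next        # a lone edge, not a ring
    in_ring[v] <- TRUE
  }
  list(in_ring = in_ring, graph = g, aromatic = aromatic)
}

#' Assign Sybyl atom types
#'
#' Rule-based Sybyl/MOL2 typing from elements and a (kekulized) bond
#' table: element x aromaticity x hybridization plus the usual special
#' cases (N.am amide nitrogen, O.co2 carboxylate oxygen, S.o/S.o2
#' oxidized sulfur). Unknown combinations are typed `<element>.generic`
#' with a warning and encoded on the shared generic feature slot.
#'
#' @param atoms data.frame with column `element` (and coordinates if
#'   `bonds` is missing, in which case connectivity is perceived with
#'   [perceiveBonds()]).
#' @param bonds data.frame (i, j, order); order 4 marks an aromatic bond.
#' @return the `atoms` data.frame with a `sybyl` column added.
#' @export
assignSybylTypes <- function(atoms, bonds = NULL) {
  n <- nrow(atoms)
  if (is.null(bonds)) bonds <- perceiveBonds(atoms)
  el <- atoms$element
  ## neighbor bookkeeping
  nb <- vector("list", n)
  border <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]; o <- bonds$order[k]
    nb[[i]] <- c(nb[[i]], j); border[[i]] <- c(border[[i]], o)
    nb[[j]] <- c(nb[[j]], i); border[[j]] <- c(border[[j]], o)
  }
  deg <- lengths(nb)
  has_ord <- function(i, o) any(border[[i]] == o)
  ri <- .ring_info(n, bonds)
  in_ring <- ri$in_ring
  ## aromatic perception: explicit order-4 bonds win; otherwise a ring
  ## system over C/N/O/S in which every ring carbon is sp2 (has a double
  ## bond) is taken as aromatic
  aromatic <- rep(FALSE, n)
  for (k in seq_len(nrow(bonds)))
    if (bonds$order[k] == 4L) aromatic[c(bonds$i[k], bonds$j[k])] <- TRUE
  if (nrow(bonds) && any(in_ring & !aromatic)) {
    g <- ri$graph
    bc <- igraph::biconnected_components(g)
    for (comp in bc$components) {
      v <- as.integer(igraph::as_ids(comp))
      if (length(v) < 5) next
      if (!all(el[v] %in% c("C", "N", "O", "S"))) next
      carbons <- v[el[v] == "C"]
      if (length(carbons) && all(vapply(carbons, has_ord, logical(1), 2L)))
        aromatic[v] <- TRUE
    }
  }
  type <- character(n)
  unknown <- character(0)
  for (i in seq_len(n)) {
    e <- el[i]
    t <- switch(
      e,
      C = if (aromatic[i]) "C.ar"
          else if (has_ord(i, 3L)) "C.1"
          else if (has_ord(i, 2L)) "C.2" else "C.3",
      N = {
        amide <- any(vapply(seq_along(nb[[i]]), function(k) {
          c_at <- nb[[i]][k]
          border[[i]][k] == 1L && el[c_at] == "C" &&
            any(el[nb[[c_at]]] == "O" & border[[c_at]] == 2L)
        }, logical(1)))
        if (has_ord(i, 3L)) "N.1"
        else if (amide) "N.am"
        else if (aromatic[i]) "N.ar"
        else if (deg[i] >= 4L) "N.4"
        else if (has_ord(i, 2L)) "N.2"
        else if (any(aromatic[nb[[i]]])) "N.pl3"
        else "N.3"
      },
      O = {
        co2 <- deg[i] == 1L && length(nb[[i]]) == 1L && el[nb[[i]]] == "C" && {
          c_at <- nb[[i]][1]
          os <- nb[[c_at]][el[nb[[c_at]]] == "O"]
          length(os) >= 2L && any(border[[c_at]][el[nb[[c_at]]] == "O"] == 2L)
        }
        if (co2) "O.co2" else if (has_ord(i, 2L)) "O.2" else "O.3"
      },
      S = {
        o2nb <- sum(el[nb[[i]]] == "O" & border[[i]] == 2L)
        if (o2nb >= 2L) "S.o2" else if (o2nb == 1L) "S.o"
        else if (has_ord(i, 2L)) "S.2" else "S.3"
      },
      P = "P.3", H = "H", F = "F", Cl = "Cl", Br = "Br", I = "I",
      NULL)
    if (is.null(t)) {
      t <- paste0(e, ".generic")
      unknown <- c(unknown, e)
    }
    type[i] <- t
  }
  if (length(unknown))
    warning("no Sybyl rule for element(s) ", paste(unique(unknown),
            collapse = ", "), "; typed as <element>.generic")
  atoms$sybyl <- type
  atoms
}

#' Truncate a receptor around a ligand pose
#'
#' Keeps every receptor atom whose minimum distance to any ligand atom is
#' at most the cutoff (boundary inclusive: an atom at exactly the cutoff
#' is kept, atoms strictly beyond it are excluded).
#'
#' @param receptor,ligand data.frames with x, y, z columns.
#' @param cutoff truncation radius in Angstrom (default 7).
#' @return the retained rows of `receptor`.
#' @export
truncateReceptor <- function(receptor, ligand, cutoff = 7.0) {
  if (nrow(ligand) == 0L)
    stop("cannot truncate receptor: pose has no ligand atoms", call. = FALSE)
  if (nrow(receptor) == 0L) return(receptor)
  rxyz <- as.matrix(receptor[, c("x", "y", "z")])
  lxyz <- as.matrix(ligand[, c("x", "y", "z")])
  keep <- vapply(seq_len(nrow(rxyz)), function(i) {
    d2 <- colSums((t(lxyz) - rxyz[i, ])^2)
    sqrt(min(d2)) <= cutoff
  }, logical(1))
  out <- receptor[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a protein-ligand pose
#'
#' Applies receptor truncation and bundles typed ligand and receptor atoms
#' into a [ComplexPose-class]. Atom tables must carry `element`, `x`, `y`,
#' `z`; a `sybyl` column is computed with [assignSybylTypes()] when
#' missing.
#'
#' @param ligandAtoms,receptorAtoms atom data.frames.
#' @param poseId,targetId,ligandId identifiers.
#' @param ligandBonds optional bond table for ligand typing.
#' @param receptorCutoff truncation radius (Angstrom).
#' @return a [ComplexPose-class].
#' @export
complexPose <- function(ligandAtoms, receptorAtoms, poseId = "pose1",
                        targetId = "target", ligandId = "ligand",
                        ligandBonds = NULL, receptorCutoff = 7.0) {
  if (!"sybyl" %in% names(ligandAtoms))
    ligandAtoms <- assignSybylTypes(ligandAtoms, ligandBonds)
  if (!"sybyl" %in% names(receptorAtoms) && nrow(receptorAtoms))
    receptorAtoms <- suppressWarnings(assignSybylTypes(receptorAtoms))
  receptorAtoms <- truncateReceptor(receptorAtoms, ligandAtoms,
                                    cutoff = receptorCutoff)
  keep <- intersect(c(.atom_cols, "resid", "resno"), names(ligandAtoms))
  new("ComplexPose",
      ligandAtoms = ligandAtoms[, intersect(.atom_cols, names(ligandAtoms))],
      receptorAtoms = if (nrow(receptorAtoms))
        receptorAtoms[, intersect(.atom_cols, names(receptorAtoms))]
      else data.frame(element = character(0), sybyl = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)),
      poseId = poseId, targetId = targetId, ligandId = ligandId)
}

## one-hot encode sybyl types over the packaged vocabulary (+ role bit)
.encode_nodes <- function(sybyl, is_ligand, vocab = sybylVocabulary()$type) {
  idx <- match(sybyl, vocab)
  idx[is.na(idx)] <- match("generic", vocab)
  m <- matrix(0, nrow = length(sybyl), ncol = length(vocab) + 1L)
  m[cbind(seq_along(sybyl), idx)] <- 1
  m[, length(vocab) + 1L] <- as.numeric(is_ligand)
  colnames(m) <- c(vocab, "is_ligand")
  m
}

#' Build the graph representation of a pose
#'
#' For each cutoff radius r, an undirected edge (i, j, d) is created for
#' every atom pair at distance 0 < d <= r (both directions are stored, so
#' edge lists are symmetric). Node features are the one-hot Sybyl type over
#' the packaged vocabulary plus a ligand/receptor role bit. Coincident
#' distinct atoms (d = 0) trigger a warning and the edge is skipped.
#'
#' @param pose a [ComplexPose-class].
#' @param cutoffs edge cutoff radii in Angstrom (default `c(5, 7)`).
#' @return a [ComplexGraph-class].
#' @export
buildComplexGraph <- function(pose, cutoffs = c(5, 7)) {
  stopifnot(is(pose, "ComplexPose"))
  atoms <- rbind(pose@ligandAtoms[, .atom_cols],
                 pose@receptorAtoms[, .atom_cols])
  is_lig <- c(rep(TRUE, nrow(pose@ligandAtoms)),
              rep(FALSE, nrow(pose@receptorAtoms)))
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  if (n > 1) {
    zero <- which(dm == 0 & upper.tri(dm), arr.ind = TRUE)
    if (nrow(zero))
      warning("coincident coordinates for ", nrow(zero),
              " atom pair(s); zero-distance edges skipped")
  }
  edge_sets <- list()
  for (r in cutoffs) {
    hit <- which(dm > 0 & dm <= r & upper.tri(dm), arr.ind = TRUE)
    if (nrow(hit)) {
      e <- data.frame(i = c(hit[, 1], hit[, 2]),
                      j = c(hit[, 2], hit[, 1]),
                      d = c(dm[hit], dm[hit]))
    } else {
      e <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
    }
    edge_sets[[as.character(r)]] <- e
  }
  new("ComplexGraph",
      nodeFeatures = .encode_nodes(atoms$sybyl, is_lig),
      edgeSets = edge_sets, ligandMask = is_lig,
      cutoffs = as.numeric(cutoffs),
      poseId = pose@poseId, targetId = pose@targetId,
      ligandId = pose@ligandId)
}

#' Read ligand poses from SDF or MOL2
#'
#' SDF poses get Sybyl types from [assignSybylTypes()] using the file's
#' bond block; MOL2 poses honor the Sybyl types stored in the file.
#'
#' @param path an `.sdf` or `.mol2` file.
#' @return list of atom data.frames (element, sybyl, x, y, z) named by
#'   record id, each with the bond table in attribute `"bonds"`.
#' @export
readLigandPoses <- function(path) {
  if (grepl("\\.mol2$", path, ignore.case = TRUE)) {
    m <- bio3d::read.mol2(path)
    at <- m$atom
    el <- sub("\\..*$", "", at$elety)
    df <- data.frame(element = el, sybyl = at$elety,
                     x = at$x, y = at$y, z = at$z)
    df <- df[df$element != "H", , drop = FALSE]
    rownames(df) <- NULL
    return(setNames(list(df), m$name %||% "mol1"))
  }
  sdf <- ChemmineR::read.SDFset(path)
  out <- list()
  ids <- ChemmineR::sdfid(sdf)
  for (k in seq_along(sdf)) {
    ab <- ChemmineR::atomblock(sdf[[k]])
    bb <- ChemmineR::bondblock(sdf[[k]])
    el <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2],
                        z = if (ncol(ab) >= 3) ab[, 3] else 0)
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    keep <- atoms$element != "H"
    remap <- cumsum(keep)
    bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
    atoms <- assignSybylTypes(atoms, bonds)
    attr(atoms, "bonds") <- bonds
    out[[ids[k]]] <- atoms
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
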