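## Analog expansion around confirmed hits: fingerprint nearest neighbors,
## Murcko-framework substructure augmentation, regression-model ranking,
## follow-up set composition.

#' Analog-expansion configuration
#'
#' @param nNeighbors fingerprint nearest neighbors pulled per hit
#'   (default 1000).
#' @param nSelectMin,nSelectMax follow-up set size window (default 20-35).
#' @param includeParent include the parent hit in the follow-up set.
#' @param simFloor minimum Tanimoto similarity to the parent for a
#'   selected analog (default 0.35).
#' @return an `AnalogConfig` list.
#' @export
analogConfig <- function(nNeighbors = 1000L, nSelectMin = 20L,
                         nSelectMax = 35L, includeParent = TRUE,
                         simFloor = 0.35) {
  stopifnot(nSelectMin <= nSelectMax, nSelectMax <= nNeighbors)
  structure(list(nNeighbors = as.integer(nNeighbors),
                 nSelectMin = as.integer(nSelectMin),
                 nSelectMax = as.integer(nSelectMax),
                 includeParent = isTRUE(includeParent),
                 simFloor = simFloor),
            class = "AnalogConfig")
}

#' Fingerprint nearest neighbors of a hit
#'
#' Ranks the library by Tanimoto similarity to the hit (descending, ties
#' broken by canonical SMILES) and returns the top n. Exact structural
#' copies of the hit are excluded unless `includeParent`.
#'
#' @param hitSmiles the hit's SMILES (canonicalized internally).
#' @param library a [MoleculeSet-class].
#' @param n how many neighbors (default 1000).
#' @param includeParent keep exact copies of the hit (default FALSE).
#' @return data.frame (id, smiles, similarity), best first.
#' @export
nearestNeighbors <- function(hitSmiles, library, n = 1000L,
                             includeParent = FALSE) {
  stopifnot(is(library, "MoleculeSet"))
  if (length(library) == 0L)
    return(data.frame(id = character(0), smiles = character(0),
                      similarity = numeric(0)))
  can <- canonicalizeSmiles(hitSmiles)
  fp <- computeFingerprints(can, library@fpConfig)
  sim <- as.numeric(tanimotoMatrix(fp, library@fingerprints))
  keep <- rep(TRUE, length(library))
  if (!includeParent) keep <- library@smiles != can
  ord <- order(-sim[keep], library@smiles[keep])
  idx <- which(keep)[ord][seq_len(min(n, sum(keep)))]
  data.frame(id = library@ids[idx], smiles = library@smiles[idx],
             similarity = sim[idx], row.names = NULL)
}

## molecular graph (igraph; element and Sybyl-type vertex attributes)
.mol_graphs <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(setNames(smiles, sprintf("g%05d",
                                                        seq_along(smiles))))
  lapply(seq_along(smiles), function(k) {
    ab <- ChemmineR::atomblock(sdf[[k]])
    bb <- ChemmineR::bondblock(sdf[[k]])
    el <- sub("_.*$", "", rownames(ab))
    keep <- el != "H"
    remap <- cumsum(keep)
    bonds <- data.frame(i = remap[as.integer(bb[, 1])],
                        j = remap[as.integer(bb[, 2])],
                        order = as.integer(bb[, 3]))
    bonds <- bonds[keep[as.integer(bb[, 1])] & keep[as.integer(bb[, 2])], ,
                   drop = FALSE]
    atoms <- data.frame(element = el[keep])
    typed <- suppressWarnings(assignSybylTypes(atoms, bonds))
    igraph::graph_from_data_frame(
      data.frame(from = bonds$i, to = bonds$j),
      directed = FALSE,
      vertices = data.frame(name = seq_len(sum(keep)),
                            element = typed$element, sybyl = typed$sybyl))
  })
}

#' Murcko-style framework of a molecule
#'
#' Iteratively removes terminal (degree-1) heavy atoms, leaving the ring
#' systems and the linkers between them. Acyclic molecules have an empty
#' framework.
#'
#' @param smiles a single SMILES.
#' @return an igraph with an `element` vertex attribute (possibly with 0
#'   vertices).
#' @export
murckoFramework <- function(smiles) {
  g <- .mol_graphs(smiles)[[1]]
  repeat {
    deg <- igraph::degree(g)
    drop <- which(deg <= 1L)
    if (!length(drop) || igraph::vcount(g) == 0L) break
    g <- igraph::delete_vertices(g, drop)
  }
  g
}

#' Substructure augmentation of an analog set
#'
#' Finds every library molecule that contains the hit's Murcko framework
#' as a Sybyl-typed subgraph (element, aromaticity and hybridization must
#' all match, so a benzene query does not hit cyclohexane). When the hit
#' is acyclic (empty
#' framework) the whole hit graph is used as the query instead. Molecules
#' already present in the neighbor list are not added twice.
#'
#' @param hitSmiles the hit's SMILES.
#' @param library a [MoleculeSet-class].
#' @param neighborIds ids already found by [nearestNeighbors()] (for
#'   deduplication).
#' @return data.frame (id, smiles, provenance = "substructure").
#' @export
substructureAugment <- function(hitSmiles, library,
                                neighborIds = character(0)) {
  stopifnot(is(library, "MoleculeSet"))
  if (length(library) == 0L)
    return(data.frame(id = character(0), smiles = character(0),
                      provenance = character(0)))
  query <- murckoFramework(canonicalizeSmiles(hitSmiles))
  if (igraph::vcount(query) == 0L)
    query <- .mol_graphs(canonicalizeSmiles(hitSmiles))[[1]]
  libg <- .mol_graphs(library@smiles)
  levels <- sort(unique(c(igraph::V(query)$sybyl,
                          unlist(lapply(libg, function(g)
                            igraph::V(g)$sybyl)))))
  qcol <- as.integer(factor(igraph::V(query)$sybyl, levels = levels))
  hit <- vapply(libg, function(g) {
    if (igraph::vcount(g) < igraph::vcount(query)) return(FALSE)
    tcol <- as.integer(factor(igraph::V(g)$sybyl, levels = levels))
    ## vf2 takes the target graph's colors as vertex.color1
    igraph::subgraph_isomorphic(query, g, method = "vf2",
                                vertex.color1 = tcol, vertex.color2 = qcol)
  }, logical(1))
  keep <- hit & !(library@ids %in% neighborIds)
  data.frame(id = library@ids[keep], smiles = library@smiles[keep],
             provenance = rep("substructure", sum(keep)), row.names = NULL)
}

#' Rank analogs with a regression-head model
#'
#' Scores analog complex graphs with a regression-head ensemble (identical
#' trunk to the multitask scorer, single linear output trained with MSE on
#' negative log activity) and ranks them best-first (higher predicted
#' potency = better). Deterministic; ties broken by the tie key.
#'
#' @param regressionEnsemble a [GNNEnsemble-class] with head
#'   `"regression"`.
#' @param graphs list of [ComplexGraph-class] (one per analog, or several
#'   poses with the same `ligandId`).
#' @param smiles optional named character tie key.
#' @return data.frame (ligand_id, predicted, rank), best first.
#' @export
rankAnalogs <- function(regressionEnsemble, graphs, smiles = NULL) {
  stopifnot(is(regressionEnsemble, "GNNEnsemble"))
  if (regressionEnsemble@config$gnn$head != "regression")
    stop("rankAnalogs needs a regression-head ensemble", call. = FALSE)
  tab <- scoreLibrary(regressionEnsemble, graphs, smiles = smiles,
                      poseAggregate = "max")
  out <- data.frame(ligand_id = tab$ligand_id, predicted = tab$score)
  out$rank <- seq_len(nrow(out))
  out
}

#' Compose the follow-up analog set
#'
#' Walks the model ranking best-first, keeping analogs whose similarity to
#' the parent reaches the similarity floor, until `nSelectMax` compounds
#' are collected (the parent, when included, occupies one slot and appears
#' exactly once). If fewer than `nSelectMin` candidates qualify a warning
#' is raised and all of them are returned.
#'
#' @param ranked data.frame from [rankAnalogs()].
#' @param similarities named numeric, analog id -> Tanimoto similarity to
#'   the parent hit.
#' @param cfg an [analogConfig()].
#' @param parentId id of the parent hit (used when `includeParent`).
#' @return data.frame (id, predicted, similarity, provenance).
#' @export
selectAnalogSet <- function(ranked, similarities, cfg = analogConfig(),
                            parentId = NULL) {
  slots <- cfg$nSelectMax
  rows <- list()
  if (cfg$includeParent && !is.null(parentId)) {
    rows[[1]] <- data.frame(id = parentId, predicted = NA_real_,
                            similarity = 1, provenance = "parent")
    slots <- slots - 1L
  }
  cand <- ranked[ranked$ligand_id != (parentId %||% ""), , drop = FALSE]
  for (k in seq_len(nrow(cand))) {
    if (slots <= 0L) break
    id <- cand$ligand_id[k]
    sim <- similarities[id]
    if (is.na(sim) || sim < cfg$simFloor) next
    rows[[length(rows) + 1L]] <- data.frame(id = id,
                                            predicted = cand$predicted[k],
                                            similarity = unname(sim),
                                            provenance = "knn")
    slots <- slots - 1L
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = character(0),
                                      predicted = numeric(0),
                                      similarity = numeric(0),
                                      provenance = character(0))
  if (nrow(out) < cfg$nSelectMin)
    warning("only ", nrow(out), " analog candidates met the similarity ",
            "floor; fewer than nSelectMin = ", cfg$nSelectMin)
  rownames(out) <- NULL
  out
}
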