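## Diversity selection: top-k, Butina clustering, exemplar picking,
## frequent-hitter removal and blinded plate assembly.

#' Selection configuration
#'
#' @param topK how many top-ranked molecules enter clustering
#'   (default 30000).
#' @param clusterSimCutoff Tanimoto similarity at or above which two
#'   molecules are Butina neighbors (default 0.35). Set
#'   `cutoffIsDistance = TRUE` to read the cutoff as a distance
#'   (neighbors iff `1 - sim <= cutoff`) instead.
#' @param nPick number of exemplars to carry forward (85 matches a single
#'   96-well plate with controls; use 440 for larger campaigns).
#' @param plateSize wells per plate (default 96).
#' @param nControls DMSO-only negative-control wells (default 2).
#' @param scrambleSeed seed for the blinded plate scramble.
#' @param cutoffIsDistance see `clusterSimCutoff`.
#' @return a `SelectionConfig` list.
#' @export
selectionConfig <- function(topK = 30000L, clusterSimCutoff = 0.35,
                            nPick = 85L, plateSize = 96L, nControls = 2L,
                            scrambleSeed = 1L, cutoffIsDistance = FALSE) {
  stopifnot(clusterSimCutoff > 0, clusterSimCutoff < 1)
  structure(list(topK = as.integer(topK),
                 clusterSimCutoff = clusterSimCutoff,
                 nPick = as.integer(nPick), plateSize = as.integer(plateSize),
                 nControls = as.integer(nControls),
                 scrambleSeed = as.integer(scrambleSeed),
                 cutoffIsDistance = isTRUE(cutoffIsDistance)),
            class = "SelectionConfig")
}

#' Take the top k of a ranked score table
#'
#' Defensively re-sorts by descending score, breaking ties by the tie key
#' (canonical SMILES when present as a `smiles` column, else ligand id),
#' then returns the first `min(k, n)` rows.
#'
#' @param ranked data.frame with columns `ligand_id`, `score` and
#'   optionally `smiles`.
#' @param k how many rows to keep.
#' @return the top-k sub-table.
#' @export
takeTopK <- function(ranked, k) {
  key <- if ("smiles" %in% names(ranked)) ranked$smiles else ranked$ligand_id
  ord <- order(-ranked$score, key)
  out <- ranked[ord, , drop = FALSE][seq_len(min(k, nrow(ranked))), ,
                                     drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Butina sphere-exclusion clustering
#'
#' Classic Butina clustering: two items are neighbors when their Tanimoto
#' similarity reaches the cutoff; repeatedly, the unassigned item with the
#' most unassigned neighbors (ties broken by lower input index) becomes a
#' centroid and claims itself plus its unassigned neighbors.
#'
#' @param fps logical fingerprint matrix (rows named by molecule id, or
#'   ids default to the row index).
#' @param simCutoff neighbor threshold (default 0.35).
#' @param cutoffIsDistance read the cutoff as `1 - sim` instead.
#' @return a `ClusterAssignment`: list with `clusters` (list of
#'   `list(centroid=, members=)` in formation order), `assignment` (integer
#'   cluster index per input row) and `singleton` (logical per cluster).
#' @export
butinaCluster <- function(fps, simCutoff = 0.35, cutoffIsDistance = FALSE) {
  n <- nrow(fps)
  stopifnot(n >= 1)
  ids <- rownames(fps)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sim <- tanimotoMatrix(fps)
  thr <- if (cutoffIsDistance) 1 - simCutoff else simCutoff
  nb <- sim >= thr
  diag(nb) <- FALSE
  unassigned <- rep(TRUE, n)
  assignment <- integer(n)
  clusters <- list()
  singleton <- logical(0)
  while (any(unassigned)) {
    cand <- which(unassigned)
    counts <- vapply(cand, function(i) sum(nb[i, ] & unassigned), integer(1))
    centroid <- cand[which.max(counts)]      # ties -> lower index
    members <- c(centroid, which(nb[centroid, ] & unassigned))
    members <- setdiff(members, centroid)
    cl <- c(centroid, members)
    k <- length(clusters) + 1L
    assignment[cl] <- k
    unassigned[cl] <- FALSE
    clusters[[k]] <- list(centroid = ids[centroid], members = ids[cl])
    singleton[k] <- length(cl) == 1L
  }
  structure(list(clusters = clusters, assignment = assignment,
                 singleton = singleton, ids = ids),
            class = "ClusterAssignment")
}

#' Select the highest-scoring exemplar of each cluster
#'
#' Exactly one molecule per cluster: the maximum-score member, ties broken
#' by the tie key (canonical SMILES when supplied, else id). The output is
#' sorted by descending score and truncated to `nPick`. Fully
#' deterministic; no manual cherry-picking step exists.
#'
#' @param clustering a `ClusterAssignment` from [butinaCluster()].
#' @param scores named numeric (id -> score); every clustered id needs a
#'   score.
#' @param nPick truncate the exemplar list to this many (default all).
#' @param smiles optional named character used as the tie key.
#' @return data.frame (rank, id, score, cluster, cluster_size).
#' @export
selectExemplars <- function(clustering, scores, nPick = Inf, smiles = NULL) {
  stopifnot(inherits(clustering, "ClusterAssignment"))
  miss <- setdiff(unlist(lapply(clustering$clusters, `[[`, "members")),
                  names(scores))
  if (length(miss))
    stop("missing score for: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_along(clustering$clusters), function(k) {
    mem <- clustering$clusters[[k]]$members
    s <- scores[mem]
    key <- if (!is.null(smiles)) unname(smiles[mem]) else mem
    best <- mem[order(-s, key)][1]
    data.frame(id = best, score = unname(scores[best]), cluster = k,
               cluster_size = length(mem))
  })
  out <- do.call(rbind, rows)
  key <- if (!is.null(smiles)) unname(smiles[out$id]) else out$id
  out <- out[order(-out$score, key), , drop = FALSE]
  out <- utils::head(out, nPick)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Flag frequent hitters across targets
#'
#' Molecules showing measurable activity toward more than one target are
#' likely assay artifacts; this returns the set active in two or more
#' distinct targets so downstream analytics can exclude them.
#'
#' @param results named list, target id -> character vector of active
#'   molecule ids (at least two targets).
#' @return character vector of flagged molecule ids.
#' @export
frequentHitterFilter <- function(results) {
  if (length(results) < 2L)
    stop("frequent-hitter filtering needs results from at least two targets",
         call. = FALSE)
  per_target <- lapply(results, unique)
  tab <- table(unlist(per_target))
  sort(names(tab)[tab >= 2L])
}

#' Assemble a blinded assay plate
#'
#' Lays out the selection plus DMSO-only negative controls on 96-well
#' plates (wells A1..H12, row-major), then scrambles the well order with a
#' seeded Fisher-Yates shuffle so testing is blinded. Returns both the
#' unblinded layout and the blinded copy (compound ids withheld).
#'
#' @param selection data.frame from [selectExemplars()] (needs `id`; other
#'   columns are carried along).
#' @param cfg a [selectionConfig()]; `plateSize`, `nControls` and
#'   `scrambleSeed` are used.
#' @param nPlates number of plates available (default 1).
#' @return list with `layout` and `blinded` data.frames (plate, well,
#'   content, id).
#' @export
assemblePlate <- function(selection, cfg = selectionConfig(), nPlates = 1L) {
  n <- nrow(selection) + cfg$nControls
  capacity <- cfg$plateSize * nPlates
  if (n > capacity)
    stop("selection of ", nrow(selection), " plus ", cfg$nControls,
         " controls needs ", ceiling(n / cfg$plateSize),
         " plate(s) of ", cfg$plateSize, " wells", call. = FALSE)
  rows <- LETTERS[1:8]
  cols <- seq_len(cfg$plateSize / 8L)
  wells <- as.vector(t(outer(rows, cols, paste0)))   # A1..A12, B1..
  content <- c(selection$id, rep("DMSO", cfg$nControls))
  kind <- c(rep("compound", nrow(selection)), rep("control", cfg$nControls))
  ## seeded Fisher-Yates shuffle of the occupied wells
  perm <- .with_seed(cfg$scrambleSeed, {
    k <- length(content)
    p <- seq_len(k)
    for (i in k:2) {
      j <- sample.int(i, 1L)
      tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    }
    p
  })
  plate_no <- ((seq_along(content) - 1L) %/% cfg$plateSize) + 1L
  well <- wells[((seq_along(content) - 1L) %% cfg$plateSize) + 1L]
  layout <- data.frame(plate = plate_no, well = well,
                       content = content[perm], kind = kind[perm])
  blinded <- layout
  blinded$content <- ifelse(blinded$kind == "control", "DMSO",
                            sprintf("well_%03d", seq_len(nrow(blinded))))
  blinded$kind <- NULL
  list(layout = layout, blinded = blinded)
}
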