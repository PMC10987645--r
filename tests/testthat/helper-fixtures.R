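## Shared fixtures (computed lazily, cached for the session) and
## independent brute-force oracles used across the test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## small synthetic study used by most module tests
small_spec <- function() fixtureSpec(seed = 7, nLigands = 60, nTargets = 6)

small_library <- function() cached("small_library",
                                   genToyLibrary(small_spec()))

small_complexes <- function() cached("small_complexes", {
  spec <- small_spec()
  lib <- small_library()
  px <- genToyPocketAndPoses(spec, lib)
  lab <- plantActivityLabels(lib, px$poses, spec)
  graphs <- lapply(px$poses, buildComplexGraph)
  list(spec = spec, lib = lib, poses = px$poses, targets = px$targets,
       labels = lab$labels, truth = lab$truth, graphs = graphs)
})

## the full-scale synthetic study (documented conditions: 1000 ligands,
## 12 targets, 2000 complexes); computed once for the acceptance tests
full_study <- function() cached("full_study", {
  spec <- fixtureSpec(seed = 1)
  lib <- genToyLibrary(spec)
  px <- genToyPocketAndPoses(spec, lib)
  lab <- plantActivityLabels(lib, px$poses, spec)
  graphs <- lapply(px$poses, buildComplexGraph)
  list(spec = spec, lib = lib, poses = px$poses, targets = px$targets,
       labels = lab$labels, truth = lab$truth, graphs = graphs)
})

## held-out AUC of every ensemble member against the planted truth
member_heldout_aucs <- function(ens, graphs, truth) {
  gt <- vapply(graphs, function(g) g@targetId, character(1))
  docked <- grepl("_p[0-9]+$", vapply(graphs, function(g) g@poseId,
                                      character(1)))
  vapply(seq_along(ens@members), function(m) {
    ho <- names(ens@foldMap)[ens@foldMap == m]
    idx <- which(gt %in% ho & docked)
    pr <- predictGraphs(ens, graphs[idx], members = m)
    ligs <- vapply(graphs[idx], function(g) g@ligandId, character(1))
    rankingAuc(pr[, 1], truth[ligs])
  }, numeric(1))
}

## pooled cross-validated AUC: each ligand is scored by the member that
## held out its fold, and one AUC is computed over the pooled predictions
pooled_cv_auc <- function(ens, graphs, truth) {
  gt <- vapply(graphs, function(g) g@targetId, character(1))
  docked <- grepl("_p[0-9]+$", vapply(graphs, function(g) g@poseId,
                                      character(1)))
  scores <- labels <- numeric(0)
  for (m in seq_along(ens@members)) {
    ho <- names(ens@foldMap)[ens@foldMap == m]
    idx <- which(gt %in% ho & docked)
    if (!length(idx)) next
    pr <- predictGraphs(ens, graphs[idx], members = m)
    ligs <- vapply(graphs[idx], function(g) g@ligandId, character(1))
    scores <- c(scores, pr[, 1])
    labels <- c(labels, as.numeric(truth[ligs]))
  }
  rankingAuc(scores, labels)
}

## small trained ensembles shared across test files
tiny_ensemble <- function() cached("tiny_ensemble", {
  cx <- small_complexes()
  trainEnsemble(cx$graphs,
                cx$labels[, c("activity", "pose_quality", "dock_score")],
                cx$targets, cfg = trainingConfig(epochs = 2, seed = 11))
})

## seeded random fingerprint matrix
random_fps <- function(n, bits = 128, density = 0.12, seed = 1) {
  set.seed(seed)
  matrix(runif(n * bits) < density, nrow = n,
         dimnames = list(sprintf("r%04d", seq_len(n)), NULL))
}

## ---- independent oracles --------------------------------------------

naive_tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 0 else sum(a & b) / u
}

## brute-force Butina reference: neighbor lists, then repeatedly take the
## unassigned item with most unassigned neighbors (ties: lower index)
naive_butina <- function(fps, cutoff) {
  n <- nrow(fps)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    sim[i, j] <- naive_tanimoto(fps[i, ], fps[j, ])
  assigned <- rep(FALSE, n)
  assignment <- integer(n)
  k <- 0L
  while (!all(assigned)) {
    best <- -1L; centroid <- 0L
    for (i in seq_len(n)) {
      if (assigned[i]) next
      cnt <- sum(!assigned & sim[i, ] >= cutoff) - 1L  # exclude self
      if (cnt > best) { best <- cnt; centroid <- i }
    }
    k <- k + 1L
    members <- which(!assigned & sim[centroid, ] >= cutoff)
    members <- unique(c(centroid, members))
    assignment[members] <- k
    assigned[members] <- TRUE
  }
  assignment
}

## brute-force receptor truncation
naive_truncate <- function(receptor, ligand, cutoff) {
  keep <- logical(nrow(receptor))
  for (i in seq_len(nrow(receptor))) {
    dmin <- Inf
    for (j in seq_len(nrow(ligand))) {
      d <- sqrt(sum((as.numeric(receptor[i, c("x", "y", "z")]) -
                     as.numeric(ligand[j, c("x", "y", "z")]))^2))
      dmin <- min(dmin, d)
    }
    keep[i] <- dmin <= cutoff
  }
  keep
}

## brute-force adjacency at a cutoff
naive_edges <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > 0 && d <= cutoff) out <- rbind(out, c(i, j, d))
  }
  out
}

## rigid rotation + translation of a pose
transform_pose <- function(pose, angles = c(0.4, 1.1, -0.7),
                           shift = c(3, -2, 5)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  R <- rx %*% ry %*% rz
  for (s in c("ligandAtoms", "receptorAtoms")) {
    a <- slot(pose, s)
    if (!nrow(a)) next
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + shift[1]
    a$y <- xyz[, 2] + shift[2]
    a$z <- xyz[, 3] + shift[3]
    slot(pose, s) <- a
  }
  pose
}

## permute the atom order within the ligand and receptor tables
permute_pose <- function(pose, seed = 1) {
  set.seed(seed)
  for (s in c("ligandAtoms", "receptorAtoms")) {
    a <- slot(pose, s)
    if (nrow(a) > 1) slot(pose, s) <- a[sample(nrow(a)), , drop = FALSE]
  }
  pose
}
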