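## Multi-task graph-convolutional scoring network: configuration,
## forward/backward passes, ADAM training, sequence-identity folds,
## active-proportional target sampling, ensemble scoring.

## evaluate expr under a temporary, deterministic RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Network configuration
#'
#' Five graph-convolution blocks: the first two consider all ligand and
#' receptor atoms within 5 Angstrom of each other with 64 filters per
#' block, the third raises the cutoff and filters to 7 Angstrom and 128,
#' and the last two keep those settings but consider ligand features only.
#' The sum-pool of the ligand-only representation feeds the task head:
#' three outputs (bioactivity probability, pose-quality probability and a
#' real-valued docking-score prediction) for the multi-task head, or a
#' single linear output for the regression variant.
#'
#' @param blocks list of 5 block specs, each `list(cutoff=, filters=,
#'   scope=)` with scope `"all"` or `"ligand"`.
#' @param rbfCenters centers (Angstrom) of the Gaussian distance basis
#'   used by the edge gates.
#' @param rbfWidth Gaussian width (Angstrom).
#' @param head `"multitask"` (3 outputs) or `"regression"` (1 output).
#' @param featureDim node feature dimension; defaults to the packaged
#'   Sybyl vocabulary plus the ligand role bit.
#' @return a `GNNConfig` list.
#' @export
gnnConfig <- function(blocks = list(
                        list(cutoff = 5, filters = 64, scope = "all"),
                        list(cutoff = 5, filters = 64, scope = "all"),
                        list(cutoff = 7, filters = 128, scope = "all"),
                        list(cutoff = 7, filters = 128, scope = "ligand"),
                        list(cutoff = 7, filters = 128, scope = "ligand")),
                      rbfCenters = seq(0.5, 7.5, by = 0.5),
                      rbfWidth = 0.5,
                      head = c("multitask", "regression"),
                      featureDim = nrow(sybylVocabulary()) + 1L) {
  head <- match.arg(head)
  if (length(blocks) != 5L)
    stop("the network has five graph convolutional blocks; got ",
         length(blocks), call. = FALSE)
  if (blocks[[5]]$scope != "ligand")
    stop("the last block must be ligand-only (its sum-pool feeds the head)",
         call. = FALSE)
  for (b in blocks) {
    stopifnot(b$filters > 0, b$cutoff > 0, b$scope %in% c("all", "ligand"))
  }
  structure(list(blocks = blocks, rbfCenters = rbfCenters,
                 rbfWidth = rbfWidth, head = head,
                 nOut = if (head == "multitask") 3L else 1L,
                 featureDim = as.integer(featureDim)),
            class = "GNNConfig")
}

#' Training configuration
#'
#' Ensemble training settings: six models over six sequence-identity
#' cross-validation folds (70 percent identity cutoff), 10 epochs with the
#' ADAM optimizer at learning rate 0.001, targets sampled with replacement
#' proportionally to their active-compound counts, one minibatch of the
#' sampled target's examples per draw.
#'
#' @param nModels,nFolds ensemble size = fold count (default 6).
#' @param foldIdentityThreshold percent identity above which two targets
#'   must share a fold (default 70).
#' @param epochs training epochs per member (default 10).
#' @param learningRate ADAM learning rate (default 0.001).
#' @param batchSize examples per minibatch (default 32).
#' @param lossWeights named weights for the activity/pose/dock tasks.
#' @param seed master seed; every random choice in training derives from
#'   it.
#' @return a `TrainingConfig` list.
#' @export
trainingConfig <- function(nModels = 6L, nFolds = 6L,
                           foldIdentityThreshold = 70, epochs = 10L,
                           learningRate = 0.001, batchSize = 32L,
                           lossWeights = c(activity = 1, pose = 1, dock = 1),
                           seed = 1L) {
  if (nModels != nFolds)
    stop("nModels must equal nFolds (one held-out fold per member)",
         call. = FALSE)
  stopifnot(epochs > 0, learningRate > 0, batchSize > 0)
  structure(list(nModels = as.integer(nModels), nFolds = as.integer(nFolds),
                 foldIdentityThreshold = foldIdentityThreshold,
                 epochs = as.integer(epochs), learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 lossWeights = lossWeights, seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Initialize network parameters
#'
#' He-scaled Gaussian initialization, deterministic given the seed. Layer
#' widths follow the block specs (feature dim -> 64 -> 64 -> 128 -> 128 ->
#' 128 -> head).
#'
#' @param cfg a [gnnConfig()].
#' @param seed integer seed.
#' @return parameter list with one entry per block (`Wself`, `Wnbr`, `b`,
#'   `wg`) plus the head (`Wh`, `bh`).
#' @export
initModel <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "GNNConfig"))
  K <- length(cfg$rbfCenters)
  .with_seed(seed, {
    din <- cfg$featureDim
    blocks <- lapply(cfg$blocks, function(b) {
      dout <- b$filters
      p <- list(
        Wself = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
        Wnbr = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
        b = numeric(dout),
        ## near-zero gates: the network starts as a per-node map of
        ## well-scaled activations and learns to open the distance gates
        wg = stats::rnorm(K, sd = 0.05))
      din <<- dout
      p
    })
    dlast <- cfg$blocks[[5]]$filters
    head <- list(
      Wh = matrix(stats::rnorm(dlast * cfg$nOut, sd = sqrt(1 / dlast)),
                  dlast, cfg$nOut),
      bh = numeric(cfg$nOut))
    list(blocks = blocks, head = head)
  })
}

## Gaussian radial-basis expansion of edge distances: E x K matrix
.rbf_expand <- function(d, centers, width) {
  exp(-outer(d, centers, function(a, b) (a - b)^2) / (2 * width^2))
}

#' Apply one graph-convolution block
#'
#' The package's declared convolution operator: for node v,
#' `h'_v = relu(Wself' h_v + sum_u phi(d_uv) Wnbr' h_u + b)`, where the sum
#' runs over the neighbors of v in the block's edge set and `phi(d)`
#' projects a Gaussian radial-basis expansion of the edge distance to a
#' scalar gate (`phi(d) = rbf(d) . wg`). With ligand scope, only
#' ligand-ligand edges contribute and only ligand rows are meaningful.
#'
#' @param features numeric node-feature matrix (n x d_in).
#' @param edges data.frame (i, j, d) of directed edges (j -> i messages);
#'   symmetric lists give the undirected behavior.
#' @param params block parameters (`Wself`, `Wnbr`, `b`, `wg`).
#' @param rbfCenters,rbfWidth distance-basis settings.
#' @return updated feature matrix (n x d_out).
#' @export
graphConvBlock <- function(features, edges, params,
                           rbfCenters = seq(0.5, 7.5, by = 0.5),
                           rbfWidth = 0.5) {
  n <- nrow(features)
  msg <- matrix(0, n, ncol(params$Wnbr))
  if (nrow(edges)) {
    B <- .rbf_expand(edges$d, rbfCenters, rbfWidth)
    g <- as.numeric(B %*% params$wg)
    A <- Matrix::sparseMatrix(i = edges$i, j = edges$j, x = g, dims = c(n, n))
    msg <- as.matrix(A %*% (features %*% params$Wnbr))
  }
  z <- features %*% params$Wself + msg +
    matrix(params$b, n, length(params$b), byrow = TRUE)
  pmax(z, 0)
}

## ---- batched tensors -------------------------------------------------

## Per-graph precomputation: ligand-first node ordering, per-(cutoff,scope)
## edge lists with RBF basis matrices.
.graph_tensors <- function(g, cfg) {
  stopifnot(is(g, "ComplexGraph"))
  perm <- order(!g@ligandMask)              # ligand atoms first, stable
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  H0 <- g@nodeFeatures[perm, , drop = FALSE]
  nL <- sum(g@ligandMask)
  n <- nrow(H0)
  need <- unique(vapply(cfg$blocks, function(b)
    paste0(b$cutoff, ":", b$scope), character(1)))
  es <- list()
  for (key in need) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    cut <- parts[1]; scope <- parts[2]
    if (!cut %in% names(g@edgeSets))
      stop("graph lacks the ", cut, " Angstrom edge set required by the ",
           "network configuration", call. = FALSE)
    e <- g@edgeSets[[cut]]
    i <- inv[e$i]; j <- inv[e$j]; d <- e$d
    if (scope == "ligand") {
      keep <- i <= nL & j <= nL
      i <- i[keep]; j <- j[keep]; d <- d[keep]
    }
    es[[key]] <- list(i = i, j = j,
                      B = .rbf_expand(d, cfg$rbfCenters, cfg$rbfWidth))
  }
  list(H0 = H0, n = n, nL = nL, edges = es,
       ligandId = g@ligandId, targetId = g@targetId, poseId = g@poseId)
}

## Concatenate per-graph tensors into one block-diagonal batch.
.make_batch <- function(tensors, cfg) {
  G <- length(tensors)
  ns <- vapply(tensors, `[[`, integer(1), "n")
  nLs <- vapply(tensors, `[[`, integer(1), "nL")
  off_full <- cumsum(c(0L, ns[-G]))
  off_lig <- cumsum(c(0L, nLs[-G]))
  H0 <- do.call(rbind, lapply(tensors, `[[`, "H0"))
  keys <- names(tensors[[1]]$edges)
  edges <- list()
  for (key in keys) {
    scope <- strsplit(key, ":", fixed = TRUE)[[1]][2]
    off <- if (scope == "ligand") off_lig else off_full
    i <- unlist(lapply(seq_len(G), function(k)
      tensors[[k]]$edges[[key]]$i + off[k]))
    j <- unlist(lapply(seq_len(G), function(k)
      tensors[[k]]$edges[[key]]$j + off[k]))
    B <- do.call(rbind, lapply(tensors, function(t) t$edges[[key]]$B))
    edges[[key]] <- list(i = i, j = j, B = B)
  }
  ## ligand rows within the full space: first nL rows of every graph
  lig_rows <- unlist(lapply(seq_len(G), function(k)
    off_full[k] + seq_len(nLs[k])))
  Nlig <- sum(nLs)
  pool <- Matrix::sparseMatrix(
    i = rep(seq_len(G), nLs), j = seq_len(Nlig), x = 1,
    dims = c(G, Nlig))
  list(H0 = H0, G = G, N = sum(ns), Nlig = Nlig, edges = edges,
       lig_rows = lig_rows, pool = pool)
}

## ---- forward / backward ----------------------------------------------

.block_key <- function(b) paste0(b$cutoff, ":", b$scope)

## Forward pass over a batch; keeps intermediates for backprop.
.forward_batch <- function(params, batch, cfg, keep = FALSE) {
  H <- batch$H0
  cache <- vector("list", 5L)
  in_lig_space <- FALSE
  for (bi in seq_len(5L)) {
    spec <- cfg$blocks[[bi]]
    if (spec$scope == "ligand" && !in_lig_space) {
      H <- H[batch$lig_rows, , drop = FALSE]
      in_lig_space <- TRUE
    }
    es <- batch$edges[[.block_key(spec)]]
    p <- params$blocks[[bi]]
    ns <- nrow(H)
    g <- as.numeric(es$B %*% p$wg)
    A <- Matrix::sparseMatrix(i = es$i, j = es$j, x = g, dims = c(ns, ns))
    AH <- as.matrix(A %*% H)
    Z <- H %*% p$Wself + AH %*% p$Wnbr +
      matrix(p$b, ns, length(p$b), byrow = TRUE)
    Hout <- Z * (Z > 0)
    if (keep)
      cache[[bi]] <- list(Hin = H, AH = AH, Z = Z, A = A, es = es,
                          lig_entry = spec$scope == "ligand")
    H <- Hout
  }
  pooled <- as.matrix(batch$pool %*% H)
  logits <- pooled %*% params$head$Wh +
    matrix(params$head$bh, batch$G, cfg$nOut, byrow = TRUE)
  list(logits = logits, pooled = pooled, Hlast = H, cache = cache)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Multi-task loss
#'
#' Weighted sum of binary cross-entropy on the activity and pose-quality
#' probabilities and mean squared error on the docking-score output,
#' averaged over the batch. The label mask marks which task labels exist
#' per example; masked tasks contribute 0. Probabilities are clipped at
#' 1e-7 inside the cross-entropy.
#'
#' @param preds numeric matrix (n x 3): activity probability, pose
#'   probability, dock prediction.
#' @param labels numeric matrix (n x 3); entries may be NA where masked.
#' @param mask logical matrix (n x 3); defaults to `!is.na(labels)`.
#' @param weights length-3 task weights.
#' @return scalar loss.
#' @export
multitaskLoss <- function(preds, labels, mask = NULL,
                          weights = c(1, 1, 1)) {
  if (is.null(mask)) mask <- !is.na(labels)
  if (!any(mask))
    stop("all task labels are masked; nothing to train on", call. = FALSE)
  eps <- 1e-7
  n <- nrow(preds)
  total <- 0
  for (t in 1:2) {
    m <- mask[, t]
    if (any(m)) {
      p <- pmin(pmax(preds[m, t], eps), 1 - eps)
      y <- labels[m, t]
      total <- total + weights[t] * sum(-(y * log(p) + (1 - y) * log(1 - p)))
    }
  }
  m <- mask[, 3]
  if (any(m))
    total <- total + weights[3] * sum((preds[m, 3] - labels[m, 3])^2)
  total / n
}

## loss + gradients for one batch (multitask or regression head)
.loss_and_grads <- function(params, batch, cfg, labels, mask, weights) {
  fw <- .forward_batch(params, batch, cfg, keep = TRUE)
  G <- batch$G
  logits <- fw$logits
  if (cfg$head == "multitask") {
    probs <- cbind(.sigmoid(logits[, 1]), .sigmoid(logits[, 2]), logits[, 3])
    loss <- multitaskLoss(probs, labels, mask, weights)
    dlog <- matrix(0, G, 3L)
    for (t in 1:2)
      dlog[, t] <- ifelse(mask[, t], weights[t] * (probs[, t] - labels[, t]), 0)
    dlog[, 3] <- ifelse(mask[, 3],
                        weights[3] * 2 * (logits[, 3] - labels[, 3]), 0)
    dlog[is.na(dlog)] <- 0
    dlog <- dlog / G
  } else {
    err <- logits[, 1] - labels[, 1]
    err[!mask[, 1]] <- 0
    loss <- sum(err^2) / G
    dlog <- matrix(2 * err / G, G, 1L)
  }
  ## head gradients
  ghead <- list(Wh = crossprod(fw$pooled, dlog),
                bh = colSums(dlog))
  dpooled <- dlog %*% t(params$head$Wh)
  dH <- as.matrix(Matrix::crossprod(batch$pool, dpooled))
  gblocks <- vector("list", 5L)
  for (bi in 5:1) {
    cc <- fw$cache[[bi]]
    p <- params$blocks[[bi]]
    dZ <- dH * (cc$Z > 0)
    U <- dZ %*% t(p$Wnbr)
    gb <- list(Wself = crossprod(cc$Hin, dZ),
               Wnbr = crossprod(cc$AH, dZ),
               b = colSums(dZ), wg = NULL)
    ## gate gradient: for edge e=(i<-j), dg_e = U[i,] . Hin[j,]
    es <- cc$es
    if (length(es$i)) {
      dg <- rowSums(U[es$i, , drop = FALSE] * cc$Hin[es$j, , drop = FALSE])
      gb$wg <- as.numeric(crossprod(es$B, dg))
    } else gb$wg <- numeric(length(p$wg))
    ## gradient to the block input
    dHin <- dZ %*% t(p$Wself) +
      as.matrix(Matrix::crossprod(cc$A, U))
    if (cc$lig_entry && bi >= 1 && (bi == 1 || !fw$cache[[bi - 1]]$lig_entry)) {
      ## entering the ligand-only space happened here: scatter back to full
      full <- matrix(0, batch$N, ncol(dHin))
      full[batch$lig_rows, ] <- dHin
      dHin <- full
    }
    gblocks[[bi]] <- gb
    dH <- dHin
  }
  list(loss = loss, grads = list(blocks = gblocks, head = ghead))
}

## ---- ADAM ------------------------------------------------------------

.adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

## ---- folds & sampling ------------------------------------------------

#' Assign targets to sequence-identity folds
#'
#' Single-linkage clusters under the identity threshold (connected
#' components of the "identity at or above threshold" graph) are
#' fold-atomic; clusters are packed greedily (largest active count first,
#' into the currently lightest fold) to balance total active counts. No
#' pair of targets in different folds can reach the identity threshold.
#'
#' @param targets list of [targetRecord()]s (sequences required).
#' @param k number of folds (default 6).
#' @param identityThreshold percent identity (default 70).
#' @param activeCounts named numeric; active compounds per target id.
#'   Defaults to each record's positive-activity binder count.
#' @return named integer vector, target id -> fold in `1..k`.
#' @export
assignFolds <- function(targets, k = 6L, identityThreshold = 70,
                        activeCounts = NULL) {
  n <- length(targets)
  ids <- vapply(targets, function(t) t@targetId, character(1))
  if (is.null(activeCounts)) {
    activeCounts <- vapply(targets, function(t)
      sum(t@activities > 0), numeric(1))
    names(activeCounts) <- ids
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    adj[i, j] <- adj[j, i] <-
      sequenceIdentity(targets[[i]]@sequence, targets[[j]]@sequence) >=
      identityThreshold
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ncl <- max(comp)
  if (ncl < k)
    stop("only ", ncl, " sequence clusters for ", k,
         " folds; use a smaller k", call. = FALSE)
  clw <- vapply(seq_len(ncl), function(c)
    sum(activeCounts[ids[comp == c]]), numeric(1))
  ord <- order(-clw, seq_len(ncl))        # largest first, ties by index
  fold_of_cluster <- integer(ncl)
  load <- numeric(k)
  for (c in ord) {
    f <- which.min(load)                  # lightest fold, ties by index
    fold_of_cluster[c] <- f
    load[f] <- load[f] + clw[c]
  }
  setNames(fold_of_cluster[comp], ids)
}

#' Sample training targets proportionally to active counts
#'
#' i.i.d. draws with replacement, `P(target) = actives / sum(actives)`,
#' deterministic given the seed.
#'
#' @param targetIds character vector.
#' @param activeCounts non-negative counts, parallel to `targetIds`; at
#'   least one must be positive.
#' @param nDraws number of draws.
#' @param seed integer seed.
#' @return character vector of length `nDraws`.
#' @export
sampleTrainingTargets <- function(targetIds, activeCounts, nDraws,
                                  seed = 1L) {
  stopifnot(length(targetIds) == length(activeCounts), all(activeCounts >= 0))
  if (sum(activeCounts) <= 0)
    stop("all active counts are zero; nothing to sample", call. = FALSE)
  .with_seed(seed,
    sample(targetIds, size = nDraws, replace = TRUE,
           prob = activeCounts / sum(activeCounts)))
}

## ---- training --------------------------------------------------------

#' Train the six-member scoring ensemble
#'
#' Builds sequence-identity folds with [assignFolds()]; member m holds out
#' fold m and trains on the remaining folds for `cfg$epochs` epochs. Each
#' epoch draws targets with [sampleTrainingTargets()] (probability
#' proportional to the training-set active count) and takes one ADAM step
#' on one minibatch of the drawn target's examples per draw. Fully
#' reproducible given `cfg$seed`. Dock-score labels are standardized
#' internally (mean/sd stored with each member).
#'
#' @param graphs list of [ComplexGraph-class] objects.
#' @param labels data.frame, one row per graph: `activity`, `pose_quality`,
#'   `dock_score` for the multitask head (NA = masked), or `potency` for
#'   the regression head.
#' @param targets list of [targetRecord()]s covering every `targetId`
#'   occurring in `graphs`.
#' @param cfg a [trainingConfig()].
#' @param gnn a [gnnConfig()].
#' @return a [GNNEnsemble-class].
#' @export
trainEnsemble <- function(graphs, labels, targets, cfg = trainingConfig(),
                          gnn = gnnConfig()) {
  stopifnot(inherits(cfg, "TrainingConfig"), inherits(gnn, "GNNConfig"))
  ng <- length(graphs)
  stopifnot(nrow(labels) == ng)
  gtarget <- vapply(graphs, function(g) g@targetId, character(1))
  if (gnn$head == "multitask") {
    lab <- as.matrix(labels[, c("activity", "pose_quality", "dock_score")])
  } else {
    lab <- matrix(labels$potency, ncol = 1L)
  }
  mask <- !is.na(lab)
  if (!any(mask)) stop("every example must carry at least one task label",
                       call. = FALSE)
  ## actives per target (activity task when present, else any labelled row)
  act_col <- if (gnn$head == "multitask") lab[, 1] else lab[, 1] * 0 + 1
  active_counts <- vapply(unique(gtarget), function(t)
    sum(act_col[gtarget == t] > 0, na.rm = TRUE), numeric(1))
  names(active_counts) <- unique(gtarget)
  fold_map <- assignFolds(targets, k = cfg$nFolds,
                          identityThreshold = cfg$foldIdentityThreshold,
                          activeCounts = active_counts[
                            vapply(targets, function(t) t@targetId,
                                   character(1))])
  missing <- setdiff(unique(gtarget), names(fold_map))
  if (length(missing))
    stop("no target record for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tensors <- lapply(graphs, .graph_tensors, cfg = gnn)
  by_target <- split(seq_len(ng), gtarget)
  members <- vector("list", cfg$nModels)
  log_rows <- list()
  ## regression targets are standardized for training (mean/sd stored with
  ## the members so predictions come back on the label scale)
  dock_mu <- 0; dock_sd <- 1
  if (gnn$head == "multitask" && any(mask[, 3])) {
    dock_mu <- mean(lab[mask[, 3], 3])
    dock_sd <- stats::sd(lab[mask[, 3], 3])
    if (!is.finite(dock_sd) || dock_sd == 0) dock_sd <- 1
    lab[, 3] <- (lab[, 3] - dock_mu) / dock_sd
  }
  if (gnn$head == "regression" && any(mask[, 1])) {
    dock_mu <- mean(lab[mask[, 1], 1])
    dock_sd <- stats::sd(lab[mask[, 1], 1])
    if (!is.finite(dock_sd) || dock_sd == 0) dock_sd <- 1
    lab[, 1] <- (lab[, 1] - dock_mu) / dock_sd
  }
  w <- if (gnn$head == "multitask")
    cfg$lossWeights[c("activity", "pose", "dock")] else 1
  for (m in seq_len(cfg$nModels)) {
    train_targets <- names(fold_map)[fold_map != m]
    train_targets <- intersect(train_targets, names(by_target))
    train_idx <- unlist(by_target[train_targets], use.names = FALSE)
    draws_per_epoch <- max(1L, ceiling(length(train_idx) / cfg$batchSize))
    params <- initModel(gnn, seed = cfg$seed * 1000L + m)
    opt <- .adam_init(params)
    .with_seed(cfg$seed * 100L + m, {
      for (ep in seq_len(cfg$epochs)) {
        drawn <- sampleTrainingTargets(
          train_targets, active_counts[train_targets],
          nDraws = draws_per_epoch,
          seed = sample.int(.Machine$integer.max, 1L))
        losses <- numeric(draws_per_epoch)
        for (dr in seq_len(draws_per_epoch)) {
          pool <- by_target[[drawn[dr]]]
          take <- if (length(pool) > cfg$batchSize)
            sample(pool, cfg$batchSize) else pool
          batch <- .make_batch(tensors[take], gnn)
          lg <- .loss_and_grads(params, batch, gnn,
                                lab[take, , drop = FALSE],
                                mask[take, , drop = FALSE], w)
          st <- .adam_step(params, lg$grads, opt, lr = cfg$learningRate)
          params <- st$params; opt <- st$state
          losses[dr] <- lg$loss
        }
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(member = m, epoch = ep, loss = mean(losses))
      }
    })
    params$held_out_fold <- m
    params$dock_mu <- dock_mu
    params$dock_sd <- dock_sd
    members[[m]] <- params
  }
  new("GNNEnsemble", members = members, foldMap = fold_map,
      config = list(gnn = gnn, training = cfg),
      trainingLog = do.call(rbind, log_rows))
}

## ---- scoring ---------------------------------------------------------

#' Forward pass on a single complex graph
#'
#' @param params model parameters from [initModel()] or an ensemble
#'   member.
#' @param graph a [ComplexGraph-class].
#' @param cfg the matching [gnnConfig()].
#' @return named numeric: `p_activity`, `p_pose`, `dock_pred` for the
#'   multitask head; `prediction` for the regression head.
#' @export
gnnForward <- function(params, graph, cfg = gnnConfig()) {
  batch <- .make_batch(list(.graph_tensors(graph, cfg)), cfg)
  logits <- .forward_batch(params, batch, cfg)$logits
  if (cfg$head == "multitask") {
    c(p_activity = .sigmoid(logits[1, 1]), p_pose = .sigmoid(logits[1, 2]),
      dock_pred = logits[1, 3])
  } else c(prediction = logits[1, 1])
}

## batched member predictions for a list of graphs
.predict_graphs <- function(member, graphs, cfg, chunk = 256L) {
  out <- numeric(length(graphs))
  tensors <- lapply(graphs, .graph_tensors, cfg = cfg)
  for (start in seq(1L, length(graphs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(graphs))
    batch <- .make_batch(tensors[idx], cfg)
    logits <- .forward_batch(member, batch, cfg)$logits
    out[idx] <- if (cfg$head == "multitask") .sigmoid(logits[, 1])
                else logits[, 1] * (member$dock_sd %||% 1) +
                  (member$dock_mu %||% 0)
  }
  out
}

#' Score a library with a trained ensemble
#'
#' Per ligand, each member's activity probability is aggregated over that
#' ligand's poses (maximum by default), then averaged across the ensemble
#' members. The table is sorted by descending score with ties broken by
#' the tie key (canonical SMILES when supplied, else ligand id), making
#' the ranking fully deterministic.
#'
#' @param ensemble a [GNNEnsemble-class].
#' @param graphs list of [ComplexGraph-class] (one or more poses per
#'   ligand; grouped by their `ligandId`).
#' @param smiles optional named character (ligand id -> canonical SMILES)
#'   used as the tie key.
#' @param poseAggregate `"max"` (default) or `"mean"` over poses.
#' @return data.frame (ligand_id, score, member1..memberK), sorted.
#' @export
scoreLibrary <- function(ensemble, graphs, smiles = NULL,
                         poseAggregate = c("max", "mean")) {
  poseAggregate <- match.arg(poseAggregate)
  stopifnot(is(ensemble, "GNNEnsemble"))
  cfg <- ensemble@config$gnn
  if (!length(graphs))
    return(data.frame(ligand_id = character(0), score = numeric(0)))
  ## canonical processing order: scores are bit-identical no matter how
  ## the input graphs were ordered
  ord0 <- order(vapply(graphs, function(g) g@ligandId, character(1)),
                vapply(graphs, function(g) g@poseId, character(1)))
  graphs <- graphs[ord0]
  lig <- vapply(graphs, function(g) g@ligandId, character(1))
  preds <- vapply(ensemble@members, .predict_graphs, numeric(length(graphs)),
                  graphs = graphs, cfg = cfg)
  preds <- matrix(preds, nrow = length(graphs))
  agg <- function(x) if (poseAggregate == "max") max(x) else mean(x)
  ids <- sort(unique(lig))
  per_member <- t(vapply(ids, function(l) {
    apply(preds[lig == l, , drop = FALSE], 2, agg)
  }, numeric(ncol(preds))))
  score <- rowMeans(per_member)
  key <- if (!is.null(smiles)) unname(smiles[ids]) else ids
  out <- data.frame(ligand_id = ids, score = score,
                    stringsAsFactors = FALSE)
  colnames(per_member) <- paste0("member", seq_len(ncol(per_member)))
  out <- cbind(out, per_member)
  ord <- order(-out$score, key)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-member predictions for a list of graphs
#'
#' @param ensemble a [GNNEnsemble-class].
#' @param graphs list of [ComplexGraph-class].
#' @param members which ensemble members to use (default all).
#' @return numeric matrix, one row per graph and one column per member
#'   (activity probability for the multitask head, linear prediction for
#'   the regression head).
#' @export
predictGraphs <- function(ensemble, graphs,
                          members = seq_along(ensemble@members)) {
  stopifnot(is(ensemble, "GNNEnsemble"))
  cfg <- ensemble@config$gnn
  out <- vapply(ensemble@members[members], .predict_graphs,
                numeric(length(graphs)), graphs = graphs, cfg = cfg)
  matrix(out, nrow = length(graphs),
         dimnames = list(NULL, paste0("member", members)))
}

#' Ranking AUC
#'
#' Area under the ROC curve computed from rank sums (equivalent to the
#' Mann-Whitney statistic); ties receive average ranks.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 (or logical) class labels.
#' @return AUC in `[0, 1]`.
#' @export
rankingAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}
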