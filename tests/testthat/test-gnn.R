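test_that("model initialization is deterministic with the configured shapes", {
  cfg <- gnnConfig()
  p1 <- initModel(cfg, seed = 5)
  p2 <- initModel(cfg, seed = 5)
  expect_identical(p1, p2)
  widths <- vapply(p1$blocks, function(b) ncol(b$Wself), integer(1))
  expect_equal(widths, c(64L, 64L, 128L, 128L, 128L))
  expect_equal(dim(p1$head$Wh), c(128L, 3L))
  ## a 4-block configuration violates the architecture invariant
  expect_error(gnnConfig(blocks = list(
    list(cutoff = 5, filters = 64, scope = "all"),
    list(cutoff = 5, filters = 64, scope = "all"),
    list(cutoff = 7, filters = 128, scope = "ligand"),
    list(cutoff = 7, filters = 128, scope = "ligand"))), "five")
})

test_that("graphConvBlock matches a hand-computed message sum", {
  set.seed(3)
  ## 4-node toy graph with hand-set weights
  H <- matrix(rnorm(4 * 3), 4, 3)
  edges <- data.frame(i = c(1, 2, 2, 3, 1, 4), j = c(2, 1, 3, 2, 4, 1),
                      d = c(1.2, 1.2, 2.5, 2.5, 4.0, 4.0))
  params <- list(Wself = matrix(rnorm(3 * 2), 3, 2),
                 Wnbr = matrix(rnorm(3 * 2), 3, 2),
                 b = c(0.1, -0.2), wg = rnorm(15))
  centers <- seq(0.5, 7.5, by = 0.5)
  out <- graphConvBlock(H, edges, params, centers, 0.5)
  ## independent naive computation, one node at a time
  gate <- function(d) sum(exp(-(d - centers)^2 / (2 * 0.25)) * params$wg)
  for (v in 1:4) {
    acc <- H[v, ] %*% params$Wself
    for (e in seq_len(nrow(edges))) {
      if (edges$i[e] == v)
        acc <- acc + gate(edges$d[e]) * (H[edges$j[e], ] %*% params$Wnbr)
    }
    expect_equal(out[v, ], pmax(as.numeric(acc) + params$b, 0),
                 tolerance = 1e-12)
  }
  ## zero weights give zero output; an isolated node sees only Wself
  zero <- list(Wself = params$Wself * 0, Wnbr = params$Wnbr * 0,
               b = params$b * 0, wg = params$wg)
  expect_true(all(graphConvBlock(H, edges, zero, centers, 0.5) == 0))
  iso <- graphConvBlock(H, edges[0, ], params, centers, 0.5)
  expect_equal(iso, pmax(H %*% params$Wself +
                           matrix(params$b, 4, 2, byrow = TRUE), 0))
})

test_that("forward pass collapses to the head biases when weights are zero", {
  cx <- small_complexes()
  cfg <- gnnConfig()
  p <- initModel(cfg, seed = 1)
  p$head$Wh[] <- 0
  p$head$bh <- c(0.3, -0.4, 1.7)
  out <- gnnForward(p, cx$graphs[[1]], cfg)
  expect_equal(unname(out["p_activity"]), 1 / (1 + exp(-0.3)))
  expect_equal(unname(out["p_pose"]), 1 / (1 + exp(0.4)))
  expect_equal(unname(out["dock_pred"]), 1.7)
})

test_that("forward outputs are invariant to rigid motion and permutation", {
  cx <- small_complexes()
  cfg <- gnnConfig()
  p <- initModel(cfg, seed = 2)
  for (k in c(1, 5, 9)) {
    pose <- cx$poses[[k]]
    base <- gnnForward(p, buildComplexGraph(pose), cfg)
    rot <- gnnForward(p, buildComplexGraph(transform_pose(pose)), cfg)
    prm <- gnnForward(p, buildComplexGraph(permute_pose(pose, seed = k)),
                      cfg)
    expect_equal(base, rot, tolerance = 1e-6)
    expect_equal(base, prm, tolerance = 1e-6)
  }
})

test_that("multitask loss follows the masked BCE/BCE/MSE definition", {
  perfect <- cbind(1 - 1e-9, 1e-9, 2.5)
  labels <- cbind(1, 0, 2.5)
  expect_lt(multitaskLoss(perfect, labels), 1e-6)
  ## p = 0.5 on one binary label -> ln 2
  expect_equal(multitaskLoss(cbind(0.5, NA, NA), cbind(1, NA, NA)), log(2))
  ## masked dock task: loss unchanged when the dock prediction varies
  l1 <- multitaskLoss(cbind(0.7, 0.2, 10), cbind(1, 0, NA))
  l2 <- multitaskLoss(cbind(0.7, 0.2, -99), cbind(1, 0, NA))
  expect_identical(l1, l2)
  ## weights scale the task contributions
  lw <- multitaskLoss(cbind(0.5, NA, NA), cbind(1, NA, NA),
                      weights = c(2, 1, 1))
  expect_equal(lw, 2 * log(2))
  expect_error(multitaskLoss(cbind(0.5, NA, NA), cbind(NA, NA, NA)),
               "masked")
})

test_that("fold assignment is constraint-satisfying and balanced", {
  base <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  mk <- function(id, seq) targetRecord(id, seq)
  ## two identical sequences always share a fold
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- function() paste(sample(aa, 100, TRUE), collapse = "")
  ts <- c(list(mk("A1", base), mk("A2", base)),
          lapply(3:8, function(k) mk(paste0("T", k), rnd())))
  counts <- setNames(rep(1, 8), vapply(ts, function(t) t@targetId,
                                       character(1)))
  fm <- assignFolds(ts, k = 6, activeCounts = counts)
  expect_equal(fm[["A1"]], fm[["A2"]])
  ## 12 mutually dissimilar targets, equal actives, k = 6 -> folds of 2
  ts12 <- lapply(1:12, function(k) mk(sprintf("D%02d", k), rnd()))
  fm12 <- assignFolds(ts12, k = 6,
                      activeCounts = setNames(rep(3, 12),
                                              sprintf("D%02d", 1:12)))
  expect_true(all(table(fm12) == 2))
  ## fewer clusters than folds is an error
  expect_error(assignFolds(ts12[1:4], k = 6), "smaller k")
})

test_that("no cross-fold target pair reaches the identity threshold", {
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aa, 100, TRUE), collapse = "")
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- sample(aa, k, TRUE)
    paste(v, collapse = "")
  }
  ## 30 targets: 10 families of 3 (high within-family identity)
  ts <- list()
  for (fam in 1:10) {
    root <- paste(sample(aa, 100, TRUE), collapse = "")
    for (v in 1:3) {
      ts[[length(ts) + 1]] <- targetRecord(sprintf("F%02dv%d", fam, v),
                                           mutate(root, sample(0:15, 1)))
    }
  }
  counts <- setNames(sample(1:20, 30, TRUE),
                     vapply(ts, function(t) t@targetId, character(1)))
  fm <- assignFolds(ts, k = 6, activeCounts = counts)
  ## exhaustive O(n^2) constraint check
  for (i in 1:29) for (j in (i + 1):30) {
    idi <- ts[[i]]@targetId; idj <- ts[[j]]@targetId
    if (fm[[idi]] != fm[[idj]])
      expect_lt(sequenceIdentity(ts[[i]]@sequence, ts[[j]]@sequence), 70)
  }
})

test_that("target sampling is proportional to active counts", {
  s1 <- sampleTrainingTargets(c("a", "b"), c(3, 1), 400, seed = 2)
  expect_identical(s1, sampleTrainingTargets(c("a", "b"), c(3, 1), 400,
                                             seed = 2))
  ## zero-count targets are never drawn
  s2 <- sampleTrainingTargets(c("a", "b"), c(5, 0), 500, seed = 3)
  expect_false("b" %in% s2)
  expect_error(sampleTrainingTargets(c("a", "b"), c(0, 0), 10), "zero")
  ## chi-square against (0.25, 0.25, 0.5) at alpha = 0.01, n = 40000
  s3 <- sampleTrainingTargets(c("x", "y", "z"), c(1, 1, 2), 40000, seed = 4)
  obs <- table(factor(s3, levels = c("x", "y", "z")))
  chi <- chisq.test(obs, p = c(0.25, 0.25, 0.5))
  expect_gt(chi$p.value, 0.01)
})

test_that("training is reproducible and reduces the loss", {
  cx <- small_complexes()
  labels <- cx$labels[, c("activity", "pose_quality", "dock_score")]
  cfg <- trainingConfig(epochs = 2, seed = 11)
  e1 <- trainEnsemble(cx$graphs, labels, cx$targets, cfg = cfg)
  e2 <- trainEnsemble(cx$graphs, labels, cx$targets, cfg = cfg)
  expect_identical(e1@members, e2@members)
  ## ensemble structure
  expect_equal(length(e1@members), 6L)
  held <- vapply(e1@members, function(m) m$held_out_fold, integer(1))
  expect_setequal(held, 1:6)
  ## per-member loss at the last epoch is below the first epoch
  tl <- e1@trainingLog
  first <- tl$loss[tl$epoch == 1]
  last <- tl$loss[tl$epoch == max(tl$epoch)]
  expect_true(all(last <= first * 1.05))
})

test_that("ensemble scoring averages members and is order-invariant", {
  cx <- small_complexes()
  labels <- cx$labels[, c("activity", "pose_quality", "dock_score")]
  ens <- tiny_ensemble()
  docked <- vapply(cx$graphs, function(g) grepl("_p1$", g@poseId),
                   logical(1))
  tab <- scoreLibrary(ens, cx$graphs[docked], smiles = smilesOf(cx$lib))
  expect_equal(nrow(tab), sum(docked))
  expect_true(all(diff(tab$score) <= 0))
  members <- as.matrix(tab[, grep("^member", names(tab))])
  expect_equal(tab$score, rowMeans(members))
  ## permuting the input graphs leaves the ranked output identical
  perm <- sample(which(docked))
  tab2 <- scoreLibrary(ens, cx$graphs[perm], smiles = smilesOf(cx$lib))
  expect_identical(tab, tab2)
  ## single model, single pose: score equals that model's probability
  one <- scoreLibrary(new("GNNEnsemble", members = ens@members[1],
                          foldMap = ens@foldMap, config = ens@config,
                          trainingLog = ens@trainingLog),
                      cx$graphs[which(docked)[1]])
  fw <- gnnForward(ens@members[[1]], cx$graphs[[which(docked)[1]]],
                   ens@config$gnn)
  expect_equal(one$score, unname(fw["p_activity"]))
  ## pose aggregation: max over the docked/decoy pair per member
  lig1 <- cx$graphs[[1]]@ligandId
  pair <- which(vapply(cx$graphs, function(g) g@ligandId == lig1,
                       logical(1)))
  both <- scoreLibrary(ens, cx$graphs[pair])
  p1 <- predictGraphs(ens, cx$graphs[pair])
  expect_equal(both$score, mean(apply(p1, 2, max)))
})

test_that("graphs missing a required cutoff edge set are rejected", {
  cx <- small_complexes()
  g <- cx$graphs[[1]]
  g@edgeSets <- g@edgeSets["5"]
  g@cutoffs <- 5
  p <- initModel(gnnConfig(), seed = 1)
  expect_error(gnnForward(p, g), "edge set")
})

test_that("rankingAuc matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (k in 1:5) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                 direction = "<")))
    expect_equal(rankingAuc(s, y), ref, tolerance = 1e-12)
  }
})
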