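test_that("PDB loading parses records and applies the drop rules", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(element = c("C", "N", "O"),
                      x = c(1.5, -2.25, 0), y = c(0, 3.125, -1),
                      z = c(-4.5, 2, 0.75))
  writeReceptorPdb(atoms, pdb)
  got <- loadReceptorPdb(pdb)
  expect_equal(nrow(got), 3L)
  expect_equal(got$element, c("C", "N", "O"))
  expect_equal(got$x, atoms$x, tolerance = 1e-3)
  expect_equal(got$z, atoms$z, tolerance = 1e-3)
  ## waters and hydrogens are dropped
  atoms2 <- rbind(atoms,
                  data.frame(element = c("O", "H"), x = c(9, 10),
                             y = 0, z = 0))
  atoms2$resid <- c("PKT", "PKT", "PKT", "HOH", "PKT")
  writeReceptorPdb(atoms2, pdb)
  got2 <- loadReceptorPdb(pdb)
  expect_equal(nrow(got2), 3L)
})

test_that("malformed PDB records raise errors naming the line", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(element = c("C", "C"), x = c(0, 1), y = c(0, 1),
                      z = c(0, 1))
  writeReceptorPdb(atoms, pdb)
  lines <- readLines(pdb)
  broken <- lines
  substr(broken[2], 31, 38) <- "  xx.yyy"
  writeLines(broken, pdb)
  expect_error(loadReceptorPdb(pdb), "line 2")
  writeLines(c(lines[1], substr(lines[2], 1, 40), "END"), pdb)
  expect_error(loadReceptorPdb(pdb), "line 2")
})

test_that("Sybyl typing covers the standard cases", {
  ## benzene: 6 aromatic carbons (kekulized bond orders)
  benz <- data.frame(element = rep("C", 6), x = 0, y = 0, z = 0)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  t1 <- assignSybylTypes(benz, bonds)
  expect_true(all(t1$sybyl == "C.ar"))
  ## acetamide: N.am, carbonyl C.2 and O.2, methyl C.3
  acet <- data.frame(element = c("C", "C", "O", "N"), x = 0, y = 0, z = 0)
  ab <- data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1, 2, 1))
  t2 <- assignSybylTypes(acet, ab)
  expect_equal(t2$sybyl, c("C.3", "C.2", "O.2", "N.am"))
  ## carboxylate: both oxygens O.co2
  carb <- data.frame(element = c("C", "C", "O", "O"), x = 0, y = 0, z = 0)
  cb <- data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1, 2, 1))
  t3 <- assignSybylTypes(carb, cb)
  expect_equal(t3$sybyl[3:4], c("O.co2", "O.co2"))
  ## pyridine nitrogen is aromatic
  pyr <- data.frame(element = c(rep("C", 5), "N"), x = 0, y = 0, z = 0)
  pb <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  t4 <- assignSybylTypes(pyr, pb)
  expect_equal(t4$sybyl[6], "N.ar")
  ## unknown element falls back to generic with a warning
  zn <- data.frame(element = "Zn", x = 0, y = 0, z = 0)
  expect_warning(t5 <- assignSybylTypes(zn,
    data.frame(i = integer(0), j = integer(0), order = integer(0))),
    "generic")
  expect_equal(t5$sybyl, "Zn.generic")
})

test_that("Sybyl typing of SDF ligands matches Open Babel's MOL2 typing", {
  smis <- c("CC(=O)Nc1ccccc1", "OC(=O)c1ccccc1", "c1ccncc1")
  sdf_txt <- atomscreen:::.ob_smiles_to_sdf(smis, c("m1", "m2", "m3"))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf_txt, sdf)
  ours <- readLigandPoses(sdf)
  mol2 <- withr::local_tempfile(fileext = ".mol2")
  system2("obabel", c(sdf, "-omol2", "-O", mol2), stderr = FALSE)
  ref_lines <- readLines(mol2)
  ## collect reference types per molecule block
  starts <- grep("@<TRIPOS>ATOM", ref_lines)
  ends <- grep("@<TRIPOS>BOND", ref_lines)
  for (k in seq_along(ours)) {
    blk <- ref_lines[(starts[k] + 1):(ends[k] - 1)]
    f <- strsplit(trimws(blk), "[[:space:]]+")
    ref_types <- vapply(f, `[[`, character(1), 6)
    ref_el <- vapply(f, `[[`, character(1), 2)
    ref_types <- ref_types[!grepl("^H", ref_el)]
    expect_equal(ours[[k]]$sybyl, ref_types, label = names(ours)[k])
  }
})

test_that("receptor truncation keeps the closed 7 A boundary", {
  lig <- data.frame(element = "C", x = 0, y = 0, z = 0)
  rec <- data.frame(element = c("C", "C", "C"),
                    x = c(6.9, 7.0, 7.1), y = 0, z = 0)
  kept <- truncateReceptor(rec, lig, cutoff = 7)
  expect_equal(kept$x, c(6.9, 7.0))          # 7.0 exactly is kept
  ## an entirely distant receptor leaves an empty (still valid) pocket
  far <- data.frame(element = "C", x = 30, y = 0, z = 0)
  expect_equal(nrow(truncateReceptor(far, lig)), 0L)
  expect_error(truncateReceptor(rec, lig[0, ]), "no ligand atoms")
})

test_that("truncation equals brute force on a random 200-atom pocket", {
  set.seed(5)
  rec <- data.frame(element = "C", x = runif(200, -12, 12),
                    y = runif(200, -12, 12), z = runif(200, -12, 12))
  lig <- data.frame(element = "C", x = runif(12, -3, 3),
                    y = runif(12, -3, 3), z = runif(12, -3, 3))
  kept <- truncateReceptor(rec, lig, cutoff = 7)
  manual <- naive_truncate(rec, lig, 7)
  expect_equal(nrow(kept), sum(manual))
  expect_equal(kept$x, rec$x[manual])
})

test_that("graph edges respect cutoffs and match brute force", {
  ## two atoms at 4.9 A: edge in both sets; at 6.0 A: only in the 7 A set
  mk <- function(d) {
    lig <- data.frame(element = c("C", "C"), sybyl = c("C.3", "C.3"),
                      x = c(0, d), y = 0, z = 0)
    complexPose(lig, lig[0, ], poseId = "p", targetId = "t",
                ligandId = "l")
  }
  g49 <- buildComplexGraph(mk(4.9))
  expect_equal(nrow(g49@edgeSets[["5"]]), 2L)
  expect_equal(nrow(g49@edgeSets[["7"]]), 2L)
  g60 <- buildComplexGraph(mk(6.0))
  expect_equal(nrow(g60@edgeSets[["5"]]), 0L)
  expect_equal(nrow(g60@edgeSets[["7"]]), 2L)
  ## 50 random atoms vs O(n^2) adjacency
  set.seed(9)
  lig <- data.frame(element = "C", sybyl = "C.3",
                    x = runif(20, -4, 4), y = runif(20, -4, 4),
                    z = runif(20, -4, 4))
  rec <- data.frame(element = "O", sybyl = "O.3",
                    x = runif(30, -6, 6), y = runif(30, -6, 6),
                    z = runif(30, -6, 6))
  pose <- complexPose(lig, rec, poseId = "p", targetId = "t",
                      ligandId = "l")
  g <- buildComplexGraph(pose)
  xyz <- as.matrix(rbind(pose@ligandAtoms, pose@receptorAtoms)[,
                                                               c("x", "y", "z")])
  for (cut in c("5", "7")) {
    ref <- naive_edges(xyz, as.numeric(cut))
    got <- g@edgeSets[[cut]]
    expect_equal(nrow(got), nrow(ref))
    key <- function(i, j, d) paste(i, j, round(d, 9))
    expect_setequal(key(got$i, got$j, got$d), key(ref[, 1], ref[, 2], ref[, 3]))
  }
  ## edge counts are monotone in the cutoff
  expect_gte(nrow(g@edgeSets[["7"]]), nrow(g@edgeSets[["5"]]))
})

test_that("graphs are invariant to rigid motion and atom permutation", {
  cx <- small_complexes()
  pose <- cx$poses[[3]]
  g0 <- buildComplexGraph(pose)
  g1 <- buildComplexGraph(transform_pose(pose))
  for (cut in c("5", "7")) {
    e0 <- g0@edgeSets[[cut]]; e1 <- g1@edgeSets[[cut]]
    expect_equal(nrow(e0), nrow(e1))
    o0 <- order(e0$i, e0$j); o1 <- order(e1$i, e1$j)
    expect_equal(e0$i[o0], e1$i[o1])
    expect_equal(e0$d[o0], e1$d[o1], tolerance = 1e-9)
  }
  ## permuted atoms: same multiset of edge distances, permuted features
  g2 <- buildComplexGraph(permute_pose(pose, seed = 4))
  expect_equal(sort(g2@edgeSets[["7"]]$d), sort(g0@edgeSets[["7"]]$d),
               tolerance = 1e-9)
  expect_equal(colSums(g2@nodeFeatures), colSums(g0@nodeFeatures))
})

test_that("coincident atoms warn and the zero-distance edge is skipped", {
  lig <- data.frame(element = c("C", "C"), sybyl = "C.3",
                    x = c(0, 0), y = 0, z = 0)
  pose <- complexPose(lig, lig[0, ], poseId = "p", targetId = "t",
                      ligandId = "l")
  expect_warning(g <- buildComplexGraph(pose), "coincident")
  expect_equal(nrow(g@edgeSets[["5"]]), 0L)
})

test_that("MOL2 input honors the stored Sybyl types", {
  mol2 <- withr::local_tempfile(fileext = ".mol2")
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines("c1ccccc1 benzene", smi)
  system2("obabel", c(smi, "-omol2", "--gen2D", "-O", mol2), stderr = FALSE)
  atoms <- readLigandPoses(mol2)[[1]]
  expect_true(all(atoms$sybyl[atoms$element == "C"] == "C.ar"))
})
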