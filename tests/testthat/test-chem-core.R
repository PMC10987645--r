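test_that("canonicalization unifies equivalent notations and is idempotent", {
  can <- canonicalizeSmiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(can[1], can[2])
  expect_identical(canonicalizeSmiles(can[1]), can[1])
  ## atom-order permuted ethanol variants
  can2 <- canonicalizeSmiles(c("CCO", "OCC", "C(O)C"))
  expect_length(unique(can2), 1L)
})

test_that("unparsable SMILES raise an error naming the input", {
  expect_error(canonicalizeSmiles("not_a_smiles"), "not_a_smiles")
  expect_error(moleculeSet(c("CCO", "xx$yy")), "xx\\$yy")
})

test_that("standardization strips salts and neutralizes", {
  expect_identical(canonicalizeSmiles("CCO.[Na]", standardize = TRUE),
                   canonicalizeSmiles("CCO"))
  expect_identical(
    canonicalizeSmiles("c1ccc(cc1)C(=O)[O-]", standardize = TRUE),
    canonicalizeSmiles("c1ccc(cc1)C(=O)O"))
})

test_that("fingerprints are deterministic, sized by config, and sparse", {
  cfg <- fingerprintConfig()
  f1 <- computeFingerprints(c("c1ccccc1", "C"), cfg)
  f2 <- computeFingerprints(c("c1ccccc1", "C"), cfg)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 1024L)
  expect_false(identical(f1[1, ], f1[2, ]))  # benzene differs from methane
  expect_true(all(rowSums(f1) <= 1024))
  ## folding: 2048-bit version has at least as many set bits
  f3 <- computeFingerprints("c1ccccc1", fingerprintConfig(fpBits = 2048L))
  expect_equal(ncol(f3), 2048L)
  expect_gte(sum(f3), sum(f1[1, ]))
})

test_that("fingerprint bits match the frozen regression fixture", {
  ref <- read.csv(test_path("fixtures", "fp_regression.csv"),
                  stringsAsFactors = FALSE)
  fps <- computeFingerprints(ref$smiles)
  for (k in seq_len(nrow(ref))) {
    got <- which(fps[k, ]) - 1L
    exp <- if (nzchar(ref$bits[k]))
      as.integer(strsplit(ref$bits[k], ";")[[1]]) else integer(0)
    expect_identical(got, exp, label = ref$id[k])
  }
})

test_that("fingerprint config validity is enforced", {
  expect_error(fingerprintConfig(fpBits = 1000), "power of two")
  expect_error(fingerprintConfig(radius = -1), "non-negative")
})

test_that("tanimoto matches hand counts and its invariants", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(FALSE, TRUE, TRUE, FALSE)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(tanimoto(logical(4), logical(4)), 0)  # all-zero convention
  expect_error(tanimoto(a, b[1:3]), "length mismatch")
  ## symmetry + bounds + identity property on random vectors
  set.seed(1)
  for (k in 1:25) {
    x <- runif(64) < 0.3; y <- runif(64) < 0.3
    s <- tanimoto(x, y)
    expect_identical(s, tanimoto(y, x))
    expect_gte(s, 0); expect_lte(s, 1)
    if (any(x) && s == 1) expect_identical(x, y)
  }
})

test_that("tanimotoMatrix equals the elementwise naive computation", {
  fps <- random_fps(12, bits = 64, seed = 3)
  m <- tanimotoMatrix(fps)
  for (i in 1:12) for (j in 1:12)
    expect_equal(m[i, j], naive_tanimoto(fps[i, ], fps[j, ]))
})

test_that("descriptors reproduce reference values", {
  d <- computeDescriptors(c("O", "CC", "C"))
  expect_equal(d$hbd[1], 1)           # water donates and accepts
  expect_equal(d$hba[1], 1)
  expect_equal(d$rotatable_bonds[1], 0)
  expect_equal(d$hbd[2], 0)           # ethane has no heteroatoms
  expect_equal(d$hba[2], 0)
  expect_equal(d$mw[3], 16.04, tolerance = 1e-3)  # methane mass sum
  ## independent molecular-weight oracle: atomic-mass sums
  masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
  d2 <- computeDescriptors(c("CCO", "NC(=O)c1ccccc1"))
  expect_equal(d2$mw[1], 2 * masses["C"] + 6 * masses["H"] + masses["O"],
               tolerance = 1e-2, ignore_attr = TRUE)
  expect_equal(d2$mw[2], 7 * masses["C"] + 7 * masses["H"] + masses["N"] +
                 masses["O"], tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("descriptors match the frozen 50-molecule reference within 1e-2", {
  ref <- read.csv(test_path("fixtures", "descriptor_reference.csv"),
                  stringsAsFactors = FALSE)
  d <- computeDescriptors(ref$smiles)
  for (col in c("mw", "clogp", "tpsa"))
    expect_equal(d[[col]], ref[[col]], tolerance = 1e-2,
                 ignore_attr = TRUE, label = col)
  for (col in c("hbd", "hba", "rotatable_bonds"))
    expect_identical(d[[col]], ref[[col]], label = col)
})

test_that("MoleculeSet round-trips through SMILES files and subsets", {
  ms <- small_library()
  p <- withr::local_tempfile(fileext = ".smi")
  writeSmilesFile(ms, p)
  back <- readSmilesFile(p, standardize = FALSE)
  expect_identical(smilesOf(back), smilesOf(ms))
  sub <- ms[c("lig00002", "lig00005")]
  expect_equal(length(sub), 2L)
  expect_identical(unname(smilesOf(sub)[1]), unname(smilesOf(ms)["lig00002"]))
  expect_error(ms["nope"], "unknown molecule id")
})
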