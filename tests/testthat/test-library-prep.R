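test_that("property filters partition the input with a complete audit", {
  lib <- small_library()
  ## vacuous rule set retains everything
  empty <- filterRuleSet()
  r0 <- applyPropertyFilters(lib, empty)
  expect_equal(length(r0$retained), length(lib))
  expect_equal(nrow(r0$rejected), 0L)
  ## single mw rule
  rules <- filterRuleSet(property_ranges = data.frame(
    descriptor = "mw", min = -Inf, max = 150))
  r1 <- applyPropertyFilters(lib, rules)
  expect_setequal(c(moleculeIds(r1$retained), r1$rejected$id),
                  moleculeIds(lib))
  expect_true(all(grepl("mw", r1$rejected$rule)))
  ## brute-force per-molecule re-evaluation (Lipinski-style ranges)
  lip <- filterRuleSet(property_ranges = data.frame(
    descriptor = c("mw", "clogp", "hbd", "hba"),
    min = c(0, -5, 0, 0), max = c(500, 5, 5, 10)))
  r2 <- applyPropertyFilters(lib, lip)
  d <- descriptors(lib)
  manual <- d$mw <= 500 & d$clogp >= -5 & d$clogp <= 5 & d$hbd <= 5 &
    d$hba <= 10
  expect_identical(moleculeIds(r2$retained), moleculeIds(lib)[manual])
  ## unknown descriptor is a config error
  bad <- filterRuleSet(property_ranges = data.frame(
    descriptor = "nope", min = 0, max = 1))
  expect_error(applyPropertyFilters(lib, bad), "unknown descriptor")
})

test_that("structural alerts reject by substructure with named reasons", {
  ms <- moleculeSet(c("c1ccc(cc1)[N+](=O)[O-]", "CCO", "O=[N+]([O-])C"),
                    ids = c("nitrobenzene", "ethanol", "nitromethane"))
  rules <- filterRuleSet(alert_patterns = data.frame(
    name = "nitro", smarts = "[N+](=O)[O-]"))
  r <- applyStructuralAlerts(ms, rules)
  expect_setequal(r$rejected$id, c("nitrobenzene", "nitromethane"))
  expect_true(all(r$rejected$rule == "nitro"))
  expect_identical(moleculeIds(r$retained), "ethanol")
  ## empty alert list retains all; a molecule equal to its pattern matches
  expect_equal(nrow(applyStructuralAlerts(ms, filterRuleSet())$rejected), 0L)
  self <- moleculeSet("O=[N+]([O-])c1ccccc1", ids = "self")
  rself <- applyStructuralAlerts(self, filterRuleSet(
    alert_patterns = data.frame(name = "itself",
                                smarts = "O=[N+]([O-])c1ccccc1")))
  expect_identical(rself$rejected$id, "self")
  ## unparsable pattern fails at load time
  expect_error(filterRuleSet(alert_patterns = data.frame(
    name = "broken", smarts = "[[Q")), "does not parse")
})

test_that("the packaged default rules load and run", {
  rules <- defaultFilterRules()
  expect_gt(nrow(rules$property_ranges), 3)
  expect_gt(nrow(rules$alert_patterns), 20)
  lib <- small_library()
  r <- applyStructuralAlerts(lib, rules)
  expect_equal(length(r$retained) + nrow(r$rejected), length(lib))
})

test_that("sequence identity follows the global-alignment definition", {
  expect_equal(sequenceIdentity("MKVL", "MKVL"), 100)
  expect_equal(sequenceIdentity("AAAA", "AAAT"), 75)
  expect_equal(sequenceIdentity("ACDEFG", "ACDEFG"), 100)
  ## symmetry and bounds on random sequences
  set.seed(2)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:8) {
    a <- paste(sample(aa, 30, TRUE), collapse = "")
    b <- paste(sample(aa, 25, TRUE), collapse = "")
    s <- sequenceIdentity(a, b)
    expect_equal(s, sequenceIdentity(b, a))
    expect_gte(s, 0); expect_lte(s, 100)
    if (s == 100) expect_identical(a, b)
  }
  expect_error(sequenceIdentity("", "AAA"), "non-empty")
})

## helper: a target record with binders drawn from the small library
.mk_target <- function(id, seq, binder_idx, labels = character(0)) {
  lib <- small_library()
  targetRecord(id, seq, classLabels = labels,
               binders = lib[binder_idx],
               activities = rep(1, length(binder_idx)))
}

test_that("exclusion sets honor homology threshold and kinase mode", {
  base <- paste(rep("ACDEFGHIKL", 10), collapse = "")   # 100 aa
  ## homolog at >= 70%: mutate 25 of 100 positions -> 75%
  mut75 <- paste0(substr(base, 1, 75), paste(rep("W", 25), collapse = ""))
  ## below threshold: mutate 35 -> 65%
  mut65 <- paste0(substr(base, 1, 65), paste(rep("W", 35), collapse = ""))
  expect_equal(sequenceIdentity(base, mut75), 75)
  expect_equal(sequenceIdentity(base, mut65), 65)
  t0 <- .mk_target("T0", base, 1:3)
  th <- .mk_target("TH", mut75, 4:5)
  tl <- .mk_target("TL", mut65, 6:8)
  ## db containing only the target: its own binders
  ex0 <- collectExclusionSet(t0, list(t0))
  expect_equal(nrow(ex0$fingerprints), 3L)
  ## homolog included, sub-threshold excluded
  ex1 <- collectExclusionSet(t0, list(t0, th, tl))
  expect_setequal(ex1$ids, c(moleculeIds(small_library()[1:3]),
                             moleculeIds(small_library()[4:5])))
  ## kinase mode pulls in kinase-labelled targets regardless of identity
  k0 <- .mk_target("K0", base, 1:2, labels = "kinase")
  k1 <- .mk_target("K1", mut65, 9:10, labels = "kinase")
  g1 <- .mk_target("G1", mut65, 11:12, labels = "GPCR")
  exk <- collectExclusionSet(k0, list(k0, k1, g1),
                             exclusionPolicy(kinaseMode = TRUE))
  expect_setequal(exk$ids, moleculeIds(small_library()[c(1:2, 9:10)]))
  ## without kinase mode the dissimilar kinase stays out
  exn <- collectExclusionSet(k0, list(k0, k1, g1))
  expect_setequal(exn$ids, moleculeIds(small_library()[1:2]))
  ## deduplication by canonical structure
  dup <- collectExclusionSet(t0, list(t0, t0))
  expect_equal(nrow(dup$fingerprints), 3L)
})

test_that("novelty exclusion removes strictly above threshold", {
  lib <- small_library()
  ## a molecule identical to a reference is removed (sim 1.0)
  ref <- fingerprints(lib)[1:5, , drop = FALSE]
  r <- excludeKnownChemotypes(lib, ref)
  expect_true(all(moleculeIds(lib)[1:5] %in% r$excluded$id))
  ## post-condition: every retained molecule is <= 0.5 to all references
  sims <- tanimotoMatrix(fingerprints(r$retained), ref)
  expect_true(all(sims <= 0.5))
  ## boundary: exactly at the threshold is retained
  fp <- matrix(FALSE, 1, 1024)
  fp[1, 1:10] <- TRUE
  refb <- matrix(FALSE, 1, 1024)
  refb[1, 6:15] <- TRUE                       # intersection 5, union 15
  ms <- lib[1]
  ms@fingerprints <- fp
  pol <- exclusionPolicy(simThreshold = 1 / 3)
  expect_equal(tanimoto(fp[1, ], refb[1, ]), 1 / 3)
  keep <- excludeKnownChemotypes(ms, refb, pol)
  expect_equal(length(keep$retained), 1L)     # = threshold -> retained
  refb2 <- matrix(FALSE, 1, 1024)
  refb2[1, 5:15] <- TRUE                      # intersection 6 / union 15
  drop <- excludeKnownChemotypes(ms, refb2, pol)
  expect_equal(length(drop$retained), 0L)
  expect_equal(drop$excluded$similarity, 6 / 15)
})

test_that("novelty exclusion equals the brute-force all-pairs check", {
  cand <- random_fps(100, bits = 256, seed = 11)
  refs <- random_fps(10, bits = 256, density = 0.25, seed = 12)
  lib <- small_library()
  ms <- lib[rep(1, 0)]  # empty set, then rebuild with random fps
  ms <- new("MoleculeSet", ids = rownames(cand),
            smiles = sprintf("C%d", seq_len(nrow(cand))),
            fingerprints = cand,
            descriptors = data.frame(mw = numeric(100), clogp = numeric(100),
                                     hbd = integer(100), hba = integer(100),
                                     rotatable_bonds = integer(100),
                                     tpsa = numeric(100)),
            fpConfig = fingerprintConfig(fpBits = 256L))
  pol <- exclusionPolicy(simThreshold = 0.3)
  r <- excludeKnownChemotypes(ms, refs, pol)
  manual_keep <- vapply(seq_len(nrow(cand)), function(i) {
    all(vapply(seq_len(nrow(refs)), function(j)
      naive_tanimoto(cand[i, ], refs[j, ]) <= 0.3, logical(1)))
  }, logical(1))
  expect_identical(moleculeIds(r$retained), rownames(cand)[manual_keep])
})

test_that("aggregator similarity pass flags the reference compounds", {
  ref_path <- system.file("extdata", "aggregator_reference.smi",
                          package = "atomscreen")
  refs <- readSmilesFile(ref_path)
  flags <- flagAggregatorLike(refs)        # each is similar to itself
  expect_true(all(flags))
  clean <- moleculeSet(c("CCO", "CCCCO"), ids = c("a", "b"))
  expect_false(any(flagAggregatorLike(clean)))
})

test_that("the full preparation stage leaves a complete audit trail", {
  lib <- small_library()
  base <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  target <- .mk_target("T0", base, 1:4)
  rules <- filterRuleSet(
    property_ranges = data.frame(descriptor = "mw", min = 0, max = 400),
    alert_patterns = data.frame(name = "nitro", smarts = "[N+](=O)[O-]"))
  prep <- prepareLibrary(lib, rules = rules, target = target,
                         binderDb = list(target))
  expect_setequal(prep$audit$id, moleculeIds(lib))
  retained <- prep$audit$id[prep$audit$stage == "retained"]
  expect_identical(sort(retained), sort(moleculeIds(prep$retained)))
  ## every molecule appears exactly once
  expect_equal(anyDuplicated(prep$audit$id), 0L)
})
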