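## Synthetic fixtures: a fragment-grammar molecule generator, toy binding
## pockets with docked/decoy poses, planted structure-activity labels and
## synthetic campaign tables. Every generator is a pure function of its
## spec (seed included), so tests and examples run with no external data.

#' Fixture specification
#'
#' Defines the synthetic study conditions used throughout the test suite
#' and the worked examples: library size, toy-pocket geometry, the planted
#' structure-activity rule, its label noise, and the pose jitter.
#'
#' @param seed master seed.
#' @param nLigands library size (each ligand gets one docked and one decoy
#'   pose, so the complex set is twice this).
#' @param nTargets number of synthetic protein targets.
#' @param pocketAtomCount receptor atoms per toy pocket.
#' @param pocketRadius radius (Angstrom) of the hemispherical pocket
#'   shell.
#' @param signalRule the planted activity rule: a list with `fragment`
#'   (SMARTS the ligand must contain) and `mwMax` (maximum molecular
#'   weight, g/mol).
#' @param labelNoise probability of flipping an activity label
#'   (`0 <= eps < 0.5`).
#' @param poseJitter isotropic Gaussian jitter (Angstrom) applied to
#'   docked ligand coordinates.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, nLigands = 1000L, nTargets = 12L,
                        pocketAtomCount = 24L, pocketRadius = 6.0,
                        signalRule = list(fragment = "[n]", mwMax = 350),
                        labelNoise = 0.1, poseJitter = 0.3) {
  stopifnot(labelNoise >= 0, labelNoise < 0.5, nLigands > 0, nTargets > 0,
            pocketAtomCount > 0, pocketRadius > 0, poseJitter >= 0)
  allowed <- c("fragment", "mwMax")
  if (length(setdiff(names(signalRule), allowed)))
    stop("signal rule references unknown feature(s): ",
         paste(setdiff(names(signalRule), allowed), collapse = ", "),
         call. = FALSE)
  structure(list(seed = as.integer(seed), nLigands = as.integer(nLigands),
                 nTargets = as.integer(nTargets),
                 pocketAtomCount = as.integer(pocketAtomCount),
                 pocketRadius = pocketRadius, signalRule = signalRule,
                 labelNoise = labelNoise, poseJitter = poseJitter),
            class = "FixtureSpec")
}

## ring cores (with one substitution site), linkers and tails of the
## fragment grammar; every combination is a valid molecule
.grammar <- list(
  rings = c("c1ccc(%s)cc1",      # benzene
            "c1ccc(%s)nc1",      # pyridine
            "c1ncc(%s)cn1",      # pyrimidine
            "c1cc(%s)co1",       # furan
            "c1cc(%s)cs1",       # thiophene
            "c1cc(%s)c[nH]1",    # pyrrole
            "C1CCC(%s)CC1",      # cyclohexane
            "C1CCN(%s)CC1"),     # piperidine (N-substituted)
  linkers = c("", "C", "CC", "C(=O)", "C(=O)N", "O", "OC", "N", "S(=O)(=O)",
              "C=C"),
  tails = c("C", "CC", "C(C)C", "O", "N", "C(=O)O", "C(=O)N", "C#N", "F",
            "Cl", "C(F)(F)F", "OC", "N(C)C", "c2ccccc2", "c2ccncc2",
            "C2CCCCC2"))

#' Generate a toy screening library
#'
#' Enumerates molecules from a small fragment grammar (ring cores x
#' linkers x decorations), canonicalizes and deduplicates them, and
#' returns a seeded sample of the requested size as a [MoleculeSet-class].
#' Grammar molecules are guaranteed valid and give the planted
#' structure-activity rule chemical meaning.
#'
#' @param spec a [fixtureSpec()].
#' @param cfg fingerprint configuration.
#' @return a [MoleculeSet-class] with `spec$nLigands` unique molecules.
#' @export
genToyLibrary <- function(spec = fixtureSpec(), cfg = fingerprintConfig()) {
  g <- .grammar
  combos <- expand.grid(ring = g$rings, linker = g$linkers, tail = g$tails,
                        stringsAsFactors = FALSE)
  smi <- sprintf(combos$ring, paste0(combos$linker, combos$tail))
  can <- canonicalizeSmiles(smi, standardize = TRUE)
  can <- unique(can[!is.na(can)])
  if (length(can) < spec$nLigands)
    stop("fragment grammar yields only ", length(can),
         " unique molecules; requested ", spec$nLigands, call. = FALSE)
  pick <- .with_seed(spec$seed, sample(can, spec$nLigands))
  moleculeSet(pick, ids = sprintf("lig%05d", seq_len(spec$nLigands)),
              cfg = cfg, standardize = FALSE)
}

## deterministic hemispherical shell (Fibonacci spiral, z <= 0)
.pocket_shell <- function(n, radius, seed) {
  pts <- matrix(0, 0, 3)
  k <- 0L
  total <- 2L * n
  golden <- pi * (3 - sqrt(5))
  while (nrow(pts) < n) {
    total <- total + n
    i <- seq_len(total) - 0.5
    z <- 1 - 2 * i / total
    r <- sqrt(pmax(0, 1 - z^2))
    th <- golden * i
    all_pts <- cbind(r * cos(th), r * sin(th), z) * radius
    pts <- all_pts[all_pts[, 3] <= 0, , drop = FALSE]
    k <- k + 1L
    if (k > 10L) break
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  elements <- .with_seed(seed, sample(c("C", "C", "C", "N", "O", "O", "S"),
                                      n, replace = TRUE))
  data.frame(element = elements, x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Generate toy pockets and docked/decoy poses
#'
#' Places `pocketAtomCount` receptor atoms on a hemispherical shell of
#' `pocketRadius` below the ligand plane (one pocket per target, with
#' target-specific element assignment), gives each ligand its generated
#' 2D-template coordinates centered in the pocket plus seeded isotropic
#' jitter, and adds one decoy pose per ligand, rigidly translated 4.5
#' Angstrom out of the pocket. Ligands are assigned to targets round-robin.
#'
#' @param spec a [fixtureSpec()].
#' @param library a [MoleculeSet-class] from [genToyLibrary()].
#' @return list with `poses` (list of [ComplexPose-class]; docked pose
#'   `<lig>_p1` and decoy `<lig>_d1` per ligand), `targets` (list of
#'   [targetRecord()]s with synthetic sequences) and `ligandTarget`
#'   (named character, ligand id -> target id).
#' @export
genToyPocketAndPoses <- function(spec = fixtureSpec(), library) {
  stopifnot(is(library, "MoleculeSet"))
  n <- length(library)
  ## ligand connection tables + 2D coordinates, one batch call
  sdf_text <- .ob_smiles_to_sdf(library@smiles, library@ids)
  sdf_path <- tempfile(fileext = ".sdf")
  on.exit(unlink(sdf_path), add = TRUE)
  writeLines(sdf_text, sdf_path)
  lig_atoms <- readLigandPoses(sdf_path)
  lig_atoms <- lig_atoms[library@ids]
  ## synthetic targets: random sequences are mutually dissimilar
  targets <- .with_seed(spec$seed + 1L, {
    lapply(seq_len(spec$nTargets), function(t) {
      seq <- paste(sample(Biostrings::AA_STANDARD, 120, replace = TRUE),
                   collapse = "")
      targetRecord(sprintf("T%02d", t), seq,
                   classLabels = if (t <= 2) "kinase" else character(0))
    })
  })
  pockets <- lapply(seq_len(spec$nTargets), function(t)
    .pocket_shell(spec$pocketAtomCount, spec$pocketRadius,
                  seed = spec$seed + 100L + t))
  tid <- sprintf("T%02d", ((seq_len(n) - 1L) %% spec$nTargets) + 1L)
  poses <- vector("list", 2L * n)
  .with_seed(spec$seed + 2L, {
    for (k in seq_len(n)) {
      at <- lig_atoms[[k]]
      xyz <- as.matrix(at[, c("x", "y", "z")])
      xyz <- sweep(xyz, 2, colMeans(xyz))       # center in the pocket
      if (spec$poseJitter > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$poseJitter),
                            nrow(xyz), 3)
      docked <- at
      docked$x <- xyz[, 1]; docked$y <- xyz[, 2]; docked$z <- xyz[, 3]
      decoy <- docked
      decoy$z <- decoy$z + 4.5                  # rigid translation >= 4 A
      pk <- pockets[[match(tid[k], sprintf("T%02d", seq_len(spec$nTargets)))]]
      lid <- library@ids[k]
      poses[[2L * k - 1L]] <- complexPose(docked, pk,
                                          poseId = paste0(lid, "_p1"),
                                          targetId = tid[k], ligandId = lid)
      poses[[2L * k]] <- complexPose(decoy, pk,
                                     poseId = paste0(lid, "_d1"),
                                     targetId = tid[k], ligandId = lid)
    }
  })
  list(poses = poses, targets = targets,
       ligandTarget = setNames(tid, library@ids))
}

#' Evaluate the planted activity rule
#'
#' The noise-free ground truth of the planted structure-activity signal:
#' the molecule contains the rule's fragment (SMARTS) and its molecular
#' weight does not exceed `mwMax`.
#'
#' @param library a [MoleculeSet-class].
#' @param spec a [fixtureSpec()].
#' @return named logical vector (ligand id -> truth).
#' @export
signalRuleTruth <- function(library, spec = fixtureSpec()) {
  stopifnot(is(library, "MoleculeSet"))
  rule <- spec$signalRule
  truth <- rep(TRUE, length(library))
  if (!is.null(rule$fragment))
    truth <- truth & .ob_smarts_match(library@smiles, rule$fragment)
  if (!is.null(rule$mwMax))
    truth <- truth & library@descriptors$mw <= rule$mwMax
  setNames(truth, library@ids)
}

#' Plant activity, pose-quality and surrogate docking labels
#'
#' Training labels for the synthetic complexes: the activity bit is the
#' planted rule XOR a Bernoulli(labelNoise) flip (docked poses only;
#' masked for decoys); the pose-quality bit is 1 for docked and 0 for
#' decoy poses; the surrogate docking score is the negative count of
#' ligand-receptor atom pairs within 4 Angstrom plus unit Gaussian noise.
#' Deterministic given the fixture seed.
#'
#' @param library a [MoleculeSet-class].
#' @param poses the pose list from [genToyPocketAndPoses()].
#' @param spec a [fixtureSpec()].
#' @return list with `labels` (data.frame per pose: pose_id, ligand,
#'   target, activity, pose_quality, dock_score) and `truth` (named
#'   logical, noise-free rule per ligand).
#' @export
plantActivityLabels <- function(library, poses, spec = fixtureSpec()) {
  truth <- signalRuleTruth(library, spec)
  flips <- .with_seed(spec$seed + 3L,
    stats::rbinom(length(truth), 1L, spec$labelNoise) == 1L)
  observed <- setNames(xor(truth, flips), names(truth))
  noise <- .with_seed(spec$seed + 4L, stats::rnorm(length(poses)))
  rows <- lapply(seq_along(poses), function(k) {
    p <- poses[[k]]
    docked <- grepl("_p[0-9]+$", p@poseId)
    lxyz <- as.matrix(p@ligandAtoms[, c("x", "y", "z")])
    rxyz <- as.matrix(p@receptorAtoms[, c("x", "y", "z")])
    contacts <- if (nrow(rxyz)) {
      d2 <- outer(rowSums(lxyz^2), rowSums(rxyz^2), "+") -
        2 * tcrossprod(lxyz, rxyz)
      sum(d2 <= 16)
    } else 0L
    data.frame(pose_id = p@poseId, ligand = p@ligandId, target = p@targetId,
               activity = if (docked) as.numeric(observed[p@ligandId])
                          else NA_real_,
               pose_quality = as.numeric(docked),
               dock_score = -contacts + noise[k])
  })
  list(labels = do.call(rbind, rows), truth = truth)
}

#' Generate a synthetic screening-campaign table
#'
#' Synthesizes multi-project campaign records with configurable hit-rate
#' distributions, in the same schema as [internalPrograms()], for
#' exercising the portfolio analytics.
#'
#' @param nProjects number of projects.
#' @param seed integer seed.
#' @param meanTested mean compounds tested per project.
#' @param sdRateMean mean single-dose hit rate (percent); rates are drawn
#'   from an exponential with this mean, truncated to `[0, 100]`, and a
#'   seeded fraction of projects get rate 0.
#' @param zeroFraction fraction of projects with no hits.
#' @return data.frame of project records.
#' @export
genCampaignTable <- function(nProjects = 20L, seed = 1L, meanTested = 400,
                             sdRateMean = 8, zeroFraction = 0.1) {
  .with_seed(seed, {
    n_tested <- pmax(10L, stats::rpois(nProjects, meanTested))
    sd_rate <- pmin(100, stats::rexp(nProjects, rate = 1 / sdRateMean))
    zero <- stats::runif(nProjects) < zeroFraction
    sd_rate[zero] <- 0
    dr_rate <- sd_rate * stats::runif(nProjects, 0.3, 1)
    data.frame(project = sprintf("proj%03d", seq_len(nProjects)),
               n_tested = n_tested,
               sd_hit_rate = round(sd_rate, 2),
               dr_hit_rate = round(dr_rate, 2),
               n_analogs = NA_integer_,
               analog_sd_rate = NA_real_, analog_dr_rate = NA_real_)
  })
}

#' Write receptor atoms as a PDB file
#'
#' Minimal fixed-width PDB writer for toy pockets, so the PDB reading path
#' can be exercised without external structures.
#'
#' @param atoms data.frame with element, x, y, z (optionally resid,
#'   resno).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReceptorPdb <- function(atoms, path) {
  resid <- if ("resid" %in% names(atoms)) atoms$resid else
    rep("PKT", nrow(atoms))
  resno <- if ("resno" %in% names(atoms)) atoms$resno else
    seq_len(nrow(atoms))
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(paste0(atoms$element[i], i), 1, 4), "",
            resid[i], "A", resno[i], "",
            atoms$x[i], atoms$y[i], atoms$z[i], 1.00, 0.00,
            toupper(atoms$element[i]))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
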