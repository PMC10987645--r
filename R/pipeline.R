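#' Run the end-to-end screening pipeline on synthetic fixtures
#'
#' The full workflow at desk scale: generate a toy library and binding
#' pockets, prepare the library (property filters, structural alerts,
#' chemotype-novelty exclusion against a synthetic binder database),
#' featurize complexes, train the scoring ensemble on planted labels,
#' score and rank the prepared library, cluster and pick diverse
#' exemplars, and assemble the blinded assay plate. The whole run is a
#' pure function of `(seed, scale parameters)`: repeated runs write
#' byte-identical selection and plate CSVs.
#'
#' @param outDir directory for the output CSVs (created if missing).
#' @param seed master seed; drives fixture generation, training,
#'   selection and plate scrambling.
#' @param nLigands,nTargets library scale (see [fixtureSpec()]).
#' @param epochs training epochs per ensemble member.
#' @param nPick exemplar count carried to the plate.
#' @param clusterSimCutoff Butina neighbor threshold.
#' @return list with `selection`, `plate`, `files` (paths of selection,
#'   plate and blinded CSVs), `scores`, `ensemble`, `prep` and the
#'   generated `spec`.
#' @export
runScreenPipeline <- function(outDir = tempfile("screen"), seed = 1L,
                              nLigands = 150L, nTargets = 8L, epochs = 2L,
                              nPick = 20L, clusterSimCutoff = 0.35) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- fixtureSpec(seed = seed, nLigands = nLigands, nTargets = nTargets)
  lib <- genToyLibrary(spec)
  ## toy binder database: the first few library molecules are "known
  ## binders" of the screening target, so novelty exclusion has work to do
  binder_ids <- lib@ids[seq_len(min(5L, length(lib)))]
  scr_target <- targetRecord("T01",
                             paste(rep("ACDEFGHIKLMNPQRSTVWY", 6),
                                   collapse = ""),
                             binders = lib[binder_ids],
                             activities = rep(1, length(binder_ids)))
  rules <- filterRuleSet(
    property_ranges = data.frame(descriptor = c("mw", "clogp"),
                                 min = c(80, -3), max = c(500, 6)),
    alert_patterns = data.frame(name = "nitro", smarts = "[N+](=O)[O-]"),
    provenance = "toy pipeline rules")
  prep <- prepareLibrary(lib, rules = rules, target = scr_target,
                         binderDb = list(scr_target))
  ## featurize + labels on the full library (training uses every target)
  px <- genToyPocketAndPoses(spec, lib)
  lab <- plantActivityLabels(lib, px$poses, spec)
  graphs <- lapply(px$poses, buildComplexGraph)
  tcfg <- trainingConfig(epochs = epochs, seed = seed)
  labels <- lab$labels[, c("activity", "pose_quality", "dock_score")]
  ens <- trainEnsemble(graphs, labels, px$targets, cfg = tcfg)
  ## score only the prepared (retained) library, docked poses only
  keep_ids <- prep$retained@ids
  docked <- vapply(graphs, function(g)
    grepl("_p[0-9]+$", g@poseId) && g@ligandId %in% keep_ids, logical(1))
  scores <- scoreLibrary(ens, graphs[docked], smiles = smilesOf(lib))
  ## diversity selection
  scfg <- selectionConfig(topK = 30000L, clusterSimCutoff = clusterSimCutoff,
                          nPick = nPick, scrambleSeed = seed)
  top <- takeTopK(cbind(scores, smiles = unname(smilesOf(lib)[scores$ligand_id])),
                  scfg$topK)
  fps <- fingerprints(prep$retained)[top$ligand_id, , drop = FALSE]
  cl <- butinaCluster(fps, simCutoff = scfg$clusterSimCutoff)
  sel <- selectExemplars(cl, setNames(top$score, top$ligand_id),
                         nPick = scfg$nPick,
                         smiles = smilesOf(lib)[top$ligand_id])
  sel$smiles <- unname(smilesOf(lib)[sel$id])
  plate <- assemblePlate(sel, scfg)
  files <- c(selection = file.path(outDir, "selection.csv"),
             plate = file.path(outDir, "plate.csv"),
             blinded = file.path(outDir, "plate_blinded.csv"),
             audit = file.path(outDir, "prep_audit.csv"))
  utils::write.csv(sel, files["selection"], row.names = FALSE)
  utils::write.csv(plate$layout, files["plate"], row.names = FALSE)
  utils::write.csv(plate$blinded, files["blinded"], row.names = FALSE)
  utils::write.csv(prep$audit, files["audit"], row.names = FALSE)
  list(selection = sel, plate = plate, files = files, scores = scores,
       ensemble = ens, prep = prep, spec = spec, library = lib,
       labels = lab)
}
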