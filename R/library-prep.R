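#' Filter rule sets for library preparation
#'
#' A filter rule set combines descriptor ranges (drug-likeness windows) and
#' SMARTS structural-alert patterns (reactive/interfering chemotypes such
#' as PAINS motifs, aggregators and autofluorescers). The packaged default
#' (`defaultFilterRules()`) is a documented representative subset of the
#' published medicinal-chemistry rule collections: Lipinski/lead-like
#' property windows plus ~30 alert patterns.
#'
#' @param path YAML file with top-level keys `provenance`,
#'   `property_ranges` (list of descriptor/min/max) and `alert_patterns`
#'   (list of name/smarts).
#' @return a `FilterRuleSet`: list with elements `property_ranges`
#'   (data.frame descriptor/min/max), `alert_patterns` (data.frame
#'   name/smarts) and `provenance`.
#' @export
loadFilterRules <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- do.call(rbind, lapply(y$property_ranges, function(r)
    data.frame(descriptor = r$descriptor,
               min = if (is.null(r$min)) -Inf else as.numeric(r$min),
               max = if (is.null(r$max)) Inf else as.numeric(r$max))))
  if (is.null(pr)) pr <- data.frame(descriptor = character(0),
                                    min = numeric(0), max = numeric(0))
  ap <- do.call(rbind, lapply(y$alert_patterns, function(a)
    data.frame(name = a$name, smarts = a$smarts)))
  if (is.null(ap)) ap <- data.frame(name = character(0), smarts = character(0))
  if (any(pr$min > pr$max))
    stop("filter rules: property range with min > max", call. = FALSE)
  for (k in seq_len(nrow(ap))) {
    if (!.ob_smarts_valid(ap$smarts[k]))
      stop("filter rules: SMARTS pattern '", ap$name[k],
           "' does not parse: ", ap$smarts[k], call. = FALSE)
  }
  structure(list(property_ranges = pr, alert_patterns = ap,
                 provenance = if (is.null(y$provenance)) "" else y$provenance),
            class = "FilterRuleSet")
}

#' @param property_ranges data.frame (descriptor, min, max).
#' @param alert_patterns data.frame (name, smarts).
#' @param provenance free-text provenance note.
#' @rdname loadFilterRules
#' @export
filterRuleSet <- function(property_ranges = NULL, alert_patterns = NULL,
                          provenance = "ad hoc") {
  if (is.null(property_ranges))
    property_ranges <- data.frame(descriptor = character(0),
                                  min = numeric(0), max = numeric(0))
  if (is.null(alert_patterns))
    alert_patterns <- data.frame(name = character(0), smarts = character(0))
  if (any(property_ranges$min > property_ranges$max))
    stop("filter rules: property range with min > max", call. = FALSE)
  for (k in seq_len(nrow(alert_patterns))) {
    if (!.ob_smarts_valid(alert_patterns$smarts[k]))
      stop("filter rules: SMARTS pattern '", alert_patterns$name[k],
           "' does not parse: ", alert_patterns$smarts[k], call. = FALSE)
  }
  structure(list(property_ranges = property_ranges,
                 alert_patterns = alert_patterns, provenance = provenance),
            class = "FilterRuleSet")
}

#' @rdname loadFilterRules
#' @export
defaultFilterRules <- function() {
  loadFilterRules(system.file("extdata", "default_rules.yaml",
                              package = "atomscreen", mustWork = TRUE))
}

#' Apply descriptor range filters
#'
#' A molecule is retained iff every property range in the rule set is
#' satisfied. The rejection log records each rejected molecule together
#' with the first failed rule, so retained + rejections partition the
#' input; input order is preserved.
#'
#' @param mols a [MoleculeSet-class] (descriptors already computed).
#' @param rules a `FilterRuleSet` (see [loadFilterRules()]).
#' @return list with `retained` (a [MoleculeSet-class]) and `rejected`
#'   (data.frame id/rule/value).
#' @export
applyPropertyFilters <- function(mols, rules) {
  stopifnot(is(mols, "MoleculeSet"), inherits(rules, "FilterRuleSet"))
  desc <- mols@descriptors
  pr <- rules$property_ranges
  unknown <- setdiff(pr$descriptor, names(desc))
  if (length(unknown))
    stop("unknown descriptor in filter rules: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(mols@ids)
  fail_rule <- rep(NA_character_, n)
  fail_val <- rep(NA_real_, n)
  for (k in seq_len(nrow(pr))) {
    v <- desc[[pr$descriptor[k]]]
    bad <- (v < pr$min[k] | v > pr$max[k]) & is.na(fail_rule)
    lab <- sprintf("%s in [%g, %g]", pr$descriptor[k], pr$min[k], pr$max[k])
    fail_rule[bad] <- lab
    fail_val[bad] <- v[bad]
  }
  keep <- is.na(fail_rule)
  list(retained = mols[keep],
       rejected = data.frame(id = mols@ids[!keep], rule = fail_rule[!keep],
                             value = fail_val[!keep]))
}

#' Apply structural-alert (SMARTS) filters
#'
#' A molecule is rejected iff any alert pattern matches it as a
#' substructure; the log records the first matching pattern name. Patterns
#' were validated when the rule set was loaded.
#'
#' @inheritParams applyPropertyFilters
#' @return list with `retained` ([MoleculeSet-class]) and `rejected`
#'   (data.frame id/rule).
#' @export
applyStructuralAlerts <- function(mols, rules) {
  stopifnot(is(mols, "MoleculeSet"), inherits(rules, "FilterRuleSet"))
  ap <- rules$alert_patterns
  n <- length(mols@ids)
  fail <- rep(NA_character_, n)
  for (k in seq_len(nrow(ap))) {
    todo <- which(is.na(fail))
    if (!length(todo)) break
    hit <- .ob_smarts_match(mols@smiles[todo], ap$smarts[k])
    fail[todo[hit]] <- ap$name[k]
  }
  keep <- is.na(fail)
  list(retained = mols[keep],
       rejected = data.frame(id = mols@ids[!keep], rule = fail[!keep]))
}

#' Flag aggregator-like molecules by similarity
#'
#' Optional second mechanism for aggregator/autofluorescer removal: flags
#' library molecules whose fingerprint similarity to a reference list of
#' known aggregators reaches `simCutoff`.
#'
#' @param mols a [MoleculeSet-class].
#' @param reference a [MoleculeSet-class] of known aggregators; defaults to
#'   the small packaged reference list.
#' @param simCutoff Tanimoto similarity at or above which a molecule is
#'   flagged (default 0.85).
#' @return logical vector parallel to the molecules of `mols`.
#' @export
flagAggregatorLike <- function(mols, reference = NULL, simCutoff = 0.85) {
  stopifnot(is(mols, "MoleculeSet"))
  if (is.null(reference)) {
    path <- system.file("extdata", "aggregator_reference.smi",
                        package = "atomscreen", mustWork = TRUE)
    reference <- readSmilesFile(path, cfg = mols@fpConfig)
  }
  if (length(mols) == 0L || length(reference) == 0L)
    return(rep(FALSE, length(mols)))
  sim <- tanimotoMatrix(mols@fingerprints, reference@fingerprints)
  apply(sim, 1, max) >= simCutoff
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, gap -1
#' (terminal gaps penalized), then identity = matches / alignment length
#' x 100. This pairwise-global definition is the package convention for
#' the "homolog within 70 percent identity" rule.
#'
#' @param a,b amino-acid sequences (single strings over the 20-letter
#'   alphabet plus X).
#' @return percent identity in `[0, 100]`.
#' @examples
#' sequenceIdentity("AAAA", "AAAT")  # 75
#' @export
sequenceIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b))
    stop("sequence identity requires non-empty sequences", call. = FALSE)
  alpha <- c(Biostrings::AA_STANDARD, "X")
  submat <- matrix(0, length(alpha), length(alpha),
                   dimnames = list(alpha, alpha))
  diag(submat) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat, type = "global",
    gapOpening = 0, gapExtension = 1)
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  matches <- sum(s1 == s2 & s1 != "-")
  100 * matches / length(s1)
}

#' Target records and binder databases
#'
#' A target record bundles a protein target's identifier, amino-acid
#' sequence, class labels (e.g. `"kinase"`, `"GPCR"`) and its known
#' binders (with activity annotations). A binder database is simply a list
#' of target records.
#'
#' @param targetId identifier.
#' @param sequence amino-acid sequence (20-letter alphabet plus X).
#' @param classLabels character vector of class labels.
#' @param binders a [MoleculeSet-class] of known binders (may be empty).
#' @param activities numeric activity annotations parallel to `binders`
#'   (positive concentrations or 0/1 flags).
#' @return a `TargetRecord` object.
#' @export
targetRecord <- function(targetId, sequence, classLabels = character(0),
                         binders = NULL, activities = numeric(0)) {
  if (is.null(binders)) binders <- .empty_molecule_set()
  new("TargetRecord", targetId = as.character(targetId),
      sequence = toupper(as.character(sequence)),
      classLabels = as.character(classLabels), binders = binders,
      activities = as.numeric(activities))
}

#' @rdname targetRecord
#' @export
setClass("TargetRecord",
         representation(targetId = "character", sequence = "character",
                        classLabels = "character", binders = "MoleculeSet",
                        activities = "numeric"))

setValidity("TargetRecord", function(object) {
  msg <- character(0)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", object@sequence))
    msg <- c(msg, "sequence must use the 20-letter amino-acid alphabet plus X")
  if (length(object@activities) &&
      length(object@activities) != length(object@binders))
    msg <- c(msg, "activities must be parallel to binders")
  if (length(object@activities) && any(object@activities < 0))
    msg <- c(msg, "activities must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TargetRecord", function(object) {
  cat("TargetRecord", object@targetId, "(", nchar(object@sequence),
      "aa,", length(object@binders), "binders")
  if (length(object@classLabels))
    cat(";", paste(object@classLabels, collapse = ","))
  cat(")\n")
})

.empty_molecule_set <- function(cfg = fingerprintConfig()) {
  new("MoleculeSet", ids = character(0), smiles = character(0),
      fingerprints = matrix(FALSE, 0, cfg@fpBits),
      descriptors = data.frame(mw = numeric(0), clogp = numeric(0),
                               hbd = integer(0), hba = integer(0),
                               rotatable_bonds = integer(0),
                               tpsa = numeric(0)),
      fpConfig = cfg)
}

#' Chemotype-novelty exclusion policy
#'
#' @param simThreshold Tanimoto similarity above which (strictly) a library
#'   molecule is excluded as a known chemotype. Default 0.5.
#' @param homologIdentity percent sequence identity at or above which a
#'   database target counts as a homolog of the screening target.
#'   Default 70.
#' @param kinaseMode when the target carries the `"kinase"` class label,
#'   extend the reference set to the binders of every kinase-labelled
#'   target in the database (whole-kinome exclusion).
#' @return an `ExclusionPolicy` list.
#' @export
exclusionPolicy <- function(simThreshold = 0.5, homologIdentity = 70,
                            kinaseMode = FALSE) {
  stopifnot(simThreshold > 0, simThreshold <= 1,
            homologIdentity > 0, homologIdentity <= 100)
  structure(list(simThreshold = simThreshold,
                 homologIdentity = homologIdentity,
                 kinaseMode = isTRUE(kinaseMode)),
            class = "ExclusionPolicy")
}

#' Collect the reference fingerprints for novelty exclusion
#'
#' Gathers the known binders of the screening target and of every database
#' target whose sequence identity to it reaches the homolog threshold; in
#' kinase mode, when the target is kinase-labelled, the binders of all
#' kinase-labelled targets are added (whole-kinome exclusion). The result
#' is deduplicated by canonical structure.
#'
#' @param target a [targetRecord()].
#' @param binderDb list of [targetRecord()]s (may include the target).
#' @param policy an [exclusionPolicy()].
#' @return list with `fingerprints` (logical matrix), `smiles` and
#'   `ids` of the deduplicated reference binders.
#' @export
collectExclusionSet <- function(target, binderDb, policy = exclusionPolicy()) {
  stopifnot(is(target, "TargetRecord"), inherits(policy, "ExclusionPolicy"))
  take <- vapply(binderDb, function(t) {
    if (t@targetId == target@targetId) return(TRUE)
    sequenceIdentity(t@sequence, target@sequence) >= policy$homologIdentity
  }, logical(1))
  if (policy$kinaseMode && "kinase" %in% target@classLabels) {
    take <- take | vapply(binderDb, function(t)
      "kinase" %in% t@classLabels, logical(1))
  }
  sel <- c(list(target), binderDb[take])
  smi <- unlist(lapply(sel, function(t) t@binders@smiles))
  ids <- unlist(lapply(sel, function(t) t@binders@ids))
  fps <- do.call(rbind, lapply(sel, function(t) t@binders@fingerprints))
  if (is.null(fps)) fps <- matrix(FALSE, 0, target@binders@fpConfig@fpBits)
  dup <- duplicated(smi)
  list(fingerprints = fps[!dup, , drop = FALSE],
       smiles = smi[!dup], ids = ids[!dup])
}

#' Exclude known chemotypes from a library
#'
#' Removes every library molecule whose maximum Tanimoto similarity to the
#' reference fingerprints is strictly greater than the policy threshold
#' (a molecule at exactly the threshold is retained). The exclusion log
#' records the nearest reference and its similarity for each removed
#' molecule, and every retained molecule is verifiably at or below the
#' threshold to all references.
#'
#' @param mols a [MoleculeSet-class].
#' @param referenceFps logical fingerprint matrix (e.g. from
#'   [collectExclusionSet()]); row names, if present, name the references.
#' @param policy an [exclusionPolicy()].
#' @return list with `retained` ([MoleculeSet-class]) and `excluded`
#'   (data.frame id/nearest/similarity).
#' @export
excludeKnownChemotypes <- function(mols, referenceFps,
                                   policy = exclusionPolicy()) {
  stopifnot(is(mols, "MoleculeSet"), inherits(policy, "ExclusionPolicy"))
  n <- length(mols)
  if (n == 0L || nrow(referenceFps) == 0L) {
    return(list(retained = mols,
                excluded = data.frame(id = character(0),
                                      nearest = character(0),
                                      similarity = numeric(0))))
  }
  sim <- tanimotoMatrix(mols@fingerprints, referenceFps)
  best <- max.col(sim, ties.method = "first")
  best_sim <- sim[cbind(seq_len(n), best)]
  refnames <- rownames(referenceFps)
  if (is.null(refnames)) refnames <- sprintf("ref%04d", seq_len(nrow(referenceFps)))
  drop <- best_sim > policy$simThreshold
  list(retained = mols[!drop],
       excluded = data.frame(id = mols@ids[drop],
                             nearest = refnames[best[drop]],
                             similarity = best_sim[drop]))
}

#' Load a binder database from CSV + FASTA
#'
#' The CSV needs columns `target_id`, `sequence_file` (FASTA, resolved
#' relative to the CSV), `smiles`, `activity`, and optionally
#' `class_labels` (semicolon-separated). One row per known binder; targets
#' without binders may appear with empty `smiles`.
#'
#' @param path CSV file.
#' @param cfg fingerprint configuration for the binder molecules.
#' @return list of [targetRecord()]s.
#' @export
loadBinderDb <- function(path, cfg = fingerprintConfig()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  out <- list()
  for (tid in unique(df$target_id)) {
    rows <- df[df$target_id == tid, , drop = FALSE]
    seqfile <- rows$sequence_file[1]
    if (!file.exists(seqfile)) seqfile <- file.path(base, seqfile)
    seq <- as.character(Biostrings::readAAStringSet(seqfile))[1]
    labels <- character(0)
    if ("class_labels" %in% names(rows) && nzchar(rows$class_labels[1]))
      labels <- strsplit(rows$class_labels[1], ";")[[1]]
    smi <- rows$smiles[nzchar(rows$smiles)]
    act <- rows$activity[nzchar(rows$smiles)]
    binders <- if (length(smi))
      moleculeSet(smi, ids = paste0(tid, "_b", seq_along(smi)), cfg = cfg)
    else .empty_molecule_set(cfg)
    out[[tid]] <- targetRecord(tid, seq, classLabels = labels,
                               binders = binders,
                               activities = as.numeric(act))
  }
  out
}

#' Prepare a screening library
#'
#' The full library-preparation stage: descriptor-range filtering,
#' structural-alert removal, optional aggregator-similarity removal, then
#' chemotype-novelty exclusion against the known binders of the target and
#' its homologs. Returns the retained library plus a complete audit trail.
#'
#' @param mols a [MoleculeSet-class] (the raw catalog).
#' @param rules a `FilterRuleSet`; default [defaultFilterRules()].
#' @param target,binderDb,policy see [collectExclusionSet()]; when `target`
#'   is `NULL` the exclusion stage is skipped.
#' @param aggregatorPass also remove molecules similar (>= 0.85) to the
#'   packaged aggregator reference list.
#' @return list with `retained` ([MoleculeSet-class]) and `audit`, a
#'   data.frame (id, stage, reason) covering every input molecule.
#' @export
prepareLibrary <- function(mols, rules = defaultFilterRules(), target = NULL,
                           binderDb = list(), policy = exclusionPolicy(),
                           aggregatorPass = FALSE) {
  audit <- data.frame(id = character(0), stage = character(0),
                      reason = character(0))
  p1 <- applyPropertyFilters(mols, rules)
  if (nrow(p1$rejected))
    audit <- rbind(audit, data.frame(id = p1$rejected$id, stage = "property",
                                     reason = p1$rejected$rule))
  p2 <- applyStructuralAlerts(p1$retained, rules)
  if (nrow(p2$rejected))
    audit <- rbind(audit, data.frame(id = p2$rejected$id, stage = "alert",
                                     reason = p2$rejected$rule))
  cur <- p2$retained
  if (aggregatorPass) {
    flag <- flagAggregatorLike(cur)
    if (any(flag))
      audit <- rbind(audit, data.frame(id = cur@ids[flag],
                                       stage = "aggregator",
                                       reason = "similar to known aggregator"))
    cur <- cur[!flag]
  }
  if (!is.null(target)) {
    ref <- collectExclusionSet(target, binderDb, policy)
    rownames(ref$fingerprints) <- ref$ids
    ex <- excludeKnownChemotypes(cur, ref$fingerprints, policy)
    if (nrow(ex$excluded))
      audit <- rbind(audit, data.frame(id = ex$excluded$id, stage = "novelty",
                                       reason = sprintf("sim %.3f to %s",
                                                        ex$excluded$similarity,
                                                        ex$excluded$nearest)))
    cur <- ex$retained
  }
  retained_rows <- data.frame(id = cur@ids, stage = "retained",
                              reason = "")
  list(retained = cur, audit = rbind(audit, retained_rows))
}
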