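## Thin batch interface to the Open Babel command line (`obabel`), used for
## SMILES canonicalization, circular fingerprints and SMARTS screening.
## Batching through one process per call is orders of magnitude faster than
## per-molecule calls and keeps results identical to the ChemmineOB bindings
## (verified in the test suite).

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("the 'obabel' executable is required but was not found on PATH",
         call. = FALSE)
  }
  p
}

## run obabel on a temporary .smi input; returns stdout lines
.obabel_run <- function(smiles, ids, args) {
  stopifnot(length(smiles) == length(ids))
  if (any(grepl("[[:space:]]", ids))) {
    stop("molecule ids must not contain whitespace", call. = FALSE)
  }
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, ids), infile)
  out <- suppressWarnings(
    system2(.obabel_path(), c(infile, args, "-e"),
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel exited with status ", status, call. = FALSE)
  }
  out
}

## Canonical SMILES for a vector of input SMILES. Unparsable entries yield
## NA unless strict = TRUE, in which case the offending input is named.
.ob_canonical <- function(smiles, strict = TRUE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  ids <- sprintf("m%07d", seq_len(n))
  out <- .obabel_run(smiles, ids, c("-ocan"))
  out <- out[nzchar(out)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  got_id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                   character(1))
  got_smi <- vapply(parts, `[[`, character(1), 1)
  res <- rep(NA_character_, n)
  res[match(got_id, ids)] <- got_smi
  if (strict && anyNA(res)) {
    bad <- smiles[which(is.na(res))[1]]
    stop("SMILES parse error: could not parse '", bad, "'", call. = FALSE)
  }
  res
}

## Salt stripping (largest covalent fragment) + neutralization.
.ob_standardize <- function(smiles, strict = TRUE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  ids <- sprintf("m%07d", seq_len(n))
  out <- .obabel_run(smiles, ids, c("-ocan", "-r", "--neutralize"))
  out <- out[nzchar(out)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  got_id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                   character(1))
  got_smi <- vapply(parts, `[[`, character(1), 1)
  res <- rep(NA_character_, n)
  res[match(got_id, ids)] <- got_smi
  if (strict && anyNA(res)) {
    bad <- smiles[which(is.na(res))[1]]
    stop("SMILES parse error: could not parse '", bad, "'", call. = FALSE)
  }
  res
}

## 256 x 8 lookup: bits set in each byte value, LSB-first (FPS convention).
.byte_bits <- local({
  m <- matrix(0L, nrow = 256, ncol = 8)
  for (b in 0:255) m[b + 1L, ] <- as.integer(bitwAnd(b, bitwShiftL(1L, 0:7)) > 0L)
  m
})

## Parse FPS hex lines into a logical matrix (n x nbits_raw).
.fps_to_matrix <- function(hex, nbits) {
  n <- length(hex)
  nbytes <- nbits / 8L
  out <- matrix(FALSE, nrow = n, ncol = nbits)
  for (i in seq_len(n)) {
    h <- hex[i]
    bytes <- strtoi(substring(h, seq(1L, nchar(h), 2L), seq(2L, nchar(h), 2L)),
                    16L)
    bits <- .byte_bits[bytes + 1L, , drop = FALSE]
    out[i, ] <- as.logical(t(bits))[seq_len(nbits)]
  }
  out
}

## Batch ECFP-style circular fingerprints via obabel's FPS output,
## folded from the raw 4096 bits down to fp_bits by modular OR.
.ob_fingerprints <- function(smiles, radius = 2L, fp_bits = 1024L) {
  n <- length(smiles)
  fpname <- paste0("ECFP", 2L * radius)
  if (n == 0L) {
    return(matrix(FALSE, nrow = 0, ncol = fp_bits))
  }
  ids <- sprintf("m%07d", seq_len(n))
  out <- .obabel_run(smiles, ids, c("-ofps", paste0("-xf", fpname)))
  out <- out[nzchar(out) & !startsWith(out, "#")]
  parts <- strsplit(out, "\t", fixed = TRUE)
  got_id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                   character(1))
  hex <- vapply(parts, `[[`, character(1), 1)
  keep <- match(ids, got_id)
  if (anyNA(keep)) {
    bad <- smiles[which(is.na(keep))[1]]
    stop("fingerprint failure: could not parse '", bad, "'", call. = FALSE)
  }
  raw_bits <- 4L * nchar(hex[keep[1]])
  raw <- .fps_to_matrix(hex[keep], raw_bits)
  if (fp_bits >= raw_bits) {
    if (fp_bits > raw_bits) {
      raw <- cbind(raw, matrix(FALSE, nrow(raw), fp_bits - raw_bits))
    }
    return(raw)
  }
  folded <- matrix(FALSE, nrow = n, ncol = fp_bits)
  for (blk in seq_len(raw_bits / fp_bits)) {
    cols <- ((blk - 1L) * fp_bits + 1L):(blk * fp_bits)
    folded <- folded | raw[, cols, drop = FALSE]
  }
  folded
}

## Which molecules match a SMARTS pattern (substructure screen).
.ob_smarts_match <- function(smiles, smarts) {
  n <- length(smiles)
  if (n == 0L) return(logical(0))
  ids <- sprintf("m%07d", seq_len(n))
  out <- .obabel_run(smiles, ids, c("-osmi", "-s", shQuote(smarts)))
  out <- out[nzchar(out)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  got_id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                   character(1))
  ids %in% got_id
}

## SMILES -> SDF text with generated 2D coordinates (one call per batch).
.ob_smiles_to_sdf <- function(smiles, ids) {
  out <- .obabel_run(smiles, ids, c("-osdf", "--gen2D"))
  paste(out, collapse = "\n")
}

## Validate a SMARTS pattern (compilation check at rules-load time).
.ob_smarts_valid <- function(smarts) {
  ok <- try(suppressWarnings(
    ChemmineOB::forEachMol("SMILES", "C probe\n", function(m)
      ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE))
  ), silent = TRUE)
  !inherits(ok, "try-error")
}
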