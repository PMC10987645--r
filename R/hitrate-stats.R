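## Campaign analytics: per-project hit rates, portfolio summaries,
## hit-rate-vs-training-data regression, scaffold-novelty distributions.

## round half up at the printed precision (R's round() is half-even)
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hit rate of a screen
#'
#' The percentage of tested molecules that were active:
#' `100 * n_hits / n_tested`.
#'
#' @param nHits,nTested counts with `0 <= nHits <= nTested`,
#'   `nTested > 0`.
#' @return percent in `[0, 100]`.
#' @examples
#' hitRate(40, 376)  # 10.638...
#' @export
hitRate <- function(nHits, nTested) {
  if (any(nTested <= 0))
    stop("hit rate undefined for nTested = 0", call. = FALSE)
  if (any(nHits < 0 | nHits > nTested))
    stop("need 0 <= nHits <= nTested", call. = FALSE)
  100 * nHits / nTested
}

#' Success ratio of a project portfolio
#'
#' Percent of projects that succeeded (identified at least one hit),
#' rounded half-up to a whole percent - the convention used for printed
#' portfolio success and hit-finding rates.
#'
#' @param nSuccess,nProjects counts.
#' @return whole percent.
#' @examples
#' successRatio(215, 296)  # 73
#' @export
successRatio <- function(nSuccess, nProjects) {
  .round_half_up(100 * nSuccess / nProjects)
}

#' Load screening-project records
#'
#' Reads a CSV of per-project screening results. Expected columns:
#' `project`, `n_tested`, `sd_hit_rate`, `dr_hit_rate` (optional),
#' `n_analogs`, `analog_sd_rate`, `analog_dr_rate` (optional), plus any
#' optional strata such as `structure_source` or `target_class`. Rates are
#' percentages in `[0, 100]`.
#'
#' @param path CSV file.
#' @return data.frame of project records.
#' @export
readProjectRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("project", "n_tested", "sd_hit_rate") %in% names(df)))
  rates <- intersect(c("sd_hit_rate", "dr_hit_rate", "analog_sd_rate",
                       "analog_dr_rate"), names(df))
  for (r in rates) {
    v <- df[[r]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("rate column ", r, " outside [0, 100]", call. = FALSE)
  }
  if (any(df$n_tested < 0)) stop("counts must be non-negative", call. = FALSE)
  df
}

#' The packaged internal screening-campaign table
#'
#' Per-project results of 22 internal structure-based screening programs
#' (compounds tested, single-dose and dose-response hit rates, analog
#' round sizes and rates), shipped as a plain-text fixture and used by the
#' portfolio-summary examples and tests.
#'
#' @return data.frame of 22 project records.
#' @export
internalPrograms <- function() {
  readProjectRecords(system.file("extdata", "table1_internal_programs.csv",
                                 package = "atomscreen", mustWork = TRUE))
}

#' Summarize a screening portfolio
#'
#' Unweighted arithmetic means over non-missing values per rate column
#' (reported half-up at one decimal), the portfolio success rate (percent
#' of projects with a nonzero single-dose hit rate) and the reconfirmation
#' rate (percent of dose-response-screened projects with a nonzero DR hit
#' rate), both as whole percents. Optionally stratified by a grouping
#' column, and optionally weighted by `n_tested`.
#'
#' @param records data.frame from [readProjectRecords()] /
#'   [internalPrograms()].
#' @param by optional column name for stratified means.
#' @param weightByTested weight rate means by `n_tested` instead of the
#'   default unweighted means.
#' @return a `PortfolioSummary` list; `print()` shows the headline rates.
#' @export
summarizePortfolio <- function(records, by = NULL, weightByTested = FALSE) {
  stopifnot(nrow(records) >= 1)
  wmean <- function(v, w) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    if (weightByTested) sum(v[ok] * w[ok]) / sum(w[ok]) else mean(v[ok])
  }
  col <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA_real_, nrow(records))
  raw <- list(
    n_projects = nrow(records),
    mean_tested = wmean(col("n_tested"), col("n_tested")),
    mean_sd_hit_rate = wmean(col("sd_hit_rate"), col("n_tested")),
    mean_dr_hit_rate = wmean(col("dr_hit_rate"), col("n_tested")),
    mean_analog_sd_rate = wmean(col("analog_sd_rate"), col("n_analogs")),
    mean_analog_dr_rate = wmean(col("analog_dr_rate"), col("n_analogs")),
    n_analog_projects = sum(!is.na(col("analog_sd_rate"))))
  sd_rate <- col("sd_hit_rate")
  raw$success_rate <- .round_half_up(100 * mean(sd_rate > 0, na.rm = TRUE))
  dr <- col("dr_hit_rate")
  raw$reconfirmation_rate <- if (all(is.na(dr))) NA_real_ else
    reconfirmationRate(records)
  rounded <- raw
  for (nm in c("mean_sd_hit_rate", "mean_dr_hit_rate",
               "mean_analog_sd_rate", "mean_analog_dr_rate",
               "mean_tested"))
    rounded[[nm]] <- .round_half_up(raw[[nm]], 1)
  out <- list(summary = rounded, unrounded = raw)
  if (!is.null(by)) {
    stopifnot(by %in% names(records))
    out$strata <- lapply(split(records, records[[by]]), function(s)
      summarizePortfolio(s, weightByTested = weightByTested)$summary)
  }
  structure(out, class = "PortfolioSummary")
}

#' @export
print.PortfolioSummary <- function(x, ...) {
  s <- x$summary
  cat("Portfolio of", s$n_projects, "projects",
      sprintf("(mean %.1f compounds tested)\n", s$mean_tested))
  cat(sprintf("  mean SD hit rate: %.1f%%   mean DR hit rate: %.1f%%\n",
              s$mean_sd_hit_rate, s$mean_dr_hit_rate))
  if (!is.na(s$reconfirmation_rate))
    cat(sprintf("  reconfirmation rate: %d%%\n",
                as.integer(s$reconfirmation_rate)))
  if (!is.na(s$mean_analog_sd_rate))
    cat(sprintf("  analog rounds (%d projects): SD %.1f%%, DR %.1f%%\n",
                s$n_analog_projects, s$mean_analog_sd_rate,
                s$mean_analog_dr_rate))
  invisible(x)
}

#' Reconfirmation rate
#'
#' Percent of projects whose single-dose hits reconfirmed in dose-response
#' (`dr_hit_rate > 0`), rounded half-up to a whole percent. Records with a
#' missing DR rate are excluded.
#'
#' @param records data.frame with a `dr_hit_rate` column.
#' @return whole percent.
#' @export
reconfirmationRate <- function(records) {
  dr <- records$dr_hit_rate
  dr <- dr[!is.na(dr)]
  if (!length(dr)) stop("no dose-response rates present", call. = FALSE)
  .round_half_up(100 * sum(dr > 0) / length(dr))
}

#' Hit rate versus training-data regression
#'
#' Ordinary least squares of project hit rate on the number of training
#' actives available for the project's target (closed form), with the
#' coefficient of determination and the two-sided t-test p-value on the
#' slope. Used to ask whether screening performance depends on the
#' availability of on-target training data.
#'
#' @param x number of training actives per project.
#' @param y hit rate per project (percent).
#' @return list (slope, intercept, r_squared, p_value, n).
#' @export
hitrateVsTrainingRegression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in x; slope undefined", call. = FALSE)
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - ym)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  if (ss_res == 0) {
    p <- 0
  } else {
    se <- sqrt(ss_res / (n - 2) / sxx)
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p,
       n = n)
}

#' Scaffold-novelty distribution
#'
#' For each hit, the maximum Tanimoto similarity to any training-set
#' active (0 when the training set is empty: hits for targets without any
#' annotated bioactivity have novelty value zero by convention).
#'
#' @param hitFps logical fingerprint matrix of the hits.
#' @param trainingFps logical fingerprint matrix of the training actives
#'   (possibly 0 rows).
#' @param breaks histogram breaks (default width 0.05 on `[0, 1]`).
#' @return list with `values` (per-hit max similarity) and `histogram`
#'   (data.frame mid/count).
#' @export
noveltyDistribution <- function(hitFps, trainingFps,
                                breaks = seq(0, 1, by = 0.05)) {
  n <- nrow(hitFps)
  if (is.null(trainingFps) || nrow(trainingFps) == 0L) {
    values <- rep(0, n)
  } else {
    sim <- tanimotoMatrix(hitFps, trainingFps)
    values <- apply(sim, 1, max)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(values = values,
       histogram = data.frame(mid = h$mids, count = h$counts))
}
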