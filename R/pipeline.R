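# Orchestration: run the full statistical battery on a detection table and
# serialise the report.

#' Run the statistical battery on a detection table
#'
#' For every analysis label present in the detection table: the
#' carboxyl-terminal bias table against the supplied genome composition,
#' the two-cell K/R enrichment chi-square, and (when `next_nterm` is
#' present) the next-peptide N-terminal bias control. The per-analysis K/R
#' p-values are Fisher-combined. When per-transformation coverage is
#' supplied, the one-tailed peptide/RNA correlation suite and the one-cell
#' mapping-enrichment test are added.
#'
#' @param detections data.frame of detection records (columns sequence,
#'   analysis, cterm; optional next_nterm, transform_id, maps_on_rna,
#'   xcorr, q).
#' @param compositions named list, one entry per analysis: a
#'   [residueComposition()] result (or named count vector) for the
#'   hypothetical translations of the corresponding transformed genome.
#' @param coverage optional named list per analysis of named
#'   coverage-fraction vectors per transformation.
#' @param filter apply [filterDetections()] first (default TRUE).
#' @return List with elements `bias`, `kr_tests`, `kr_combined`,
#'   `tryptic_fraction`, and optionally `nterm_bias`, `correlations`,
#'   `mapping`.
#' @export
statsReport <- function(detections, compositions, coverage = NULL,
                        filter = TRUE) {
  require_columns(detections, c("sequence", "analysis", "cterm"),
                  "detection table")
  if (filter) detections <- filterDetections(detections)
  if (!is.null(coverage))
    require_columns(detections, "transform_id", "detection table")
  analyses <- unique(detections$analysis)
  missing <- setdiff(analyses, names(compositions))
  if (length(missing))
    stop("no composition for analysis: ", paste(missing, collapse = ", "))
  bias <- list()
  nterm_bias <- list()
  kr_tests <- list()
  count_rows <- list()
  for (an in analyses) {
    d <- detections[detections$analysis == an, , drop = FALSE]
    comp <- compositions[[an]]
    if (!is.list(comp)) comp <- list(counts = comp, total = sum(comp))
    cnt <- countTerminal(d, "cterm")
    bias[[an]] <- terminalBias(cnt, comp)
    kr_tests[[an]] <- trypticEnrichmentTest(
      sum(cnt[c("K", "R")]), sum(cnt),
      sum(comp$counts[c("K", "R")]), comp$total)
    count_rows[[an]] <- data.frame(analysis = an, residue = names(cnt),
                                   detected = as.integer(cnt),
                                   stringsAsFactors = FALSE)
    if ("next_nterm" %in% names(d) && any(!is.na(d$next_nterm)))
      nterm_bias[[an]] <- terminalBias(countTerminal(d, "next_nterm"), comp)
  }
  out <- list(
    bias = bias,
    kr_tests = kr_tests,
    kr_combined = fisherCombine(vapply(kr_tests, function(h) h$p.value, 0)),
    tryptic_fraction =
      trypticFractionSingleAlternative(do.call(rbind, count_rows)))
  if (length(nterm_bias)) out$nterm_bias <- nterm_bias
  if (!is.null(coverage)) {
    counts <- lapply(analyses, function(an) {
      d <- detections[detections$analysis == an, , drop = FALSE]
      rules <- names(coverage[[an]])
      cnt <- table(factor(d$transform_id, levels = rules))
      stats::setNames(as.numeric(cnt), rules)
    })
    names(counts) <- analyses
    out$correlations <- correlationSuite(counts, coverage[analyses])
    if ("maps_on_rna" %in% names(detections)) {
      observed <- sum(detections$maps_on_rna, na.rm = TRUE)
      expected <- sum(vapply(analyses, function(an) {
        d <- detections[detections$analysis == an, , drop = FALSE]
        expectedMapping(d$transform_id, coverage[[an]])
      }, 0))
      out$mapping <- list(observed = observed, expected = expected,
                          test = mappingEnrichment(observed, expected))
    }
  }
  out
}

htest_json <- function(h) {
  list(method = h$method, statistic = unname(h$statistic),
       df = unname(h$parameter), p = h$p.value)
}

#' Serialise a stats report to JSON
#'
#' @param report list from [statsReport()].
#' @param path output JSON file.
#' @export
writeStatsReport <- function(report, path) {
  to_json <- list(
    bias = lapply(report$bias, function(b) b),
    kr_tests = lapply(report$kr_tests, htest_json),
    kr_combined = htest_json(report$kr_combined),
    tryptic_fraction = report$tryptic_fraction$fraction)
  if (!is.null(report$nterm_bias))
    to_json$nterm_bias <- report$nterm_bias
  if (!is.null(report$correlations))
    to_json$correlations <- list(
      table = report$correlations$table,
      combined = htest_json(report$correlations$combined))
  if (!is.null(report$mapping))
    to_json$mapping <- list(observed = report$mapping$observed,
                            expected = report$mapping$expected,
                            test = htest_json(report$mapping$test))
  jsonlite::write_json(to_json, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
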