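# Statistical battery applied to detected-peptide populations.
#
# Two chi-square conventions coexist, each frozen to its pipeline stage:
# the carboxyl-terminal K/R enrichment test uses the two-cell
# goodness-of-fit statistic with df = 1, while the peptide-on-RNA mapping
# enrichment uses the one-cell (O - E)^2 / E statistic with df = 1. Both
# are exported; neither substitutes for the other.

as_htest <- function(statistic, df, p, method, alternative = "greater",
                     estimate = NULL) {
  out <- list(statistic = c(statistic = statistic),
              parameter = c(df = df), p.value = p, method = method,
              alternative = alternative, data.name = "")
  if (!is.null(estimate)) out$estimate <- estimate
  structure(out, class = "htest")
}

#' Terminal-residue bias table
#'
#' For each of the 19 merged residue categories, the frequency of the
#' residue at the inspected terminal position of detected peptides divided
#' by the residue's frequency in the hypothetical translations of the
#' corresponding transformed genome. Residues with zero detections get
#' bias 0. The weighted mean of the biases with genome-frequency weights is
#' exactly 1 whenever the detected total equals the sum of the counts.
#'
#' @param detected named integer vector of detection counts per residue
#'   category (I/L merged), e.g. from [countTerminal()].
#' @param composition list with `counts` and `total` as returned by
#'   [residueComposition()], or a named count vector.
#' @param detectedTotal denominator for detected frequencies; defaults to
#'   `sum(detected)`. An explicit value supports published tables whose
#'   printed totals differ from their column sums.
#' @return data.frame with columns residue, detected, detected_total,
#'   genome, genome_total, bias.
#' @export
terminalBias <- function(detected, composition,
                         detectedTotal = sum(detected)) {
  if (is.list(composition)) {
    gcounts <- composition$counts
    gtotal <- composition$total
  } else {
    gcounts <- composition
    gtotal <- sum(composition)
  }
  stopifnot(gtotal > 0, detectedTotal > 0)
  missing <- setdiff(names(detected), names(gcounts))
  if (length(missing))
    stop("residue(s) absent from composition: ",
         paste(missing, collapse = ", "))
  residues <- names(gcounts)
  det <- stats::setNames(rep(0L, length(residues)), residues)
  det[names(detected)] <- detected
  bias <- ifelse(det == 0, 0,
                 (det / detectedTotal) / (gcounts / gtotal))
  data.frame(residue = residues, detected = as.integer(det),
             detected_total = detectedTotal,
             genome = as.integer(gcounts), genome_total = gtotal,
             bias = as.numeric(bias), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Count terminal residues of a detection table
#'
#' @param detections data.frame with at least the column named by `column`
#'   (single residues; I and L are merged).
#' @param column `"cterm"` (carboxyl terminus) or `"next_nterm"` (first
#'   residue of the next predicted peptide, the negative control).
#' @return Named integer vector over the 19 residue categories.
#' @export
countTerminal <- function(detections, column = c("cterm", "next_nterm")) {
  column <- match.arg(column)
  if (!column %in% names(detections))
    stop("detections table has no column '", column, "'")
  r <- mergeIL(stats::na.omit(as.character(detections[[column]])))
  counts <- table(factor(r, levels = AA_CATEGORIES))
  stats::setNames(as.integer(counts), AA_CATEGORIES)
}

#' K/R carboxyl-terminal enrichment chi-square
#'
#' Two-cell goodness-of-fit test with df = 1 for the number of tryptic
#' (K/R-ending) peptides among all detections, against the tryptic fraction
#' of the hypothetical translated genome: E = total * trypticGenome /
#' genomeTotal, chi2 = (O-E)^2/E + ((total-O)-(total-E))^2/(total-E),
#' upper-tail p.
#'
#' @param trypticCount observed K/R-ending detections.
#' @param totalCount all detections.
#' @param trypticGenome K+R residue count in the genome translations.
#' @param genomeTotal total residue count in the genome translations.
#' @return An object of class `htest`.
#' @export
trypticEnrichmentTest <- function(trypticCount, totalCount,
                                  trypticGenome, genomeTotal) {
  stopifnot(totalCount > 0, genomeTotal > 0)
  p0 <- trypticGenome / genomeTotal
  E <- totalCount * p0
  if (E <= 0 || E >= totalCount)
    stop("degenerate expected cell (E = ", E, ")")
  stat <- (trypticCount - E)^2 / E +
    ((totalCount - trypticCount) - (totalCount - E))^2 / (totalCount - E)
  as_htest(stat, 1L, stats::pchisq(stat, 1L, lower.tail = FALSE),
           "two-cell chi-square goodness of fit (df = 1)")
}

#' One-cell mapping-enrichment chi-square
#'
#' Statistic (O - E)^2 / E with df = 1 and upper-tail p, for the number of
#' detected peptides mapping on previously detected RNAs against the
#' expectation under random mapping. This one-cell convention (not the
#' two-cell one) is the convention under which the published mapping
#' p-values reproduce.
#'
#' @param observed observed count.
#' @param expected expected count under random mapping (> 0).
#' @return An object of class `htest`.
#' @export
mappingEnrichment <- function(observed, expected) {
  if (expected <= 0) stop("expected count must be positive")
  stat <- (observed - expected)^2 / expected
  as_htest(stat, 1L, stats::pchisq(stat, 1L, lower.tail = FALSE),
           "one-cell chi-square (O-E)^2/E (df = 1)")
}

#' Fisher's method for combining p-values
#'
#' Statistic -2 * sum(log p_i), referred to a chi-square distribution with
#' 2k degrees of freedom.
#'
#' @param ps numeric vector of p-values in (0, 1].
#' @return An object of class `htest`.
#' @export
fisherCombine <- function(ps) {
  ps <- as.numeric(ps)
  if (length(ps) == 0L) stop("no p-values supplied")
  if (any(ps <= 0 | ps > 1)) stop("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(ps))
  df <- 2L * length(ps)
  as_htest(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
           "Fisher combination of p-values")
}

#' One-tailed p-value from a Pearson correlation
#'
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) referred to the upper tail of the t
#' distribution with n - 2 df (one tailed, expecting positive correlation;
#' negative r therefore gives p > 0.5).
#'
#' @param r Pearson correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @return One-tailed p-value.
#' @export
pFromR <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' One-tailed Pearson correlation
#'
#' @param x,y paired numeric vectors (length >= 3, non-constant).
#' @return An `htest` with the correlation as `estimate`, the t statistic,
#'   and the upper-tail (positive-association) p-value.
#' @export
pearsonOneTailed <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  n <- length(x)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  as_htest(t, n - 2L, pFromR(r, n),
           "one-tailed Pearson correlation (t transform)",
           estimate = c(r = r))
}

#' Peptide-count / RNA-coverage correlation suite
#'
#' One-tailed Pearson correlation per analysis between per-transformation
#' peptide counts and per-transformation RNA coverage, followed by a Fisher
#' combination across analyses.
#'
#' @param counts named list (one element per analysis) of named numeric
#'   vectors: peptide count per transformation.
#' @param coverage named list with the same structure: RNA coverage per
#'   transformation; keys must match within each analysis.
#' @return List with `table` (data.frame analysis, n, r, p) and `combined`
#'   (Fisher `htest`).
#' @export
correlationSuite <- function(counts, coverage) {
  if (!setequal(names(counts), names(coverage)))
    stop("analyses differ between counts and coverage")
  res <- lapply(names(counts), function(an) {
    x <- counts[[an]]
    y <- coverage[[an]]
    if (!setequal(names(x), names(y)))
      stop("transformation keys differ for analysis '", an, "'")
    y <- y[names(x)]
    ht <- pearsonOneTailed(as.numeric(x), as.numeric(y))
    data.frame(analysis = an, n = length(x),
               r = unname(ht$estimate), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  list(table = tab, combined = fisherCombine(tab$p))
}

#' Does a peptide map on detected RNA of the same transformation?
#'
#' TRUE iff every source interval of the peptide is fully contained in the
#' union of the RNA intervals of the same transformation (containment
#' rule). With `minOverlap < 1`, that fraction of the peptide's positions
#' covered suffices instead.
#'
#' @param peptideIntervals integer matrix (columns start, end; 0-based
#'   half-open source coordinates), e.g. from [projectToSource()].
#' @param rnaIntervals matrix of the same shape for the detected RNAs.
#' @param minOverlap fraction of peptide positions that must be covered;
#'   default 1 (full containment).
#' @return TRUE/FALSE.
#' @export
peptideMapsOnRna <- function(peptideIntervals, rnaIntervals, minOverlap = 1) {
  to_ir <- function(m) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2])
  }
  pep <- IRanges::reduce(to_ir(peptideIntervals))
  if (is.null(rnaIntervals) || NROW(rnaIntervals) == 0L) return(FALSE)
  rna <- IRanges::reduce(to_ir(rnaIntervals))
  inter <- IRanges::intersect(pep, rna)
  covered <- sum(IRanges::width(inter))
  covered >= minOverlap * sum(IRanges::width(pep))
}

#' Expected number of peptides mapping on RNA under random mapping
#'
#' Sum over peptides of the RNA coverage fraction of that peptide's
#' transformation.
#'
#' @param peptideTransforms character vector: transformation of each
#'   detected peptide.
#' @param coverageFractions named numeric vector in [0, 1]: coverage
#'   fraction per transformation.
#' @return Expected count.
#' @export
expectedMapping <- function(peptideTransforms, coverageFractions) {
  if (any(coverageFractions < 0 | coverageFractions > 1))
    stop("coverage fractions must lie in [0, 1]")
  missing <- setdiff(unique(peptideTransforms), names(coverageFractions))
  if (length(missing))
    stop("no coverage for transformation(s): ",
         paste(missing, collapse = ", "))
  sum(coverageFractions[peptideTransforms])
}

#' Average tryptic fraction against single alternative termini
#'
#' For each analysis, the fraction T / (T + n_r) of tryptic peptides when
#' only one alternative carboxyl-terminal residue r is considered, averaged
#' over all (analysis x non-tryptic residue) cells; T is the K+R count of
#' the analysis and n_r the count for residue r. Zero-count residues
#' contribute a fraction of 1.
#'
#' @param countTable data.frame with columns `analysis`, `residue` (19
#'   merged categories) and `detected`.
#' @return List with `fraction` (the grand mean), `n_cells`, and
#'   `per_cell` (data.frame of the individual fractions).
#' @export
trypticFractionSingleAlternative <- function(countTable) {
  stopifnot(all(c("analysis", "residue", "detected") %in% names(countTable)))
  cells <- lapply(split(countTable, countTable$analysis), function(d) {
    T <- sum(d$detected[d$residue %in% c("K", "R")])
    if (T == 0) stop("analysis '", d$analysis[1], "' has no tryptic peptides")
    other <- d[!d$residue %in% c("K", "R"), , drop = FALSE]
    data.frame(analysis = d$analysis[1], residue = other$residue,
               fraction = T / (T + other$detected),
               stringsAsFactors = FALSE)
  })
  per_cell <- do.call(rbind, cells)
  rownames(per_cell) <- NULL
  list(fraction = mean(per_cell$fraction), n_cells = nrow(per_cell),
       per_cell = per_cell)
}

#' Bias of amino acids inserted at stop codons
#'
#' Compares the distribution of residues observed at stop positions of
#' detected peptides (summed across analyses) to the residue composition of
#' the canonical mitogenome-encoded proteins. Bias is the ratio of the two
#' frequencies; each residue also gets a one-cell chi-square ((O-E)^2/E,
#' df = 1, upper tail) against the expected count at canonical frequencies.
#'
#' @param stopCounts named integer vector: residues observed at stop
#'   positions, summed over analyses.
#' @param mitoComposition named integer vector: residue counts in canonical
#'   proteins (same categories).
#' @return data.frame residue, observed, expected, mito, bias, statistic,
#'   p, sorted by decreasing bias.
#' @export
stopInsertionBias <- function(stopCounts, mitoComposition) {
  residues <- names(mitoComposition)
  if (any(mitoComposition <= 0)) stop("all canonical residue counts must be > 0")
  obs <- stats::setNames(rep(0L, length(residues)), residues)
  obs[names(stopCounts)] <- stopCounts
  total_obs <- sum(obs)
  total_mito <- sum(mitoComposition)
  stopifnot(total_obs > 0)
  freq_mito <- mitoComposition / total_mito
  expected <- total_obs * freq_mito
  bias <- (obs / total_obs) / freq_mito
  stat <- (obs - expected)^2 / expected
  p <- stats::pchisq(stat, 1L, lower.tail = FALSE)
  out <- data.frame(residue = residues, observed = as.integer(obs),
                    expected = as.numeric(expected),
                    mito = as.integer(mitoComposition),
                    bias = as.numeric(bias),
                    statistic = as.numeric(stat), p = as.numeric(p),
                    stringsAsFactors = FALSE)
  out[order(-out$bias), , drop = FALSE]
}

#' Sequest-style spectrum cross-correlation at a fixed lag
#'
#' Xcorr = sum_{i=0}^{n-1} x_i * y_{i + tau}; indices beyond the range of y
#' contribute zero.
#'
#' @param x,y equal-length numeric vectors (predicted and observed
#'   spectra).
#' @param tau integer displacement (lag), may be negative.
#' @return The lagged dot product.
#' @export
xcorr <- function(x, y, tau = 0L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  j <- seq_len(n) + as.integer(tau)   # y index for each x index
  ok <- j >= 1L & j <= n
  sum(x[ok] * y[j[ok]])
}

#' Filter a detection table by the standard score thresholds
#'
#' Keeps rows with q < `qMax` and Xcorr > `xcorrMin`; each filter is
#' applied only where the score column is present and non-NA (scores are
#' pass-through metadata).
#'
#' @param detections data.frame possibly containing columns `q` and
#'   `xcorr`.
#' @param qMax FDR threshold, default 0.05.
#' @param xcorrMin Xcorr threshold, default 1.99.
#' @return Filtered data.frame.
#' @export
filterDetections <- function(detections, qMax = 0.05, xcorrMin = 1.99) {
  keep <- rep(TRUE, nrow(detections))
  if ("q" %in% names(detections))
    keep <- keep & (is.na(detections$q) | detections$q < qMax)
  if ("xcorr" %in% names(detections))
    keep <- keep & (is.na(detections$xcorr) | detections$xcorr > xcorrMin)
  detections[keep, , drop = FALSE]
}
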