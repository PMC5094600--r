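# Readers and writers for the standard formats the pipeline consumes:
# nucleotide/protein FASTA via Biostrings, TSV detection/coverage/count
# tables, JSON reports.

#' Read a genome from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param circular logical flag stored on the genome.
#' @return A [GenomeSequence-class].
#' @export
readGenomeFasta <- function(path, circular = FALSE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  genomeSequence(as.character(set[[1]]),
                 id = sub("\\s.*$", "", names(set)[1]), circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome a [GenomeSequence-class].
#' @param path output file.
#' @export
writeGenomeFasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome@sequence)
  names(set) <- genome@id
  Biostrings::writeXStringSet(set, path)
}

#' Write transformed sequences to FASTA
#'
#' Records are named `<source>|<rule>|<phase>|<strand>`.
#'
#' @param tsList list of [TransformedSeq-class] objects.
#' @param path output file.
#' @export
writeTransformedFasta <- function(tsList, path) {
  if (is(tsList, "TransformedSeq")) tsList <- list(tsList)
  set <- Biostrings::DNAStringSet(vapply(tsList, transformedResidues, ""))
  names(set) <- vapply(tsList, function(ts)
    paste(ts@sourceId, ts@rule,
          ifelse(is.na(ts@phase), "NA", ts@phase), ts@strand, sep = "|"), "")
  Biostrings::writeXStringSet(set, path)
}

#' Write a peptide database to protein FASTA
#'
#' One record per database entry; the header is the provenance string
#' `<analysis>|<rule>|<size>|<frame>|<strand>|<start>-<end>|<replacement>`.
#' By default the in-memory stop marker 'X' is written as-is; set
#' `stopAsAsterisk = TRUE` to emit '*' for interoperability.
#'
#' @param database data.frame from [buildPeptideDatabase()].
#' @param path output file.
#' @param stopAsAsterisk write stops as '*' instead of 'X'.
#' @export
writePeptideFasta <- function(database, path, stopAsAsterisk = FALSE) {
  seqs <- database$sequence
  if (stopAsAsterisk) seqs <- gsub("X", "*", seqs, fixed = TRUE)
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- sprintf("%s|%s|%d|%d|%s|%d-%d|%s", database$analysis,
                        database$rule, database$size, database$frame,
                        database$strand, database$start, database$end,
                        database$replacement)
  Biostrings::writeXStringSet(set, path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read / write a detection table (TSV)
#'
#' Required columns: sequence, analysis, cterm. Optional: next_nterm,
#' transform_id, maps_on_rna, xcorr, q, pep.
#'
#' @param path TSV file.
#' @return data.frame of detection records.
#' @export
readDetectionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("sequence", "analysis", "cterm"), "detection table")
}

#' @rdname readDetectionTable
#' @param detections data.frame of detection records.
#' @export
writeDetectionTable <- function(detections, path) {
  utils::write.table(detections, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a coverage table (TSV)
#'
#' Either fraction form (columns analysis, transform, fraction) or
#' interval form (columns analysis, transform, start, end), in which case
#' fractions are computed as covered length over `genomeLength`.
#'
#' @param path TSV file.
#' @param genomeLength required for the interval form.
#' @return Named list per analysis of named coverage-fraction vectors.
#' @export
readCoverageTable <- function(path, genomeLength = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("analysis", "transform"), "coverage table")
  if ("fraction" %in% names(df)) {
    sp <- split(df, df$analysis)
    return(lapply(sp, function(d)
      stats::setNames(d$fraction, d$transform)))
  }
  require_columns(df, c("start", "end"), "coverage table (interval form)")
  if (is.null(genomeLength))
    stop("genomeLength is required for interval-form coverage")
  sp <- split(df, df$analysis)
  lapply(sp, function(d) {
    byt <- split(d, d$transform)
    stats::setNames(vapply(byt, function(t) {
      ir <- IRanges::reduce(IRanges::IRanges(t$start + 1L, t$end))
      sum(IRanges::width(ir)) / genomeLength
    }, 0), names(byt))
  })
}

ref_table <- function(file) {
  utils::read.delim(system.file("extdata", file, package = "swingerome",
                                mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Bundled reference tables from the published unbiased reanalyses
#'
#' Count and statistics tables transcribed from the published unbiased
#' (no-enzyme) reanalyses of tryptic human mitoproteome MS/MS data, used
#' as desk-scale inputs for the statistical pipeline:
#' \describe{
#'   \item{`referenceCtermCounts()`}{per-residue carboxyl-terminal counts
#'     of detected peptides, the residue totals of the hypothetical
#'     translations ("genome"), and RNA-mapped counts, for the four
#'     analyses (del, swinger tri/tetra/penta).}
#'   \item{`referenceTotals()`}{published per-analysis totals: detected and
#'     genome totals as printed (for the tetracodon analysis the printed
#'     detected total, 127, is the denominator every published statistic
#'     uses even though the residue cells sum to 131), plus the
#'     tryptic/other RNA-mapped counts and their random-mapping
#'     expectations derived from published RNA coverage.}
#'   \item{`referenceNtermCounts()`}{the downstream next-peptide N-terminal
#'     residue counts (negative control).}
#'   \item{`referenceCorrelations()`}{per-analysis Pearson r between
#'     peptide counts and RNA coverage with the number of observations
#'     (9 del transformations, 23 swinger transformations).}
#'   \item{`referenceStopInsertions()`}{residues observed inserted at stop
#'     codons per analysis, and the canonical mitochondrial protein
#'     composition.}
#' }
#'
#' @return A data.frame (shape described above).
#' @export
referenceCtermCounts <- function() ref_table("cterm_counts.tsv")

#' @rdname referenceCtermCounts
#' @export
referenceTotals <- function() ref_table("analysis_totals.tsv")

#' @rdname referenceCtermCounts
#' @export
referenceNtermCounts <- function() ref_table("nterm_counts.tsv")

#' @rdname referenceCtermCounts
#' @export
referenceCorrelations <- function() ref_table("correlations.tsv")

#' @rdname referenceCtermCounts
#' @export
referenceStopInsertions <- function() ref_table("stop_insertions.tsv")

#' @rdname referenceCtermCounts
#' @export
referenceRankPvalues <- function() ref_table("rank_pvalues.tsv")
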