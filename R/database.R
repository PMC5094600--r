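# In-silico tryptic peptide database construction: trypsinization of all
# translation products, 19-fold expansion of stop-containing peptides,
# length filtering, deduplication, and the residue-composition denominators
# used by the bias statistics.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
# I and L are indistinguishable by mass spectrometry: 19 merged categories
AA_CATEGORIES <- c("A", "C", "D", "E", "F", "G", "H", "IL", "K", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STOP_REPLACEMENTS <- setdiff(AA20, c("L", "I"))  # 18 residues

#' Merge I and L into the single category "IL"
#'
#' @param residues character vector of single residues.
#' @return Character vector over the 19 merged categories.
#' @export
mergeIL <- function(residues) ifelse(residues %in% c("I", "L"), "IL", residues)

#' In-silico tryptic digestion
#'
#' Cleaves after every K and R (no proline exception by default, matching
#' specific cleavage after K or R; set `prolineRule = TRUE` for the Keil
#' "not before P" variant). With `missedCleavages > 0`, every join of up to
#' that many consecutive fragments is also returned, ordered by start
#' position then number of missed cleavages.
#'
#' @param protein residue string (may contain the stop marker 'X').
#' @param missedCleavages maximum number of internal K/R sites, default 0.
#' @param prolineRule if TRUE, do not cleave K/R-P bonds.
#' @return Character vector of peptides; concatenating the
#'   zero-missed-cleavage fragments reproduces the input.
#' @examples
#' trypsinize("MKRAAAK")      # "MK" "R" "AAAK"
#' trypsinize("MKRA", 1)      # includes "MKR"
#' @export
trypsinize <- function(protein, missedCleavages = 0L, prolineRule = FALSE) {
  protein <- as.character(protein)
  if (!nzchar(protein)) stop("protein sequence is empty")
  pat <- if (prolineRule) "(?<=[KR])(?!P)" else "(?<=[KR])"
  frags <- strsplit(protein, pat, perl = TRUE)[[1]]
  if (missedCleavages == 0L) return(frags)
  nf <- length(frags)
  out <- character(0)
  for (i in seq_len(nf))
    for (m in 0:min(missedCleavages, nf - i))
      out <- c(out, paste(frags[i:(i + m)], collapse = ""))
  out
}

# fragment start offsets (0-based, residues) matching trypsinize(p, 0)
tryptic_starts <- function(protein) {
  frags <- strsplit(protein, "(?<=[KR])", perl = TRUE)[[1]]
  c(0L, cumsum(nchar(frags)))[seq_along(frags)]
}

#' Expand stop-containing peptides 19-fold
#'
#' A predicted peptide containing at least one stop ('X') is represented 19
#' times in the search database: once with stops rendered as Leu (the form
#' matched as Leu/Ile, which are isobaric) and once for each of the 18
#' remaining amino acids substituted uniformly at ALL stop positions
#' (excluding Leu and Ile). Peptides without stops are returned unchanged.
#'
#' @param peptide residue string.
#' @return Named character vector (names give the replacement residue);
#'   length 19 for stop-containing peptides, length 1 otherwise.
#' @export
expandStops <- function(peptide) {
  if (!grepl("X", peptide, fixed = TRUE))
    return(stats::setNames(peptide, ""))
  reps <- c("L", STOP_REPLACEMENTS)
  stats::setNames(vapply(reps, function(r)
    gsub("X", r, peptide, fixed = TRUE), ""), reps)
}

analysis_plan <- function(analyses) {
  # each analysis is a set of transformation rules plus a codon size
  plans <- list(
    del           = list(rules = delRules(),     size = 3L),
    swinger_tri   = list(rules = swingerRules(), size = 3L),
    swinger_tetra = list(rules = swingerRules(), size = 4L),
    swinger_penta = list(rules = swingerRules(), size = 5L),
    identity      = list(rules = list(identity = "identity"), size = 3L)
  )
  unknown <- setdiff(analyses, names(plans))
  if (length(unknown))
    stop("unknown analyses: ", paste(unknown, collapse = ", "))
  plans[analyses]
}

#' Build the non-redundant predicted-peptide database
#'
#' Runs the full cross-product of transformations and codon sizes for the
#' requested analyses (del transforms with tricodons; swinger transforms
#' with tri-, tetra- and pentacodons), translates all frames of both
#' strands under the vertebrate mitochondrial code, trypsinizes every
#' product, expands stop-containing peptides 19-fold, filters by length and
#' deduplicates on the amino-acid sequence. Construction is deterministic.
#'
#' @param genome a [GenomeSequence-class] or nucleotide string.
#' @param analyses subset of `"del"`, `"swinger_tri"`, `"swinger_tetra"`,
#'   `"swinger_penta"` (plus `"identity"` for the untransformed genome).
#' @param code codon table, default vertebrate mitochondrial.
#' @param lengthRange inclusive peptide length bounds, default 6-50
#'   residues (a typical MS-searchable range).
#' @param missedCleavages passed to [trypsinize()].
#' @param expandStopPeptides if FALSE, stop-containing peptides are dropped
#'   instead of expanded.
#' @return List with elements `database` (data.frame of unique peptides:
#'   sequence, analysis, rule, size, frame, strand, start, end in
#'   transformed coordinates, stop_count, replacement; first provenance
#'   retained) and `provenance` (all entries before deduplication).
#' @export
buildPeptideDatabase <- function(genome,
                                 analyses = c("del", "swinger_tri",
                                              "swinger_tetra",
                                              "swinger_penta"),
                                 code = geneticCodeTable(),
                                 lengthRange = c(6L, 50L),
                                 missedCleavages = 0L,
                                 expandStopPeptides = TRUE) {
  if (length(analyses) == 0L) stop("at least one analysis must be requested")
  if (!is(genome, "GenomeSequence")) genome <- genomeSequence(genome)
  plans <- analysis_plan(analyses)
  rows <- list()
  for (an in names(plans)) {
    plan <- plans[[an]]
    for (rn in names(plan$rules)) {
      ts <- transformGenome(genome, plan$rules[[rn]])
      products <- translateAllFrames(ts, code, plan$size)
      for (pr in products) {
        aa <- aaSequence(pr)
        if (nchar(aa) == 0L) next
        peps <- trypsinize(aa, missedCleavages)
        if (missedCleavages == 0L) {
          starts <- tryptic_starts(aa)
        } else {
          # locate each (possibly joined) peptide by position bookkeeping
          base <- trypsinize(aa, 0L)
          base_starts <- tryptic_starts(aa)
          starts <- unlist(lapply(seq_along(base), function(i)
            rep(base_starts[i], min(missedCleavages, length(base) - i) + 1L)))
        }
        keep <- nchar(peps) >= lengthRange[1] & nchar(peps) <= lengthRange[2]
        peps <- peps[keep]
        starts <- starts[keep]
        if (!length(peps)) next
        cs <- codonStarts(pr)
        nt_start <- cs[starts + 1L]
        nt_end <- cs[starts + nchar(peps)] + pr@size
        nstop <- nchar(peps) - nchar(gsub("X", "", peps, fixed = TRUE))
        has_stop <- nstop > 0L
        if (any(has_stop) && !expandStopPeptides) {
          peps <- peps[!has_stop]; nt_start <- nt_start[!has_stop]
          nt_end <- nt_end[!has_stop]; nstop <- nstop[!has_stop]
          has_stop <- has_stop[!has_stop]
          if (!length(peps)) next
        }
        reps_all <- c("L", STOP_REPLACEMENTS)
        i0 <- which(!has_stop)
        i1 <- which(has_stop)
        seqs <- peps[i0]; repl <- rep("", length(i0)); idx <- i0
        if (length(i1)) {
          for (r in reps_all) {
            seqs <- c(seqs, gsub("X", r, peps[i1], fixed = TRUE))
            repl <- c(repl, rep(r, length(i1)))
            idx <- c(idx, i1)
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seqs, analysis = an, rule = ts@rule,
          size = pr@size, frame = pr@frame, strand = pr@strand,
          start = nt_start[idx], end = nt_end[idx],
          stop_count = nstop[idx], replacement = repl,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    empty <- data.frame(sequence = character(0), analysis = character(0),
                        rule = character(0), size = integer(0),
                        frame = integer(0), strand = character(0),
                        start = integer(0), end = integer(0),
                        stop_count = integer(0), replacement = character(0))
    return(list(database = empty, provenance = empty))
  }
  provenance <- do.call(rbind, rows)
  rownames(provenance) <- NULL
  database <- provenance[!duplicated(provenance$sequence), , drop = FALSE]
  rownames(database) <- NULL
  list(database = database, provenance = provenance)
}

#' Residue composition of translation products
#'
#' Counts residues over the supplied translations, merging I and L into the
#' single category "IL" (isobaric under MS); the stop marker 'X' is not a
#' residue category and is excluded from the totals. These counts are the
#' denominators of the terminal-residue bias statistics.
#'
#' @param translations list of [TranslationProduct-class] objects and/or
#'   amino-acid strings.
#' @return List with `counts` (named integer vector over the 19 categories)
#'   and `total`.
#' @export
residueComposition <- function(translations) {
  if (is.character(translations)) translations <- as.list(translations)
  if (!is.list(translations)) translations <- list(translations)
  aa <- vapply(translations, function(x)
    if (is(x, "TranslationProduct")) aaSequence(x) else as.character(x), "")
  letters <- strsplit(paste(aa, collapse = ""), "")[[1]]
  letters <- mergeIL(letters[letters != "X"])
  counts <- table(factor(letters, levels = AA_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), AA_CATEGORIES)
  list(counts = counts, total = sum(counts))
}
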