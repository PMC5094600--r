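# Translation of (transformed) sequences under tri-, tetra- and pentacodons.
# Only the first three nucleotides of an expanded codon are read; the
# trailing one or two positions are silent, which makes tetracodon
# translation of a sequence identical to tricodon translation of its del3-1
# transform (and pentacodon <-> del3-2).

#' Built-in genetic code tables
#'
#' Returns the codon table for the vertebrate mitochondrial code (NCBI
#' translation table 2) or the standard nuclear code (table 1), as a named
#' character vector over the 64 trinucleotides. Stop codons are rendered
#' `"X"`, the in-memory stop marker used throughout the package; the set of
#' stop codons is attached as attribute `"stops"`. The two codes differ at
#' exactly four codons (AGA, AGG, ATA, TGA), i.e. 60/64 = 93.75% identity.
#'
#' @param name `"vertebrate_mitochondrial"` or `"standard_nuclear"`.
#' @return Named character vector of 64 amino-acid letters.
#' @export
geneticCodeTable <- function(name = c("vertebrate_mitochondrial",
                                      "standard_nuclear")) {
  name <- match.arg(name)
  id <- if (name == "vertebrate_mitochondrial") "2" else "1"
  tab <- Biostrings::getGeneticCode(id)
  stops <- names(tab)[tab == "*"]
  tab[tab == "*"] <- "X"
  attr(tab, "stops") <- stops
  attr(tab, "name") <- name
  tab
}

#' Fraction of codons assigned identically by two genetic codes
#'
#' Stop is treated as its own symbol. Symmetric; 1 for identical codes;
#' 0.9375 (60/64) for the built-in nuclear vs vertebrate mitochondrial
#' pair.
#'
#' @param codeA,codeB codon tables from [geneticCodeTable()].
#' @return Fraction in [0, 1].
#' @export
codeIdentityFraction <- function(codeA, codeB) {
  stopifnot(length(codeA) == 64L, length(codeB) == 64L)
  mean(codeA[names(codeA)] == codeB[names(codeA)])
}

#' Codons assigned differently by two genetic codes
#'
#' @inheritParams codeIdentityFraction
#' @return Character vector of codons (sorted).
#' @export
codeDifferences <- function(codeA, codeB) {
  sort(names(codeA)[codeA[names(codeA)] != codeB[names(codeA)]])
}

#' Translate one frame of a sequence along expanded codons
#'
#' Reads consecutive blocks of `size` nucleotides starting at `frame`
#' (0-based); only the first three nucleotides of each block determine the
#' amino acid, the remaining positions being silent. A trailing block is
#' translated whenever its three coding positions exist, even if its silent
#' positions are truncated (this preserves the exact equivalence between
#' expanded-codon translation and del-transform + tricodon translation at
#' every sequence length). Stop codons yield `"X"`. Codons whose coding
#' positions contain ambiguity letters are skipped with a warning; codon
#' start bookkeeping is preserved for the residues that are emitted.
#'
#' @param sequence nucleotide string or [TransformedSeq-class] (plus-strand
#'   residues are read).
#' @param code codon table from [geneticCodeTable()].
#' @param size codon size 3, 4 or 5.
#' @param frame 0-based offset, `frame < size`.
#' @param strand strand label stored in the product ("+" by default; the
#'   sequence itself is always read left to right).
#' @return A [TranslationProduct-class].
#' @examples
#' aaSequence(translateCodons("ATGAAA", size = 3))   # "MK"
#' aaSequence(translateCodons("ATGGAAAC", size = 4)) # "MK"
#' @export
translateCodons <- function(sequence,
                            code = geneticCodeTable(),
                            size = 3L, frame = 0L, strand = "+") {
  if (is(sequence, "TransformedSeq")) sequence <- sequence@sequence
  sequence <- toupper(as.character(sequence))
  size <- as.integer(size)
  frame <- as.integer(frame)
  if (!size %in% 3:5) stop("codon size must be 3, 4 or 5")
  if (frame < 0L || frame >= size)
    stop("frame must lie in [0, size); got ", frame)
  len <- nchar(sequence)
  if (len - frame < 3L) {
    return(new("TranslationProduct", aa = "", codonStarts = integer(0),
               size = size, frame = frame, strand = strand))
  }
  starts <- seq.int(frame, len - 3L, by = size)
  codons <- substring(sequence, starts + 1L, starts + 3L)
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    warning("skipped ", sum(is.na(aa)),
            " codon(s) containing ambiguity letters")
    starts <- starts[!is.na(aa)]
    aa <- aa[!is.na(aa)]
  }
  new("TranslationProduct", aa = paste(aa, collapse = ""),
      codonStarts = as.integer(starts), size = size, frame = frame,
      strand = strand)
}

#' Translate all frames of both strands
#'
#' Produces `size` frames for the plus strand followed by `size` frames for
#' the minus strand (the reverse complement of the transformed sequence),
#' i.e. 6, 8 or 10 products for tri-, tetra- and pentacodons.
#'
#' @param ts a [TransformedSeq-class] or nucleotide string.
#' @param code codon table from [geneticCodeTable()].
#' @param size codon size 3, 4 or 5.
#' @return List of `2 * size` [TranslationProduct-class] objects, plus
#'   frames ascending then minus frames ascending.
#' @export
translateAllFrames <- function(ts, code = geneticCodeTable(), size = 3L) {
  seq_plus <- if (is(ts, "TransformedSeq")) ts@sequence else as.character(ts)
  seq_minus <- revComp(seq_plus)
  size <- as.integer(size)
  c(lapply(0:(size - 1L), function(f)
      translateCodons(seq_plus, code, size, f, strand = "+")),
    lapply(0:(size - 1L), function(f)
      translateCodons(seq_minus, code, size, f, strand = "-")))
}

#' Check the del / expanded-codon translation equivalence
#'
#' Deleting the silent positions before translation (a del transform
#' followed by tricodon translation) or ignoring them during translation
#' (expanded-codon translation) is the same operation. For phase/frame 0
#' the two amino-acid strings are identical. For a shifted phase p, the
#' del transform retains the p residues before its offset verbatim, so its
#' tricodon translation in frame p mod 3 carries floor(p / 3) extra
#' leading codons read from that prefix; after dropping them it equals
#' expanded-codon translation in frame p.
#'
#' @param sequence nucleotide string.
#' @param skip 1 (tetracodon equivalence) or 2 (pentacodon equivalence).
#' @param phase del phase / expanded translation frame, default 0.
#' @param code codon table.
#' @return TRUE if the two amino-acid sequences are identical.
#' @export
expandedCodonEquivalence <- function(sequence, skip, phase = 0L,
                                     code = geneticCodeTable()) {
  phase <- as.integer(phase)
  ts <- applyDel(sequence, delRule(skip, phase))
  via_del <- aaSequence(translateCodons(ts, code, size = 3L,
                                        frame = phase %% 3L))
  via_del <- substring(via_del, phase %/% 3L + 1L)
  direct <- aaSequence(translateCodons(sequence, code, size = 3L + skip,
                                       frame = phase))
  identical(via_del, direct)
}

#' Is a peptide's encoding compatible with the nuclear genetic code?
#'
#' A detected peptide matches nuclear-code translation only if every coding
#' trinucleotide translates to the same residue under both codes. Positions
#' that were stops under the mitochondrial code (replaced in the database by
#' a substitute residue) are compatible only when the nuclear translation
#' equals the replacement residue.
#'
#' @param codons character vector of coding trinucleotides, in order.
#' @param replacement single residue substituted at mitochondrial stop
#'   codons (the database's stop replacement), or NULL if the peptide
#'   contains no stop.
#' @param mito,nuclear codon tables.
#' @return TRUE/FALSE.
#' @export
nuclearCompatible <- function(codons, replacement = NULL,
                              mito = geneticCodeTable("vertebrate_mitochondrial"),
                              nuclear = geneticCodeTable("standard_nuclear")) {
  if (length(codons) == 0L) stop("peptide carries no codon provenance")
  codons <- toupper(codons)
  if (anyNA(mito[codons])) stop("invalid codon in provenance")
  m <- unname(mito[codons])
  n <- unname(nuclear[codons])
  is_stop <- m == "X"
  if (any(is_stop)) {
    if (is.null(replacement))
      stop("peptide contains stop codons but no replacement residue given")
    m[is_stop] <- replacement
  }
  all(m == n)
}

#' Expected number of peptides compatible with the nuclear code
#'
#' With a fraction `shared` of codons translated identically by the nuclear
#' and mitochondrial codes, a detected peptide of length k is compatible
#' with both codes with probability `shared^k`; the expectation over a set
#' of detected peptides is the sum of `shared^k` over their lengths. The
#' expectation is always below the number of peptides for `shared < 1`.
#'
#' @param lengths integer vector of peptide lengths (residues), all >= 1.
#' @param shared fraction of identically assigned codons, default
#'   60/64 = 0.9375.
#' @return Expected count (numeric scalar).
#' @export
nuclearCodeExpected <- function(lengths, shared = 0.9375) {
  if (length(lengths) == 0L) stop("no peptide lengths supplied")
  if (any(lengths < 1L)) stop("peptide lengths must be >= 1")
  sum(shared^lengths)
}
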