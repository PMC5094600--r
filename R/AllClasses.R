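#' @import methods
NULL

DNA_LETTERS <- c("A", "C", "G", "T")
# IUPAC ambiguity letters pass through transformations untouched
IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' GenomeSequence: a nucleotide sequence with a circular/linear flag
#'
#' Container for the source genome of a transformation pipeline. Residues
#' are normalised to upper case at construction; the alphabet is the DNA
#' letters A, C, G, T plus the IUPAC ambiguity letters.
#'
#' @slot id character label for the sequence.
#' @slot sequence character scalar holding the residues.
#' @slot circular logical; circular genomes are accepted but transformations
#'   treat sequences linearly (no wrap-around codons) unless stated.
#'
#' @exportClass GenomeSequence
setClass("GenomeSequence",
  representation(id = "character", sequence = "character",
                 circular = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
      msg <- c(msg, "sequence must be a single non-empty string")
    bad <- setdiff(strsplit(object@sequence, "")[[1]],
                   c(DNA_LETTERS, IUPAC_EXTRA))
    if (length(bad))
      msg <- c(msg, paste0("invalid residue letters: ",
                           paste(unique(bad), collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a GenomeSequence
#'
#' @param sequence nucleotide string (or a [Biostrings::DNAString]); lower
#'   case is accepted and normalised.
#' @param id label for the sequence.
#' @param circular logical flag, default linear.
#' @return A [GenomeSequence-class] object.
#' @examples
#' g <- genomeSequence("acgtACGT", id = "toy")
#' genomeLength(g)
#' @export
genomeSequence <- function(sequence, id = "genome", circular = FALSE) {
  sequence <- toupper(as.character(sequence))
  new("GenomeSequence", id = id, sequence = sequence, circular = circular)
}

#' @describeIn genomeSequence Length of the sequence in nucleotides.
#' @param x a GenomeSequence.
#' @export
genomeLength <- function(x) nchar(x@sequence)

#' @describeIn genomeSequence Residues as a character scalar.
#' @export
genomeResidues <- function(x) x@sequence

setMethod("show", "GenomeSequence", function(object) {
  cat("GenomeSequence", object@id,
      sprintf("(%d nt, %s)\n", nchar(object@sequence),
              if (object@circular) "circular" else "linear"))
  s <- object@sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
})

#' SwingerRule: a bijective nucleotide exchange
#'
#' One of the 23 non-identity permutations of \{A, C, G, T\}. Nine rules are
#' symmetric (self-inverse: the six single transpositions such as A<->C plus
#' the three double transpositions such as A<->C,G<->T) and fourteen are
#' asymmetric (the eight 3-cycles such as A>C>G>A and the six 4-cycles).
#'
#' @slot name canonical ASCII label ("A<->C", "A>C>G>A", ...).
#' @slot mapping named character vector: image of each of A, C, G, T.
#'
#' @exportClass SwingerRule
setClass("SwingerRule",
  representation(name = "character", mapping = "character"),
  validity = function(object) {
    m <- object@mapping
    if (!identical(sort(names(m)), sort(DNA_LETTERS)) ||
        !identical(sort(unname(m)), sort(DNA_LETTERS)))
      return("mapping must be a permutation of A, C, G, T")
    if (all(m[DNA_LETTERS] == DNA_LETTERS))
      return("identity permutation is not a swinger rule")
    TRUE
  }
)

setMethod("show", "SwingerRule", function(object) {
  cat("SwingerRule", object@name, "\n")
})

#' DelRule: systematic deletion after each trinucleotide
#'
#' Keep three nucleotides, delete `skip` (one or two), repeat; the first
#' `phase` residues are retained verbatim before the periodic pattern
#' starts. Period is 4 (del3-1) or 5 (del3-2); there are four del3-1 phases
#' and five del3-2 phases, nine del rules in total.
#'
#' @slot skip integer 1 or 2 (number of residues deleted per period).
#' @slot phase integer offset in [0, 3 + skip).
#'
#' @exportClass DelRule
setClass("DelRule",
  representation(skip = "integer", phase = "integer"),
  validity = function(object) {
    if (!object@skip %in% c(1L, 2L)) return("skip must be 1 or 2")
    if (object@phase < 0L || object@phase >= 3L + object@skip)
      return("phase must lie in [0, keep + skip)")
    TRUE
  }
)

setMethod("show", "DelRule", function(object) {
  cat(sprintf("DelRule del3-%d.%d (keep 3, skip %d, phase %d)\n",
              object@skip, object@phase, object@skip, object@phase))
})

#' TransformedSeq: a transformed sequence with its coordinate map
#'
#' Holds the residues produced by a swinger rule, a del rule or the identity
#' transform, together with `posmap`, the 0-based source position every
#' transformed position derives from. Swinger transforms preserve length
#' (posmap is the identity map); del transforms shorten the sequence.
#'
#' @slot sourceId label of the source genome.
#' @slot rule canonical rule label ("A<->C", "del3-1.0", "identity").
#' @slot phase integer del phase (NA for swinger/identity).
#' @slot strand "+" or "-"; "-" sequences are reverse complements reported
#'   in plus coordinates of the transformed sequence.
#' @slot sequence transformed residues.
#' @slot posmap integer vector, 0-based source position per residue.
#' @slot sourceLength length of the source sequence.
#'
#' @exportClass TransformedSeq
setClass("TransformedSeq",
  representation(sourceId = "character", rule = "character",
                 phase = "integer", strand = "character",
                 sequence = "character", posmap = "integer",
                 sourceLength = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nchar(object@sequence) != length(object@posmap))
      msg <- c(msg, "posmap length must equal sequence length")
    if (length(object@posmap) &&
        (min(object@posmap) < 0L || max(object@posmap) >= object@sourceLength))
      msg <- c(msg, "posmap entries must lie in [0, source length)")
    if (!object@strand %in% c("+", "-"))
      msg <- c(msg, "strand must be '+' or '-'")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "TransformedSeq", function(object) {
  cat(sprintf("TransformedSeq %s | %s | strand %s (%d nt from %d nt source)\n",
              object@sourceId, object@rule, object@strand,
              nchar(object@sequence), object@sourceLength))
})

#' Accessors for TransformedSeq
#'
#' @param x a [TransformedSeq-class] object.
#' @return `transformedResidues` returns the sequence string; `posmap` the
#'   0-based source position of every transformed position; `ruleLabel` the
#'   canonical rule name.
#' @export
transformedResidues <- function(x) x@sequence

#' @rdname transformedResidues
#' @export
posmap <- function(x) x@posmap

#' @rdname transformedResidues
#' @export
ruleLabel <- function(x) x@rule

#' TranslationProduct: one frame of a translated sequence
#'
#' @slot aa amino-acid string; stop codons are rendered 'X'.
#' @slot codonStarts 0-based transformed-coordinate start of the codon
#'   encoding each residue.
#' @slot size codon size (3 tricodon, 4 tetracodon, 5 pentacodon).
#' @slot frame frame offset in [0, size).
#' @slot strand "+" or "-".
#'
#' @exportClass TranslationProduct
setClass("TranslationProduct",
  representation(aa = "character", codonStarts = "integer",
                 size = "integer", frame = "integer", strand = "character"),
  validity = function(object) {
    if (nchar(object@aa) != length(object@codonStarts))
      return("codonStarts must have one entry per residue")
    if (object@frame < 0L || object@frame >= object@size)
      return("frame must lie in [0, size)")
    TRUE
  }
)

setMethod("show", "TranslationProduct", function(object) {
  cat(sprintf("TranslationProduct size %d frame %d strand %s (%d aa)\n",
              object@size, object@frame, object@strand, nchar(object@aa)))
})

#' @describeIn aaSequence Codon start coordinates (0-based, transformed
#'   sequence of the product's strand).
#' @export
codonStarts <- function(x) x@codonStarts

#' Amino-acid string of a TranslationProduct
#'
#' @param x a [TranslationProduct-class].
#' @export
aaSequence <- function(x) x@aa
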