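# Systematic genome transformations: the 23 swinger bijections and the
# nine del rules, with exact coordinate maps back to the source.

perm_cycles <- function(mapping) {
  # cycle decomposition of a permutation of the 4 DNA letters
  seen <- character(0)
  cycles <- list()
  for (l in DNA_LETTERS) {
    if (l %in% seen) next
    cyc <- l
    nxt <- unname(mapping[[l]])
    while (nxt != l) {
      cyc <- c(cyc, nxt)
      nxt <- unname(mapping[[nxt]])
    }
    seen <- c(seen, cyc)
    if (length(cyc) > 1L) cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

swinger_name <- function(mapping) {
  cycles <- perm_cycles(mapping)
  paste(vapply(cycles, function(cyc) {
    if (length(cyc) == 2L) paste0(cyc[1], "<->", cyc[2])
    else paste(c(cyc, cyc[1]), collapse = ">")
  }, ""), collapse = ",")
}

#' Enumerate the 23 swinger rules
#'
#' All non-identity permutations of \{A, C, G, T\}: six single
#' transpositions, three double transpositions (together the nine symmetric
#' exchanges X<->Y), eight 3-cycles and six 4-cycles (the fourteen
#' asymmetric exchanges). The list is sorted by canonical name, so the
#' ordering is deterministic.
#'
#' @return Named list of 23 [SwingerRule-class] objects.
#' @examples
#' length(swingerRules())                       # 23
#' sum(vapply(swingerRules(), isSymmetricRule, TRUE))  # 9
#' @export
swingerRules <- function() {
  perms <- expand.grid(A = DNA_LETTERS, C = DNA_LETTERS, G = DNA_LETTERS,
                       T = DNA_LETTERS, stringsAsFactors = FALSE)
  keep <- apply(perms, 1L, function(p) length(unique(p)) == 4L)
  perms <- perms[keep, , drop = FALSE]
  rules <- list()
  for (i in seq_len(nrow(perms))) {
    m <- unlist(perms[i, , drop = TRUE])
    names(m) <- DNA_LETTERS
    if (all(m == DNA_LETTERS)) next
    nm <- swinger_name(m)
    rules[[nm]] <- new("SwingerRule", name = nm, mapping = m)
  }
  rules[order(names(rules))]
}

#' Look up a swinger rule by name
#'
#' @param name canonical label such as `"A<->C"` or `"A>C>G>A"`.
#' @return A [SwingerRule-class].
#' @export
swingerRule <- function(name) {
  rules <- swingerRules()
  if (!name %in% names(rules))
    stop("unknown swinger rule '", name, "'; valid names: ",
         paste(names(rules), collapse = ", "))
  rules[[name]]
}

#' Is a swinger rule symmetric (self-inverse)?
#'
#' @param rule a [SwingerRule-class].
#' @return TRUE for the nine X<->Y exchanges, FALSE for the fourteen
#'   asymmetric ones.
#' @export
isSymmetricRule <- function(rule) {
  m <- rule@mapping
  all(m[m[DNA_LETTERS]] == DNA_LETTERS)
}

#' Invert a swinger rule
#'
#' @param rule a [SwingerRule-class].
#' @return The [SwingerRule-class] whose mapping is the inverse permutation.
#' @export
inverseRule <- function(rule) {
  m <- rule@mapping
  inv <- stats::setNames(names(m), unname(m))[DNA_LETTERS]
  new("SwingerRule", name = swinger_name(inv), mapping = inv)
}

#' Compose two swinger mappings
#'
#' Applies `a` then `b`; returns the composite mapping (possibly the
#' identity, which is not itself a swinger rule).
#'
#' @param a,b [SwingerRule-class] objects.
#' @return Named character vector mapping each DNA letter to its image.
#' @export
composeRules <- function(a, b) {
  m <- b@mapping[a@mapping[DNA_LETTERS]]
  stats::setNames(unname(m), DNA_LETTERS)
}

#' Apply a swinger rule to a nucleotide sequence
#'
#' Every A, C, G, T is replaced by its image under the rule; IUPAC
#' ambiguity letters pass through unchanged (with a warning) and length is
#' preserved.
#'
#' @param sequence nucleotide string, [GenomeSequence-class] or
#'   [Biostrings::DNAString].
#' @param rule a [SwingerRule-class] or a canonical rule name.
#' @return Transformed nucleotide string.
#' @examples
#' applySwinger("ACGT", "A<->C")  # "CAGT"
#' @export
applySwinger <- function(sequence, rule) {
  if (is(sequence, "GenomeSequence")) sequence <- sequence@sequence
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("cannot transform an empty sequence")
  if (is.character(rule)) rule <- swingerRule(rule)
  if (grepl(paste0("[", paste(IUPAC_EXTRA, collapse = ""), "]"), sequence))
    warning("ambiguity letters present; passed through unchanged")
  m <- rule@mapping
  chartr(paste(DNA_LETTERS, collapse = ""),
         paste(m[DNA_LETTERS], collapse = ""), sequence)
}

#' Enumerate the nine del rules
#'
#' Four del3-1 rules (delete one nucleotide after each trinucleotide,
#' phases 0-3) and five del3-2 rules (delete a dinucleotide, phases 0-4).
#'
#' @return Named list of nine [DelRule-class] objects
#'   (`del3-1.0` ... `del3-2.4`).
#' @export
delRules <- function() {
  rules <- list()
  for (skip in c(1L, 2L))
    for (phase in seq_len(3L + skip) - 1L) {
      nm <- sprintf("del3-%d.%d", skip, phase)
      rules[[nm]] <- new("DelRule", skip = skip, phase = as.integer(phase))
    }
  rules
}

#' @rdname delRules
#' @param skip 1 or 2 deleted nucleotides per period.
#' @param phase offset in [0, 3 + skip); residues before the offset are
#'   retained verbatim.
#' @export
delRule <- function(skip, phase = 0L) {
  new("DelRule", skip = as.integer(skip), phase = as.integer(phase))
}

del_kept_positions <- function(len, skip, phase) {
  # 0-based source positions retained by a del rule
  period <- 3L + skip
  p <- 0:(len - 1L)
  p[p < phase | (p - phase) %% period < 3L]
}

#' Apply a del rule to a sequence
#'
#' Starting at the rule's phase offset, keeps three residues and deletes
#' `skip`, repeating along the sequence; residues before the offset are
#' retained verbatim. The returned object carries `posmap`, the 0-based
#' source position of every kept residue.
#'
#' @param sequence nucleotide string or [GenomeSequence-class].
#' @param rule a [DelRule-class] (see [delRule()]).
#' @param sourceId label recorded in the result.
#' @return A [TransformedSeq-class].
#' @examples
#' ts <- applyDel("ACGTACGT", delRule(1, 0))
#' transformedResidues(ts)  # "ACGACG"
#' posmap(ts)               # 0 1 2 4 5 6
#' @export
applyDel <- function(sequence, rule, sourceId = "genome") {
  if (is(sequence, "GenomeSequence")) {
    sourceId <- sequence@id
    sequence <- sequence@sequence
  }
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  if (len < 3L + rule@skip)
    stop("sequence shorter than the del period (", 3L + rule@skip, ")")
  kept <- del_kept_positions(len, rule@skip, rule@phase)
  res <- paste(strsplit(sequence, "")[[1]][kept + 1L], collapse = "")
  new("TransformedSeq", sourceId = sourceId,
      rule = sprintf("del3-%d.%d", rule@skip, rule@phase),
      phase = rule@phase, strand = "+", sequence = res,
      posmap = as.integer(kept), sourceLength = len)
}

#' Transform a genome by any rule, keeping the coordinate map
#'
#' Dispatches on the rule type: swinger rules preserve length (identity
#' posmap), del rules shorten the sequence, and the string `"identity"`
#' returns the untransformed sequence.
#'
#' @param genome a [GenomeSequence-class] or nucleotide string.
#' @param rule a [SwingerRule-class], [DelRule-class], canonical rule name,
#'   or `"identity"`.
#' @return A [TransformedSeq-class] on the plus strand.
#' @export
transformGenome <- function(genome, rule = "identity") {
  if (!is(genome, "GenomeSequence")) genome <- genomeSequence(genome)
  len <- genomeLength(genome)
  if (is(rule, "DelRule")) return(applyDel(genome, rule))
  if (is.character(rule) && grepl("^del3-", rule)) {
    parts <- as.integer(strsplit(sub("^del3-", "", rule), ".", fixed = TRUE)[[1]])
    return(applyDel(genome, delRule(parts[1], parts[2])))
  }
  if (identical(rule, "identity")) {
    return(new("TransformedSeq", sourceId = genome@id, rule = "identity",
               phase = NA_integer_, strand = "+",
               sequence = genome@sequence,
               posmap = 0:(len - 1L), sourceLength = len))
  }
  if (is.character(rule)) rule <- swingerRule(rule)
  new("TransformedSeq", sourceId = genome@id, rule = rule@name,
      phase = NA_integer_, strand = "+",
      sequence = applySwinger(genome, rule),
      posmap = 0:(len - 1L), sourceLength = len)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement (ambiguity letters handled by
#' Biostrings).
#'
#' @param sequence nucleotide string.
#' @return Reverse-complemented string.
#' @export
revComp <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(as.character(sequence))))
}

#' Project a transformed-coordinate interval back onto the source
#'
#' Maps a 0-based half-open interval `[start, end)` of the transformed
#' sequence to the minimal sorted set of half-open source intervals covering
#' exactly the source positions it derives from. Swinger intervals project
#' to a single interval of equal length; del intervals may split at every
#' deletion.
#'
#' @param ts a [TransformedSeq-class].
#' @param start,end 0-based half-open interval in transformed coordinates.
#' @return Integer matrix with columns `start`, `end` (0-based half-open
#'   source coordinates), one row per interval.
#' @export
projectToSource <- function(ts, start, end) {
  n <- length(ts@posmap)
  if (start < 0L || end > n || start >= end)
    stop("interval [", start, ",", end, ") out of range for length ", n)
  pos <- sort(ts@posmap[(start + 1L):end])
  breaks <- which(diff(pos) != 1L)
  first <- pos[c(1L, breaks + 1L)]
  last <- pos[c(breaks, length(pos))]
  cbind(start = first, end = last + 1L)
}
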