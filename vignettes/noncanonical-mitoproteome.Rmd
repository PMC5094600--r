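---
title: "Systematic genome transformations, expanded-codon translation and the statistics of non-canonical peptide populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systematic genome transformations, expanded-codon translation and the statistics of non-canonical peptide populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swingerome)
```

## The problem

Human mitochondria produce, besides canonical transcripts, two families of
non-canonical RNAs. *Swinger* RNAs match the mitogenome only after a
systematic bijective exchange of nucleotides applied along their whole
length — one of the 23 non-identity permutations of {A, C, G, T} (nine
symmetric exchanges X&harr;Y and fourteen asymmetric cyclic exchanges).
*delRNAs* match the mitogenome after systematic deletion of one (del3&ndash;1)
or two (del3&ndash;2) nucleotides after every retained trinucleotide; the
deletion pattern can start at any offset ("phase"), giving four del3&ndash;1
and five del3&ndash;2 transformations. A related phenomenon is translation by
*expanded codons*: tetracodons and pentacodons read three coding
nucleotides and skip one or two silent trailing nucleotides. Reading a
sequence by tetracodons is mathematically identical to first applying the
del3&ndash;1 transform and then reading regular tricodons — this equivalence
anchors several design choices below.

Peptides matching translations of these transformed genomes have been
reported in tryptic human mitoproteome MS/MS data. The analyses this
package implements interrogate such *detected-peptide populations*: if an
unbiased (no-enzyme) database search of a trypsin-digested sample recovers
an enrichment of K/R carboxyl termini, the detected population cannot be
dominated by false positives; if detected peptides preferentially map onto
independently detected non-canonical RNAs of the *same* transformation,
transcription and translation evidence corroborate each other.

The package provides four groups of tools:

1. **Genome transformations** (`swingerRules()`, `applySwinger()`,
   `delRules()`, `applyDel()`, `transformGenome()`, `projectToSource()`)
   with exact 0-based coordinate maps back to the source genome.
2. **Non-canonical translation** (`translateCodons()`,
   `translateAllFrames()`, `geneticCodeTable()`) under the vertebrate
   mitochondrial code (NCBI table 2), codon sizes 3–5, all frames of both
   strands, with stops rendered `X`.
3. **Database construction** (`trypsinize()`, `expandStops()`,
   `buildPeptideDatabase()`, `residueComposition()`): in-silico tryptic
   digestion, 19-fold stop expansion, length filtering, deduplication.
4. **Enrichment statistics** (`terminalBias()`, `trypticEnrichmentTest()`,
   `fisherCombine()`, `pearsonOneTailed()`, `mappingEnrichment()`,
   `nuclearCodeExpected()`, `stopInsertionBias()`,
   `trypticFractionSingleAlternative()`, `xcorr()`), plus a synthetic-data
   generator so every stage is testable without external data.

## The transformations

```{r rules}
length(swingerRules())
table(vapply(swingerRules(), isSymmetricRule, TRUE))
applySwinger("ACGT", "A<->C")
ts <- applyDel("ACGTACGT", delRule(1, 0))
transformedResidues(ts)
posmap(ts)
```

The 23 swinger rules are *defined* as all non-identity permutations of the
four letters. The symmetric/asymmetric census (9 + 14) only works out if
the six 4-cycles are included among the asymmetric exchanges, although the
X&rarr;Y&rarr;Z&rarr;X notation names 3-cycles; the enumeration therefore
covers the full symmetric group minus the identity, which is the only
reading that yields 23.

For del rules, the four del3&ndash;1 phases are offsets 0–3 and the five
del3&ndash;2 phases are offsets 0–4 (period = keep + skip). Residues before
the phase offset are retained verbatim; this convention makes phase p
correspond exactly to expanded-codon frame p (see below). Coordinates are
0-based and half-open throughout; `projectToSource()` returns the minimal
sorted set of source intervals for any transformed interval.

**Strand handling.** The genome is transformed once; the negative strand
is the reverse complement of the transformed sequence. For non-involutive
swinger rules this differs from transforming the reverse complement — the
package adopts the first convention because frames are taken "for each
strand" *of transformed sequences*; the alternative can be obtained by
composing `revComp()` with `transformGenome()` explicitly.

**Circularity.** Genomes carry a `circular` flag but transformations and
translation treat sequences linearly (no wrap-around codons). Wrap-around
would add at most one codon per frame on a 16.5 kb genome — negligible for
population statistics — and keeping coordinates linear makes the position
maps unambiguous.

**Ambiguity letters** pass through transformations unchanged (with a
warning); any codon whose three coding positions contain one translates to
nothing, with codon-start bookkeeping preserved for the residues that are
emitted.

## Translation and the expanded-codon equivalence

Expanded codons read only their first three nucleotides; the trailing one
or two positions are silent and fixed (not configurable), which is forced
by the del equivalence:

```{r equiv}
s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
expandedCodonEquivalence(s, skip = 1)   # del3-1 + tricodon == tetracodon
expandedCodonEquivalence(s, skip = 2)   # del3-2 + tricodon == pentacodon
```

One numerical choice matters here: a trailing codon is translated whenever
its three *coding* positions exist, even if its silent positions are
truncated by the sequence end. Under the alternative (requiring the full
block), the equivalence would fail for sequence lengths where the del
transform retains a final complete trinucleotide whose silent partner is
truncated. For a shifted phase p, the del-then-tricodon route (frame
p mod 3) carries &lfloor;p/3&rfloor; extra leading codons read from the
verbatim prefix; `expandedCodonEquivalence()` drops them before comparing.

Stops are rendered `X` in memory (writers can emit `*` behind a flag). The
built-in codes are NCBI tables 2 and 1; they differ at exactly AGA, AGG
(stop vs Arg), ATA (Met vs Ile) and TGA (Trp vs stop), i.e. 60/64 = 93.75%
identity. Initiator-codon special-casing is deliberately ignored: all
frames are treated uniformly, so ATA translates to Met everywhere under
the mitochondrial code.

```{r codes}
codeDifferences(geneticCodeTable("vertebrate_mitochondrial"),
                geneticCodeTable("standard_nuclear"))
```

## The peptide database

`buildPeptideDatabase()` runs the four analyses (del transforms with
tricodons; swinger transforms with tri-, tetra- and pentacodons),
translates all frames of both strands, trypsinizes every product, expands
stop-containing peptides 19-fold and deduplicates:

```{r db}
g <- randomGenome(2000, gc = 0.44, seed = 11)
db <- buildPeptideDatabase(g, analyses = c("del", "swinger_tri"))
nrow(db$database)
head(db$database[, c("sequence", "analysis", "rule", "frame", "strand")], 3)
```

Decisions a user should know about:

* **Trypsin rule**: cleavage after every K and R with *no* proline
  exception (matching "specific cleavage after K or R" literally); the
  Keil "not before P" variant is available via `prolineRule = TRUE`.
  Missed cleavages default to 0 and are configurable.
* **Stop expansion**: a peptide with at least one stop appears 19 times —
  once with stops rendered Leu (Leu/Ile being isobaric, one database entry
  stands for both) and once per replacement by each of the 18 remaining
  amino acids, applied uniformly to *all* stops of the peptide.
* **Length bounds** default to 6–50 residues, a typical MS-searchable
  range; the underlying study does not state its bounds.
* **Composition denominators**: `residueComposition()` counts residues
  over the *full* translation products, not over the trypsinized filtered
  database. Which of the two the original genome totals used is not
  derivable from the published counts, so both routes are available (pass
  database sequences instead of translation products for the second); the
  full-translation route is the default because the bias denominators are
  described as residue frequencies of complete transformed-genome
  translations. I and L are merged into one category (19 categories
  total); the stop marker is not a residue category.

## The statistical battery

Two chi-square conventions coexist, each frozen to its stage because each
is the convention under which the corresponding published p-values
reproduce exactly:

* `trypticEnrichmentTest()` — **two-cell** goodness of fit, df = 1, for
  K/R carboxyl-terminal enrichment;
* `mappingEnrichment()` — **one-cell** (O&minus;E)&sup2;/E, df = 1, for
  peptide-on-RNA mapping enrichment.

```{r stats}
tot <- referenceTotals()
tri <- tot[tot$analysis == "swinger_tri", ]
trypticEnrichmentTest(tri$tryptic_detected, tri$detected_total,
                      tri$tryptic_genome, tri$genome_total)$p.value
mappingEnrichment(33, 15.65)$p.value
fisherCombine(c(1/18, 0.17, 0.11, 0.11))$p.value
pFromR(0.446, 23)
```

`terminalBias()` divides each residue's frequency at the inspected
terminal position of detections by its frequency in the hypothetical
translations; residues with zero detections get bias 0 and stay in the
table (they are excluded from any log-based summary). The
genome-frequency-weighted mean of the biases is exactly 1 whenever the
detected total is the column sum — a conservation law the tests exercise.
`terminalBias()` also accepts an explicit detected total because published
count tables can carry printed totals that differ from their cell sums,
and every derived statistic then uses the printed total.

One-tailed Pearson p-values use the t transform
t = r&radic;(n&minus;2)/&radic;(1&minus;r&sup2;), upper tail: a negative r
gives p &gt; 0.5 by design (the alternative is positive association).
`fisherCombine()` refers &minus;2&Sigma;ln p to &chi;&sup2; with 2k df and
demands p &gt; 0: a zero p-value is an error, not &infin;.

`peptideMapsOnRna()` uses full containment of every peptide source
interval in the union of same-transformation RNA intervals; an
overlap-fraction relaxation is available via `minOverlap`. The
transformation identity matters: a peptide can only map on RNA of its own
transformation.

`nuclearCodeExpected()` computes &Sigma; 0.9375^k over detected peptide
lengths — the expected number of detections also compatible with the
nuclear code. The published formula prints a negative exponent, which
would make the expectation exceed N; since the quantity is a product of
per-residue probabilities below 1, the positive exponent is the only
self-consistent reading and is what the package implements. The
expectation is structurally below N for any shared fraction below 1.

`xcorr()` is the Sequest-style lagged dot product, provided as a
standalone utility only; spectrum matching, FDR estimation and posterior
error probabilities are out of scope — q and PEP are pass-through metadata
filtered by `filterDetections()` (q &lt; 0.05, Xcorr &gt; 1.99, applied
only where present).

## What the synthetic generator emulates

`simulateDetections()` emulates an unbiased search of a naturally
proteolysed sample: each detection is a random-cleavage sub-peptide of a
database entry (uniform entry, uniform carboxyl-terminal position from
residue 6 onwards, uniform length 6–30), so that under
`krEnrichment = 1` the carboxyl-terminal residue follows the background
residue frequencies — the correct null for the enrichment test. The
enrichment parameter &beta; acts as a *multiplicative odds factor* on K/R
termini, implemented by exact rejection sampling, so the recovered odds
ratio estimates &beta; directly. `nullTrypticFraction()` returns the exact
null K/R probability for a given database. `simulateCoverage()` mixes
standardized counts with independent Gaussian noise to reach a target
population correlation, then maps to coverage fractions and clips to
[0, 1]; clipping slightly attenuates the realized correlation, which the
tests absorb inside the Fisher-z interval.

Defaults are the study conditions: a 16,569 nt genome (the human
mitogenome length) at GC 0.44, per-analysis detection totals
148/106/127/105, a mapped fraction of 6.7% and a target correlation of
0.45 (the published tryptic swinger value). The default &beta; of 3 gives
enrichment of the magnitude the published biases show. One root seed
drives deterministic sub-stage seeds so stages can be re-run
independently.

What the generator does **not** emulate: mass spectra, retention times,
instrument noise, peptide length-dependent detectability, shared peptides
between transformations, or correlated residue usage along the genome.
Passing tests therefore show that the statistics recover planted
parameters under a clean sampling model — not that the pipeline is robust
to every artefact of real MS/MS data.

## Problem sizes used by the test suite

The suite exercises full databases on synthetic genomes of 0.15–2 kb
(which already produce tens of thousands of database entries for the del +
swinger-tricodon analyses), 1000 random sequences for the expanded-codon
equivalences, 2000 simulated null tables for the size of the enrichment
test (observed type-I error is required to stay within 0.06 at nominal
0.05), and 100 seeds for the power check at &beta; = 3, n = 127. The
desk-scale published statistics are recomputed from the bundled reference
tables in `inst/extdata/`.

## Known limitations

* The genome residue totals of the published count tables (e.g. 183,202
  for the del analysis) could not be rederived from first principles —
  whether they count full translations, the non-redundant database, or
  length-filtered entries is unstated. They are treated as inputs.
* The published tetracodon detected total (127) differs from its
  per-residue column sum (131); all published derived statistics use 127,
  so the bias table accepts an explicit total.
* Published per-residue stop-insertion biases are not exactly the ratio
  of the printed counts (a constant factor near 1.055 separates them);
  `stopInsertionBias()` implements the ratio as defined by its
  description, and the rank order (K, then Q, at the top) is what the
  tests assert.
* The published nuclear-code expectations per analysis require
  per-peptide lengths from supplementary data; only the formula and its
  distributional behaviour are tested.
* Negative-strand provenance coordinates (`start`, `end` of database
  entries) are reported in the reading coordinates of the minus strand
  (positions on the reverse complement); project through `posmap` after
  reflecting if plus-strand source intervals are needed.
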