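---
title: "Calling variant-junction associations from split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling variant-junction associations from split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svase)
```

# The problem

A substantial fraction of disease-causing mutations act by perturbing RNA
splicing, and A-to-I RNA editing can likewise create or destroy splice
sites. RNA-seq observes both signals at once: a read that spans an
exon-exon junction (a *split read*, aligned with an `N` gap in its CIGAR)
witnesses a specific splicing event, and the bases it carries on either
side of the gap witness the allele present on that transcript. `svase`
asks, for every junction and every substitution observed near it, whether
the alternative allele is statistically enriched among the reads that
support that junction — a *sequence variant associated with a splicing
event* (SVASE).

The caller deliberately uses **only split reads** for variant discovery.
General-purpose variant callers pool all covering reads, so their calls
cannot be attributed to one splicing event among several sharing a
boundary; restricting the pileup to junction-supporting reads, and
analysing the two sides of each junction independently, keeps the
attribution exact. Annotation is optional: junctions are discovered de
novo, and a provided annotation only adds known/novel labels, shift
detection and signal-model training data.

# The procedure

The stages run in a fixed order; every stage is a pure function of its
inputs, so runs are deterministic.

**1. Read QC.** Stringent rule-based filters reject unmapped records,
multi-mapping alignments (secondary/supplementary flags, plus a MAPQ floor
with default 1), PCR duplicates, QC-fail records, unpaired mates of
paired-end libraries, indel-containing alignments, reads with more than 3
mismatches, reads shorter than 30 bp, and reads whose *mean* base quality
is below Q30. Reasons are checked in a fixed order and tallied
exclusively, so the rejection report is reproducible. Base quality also
acts a second time: individual bases below Q30 are masked out of every
pileup and count downstream, while the read still supports its junction.
The threshold's dual role (whole-read gate plus per-base mask) is a
deliberate design choice: a read-level mean gate alone would let
error-prone bases seed false variants, while a mask alone would let
low-quality reads vote on junction existence. Both thresholds are
independently configurable in `qc_params()`.

**2. Junction discovery.** Each CIGAR `N` operation in a passing read
yields one junction observation keyed by its intron interval, recorded
0-based half-open — the single coordinate convention used everywhere
internally; conversion happens only at format boundaries (BED is native,
GTF/GFF/VCF are shifted on read/write). Both flanking anchors must be at
least 8 bp aligned; for multi-intron reads the inter-intron block serves
as the anchor of both neighbours. Depth counts distinct supporting reads,
and junctions below depth 3 are discarded. Mates of a pair spanning the
same junction count as two reads: after upstream deduplication they are
treated as independent molecules.

**3. Background-expression filter.** Junctions sharing an intron start or
intron end compete for the same splice sites. With `N` the pooled depth of
the junction and its related set and `b = ceiling(0.01 N)` background
reads, the junction is kept when the one-sided Fisher exact p of
`[[depth, N-depth], [b, N-b]]` is at most 0.05. A junction with no related
events faces no competition and is kept with p recorded as 0. The exact
2x2 construction for this filter was a genuinely open design point; we
test the junction's read share against a configurable background
proportion (default 1%) and isolate the construction in one function so
alternatives can be swapped.

**4. Known/novel classification and shift detection.** With an annotation
loaded, exact intron-interval matches are `known`; `keep_known = FALSE`
restricts all further analysis to novel junctions. A novel junction is
reclassified as a *shift* of a known intron when an identical-length known
intron sits within ±10 bp **and** the genomic sequence makes the two
placements indistinguishable (introns `[s,e)` and `[s+k,e+k)` splice
identically iff `genome[s,s+k) == genome[e,e+k)`). The smallest |offset|
wins, ties broken toward the positive offset. Shift events are alignment
artifacts, not biology, and are labelled so downstream counts can exclude
them.

**5. Per-side variant calling.** Each junction is split into its left
(5'ss-adjacent) and right (3'ss-adjacent) exonic parts. The pileup for a
part counts only unmasked bases from the anchor blocks of supporting reads
— not whole reads — which keeps the two parts genuinely independent and
matches where a split read's evidence actually lies. Candidates need depth
≥ 3, ALT reads ≥ 3, ALT fraction ≥ 0.1, and a one-sided Fisher p ≤ 0.05
against the sequencing-error expectation `[[alt, depth-alt], [e,
depth-e]]` with `e = round(0.001 * depth)` (the Q30 error probability;
configurable). Only SNVs are possible by construction since indel reads
were rejected upstream. Multiple ALT bases at one column are independent
candidates.

**6. Consistency and association.** For each candidate, ALT frequencies
are compared between target-junction reads and reads of the side-specific
related junctions (for a left-part variant, the junctions sharing the
intron *end* — the competing donors joined to the same acceptor — and
symmetrically for the right part). If the two-sided Fisher p exceeds 0.05,
or the related stratum has no coverage, the frequencies are *consistent*
and the association is assessed using the target junction's reads alone;
otherwise the pooled target-plus-related reads form the splicing-
supporting row. The association table contrasts that row against all
remaining covering reads (non-split reads, and related-junction reads in
the consistent branch), ALT vs REF; the one-sided p must be ≤ 0.05. When
no covering read falls outside the splicing-supporting row the variant is
junction-private: it is kept with p = 0 and a no-contrast flag, since
junction-private variants are the signal of interest, not noise. No
multiple-testing correction is applied by default (raw p ≤ 0.05 is the
method's convention); Benjamini-Hochberg is available via
`assoc_params(multiple_testing = "BH")`.

**7. Signal scoring and annotation.** Intron-terminal dinucleotides give
the motif class (GT-AG/+, its reverse complement CT-AC/−, the minor
GC-AG and AT-AC classes on either strand, else `other`) and the inferred
strand. Donor (9-mer: 3 exonic + 6 intronic) and acceptor (23-mer: 20
intronic + 3 exonic) windows are scored on the transcribed strand by a
first-order position weight matrix in log2 odds against a uniform
background. The scorer follows the standard window conventions of
maximum-entropy splice models but is deliberately a pluggable interface —
the PWM is trained on the provided annotation (or, absent one, on the
called canonical-motif junctions; pseudocount 0.25), and any scorer
honouring the window contract can replace it, including a wrapper around
an external maximum-entropy tool. Scores are **annotation only, never a
filter**: the ref-vs-alt score comparison is reported so users can see
whether a variant strengthens or weakens a site, but the published
observation that ref and alt score similarly is descriptive, not a gate.
For `other`-motif junctions, both orientations are scored, the better one
reported and flagged low-confidence. Source-type labels come from optional
DNA-mutation and RNA-editing site lists: allele-exact matches are labelled
as such (both labels when both match), position-only matches get the
weaker `position-known` (public dumps vary in allele orientation), else
`novel`.

**8. Reporting.** Every record carries its counts, the three p-values
(variant, junction background, association), signal scores, distances and
source type, and is written as TSV and VCF 4.2 (all INFO keys defined in
the header; REF cross-checked against the genome on write). Flanking
sequences (default ±50 bp, ref and alt versions) are exported as FASTA for
external splicing-regulatory-element tools. Summary tables mirror the
field's standard characteristics figures — junction depth and motif-class
distributions, ref/alt signal scores, distance histograms, the
substitution spectrum and the transition fraction — in `all` and
`novel`-only universes, with `autoplot()` conveniences.

# Distance conventions

Distances are reported on the genome strand with 1-based adjacency: the
exonic base immediately next to an intron boundary is at distance 1.
Because the caller may run without any annotation, "exon end" can only
mean the anchor-covered exon segment (from the junction boundary to the
farthest anchor base among supporting reads); distances to both ends of
that segment are reported. Measuring to annotated exon boundaries instead
is a documented alternative a user can compute from the BED output.

# The synthetic-data generator

`simulate_splice_reads()` writes a uniform-random multi-chromosome genome
with canonical splice motifs at planted introns, junction-spanning reads
with configurable anchor lengths and depths, planted variant alleles at a
configurable ALT fraction, non-split "decoy" coverage, base-call errors,
and optional QC-noise records (duplicates, secondaries, QC-fail,
low-quality, short). Reads are emitted as truthful alignments — the
generator writes the SAM an ideal aligner would produce — because the
artifact under test is the caller, not an aligner. Everything is
deterministic per seed, to the byte.

The default configuration **is** the package's reference validation
condition: one 1 Mb chromosome, 200 GT-AG junctions at depth 30 with
12-38 bp anchors, 50 junction-private plants at ALT fraction 0.9, error
rate 0.001, and 5 decoy reads per junction side. Depth 30 and ~200
junctions/Mb are typical of a moderately expressed transcriptome at
desk-scale; ALT fraction 0.9 models a near-homozygous variant or
high-efficiency editing site; 0.001 is the Q30 error rate the QC gate
assumes. Plants sit within 8 bp of the junction boundary so that every
supporting read and every decoy covers them — recovery then measures the
statistical engine, not coverage luck. Variant placement can instead be
`shared-with-related` (the ALT rides all junctions sharing the acceptor;
under the literal consistency-branch semantics such variants are usually
*not* called, since the target-only association loses its contrast — a
property worth knowing when interpreting real data) or `genome-wide` (the
ALT is uniform across junction and non-junction reads, modelling an
expressed genomic SNP, which the association test must reject).

What the generator does **not** emulate — realistic expression and
fragment-size distributions, sequencing-machine error profiles, alignment
artifacts other than boundary-shift ambiguity, allele-specific expression
— bounds what green tests mean: they validate the statistical machinery
and bookkeeping under idealised alignments, not performance on real
libraries, where aligner behaviour near junctions is the dominant error
source.

The truth table records, for every plant, the expected-detection flag
computed from configuration arithmetic alone (counts and the same Fisher
forms), and the test suite audits that arithmetic against an independent
enumeration oracle.

# Numerical choices

* All four tests use the exact hypergeometric tail (`phyper`/`dhyper`);
  the two-sided convention sums table probabilities ≤ observed × (1 +
  1e-7), matching `stats::fisher.test`. The test suite verifies agreement
  with an exhaustive `lchoose` enumeration over every 2×2 table with N ≤
  30 to 1e-9.
* Significance gates compare `p ≤ alpha + 1e-12`: tables lying exactly on
  the threshold (e.g. p = 1/20 at alpha 0.05, which the method's examples
  treat as passing) would otherwise be lost to floating-point
  representation of the tail sum.
* `p = 0` is a sentinel meaning "no competition/contrast", used by the
  background test (empty related set) and the association test (empty
  row 2); it always passes its gate and is flagged in the output.
* Degenerate Fisher tables (an empty margin) return p = 1.
* Shift ties between +k and −k break toward +k; offsets are scanned in
  order of |k| so the smallest compatible shift is reported.
* Iteration orders are fixed (coordinate sort everywhere); no stage
  samples, so byte-identical outputs follow from identical inputs.

# Problem sizes used in validation

The shipped tests and the acceptance script run the reference condition
above (~8,000 reads per run), ten plant-free replicates of it for the
specificity estimate, one genome-wide-placement run, a 20-intron
boundary-repeat fixture for shift detection, and a 30-junction
mirrored-genome run for the strand-involution property. These sizes give
binomial standard errors of a few percent on the recovery rates while
keeping a full validation run in minutes on one CPU core.

# Known limitations

* The read universe for association is the QC-passed alignment set;
  transcripts expressed below the depth/anchor thresholds are invisible.
* The literal consistency-branch semantics (target-only contrast when
  frequencies are consistent) means variants shared uniformly across
  related junctions are usually not reported; they are arguably real
  SVASEs of the junction *group*.
* Shift detection needs an annotation; without one, shift artifacts
  surface as novel junctions.
* The PWM signal model ignores positional dependencies a maximum-entropy
  model captures; scores are comparative annotation, not calibrated
  probabilities.
* Multi-sample joint calling, CRAM input, indel/MNV variants and
  transcript assembly are out of scope.
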