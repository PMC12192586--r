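---
title: "Methods: ABO genotyping from long-read amplicon pileups"
author: "abolong authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABO genotyping from long-read amplicon pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abolong)
```

## The model

The common *ABO* allele classes are separated by five diagnostic sites in
exons 6 and 7, indexed here both by 1-based exon offset and by
coding-sequence (cDNA) coordinate (cDNA = offset + 239 for exon 6, + 374
for exon 7):

```{r}
abo_positions()
allele_patterns()
```

A diploid genotype's expected state at a position is the union of its two
alleles' symbols — one symbol if homozygous, two if heterozygous. All 15
unordered pairs over the five alleles produce pairwise-distinct
five-position state vectors, so exact per-position set matching identifies
the genotype uniquely:

```{r}
head(rule_table("5snv")[, 1:10])
```

The classical three-position panel (c.261, c.796, c.803) collapses O1, O2
and O3 into a single O allele and cannot distinguish O2/O3 from A: an
O2-carrying heterozygote looks A-homozygous at all three sites. The
five-position panel's two additional sites (c.802, c.805) resolve exactly
those cases, which is why `classify_profile()` supports both modes — the
3-SNV mode exists to demonstrate what it gets wrong.

### Position calling: the allele-balance rule

At each diagnostic position the pileup yields fractions of A, C, G, T and
DEL over the covering reads. With depth ≥ `min_depth` (default 20), every
symbol whose fraction reaches `het_threshold` (default 0.20) is called.
Design choices here:

* **The 80:20 boundary is inclusive** — an exact 80:20 split is still a
  heterozygote. A `1e-9` epsilon guards the comparison, because a minor
  fraction arising as `1 - 0.8` in floating point falls one ulp short of
  `0.2`.
* **Three or more called symbols** make the position ambiguous and the
  sample `unknown` rather than an error: such samples exist in practice
  and are reviewed manually.
* **Precedence**: a position under the depth gate flags the whole sample
  `low_coverage`, which outranks `unknown` — the remedy for low coverage
  is repeat sequencing, not manual review.
* **The depth gate is per position**: the gating read count of a sample is
  the *minimum* depth across the panel positions of the mode in use. This
  is the conservative reading for clinical use: exon coverage may be
  uneven, and a well-covered exon 6 must not rescue an under-covered
  exon 7. The same minimum is used for the reliability tier (VeryLow < 20,
  Low 20–49, Moderate 50–499, Robust ≥ 500; the unnamed 50–499 band is
  labelled Moderate).

### Genotype matching

The called state vector is matched against the rule table by exact set
equality per position. A heterozygous call at one of the two linked
B-allele positions (c.796, c.803) without its partner matches no rule and
is reported `unknown` — biologically, the two variants travel together on
the B allele, so a lone heterozygous call there indicates either error or
a rare allele outside the panel's scope. Consequently, when the
allele-balance boundary is probed with an A/B mixture (as
`scripts/acceptance.R` does), the minor fraction is swept at both linked
positions jointly: at 80:20 the call is AB, at 81:19 the minor symbols
drop out and the call is AA.

## The aligner

Reads are aligned to each exon reference with an embedded
Smith–Waterman–Gotoh local aligner (Rcpp): match +2, mismatch −4, a gap of
length L costs 4 + 2L. An embedded aligner, rather than an external
mapper, keeps alignments fully deterministic and under test:

* the optimum cell is the first maximum in row-major scan order;
* traceback prefers diagonal over deletion over insertion;
* after traceback, single gaps are shifted left within homopolymer runs
  whenever the shift is score-neutral, so deletion columns are stable —
  in particular the c.261delG gap always lands on the diagnostic column,
  helped by the reference guard described below.

Alignments are discarded when identity (matches / aligned columns) falls
below 0.7 — tolerant of nanopore-scale error, rejecting junk — or when
the aligned span covers less than 90% of the exon reference. The coverage
filter is deliberately defined against the whole exon (the amplicon
target), not just the diagnostic window: local alignment of a read against
the *other* exon's reference routinely finds 8–15 bp micro-alignments at
high identity, and a 1 bp exon-6 window would accept them and dilute the
pileup. Both filters are exposed as arguments (`min_identity`,
`min_ref_cover`). Every read is aligned to both references and may in
principle contribute to both exons; with the coverage filter, cross-exon
assignments of amplicon reads do not occur in practice. The aligner's
scores are verified in the test suite against a brute-force dynamic
programming oracle and against `Biostrings::pairwiseAlignment()` under the
same scoring.

Pileups assign each aligned read exactly one symbol per covered reference
position — its base, or DEL where the alignment skips the reference base.
Insertions between reference positions create no columns, matching how
c.804dupG is tabulated: as a shifted readout (G instead of T) at c.805,
not as an insertion event. The O3 allele is accordingly modelled as a
substitution at exon-7 offset 431.

## Synthetic references and the read simulator

`build_synthetic_references()` generates stand-ins for the exon 6/7
regions of an A1-type reference allele: A-allele symbols at all five
diagnostic positions, uniform random bases elsewhere, default lengths 135
and 691 bp to mimic the real exon sizes. The bases flanking exon-6
offset 22 are constrained to differ from the base at 22, so the
single-base O1 deletion cannot be left-shifted away from its diagnostic
column — an ambiguity real references avoid only by luck. Real
NG_006669.2-derived exon sequences can be substituted via
`read_references()`; nothing downstream depends on the synthetic
composition.

The simulator emulates demultiplexed, per-exon amplicon FASTQ:

* **Deterministic allele assignment**: `round(n_reads * allele_ratio)`
  reads from the first allele. Expected fractions are exact, which makes
  the zero-error examples exactly checkable; biological sampling noise is
  deliberately absent.
* **Error model**: per base i.i.d. — deletion drops the base, insertion
  duplicates it (homopolymer-biased, as nanopore indels are), substitution
  draws uniformly from the three alternatives. Rates are capped at 0.3.
* **Read spans**: fraction of the exon drawn uniformly in
  `[min_span, max_span]`, default 1.0 (full-length amplicons). Reads that
  miss a diagnostic position are warned about, not rejected.
* **Base qualities** are a constant Q20 placeholder: the pipeline's
  quality filter uses mean quality only, and the upstream base caller's
  quality model is out of scope.

What the simulator does *not* emulate: realistic quality-score
distributions, context-dependent error hotspots beyond the duplication
bias, chimeric reads, barcode demultiplexing errors, or DNA-quality
effects (the dominant cause of low-coverage failures in buccal-swab
cohorts). Tests passing on simulated reads therefore demonstrate the
pipeline's logic — quantification, thresholds, rule matching — not the
wet-lab failure modes of real data.

A consequence of indel-type errors worth knowing: at c.261, alignment
absorbs a genuine deleted base whenever a nearby insertion error cancels
it (or merges it with an adjacent deletion error), so at 2% indel rates
the observed DEL fraction of a true heterozygote sits near 0.35–0.45 and
of a true O1 homozygote near 0.7, not at the nominal 0.5/1.0. The 20%
allele-balance threshold absorbs this comfortably at depth 100; it is the
reason the threshold must not be raised casually.

## Numerical and procedural choices

* Genotype labels follow the run-report convention: collapsed genotypes
  `AO`, `BO`, `OO`, `AA`, `BB`, `AB`; extended genotypes put the non-O
  allele first (`AO1`, `BO2`) and order O subtypes numerically (`O1O2`).
* In 3-SNV mode the O subtype is not resolvable, so the extended genotype
  equals the collapsed one.
* `aggregate_run()` writes every sample (with status) to the results
  table and only passing samples to `final_export.csv`; flagged samples
  are queued for repeat testing. A `timestamps = FALSE` switch makes all
  run outputs byte-stable for regression comparison.
* Concordance metrics are one-vs-rest per phenotype (sensitivity
  TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP)) over
  passing calls only; excluded samples are counted and reported.
* Problem sizes in the test suite — 100 reads per exon, seeds 1–5 for the
  15-genotype recovery sweep, 200 random pairs for the aligner oracle —
  were chosen as the smallest sets that exercise every genotype and both
  boundary conditions with clear margins.

## Known limitations

* Only the five-position panel: rare alleles (cis-AB, A1 vs A2 subtyping,
  O variants outside the panel) are out of scope and surface as `unknown`
  or as false A/B calls, exactly as on the three-position panel for O2/O3.
* The aligner is quadratic-time and sized for exon-scale references
  (≤ ~1 kb); it is not a general-purpose mapper. An adapter seam exists:
  any aligner that produces the gapped pair of strings per read can feed
  `build_pileup()`.
* Depth imbalance between exons is handled only by the per-position gate;
  no attempt is made to model why one exon under-amplified.
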