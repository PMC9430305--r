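---
title: "Methods: HML-2 LTR subtype discovery, motif profiling, and reporter quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HML-2 LTR subtype discovery, motif profiling, and reporter quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and design choices behind
`hml2ltr`. It is the package's own account of its methods; every number used
below is either a configured parameter or a quantity the test suite and
`scripts/acceptance.R` compute at run time.

## The problem

HML-2, the youngest clade of the human endogenous retrovirus K family, has
left hundreds of solo LTRs in the human genome. These fall into three
subtypes — LTR5A, LTR5B (the ancestral type), and LTR5Hs (the youngest) —
that differ in promoter strength. The package covers the computational
pipeline for characterizing that difference: finding LTR-like loci, screening
and classifying them, placing them on a subtype phylogeny, profiling
transcription-factor binding sites (TFBSs) in the TSS-proximal
enhancer/core-promoter fragment, associating elements with genes, designing
reporter constructs, and quantifying reporter/qPCR readouts.

## Coordinates and alignment primitives

**Coordinates.** Internally every interval is 0-based half-open. Printed loci
use the conventional 1-based inclusive `contig:start-end` form;
`format_interval()` is the only place the shift happens. BED output stays
0-based per the BED standard.

**TSS-relative frame.** The LTR frame is defined on the LTR5Hs reference:
position +1 is the first base of R, U3 occupies −792..0. Position 0 exists
and belongs to U3 — this is the only reading under which the printed section
pairs (−263 to 0) and (1 to 177) are adjacent and exhaustive. The four
canonical sections are 5Hs1 (−792..−553, 240 nt), 5Hs2 (−552..−264, 289 nt),
5Hs3 (−263..0, 264 nt, the enhancer/core-promoter fragment), and 5Hs4
(1..177, 177 nt).

**Alignment.** Global pairwise alignment (Needleman–Wunsch with affine gaps,
via Biostrings) with match +2, mismatch −1, gap opening 4, gap extension 1;
a gap of length L costs `open + L·ext`. These are standard nucleotide
defaults; identity statistics should always be read alongside the scoring
used, since the multiple-alignment settings behind published similarity
statistics are generally unpublished. N aligns freely (score 0 against
everything) but never counts as a match in identity. Gap-stripped identity
is matches over columns where neither row is gapped, ×100. Gap stripping is
per-pair, not across a multiple alignment; output consumers should note this
when comparing against MSA-derived statistics.

## Element discovery

The genome is indexed with all k-mers (k = 11) at stride 5, excluding
k-mers containing N and k-mers occurring more than 1,000 times
(repeat-heavy). The query consensus is scanned at stride 1 in both
orientations — indexing sparsely and querying densely is the scheme that
keeps the stated index density while maximizing sensitivity. Seeds on the
same contig and strand are chained when consecutive genomic gaps are ≤ 100
nt and the diagonal drifts by ≤ 50 nt; chains with ≥ 8 seeds become
candidates (a ~970-nt consensus yields ~960 query k-mers, so 8 seeds
tolerates heavy divergence while suppressing noise). Candidate spans are
padded by the consensus overhangs plus 10 nt and clipped to the contig.

Extension aligns the whole consensus against a local stretch of the padded
candidate (ends-free in the candidate), so padding never bleeds into the
reported boundaries. A candidate is discarded below 60% identity. Coverage
is the fraction of consensus positions aligned to element bases: ≤ 1,
insensitive to element insertions, sensitive to truncation. Overlapping hits
from different references (reciprocal overlap > 50%) collapse to the hit
with the highest identity × coverage; with consensus-position coverage this
correctly prefers the right subtype even when an insertion-bearing copy
aligns end-to-end against a shorter sister consensus.

Raw genome-wide hit counts from the original BLAT analysis are not a
reproduction target: they depend on BLAT's exact heuristics and on hg38.
The package's property target instead is exact recovery (recall = precision
= 1, coordinate error ≤ 5 nt) on seeded synthetic genomes with planted,
indel-free copies at ≤ 5% divergence, which the acceptance script measures.

## Screening and classification

The length screen keeps an element iff its length is ≥ 60% of its subtype
consensus length; it is a separate, idempotent stage, so classification
still works on sub-threshold fragments. Classification assigns the subtype
of the reference with the highest gap-stripped identity; ties break by
higher coverage, then by name order LTR5A < LTR5B < LTR5Hs (determinism for
tests).

## Phylogeny

Published subtype trees were built by maximum likelihood under K2+G with
NNI search. The gamma shape parameter behind K2+G is not published, so a
faithful ML reimplementation is not possible; the package instead uses K2P
distances + neighbor joining + nonparametric bootstrap. This is deliberate:
the scientific claim being checked is clade structure (LTR5Hs separated;
LTR5A nested within LTR5B), not branch lengths, and the distance approach is
deterministic and desk-scale. K2P distances use each pair's mutually
gap-free, unambiguous columns; saturated pairs (non-positive log arguments)
are set to a ceiling of 5.0 substitutions/site with a warning. Negative NJ
branch lengths are clamped to zero and flagged (standard practice).
Bootstrap support is the fraction of column-resampled replicate NJ trees
containing each original bipartition, reported in [0, 1].

## Motif profiling

Elements are anchored to the frame by global alignment (anchoring fails
below 60% identity, and failures are enumerated rather than silently
dropped); the anchoring map sends each frame position to an element position
or NA. A section is extracted as the element subsequence between the
outermost mapped section positions, and an element enters a section's
statistics only if ≥ 80% of the section's positions are mapped.

Motif matching is exact IUPAC-degenerate matching of single consensus
strings — not PWM scanning — because the biology under study contrasts
discrete alleles (e.g. GGGCTGG vs TGGCTGG); an N in the element matches only
an N in the motif. Presence is scored on the sense strand of the LTR.
Frequencies are per-subtype percentages of elements with ≥ 1 match in the
extracted section, rounded half-up to 2 decimals. Both the section-scoped
and the whole-LTR frequency can be computed; the section-scoped value is the
headline, matching how the motif profile of the third fragment is reported.
Conservation is summarized per column as information content 2 − H in bits
over A/C/G/T counts, without small-sample correction.

## Regulatory domains

The GREAT "basal plus extension" rule: each gene's basal domain is 5,000 bp
upstream and 1,000 bp downstream of its TSS (strand-aware); the extension
runs to the nearer of the neighboring gene's basal boundary, 1 Mb, or the
contig edge, and extended domains may still overlap other basal domains.
GREAT's curated regulatory domains cannot be reproduced without its internal
curation and are omitted. An element associates with every gene whose
extended domain contains the element midpoint (whole-element overlap is
available as an option); element strand is ignored, as nothing in the source
analysis indicates antisense elements were treated differently. Published
gene counts and Venn overlaps are annotation-snapshot-dependent and are not
reproduction targets; the oracle-checked rule itself is.

## Construct design

Chimeras replace the backbone subsequence homologous to a section (located
by anchoring) with the donor's section. Site-directed mutations replace an
exact occurrence of the wild-type site with the variant string
(TATAA→TGTAA, AGGGAAAAACCG→AGGGGAGAATGG, GGGCTGG→TGGCTGG, GGGCAGC→TGGCAGC,
TGTATGCATAT→ a 30-nt replacement); when the site occurs more than once the
operation refuses unless an occurrence is designated — silent off-target
edits are the classic cloning-design bug. Edits are ordered and coordinates
re-derived after each edit, so unequal-length edits compose; replaying the
edit list reproduces the final insert byte-for-byte, and the length delta is
book-kept. Vector backbone modelling, primers, and restriction checks are
out of scope.

## Assay quantification

Dual-luciferase: fold change = mean(firefly/Renilla) over a construct's
wells in a stimulus ÷ mean(firefly/Renilla) of the empty vector in plain
medium — the denominator is always the medium condition. Ratios are averaged
arithmetically (the formula averages ratios, not sums). qPCR: ΔCT = mean
CT(target) − mean CT(reference) per sample, ΔΔCT = ΔCT(treated) −
ΔCT(control), fold = 2^−ΔΔCT. ChIP-qPCR quantification is not specified in
the source; the default here is ΔΔCT enrichment over the negative-control
probe (the probe layout implies an NC-normalized design), with
percent-of-input as an alternative. The one-way ANOVA is the classical
fixed-effects test; no multiple-testing correction is applied, matching
per-comparison reporting. Error bars in the source are described only as
"standard errors"; where the package summarizes replicate spread it reports
SEM and says so.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, fixed once:

* **References.** A 970-nt LTR5Hs-like frame (U3 −792..0 + R/U5 1..177)
  carrying the wild-type TFBS alleles at fixed frame positions (NF-κB at
  −250, TP53-1 at −200, TP53-2 at −160, POU2F1 at −120, OCT4 at −100, TATA
  at −30, YY1 at −780); an LTR5B-like consensus derived from it at 10%
  substitution divergence with the variant alleles (983 nt); an LTR5A-like
  consensus derived from LTR5B at 5% (1,027 nt). Lengths mirror the
  representative loci. Chance near-matches (Hamming ≤ 1) to any registry
  motif are removed outside planted sites, plus exact occurrences of the
  5-mer TATAA, so motif presence is controlled by planting alone and the
  TATA edit is unambiguous on construct backbones.
* **Mutator.** Per-site substitutions with transition:transversion 2:1
  (consistent with the K2 model family), geometric indels (mean length 2) at
  a configurable rate, and a consensus→element coordinate map.
* **Curated set.** 704/828/256 raw elements per subtype of which 43/62/194
  are full-length; the rest are fragments truncated to 15–55% of consensus
  length (the raw-set length distribution is unstated anywhere, so the
  generator reproduces the survivor counts by construction). Substitution
  rates 0.0579/0.0884/0.0175 are back-computed from the reported mean
  identities of each subtype set to its consensus (94.21/91.16/98.25%).
  Motif planting happens after mutation: with probability p the site is
  written as the wild-type allele, otherwise as the variant; p equals the
  reported frequencies (TATA 46.51/79.03/98.45%; LTR5Hs NF-κB 73.71%,
  TP53-1 92.78%, TP53-2 93.30%, POU2F1 94.85%; extras YY1 0.90 and OCT4 0.95
  chosen as "conserved" placeholders). Planted motifs are independent, so
  co-occurrence is the product of margins (the reported TP53-1∧TP53-2 value
  sits within sampling error of it).
* **Genomes.** i.i.d. background at GC 0.41 (human-like) with planted,
  ~50% reverse-complemented copies at ≥ 1 kb spacing; default 6 copies
  (2 per subtype) at 3% divergence on 100 kb.
* **Phylogeny panel.** Equal-length (substitution-only, hence pre-aligned)
  leaves: an LTR5B radiation with two sub-lineages (0.04 + 0.04), an LTR5A
  clade branching from inside one of them (0.02 + 0.02), and an LTR5Hs
  clade at 0.10 from the root with tight within-group divergence (0.0175) —
  the topology the phylogeny stage should recover.
* **Plates and CT tables.** Per-well firefly/Renilla ratio = true fold ×
  baseline × lognormal(0, σ); CT values = baseline + sample shift + gene
  offsets + normal(0, σ_CT). At σ = 0 both estimators recover effects
  exactly.

What the generator does **not** emulate: real repeat landscapes (no
Alu/LINE decoys), sequencing reads, alignment-induced biases of a true
ClustalW MSA, correlated motif loss along the phylogeny (planting is
independent per element), and real luciferase plate artifacts (edge
effects, transfection batch effects). Passing tests therefore demonstrate
correctness of the computations under controlled conditions, not
performance on hg38.

## Numerical choices and degenerate inputs

* Alignment ties are resolved by Biostrings' deterministic traceback;
  scores are oracle-checked exhaustively on small instances.
* Percent values round half-up to 2 decimals (so 0.875 → 0.88).
* Saturated K2P pairs → ceiling 5.0 + flag; zero gap-free columns → error.
* ANOVA with zero within-group variance and unequal means returns F = ∞,
  p = 0 with a `degenerate` flag; identical groups return F = 0, p = 1.
* Empty subtypes are dropped from frequency tables with a warning; anchoring
  failures are enumerated in the extraction report.

## Statistical expectations and problem sizes

With n = 43/62/194 elements, a single generated set's motif percentages
scatter binomially around the planting probabilities (sd ≈ 7.6 points for
TATA at n = 43, ≈ 0.9 points for TATA at n = 194). Tests therefore compare
single-replicate counts against exact 99% binomial intervals, and the
acceptance script averages the frequency table over 12 replicate element
sets to report a stable estimate. For the noisy-plate property, the per-well
log-ratio sd of 0.1 implies a per-plate fold-estimate log-sd of
0.1·√(2/3) ≈ 0.082 at n = 3 wells, so individual plates land within ±10% of
the true fold only ~76% of the time; the stable, testable property is
central (median) recovery across many plates, which the suite checks over
500 seeded plates, and the acceptance script reports the measured per-plate
fraction alongside it. Default suite sizes — 100-replicate bootstraps,
500-plate recovery runs, 100-kb genomes — keep the whole suite at desk
scale.

## Known limitations

* The discovery stage is a desk-scale surrogate for BLAT, not a
  reimplementation; sensitivity on heavily diverged or heavily repeated real
  loci is untested.
* Subtype classification by best consensus identity can blur for elements
  whose within-subtype divergence approaches the between-consensus distance;
  the phylogeny stage is the arbiter in that regime.
* Pairwise (not multiple) alignment underlies identities and distances;
  statistics computed from an MSA would differ slightly.
* The frame is defined on the LTR5Hs reference; anchoring quality degrades
  for elements below ~60% identity to it, and those elements are excluded
  (and reported) rather than rescued.
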