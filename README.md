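# hml2ltr

Tools for characterizing the three long terminal repeat (LTR) subtypes of the
human endogenous retrovirus K family, HML-2 clade — **LTR5A**, **LTR5B**, and
**LTR5Hs** — and for quantifying the reporter experiments used to probe their
promoter activity.

Solo LTRs of HML-2 are scattered through the human genome and carry
enhancer/core-promoter elements. The three subtypes differ sharply in
transcriptional activity, and that difference maps to the TSS-proximal
fragment (positions −263..0 of the U3 region) and, within it, to the TATA box
and two p53 binding sites that are conserved in LTR5Hs but not in LTR5A/5B.
This package reimplements the computational side of that analysis as a
tested, reusable pipeline:

* **Element discovery** — BLAT-style k-mer seeded search of a genome against
  subtype consensus references (genome indexed with 11-mers at stride 5,
  query scanned at stride 1 in both orientations; co-linear seeds chained,
  candidates extended by alignment).
* **Screening and classification** — the ≥60%-of-consensus-length screen;
  subtype assignment by best gap-stripped identity
  (matches / gap-free columns × 100) under global alignment.
* **Phylogeny** — Kimura two-parameter distances,
  d = −½·ln(1−2P−Q) − ¼·ln(1−2Q) with P, Q the transition/transversion
  proportions; neighbor-joining topology; nonparametric bootstrap support
  from column resampling.
* **Motif profiling** — anchoring of every element to the TSS-relative LTR
  coordinate frame, extraction of the four canonical sections
  (−792..−553, −552..−264, −263..0, 1..177), exact IUPAC consensus scanning
  (TATAAA; NF-κB AGGGAAAAACCG; TP53-1 GGGCTGG; TP53-2 GGGCAGC; POU2F1
  TGTATGCATAT), per-subtype frequency, co-occurrence, and per-column
  information content.
* **Regulatory domains** — the GREAT basal+extension association rule
  (5 kb upstream / 1 kb downstream basal, extension to the nearest
  neighboring basal domain up to 1 Mb) and three-set Venn overlaps.
* **Construct design** — in-silico section-replacement chimeras
  (e.g. 5Hs3-5B), site-directed mutants (TATAA→TGTAA, GGGCTGG→TGGCTGG, ...),
  reverse-orientation inserts, and motif-content validation with full edit
  replay.
* **Assay quantification** — normalized dual-luciferase fold change
  (mean firefly/Renilla over construct wells in a stimulus ÷ the empty-vector
  medium baseline), 2^−ΔΔCT expression folds, ChIP-qPCR enrichment over a
  negative-control probe, and one-way ANOVA.
* **Synthetic data** — seeded generators for every input, with ground truth:
  subtype consensus references with planted TFBS alleles, curated-style
  element sets at configured motif frequencies, genomes with planted diverged
  copies, luciferase plates, and qPCR CT tables.

All real-genome inputs (hg38, Dfam consensus sequences) are replaced by the
synthetic reference set for testing; every synthetic object is labelled as
such in its identifier.

## Worked example

Generate the curated-style element set under the default study conditions,
apply the length screen, and profile the −263..0 fragment:

```r
library(hml2ltr)

rs <- hml2_reference_set()                 # synthetic LTR5A/5B/5Hs references
es <- simulate_element_set(rs, seed = 1)   # 704/828/256 raw elements

survivors <- length_screen(elements_as_hits(es), rs$refs)
table(vapply(survivors, function(h) h$subtype, ""))
#>  LTR5A  LTR5B LTR5Hs
#>     43     62    194

kept <- lapply(es$elements, function(l)
  l[es$truth$kept[match(names(l), es$truth$id)]])
secs <- lapply(kept, function(els)
  extract_sections(els, rs$frame_ref, rs$tss_index, ltr_sections()[3, ])$seqs)
tab <- motif_frequency_table(secs, default_motif_registry())
tab[tab$subtype == "LTR5Hs", ]
#>    subtype  motif n_total n_present percent
#> 11  LTR5Hs   TATA     194       193   99.48
#> 12  LTR5Hs  NF-kB     194       128   65.98
#> 13  LTR5Hs TP53-1     194       178   91.75
#> 14  LTR5Hs TP53-2     194       181   93.30
#> 15  LTR5Hs POU2F1     194       185   95.36
```

The screen keeps exactly 43/62/194 elements per subtype, and the motif
percentages scatter binomially around the generator's planting frequencies
(98.45 / 73.71 / 92.78 / 93.30 / 94.85% for LTR5Hs) — a single set of 194
elements carries a sampling sd of about 1–3 percentage points per motif.

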