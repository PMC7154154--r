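---
title: "Methods: identifying variants that act through TF binding at epigenetically stable regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying variants that act through TF binding at epigenetically stable regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varepi)
```

## The question the pipeline answers

When a pluripotent stem cell line and its induced derivative (for
example a BMP4-induced trophoblast culture) are whole-genome sequenced
as a pair, a few thousand SNVs and small indels separate the two
genomes. Most are inert. A variant becomes interesting when three
independent observations line up:

1. its local chromatin is **epigenetically stable** — the promoter mark
   H3K4me3 or the enhancer mark H3K27ac covers the site in *both*
   conditions, so an expression change at the nearby gene cannot be
   attributed to a local gain or loss of regulatory activity;
2. the **nearest-TSS gene is differentially expressed** between the two
   conditions;
3. the variant sits in a transcription-factor binding site, and
   **allele-aware motif rescoring** shows the alternate allele (the
   induced genome) binds an expressed TF more strongly than the
   reference allele.

A variant passing all three filters is the candidate mechanism: the
genomic change itself, not an epigenetic one, alters TF affinity and
thereby the gene's expression. `run_pipeline()` executes the whole
chain; each stage is also exposed as ordinary functions.

## Stage by stage

### Region annotation

Each variant (anchored at its first reference base, indels included) is
assigned one category with fixed precedence
`exonic > UTR5 > UTR3 > intronic > ncRNA_intronic > upstream >
downstream > intergenic`; up/downstream means within `flank` (default
1000 bp) of a TSS/TES in gene orientation, and introns of
noncoding-biotype transcripts are labeled `ncRNA_intronic`. Fold
enrichment of a category is the share of variants in it divided by the
share of the genome it occupies,
$r_c = (n_c/N)\,/\,(L_c/L)$, with genomic shares computed under the
same precedence. The substitution spectrum is reported over the 12
ordered substitutions or the strand-collapsed 6 classes. Distances to
the nearest TSS are signed in gene orientation (negative upstream) and
profiled in 50-bp bins over ±2500 bp; the bin width is not a quantity
with a canonical value, it is a display resolution, and it is
configurable.

### Epigenetic state and switch classes

A site's state for a mark in a condition is binary: inside any peak of
that mark (`A` for the activating marks H3K4me3/H3K27ac, `In` for the
repressive signals H3K27me3/DNA methylation) or outside (`I`/`T`). The
point predicate is `start <= pos < end` on the peak's half-open
interval. Pairing the two conditions gives switch classes (`A->A`,
`A->I`, `I->A`, `I->I`, and the repressive analogues). A variant is
**epigenetically stable** when H3K4me3 or H3K27ac is `A->A`; the
qualifying mark is recorded, and a variant stable under both is counted
once. Repressive-mark stability is not required by default (repressive
switches are rare in this design); `require_repressive_stable = TRUE`
adds the constraint. Peak-count profiles around variants use 100-bp
bins over ±2 kb, again a configurable display resolution.

### Differential expression

Expression arrives as TPM with replicates. Testing is per gene on
log2(TPM + 1) — the pseudocount handles zeros — with a pooled-variance
two-sample t-test and Benjamini–Hochberg adjustment across tested
genes. With the 2–3 replicates typical of these designs, per-gene
variance estimates are too unstable for Welch's correction: its
effective degrees of freedom collapse toward 2 and, in simulations at 3
replicates and σ = 0.3, cost roughly a quarter of the true positives.
Variance pooling is the simple analogue of the moderated
(information-sharing) tests the field standardly uses at such replicate
counts; `var_equal = FALSE` restores Welch's test for unbalanced noise.
Two presets mirror common reporting thresholds: `default` calls FC > 2
(or < 1/2) at FDR < 0.05; `strict` calls raw p ≤ 1e-5 and FC ≥ 4 (or ≤
1/4). Note that the fold change is computed on the pseudocounted scale,
so an underlying exactly-4-fold effect lands just *below* the strict
gate — the strict preset is for effects clearly beyond 4-fold.
Single-replicate tables degrade to fold-change-only calling with a
prominent message. Target-set overlaps report percentages rounded
half-up to two decimals, matching how such tables are conventionally
printed; the paired target-shift test compares per-gene mean
log2(TPM+1) between conditions with a paired t-test.

### Motif scanning and allele rescoring

PFM counts become natural-log log-odds weights with
$\hat p = (c + s)/(\sum c + 4s)$, pseudocount $s = 0.5$, against a flat
background by default (a genome-derived background may be supplied).
Scanning scores every offset on both strands (the minus strand scores
the reverse complement) and keeps the maximum, ties resolved to the
smallest offset then the plus strand. Two window sizes serve two
purposes: 150-bp windows (half-width 75) for the cohort-level
strong-hit counting and 12-bp windows (half-width 6) for rescoring
candidate variants. The two-condition reading is: the reference allele
window stands for the stem genome, the alternate allele window for the
induced genome, since the two genomes differ only at the variants; a
positive allele delta (alt − ref best-hit score) therefore means a
binding gain in the induced cells. TF results are gated on expression
of the TF's own gene (mean TPM ≥ 3, inclusive, via a user-supplied
TF-to-gene map; no fuzzy name matching), strong hits on motif score
≥ 10, and differential TFs additionally on |count difference| ≥ 10.
Because absolute motif-score conventions differ across scanners, the
score *scale* here (natural-log, pseudocount 0.5, flat background) is a
package convention; score differences and threshold behavior, not
absolute values, are the meaningful surface. Indel alternate windows
may be re-padded from the genome to the nominal width (`pad = TRUE`,
flagged) so scans near motif-width boundaries stay comparable.

### Candidate integration

Candidates are the intersection: epigenetically stable variant AND
differentially expressed nearest gene. The qualifying mark becomes the
candidate's "modification type". Rescoring then lists, per candidate,
every expressed TF whose alternate-allele best hit reaches the score
cutoff — the gate is deliberately on the alternate allele only, because
the question is which TFs can bind the induced genome; the reference
score and the delta are reported alongside. No restriction ties
enhancer-qualified candidates to non-promoter regions: the two
annotations are independent observations and both are reported. Reports
are two TSVs plus a JSON manifest stamped with the package version and
a configuration hash; identical inputs produce byte-identical files.

## The synthetic data generator

No deposited raw data is required: `generate_bundle()` builds a fully
self-contained cohort with known ground truth, sized so that a complete
end-to-end run takes well under a minute.

* **Genome**: 500 kb i.i.d. sequence at GC 0.41 (the human average).
* **Genes**: 50 non-overlapping multi-exon genes in equal slots, both
  strands, ~20% noncoding biotype, 30-bp UTRs on coding terminal exons.
* **Variants**: 1000 calls, 55% indels of length 1–5 (echoing the
  indel-heavy ratio of paired-genome calls), placed by rejection
  sampling inside painted category maps with intron-dominated weights,
  SNV classes drawn from a C>T-dominated spectrum (G>C rarest).
* **Peaks**: each variant's switch class per mark follows a plan whose
  defaults realize the reference bookkeeping — 46 promoter-stable and
  20 enhancer-stable variants in disjoint sets, 30/30 promoter and
  18/12 enhancer activation/deactivation switches, no repressive
  switches — with peak extents trimmed so a peak never covers a
  neighbouring variant, plus background peaks clear of all variants.
* **Expression**: per-gene baseline log2 TPM ~ Normal(3, 2) truncated
  at 0; each sample adds Normal(0, 0.3) log2 noise; planted
  differential genes shift by ±2 log2 units (4-fold). Planted genes
  take a baseline floor of log2 TPM 2: a fold change at a near-zero
  baseline is swallowed by the +1 pseudocount, and the genes these
  effects emulate — induced target genes — are expressed ones. The
  bundle uses 3 replicates per condition: a power calculation at 2
  replicates puts planted 4-fold effects at the edge of the FDR
  threshold (pooled t with 2 df), while 3 replicates detect them with
  ~97% sensitivity; `generate_expression()` itself defaults to 2
  replicates for null-calibration work where power is irrelevant.
* **Causal variants**: 6 clear-standing SNVs (5 promoter-stable, 1
  enhancer-stable, mirroring the typical promoter-heavy split) at
  pairwise distinct genes; their genes are forced 4-fold up, all other
  planted differential genes are drawn from genes *not* assigned to any
  stable variant, so "stable AND differential" identifies exactly the
  causal set and recovery can be scored as precision/recall. Each
  causal site gets a motif-consensus plant whose match the alternate
  allele completes and the reference allele breaks; the construction is
  verified algebraically at plant time (complete site at the PWM
  maximum ≥ 10, one-mismatch site < 10), so gains are separable at the
  cutoff by construction, not by luck. A further 12 sites for one TF
  give the differential-TF stage a planted count difference.
* **Motifs**: ten sharp toy PFMs of widths 6–15 (consensus count 18);
  with the default PWM settings the per-column consensus weight is
  ln(3.7) ≈ 1.31, so only motifs of width ≥ 8 can cross the strong-hit
  cutoff, and only widths 8–10 can guarantee a one-mismatch site below
  it — the plantable set.

All randomness flows through one seed; the same seed regenerates a
byte-identical bundle.

### What the generator does not emulate

Real peaks have signal shape, width distributions and replicate
variability; real variants cluster with mutational processes and
linkage; TPM noise is not i.i.d. lognormal and correlates across
genes; real motif libraries are soft and redundant; and nearest-TSS
assignment is only a proxy for regulatory targeting. Passing the
planted-recovery suite therefore demonstrates that the machinery is
correct and the filters compose as intended — not that the thresholds
would achieve the same precision on experimental data.

## Numerical and degenerate-input choices

* Coordinates: VCF positions are 1-based, BED intervals 0-based
  half-open; conversion happens at the I/O boundary. A variant emitted
  as a BED interval is `(pos - 1, pos - 1 + |ref|)`.
* Multiallelic VCF records are rejected loudly rather than split;
  paired-genome somatic callers emit biallelic records.
* Nearest-TSS ties break to the lexicographically smaller gene id;
  scan ties to the smallest offset, then the plus strand — all
  deterministic.
* Genes with zero TPM everywhere are excluded from testing and
  reported `ns`; identical values in both conditions give log2FC 0 and
  `ns` (no spurious zero-variance significance).
* An empty candidate list still produces header-only report files.
* The degenerate paired test (all per-gene differences zero) returns
  t = 0, p = 1 rather than NaN.

## A worked run

```{r, eval = FALSE}
bundle <- generate_bundle(sim_config(), seed = 11, out_dir = "bundle")
res <- run_pipeline("bundle", out_dir = "report")
nrow(res$stable)        # 66 epigenetically stable variants
res$candidates          # the 6 planted causal variants
res$tf_gains            # per-candidate TF gains, alt score >= 10
res$differential_tfs    # the planted count-difference TF
```

## Known limitations

The DE stage is a deliberately simple two-sample test, not an
empirical-Bayes moderated model; very small effect sizes at 2
replicates are out of its reach. DNA methylation input is consumed as
pre-called methylated-region intervals; per-CpG calls must be
aggregated upstream. Protein-level consequence annotation, external
variant databases, peak calling and target-list retrieval are out of
scope: the pipeline consumes calls, peaks and target lists, it does not
produce them.
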