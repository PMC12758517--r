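---
title: "Methods: sex-specific regulatory networks from single-nucleus multiome data"
author: "gonadGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific regulatory networks from single-nucleus multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

gonadGRN reconstructs sex-specific transcriptional regulatory networks from
joint single-nucleus RNA + ATAC data of a differentiating tissue. The
motivating system is the embryonic mouse gonad between E11.5 and E13.5, where
bipotential supporting-cell precursors commit to Sertoli (XY, testis) or
pregranulosa (XX, ovary) fates, but every stage of the pipeline is generic:
it needs matched gene-by-cell and peak-by-cell count matrices over the same
barcodes, per-cell metadata (declared sex, developmental stage, cell type,
QC metrics), a peak interval set, gene models with TSS coordinates, a genome
sequence, a motif library, and (optionally) histone ChIP interval tracks.

The analytical chain is:

1. **Per-cell QC** — strict gates on RNA library size (1,000–25,000 counts),
   mitochondrial fraction (< 25%), ATAC library size (1,000–100,000),
   nucleosome signal (< 2) and TSS enrichment (> 1).
2. **Computational sex verification** — a rank-based module score over the
   Y-linked genes *Kdm5d*, *Eif2s3y*, *Uty* and *Ddx3y*, plus ATAC fragment
   counts in the chrY peak region. Cutoffs are anchored at the most
   differentiated reference stage (E13.5): the XY cutoff is one standard
   deviation below the mean XY reference score, the XX cutoff one standard
   deviation above the mean XX reference score. A cell declared XY is removed
   only when it has **zero** chrY fragments **and** a score strictly below the
   XY cutoff; a cell declared XX is removed when it has **any** chrY fragment
   **or** a score strictly above the XX cutoff. Reference-stage cells define
   the cutoffs and pass through unfiltered — the source procedure is silent on
   whether they should be re-filtered, and leaving the anchor population
   untouched keeps the cutoffs interpretable.
3. **Differential testing per (cell type, stage), XY vs XX** — genes by
   two-sided Wilcoxon rank-sum (detection fraction ≥ 0.25, |log2FC| ≥ 0.25),
   peaks by a logistic-regression likelihood-ratio test (detection ≥ 0.01,
   |log2FC| ≥ 0.1 for between-sex contrasts; 0.05/0.25 for one-vs-rest
   cluster markers).
4. **Peak–gene linkage over the entire dataset** — for every peak whose
   midpoint lies within ±500 kb of a gene's TSS, the Pearson correlation
   between depth-scaled peak counts and log-normalized expression across all
   cells, standardized against 200 background peaks matched on GC content,
   mean accessibility and width; links with two-sided normal p < 0.05 are
   retained, positive and negative.
5. **DEG categorization and stage transitions** — each DEG is exactly one of
   *linked DAP* (≥ 1 significantly linked peak is a DAP of the same
   contrast), *linked non-DAP* (links exist, none to a DAP), or *no linked
   peak*. Transition flows between consecutive stages are counted per gene;
   the *newly formed linked-DAP* peak set at the later stage collects the
   DAPs linked to genes that enter the linked-DAP category there, excluding
   genes already in that category earlier, with peaks deduplicated.
6. **Chromatin profiling** — midpoint-based annotation of peaks to promoter
   (TSS ± 3 kb) > exon > first intron > other intron > downstream (≤ 3 kb) >
   distal intergenic; per-cell summed accessibility in peak sets; histone
   mark overlap percentages (a DAP is mark-positive if it overlaps a ChIP
   interval by ≥ 1 bp) and bivalency (overlap with both H3K4me3 and
   H3K27me3).
7. **Motif network** — JASPAR-format PFMs are converted to log2-odds PWMs,
   scan thresholds come from the exact discretized null score distribution at
   tail mass 1e-4, both strands are scanned, enrichment of DAPs linked to
   DEGs against GC/accessibility-matched background peaks is tested with the
   hypergeometric upper tail (pass: BH-adjusted p < 0.05 and fold > 1.25),
   chromVAR-style per-cell deviations quantify motif activity, and TF→target
   edges connect each enriched motif whose TF gene is itself a focal DEG to
   every gene significantly linked to a motif-bearing focal DAP, signed by
   the link. The co-occurrence matrix counts distinct shared target genes per
   TF pair (a peak-sharing variant is available via `scope = "peak"`).

# Statistical cores and their conventions

**Wilcoxon rank-sum.** For group sizes both ≤ 25 the two-sided p-value is the
exact permutation probability `P(|W − μ| ≥ |w_obs − μ|)` computed by a
tie-aware shift algorithm (dynamic program over doubled mid-ranks); larger
groups use the normal approximation with tie correction and no continuity
correction. The exact branch reproduces full enumeration for all splits with
n₁+n₂ ≤ 10, including the classic separated 4 vs 4 case (p = 2·4!·4!/8! =
0.0286).

**Likelihood-ratio accessibility test.** Logistic regression of group
membership on a peak's normalized accessibility, fit by iteratively
reweighted least squares; the statistic is the null minus residual deviance
on 1 df. Complete separation can converge quietly with residual deviance → 0,
so it is detected from the deviance itself and flagged; the statistic is then
capped at the null deviance, its natural bound.

**Fold changes** are computed on de-logged normalized values
(`2^v − 1` before group means, pseudocount 1 in the ratio). Averaging the
log-transformed values directly would double-log the effect: a planted
twofold change appears as ≈ 0.25 rather than ≈ 1 on that scale and the 0.25
gate becomes a coin flip.

**Multiple testing.** Bonferroni for DEG/DAP calls with the total feature
count of the matrix as denominator (features failing the pre-filter still
count); BH across motifs for enrichment. The choice of Bonferroni matches the
default of the tooling family this pipeline mirrors; it is a documented
convention, not a claim about optimality.

**PWM scores.** Column probabilities are
`(count + 4·pseudocount·background) / (colsum + 4·pseudocount)` (default
pseudocount 0.8, uniform background), log2 odds against the background. The
scan threshold is the smallest discretized score whose exact null tail mass
is ≤ p (default 1e-4, resolution 0.001). Per-column scores are discretized
with **ceiling**, which makes the threshold conservative with respect to
full-precision scanning: with plain rounding, windows whose continuous score
sits just below the binned threshold leak through and the realized tail mass
can exceed the nominal p several-fold. When no score reaches tail mass ≤ p
(an uninformative matrix), the threshold falls back to the maximal achievable
score so a perfect consensus still matches.

**Module score.** Per cell, genes are ranked by descending expression with
average ranks for ties and ranks capped at `r_max`;
`score = 1 − (Σ min(rank, r_max) − |S|(|S|+1)/2) / (|S|·r_max)`. The score is
invariant under any monotone transform of the cell's expression vector. The
default cap of 1,500 presumes a transcriptome-scale panel (~20k genes) where
undetected genes are tied far beyond the cap; on small panels the pipeline
scales the cap to 65% of the panel size so that the tied rank of undetected
genes stays above it — otherwise cells with different dropout counts get
slightly different scores for an all-zero signature and the ±1 SD sex-filter
cutoffs would clip honest cells.

# The synthetic multiome generator

`simulateMultiome()` is first-class, tested code, and the package's primary
validation instrument. It emulates:

- a (sex × stage × cell type) grid of cell groups (defaults: XX/XY ×
  E11.5/E12.5/E13.5 × epithelial/presupporting/Sertoli/pregranulosa,
  85 cells per group ≈ 2,040 cells);
- negative-binomial RNA counts (dispersion 0.3) and Poisson ATAC counts with
  lognormal per-cell size factors, column-calibrated so each cell's expected
  library equals its size factor times the configured mean (5,000 RNA /
  10,000 ATAC);
- cell-type marker programs (8× rate multipliers; canonical names such as
  *Amh*/*Sox9* and *Fst*/*Foxl2* when those cell types are configured);
- sex-specific DEGs and DAPs planted per cell type as symmetric ±log2FC/2
  rate multipliers (default log2FC 1) — DAPs mix gained and lost
  accessibility, as observed in the motivating system;
- peak–gene coupling: half of each DAP set is linked to a target gene within
  500 kb of its TSS via a per-cell standard-normal latent activity factor
  **per target gene**, loading 0.6, negated on the peak side for negative
  links (25% of links). One factor per gene rather than per link: genes that
  attract several linked peaks would otherwise accumulate variance without
  bound and drown their own planted differential effect, which no real
  transcriptome does. The 0.6 loading makes coupling noise comparable to
  counting noise; it still yields essentially perfect link detection at the
  default scale while leaving the planted fold changes detectable;
- Y-linked genes and one chrY peak with exactly zero counts in XX cells and
  guaranteed nonzero counts in XY cells;
- motif consensus sites substituted into linked DAPs (planting rate 0.8) on
  a uniformly chosen strand and offset, wholly inside the host peak. The
  built-in library holds three strongly informative GC-balanced 10-mers whose
  names double as TF gene ids; GC balance matters because the scan threshold
  assumes a 0-order uniform background, and an AT-rich consensus on AT-rich
  sequence blocks would inflate the spontaneous hit rate several-fold above
  the nominal tail mass. TF genes are assigned high base expression (90th
  percentile of the lognormal expression prior): their real counterparts are
  abundant lineage regulators, and a TF drawn at the prior's low tail would
  silently drop every one of its edges;
- histone ChIP tracks covering a configured fraction of each DAP set
  (defaults 40% H3K4me3, 10% H3K27me3, 50% H3K27ac) plus decoy intervals
  that never touch peaks;
- full ground-truth tables for DEGs, DAPs, links, motif sites, network edges
  and histone membership.

All randomness derives from one seed through named substreams, so identical
configurations are byte-identical end-to-end while components stay isolated.

**What the generator does not emulate:** doublets, ambient RNA, batch
effects, trajectory structure, fragment-level ATAC data, realistic gene
structure (three schematic exons per gene), higher-order sequence
composition, or correlated motif co-occurrence. Passing the validation suite
therefore demonstrates that the implementation recovers the structures it
claims to recover under the stated statistical model — not that the defaults
reproduce every property of real multiome data.

# Null calibration and a compositional caveat

With all planted effects at zero, raw p < 0.05 rates for the Wilcoxon, LR and
linkage tests sit within three binomial standard deviations of 5%, and
chromVAR deviations under permuted annotations have |mean z| < 0.2. One
subtlety: the calibration contrast is a random split **within** one sex. An
XY-vs-XX contrast is not a clean null even with zero planted effects, because
Y-linked expression changes the library composition — depth normalization
then shifts every autosomal gene slightly between sexes, and with hundreds of
cells per group the rank test legitimately detects it. This is the classic
compositional artifact of library-size normalization, reproduced faithfully
rather than hidden.

# Problem sizes and numerical choices

The validation suite exercises: oracle equivalences at widths ≤ 6 and group
sizes ≤ 10 (exact enumeration); null calibration at 200 features × 400 cells;
parameter recovery at the default ≈ 2,000 cells, 500 genes, 2,000 peaks with
100 background peaks per link and 25 chromVAR background sets; determinism on
a compact two-cell-type configuration. These sizes were chosen so that a full
run of the generator plus every downstream stage completes in a few minutes
on a single core while keeping ≥ 50 planted effects per recovery rate.

Degenerate inputs are handled explicitly: zero cells yield a structured empty
dataset; constant features are skipped with a reason (linkage) or give
statistic 0 / p 1 (LR); empty gene annotation labels every peak distal with a
warning; an empty DAP set makes an overlap percentage undefined and is an
error; ties at a QC or sex-filter boundary resolve to "keep" because the
removal rules are stated as strict inequalities.

# Known limitations

- The LR test uses accessibility as the sole covariate; latent covariates
  (depth, batch) are out of scope.
- Linkage background matching uses nearest neighbours in a standardized
  3-feature space; the reference tooling's exact matching algorithm is
  unpublished, so calibration (not equivalence) is the tested property.
- Motif enrichment defaults to DAPs linked to DEGs as targets, following the
  documented workflow of the motivating study; an all-DAP target set is
  available through the function arguments.
- The co-occurrence matrix counts shared target genes; same-peak co-binding
  is a different (also implemented) reading.
- Peak annotation is midpoint-based; peaks straddling feature boundaries get
  a single unambiguous label by construction.
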