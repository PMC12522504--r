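---
title: "Promoter-anchored 5'-end RNA-seq analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-anchored 5'-end RNA-seq analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfeseq)
```

## The problem

During the maternal-to-zygotic transition (MZT) an oocyte's maternally
deposited transcripts are degraded while the embryo's own genome is
activated (embryonic genome activation, EGA; the 8-to-16-cell transition in
bovine embryos). 5'-end sequencing protocols that capture the capped 5'
ends of poly(A)-tailed RNAs, tag molecules with unique molecular
identifiers (UMIs) and add exogenous spike-in RNA at a known molecule input
make it possible to follow this handover quantitatively: absolute molecule
numbers, promoter-level resolution, and normalization that does not assume
stable endogenous genes (total RNA content changes several-fold across the
MZT, so library-size normalization would be badly misleading).

`tfeseq` implements the downstream analysis as a tested pipeline. Its
quantification unit is the **TFE** (transcript far 5'-end): a
strand-specific cluster of deduplicated read 5'-end positions, standing in
for one active transcription start site (TSS) region. Everything
downstream — normalization, variable-TFE selection, differential
expression, marker calling, clustering, promoter extraction — operates on
the TFE-by-sample UMI count matrix.

## Pipeline model

1. **Deduplication.** Reads sharing (sample, chromosome, strand, 5'
   position, UMI) are PCR copies of one molecule; one event per tuple
   survives. There is no cross-sample collapsing.
2. **TFE calling.** Deduplicated events are pooled over all samples and
   single-linkage clustered per chromosome and strand: positions at most
   `max_gap` (default 60 bp) apart join a cluster; clusters with fewer than
   `min_count` (default 2) pooled events are dropped. A cluster becomes the
   region `[min, max + 1)` with its *summit* at the modal position (ties
   resolve to the farthest-5' mode). Pooling before calling yields one TFE
   catalogue for the whole experiment, so counts are comparable across
   stages. Published TFE pipelines define the unit through transcript
   assembly (reads on assembled first exons); the clustering rule used here
   is a deliberately simpler surrogate with the same intent, and its two
   parameters are exposed.
3. **Annotation.** Each TFE summit is classified against same-strand gene
   models into nine positional categories (coding upstream/5'-UTR/CDS/
   3'-UTR, noncoding upstream/1st exon/other exon, intron, unannotated),
   merged to six for reporting. Priority runs from the most promoter-like
   label down (5'-UTR before upstream before CDS ...), because the method
   is promoter-centric. "Upstream" means within `upstream_bp` (default
   500 bp) 5' of a model's TSS.
4. **Normalization.** Size factors are median-of-ratios computed on
   spike-in rows only (medians taken in log space, so an even number of
   spike-ins averages the middle ratios geometrically — this matches the
   DESeq2 estimator restricted to control genes, up to a rescaling to
   geometric mean one). Log2 normalized values are
   `log2(count / (size_factor * S_ref))` with `S_ref` the mean spike-in UMI
   total per sample. On this scale 0 is one spike-in-input-equivalent, so a
   value `v` estimates `2^v * M` molecule copies when `M` spike-in
   molecules were loaded per sample; with the default `M = 9216` a value of
   −10 is exactly 9 copies, the operational "expressed" threshold. Zero
   counts map to the sentinel `-Inf` (no pseudocount), which compares below
   any finite threshold; a pseudocount-1 variant exists for correlation and
   clustering inputs, a light variance-stabilization proxy.
5. **Relative poly(A) content.** Per sample, the endogenous mapped total
   divided by the spike-in total; averaged per stage, scaled so the
   reference stage (GV) is 1. Spike-ins are excluded from the numerator
   because the quantity of interest is endogenous RNA.
6. **Technical noise and variable TFEs.** The squared coefficient of
   variation of spike-ins follows `CV2_tech(mu) = a1/mu + a0`, fitted by a
   gamma GLM with identity link on (1/mu, CV2) (ordinary least squares as a
   logged fallback if IRLS fails). A TFE's excess variability is tested
   with `T = (n-1) CV2 / CV2_tech(mu)` against a chi-square with `n-1`
   degrees of freedom; the top `K = 20000` TFEs by CV2 among those with
   BH-adjusted p < 0.05 feed sample correlation and clustering.
7. **Differential expression.** For each consecutive stage pair (MII|GV,
   2c|MII, ..., Blc|16c), a negative binomial Wald test on normalized
   counts: group means (a zero mean is replaced by half the smallest
   positive normalized count so fold changes stay finite), per-TFE
   dispersion by method of moments pooled within groups and floored at
   1e-8, delta-method standard error, and a **t reference with
   n1 + n2 - 2 degrees of freedom**. This is a declared simplification of
   DESeq2: no dispersion-trend shrinkage, no LFC shrinkage, no independent
   filtering, no outlier handling. Two estimator details matter and were
   chosen on statistical grounds: (i) with the dispersion estimated from so
   few residual degrees of freedom a normal reference is anticonservative,
   and the t reference restores type-I control at typical replicate
   numbers; (ii) the zero-mean offset enters the point estimate only — an
   all-zero group contributes zero plug-in variance, which preserves power
   for on/off contrasts such as stage-exclusive markers.
8. **Stage-exclusive markers.** Per-stage medians of log2 values (sentinels
   propagate as −Inf); a TFE is a marker of stage S when its median is
   strictly above −10 in S, strictly below −10 in every other stage, and it
   is significantly upregulated (BH p < 0.05, LFC > 3) against the
   preceding stage. The first stage (GV) has no predecessor and is tested
   against MII instead (upregulation appears as a significant negative
   fold change in the MII|GV contrast). The default marker stages are GV,
   MII, 16c and Blc; the cleavage stages are transcriptionally too similar
   for exclusivity to be meaningful, but any subset can be requested.
9. **Temporal clustering.** Row-z-scored values of the selected TFEs are
   clustered with seeded k-means (k = 6, 1000 restarts, 20 Lloyd iterations
   per restart, best within-cluster sum of squares kept). The
   implementation is a thin Lloyd loop because reproducibility required a
   single seeded restart stream, an explicit empty-cluster repair (reseed
   at the farthest point) and an iteration WCSS trace for testing; it is
   cross-checked against `stats::kmeans` on separable data. Clustering runs
   on sample-level scaled values by default; stage medians can be
   substituted upstream.
10. **Promoters.** Windows of 400 bp upstream and 100 bp downstream are
    anchored on the TFE summit ("downstream" includes the anchor base, so
    an unclipped window is exactly 500 bp); minus-strand windows are
    mirrored and their sequences reverse-complemented. The BED and FASTA
    outputs are direct input for external motif-discovery suites; motif
    discovery itself, and deep-learning-based TSS noise filtering, are out
    of scope.

## The synthetic experiment

The generator (`sim_config()`, `simulate_experiment()`) is first-class,
tested code: it defines the conditions under which every statistical
guarantee of the package is demonstrated. Defaults describe a miniature
MZT study: seven ordered stages (GV, MII, 2c, 4c, 8c, 16c, Blc) with four
samples each; ~2,000 transcription units (1,400 coding, 600 noncoding,
plus 10% unannotated extra units expressed but absent from the GTF) on
four 1.6-Mb chromosomes; 50 spike-in references carrying 9,216 molecules
per sample in a ~3-decade dilution series.

Expression classes: maternal genes decay multiplicatively with cumulative
per-stage factors (1, 1, 0.35, 0.9, 0.9, 0.5, 1) — the two large drops
after fertilization and at the 16-cell stage; zygotic genes switch on at
the 16-cell stage; housekeeping and unannotated units are flat; 20 marker
genes per stage are expressed in exactly one stage. Stage totals are
rescaled to the content multipliers (1, 1, 0.8, 0.65, 0.55, 0.35, 0.75),
a decline-to-EGA-then-recover shape chosen qualitatively, not a measured
series. Molecule counts are negative binomial with biological CV2 = 0.1
around stage means; capture is binomial with efficiency 0.2 (a realistic
single-oocyte capture rate); each captured molecule emits one event at the
true TSS with Normal(0, 5 bp) positional jitter and a random 8-mer UMI;
PCR duplication replicates whole event tuples at an expected rate of 1
extra read per molecule.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and base qualities, mappability
and multimapping structure, internal priming artifacts, transcript
assembly ambiguity, within-embryo cell heterogeneity, batch effects, and
any real spike-in mix composition. Parameter-recovery results (content
multipliers to within ±10%, marker sensitivity ≥ 0.95 at FDP ≤ 0.05,
≥ 99% of callable TSS loci recovered as single TFEs) are statements about
this generative model at this depth, not about any particular biological
dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF (1-based closed) is
  converted at the boundary, BED is written natively.
* The `-Inf` sentinel makes "not expressed" exact under any finite
  threshold and propagates through medians the way an order statistic
  should; it is refused by `value_to_copies()` and by correlation (which
  requires the pseudocount variant).
* Summit ties break toward the farthest-5' mode; gene-model transcript
  ties break by lexicographic transcript id; variable-TFE ties break by
  TFE ordinal id — every ordering in the pipeline is total, which is what
  makes reruns byte-identical.
* The dispersion floor (1e-8) keeps the Wald SE finite for underdispersed
  rows; all-zero rows give LFC 0 and p 1 rather than NA.
* Empty inputs return empty, typed results (`call_tfes` on no events, a
  marker stage with no hits); genuinely unusable inputs (all-zero spike-in
  sample, unsorted event file, window outside its chromosome) are errors
  that name the offender.

## Problem sizes in the checks

The packaged checks run the full pipeline twice at the default scale
(~2,000 units, 50 spike-ins, 28 samples, ~2.5 million read events) for
byte-reproducibility, plus oracle comparisons on 1,000 randomized small
clustering instances and simulation-based calibration of both tests
(10,000 null TFEs for the variability test; 2,000 TFEs at 4 vs 4 for the
Wald test). These sizes keep a complete run of the suite to a few minutes
on one CPU while leaving every estimate's Monte-Carlo error well inside
the asserted bounds.

## Known limitations

* The TFE caller is a clustering surrogate for assembly-based first-exon
  filtering; very closely spaced alternative TSSs (< `max_gap` apart)
  merge into one TFE.
* Spike-in-only size factors inherit spike-in pipetting noise; with few
  spike-ins the median-of-ratios estimate is coarse.
* The NB test's method-of-moments dispersion is noisy at n = 4 per group;
  the t reference compensates on average but individual standard errors
  remain rough compared to shrinkage estimators.
* `value_to_copies()` assumes capture efficiency affects endogenous and
  spike-in molecules equally; protocol-specific capture biases are not
  modelled.
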