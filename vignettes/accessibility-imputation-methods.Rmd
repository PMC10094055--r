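---
title: "Methods: accessibility-based dropout imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accessibility-based dropout imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiImpute)
```

## The model

Dropouts are zeros in an scRNA-seq count matrix caused by failure to capture
an expressed transcript. `epiImpute` rescues them with evidence from a
*matched* scATAC-seq experiment: if a gene's regulatory elements are open in
the chromatin of a cell population, the gene is plausibly expressed there,
and its zeros in that population's cells are likely technical.

Let $X \in \mathbb{N}^{G \times C}$ be the raw expression matrix, $t(c)$ the
annotated cell type of cell $c$, and $A \in [0,1]^{G \times T}$ a per-type
*population activity* matrix derived from ATAC fragments. The imputed matrix
is the additive update

$$\tilde X_{gc} = X_{gc} + A_{g,\,t(c)}.$$

Because the added term is constant within a cell type, the update never
reduces a count, preserves the within-type ranking of every gene, and gives
$\tilde X - X$ a block structure of rank at most $T$.

## From fragments to activity

1. **Tn5 offset correction.** Fragment starts are shifted $+4$ bp and ends
   $-5$ bp (`tn5_shift()`), because the Tn5 transposase inserts its two
   adaptors 9 bp apart. Files that already carry the offsets (the 10x
   convention) are read with `shifted = TRUE` and are never shifted twice.
2. **Counting windows.** Promoters get a strand-aware $-500/+200$ bp window
   around the TSS (`promoter_window()`; coordinates are 0-based half-open
   throughout, and the TSS of a "−" record is `end − 1`). Enhancers shorter
   than 700 bp are replaced by a 700 bp window around their midpoint; longer
   ones are used as-is. Fragments with a MAPQ column are kept only if
   MAPQ $> 30$; a fragment counts in every window it overlaps
   (`count_fragments()`).
3. **Per-cell noise threshold.** Blacklist regions carry no true regulatory
   signal, so the per-bp fragment rate a cell shows there estimates its
   background. The threshold vector is
   $\theta_c = \mathrm{rate}_c \times 700\,\mathrm{bp}$
   (`build_threshold_vector()`); an element is *open* in cell $c$ iff its
   value is strictly above $\theta_c$.
4. **Normalization.** Element counts are quantile-normalized with a smooth,
   group-aware reference (`smooth_quantile_normalize()`): per rank, the
   reference blends the cell-type-specific quantile and the global quantile
   by the between-type share of variance, so genuine biology between types is
   kept while technical depth differences are removed. A binned GC step
   (`gc_normalize()`) then equalizes per-cell means across equal-frequency GC
   bins. Crucially, the raw threshold vector travels through both transforms
   as a pseudo-element row (`normalize_with_threshold()`), so threshold and
   signal stay on one scale.
5. **Gene activity.** A gene's accessibility is the maximum margin
   (value − threshold) over its promoter and linked enhancers — the gene's
   open call is the OR of its elements' calls — mapped to a probability with
   a sigmoid $\sigma(k \cdot \mathrm{margin})$. By default $k$ is calibrated
   as $4/\mathrm{median}(\text{positive margins})$, placing a typical open
   gene near activity $0.88$; activity $> 0.5$ is exactly the strict open
   call.
6. **Aggregation.** Per cell type, the population activity is the median over
   cells. The pipeline default (`binarize_before_median = TRUE`) thresholds
   activities at 0.5 first, so the aggregate is the median *open state*:
   genes closed across a population contribute exactly 0 and true zeros are
   never converted into spurious expression. Set it to `FALSE` to aggregate
   the continuous probabilities instead (every entry then receives a small
   positive term).

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `flank_up` / `flank_down` | 500 / 200 bp | canonical promoter window around the TSS |
| `mapq_min` | 30 (strict `>`) | discard ambiguous alignments |
| `tn5_plus_offset` / `tn5_minus_offset` | +4 / −5 | Tn5 dimer geometry |
| `sigmoid_k` | auto (`4 / median positive margin`) | adapts steepness to sequencing depth |
| `gc_bins` | 10 | equal-frequency bins; small bins are merged |
| `lhs_strata` | 10 | rank strata for dropout injection |
| `count_mode` | `"overlap"` | `"insertion"` counts each Tn5 end instead |

All of these live in `pipeline_config()` and are recorded in the CLI
manifest.

## The synthetic generator, its realism and limits

`synthetic_design()` / `simulate_dataset()` produce a matched dataset with
known ground truth: 3 cell types × 200 cells × 1500 genes by default, with
20 positive and 20 negative markers per type (negatives are sampled from
other types' positives), a background block of genes expressed everywhere
(log-normal means), a housekeeping pair with latent Pearson correlation 0.7
(Gaussian copula over negative-binomial marginals), and NB counts with
dispersion 2. The ATAC side places Poisson(3) fragments per open element per
cell uniformly inside the counting windows, over a uniform genome-wide
background of 0.2 fragments/kb/cell that also covers one blacklist region
per synthetic chromosome. The problem sizes and rates are this package's own
choices, selected at design time so the signal-to-noise regime is decisively
informative for the benchmark without being trivial.

Two deliberate idealizations: real scATAC-seq is far sparser (often well
under one fragment per element per cell) and real accessibility is only
partially concordant with expression. The generator models the favourable
regime in which the method's assumptions hold, so the benchmark measures the
machinery, not the biology. RNA and ATAC barcodes are distinct namespaces;
the modalities are matched only through cell-type labels, as in unpaired
experiments.

`inject_dropouts()` zeroes exactly `round(rate × nnz)` non-zero entries per
cell type, spread over 10 equal-rank value strata with per-stratum quotas
within one of the even split (Latin-hypercube style), and `restore_dropouts()`
inverts it exactly.

## Benchmarks

- **Marker test** — over positive-marker entries whose truth is non-zero:
  TPR of imputed-non-zero; over negative-marker entries whose truth is zero:
  FPR. "Non-zero" means strictly positive at tolerance 0.
- **Bulk test** — the positive class is the top 10% of genes in a per-type
  (pseudo-)bulk profile, the negative class genes with bulk value 0.
- **Stratified 1−F1 error** — recovery of injected dropouts stratified by
  the true value; the lowest stratum is anchored at 0, so false positives on
  true zeros are charged to it.
- **Correlation preservation** — Pearson $r$ of a gene pair against a
  reference $r$; by default computed over cells where at least one gene of
  the pair is non-zero. This filtering matters: the additive term is constant
  within a type, so over a *fixed* cell set imputation cannot change $r$;
  what it does change is *which* cells pass the non-zero filter, which is
  exactly how dropout distorts measured correlations in practice.

## Numerical conventions

- Coordinates are BED-native 0-based half-open everywhere; conversion to
  1-based closed happens only at the interval-overlap boundary.
- Quantile normalization interpolates tied ranks as the mean of the two
  bracketing reference values; both normalizations are idempotent.
- Medians of even-sized populations average the two middle values.
- All randomness flows through explicit integer seeds (`withr::with_seed`),
  and identical seeds give byte-identical written matrices.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_dataset(synthetic_design(seed = 1))
dd  <- inject_dropouts(sim$expression, 0.5, sim$rna_annotation, seed = 1)
res <- epi_impute(dd$matrix, sim$rna_annotation, sim$fragments,
                  sim$atac_annotation, sim$promoters, sim$enhancers,
                  blacklist = sim$blacklist)
marker_test(res$imputed, sim$expression, sim$truth$marker_sets,
            sim$rna_annotation)
```
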