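---
title: "Detecting cell-type-specific alternative transcript isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-type-specific alternative transcript isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsai)
```

## The problem

*Volvox carteri* has exactly two cell types: large reproductive gonidia
(germ cells) and small biflagellate somatic cells. Most cell-type
specialization in this alga is driven by differential gene expression, but a
gene can also express *different transcript isoforms* in the two cell types —
cell-type-specific alternative transcript isoforms (CTSAI). This package
detects such genes from transcript-level FPKM tables: genes with exactly two
isoforms where one isoform is soma-biased and the other gonidia-biased.

The pipeline has four stages, each a module with a small surface:

1. **Census** (`filter_expressed_genes()`, `census()`): apply the expression
   floor, count isoforms per gene, select the two-isoform analysis set.
2. **Filter cascade** (`run_detection()`): per-isoform cell-type expression
   ratios, a combined between-isoform bias, and per-isoform differential
   p-values, applied as three nested cutoffs.
3. **Curation** (`curate()`, `detect_convergent_pairs()`): quantitative
   read-density (RD) and relative-support (REL) checks against per-base
   coverage, plus a screen for convergent antisense gene pairs miscalled as
   isoform pairs.
4. **Context screens** (`as_conservation_overlap()`, `classify_rbp_bias()`):
   cross-species conservation of alternative splicing over a 1:1 ortholog
   map, and cell-type bias tiers for RNA-binding-protein (RBP) genes.

## The model and its statistics

For a transcript $t$ let $\bar{x}_s(t)$ and $\bar{x}_g(t)$ be its mean FPKM
over somatic and gonidial replicates. The **expression ratio** is

$$\mathrm{ER}(t) = \frac{\bar{x}_s(t) + \varepsilon}{\bar{x}_g(t) + \varepsilon},$$

with pseudocount $\varepsilon = 0.01$ FPKM in numerator and denominator. The
pseudocount guards against zero gonidial means (an unexpressed isoform gives a
large but finite ratio, e.g. means 4 vs 0 give $\mathrm{ER} = 401$); it is two
orders of magnitude below the 1-FPKM expression floor, so ratios of expressed
transcripts are essentially unperturbed. It is configurable via
`ctsai_thresholds(pseudocount = )`.

Within a two-isoform gene the isoforms are relabeled so isoform 1 has the
larger ER; the **combined bias** is $B = \mathrm{ER}_1 / \mathrm{ER}_2 \ge 1$.
This makes the cascade orientation-free: which isoform the assembler listed
first carries no information.

The three cutoffs, with defaults:

| stage | criterion | default |
|---|---|---|
| 1 | opposite biases: $\mathrm{ER}_1 > \tau_{bias}$ and $\mathrm{ER}_2 < 1/\tau_{bias}$ | $\tau_{bias} = 2$ |
| 2 | combined bias: $B > \tau_B$ | $\tau_B = 8$ |
| 3 | both isoform p-values $< \tau_p$ | $\tau_p = 0.1$ |

All inequalities are strict; ties fail. Stage 1 at the default is equivalent
to requiring $|\log_2 \mathrm{ER}| > 1$ for both isoforms with opposite signs
(unit-tested). Because the two per-isoform tests concern different
transcripts, their p-values multiply into an aggregate
$p_1 p_2 < \tau_p^2 = 0.01$; no further multiple-testing correction is
applied — the aggregate is per-gene, not FDR-controlled across genes.

### The differential test

The per-isoform p-value comes from an F-test of the cell-type term in a
linear model on $\log_2(\mathrm{FPKM} + 1)$, which for two groups equals a
two-sided pooled-variance t-test (the suite checks agreement with an explicit
t-CDF computation to $10^{-10}$). The log transform stabilizes the
multiplicative noise of FPKM; the $+1$ offset keeps zeros finite. The test
carries a documented degenerate contract for noise-free data: when the
within-group variance is zero in both groups, $p = 1$ if the group means are
equal and $p = 0$ otherwise. This convention makes noise-free recovery tests
exact rather than dependent on floating-point residuals.

## Curation criteria, formalized

The RD and REL criteria quantify checks that are traditionally done by eye on
genome-browser coverage tracks. Their cutoffs are choices of this package,
not published values, and all are configurable.

**Differential regions.** For a two-isoform gene, `differential_regions()`
partitions the union of both exonic footprints into bases unique to isoform
1, unique to isoform 2, and shared (exact interval arithmetic on 0-based
half-open intervals, cross-checked against per-base brute force).

**RD (read density).** In the cell type where an isoform is claimed expressed
(soma for the higher-ER isoform), its unique regions must show mean depth
$\ge 5$ and a covered-base fraction $\ge 0.8$. Both cutoffs are inclusive —
the thresholds are artifact-defined, so boundary behaviour is a free choice
and $\ge$ is the less surprising one. An isoform with no unique region passes
vacuously.

**REL (relative support).** With unique-region mean depths $u_1(c), u_2(c)$
and shared-region mean depth $s(c)$ per cell type $c$ (each plus pseudodepth
0.5), the score is

$$\mathrm{rel} = \log_2\frac{u_1(s)/s(s)}{u_1(g)/s(g)} - \log_2\frac{u_2(s)/s(s)}{u_2(g)/s(g)}.$$

Normalizing by the shared region cancels overall transcript-abundance
differences between cell types — a gene that is simply 10× higher in soma
scores 0 — which is precisely the artifact REL exists to reject. The check
passes when $|\mathrm{rel}| \ge 2$ and the two bracketed terms have opposite
signs. When one isoform is an exonic subset of the other (internal start or
extra terminal exon — two of the three common CTSAI architectures), it has no
unique region: its term is then a null reference whose sign is
noise-determined, so the magnitude criterion alone decides. Without this
provision the opposite-sign requirement would reject most genuine
subset-architecture switches.

**CT (convergent transcripts).** Unstranded libraries let assemblers fuse two
adjacent convergent genes into one locus with two "isoforms".
`detect_convergent_pairs()` finds gene pairs on opposite strands whose exonic
footprints overlap at both partners' 3'-most exons (overlapping 3'UTRs);
`curate()` applies the same geometry to a candidate's own isoform pair, using
the annotation's strands. Exclusion reasons are assigned in the fixed order
RD, REL, CT.

## The synthetic data generator

`simulate_dataset()` provides ground-truth data for every stage. Its defaults
are the package's study conditions:

* 200 genes on one chromosome, fixed intergenic spacing (500 bp), exons of
  200 bp with 100 bp introns;
* 20 planted CTSAI genes, each with two isoforms cycling through three
  architectures: extra 3' exon, alternative first exon, internal start;
* 4 planted convergent pairs, adjacent genes on opposite strands with
  3'-most exons overlapping by 50 bp;
* null genes draw isoform counts from (0.888, 0.088, 0.024) for 1, 2, 3
  isoforms — the approximate single/double/higher split observed in
  assembled Volvox transcriptomes;
* per-transcript baseline FPKM ~ lognormal(meanlog = log 20, sdlog = 1), a
  right-skewed distribution centred comfortably above the 1-FPKM floor;
* planted effect: $|\log_2 \mathrm{ER}| = 2$ per isoform (isoform 1
  soma-biased, isoform 2 gonidia-biased; convergent partners get
  whole-transcript biases of opposite sign);
* replicate noise: multiplicative lognormal with CV = 0.2, unit mean, 4
  replicates per cell type. FPKM are positive and right-skewed, so a
  lognormal noise model is the natural minimal choice; CV 0.2 is a typical
  between-replicate spread for bulk RNA-seq of sorted cell populations.

Coverage tracks are derived deterministically: each base's depth is the sum
over covering transcripts of round(cell-type mean FPKM × 2). With
`replicate_cv = 0` the replicates are exactly identical, so recovery of every
planted gene is exact by the degenerate test contract.

What the generator does **not** emulate: read-level sampling noise, 3'
coverage bias, mappability gaps, library-size artifacts, isoform-assignment
ambiguity in quantification, and genes with partially shared exon boundaries.
Passing recovery tests therefore demonstrate the pipeline's logic and
statistics, not robustness to quantification error in real data.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; conversion
  happens only at the GFF3 (1-based inclusive) and bedGraph boundaries.
* **Expression floor** defaults to the gene level: mean over samples of
  summed transcript FPKM, strictly $> 1$. A per-transcript pre-floor is
  available (`transcript_floor = TRUE`) for the stricter reading in which
  each transcript must individually clear the floor.
* **Percentages** in the census funnel are integer-truncated (974 of 1235
  multi-isoform genes reports 78%).
* **Missing FPKM values are hard errors**, never imputed: a silent imputation
  would corrupt ratios invisibly.
* **Gene-identifier normalization** before set operations strips one trailing
  all-digit suffix (transcript/version) and the legacy `m.g` gene-model
  suffix; locus components containing letters (e.g. `0004s0224`) are never
  stripped.
* **RBP tiers**: fold bias $\max(\mathrm{ER}, 1/\mathrm{ER})$ with `similar`
  $< 2$, `modest` $[2, 5]$, `specific` $> 5$; the boundary folds 2 and 5 are
  assigned to the modest tier, following the strict `<`/`>` glyphs used for
  the outer tiers. The default PFAM list covers RRM, KH, G-patch and the two
  DEAD-box helicase domains and is extensible.

## Worked example

```{r example}
params <- simulation_params(seed = 11)
d <- simulate_dataset(params)
res <- detect_ctsai(d$expression, d$models)
res$funnel
res$detection$funnel

planted <- d$truth$gene_id[d$truth$label == "ctsai"]
all(sort(res$candidates) == sort(planted))

is_cand <- vapply(res$detection$records, `[[`, character(1),
                  "verdict") == "candidate"
cur <- curate(res$detection$records[is_cand], d$models, d$coverage)
cur$summary

detect_convergent_pairs(d$models)[, 1:3]
```

## Limitations

* The RD/REL cutoffs cannot be validated against the by-eye judgments they
  formalize; they are tuned to be conservative on the synthetic conditions.
* The differential test is a pooled-variance test on log FPKM, a deliberate
  simplification of assembler-specific variance models; with 2–4 replicates
  per group its power is limited and the per-isoform $\tau_p = 0.1$ reflects
  that.
* Genes with three or more isoforms are counted but never analyzed; the
  two-isoform restriction is inherent to the paired-ratio design.
* Convergent-pair geometry relies entirely on annotation strands; no
  strand inference from reads or splice-site polarity is attempted.
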