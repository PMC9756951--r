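---
title: "Scoring TR activity and targets from single-cell ATAC-seq"
author: "scTRact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring TR activity and targets from single-cell ATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTRact)
```

## The problem

scATAC-seq measures chromatin accessibility in single cells, but accessibility
alone does not say *which* transcription regulator (TR) occupies an open
region. Motif-based scores (chromVAR-style deviations) cannot separate family
members sharing a motif and cannot score chromatin regulators that bind DNA
indirectly. scTRact instead asks, for each cell, how strongly the cell's open
chromatin overlaps each dataset in a large curated compendium of TR ChIP-seq
peak sets (supplemented by motif-derived pseudo-peaks for factors lacking
ChIP data), and converts those overlap counts into a per-cell TR activity
score. Because every activity call is anchored to a concrete reference
dataset, the same machinery then imputes per-cell binding sites and scores
target genes, which is what permits differential-target analysis and
single-cell gene-regulatory network (GRN) construction — something a motif
deviation score cannot provide.

## The activity model

Let $M_{j,i}$ be the number of overlapping (cell feature, reference peak)
pairs between cell $i$'s open features (count > 0, i.e. binarized) and
reference dataset $j$. Overlaps use bedtools semantics: one shared base pair
makes one overlap, counted per pair, on unstranded, 0-based half-open (BED)
intervals. The chain of transformations is:

1. **Size normalization.** $M'_{j,i} = M_{j,i} / (D_j \, Q_i)$ where $D_j$ is
   dataset $j$'s peak count and $Q_i$ the total bp open in cell $i$ per
   $10^8$ bp. This removes the advantage of large reference datasets and
   deeply covered cells.
2. **Dataset centering.** $M''_{j,\cdot} = M'_{j,\cdot} -
   \mathrm{mean}(M'_{j,\cdot})$, making datasets with different baseline
   enrichment comparable.
3. **Deduplication.** Each TR usually has several datasets (tissues, cell
   lines, possibly a motif set). Per cell and TR, the largest centered score
   wins, $Y_{i,k} = \max_{j \in k} M''_{j,i}$, and the winning dataset is
   recorded as that cell's *best match* for the TR. An `average` strategy is
   available; it defines no best match.
4. **Sigmoid compression.** Per TR, scores are z-scored across cells
   (population sd) and passed through $1/(1+e^{-z})$, compressing outliers
   into $(0,1)$ with the TR mean at 0.5.
5. **Per-cell z-score.** Each cell's scores over TRs are scaled to mean 0,
   sd 1, giving all cells the same dynamic range for clustering.

Two exact invariants follow and are enforced by tests to $10^{-10}$: each
dataset row of $M''$ has zero mean, and every final cell column has mean 0
and unit sd. The chain is also invariant to rescaling all $D_j$ by a common
factor — a useful sanity property because it means unit conventions in the
reference metadata cannot shift the biology.

Before scoring, sparse cell profiles are optionally smoothed with their
$k$ nearest neighbors: the binarized matrix is TF-IDF weighted, embedded by
a truncated SVD (LSI), neighbors found by cosine similarity, and profiles
combined by union (default) or summed counts. Defaults are $k = 20$ and 50
dimensions — standard scATAC-seq practice. The embedding uses a dense SVD,
which is exact and dependency-free and comfortably handles the matrix sizes
the package targets (up to a few thousand cells); larger matrices should be
smoothed upstream or scored with `knn_k = 0`. Smoothing precedes all scoring
steps, so $Q$ is recomputed from the smoothed profiles.

### Numerical choices

* z-scores use the population (1/n) denominator, consistently in the sigmoid
  step, the per-cell step, and differential-target scaling.
* A TR constant across cells has no z-score; its sigmoid output is fixed at
  0.5 with a warning. A cell constant across TRs gets zeros with a warning.
  Cells with no open features get zero overlap counts and a warning rather
  than an error, but a cell with zero covered bp cannot be normalized and is
  an error at the $Q$ division.
* Argmax ties in deduplication break to the lexicographically smallest
  dataset id, so repeated runs and platform changes cannot flip best-match
  assignments.

## The regulatory-potential model

For a TR and cell, binding sites are imputed as the peaks of the cell's
best-matched dataset that overlap the cell's open features (`extended` mode
first pools every dataset that is the best match for at least one cell of
the TR, which helps when individual datasets are shallow). A gene $g$ is then
scored

$$ S_g = \sum_{i=1}^{n} 2^{-d_i / d_0}, $$

where $d_i$ is the distance from the $i$-th site's center to the gene's TSS
and $d_0$ the half-decay distance. Only sites within $15\,d_0$ of the TSS are
summed; beyond that a site's contribution is below 0.0005, and tests verify
the truncated mass is bounded accordingly. Under `d0 = "auto"` the TR's
regulatory range is classified from its full reference peak set: more than
20% of peaks overlapping promoter windows (TSS ± 1 kb) makes it
promoter-type ($d_0 = 1$ kb), otherwise enhancer-type ($d_0 = 10$ kb); the
boundary is strict, so exactly 20% is enhancer-type. Distances use peak
centers and are strand-independent; the TSS itself is strand-aware.

The **enhanced** model adds two refinements: a site inside an exon of $g$
contributes $1/(\text{total exon length of } g\text{ in kb})$ instead of the
decay term (exon length in kb keeps the magnitude comparable to decay
contributions near the TSS), and a site inside the promoter or exon of a
*different* gene within the search window contributes 0 to $g$ — it is
accounted to that gene. When neither rule fires, enhanced and simple scores
are identical, which the tests check explicitly. The simple model with
`d0 = "auto"` is the default.

**Differential targets** between two cell groups: RP is normalized as
$\ln(1+\mathrm{RP})$ and scaled within each cell; per gene a two-sided
Wilcoxon rank-sum test compares groups, with the log fold change taken as
the difference of group means on the ln scale. A gene is called at
$|\mathrm{logFC}| \ge 0.25$ and $p \le 0.01$ (both inclusive). Genes with
zero RP in every cell of both groups are removed before testing; the
package defines "low RP" as exactly zero, the most conservative reading.

**GRNs**: per TR and cell type, the 500 cells with the highest total RP are
kept (all, when fewer exist), RP is aggregated per gene over those cells
(max by default — a pile-up across the retained cells — with mean as an
option), and the top 1000 targets become weighted TR→gene edges sharing gene
nodes across TRs.

## Reference curation

Raw ChIP-seq peak sets pass six quality gates, all strict inequalities:
median base quality above 25, uniquely-mapped fraction above 0.5, PBC above
0.8, more than 100 ten-fold peaks, FRiP above 0.01, and more than 70% of the
top 5000 peaks in union DHS. Retained sets keep only peaks with fold
enrichment ≥ 5 (a five-fold peak satisfies its own definition, hence the
inclusive boundary), and datasets left with fewer than 1000 peaks are
dropped. Motif scan hits become pseudo-peaks by (i) keeping hits overlapping
the union of ccRE and DHS catalogs — union rather than intersection, to
maximize retention of genuinely regulatory sites, (ii) removing blacklist
overlaps, (iii) extending each survivor symmetrically about its midpoint to
exactly 340 bp (typical ChIP peak width), odd base to the left, clipped at
the chromosome start, with the blacklist re-checked after extension so
extension cannot smuggle a site back over a blacklisted region, and (iv)
capping at the 25,000 smallest-p-value sites — the cap applies after the
region filters, so it reflects sites that survived curation. Filtering
happens on the original scanned intervals and extension afterwards, so the
region tests see the motif hit itself, not an inflated window. PWM scanning
is out of scope: the builder consumes already-scanned sites with p-values.

## What the synthetic data does and does not emulate

`makeToyWorld()` plants the one assumption the method rests on:
cell-type-specific TR binding shows up in that cell type's open chromatin.
On a 2 × 10 Mb toy genome (two chromosomes keep multi-chromosome arithmetic
honest), each of 3 cell types gets a TR with 1000 disjoint 500 bp sites;
cells open their own TR's sites at rate 0.6 and everything else (other TRs'
sites plus an equal number of background features) at rate 0.1. The signal
rate reflects the per-cell detection efficiency of accessible sites; the
background rate models nonspecific accessibility, and the generator rejects
configurations where background is not strictly below signal. Gene models
(200 three-exon genes) are scattered for RP tests. The generator is exactly
reproducible per seed and restores the caller's RNG state.

It deliberately does not model fragment-level artifacts (duplication, Tn5
sequence bias), doublets, batch effects, or overlapping reference datasets
of unequal quality. Passing the planted-recovery tests therefore shows the
scoring chain extracts the designed signal under realistic sparsity — not
that it is robust to every pathology of real libraries.

Problem sizes in the tests and acceptance script — 150 cells × 4000
features, 50 random overlap instances up to 1000 intervals per side, 200
genes × 50+50 cells for differential targets — were chosen as the smallest
instances that exercise every code path with stable stochastic margins.

## Worked example

```{r example}
tw <- makeToyWorld(n_cell_types = 3, cells_per_type = 20,
                   peaks_per_dataset = 300, seed = 42)
act <- trActivity(tw$cells, tw$index, knn_k = 5, seed = 42)
A <- activityScores(act)
round(A[, 1:4], 2)

# fraction of cells whose top-scoring TR is the planted one
top <- rownames(A)[apply(A, 2, which.max)]
mean(top == unname(tw$tr_of_type[tw$labels]))

# target genes of TR1 via the RP model
rp <- rpMatrix(tw$cells, tw$index, "TR1", bestMatch(act), tw$genes,
               d0 = "auto")
head(rankTargets(rp, 5))
```

## Known limitations

* Overlap counting and RP scoring are exact but in-memory; the package is
  sized for desk-scale matrices, not atlas-scale runs.
* Best-match assignment is winner-takes-all per cell; a cell genuinely
  intermediate between two reference contexts is still assigned one dataset.
* The `average` deduplication strategy defines no best match, so target
  imputation requires the default `max` strategy.
* QC filtering requires all six metrics; there is no partial-evidence mode.
* GTF gene models take each symbol's longest transcript for the TSS; genes
  with widely separated alternative promoters are represented by one TSS.
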