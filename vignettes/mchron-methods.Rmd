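---
title: "Methods: time-lagged multi-omics association and chromatin regulatory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-lagged multi-omics association and chromatin regulatory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mchron)
```

# Scope

`mchron` implements the bespoke computational steps of a multi-omics
differentiation time-course analysis: chromatin accessibility (ATAC),
transcriptome (RNA) and proteome are measured at several days of an
ESC-to-neuron differentiation, complemented by ChIP peak sets for a
transcription factor of interest and chromatin-bound interactome
(ChIP-SICAP style) pull-down tables. The package deliberately does *not*
re-implement upstream machinery that mature tools already provide (read
alignment, peak calling, DESeq2/limma model fits, motif databases):
externally computed differential tables are first-class inputs, and the
internal differential test is a simple, clearly-labeled stand-in.

# Coordinate conventions

All on-disk formats (BED6, narrowPeak, bedGraph, TSS tables, gene
models) use 0-based half-open coordinates; in memory everything is a
`GRanges` (1-based closed), converted only at the I/O boundary. Two
conventions are fixed for determinism:

* **Distance to an interval** is measured to the nearest *included*
  base, i.e. `min(|pos - start|, |pos - (end - 1)|)` in BED terms and 0
  inside the interval. Adjacent half-open intervals therefore have
  distance 1, never 0.
* **Nearest-gene ties** are broken by smaller distance, then
  lexicographically smaller gene id; the per-gene promoter peak is the
  single closest peak within the promoter window, ties broken by peak
  id.

Midpoint extension (`extendAroundMidpoint`) uses
`mid = floor((start + end)/2)` and clips at the chromosome start, so
widths are exactly `2 * flank` except at the left edge. Consensus peak
sets (`mergeConsensus`) are reported as maximal runs of per-base
coverage by at least `minSets` distinct input sets - the simplest
contract that captures "present in at least two samples".

Two promoter windows coexist on purpose: peak-to-gene linking for
association testing uses 1.5 kb, while genomic-category annotation uses
1 kb. The analyses they serve are different and both windows are exposed
as parameters (`promoterWindow`) rather than reconciled.

# Cross-layer association model

For each pair group (gene RNA vs protein; promoter-peak accessibility vs
RNA; distal-peak accessibility vs RNA) the unit of analysis is a *linked
pair* of features measured in both layers. For a source contrast, a
target contrast and a direction combination (up/up, up/down, down/up,
down/down), a 2x2 table is formed over the full pair universe:
pairs moving in the source direction and the target direction (`a`),
source only (`b`), target only (`c`), neither (`d`). Features that are
measured but not significantly changed (`ns`) stay in the universe; the
four cells always sum to the number of pairs. This "all measured pairs"
universe is one of two defensible readings of testing "proportions of
pairs which are differential"; it is the default because it makes `d`
well-defined and the test a standard enrichment test.

Two filters restrict which cells are tested:

* **Information flow**: only chromatin to RNA and RNA to protein, never
  backwards - the central-dogma constraint is structural, encoded in the
  pair-group definitions.
* **Time order**: the target contrast must not end earlier than the
  source contrast. Because the proteome is sampled on a denser grid
  (every 2 days) than RNA/ATAC (days 0/4/8/12), each protein day is
  mapped to the nearest RNA/ATAC grid day with ties going to the *later*
  day (day 10 maps to 12). With adjacent contrasts on both grids this
  yields 72 direction-resolved admissible cells
  (`admissibleCells()` enumerates them).

Each cell is tested with the two-sided Fisher exact test; the odds ratio
is reported as the sample cross-product with the Haldane-Anscombe +0.5
correction whenever a cell is zero, which keeps `log2(OR)` finite and
displayable (this is not the conditional-MLE odds ratio of
`fisher.test`, whose p-value we do use). Benjamini-Hochberg correction
is applied across all tests *within one pair group*, which is the
comparison-family the analysis defines; significance is `adj_p < 0.05`
with a strict inequality at the boundary.

# Differential TF activity

A TF's activity change between two conditions is the mean per-site
accessibility log2 fold change over its motif sites inside accessibility
peaks. Motif sites come from a log-odds PWM scan against a uniform 0.25
background (PFM counts regularized with a pseudocount; both strands;
windows containing `N` skipped; a hit requires at least 80% of the
maximum attainable score by default). Sites are extended by 50 bp on
each side before the peak overlap, and per-site fold changes are log2
ratios of pseudocounted CPM condition means.

Significance is an effect size, not a p-value: Cohen's D between the
TF's per-site fold-change distribution and a permuted-site null built
from repeated same-size draws out of the pooled in-peak sites of all
other TFs. A TF is called at `|D| > 1`. Computing D on the *site-level*
distributions (rather than on distributions of resampled means) is the
decisive design choice: on means, D reduces to `observed mean / SE of
the mean`, which grows without bound with the site count and is ~N(0,1)
for a null TF, so the fixed threshold of 1 would flag ~32% of null TFs
at any site count. On site-level distributions D is a scale-free effect
size: a planted +1 log2FC on a pool with SD 0.5 gives D = 2, and a null
TF concentrates near 0 (SD about `1/sqrt(n_sites)`), matching the
intended "activity shift of about one SD of typical accessibility
change" semantics of the threshold.

TFs with fewer than 50 in-peak sites are skipped: the mean of a handful
of sites is dominated by individual peaks. The activity mean is
unweighted; weighting by motif score is a possible refinement we did not
adopt, since the match score is a detection statistic, not a binding
strength.

TF groups are obtained by k-means (base `stats::kmeans`, 25 restarts
under a fixed seed) on the concatenated activity and expression
profiles, with k = 8 by default; groups whose mean activity profile
anticorrelates with their mean expression profile are flagged as
candidate repressors.

# Chromatin states and co-occupancy

Mark signal over peaks is the length-weighted mean of piecewise-constant
bedGraph tracks, with uncovered bases counting as signal 0 (not
missing): absence of coverage in an input track is absence of signal.
Regulatory grouping z-scores each track before k-means so that marks on
different dynamic ranges contribute equally; merging visually similar
groups is a judgment call left to the analyst. Co-occupancy fractions
use a minimum overlap of 1 bp against pre-merged (reduced) factor
regions - reduction never changes the fraction, which is tested. The
three-way partition of two factors' landscapes reports co-bound regions
in the coordinates of the factor under study, and group comparisons of
signal or nearest-gene expression use the equal-variance Student's t or
the Wilcoxon rank-sum test (exact for small tie-free samples, normal
approximation with tie correction otherwise).

# Interactome scoring

Pull-down tables are protein-by-run iBAQ-like intensity matrices with
target and IgG-control runs paired by replicate within each cell type
(`PulldownExperiment`, a `SummarizedExperiment` subclass with validity
checks). Interactors are called per cell type by the strict
both-replicates rule: *exclusive* (detected in every target replicate,
IgG identically 0) or *enriched* (at least `minFold`-fold over IgG in
every replicate, boundary inclusive); mixed IgG zero/non-zero patterns
are rejected because neither branch's condition holds in all replicates.
Protein intensity per cell type is the mean over target runs (not the
maximum), and the association-rate score is the log2 ratio of
bait-normalized intensities between cell types, making it invariant to
global intensity scaling of either cell type's runs. Correlating the
scores with protein expression fold changes separates abundance-driven
association changes from candidate regulated recruitment (large
residuals). Category enrichment (e.g. TFs, cofactors) is a Fisher test
of called interactors against the protein universe.

# Synthetic data and what it does (not) show

Every input has a seeded generator returning the data *and* the planted
truth. The defaults are the study conditions and are not tuned per test:
a 2 x 200 kb genome with 100 genes and 400 peaks (half of them within
1.5 kb of a TSS), RNA/ATAC on days 0/4/8/12 with 5/4 replicates,
proteome every 2 days to day 10 with 2 replicates, negative-binomial
counts with dispersion 0.1 over log-normal baselines, log-normal library
sizes with CV 0.2, planted |log2FC| of 1.5, cross-layer coupling with
conditional probability 0.8 and a 4-day lag (chromatin leads RNA, RNA
leads protein). Genes are tiled in the first half of each chromosome so
that a gene desert remains where distal peaks can be placed farther than
the promoter window from every TSS. ChIP data plant two regulatory
archetypes (promoter-like: high H3K4me3/accessibility; enhancer-like:
high H3K4me1/H3K27ac, per-mark noise SD 0.1), a co-bound fraction of 0.3
with +2 shifts on active marks and nearest-gene expression, and
edge-jittered replicate peak sets; pull-down tables plant 30 exclusive +
30 enriched + 140 background proteins with association rates correlated
with expression change at rho = 0.7.

The generators emulate the *statistical structure* the methods rely on -
not real motif content, read-level noise, GC effects, peak shapes,
isoforms, or missingness patterns of real MS data. Passing tests
demonstrate that the implementations compute their contracts correctly
and recover effects of the planted kind at the planted scale; they say
nothing about upstream processing of real sequencing data.

# Numerical and testing choices

* Fisher p-values come from `stats::fisher.test` and are checked against
  an exhaustive hypergeometric enumeration for all tables with margins
  up to 40; BH comes from `stats::p.adjust`.
* `kmeans` uses 25 restarts under a fixed seed; all seeded functions
  save and restore the caller's RNG state.
* The internal differential test is a Welch t on log2(CPM + 1) (counts)
  or log2 intensities. At 4 + 4 replicates the Welch-Satterthwaite
  approximation is known to be slightly conservative (empirical size
  about 0.041 at nominal 0.05, reproducible with `stats::t.test` on
  exactly normal data), which is acceptable for a stand-in whose calls
  feed enrichment tests rather than being endpoints themselves.
* Problem sizes in the test suite (toy chromosomes of 10-400 kb, 100-700
  features, 20-100 random instances per oracle check, 25-50 seeds per
  recovery property) were chosen so the whole suite and the acceptance
  script each run in a few minutes on one CPU while keeping Monte-Carlo
  margins comfortable.
* CPM normalization induces a compositional artifact when a large
  fraction of a *small* feature set shifts in one direction (library
  size absorbs part of the effect); at the default 100-gene scale the
  imbalance is minor, but planted-effect recovery is asserted at the
  default scale, not on miniature configurations.

# Known limitations

* The internal differential test makes no variance moderation across
  features; with 2 replicates (proteome scale) its power is very low,
  which is faithful to the role the full pipelines delegate to limma.
* The permuted-site null ignores site-level covariates (GC, peak width)
  that the published TF-activity tool stratifies by; the implementation
  documents its null precisely rather than claiming bit-compatibility.
* Nearest-TSS assignment stands in for chromatin-loop-based assignment;
  distal regulation over long ranges is attributed to the wrong gene
  whenever a loop skips the nearest TSS.
* Consensus regions are coverage runs, not anchored peak calls; summit
  information is not propagated through consensus building.
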