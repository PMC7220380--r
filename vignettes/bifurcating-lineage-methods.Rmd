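---
title: "Methods: bifurcating-lineage scRNA-seq analysis with permutation-based proliferation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bifurcating-lineage scRNA-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`marrowlineage` re-implements, as a tested and reusable workflow, the
computational analysis of bone-marrow mesenchymal-lineage single-cell
RNA-seq data: cells are filtered and depth-normalized, variable genes are
selected by their dispersion relative to a fitted mean-dispersion trend,
cells are clustered on a shared-nearest-neighbour graph, each cell is
classified as proliferative or not by a gene-set label-permutation test
with per-cluster FDR control, a rooted minimum-spanning-tree trajectory
orders cells in pseudotime along a Y-shaped osteogenic/adipogenic
bifurcation, and branch-dependent genes are detected with a
negative-binomial spline likelihood-ratio test. A synthetic-data
generator plants exactly the structure these stages assume, with full
ground truth, so every stage is validated against known answers.

## Quality control and normalization

Cells are excluded when they detect more than 6,000 genes (a doublet
proxy), fewer than 200 genes, or carry more than 5% of their UMIs on
mitochondrial genes (`mt-` prefix). All three exclusion rules are strict
inequalities, so boundary cells (exactly 6,000 genes, exactly 5% mito)
are retained; this follows the exclusion predicate literally. The
mitochondrial percentage is computed on UMIs, not on distinct genes —
the standard convention — and this choice is the one genuinely open
reading of the rule, so it is exposed through `qc_metrics()` where it
can be audited.

Counts are scaled so every cell totals `scale_total = 1e4` molecules and
transformed as `ln(1 + x)`. Technical covariates (total UMIs,
percent-mito) are removed per gene by ordinary least squares;
`regress_covariates()` guarantees residuals exactly orthogonal to the
design (QR-based, collinear columns dropped with a warning). The
regression method is deliberately the simplest thing meeting the
contract: the upstream description says only that the covariates were
"regressed out". Dispersion estimation intentionally uses the
*pre-residual* normalized counts, since residuals can be negative and
the dispersion model is a count model.

## Dispersion-based gene selection

For each gene the empirical negative-binomial dispersion is the
method-of-moments value `phi = max(0, (v - m) / m^2)` on depth-scaled
counts, and a mean-dispersion trend `phi_fit(mu) = a + b / mu` is fitted
by gamma-family regression over genes with positive mean and dispersion
(least-squares fallback if the gamma fit fails; the fitted value is
floored at 1e-8 so it is positive at every observed mean). Two
selections are exposed, mirroring the two toolchains the workflow
emulates, neither privileged:

* the ordering-gene rule `mean_expression >= 0.05 AND
  dispersion_empirical >= 2 * dispersion_fit` (both boundaries
  inclusive), used for trajectory reconstruction;
* `select_top_dispersion(k = 2000)`, ranking by the
  empirical-to-fitted ratio (ties broken lexicographically by gene id).
  Ranking by the ratio rather than raw dispersion avoids mean-driven
  selection; `rank = "raw"` restores the raw ordering.

## Clustering and markers

PCA (genes centred and unit-scaled; default 30 components, echoing the
30 dimensions used upstream) feeds a k-nearest-neighbour graph
(`k = 20`) converted to shared-nearest-neighbour Jaccard weights with
edges below 1/15 pruned, then Louvain modularity optimization
(`igraph`), deterministic under the run seed. Resolution defaults to
1.0; the upstream resolutions were unreported, so resolution is an
explicit configuration parameter. Cluster markers use a two-sided
Wilcoxon rank-sum test of the target cluster against all remaining
cells (normal approximation with tie and continuity corrections; exact
ties give p = 1), with the AUC, the log fold-change of depth-normalized
means, and BH correction across genes. The 2-D t-SNE/UMAP embeddings are
for plotting only — no downstream stage consumes them by default,
because embeddings distort distances; trajectory inference runs in PC
space (UMAP space is accepted as an option to mirror the upstream
Slingshot configuration).

## The proliferation permutation test

This is the workflow's centrepiece. Cycle gene sets (canonically 43 S
and 54 G2/M genes, supplied as files) are first filtered to genes
expressed in at least 5% of all cells. For each cell the observed
statistic is

    d = mean(expression over S genes) - mean(expression over G2M genes)

on the log-normalized scale. Because the joint null of the two set
scores is unknown, the null is built by label permutation: `n_S` of the
`n_S + n_G` cycle genes are resampled without replacement as pseudo-S
labels, `B = 5000` times, and the two-sided Monte-Carlo p-value is the
add-one estimator `(1 + #{|d*| >= |d|}) / (B + 1)`, which is valid for
any B. When `C(n_S + n_G, n_S) <= 1e5` the sampler is replaced by
exhaustive enumeration and the p-value is the exact fraction. Design
choices worth stating:

* **Two-sided on |d|.** "Expresses one set significantly more than the
  other" names no direction; a cell dominated by either module counts.
  A cell with both modules equally elevated is, by this definition,
  non-proliferative — a known conceptual quirk, implemented as defined.
* **One resample stream per run.** The same B label splits (one RNG
  stream keyed by the seed) are shared by all cells; per-cell streams
  are statistically equivalent, and sharing makes runs reproducible and
  the per-cell loop a single matrix product.
* **Observed diff uses the normalized (pre-residual) matrix** by
  default; the residualized matrix can be passed instead.

BH correction is applied separately *within each cluster* — exactly as
specified upstream, not globally — and a cell is proliferative iff its
within-cluster FDR is below 0.05; the dominant module (S or G2M) is the
sign of d. Per-cluster proliferative fractions summarize the result.

## Trajectory

The trajectory is a Slingshot-style object rather than a DDRTree
re-implementation: a minimum spanning tree over cluster centroids in
the reduced space (Kruskal, deterministic tie-breaks by edge length
then cluster-id pair), rooted at a user-specified progenitor cluster —
root choice is biological knowledge (the EMP-like cluster), and an
automatic stemness heuristic is deliberately out of scope. Lineages are
all root-to-leaf paths; cells are orthogonally projected onto the
nearest segment of their lineage's piecewise-linear centroid path, and
pseudotime is arc length from the root. Cells in clusters shared by all
lineages are labelled `trunk`; cells past the branch point carry their
lineage id. Simultaneous principal curves (Slingshot's refinement) are
omitted as a documented simplification; the centroid path preserves the
rooted-Y topology and ordering, which is what downstream stages
consume, and pseudotime is invariant to rigid motions of the space.

## Branch-dependent expression

For cells past the branch point, each gene's raw counts are modelled by
a log-link negative-binomial GLM with a log library-size offset and a
natural cubic spline in pseudotime (df = 3). The full model adds a
branch intercept and branch-specific spline coefficients; the reduced
model shares one smooth. The likelihood-ratio statistic is referred to
chi-square with df = 4 (branch intercept + 3 spline contrasts), BH
across genes. The per-gene dispersion is a method-of-moments estimate
held fixed during fitting — computed from full-model *Poisson
residuals*, not marginal moments, because marginal moments absorb the
modelled signal into the dispersion and deflate power for exactly the
genes of interest; profile/joint estimation is omitted for robustness
at this scale. Genes whose NB fit fails fall back to a Gaussian LRT on
log-normalized values and are flagged; all-zero genes are reported flat
with p = 1 and no fit. Per-lineage monotone trends use the same NB
machinery with a linear pseudotime term; a gene is `up`/`down` by the
sign of that coefficient when its BH-adjusted p clears 0.05, else
`flat`. `filter_tfs()` intersects any result table with a
transcription-factor list, and `heatmap_order()` produces the
branch-centred smoothed matrix (branch point at the centre, adipogenic
bins leftward, osteogenic rightward; genes grouped by peaking branch,
ordered by peak position).

## The synthetic-data generator

`simulate_dataset()` plants the structure the analysis assumes — it is
first-class, tested code, and its defaults are the study conditions for
the whole validation suite:

* **Topology**: six populations on a Y — EMP (root), LMP, LCP (branch
  point) on the trunk; OB, Ocy on the osteogenic branch; AD terminal on
  the adipogenic branch. Each population occupies a unit pseudotime
  interval; cells draw uniform positions in their interval.
* **Counts**: negative binomial with per-gene dispersion 0.3 and
  log-normal library sizes (median 1e4, sdlog 0.3, emulating ~10-12k
  UMIs/cell); 3,000 cells (500 per population) and 2,000 genes by
  default — sizes chosen so the whole suite runs in minutes on one CPU
  while leaving per-population counts comparable to the smaller
  clusters of a real dataset.
* **Programs**: gene log-means are piecewise-linear between population
  anchor points (two anchors per population, inset 0.1 from the
  interval ends). Markers (40 per population, effect ln 8) plateau
  across their population and spill at 0.35x into immediate lineage
  neighbours — differentiation programs change progressively, and
  without that spill the population centroids would be near-equidistant
  and carry no lineage geometry for the MST. Branch genes (50 per
  branch) ramp linearly from 0 at the branch point to ln 2 at their
  terminus and stay at baseline on the other branch — a deliberately
  modest two-fold end-point divergence. Cycling cells (20/15/10/5/0/0%
  of EMP/LMP/LCP/OB/Ocy/AD, concentrated in progenitors with
  non-proliferative termini) get a +1.0 natural-log shift on exactly
  one cycle module (S or G2M, 50/50), leaving the other at baseline,
  which makes the "one set more than the other" definition detectable.
  2% of genes are `mt-` prefixed for QC.
* **Determinism**: identical parameters and seed give byte-identical
  fixtures (`write_fixture()` emits the 10x MTX/barcodes/features
  layout, truth tables, and the planted gene-set files).

What the generator does **not** emulate: doublets, ambient RNA,
batch/age effects (multi-dataset integration is out of scope),
zero-inflation beyond NB sampling, gene-gene correlation beyond the
planted programs, and continuous cell-cycle phase structure. Passing
tests therefore demonstrate correctness of the algorithms under the
assumed generative model, not robustness to every artefact of real
droplet data.

## Numerical and degenerate-input conventions

Comparisons against permutation statistics use a 1e-12 absolute
tolerance so exact ties count as exceedances; the Monte-Carlo p-value
floor is 1/(B+1). Zero-variance genes get dispersion 0 and marker
p = 1; constant covariates are dropped with a warning rather than
failing the QR; empty ordering-gene selections warn rather than error;
an empty cycle set after prevalence filtering is an error because the
permutation test is undefined. MST ties break on (length, cluster-id
pair) so trees are reproducible. Clustering, embedding and resampling
are all keyed by explicit seeds.

## Known limitations

* The MST trajectory can grow short spur lineages when clustering
  over-splits boundary regions; the analysis scripts label spurs by
  their terminal cluster identity and exclude them from branch testing
  rather than forcing a binary tree.
* The branch test's power at the default two-fold end-point divergence
  is information-limited for weakly expressed genes; sensitivity
  figures in the validation suite are dominated by that tail, not by
  the estimator.
* BH within small clusters is conservative; clusters of a handful of
  cells rarely yield proliferative calls at FDR 0.05.
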