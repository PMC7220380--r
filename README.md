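# marrowlineage

Single-cell RNA-seq analysis of bifurcating mesenchymal lineages, built
for bone-marrow data in which early mesenchymal progenitors (EMPs)
differentiate through intermediate states to a branch point and then
down an osteogenic route (osteoblast → osteocyte) or an adipogenic
route (marrow adipogenic lineage precursors / adipocytes). The package
is aimed at analysts who want each stage of that workflow as a small,
tested function — plus a synthetic-data generator that plants the
assumed structure with ground truth, so the whole pipeline can be
validated end to end without any external download.

## What it computes

* **QC / normalization** — exclude cells with >6000 or <200 detected
  genes or >5% mitochondrial UMIs; scale each cell to 10^4 molecules
  and transform `ln(1 + x)`; regress out total UMIs and percent-mito
  per gene (OLS residuals, exactly orthogonal to the design).
* **Dispersion-based gene selection** — per-gene NB method-of-moments
  dispersion φ = max(0, (v − m)/m²) on depth-scaled counts, a fitted
  trend φ_fit(μ) = a + b/μ, the ordering rule
  `mean ≥ 0.05 & φ ≥ 2·φ_fit`, and top-k selection by φ/φ_fit.
* **Clustering and markers** — PCA → SNN (Jaccard) graph → Louvain;
  Wilcoxon rank-sum markers with AUC, logFC and BH correction.
* **Proliferation permutation test** — per cell, the difference d
  between mean S-set and mean G2/M-set expression; null from resampling
  the S labels across the pooled cycle genes (B = 5000, or exhaustive
  enumeration when feasible); two-sided p = (1 + #{|d*| ≥ |d|})/(B+1);
  BH **within each cluster**; proliferative ⇔ FDR < 0.05.
* **Trajectory** — minimum spanning tree over cluster centroids in PC
  space, rooted at the progenitor cluster; pseudotime = arc length of
  the orthogonal projection onto the lineage's centroid path; trunk /
  branch labels per cell.
* **Branch-dependent expression** — per gene, NB GLM with log
  library-size offset and natural spline in pseudotime (df 3); LRT of
  branch-specific vs shared smooth (χ², df 4), BH across genes;
  per-lineage up/down trends; TF filtering; branch-centred heatmap
  ordering.
* **Synthetic data** — NB counts for six populations on a Y topology
  with planted markers, branch ramps, cycling cells, mitochondrial
  genes, and full per-cell/per-gene truth; deterministic per seed.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
fixture (3,000 cells, 2,000 genes, seed 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_features_cluster.R
Rscript analysis/04_cellcycle.R
Rscript analysis/05_trajectory.R
Rscript analysis/06_branch_expression.R
```

Selected output from a run of those six scripts:

```
cells: 3000  genes: 2000
median genes/cell: 1497.5
median UMIs/cell:  10034.5
cycling cells: 265 (8.8%)
...
cells in: 3000   passing QC: 3000
ordering genes: 246  (trend coef a=0.519, b=-0.002)
clusters: 8
ARI vs planted populations: 0.948
...
cycle genes used: 43 S + 54 G2M (dropped 0)
proliferative cells: 279
sensitivity on planted cycling cells: 0.992
false-positive rate on non-cycling cells: 0.0059
  cluster n_cells n_proliferative   fraction
1       1     513             114 0.22222222
...
7       7     473               0 0.00000000
8       8     500               0 0.00000000
...
root cluster: 1
lineage_8 Spearman rho vs planted pseudotime: 0.933
branch labels: adipo=500, osteo=1000, other=477, trunk=1023
branch-dependent genes (BH < 0.05): 147 of 246 tested
```

Reading it: QC keeps all simulated cells (the generator plants few
QC failures by design); the ordering rule picks ~250 high-dispersion
genes; Louvain recovers the six planted populations at ARI 0.95 (two
small boundary clusters account for the split); the permutation test
finds essentially all planted cycling cells at a sub-1% false-positive
rate, with the two terminal populations — simulated non-proliferative,
as osteocytes and adipocytes are — at exactly 0; the rooted MST orders
cells along both branches at Spearman ρ ≈ 0.93 against the planted
pseudotime; and the branch LRT flags the genes whose programs diverge
between the osteogenic and adipogenic routes.

Programmatic use mirrors the scripts:

```r
library(marrowlineage)
sim  <- simulate_dataset(sim_params(seed = 1))
res  <- run_all(run_config(seed = 1), counts = sim$counts,
                gene_sets = list(
                  s_genes   = subset(sim$truth$genes, program == "cycle-S")$gene_id,
                  g2m_genes = subset(sim$truth$genes, program == "cycle-G2M")$gene_id))
res$cellcycle$fractions
```

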