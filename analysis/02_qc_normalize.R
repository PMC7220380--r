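#!/usr/bin/env Rscript
# QC filtering (genes > 6000, genes < 200 or > 5% mitochondrial UMIs
# excluded), depth normalization to 1e4 molecules per cell with natural
# log transform, and per-gene regression of UMI count and percent-mito.

suppressMessages(library(marrowlineage))

counts <- read_10x_mtx("results/fixture")
qc <- qc_filter(counts, max_genes = 6000, min_genes = 200,
                max_pct_mito = 5)
message("cells in: ", ncol(counts), "   passing QC: ", sum(qc$qc$pass))
write.table(qc$qc, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

norm <- normalize_log(qc$counts, scale_total = 1e4)
covs <- qc$qc[qc$qc$pass, c("n_umi", "pct_mito")]
resid <- regress_covariates(norm, covs)
message("max |residual x covariate| after regression: ",
        format(max(abs(resid %*% cbind(1, as.matrix(covs)))), digits = 3))
invisible(Matrix::writeMM(norm, "results/normalized.mtx"))
writeLines(rownames(norm), "results/normalized_genes.txt")
writeLines(colnames(norm), "results/normalized_cells.txt")
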