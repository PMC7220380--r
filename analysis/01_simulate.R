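#!/usr/bin/env Rscript
# Generate the default synthetic endosteal bone-marrow fixture: 6
# mesenchymal populations (EMP > LMP > LCP branching into OB > Ocy and
# AD) with planted markers, branch programs, cycling cells and
# mitochondrial genes, written in 10x layout with full ground truth.

suppressMessages(library(marrowlineage))

out <- "results/fixture"
params <- sim_params(seed = 1)
sim <- simulate_dataset(params)
write_fixture(sim, out)

# a synthetic stand-in for a transcription-factor list: a deterministic
# subset of the planted programme genes (real analyses would supply a
# curated TF database here)
g <- sim$truth$genes
program_genes <- g$gene_id[g$program %in% c("marker", "branch")]
writeLines(program_genes[seq(1, length(program_genes), by = 4)],
           file.path(out, "tf_list_synthetic.txt"))

counts <- sim$counts
message("cells: ", ncol(counts), "  genes: ", nrow(counts))
message("median genes/cell: ", median(Matrix::colSums(counts > 0)))
message("median UMIs/cell:  ", median(Matrix::colSums(counts)))
message("cycling cells: ", sum(sim$truth$cells$cycling),
        " (", round(100 * mean(sim$truth$cells$cycling), 1), "%)")
message("fixture written to ", out)
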