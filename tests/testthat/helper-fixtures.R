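# lazily-built shared fixtures; heavy objects are computed once per run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the default 3,000-cell bifurcating fixture (package default parameters)
default_sim <- function() {
  fixture("default_sim", function() simulate_dataset(sim_params()))
}

default_norm <- function() {
  fixture("default_norm",
          function() normalize_log(qc_filter(default_sim()$counts)$counts))
}

default_pcs <- function() {
  fixture("default_pcs", function() {
    sim <- default_sim()
    disp <- fit_dispersion_trend(estimate_dispersion(sim$counts))
    run_pca(default_norm(), select_ordering_genes(disp), 30)
  })
}

default_clusters <- function() {
  fixture("default_clusters",
          function() cluster_cells(default_pcs(), 20, 1.0, seed = 1))
}

default_gene_sets <- function() {
  g <- default_sim()$truth$genes
  list(s_genes = g$gene_id[g$program == "cycle-S"],
       g2m_genes = g$gene_id[g$program == "cycle-G2M"])
}

# a small fast fixture for structural tests
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_dataset(sim_params(
      n_cells_per_population = 60, n_genes = 300,
      n_marker_genes_per_population = 10, n_branch_genes_per_branch = 10,
      n_s_genes = 12, n_g2m_genes = 15, seed = 42))
  })
}

# independent enumeration oracle for the cycle permutation test: all
# C(n, n_s) splits, two-sided count of |mean diff| at least the observed
perm_pvalue_oracle <- function(values, n_s) {
  n <- length(values)
  obs <- mean(values[seq_len(n_s)]) - mean(values[-seq_len(n_s)])
  splits <- utils::combn(n, n_s)
  diffs <- apply(splits, 2, function(s)
    mean(values[s]) - mean(values[-s]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

# brute-force minimum spanning tree weight via Pruefer-sequence
# enumeration of all n^(n-2) labeled trees
mst_weight_oracle <- function(centroids) {
  n <- nrow(centroids)
  D <- as.matrix(stats::dist(centroids))
  pruefer_to_edges <- function(seq) {
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (i in seq_along(seq)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, seq[i])
      degree[leaf] <- 0L
      degree[seq[i]] <- degree[seq[i]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  min(apply(seqs, 1, function(s) {
    e <- pruefer_to_edges(as.integer(s))
    sum(D[e])
  }))
}
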