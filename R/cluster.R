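#' Principal component analysis over selected genes
#'
#' Genes are centered and unit-scaled across cells (constant genes get
#' scale 1) before the cells are projected; components are ordered by
#' decreasing explained variance.
#'
#' @param norm genes x cells expression matrix.
#' @param genes genes to use (default all).
#' @param n_pcs number of components, `< min(n_cells, n_genes)`.
#' @return cells x `n_pcs` score matrix; attribute `sdev` holds the
#'   component standard deviations.
#' @export
run_pca <- function(norm, genes = rownames(norm), n_pcs = 30) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing))
    stop("genes not in matrix: ", paste(utils::head(missing, 5),
                                        collapse = ", "))
  X <- t(as.matrix(norm[genes, , drop = FALSE]))   # cells x genes
  if (n_pcs >= min(dim(X))) stop("n_pcs must be < min(n_cells, n_genes)")
  sds <- matrixStats::colSds(X)
  sds[sds == 0] <- 1
  X <- scale(X, center = TRUE, scale = sds)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  out <- pc$x
  rownames(out) <- colnames(norm)
  attr(out, "sdev") <- pc$sdev[seq_len(n_pcs)]
  out
}

#' Graph-based clustering of cells
#'
#' Builds a k-nearest-neighbour graph in PC space, converts it to a
#' shared-nearest-neighbour (Jaccard) graph, prunes weak edges, and runs
#' Louvain modularity optimization. Deterministic under a fixed seed.
#'
#' @param pcs cells x PCs matrix.
#' @param k_neighbors neighbourhood size (>= 2).
#' @param resolution Louvain resolution.
#' @param seed RNG seed for the community search.
#' @param prune drop SNN edges with Jaccard below this.
#' @return integer cluster id per cell (named by cell id).
#' @export
cluster_cells <- function(pcs, k_neighbors = 20, resolution = 1.0,
                          seed = 0L, prune = 1 / 15) {
  n <- nrow(pcs)
  if (k_neighbors < 2) stop("k_neighbors must be >= 2")
  if (n < k_neighbors) stop("fewer cells (", n, ") than k_neighbors")
  knn <- FNN::get.knn(pcs, k = k_neighbors - 1)$nn.index
  nbr <- cbind(seq_len(n), knn)                 # each cell includes itself
  # shared-neighbour (Jaccard) weights via sparse indicator cross-product
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nbr)),
                            j = as.vector(nbr), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  k <- ncol(nbr)
  snn <- shared
  snn@x <- snn@x / (2 * k - snn@x)              # |a&b| / |a|b| union
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  out <- as.integer(igraph::membership(cl))
  names(out) <- rownames(pcs)
  out
}

#' Two-dimensional embedding for visualization
#'
#' t-SNE or UMAP on the PC scores. The coordinates are for plotting
#' only; trajectory inference uses the PC space directly.
#'
#' @param pcs cells x PCs matrix.
#' @param method `"umap"` or `"tsne"`.
#' @param seed RNG seed (fixed seed gives identical output).
#' @return cells x 2 coordinate matrix.
#' @export
embed_2d <- function(pcs, method = c("umap", "tsne"), seed = 0L) {
  method <- match.arg(method)
  set.seed(seed)
  out <- if (method == "umap") {
    uwot::umap(pcs, n_neighbors = min(15, nrow(pcs) - 1), n_threads = 1,
               n_sgd_threads = 1)
  } else {
    perp <- max(1, min(30, floor((nrow(pcs) - 1) / 3)))
    Rtsne::Rtsne(pcs, perplexity = perp, check_duplicates = FALSE,
                 pca = FALSE, num_threads = 1)$Y
  }
  rownames(out) <- rownames(pcs)
  colnames(out) <- paste0(toupper(method), "_", 1:2)
  out
}

# rank-sum test of x vs y: normal approximation with tie correction and
# continuity correction; returns U, AUC and two-sided p
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(c(U = U, auc = auc, p = 1))
  z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  c(U = U, auc = auc, p = min(1, 2 * stats::pnorm(-max(z, 0))))
}

#' Cluster marker detection by Wilcoxon rank-sum
#'
#' Tests every gene in the target cluster against all remaining cells
#' (two-sided), reporting the log fold-change of depth-normalized means,
#' the rank-sum AUC, and BH-adjusted p-values across genes.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param clusters integer/character cluster id per cell.
#' @param target_cluster cluster to contrast against the rest.
#' @param genes genes to test (default all).
#' @return data frame sorted by p-value: `gene_id`, `log_fc`, `auc`,
#'   `p_value`, `p_adj`.
#' @export
find_markers <- function(norm, clusters, target_cluster,
                         genes = rownames(norm)) {
  if (!target_cluster %in% clusters) stop("cluster not found: ",
                                          target_cluster)
  in_cl <- clusters == target_cluster
  if (sum(in_cl) < 3) stop("target cluster has < 3 cells")
  X <- as.matrix(norm[genes, , drop = FALSE])
  res <- t(apply(X, 1, function(v) rank_sum_test(v[in_cl], v[!in_cl])))
  eps <- 1e-9
  lfc <- log(rowMeans(expm1(X[, in_cl, drop = FALSE])) + eps) -
         log(rowMeans(expm1(X[, !in_cl, drop = FALSE])) + eps)
  out <- data.frame(gene_id = genes, log_fc = as.numeric(lfc),
                    auc = res[, "auc"], p_value = res[, "p"],
                    p_adj = stats::p.adjust(res[, "p"], "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$gene_id), ]
}
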