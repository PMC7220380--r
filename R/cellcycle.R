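#' Prevalence-filter the cell-cycle gene sets
#'
#' Intersects the S and G2M lists with the expression matrix and removes
#' genes expressed (nonzero) in fewer than `min_prevalence` of all
#' cells, mirroring the convention of filtering a 43 + 54 core set down
#' to the genes detectable in the dataset.
#'
#' @param norm genes x cells log-normalized matrix (all retained cells).
#' @param sets list with `s_genes`, `g2m_genes` (see [read_gene_sets()]).
#' @param min_prevalence minimum fraction of cells with nonzero
#'   expression.
#' @return list `s_used`, `g2m_used`, `dropped` (data frame of removed
#'   genes with reasons).
#' @export
filter_cycle_genes <- function(norm, sets, min_prevalence = 0.05) {
  prev_of <- function(genes, label) {
    absent <- setdiff(genes, rownames(norm))
    present <- intersect(genes, rownames(norm))
    if (!length(present))
      stop("no ", label, " genes found in the expression matrix")
    prev <- Matrix::rowMeans(norm[present, , drop = FALSE] > 0)
    keep <- present[prev >= min_prevalence]
    low <- present[prev < min_prevalence]
    dropped <- data.frame(
      gene_id = c(absent, low),
      set = rep(label, length(absent) + length(low)),
      reason = rep(c("absent", "low_prevalence"),
                   c(length(absent), length(low))),
      stringsAsFactors = FALSE)
    list(keep = keep, dropped = dropped)
  }
  s <- prev_of(sets$s_genes, "S")
  g <- prev_of(sets$g2m_genes, "G2M")
  if (!length(s$keep) || !length(g$keep))
    stop("a cycle gene set is empty after the prevalence filter; ",
         "the permutation test is undefined")
  list(s_used = s$keep, g2m_used = g$keep,
       dropped = rbind(s$dropped, g$dropped))
}

# all C(n_total, n_s) label splits as a contrast matrix (n_total x B):
# +1/n_s on pseudo-S rows, -1/n_g on the rest, so E %*% C gives the
# mean-difference under every split
split_contrasts <- function(idx_sets, n_total, n_s) {
  n_g <- n_total - n_s
  B <- ncol(idx_sets)
  C <- matrix(-1 / n_g, nrow = n_total, ncol = B)
  C[cbind(as.vector(idx_sets), rep(seq_len(B), each = n_s))] <- 1 / n_s
  C
}

#' Permutation p-value for one cell's S-vs-G2M mean difference
#'
#' The observed statistic is `mean(values[1:n_s]) - mean(values[-(1:n_s)])`
#' (S genes first). The null resamples `n_s` of the `n_total` genes
#' without replacement as pseudo-S labels. Two-sided Monte-Carlo p-value
#' with the add-one estimator `(1 + r) / (B + 1)`; when the number of
#' distinct splits `C(n_total, n_s)` is at most `exhaustive_limit` (and
#' `exhaustive` is `"auto"` or `"on"`), all splits are enumerated and the
#' p-value is the exact fraction `r / C(n_total, n_s)`.
#'
#' @param values expression of the cell over the cycle genes, S genes
#'   first.
#' @param n_s number of S genes at the head of `values`.
#' @param B number of Monte-Carlo resamples.
#' @param seed RNG seed.
#' @param exhaustive `"auto"`, `"on"` or `"off"`.
#' @param exhaustive_limit split-count ceiling for enumeration.
#' @return list `observed_diff`, `p_value`, `exhaustive` (logical).
#' @export
permutation_pvalue <- function(values, n_s, B = 5000, seed = 0L,
                               exhaustive = c("auto", "on", "off"),
                               exhaustive_limit = 1e5) {
  res <- cycle_score_matrix(matrix(values, nrow = 1), n_s, B = B,
                            seed = seed, exhaustive = exhaustive,
                            exhaustive_limit = exhaustive_limit)
  list(observed_diff = res$observed_diff[1], p_value = res$p_value[1],
       exhaustive = res$exhaustive)
}

#' Permutation test over a cells x cycle-genes expression matrix
#'
#' Vectorized form of [permutation_pvalue()]: one set of resampled label
#' splits (a single RNG stream keyed by `seed`) is shared by all cells.
#'
#' @param E cells x n_total expression matrix, S genes in the first
#'   `n_s` columns.
#' @inheritParams permutation_pvalue
#' @return list `observed_diff` (per cell), `p_value` (per cell),
#'   `exhaustive`, `n_splits`.
#' @export
cycle_score_matrix <- function(E, n_s, B = 5000, seed = 0L,
                               exhaustive = c("auto", "on", "off"),
                               exhaustive_limit = 1e5) {
  exhaustive <- match.arg(exhaustive)
  E <- as.matrix(E)
  n_total <- ncol(E)
  n_g <- n_total - n_s
  if (n_s <= 0 || n_g <= 0) stop("need 0 < n_s < n_total cycle genes")
  if (B < 1) stop("B must be >= 1")
  obs <- rowMeans(E[, seq_len(n_s), drop = FALSE]) -
         rowMeans(E[, n_s + seq_len(n_g), drop = FALSE])
  n_splits <- choose(n_total, n_s)
  do_exhaustive <- switch(exhaustive,
    on = TRUE, off = FALSE, auto = n_splits <= exhaustive_limit)
  if (do_exhaustive && n_splits > 1e7)
    stop("exhaustive enumeration over ", n_splits, " splits is infeasible")
  if (do_exhaustive) {
    idx <- utils::combn(n_total, n_s)
  } else {
    set.seed(seed)
    idx <- replicate(B, sample.int(n_total, n_s))
  }
  null_diff <- E %*% split_contrasts(idx, n_total, n_s)
  tol <- 1e-12
  exceed <- rowSums(abs(null_diff) >= abs(obs) - tol)
  p <- if (do_exhaustive) exceed / ncol(idx) else (1 + exceed) / (B + 1)
  list(observed_diff = as.numeric(obs), p_value = as.numeric(p),
       exhaustive = do_exhaustive, n_splits = ncol(idx))
}

#' Per-cell proliferation p-values from the permutation test
#'
#' Convenience driver: extracts the filtered cycle genes from the
#' matrix, orients S genes first, and runs [cycle_score_matrix()].
#'
#' @param norm genes x cells log-normalized matrix.
#' @param cycle_sets result of [filter_cycle_genes()].
#' @inheritParams permutation_pvalue
#' @return data frame: `cell_id`, `observed_diff`, `p_value`.
#' @export
cycle_scores <- function(norm, cycle_sets, B = 5000, seed = 0L,
                         exhaustive = c("auto", "on", "off")) {
  genes <- c(cycle_sets$s_used, cycle_sets$g2m_used)
  E <- t(as.matrix(norm[genes, , drop = FALSE]))
  res <- cycle_score_matrix(E, length(cycle_sets$s_used), B = B,
                            seed = seed, exhaustive = exhaustive)
  data.frame(cell_id = colnames(norm), observed_diff = res$observed_diff,
             p_value = res$p_value, stringsAsFactors = FALSE)
}

#' Classify proliferative cells with per-cluster FDR control
#'
#' Benjamini-Hochberg correction applied separately within each cluster;
#' a cell is proliferative iff its within-cluster FDR is below `alpha`.
#' The dominant set is S when the observed difference is positive, G2M
#' when negative, and `none` for non-proliferative cells.
#'
#' @param scores data frame from [cycle_scores()].
#' @param clusters cluster id per cell (aligned with `scores`).
#' @param alpha FDR cutoff.
#' @return `scores` with `cluster`, `fdr`, `proliferative`,
#'   `dominant_set` columns.
#' @export
classify_proliferative <- function(scores, clusters, alpha = 0.05) {
  if (length(clusters) != nrow(scores))
    stop("clusters must align with scores rows")
  scores$cluster <- clusters
  scores$fdr <- NA_real_
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    scores$fdr[idx] <- stats::p.adjust(scores$p_value[idx], "BH")
  }
  scores$proliferative <- scores$fdr < alpha
  scores$dominant_set <- ifelse(!scores$proliferative, "none",
                                ifelse(scores$observed_diff > 0, "S", "G2M"))
  scores
}

#' Per-cluster proliferative fractions
#'
#' @param calls output of [classify_proliferative()].
#' @return data frame: `cluster`, `n_cells`, `n_proliferative`,
#'   `fraction`.
#' @export
proliferative_fraction <- function(calls) {
  agg <- stats::aggregate(proliferative ~ cluster, data = calls,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(cluster = agg$cluster,
                    n_cells = agg$proliferative[, "n"],
                    n_proliferative = agg$proliferative[, "k"])
  out$fraction <- out$n_proliferative / out$n_cells
  out[order(out$cluster), ]
}
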