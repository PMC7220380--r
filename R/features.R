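#' Per-gene empirical dispersion on depth-scaled counts
#'
#' Counts are scaled so every cell totals `scale_total` molecules; per
#' gene the mean `mu` and variance `v` across cells then give the
#' negative-binomial method-of-moments dispersion
#' `phi = max(0, (v - mu) / mu^2)` (0 for degenerate genes).
#'
#' @param counts genes x cells count matrix.
#' @param scale_total depth-scaling target.
#' @return data frame: `gene_id`, `mean_expression`,
#'   `dispersion_empirical`.
#' @export
estimate_dispersion <- function(counts, scale_total = 1e4) {
  if (ncol(counts) < 2) stop("need >= 2 cells")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("zero-total cell; run qc_filter first")
  sc <- counts %*% Matrix::Diagonal(ncol(counts), scale_total / totals)
  mu <- Matrix::rowMeans(sc)
  ex2 <- Matrix::rowMeans(sc^2)
  v <- (ex2 - mu^2) * ncol(sc) / (ncol(sc) - 1)
  phi <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  data.frame(gene_id = rownames(counts), mean_expression = as.numeric(mu),
             dispersion_empirical = as.numeric(phi),
             stringsAsFactors = FALSE)
}

#' Fit the mean-dispersion trend phi(mu) = a + b / mu
#'
#' Gamma-family regression of empirical dispersion on inverse mean over
#' genes with positive mean and positive dispersion; falls back to least
#' squares if the gamma fit does not converge. The fitted value is
#' clamped to a small positive floor so `dispersion_fit > 0` at every
#' observed mean.
#'
#' @param tab output of [estimate_dispersion()].
#' @return `tab` with a `dispersion_fit` column; attribute `trend_coef`
#'   holds `c(a, b)`.
#' @export
fit_dispersion_trend <- function(tab) {
  use <- tab$mean_expression > 0 & tab$dispersion_empirical > 0
  if (sum(use) < 10)
    stop("need >= 10 genes with positive mean and dispersion (have ",
         sum(use), ")")
  mu <- tab$mean_expression[use]
  phi <- tab$dispersion_empirical[use]
  inv_mu <- 1 / mu
  if (stats::sd(inv_mu) < 1e-12) {
    coefs <- c(mean(phi), 0)          # all genes at one mean: flat trend
  } else {
    fit <- tryCatch(
      stats::glm(phi ~ inv_mu, family = stats::Gamma(link = "identity"),
                 start = c(mean(phi) / 2, stats::median(phi * mu) / 2)),
      error = function(e) NULL, warning = function(w) NULL)
    coefs <- if (!is.null(fit) && fit$converged) stats::coef(fit)
             else stats::coef(stats::lm(phi ~ inv_mu))
  }
  floor_fit <- 1e-8
  tab$dispersion_fit <- ifelse(
    tab$mean_expression > 0,
    pmax(coefs[1] + coefs[2] / tab$mean_expression, floor_fit),
    NA_real_)
  attr(tab, "trend_coef") <- stats::setNames(as.numeric(coefs), c("a", "b"))
  tab
}

#' Select ordering genes for trajectory reconstruction
#'
#' Keeps genes satisfying `mean_expression >= min_mean` and
#' `dispersion_empirical >= fold * dispersion_fit` (both boundaries
#' inclusive).
#'
#' @param tab dispersion table with trend fitted.
#' @param min_mean mean-expression floor.
#' @param fold required ratio of empirical to fitted dispersion.
#' @return character vector of gene ids.
#' @export
select_ordering_genes <- function(tab, min_mean = 0.05, fold = 2) {
  if (is.null(tab$dispersion_fit)) stop("fit_dispersion_trend first")
  keep <- !is.na(tab$dispersion_fit) &
    tab$mean_expression >= min_mean &
    tab$dispersion_empirical >= fold * tab$dispersion_fit
  genes <- tab$gene_id[keep]
  if (!length(genes)) warning("no genes pass the ordering rule")
  genes
}

#' Select the top-k most variable genes
#'
#' Ranks genes by `dispersion_empirical / dispersion_fit` (default) or by
#' raw empirical dispersion; ties broken by lexicographic gene id.
#'
#' @param tab dispersion table with trend fitted.
#' @param k number of genes.
#' @param rank `"ratio"` or `"raw"`.
#' @return character vector of k gene ids.
#' @export
select_top_dispersion <- function(tab, k = 2000, rank = c("ratio", "raw")) {
  rank <- match.arg(rank)
  if (k > nrow(tab)) stop("k exceeds number of genes")
  score <- if (rank == "ratio") {
    ifelse(is.na(tab$dispersion_fit), 0,
           tab$dispersion_empirical / tab$dispersion_fit)
  } else tab$dispersion_empirical
  ord <- order(-score, tab$gene_id)
  tab$gene_id[ord][seq_len(k)]
}
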