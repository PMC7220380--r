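# NB GLM deviance with fixed theta; returns NULL on failure
nb_deviance <- function(y, X, offset, theta) {
  fit <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, offset = offset,
                   family = MASS::negative.binomial(theta = theta,
                                                    link = "log"))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  fit$deviance
}

# per-gene method-of-moments theta from full-model Poisson residuals
# (marginal moments would absorb the modelled signal into the dispersion
# and deflate the LRT); clamped for GLM stability, near-Poisson genes
# get a large theta
gene_theta <- function(y, X, offset) {
  f <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, offset = offset, family = stats::poisson())),
    error = function(e) NULL)
  if (is.null(f)) return(1e4)
  mu <- f$fitted.values
  phi <- max(0, sum((y - mu)^2 - mu) / sum(mu^2))
  if (phi < 1e-4) 1e4 else min(1 / phi, 1e4)
}

#' Branch-dependent expression test (BEAM-style likelihood ratio)
#'
#' For each gene, negative-binomial log-link regression of raw counts on
#' a natural cubic spline in pseudotime (df = 3) with a log library-size
#' offset. The full model adds a branch intercept and branch-specific
#' spline coefficients; the reduced model shares one smooth across
#' branches. The likelihood-ratio statistic is referred to a chi-square
#' with df = 4 (branch intercept + 3 spline contrasts). Genes whose NB
#' fit fails fall back to a Gaussian LRT on log1p depth-normalized
#' expression (flagged in the output); all-zero genes get p = 1 with no
#' fit. Only cells past the branch point (branch not `"trunk"`) enter.
#'
#' @param counts genes x cells raw count matrix.
#' @param pseudotime per-cell pseudotime.
#' @param branch per-cell branch id; `"trunk"` cells are excluded.
#' @param genes genes to test (default all).
#' @param spline_df natural-spline degrees of freedom.
#' @param alpha BH threshold for the `branch_dependent` flag.
#' @return data frame: `gene_id`, `lrt`, `df`, `p_value`, `p_adj`,
#'   `branch_dependent`, `fit` ("nb", "gaussian" or "none").
#' @export
branch_dependence_test <- function(counts, pseudotime, branch,
                                   genes = rownames(counts),
                                   spline_df = 3, alpha = 0.05) {
  use <- branch != "trunk"
  branches <- sort(unique(branch[use]))
  if (length(branches) != 2) stop("need exactly 2 non-trunk branches")
  if (min(table(branch[use])) < 10)
    stop("each branch needs >= 10 cells past the branch point")
  pt <- pseudotime[use]
  b <- factor(branch[use])
  ls <- Matrix::colSums(counts)[use]
  off <- log(ls)
  S <- splines::ns(pt, df = spline_df)
  X_red <- stats::model.matrix(~ S)
  X_full <- stats::model.matrix(~ b * S)
  df_lrt <- ncol(X_full) - ncol(X_red)
  Y <- as.matrix(counts[genes, use, drop = FALSE])
  lognorm <- log1p(t(t(Y) / ls) * 1e4)
  out <- data.frame(gene_id = genes, lrt = 0, df = df_lrt, p_value = 1,
                    fit = "none", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    y <- Y[i, ]
    if (all(y == 0)) next
    theta <- gene_theta(y, X_full, off)
    d_full <- nb_deviance(y, X_full, off, theta)
    d_red <- nb_deviance(y, X_red, off, theta)
    if (!is.null(d_full) && !is.null(d_red)) {
      out$lrt[i] <- max(0, d_red - d_full)
      out$fit[i] <- "nb"
    } else {
      z <- lognorm[i, ]
      rss_f <- sum(stats::lm.fit(X_full, z)$residuals^2)
      rss_r <- sum(stats::lm.fit(X_red, z)$residuals^2)
      out$lrt[i] <- max(0, length(z) * log(rss_r / max(rss_f, 1e-12)))
      out$fit[i] <- "gaussian"
    }
    out$p_value[i] <- stats::pchisq(out$lrt[i], df_lrt, lower.tail = FALSE)
  }
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$branch_dependent <- out$p_adj < alpha & out$fit != "none"
  out
}

#' Expression trend along one lineage
#'
#' Negative-binomial regression of a gene's counts on pseudotime (linear
#' term, log library-size offset) over the cells of one lineage
#' (trunk + branch). Direction is the sign of the pseudotime coefficient
#' when the BH-adjusted LRT p-value clears `threshold`, else `flat`.
#'
#' @param counts genes x cells raw count matrix.
#' @param pseudotime per-cell pseudotime.
#' @param cells logical or index vector selecting the lineage's cells.
#' @param genes genes to test (default all).
#' @param threshold BH significance threshold for a non-flat call.
#' @return data frame: `gene_id`, `slope`, `p_value`, `p_adj`,
#'   `direction` (`up`/`down`/`flat`).
#' @export
lineage_trend <- function(counts, pseudotime, cells, genes = rownames(counts),
                          threshold = 0.05) {
  Y <- as.matrix(counts[genes, cells, drop = FALSE])
  pt <- pseudotime[cells]
  if (ncol(Y) < 10) stop("lineage needs >= 10 cells")
  ls <- Matrix::colSums(counts)[cells]
  off <- log(ls)
  X1 <- cbind(1, pt)
  X0 <- matrix(1, ncol(Y), 1)
  out <- data.frame(gene_id = genes, slope = 0, p_value = 1,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    y <- Y[i, ]
    if (all(y == 0)) next
    theta <- gene_theta(y, X1, off)
    fit1 <- tryCatch(suppressWarnings(
      stats::glm.fit(X1, y, offset = off,
                     family = MASS::negative.binomial(theta, link = "log"))),
      error = function(e) NULL)
    d0 <- nb_deviance(y, X0, off, theta)
    if (is.null(fit1) || !fit1$converged || is.null(d0)) {
      z <- log1p(y / ls * 1e4)
      f <- stats::lm(z ~ pt)
      out$slope[i] <- stats::coef(f)[2]
      out$p_value[i] <- summary(f)$coefficients[2, 4]
    } else {
      out$slope[i] <- fit1$coefficients[2]
      lrt <- max(0, d0 - fit1$deviance)
      out$p_value[i] <- stats::pchisq(lrt, 1, lower.tail = FALSE)
    }
  }
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$direction <- ifelse(out$p_adj < threshold,
                          ifelse(out$slope > 0, "up", "down"), "flat")
  out
}

#' Restrict a result table to transcription factors
#'
#' @param tab data frame with a `gene_id` column.
#' @param tfs character vector of TF symbols (see [read_tf_list()]).
#' @return the rows whose gene is in `tfs`, order preserved.
#' @export
filter_tfs <- function(tab, tfs) {
  tab[tab$gene_id %in% tfs, , drop = FALSE]
}

#' Branch-centred smoothed expression matrix for heatmaps
#'
#' Cells past the branch point are binned along pseudotime within each
#' branch; per gene, bin means are smoothed with a centred rolling mean.
#' Columns run adipogenic-terminus -> branch point -> osteogenic
#' terminus (adipo bins reversed, branch point at the centre). Genes are
#' grouped by the branch in which their smoothed profile peaks
#' (osteo-peaking block first), ordered within a block by peak position.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param pseudotime per-cell pseudotime.
#' @param branch per-cell branch id (`"trunk"` excluded); the two branch
#'   labels sorted alphabetically map to (adipo, osteo) = left, right —
#'   override with `branch_order`.
#' @param genes rows to include.
#' @param n_bins pseudotime bins per branch.
#' @param smooth_window rolling-mean window (odd).
#' @param branch_order length-2: c(left_branch, right_branch).
#' @return genes x (2 n_bins) matrix; attribute `peak_branch` gives each
#'   gene's group.
#' @export
heatmap_order <- function(norm, pseudotime, branch, genes,
                          n_bins = 25, smooth_window = 3,
                          branch_order = NULL) {
  use <- branch != "trunk"
  branches <- sort(unique(branch[use]))
  if (length(branches) != 2) stop("need exactly 2 non-trunk branches")
  if (is.null(branch_order)) branch_order <- branches
  X <- as.matrix(norm[genes, , drop = FALSE])
  bin_means <- function(bn) {
    idx <- which(branch == bn)
    ptb <- pseudotime[idx]
    brk <- seq(min(ptb), max(ptb), length.out = n_bins + 1)
    bin <- pmin(n_bins, findInterval(ptb, brk, rightmost.closed = TRUE))
    M <- matrix(NA_real_, length(genes), n_bins)
    for (k in seq_len(n_bins)) {
      j <- idx[bin == k]
      if (length(j)) M[, k] <- rowMeans(X[, j, drop = FALSE])
    }
    # fill empty bins from the nearest filled bin
    for (g in seq_len(nrow(M))) {
      na <- which(is.na(M[g, ]))
      if (length(na) && length(na) < n_bins) {
        ok <- which(!is.na(M[g, ]))
        M[g, na] <- M[g, vapply(na, function(k) ok[which.min(abs(ok - k))],
                                integer(1))]
      }
    }
    M
  }
  roll <- function(v, w) {
    if (w <= 1) return(v)
    half <- floor(w / 2)
    vapply(seq_along(v), function(i)
      mean(v[max(1, i - half):min(length(v), i + half)]), numeric(1))
  }
  smooth_rows <- function(M, w) {
    for (g in seq_len(nrow(M))) M[g, ] <- roll(M[g, ], w)
    M
  }
  left <- smooth_rows(bin_means(branch_order[1]), smooth_window)
  right <- smooth_rows(bin_means(branch_order[2]), smooth_window)
  peak_branch <- ifelse(
    apply(right, 1, max) >= apply(left, 1, max),
    branch_order[2], branch_order[1])
  peak_pos <- vapply(seq_along(genes), function(g) {
    if (peak_branch[g] == branch_order[2]) which.max(right[g, ])
    else which.max(left[g, ])
  }, integer(1))
  ord <- order(peak_branch != branch_order[2], peak_pos)
  M <- cbind(left[, n_bins:1, drop = FALSE], right)[ord, , drop = FALSE]
  rownames(M) <- genes[ord]
  colnames(M) <- c(paste0(branch_order[1], "_bin", n_bins:1),
                   paste0(branch_order[2], "_bin", seq_len(n_bins)))
  attr(M, "peak_branch") <- stats::setNames(peak_branch[ord], genes[ord])
  M
}
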