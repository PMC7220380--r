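#' Per-cell QC metrics
#'
#' @param counts genes x cells sparse count matrix.
#' @param mito_prefix rowname prefix identifying mitochondrial genes.
#' @return data frame with `cell_id`, `n_genes_detected`, `n_umi`,
#'   `pct_mito` (percent of UMIs from mitochondrial genes).
#' @export
qc_metrics <- function(counts, mito_prefix = "mt-") {
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE])
              else numeric(ncol(counts))
  data.frame(cell_id = colnames(counts),
             n_genes_detected = as.integer(n_genes),
             n_umi = as.integer(n_umi),
             pct_mito = ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0),
             stringsAsFactors = FALSE)
}

#' Filter doublets and low-quality cells
#'
#' A cell is excluded iff it detects more than `max_genes` genes, fewer
#' than `min_genes` genes, or has more than `max_pct_mito` percent of its
#' UMIs on mitochondrial genes; boundary cells (exactly at a threshold)
#' are retained. Genes are never removed.
#'
#' @inheritParams qc_metrics
#' @param max_genes,min_genes detected-gene ceiling/floor (strict).
#' @param max_pct_mito mitochondrial-percentage ceiling (strict).
#' @return list with `counts` (retained cells) and `qc` (metrics for all
#'   input cells plus a `pass` flag).
#' @export
qc_filter <- function(counts, max_genes = 6000, min_genes = 200,
                      max_pct_mito = 5, mito_prefix = "mt-") {
  stopifnot(max_genes > 0, min_genes > 0, max_pct_mito > 0)
  qc <- qc_metrics(counts, mito_prefix)
  qc$pass <- !(qc$n_genes_detected > max_genes |
               qc$n_genes_detected < min_genes |
               qc$pct_mito > max_pct_mito)
  if (!any(qc$pass))
    stop("no cells survive QC (", ncol(counts), " cells examined)")
  list(counts = counts[, qc$pass, drop = FALSE], qc = qc)
}

#' Depth-normalize and natural-log transform
#'
#' Scales each cell to `scale_total` total molecules and applies
#' `ln(1 + x)`: entry = `ln(1 + count * scale_total / cell_total)`.
#'
#' @param counts genes x cells count matrix (every cell total > 0).
#' @param scale_total target molecules per cell.
#' @return sparse genes x cells matrix on the natural-log scale, with
#'   attribute `scale_total`.
#' @export
normalize_log <- function(counts, scale_total = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop(sum(totals == 0), " cell(s) with zero total UMIs; ",
         "run qc_filter first")
  norm <- counts %*% Matrix::Diagonal(ncol(counts), scale_total / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm <- methods::as(norm, "CsparseMatrix")
  attr(norm, "scale_total") <- scale_total
  norm
}

#' Regress technical covariates out of normalized expression
#'
#' Per gene, ordinary-least-squares residuals of expression on an
#' intercept plus the given covariates (conventionally total UMIs and
#' percent mitochondrial UMIs). Residuals are exactly orthogonal to every
#' retained design column; collinear covariate columns are dropped with a
#' warning.
#'
#' @param norm genes x cells matrix (from [normalize_log()]).
#' @param covariates cells x k numeric matrix or data frame.
#' @return dense genes x cells residual matrix, attribute
#'   `residualized = TRUE`.
#' @export
regress_covariates <- function(norm, covariates) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != ncol(norm))
    stop("covariates must have one row per cell")
  if (ncol(norm) < 3) stop("need >= 3 cells to regress covariates")
  if (!all(is.finite(covariates))) stop("covariates must be finite")
  X <- cbind(`(Intercept)` = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping collinear covariate column(s): ",
            paste(setdiff(colnames(X), colnames(X)[keep]), collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  resid <- t(qr.resid(qrX, t(as.matrix(norm))))
  dimnames(resid) <- dimnames(norm)
  attr(resid, "residualized") <- TRUE
  resid
}
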