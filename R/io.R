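#' Read a 10x-style count matrix directory
#'
#' Loads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (CellRanger v3)
#' or `genes.tsv` (v2), plain or gzipped, into a sparse genes x cells
#' integer matrix. The features file may have 1-3 columns
#' (id / symbol / type); gene symbols are taken from the second column
#' when present, otherwise the first, and duplicated symbols are
#' disambiguated deterministically with `.1`, `.2`, ... suffixes.
#'
#' @param dir directory containing the three files.
#' @return a `dgCMatrix`, rownames = gene symbols, colnames = barcodes.
#' @export
read_10x_mtx <- function(dir) {
  find1 <- function(cands) {
    for (f in cands) {
      path <- file.path(dir, f)
      if (file.exists(path)) return(path)
    }
    stop("missing file in ", dir, ": expected one of ",
         paste(cands, collapse = ", "))
  }
  mtx_path <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  bc_path <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  ft_path <- find1(c("features.tsv", "features.tsv.gz",
                     "genes.tsv", "genes.tsv.gz"))
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  barcodes <- readLines(bc_path)
  feats <- utils::read.table(ft_path, sep = "\t", header = FALSE,
                             quote = "", comment.char = "",
                             stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop("dimension mismatch: ", basename(ft_path), " has ", nrow(feats),
         " rows but ", basename(mtx_path), " declares ", nrow(m), " genes")
  if (length(barcodes) != ncol(m))
    stop("dimension mismatch: ", basename(bc_path), " has ",
         length(barcodes), " rows but ", basename(mtx_path),
         " declares ", ncol(m), " cells")
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  rownames(m) <- make.unique(symbols, sep = ".")
  colnames(m) <- make.unique(barcodes, sep = ".")
  if (any(m@x < 0)) stop("negative entries in ", basename(mtx_path))
  m
}

#' Write a count matrix in 10x plain-text layout
#'
#' @param counts genes x cells sparse matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_10x_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  feats <- data.frame(id = rownames(counts), symbol = rownames(counts),
                      type = "Gene Expression")
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

read_symbol_file <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (!length(x)) stop("empty gene list file: ", path)
  if (anyDuplicated(x)) {
    warning("dropping ", sum(duplicated(x)), " duplicated symbol(s) in ",
            path)
    x <- unique(x)
  }
  x
}

#' Read S-phase and G2/M gene lists
#'
#' One symbol per line, whitespace-trimmed, case preserved; duplicates
#' within a list are removed with a warning. The two lists must be
#' disjoint — the cell-cycle permutation test resamples labels across
#' their union, which is ill-defined for a shared gene.
#'
#' @param path_s,path_g2m file paths.
#' @return list with `s_genes` and `g2m_genes` character vectors.
#' @export
read_gene_sets <- function(path_s, path_g2m) {
  s <- read_symbol_file(path_s)
  g2m <- read_symbol_file(path_g2m)
  both <- intersect(s, g2m)
  if (length(both))
    stop("S and G2M lists overlap (", paste(both, collapse = ", "), ")")
  list(s_genes = s, g2m_genes = g2m)
}

#' Read a transcription-factor symbol list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of unique TF symbols.
#' @export
read_tf_list <- function(path) {
  read_symbol_file(path)
}
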