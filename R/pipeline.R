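#' Workflow configuration with the standard defaults
#'
#' Collects every stage parameter (QC thresholds, normalization scale,
#' feature-selection rule, clustering, permutation test, trajectory,
#' branch test) plus paths and the seed into one flat list.
#'
#' @param input_dir 10x-layout directory with the count matrix and, for
#'   simulated fixtures, gene-set files; `NULL` to pass a matrix to
#'   [run_all()] directly.
#' @param out_dir where stage tables are written (`NULL`: nowhere).
#' @param s_genes_file,g2m_genes_file cycle gene-set files; default the
#'   fixture names inside `input_dir`.
#' @param tf_file optional transcription-factor list.
#' @param root_cluster cluster id used as the trajectory root; `NULL`
#'   picks the lexicographically first leaf of the MST.
#' @param max_genes,min_genes,max_pct_mito,mito_prefix QC parameters.
#' @param scale_total depth-normalization target.
#' @param n_top_genes top-dispersion gene count.
#' @param ordering_min_mean,ordering_fold ordering-gene rule.
#' @param n_pcs,k_neighbors,resolution reduction/clustering parameters.
#' @param min_prevalence cycle-gene prevalence floor.
#' @param n_perm,alpha permutation count and FDR cutoff.
#' @param seed RNG seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir = NULL, out_dir = NULL,
                       s_genes_file = NULL, g2m_genes_file = NULL,
                       tf_file = NULL, root_cluster = NULL,
                       max_genes = 6000, min_genes = 200,
                       max_pct_mito = 5, mito_prefix = "mt-",
                       scale_total = 1e4, n_top_genes = 2000,
                       ordering_min_mean = 0.05, ordering_fold = 2,
                       n_pcs = 30, k_neighbors = 20, resolution = 1.0,
                       min_prevalence = 0.05, n_perm = 5000,
                       alpha = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a workflow configuration
#'
#' @param cfg a [run_config()] list.
#' @return character vector of all violations (length 0 when valid).
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  for (f in c("max_genes", "min_genes", "max_pct_mito", "scale_total",
              "n_top_genes", "ordering_min_mean", "ordering_fold",
              "n_pcs", "k_neighbors", "resolution", "n_perm", "alpha"))
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] > 0,
        paste0(f, " must be a positive number"))
  if (is.numeric(cfg$min_genes) && is.numeric(cfg$max_genes))
    chk(cfg$min_genes <= cfg$max_genes, "min_genes must be <= max_genes")
  chk(is.numeric(cfg$min_prevalence) && cfg$min_prevalence >= 0 &&
        cfg$min_prevalence <= 1, "min_prevalence must lie in [0,1]")
  if (!is.null(cfg$input_dir))
    chk(dir.exists(cfg$input_dir),
        paste0("input_dir does not exist: ", cfg$input_dir))
  for (f in c("s_genes_file", "g2m_genes_file", "tf_file"))
    if (!is.null(cfg[[f]]))
      chk(file.exists(cfg[[f]]), paste0(f, " does not exist: ", cfg[[f]]))
  errs
}

write_stage <- function(out_dir, name, tab) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(tab, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full workflow
#'
#' Executes read -> QC -> normalize/regress -> dispersion & gene
#' selection -> PCA/cluster/markers -> cell-cycle permutation test ->
#' MST trajectory/pseudotime -> branch-dependent expression, writing
#' each stage's table under `cfg$out_dir` and returning all results plus
#' a run report (parameters, seed, per-stage row counts). Rerunning with
#' the same config and seed reproduces every output.
#'
#' @param cfg a validated [run_config()].
#' @param counts optional genes x cells count matrix (used when
#'   `cfg$input_dir` is `NULL`).
#' @param gene_sets optional list(s_genes, g2m_genes), overriding files.
#' @return list of stage results and `report`.
#' @export
run_all <- function(cfg, counts = NULL, gene_sets = NULL) {
  errs <- validate_config(cfg)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  report <- list(seed = cfg$seed, stages = list())
  tick <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## io
  if (is.null(counts)) {
    if (is.null(cfg$input_dir)) stop("stage 'io' failed: no input")
    counts <- run_stage("io", read_10x_mtx(cfg$input_dir))
  }
  if (is.null(gene_sets)) {
    sf <- cfg$s_genes_file
    gf <- cfg$g2m_genes_file
    if (is.null(sf) && !is.null(cfg$input_dir))
      sf <- file.path(cfg$input_dir, "s_genes.txt")
    if (is.null(gf) && !is.null(cfg$input_dir))
      gf <- file.path(cfg$input_dir, "g2m_genes.txt")
    gene_sets <- run_stage("io", read_gene_sets(sf, gf))
  }
  tick("io", n_genes = nrow(counts), n_cells = ncol(counts))

  ## qc
  qc <- run_stage("qc", qc_filter(counts, cfg$max_genes, cfg$min_genes,
                                  cfg$max_pct_mito, cfg$mito_prefix))
  write_stage(cfg$out_dir, "qc_report", qc$qc)
  tick("qc", n_pass = sum(qc$qc$pass), n_fail = sum(!qc$qc$pass))

  ## normalize + regress
  norm <- run_stage("normalize", normalize_log(qc$counts, cfg$scale_total))
  covs <- qc$qc[qc$qc$pass, c("n_umi", "pct_mito")]
  resid <- run_stage("normalize", regress_covariates(norm, covs))
  tick("normalize", scale_total = cfg$scale_total)

  ## features
  disp <- run_stage("features", fit_dispersion_trend(
    estimate_dispersion(qc$counts, cfg$scale_total)))
  ordering <- select_ordering_genes(disp, cfg$ordering_min_mean,
                                    cfg$ordering_fold)
  top <- select_top_dispersion(disp, min(cfg$n_top_genes, nrow(disp)))
  disp$ordering_flag <- disp$gene_id %in% ordering
  write_stage(cfg$out_dir, "dispersion_table", disp)
  tick("features", n_ordering = length(ordering), n_top = length(top))

  ## cluster
  pca_genes <- if (length(ordering) >= cfg$n_pcs + 1) ordering else top
  pcs <- run_stage("cluster", run_pca(norm, pca_genes, cfg$n_pcs))
  clusters <- run_stage("cluster", cluster_cells(
    pcs, cfg$k_neighbors, cfg$resolution, cfg$seed))
  markers <- run_stage("cluster", {
    do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
      m <- find_markers(norm, clusters, cl, genes = pca_genes)
      m$cluster <- cl
      utils::head(m, 50)
    }))
  })
  write_stage(cfg$out_dir, "clusters",
              data.frame(cell_id = names(clusters), cluster = clusters))
  write_stage(cfg$out_dir, "markers", markers)
  tick("cluster", n_clusters = length(unique(clusters)))

  ## cellcycle
  cycle <- run_stage("cellcycle", {
    sets <- filter_cycle_genes(norm, gene_sets, cfg$min_prevalence)
    scores <- cycle_scores(norm, sets, B = cfg$n_perm, seed = cfg$seed)
    calls <- classify_proliferative(scores, clusters, cfg$alpha)
    list(sets = sets, calls = calls,
         fractions = proliferative_fraction(calls))
  })
  write_stage(cfg$out_dir, "proliferation_calls", cycle$calls)
  write_stage(cfg$out_dir, "proliferative_fractions", cycle$fractions)
  tick("cellcycle", n_s = length(cycle$sets$s_used),
       n_g2m = length(cycle$sets$g2m_used),
       n_proliferative = sum(cycle$calls$proliferative))

  ## trajectory
  traj <- run_stage("trajectory", {
    tree <- build_mst(pcs, clusters)
    root <- cfg$root_cluster
    if (is.null(root)) {
      adj <- tree_adjacency(tree)
      leaves <- sort(names(adj)[lengths(adj) == 1])
      root <- leaves[1]
    }
    tree <- extract_lineages(tree, root)
    pt <- assign_pseudotime(pcs, clusters, tree)
    list(tree = tree, pt = pt)
  })
  write_stage(cfg$out_dir, "pseudotime", traj$pt)
  tick("trajectory", n_lineages = length(traj$tree$lineages),
       root = traj$tree$root)

  ## branches
  branches <- run_stage("branches", {
    counts_f <- qc$counts
    test_genes <- intersect(ordering, rownames(counts_f))
    if (length(unique(traj$pt$branch[traj$pt$branch != "trunk"])) == 2 &&
        min(table(traj$pt$branch[traj$pt$branch != "trunk"])) >= 10) {
      bt <- branch_dependence_test(counts_f, traj$pt$pseudotime,
                                   traj$pt$branch, genes = test_genes)
      if (!is.null(cfg$tf_file))
        bt_tf <- filter_tfs(bt, read_tf_list(cfg$tf_file))
      else bt_tf <- NULL
      list(test = bt, tf = bt_tf)
    } else list(test = NULL, tf = NULL)
  })
  if (!is.null(branches$test))
    write_stage(cfg$out_dir, "branch_test", branches$test)
  tick("branches",
       n_branch_dependent = if (is.null(branches$test)) 0L
                            else sum(branches$test$branch_dependent))

  report$params <- unclass(cfg)
  list(counts = counts, qc = qc, norm = norm, resid = resid,
       dispersion = disp, ordering_genes = ordering, top_genes = top,
       pcs = pcs, clusters = clusters, markers = markers,
       cellcycle = cycle, trajectory = traj, branches = branches,
       report = report)
}
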