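#' Simulation parameters for a bifurcating mesenchymal lineage
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' simulated populations sit on a Y-shaped differentiation topology: a
#' trunk of progenitor populations (root first), ending in a branch-point
#' population from which an osteogenic and an adipogenic branch each run
#' to a terminal population. Each population occupies a unit-length
#' pseudotime interval along its lineage; gene mean curves are
#' piecewise-linear in log space between population anchor points.
#'
#' Defaults emulate an endosteal bone-marrow mesenchymal dataset: six
#' populations (EMP root, LMP, LCP branch point, OB and Ocy on the
#' osteogenic branch, AD terminal on the adipogenic branch), ~10k UMIs
#' per cell, negative-binomial counts, a cycling subpopulation
#' concentrated in the progenitor states, and `mt-` prefixed
#' mitochondrial genes for QC.
#'
#' @param n_cells_per_population cells drawn per population.
#' @param populations_trunk,populations_osteo,populations_adipo ordered
#'   population names; trunk starts at the root and ends at the branch
#'   point, each branch ends at its terminus.
#' @param n_genes total gene count.
#' @param n_marker_genes_per_population genes up-shifted in exactly one
#'   population (tent-shaped anchor curve).
#' @param n_branch_genes_per_branch genes ramping up along one branch
#'   after the branch point, flat on the other.
#' @param marker_log_fc,branch_log_fc natural-log effect sizes at the
#'   marker population / branch terminus.
#' @param libsize_lognormal_mu_sigma length-2 numeric: meanlog and sdlog
#'   of per-cell library sizes.
#' @param nb_dispersion per-gene NB dispersion phi (variance =
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param frac_mito_genes fraction of genes given the `mt-` prefix.
#' @param cycling_fraction_per_population named numeric in \[0,1\] per
#'   population; unnamed scalar recycles to all populations.
#' @param cycle_effect_delta natural-log mean shift applied to the one
#'   cycle module (S or G2M, chosen 50/50) of each cycling cell.
#' @param n_s_genes,n_g2m_genes sizes of the planted S and G2M modules.
#' @param seed RNG seed; identical params + seed give identical output.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_cells_per_population = 500,
                       populations_trunk = c("EMP", "LMP", "LCP"),
                       populations_osteo = c("OB", "Ocy"),
                       populations_adipo = c("AD"),
                       n_genes = 2000,
                       n_marker_genes_per_population = 40,
                       n_branch_genes_per_branch = 50,
                       marker_log_fc = log(8),
                       branch_log_fc = log(2),
                       libsize_lognormal_mu_sigma = c(log(1e4), 0.3),
                       nb_dispersion = 0.3,
                       cycling_fraction_per_population = c(
                         EMP = 0.20, LMP = 0.15, LCP = 0.10,
                         OB = 0.05, Ocy = 0, AD = 0),
                       cycle_effect_delta = 1.0,
                       n_s_genes = 43,
                       n_g2m_genes = 54,
                       frac_mito_genes = 0.02,
                       seed = 1L) {
  p <- list(
    n_cells_per_population = as.integer(n_cells_per_population),
    populations_trunk = as.character(populations_trunk),
    populations_osteo = as.character(populations_osteo),
    populations_adipo = as.character(populations_adipo),
    n_genes = as.integer(n_genes),
    n_marker_genes_per_population = as.integer(n_marker_genes_per_population),
    n_branch_genes_per_branch = as.integer(n_branch_genes_per_branch),
    marker_log_fc = marker_log_fc,
    branch_log_fc = branch_log_fc,
    libsize_lognormal_mu_sigma = libsize_lognormal_mu_sigma,
    nb_dispersion = nb_dispersion,
    cycling_fraction_per_population = cycling_fraction_per_population,
    cycle_effect_delta = cycle_effect_delta,
    n_s_genes = as.integer(n_s_genes),
    n_g2m_genes = as.integer(n_g2m_genes),
    frac_mito_genes = frac_mito_genes,
    seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  pops <- c(p$populations_trunk, p$populations_osteo, p$populations_adipo)
  if (length(p$populations_trunk) < 1)
    stop("invalid topology: trunk must contain at least the root population")
  if (length(p$populations_osteo) < 1 || length(p$populations_adipo) < 1)
    stop("invalid topology: each branch needs >= 1 population ",
         "(exactly one root, one branch point, two termini required)")
  if (anyDuplicated(pops))
    stop("invalid topology: duplicated population name")
  if (p$n_cells_per_population < 1) stop("n_cells_per_population must be >= 1")
  cyc <- p$cycling_fraction_per_population
  if (length(cyc) == 1 && is.null(names(cyc)))
    cyc <- stats::setNames(rep(cyc, length(pops)), pops)
  if (!all(pops %in% names(cyc)))
    stop("cycling_fraction_per_population must name every population")
  if (any(cyc < 0 | cyc > 1)) stop("cycling fractions must lie in [0,1]")
  if (p$frac_mito_genes < 0 || p$frac_mito_genes > 1)
    stop("frac_mito_genes must lie in [0,1]")
  if (p$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (p$cycle_effect_delta <= 0) stop("cycle_effect_delta must be > 0")
  if (p$n_s_genes < 1 || p$n_g2m_genes < 1)
    stop("cycle module sizes must be positive")
  n_structured <- p$n_marker_genes_per_population * length(pops) +
    2L * p$n_branch_genes_per_branch + p$n_s_genes + p$n_g2m_genes +
    ceiling(p$frac_mito_genes * p$n_genes)
  if (n_structured > p$n_genes)
    stop("n_genes too small for the requested structured genes (",
         n_structured, " needed)")
  invisible(p)
}

# population table: unit-length pseudotime interval per population,
# lineage membership, and per-lineage anchor (interval midpoint)
sim_topology <- function(p) {
  trunk <- p$populations_trunk
  nt <- length(trunk)
  tab <- rbind(
    data.frame(population = trunk, branch = "trunk",
               t_start = seq_len(nt) - 1, t_end = seq_len(nt),
               stringsAsFactors = FALSE),
    data.frame(population = p$populations_osteo, branch = "osteo",
               t_start = nt + seq_along(p$populations_osteo) - 1,
               t_end = nt + seq_along(p$populations_osteo),
               stringsAsFactors = FALSE),
    data.frame(population = p$populations_adipo, branch = "adipo",
               t_start = nt + seq_along(p$populations_adipo) - 1,
               t_end = nt + seq_along(p$populations_adipo),
               stringsAsFactors = FALSE))
  tab$t_mid <- (tab$t_start + tab$t_end) / 2
  tab
}

# two anchor points per population, inset from the interval ends so that
# population programs plateau across their own interval with narrow
# linear shoulders (width 2*inset) into the neighbouring population
anchor_grid <- function(topo, pops, inset = 0.1) {
  row <- match(pops, topo$population)
  list(t = as.vector(rbind(topo$t_start[row] + inset,
                           topo$t_end[row] - inset)))
}

# piecewise-linear interpolation of per-population anchor values along a
# lineage (constant beyond the first/last anchor midpoint)
interp_anchor <- function(t, anchor_t, anchor_v) {
  stats::approx(anchor_t, anchor_v, xout = t, rule = 2)$y
}

#' Simulate a bifurcating-lineage scRNA-seq dataset with ground truth
#'
#' Draws negative-binomial UMI counts for cells placed along a Y-shaped
#' lineage. Per-cell gene means are library-size-scaled relative
#' expression weights `exp(eta)`, where `eta` is a baseline per-gene
#' level plus piecewise-linear program effects along pseudotime (marker
#' tents, branch ramps) and, for cycling cells, a `cycle_effect_delta`
#' up-shift of one cycle module.
#'
#' @param params a [sim_params()] object.
#' @return list with `counts` (sparse genes x cells dgCMatrix) and
#'   `truth` (list of `cells` and `genes` data frames: population,
#'   pseudotime, branch, cycling flag and phase per cell; program type
#'   and target population/branch per gene).
#' @export
simulate_dataset <- function(params) {
  validate_sim_params(params)
  p <- params
  set.seed(p$seed)
  topo <- sim_topology(p)
  pops <- topo$population
  npop <- length(pops)
  n_cells <- p$n_cells_per_population * npop

  ## --- cells -------------------------------------------------------------
  population <- rep(pops, each = p$n_cells_per_population)
  row <- match(population, topo$population)
  pt <- stats::runif(n_cells, topo$t_start[row], topo$t_end[row])
  branch <- topo$branch[row]
  cyc <- p$cycling_fraction_per_population
  if (length(cyc) == 1 && is.null(names(cyc)))
    cyc <- stats::setNames(rep(cyc, npop), pops)
  cycling <- stats::runif(n_cells) < cyc[population]
  phase <- rep(NA_character_, n_cells)
  phase[cycling] <- sample(c("S", "G2M"), sum(cycling), replace = TRUE)
  libsize <- stats::rlnorm(n_cells, p$libsize_lognormal_mu_sigma[1],
                           p$libsize_lognormal_mu_sigma[2])
  cell_id <- sprintf("cell-%04d", seq_len(n_cells))

  ## --- genes -------------------------------------------------------------
  n_mito <- ceiling(p$frac_mito_genes * p$n_genes)
  gene_tab <- data.frame(
    gene_id = character(0), program = character(0), target = character(0),
    stringsAsFactors = FALSE)
  add <- function(tab, ids, program, target) {
    rbind(tab, data.frame(gene_id = ids, program = program, target = target,
                          stringsAsFactors = FALSE))
  }
  for (pop in pops) {
    if (p$n_marker_genes_per_population > 0)
      gene_tab <- add(gene_tab,
        sprintf("Mark%s.%02d", pop, seq_len(p$n_marker_genes_per_population)),
        "marker", pop)
  }
  if (p$n_branch_genes_per_branch > 0) {
    gene_tab <- add(gene_tab,
      sprintf("Osteo.%03d", seq_len(p$n_branch_genes_per_branch)),
      "branch", "osteo")
    gene_tab <- add(gene_tab,
      sprintf("Adipo.%03d", seq_len(p$n_branch_genes_per_branch)),
      "branch", "adipo")
  }
  gene_tab <- add(gene_tab, sprintf("Sgene.%02d", seq_len(p$n_s_genes)),
                  "cycle-S", "S")
  gene_tab <- add(gene_tab, sprintf("G2mgene.%02d", seq_len(p$n_g2m_genes)),
                  "cycle-G2M", "G2M")
  if (n_mito > 0)
    gene_tab <- add(gene_tab, sprintf("mt-%02d", seq_len(n_mito)),
                    "mito", NA_character_)
  n_bg <- p$n_genes - nrow(gene_tab)
  gene_tab <- add(gene_tab, sprintf("Bg.%04d", seq_len(n_bg)),
                  "background", NA_character_)
  stopifnot(nrow(gene_tab) == p$n_genes)

  base_eta <- stats::rnorm(p$n_genes, 0, 1.2)
  # keep the planted cycle modules reliably detected (>= 5% prevalence)
  is_cycle <- gene_tab$program %in% c("cycle-S", "cycle-G2M")
  base_eta[is_cycle] <- stats::rnorm(sum(is_cycle), 0.5, 0.5)

  ## --- log-mean matrix ---------------------------------------------------
  # eta[g, c] = base + program effect evaluated at the cell's pseudotime
  eta <- matrix(base_eta, nrow = p$n_genes, ncol = n_cells)
  lineages <- list(
    osteo = c(p$populations_trunk, p$populations_osteo),
    adipo = c(p$populations_trunk, p$populations_adipo))
  # cells interpolate along their own lineage; trunk cells use trunk anchors
  cell_lineage <- ifelse(branch == "trunk", NA, branch)
  t_branch <- max(topo$t_end[topo$branch == "trunk"])
  gene_anchor_values <- function(g, grid_t, lineage_pops) {
    if (gene_tab$program[g] == "marker") {
      # full effect in the marker's own population, a reduced shoulder
      # in its immediate lineage neighbours: differentiation programs
      # change progressively, not as isolated islands
      spill <- 0.35
      vals <- stats::setNames(numeric(length(lineage_pops)), lineage_pops)
      k <- match(gene_tab$target[g], lineage_pops)
      if (!is.na(k)) {
        vals[k] <- p$marker_log_fc
        if (k > 1) vals[k - 1] <- spill * p$marker_log_fc
        if (k < length(lineage_pops))
          vals[k + 1] <- spill * p$marker_log_fc
      }
      rep(vals, each = 2)
    } else {                                # branch ramp, evaluated at t
      on_branch <- gene_tab$target[g] ==
        topo$branch[match(lineage_pops, topo$population)]
      ramp_end <- max(grid_t)
      v <- p$branch_log_fc * pmax(0, grid_t - t_branch) /
        (ramp_end - t_branch)
      v * rep(as.numeric(on_branch), each = 2)
    }
  }
  for (g in which(gene_tab$program %in% c("marker", "branch"))) {
    for (ln in names(lineages)) {
      idx <- which(cell_lineage == ln)
      if (!length(idx)) next
      grid <- anchor_grid(topo, lineages[[ln]])
      eta[g, idx] <- eta[g, idx] +
        interp_anchor(pt[idx], grid$t,
                      gene_anchor_values(g, grid$t, lineages[[ln]]))
    }
    idx <- which(is.na(cell_lineage))
    if (length(idx)) {
      grid <- anchor_grid(topo, p$populations_trunk)
      eta[g, idx] <- eta[g, idx] +
        interp_anchor(pt[idx], grid$t,
                      gene_anchor_values(g, grid$t, p$populations_trunk))
    }
  }
  s_rows <- which(gene_tab$program == "cycle-S")
  g2m_rows <- which(gene_tab$program == "cycle-G2M")
  if (any(cycling)) {
    eta[s_rows, which(cycling & phase == "S")] <-
      eta[s_rows, which(cycling & phase == "S")] + p$cycle_effect_delta
    eta[g2m_rows, which(cycling & phase == "G2M")] <-
      eta[g2m_rows, which(cycling & phase == "G2M")] + p$cycle_effect_delta
  }

  ## --- counts ------------------------------------------------------------
  w <- exp(eta)
  mu <- sweep(w, 2, colSums(w), "/")
  mu <- sweep(mu, 2, libsize, "*")
  counts <- if (p$nb_dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion),
           nrow = p$n_genes)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = p$n_genes)
  }
  dimnames(counts) <- list(gene_tab$gene_id, cell_id)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  truth_cells <- data.frame(
    cell_id = cell_id, population = population, pseudotime = pt,
    branch = branch, cycling = cycling, phase = phase,
    libsize_expected = libsize, stringsAsFactors = FALSE)
  list(counts = counts,
       truth = list(cells = truth_cells, genes = gene_tab,
                    topology = topo, params = p))
}

#' Write a simulated dataset as a 10x-style plain-text fixture
#'
#' Emits `matrix.mtx`, `barcodes.tsv`, `features.tsv` (CellRanger v3
#' three-column layout), the ground-truth tables (`cell_truth.tsv`,
#' `gene_truth.tsv`) and the planted cycle gene lists (`s_genes.txt`,
#' `g2m_genes.txt`, one symbol per line).
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                            "cell_truth.tsv", "gene_truth.tsv",
                            "s_genes.txt", "g2m_genes.txt"))
  write_10x_mtx(sim$counts, dir)
  utils::write.table(sim$truth$cells, paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, paths[5], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- sim$truth$genes
  writeLines(g$gene_id[g$program == "cycle-S"], paths[6])
  writeLines(g$gene_id[g$program == "cycle-G2M"], paths[7])
  invisible(paths)
}
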