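# small planted two-branch dataset generated outside the package's
# simulator: explicit NB draws with known branch effects
branch_toy <- function(seed, n_per_branch = 200, n_null = 40,
                       n_branch = 10, lfc = log(2), phi = 0.3) {
  set.seed(seed)
  n <- 2 * n_per_branch
  pt <- runif(n, 0, 2)
  branch <- rep(c("osteo", "adipo"), each = n_per_branch)
  L <- rlnorm(n, log(5e3), 0.3)
  # moderately expressed genes (a few counts per cell)
  base <- exp(rnorm(n_null + n_branch, log(8), 0.5)) / 1e4
  mu <- outer(base, L)
  for (g in seq_len(n_branch))
    mu[g, branch == "osteo"] <- mu[g, branch == "osteo"] *
      exp(lfc * pt[branch == "osteo"] / 2)
  y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), nrow(mu))
  dimnames(y) <- list(c(sprintf("Br%02d", seq_len(n_branch)),
                        sprintf("Null%02d", seq_len(n_null))),
                      paste0("c", 1:n))
  list(counts = Matrix::Matrix(y, sparse = TRUE), pt = pt,
       branch = branch)
}

test_that("LRT degrees of freedom follow the model construction", {
  toy <- branch_toy(1)
  res <- branch_dependence_test(toy$counts, toy$pt, toy$branch,
                                genes = "Br01")
  # branch intercept + 3 branch-specific spline contrasts
  expect_equal(res$df, 4)
})

test_that("planted branch genes are detected, identical-curve genes are
           not", {
  toy <- branch_toy(2)
  res <- branch_dependence_test(toy$counts, toy$pt, toy$branch)
  planted <- startsWith(res$gene_id, "Br")
  expect_gte(mean(res$branch_dependent[planted]), 0.8)
  expect_lte(mean(res$branch_dependent[!planted]), 0.1)
  expect_true(all(res$lrt >= 0))
  expect_true(all(res$p_adj >= res$p_value))
})

test_that("all-zero genes are flat with p = 1 and no fit", {
  toy <- branch_toy(3)
  counts <- toy$counts
  counts[5, ] <- 0L
  res <- branch_dependence_test(counts, toy$pt, toy$branch)
  row <- res[res$gene_id == rownames(counts)[5], ]
  expect_equal(row$p_value, 1)
  expect_equal(row$fit, "none")
  expect_false(row$branch_dependent)
})

test_that("branch test guards its preconditions", {
  toy <- branch_toy(4)
  expect_error(branch_dependence_test(toy$counts, toy$pt,
                                      rep("osteo", length(toy$branch))),
               "exactly 2")
  small <- c(rep("osteo", 5), rep("adipo", 395))
  expect_error(branch_dependence_test(toy$counts, toy$pt, small),
               ">= 10 cells")
})

test_that("lineage trends recover planted monotone genes and stay flat
           under shuffled pseudotime", {
  toy <- branch_toy(5)
  cells <- toy$branch == "osteo"
  res <- lineage_trend(toy$counts, toy$pt, cells)
  planted <- startsWith(res$gene_id, "Br")
  expect_true(all(res$direction[planted & res$p_adj < 0.05] == "up"))
  expect_gte(mean(res$direction[planted] == "up"), 0.8)
  # global null by permuting pseudotime: >= 95% flat
  set.seed(6)
  resn <- lineage_trend(toy$counts, sample(toy$pt), cells)
  expect_gte(mean(resn$direction == "flat"), 0.95)
  # constant all-zero gene
  counts <- toy$counts; counts[3, ] <- 0L
  resz <- lineage_trend(counts, toy$pt, cells)
  expect_equal(resz$direction[3], "flat")
  expect_equal(resz$p_value[3], 1)
})

test_that("TF filtering is an order-preserving, idempotent intersection", {
  tab <- data.frame(gene_id = paste0("g", 10:1), stat = 1:10)
  tfs <- c("g3", "g7", "g9")
  got <- filter_tfs(tab, tfs)
  expect_equal(got$gene_id, c("g9", "g7", "g3"))
  expect_identical(filter_tfs(got, tfs), got)
  expect_equal(nrow(filter_tfs(tab, "absent")), 0)
})

test_that("heatmap ordering centres the branch point and groups genes
           by peaking branch", {
  set.seed(7)
  n <- 300
  pt <- runif(n, 0, 2)
  branch <- rep(c("adipo", "osteo"), each = n / 2)
  norm <- rbind(
    osteo_up = ifelse(branch == "osteo", pt, 0) + rnorm(n, 0, 0.05),
    adipo_up = ifelse(branch == "adipo", pt, 0) + rnorm(n, 0, 0.05),
    constant = rep(1, n))
  colnames(norm) <- paste0("c", 1:n)
  M <- heatmap_order(norm, pt, branch, rownames(norm), n_bins = 10)
  pk <- attr(M, "peak_branch")
  expect_equal(unname(pk["osteo_up"]), "osteo")
  expect_equal(unname(pk["adipo_up"]), "adipo")
  # osteo-peaking block precedes the adipo-peaking block
  expect_lt(which(rownames(M) == "osteo_up"),
            which(rownames(M) == "adipo_up"))
  expect_equal(ncol(M), 20)
  expect_true(startsWith(colnames(M)[1], "adipo_bin10"))
  # constant gene is flat after smoothing
  expect_lt(diff(range(M["constant", ])), 1e-8)
  # single bin per branch equals the branch means
  M1 <- heatmap_order(norm, pt, branch, rownames(norm), n_bins = 1,
                      smooth_window = 1)
  expect_equal(M1["constant", ], c(adipo_bin1 = 1, osteo_bin1 = 1))
})

test_that("heatmap ordering is invariant to input row order", {
  set.seed(8)
  n <- 200
  pt <- runif(n, 0, 2)
  branch <- rep(c("adipo", "osteo"), each = n / 2)
  norm <- matrix(rnorm(8 * n), 8, n,
                 dimnames = list(paste0("g", 1:8), paste0("c", 1:n)))
  M1 <- heatmap_order(norm, pt, branch, rownames(norm))
  M2 <- heatmap_order(norm[sample(8), ], pt, branch, rev(rownames(norm)))
  attr(M1, "peak_branch") <- NULL
  expect_equal(M1, M2[rownames(M1), , drop = FALSE])
})
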