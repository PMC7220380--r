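test_that("prevalence filter drops rare genes and keeps ubiquitous sets
           intact", {
  set.seed(30)
  n <- 200
  norm <- rbind(
    matrix(runif(43 * n, 0.5, 2), 43, n),   # ubiquitous S genes
    matrix(runif(54 * n, 0.5, 2), 54, n),   # ubiquitous G2M genes
    rare = c(rep(1, 8), rep(0, n - 8)))     # nonzero in 4% of cells
  rownames(norm) <- c(sprintf("Sg%02d", 1:43), sprintf("Gg%02d", 1:54),
                      "rare")
  colnames(norm) <- paste0("c", 1:n)
  sets <- list(s_genes = c(sprintf("Sg%02d", 1:43), "rare"),
               g2m_genes = sprintf("Gg%02d", 1:54))
  got <- filter_cycle_genes(norm, sets, min_prevalence = 0.05)
  expect_length(got$s_used, 43)
  expect_length(got$g2m_used, 54)
  expect_equal(got$dropped$gene_id, "rare")
  expect_equal(got$dropped$reason, "low_prevalence")
  # min_prevalence = 0 is the identity filter
  all_kept <- filter_cycle_genes(norm, sets, min_prevalence = 0)
  expect_length(all_kept$s_used, 44)
  # a set emptied by the filter is an error
  bad <- list(s_genes = "rare", g2m_genes = sets$g2m_genes)
  expect_error(filter_cycle_genes(norm, bad, 0.05), "empty")
})

test_that("all-equal expression gives zero difference and p = 1", {
  res <- permutation_pvalue(rep(3.3, 79), n_s = 34, B = 200, seed = 1)
  expect_equal(res$observed_diff, 0)
  expect_equal(res$p_value, 1)
})

test_that("exhaustive toy matches the enumeration oracle", {
  values <- c(10, 10, 0, 0, 0)
  res <- permutation_pvalue(values, n_s = 2, exhaustive = "on")
  expect_equal(res$observed_diff, 10)
  # frozen from perm_pvalue_oracle: only the observed split attains
  # |diff| = 10 among the C(5,2) = 10 splits
  expect_equal(perm_pvalue_oracle(values, 2), 0.1)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exhaustive)
})

test_that("Monte-Carlo p attains its add-one floor for an extreme cell", {
  values <- c(rep(10, 34), rep(0, 45))
  res <- permutation_pvalue(values, n_s = 34, B = 5000, seed = 3,
                            exhaustive = "off")
  expect_equal(res$p_value, 1 / 5001)
})

test_that("Monte-Carlo agrees with exhaustive enumeration within
           sampling error", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    n_s <- sample(2:(n - 2), 1)
    values <- rnorm(n)
    p_ex <- permutation_pvalue(values, n_s, exhaustive = "on")$p_value
    p_mc <- permutation_pvalue(values, n_s, B = 5000, seed = i,
                               exhaustive = "off")$p_value
    expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 5000) + 2e-4)
  }
})

test_that("p-values are invariant to exchanging the S and G2M labels", {
  set.seed(32)
  values <- rnorm(20)
  a <- permutation_pvalue(values, 8, exhaustive = "on")
  b <- permutation_pvalue(c(values[9:20], values[1:8]), 12,
                          exhaustive = "on")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$observed_diff, -b$observed_diff)
})

test_that("degenerate set sizes are rejected", {
  expect_error(permutation_pvalue(rnorm(10), 0), "n_s")
  expect_error(permutation_pvalue(rnorm(10), 10), "n_s")
  expect_error(permutation_pvalue(rnorm(10), 4, B = 0), "B")
})

test_that("shared resample streams make per-run results reproducible", {
  set.seed(33)
  norm <- matrix(runif(20 * 30), 20, 30,
                 dimnames = list(c(sprintf("Sg%d", 1:9),
                                   sprintf("Gg%d", 1:11)),
                                 paste0("c", 1:30)))
  sets <- list(s_used = sprintf("Sg%d", 1:9),
               g2m_used = sprintf("Gg%d", 1:11))
  a <- cycle_scores(norm, sets, B = 500, seed = 7, exhaustive = "off")
  b <- cycle_scores(norm, sets, B = 500, seed = 7, exhaustive = "off")
  expect_identical(a, b)
})

test_that("per-cluster BH matches the hand computation", {
  # cluster A: 10 cells p = 0.001 and 90 cells p = 1
  # BH for the ten = 0.001 * 100 / 10 = 0.01 < 0.05 -> proliferative
  scores <- data.frame(
    cell_id = paste0("c", 1:200),
    observed_diff = c(rep(2, 10), rep(0, 90), rep(-1, 100)),
    p_value = c(rep(0.001, 10), rep(1, 90), rep(1, 100)))
  clusters <- rep(c("A", "B"), each = 100)
  calls <- classify_proliferative(scores, clusters, alpha = 0.05)
  expect_equal(calls$fdr[1:10], rep(0.01, 10))
  expect_equal(sum(calls$proliferative[calls$cluster == "A"]), 10)
  expect_equal(sum(calls$proliferative[calls$cluster == "B"]), 0)
  expect_equal(calls$dominant_set[1:10], rep("S", 10))
  expect_equal(calls$dominant_set[11], "none")
  frac <- proliferative_fraction(calls)
  expect_equal(frac$fraction[frac$cluster == "A"], 0.1)
  expect_equal(frac$fraction[frac$cluster == "B"], 0)
  # alpha = 0: nothing is proliferative
  none <- classify_proliferative(scores, clusters, alpha = 0)
  expect_equal(sum(none$proliferative), 0)
})

test_that("proliferative fractions agree with a hand count on a 20-cell
           toy and stay within [0,1]", {
  scores <- data.frame(cell_id = paste0("c", 1:20),
                       observed_diff = rep(c(1, -1), 10),
                       p_value = rep(c(1e-6, 1), 10))
  calls <- classify_proliferative(scores, rep(c("x", "y"), each = 10))
  frac <- proliferative_fraction(calls)
  hand <- tapply(calls$proliferative, calls$cluster, mean)
  expect_equal(frac$fraction, as.numeric(hand[frac$cluster]))
  expect_true(all(frac$fraction >= 0 & frac$fraction <= 1))
  # fully proliferative cluster reaches exactly 1
  all_sig <- classify_proliferative(
    data.frame(cell_id = paste0("c", 1:5), observed_diff = 1,
               p_value = 1e-9), rep("z", 5))
  expect_equal(proliferative_fraction(all_sig)$fraction, 1)
})
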