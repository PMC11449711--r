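# Coexpression preselection: similarity, soft threshold, modules, hub genes.

block_expr <- function(seed = 1, block = 10, noise = 20, m = 40, sd_noise = 0.3) {
  set.seed(seed)
  f1 <- rnorm(m); f2 <- rnorm(m)
  vals <- rbind(
    t(sapply(seq_len(block), function(i) f1 + rnorm(m, sd = sd_noise))),
    t(sapply(seq_len(block), function(i) f2 + rnorm(m, sd = sd_noise))),
    matrix(rnorm(noise * m), noise, m))
  expression_matrix(vals, gene_ids = c(sprintf("b1_%02d", seq_len(block)),
                                       sprintf("b2_%02d", seq_len(block)),
                                       sprintf("ns_%02d", seq_len(noise))))
}

test_that("similarity is definitional Pearson correlation", {
  e <- expression_matrix(rbind(a = c(1, 2, 3), b = c(2, 4, 6),
                               c = c(-1, -2, -3), d = c(1, 2, 4)))
  S <- similarity_matrix(e)
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  # closed-form Pearson on the 3 points of (1,2,3) vs (1,2,4)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(S["a", "d"], r_hand, tolerance = 1e-14)

  e0 <- expression_matrix(rbind(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_error(similarity_matrix(e0), "zero-variance.*a")
})

test_that("soft thresholding is the beta power of |s| and order preserving", {
  S <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(soft_threshold_adjacency(S, 2)[1, 2], 0.25)
  expect_equal(soft_threshold_adjacency(matrix(1, 1, 1), 14)[1, 1], 1)
  expect_equal(soft_threshold_adjacency(matrix(0, 1, 1), 6)[1, 1], 0)
  expect_error(soft_threshold_adjacency(S, 0), "beta")

  set.seed(2)
  s <- runif(20, -0.99, 0.99)
  a3 <- abs(s)^3; a7 <- abs(s)^7
  expect_identical(order(a3), order(abs(s)))       # order preserved
  expect_true(all(a7 <= a3 + 1e-15))               # raising beta weakens
})

test_that("soft-threshold selection returns a scale-free beta or falls back", {
  e <- block_expr(3, block = 15, noise = 30, m = 30)
  res <- suppressWarnings(pick_soft_threshold(e, candidates = 1:12))
  expect_true(res$beta %in% 1:12)
  expect_identical(nrow(res$fit_table), 12L)
  expect_true(all(is.na(res$fit_table$signed_r2) |
                    abs(res$fit_table$signed_r2) <= 1))

  single <- suppressWarnings(pick_soft_threshold(e, candidates = 14))
  expect_identical(single$beta, 14)

  set.seed(9)
  white <- expression_matrix(matrix(rnorm(30 * 20), 30,
                                    dimnames = list(paste0("g", 1:30), NULL)))
  expect_warning(pick_soft_threshold(white, candidates = 1:4), "falling back")
})

test_that("module detection recovers planted blocks deterministically", {
  e <- block_expr(7, block = 10, noise = 20, m = 40)
  A <- soft_threshold_adjacency(similarity_matrix(e), 6)
  mods <- detect_modules(A, min_size = 5, cut_height = 0.9)
  b1 <- mods$module[grepl("^b1", mods$gene)]
  b2 <- mods$module[grepl("^b2", mods$gene)]
  expect_identical(length(unique(b1)), 1L)
  expect_identical(length(unique(b2)), 1L)
  expect_false(unique(b1) %in% c("grey", unique(b2)))
  expect_true(all(mods$module[grepl("^ns", mods$gene)] == "grey"))

  # permuting gene order leaves the assignment invariant
  perm <- sample(nrow(e))
  A2 <- soft_threshold_adjacency(similarity_matrix(expression_matrix(e[perm, ])), 6)
  mods2 <- detect_modules(A2, min_size = 5, cut_height = 0.9)
  m1 <- setNames(mods$module, mods$gene)
  m2 <- setNames(mods2$module, mods2$gene)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])

  set.seed(30)
  indep <- expression_matrix(matrix(rnorm(40 * 25), 40,
                                    dimnames = list(paste0("g", 1:40), NULL)))
  Ai <- soft_threshold_adjacency(similarity_matrix(indep), 6)
  expect_true(all(detect_modules(Ai, min_size = 30, cut_height = 0.5)$module == "grey"))
  expect_error(detect_modules(Ai, min_size = 0), "min_size")
})

test_that("GS/MM hub screening keeps only phenotype-linked module genes", {
  set.seed(12)
  m <- 40
  y <- rep(c(0, 1), each = m / 2)
  pheno_block <- t(sapply(1:8, function(i) y * 2 + rnorm(m, sd = 0.4)))
  null_block <- t(sapply(1:8, function(i) rnorm(m)))
  ortho <- rnorm(m) - mean(rnorm(m))
  ortho <- ortho - (sum(ortho * (y - mean(y))) / sum((y - mean(y))^2)) * (y - mean(y))
  e <- expression_matrix(rbind(pheno_block, null_block, ortho = ortho),
                         gene_ids = c(sprintf("p%02d", 1:8),
                                      sprintf("q%02d", 1:8), "ortho"))
  labels <- phenotype_labels(colnames(e), y)
  A <- soft_threshold_adjacency(similarity_matrix(e), 6)
  mods <- detect_modules(A, min_size = 4, cut_height = 0.9)
  sc <- module_scores(e, mods, labels)

  expect_true(all(sc$GS >= 0 & sc$GS <= 1, na.rm = TRUE))
  expect_true(all(sc$MM >= 0 & sc$MM <= 1, na.rm = TRUE))
  expect_equal(sc$GS[sc$gene == "ortho"], 0, tolerance = 1e-10)
  pheno_mod <- unique(mods$module[grepl("^p", mods$gene)])
  expect_identical(length(pheno_mod), 1L)
  hubs <- hub_genes(e, mods, labels, pheno_mod)
  expect_true(all(grepl("^p", hubs)))
  expect_gt(length(hubs), 0L)

  # a gene tracking the eigengene direction has MM near 1
  eg <- module_eigengene(e, mods$gene[mods$module == pheno_mod])
  expect_gt(max(abs(cor(t(e[grepl("^p", rownames(e)), ]), eg))), 0.9)

  bad <- phenotype_labels(colnames(e), rep(1L, m))
  expect_error(module_scores(e, mods, bad), "single class")
})
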