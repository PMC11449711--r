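# Discrete information quantities, the intervention distribution, and
# causal-strength pruning.

test_that("quantile binning produces the expected joint tables", {
  P <- estimate_joint(seq_len(10), bins = 2)
  expect_equal(as.numeric(P), c(0.5, 0.5))

  x <- rnorm(20)
  P2 <- estimate_joint(rbind(x, x), bins = 2)
  expect_equal(as.numeric(diag(P2)), c(0.5, 0.5))
  expect_equal(sum(abs(P2 - diag(diag(P2)))), 0)

  set.seed(11)
  P3 <- estimate_joint(rbind(runif(3000), runif(3000)), bins = 3)
  expect_equal(sum(P3), 1, tolerance = 1e-12)
  expect_lt(max(abs(P3 - outer(rowSums(P3), colSums(P3)))), 0.02)

  expect_error(estimate_joint(rbind(1:3, 1:3), bins = 4), "at least as many samples")
  Pc <- estimate_joint(rep(1, 10), bins = 2)  # constant row: one occupied bin
  expect_equal(as.numeric(Pc), c(1, 0))
})

test_that("mutual information matches analytic and brute-force values", {
  prod2 <- joint_distribution(outer(c(0.3, 0.7), c(0.6, 0.4)))
  expect_equal(mutual_information(prod2), 0)

  coupled <- joint_distribution(diag(2) / 2)
  expect_equal(mutual_information(coupled), log(2))

  p <- joint_distribution(matrix(c(0.4, 0.1, 0.1, 0.4), 2))
  expect_equal(mutual_information(p), oracle_mi(matrix(c(0.4, 0.1, 0.1, 0.4), 2)),
               tolerance = 1e-14)
  expect_error(mutual_information(joint_distribution(array(1, c(1, 1, 1)))),
               "2-variable")
})

test_that("conditional MI vanishes under conditional independence and reduces to MI", {
  # p(a,b,c) = p(c) p(a|c) p(b|c)
  pc <- c(0.4, 0.6)
  pa_c <- cbind(c(0.2, 0.8), c(0.7, 0.3))
  pb_c <- cbind(c(0.5, 0.5), c(0.1, 0.9))
  p <- array(0, c(2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    p[a, b, cc] <- pc[cc] * pa_c[a, cc] * pb_c[b, cc]
  }
  expect_equal(conditional_mutual_information(joint_distribution(p)), 0,
               tolerance = 1e-14)

  # constant conditioner: CMI == MI of the 2-variable margin
  p2 <- matrix(c(0.4, 0.1, 0.2, 0.3), 2)
  p3 <- array(0, c(2, 2, 2)); p3[, , 1] <- p2
  expect_equal(conditional_mutual_information(joint_distribution(p3)),
               mutual_information(joint_distribution(p2)), tolerance = 1e-14)

  for (s in 1:10) {
    tab <- rand_joint_table(c(2, 2, 2), s)
    expect_equal(conditional_mutual_information(joint_distribution(tab)),
                 oracle_cmi(tab), tolerance = 1e-12)
  }
})

test_that("intervention distributions conserve mass and the stated marginal", {
  for (s in 1:20) {
    dims <- if (s %% 2 == 0) c(2, 2, 2) else c(3, 3, 2)
    p <- rand_joint_table(dims, s)
    P <- joint_distribution(p)
    q <- intervention_distribution(P, "A->B")
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_equal(apply(q, c(1, 3), sum), apply(p, c(1, 3), sum), tolerance = 1e-12)
    q2 <- intervention_distribution(P, "B->A")
    expect_equal(sum(q2), 1, tolerance = 1e-12)
    expect_equal(apply(q2, c(2, 3), sum), apply(p, c(2, 3), sum), tolerance = 1e-12)
    # matches the nested-loop oracle cell by cell
    expect_equal(as.numeric(q), as.numeric(oracle_intervention(p, "A->B")),
                 tolerance = 1e-13)
    expect_equal(as.numeric(q2), as.numeric(oracle_intervention(p, "B->A")),
                 tolerance = 1e-13)
  }
})

test_that("intervention leaves conditionally independent tables unchanged", {
  pc <- c(0.3, 0.7)
  pa_c <- cbind(c(0.2, 0.8), c(0.6, 0.4))
  pb_c <- cbind(c(0.9, 0.1), c(0.25, 0.75))
  p <- array(0, c(2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    p[a, b, cc] <- pc[cc] * pa_c[a, cc] * pb_c[b, cc]
  }
  q <- intervention_distribution(joint_distribution(p), "A->B")
  expect_equal(as.numeric(q), as.numeric(p), tolerance = 1e-14)
})

test_that("deterministic A -> B chain yields a-independent b-margins per c-slice", {
  # B = A for uniform binary A, constant C
  p <- array(0, c(2, 2, 1)); p[1, 1, 1] <- 0.5; p[2, 2, 1] <- 0.5
  q <- intervention_distribution(joint_distribution(p), "A->B")
  # severing A -> B makes b uniform independently of a within the c-slice
  expect_equal(as.numeric(q[, , 1]), rep(0.25, 4), tolerance = 1e-14)
})

test_that("KL divergence follows its conventions", {
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-14)
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  expect_equal(kl_divergence(c(0, 1), c(0.5, 0.5)), log(2), tolerance = 1e-14)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)), "shapes")
})

test_that("cmi2 matches its definition, decomposition, and reductions", {
  # conditional independence: all terms vanish
  pc <- c(0.5, 0.5)
  pa_c <- cbind(c(0.1, 0.9), c(0.8, 0.2))
  pb_c <- cbind(c(0.4, 0.6), c(0.7, 0.3))
  p <- array(0, c(2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    p[a, b, cc] <- pc[cc] * pa_c[a, cc] * pb_c[b, cc]
  }
  expect_equal(cmi2(joint_distribution(p)), 0, tolerance = 1e-12)

  # constant conditioner, B = A uniform binary: zero-order reduction to MI
  p0 <- array(0, c(2, 2, 1)); p0[1, 1, 1] <- 0.5; p0[2, 2, 1] <- 0.5
  expect_equal(cmi2(joint_distribution(p0)), log(2), tolerance = 1e-12)

  for (s in 1:25) {
    tab <- rand_joint_table(c(2, 2, 2), 1000 + s)
    v <- cmi2(joint_distribution(tab))
    expect_equal(v, oracle_cmi2(tab), tolerance = 1e-12)
    expect_equal(v, oracle_decomposition_rhs(tab), tolerance = 1e-10)
  }
})

test_that("binned cmi2_score equals cmi2 of the estimated joint", {
  set.seed(3)
  x <- rnorm(60); y <- rnorm(60); z <- rnorm(60)
  expect_equal(cmi2_score(x, y, z, bins = 3, estimator = "binned"),
               cmi2(estimate_joint(rbind(x, y, z), 3)), tolerance = 1e-14)
  # order 0 equals binned mutual information
  P <- estimate_joint(rbind(x, y), 3)
  expect_equal(cmi2_score(x, y, bins = 3, estimator = "binned"),
               mutual_information(P), tolerance = 1e-12)
})

test_that("gaussian causal scores behave like their population counterparts", {
  set.seed(21)
  x <- rnorm(2000); y <- 0.8 * x + rnorm(2000, sd = 0.6)
  rho2 <- cor(x, y)^2
  expect_equal(cmi2_score(x, y), -0.5 * log(1 - rho2), tolerance = 1e-10)
  # independent pair: near zero
  expect_lt(cmi2_score(x, rnorm(2000)), 0.005)
  # conditionally independent triple: small; dependent pair given child: large
  z <- y + rnorm(2000, sd = 0.6)
  expect_lt(cmi2_score(x, z, y), 0.03)
  expect_gt(cmi2_score(x, y, z), 0.1)
})

test_that("pruning removes the indirect chain edge and keeps direct ones", {
  hits <- 0L
  for (s in 1:10) {
    net <- prune_network(sim_chain(s))
    if (setequal(paste(net$node1, net$node2), c("X Y", "Y Z"))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("pruning yields an empty graph on independent genes and a single edge on a coupled pair", {
  set.seed(5)
  e <- expression_matrix(matrix(rnorm(8 * 500), 8,
                                dimnames = list(paste0("g", 1:8), NULL)))
  net <- prune_network(e)
  expect_identical(nrow(net), 0L)
  expect_identical(select_connected_genes(net), character(0))

  m2 <- matrix(rnorm(6 * 500), 6, dimnames = list(paste0("g", 1:6), NULL))
  m2[2, ] <- m2[1, ] + rnorm(500, sd = 1e-3)
  net2 <- prune_network(expression_matrix(m2))
  expect_identical(nrow(net2), 1L)
  expect_identical(select_connected_genes(net2), c("g1", "g2"))
})

test_that("pruning is invariant to gene relabeling and input order", {
  e <- sim_chain(17)
  net <- prune_network(e)
  perm <- c(3, 1, 2)
  relabel <- c(X = "bX", Y = "aY", Z = "cZ")
  e2 <- e[perm, ]
  rownames(e2) <- relabel[rownames(e)][perm]
  net2 <- prune_network(expression_matrix(e2))
  k1 <- apply(cbind(relabel[net$node1], relabel[net$node2]), 1,
              function(r) paste(sort(r), collapse = "|"))
  k2 <- paste(net2$node1, net2$node2, sep = "|")
  expect_setequal(k1, k2)
})

test_that("select_connected_genes preserves input order", {
  net <- undirected_network(data.frame(node1 = "A", node2 = "B"),
                            nodes = c("C", "B", "A"))
  expect_identical(select_connected_genes(net), c("B", "A"))
})
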