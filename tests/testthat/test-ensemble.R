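# Bagged-Lasso ensemble: feature construction, per-target weights, and the
# inferred signed network.

small_expr <- function(seed = 1, p = 3, m = 60) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(p * m), p,
                           dimnames = list(paste0("x", seq_len(p)), NULL)))
}

test_that("bootstrap designs have the promised shape and determinism", {
  e <- small_expr(p = 3)
  cfg <- ensemble_config(n_linear = 2, n_product = 1)
  set.seed(9)
  bs <- build_bootstrap_features(e, "x3", c("x1", "x2"), cfg)
  expect_identical(ncol(bs$X), 3L)                 # 2 linear + 1 product
  expect_identical(lengths(bs$descriptors), c(1L, 1L, 2L))
  expect_setequal(bs$descriptors[[3]], c("x1", "x2"))
  expect_equal(unname(colMeans(bs$X)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(bs$X, 2, sd)), rep(1, 3), tolerance = 1e-12)

  set.seed(77)
  d1 <- build_bootstrap_features(e, "x3", c("x1", "x2"), cfg)$descriptors
  set.seed(77)
  d2 <- build_bootstrap_features(e, "x3", c("x1", "x2"), cfg)$descriptors
  expect_identical(d1, d2)

  purely_linear <- {
    set.seed(1)
    build_bootstrap_features(e, "x3", c("x1", "x2"),
                             ensemble_config(n_linear = 2, n_product = 0))
  }
  expect_identical(lengths(purely_linear$descriptors), c(1L, 1L))
  expect_error(build_bootstrap_features(e, "x3", c("x3", "x1")), "exclude the target")
})

test_that("per-target weights find planted regulators with the right sign", {
  set.seed(100)
  m <- 500
  x1 <- rnorm(m); x2 <- rnorm(m); x3 <- rnorm(m)
  up <- expression_matrix(rbind(x1 = x1, x2 = x2, x3 = x3,
                                y = 2 * x1 + rnorm(m, sd = 0.25)))
  cfg <- ensemble_config(n_bootstraps = 100, rng_seed = 4)
  w <- fit_target_weights(up, "y", c("x1", "x2", "x3"), cfg)
  w1 <- w$weight[w$regulator == "x1"]
  expect_gt(w1, 0.5)
  expect_gt(abs(w1), 5 * max(abs(w$weight[w$regulator != "x1"])))

  down <- up; down["y", ] <- -2 * x1 + rnorm(m, sd = 0.25)
  wd <- fit_target_weights(expression_matrix(down), "y", c("x1", "x2", "x3"), cfg)
  expect_lt(wd$weight[wd$regulator == "x1"], -0.5)
})

test_that("pure-noise targets stay below the weight threshold", {
  misses <- 0L
  for (s in 1:10) {
    set.seed(s)
    m <- 300
    e <- expression_matrix(matrix(rnorm(6 * m), 6,
                                  dimnames = list(c(paste0("x", 1:5), "y"), NULL)))
    w <- fit_target_weights(e, "y", paste0("x", 1:5),
                            ensemble_config(n_bootstraps = 60, rng_seed = s))
    if (any(abs(w$weight) >= 0.5)) misses <- misses + 1L
  }
  expect_lte(misses, 1L)
})

test_that("inference is deterministic, self-loop free, and threshold monotone", {
  gold <- make_star5(3)
  spec <- synthetic_spec(n_genes = 5, noise_sd = 0.25, nonlinear_fraction = 0,
                         n_samples = 300, rng_seed = 3)
  expr <- simulate_expression(gold, spec)
  cfg <- ensemble_config(n_bootstraps = 50, rng_seed = 12)
  n1 <- infer_signed_network(expr, cfg = cfg)
  n2 <- infer_signed_network(expr, cfg = cfg)
  expect_equal(as.data.frame(n1), as.data.frame(n2))
  expect_true(all(n1$regulator != n1$target))

  hi <- infer_signed_network(expr, cfg = ensemble_config(
    n_bootstraps = 50, rng_seed = 12, weight_threshold = 0.8))
  expect_true(all(paste(hi$regulator, hi$target) %in%
                    paste(n1$regulator, n1$target)))
  expect_error(infer_signed_network(expr, candidates = c("G1", "G2")),
               "at least 3")
})

test_that("weights are sign-equivariant and scale-invariant", {
  gold <- make_star5(8)
  spec <- synthetic_spec(n_genes = 5, noise_sd = 0.25, nonlinear_fraction = 0,
                         n_samples = 300, rng_seed = 8)
  expr <- simulate_expression(gold, spec)
  cfg <- ensemble_config(n_bootstraps = 40, rng_seed = 5)
  base <- infer_signed_network(expr, cfg = cfg, full_weights = TRUE)
  wb <- attr(base, "weights")

  flipped <- expr; flipped["G1", ] <- -flipped["G1", ]
  wf <- attr(infer_signed_network(expression_matrix(flipped), cfg = cfg,
                                  full_weights = TRUE), "weights")
  g1b <- wb[wb$regulator == "G1", ]; g1f <- wf[wf$regulator == "G1", ]
  expect_equal(g1f$weight[order(g1f$target)], -g1b$weight[order(g1b$target)],
               tolerance = 1e-8)

  scaled <- expr; scaled["G1", ] <- 5 * scaled["G1", ]
  ws <- infer_signed_network(expression_matrix(scaled), cfg = cfg)
  expect_equal(as.data.frame(ws)$weight, as.data.frame(base)$weight,
               tolerance = 1e-8)
})

test_that("five-gene signed systems are fully recovered", {
  for (s in c(2, 13, 31)) {
    gold <- make_star5(s)
    spec <- synthetic_spec(n_genes = 5, noise_sd = 0.25, nonlinear_fraction = 0,
                           n_samples = 500, rng_seed = s)
    expr <- simulate_expression(gold, spec)
    net <- infer_signed_network(expr, cfg = ensemble_config(n_bootstraps = 100,
                                                            rng_seed = s))
    gk <- paste(gold$regulator, gold$target, gold$sign)
    pk <- paste(net$regulator, net$target, net$sign)
    expect_true(all(gk %in% pk), label = paste("seed", s, "recovers gold edges"))
    expect_equal(accuracy(sign_confusion(net, gold)), 1)
  }
})
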