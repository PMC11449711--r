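# Shared data generators for the tests.

# three-gene linear chain X -> Y -> Z (unit weights)
sim_chain <- function(seed, m = 1000, noise_sd = 0.1) {
  set.seed(seed)
  x <- stats::rnorm(m)
  y <- x + stats::rnorm(m, sd = noise_sd)
  z <- y + stats::rnorm(m, sd = noise_sd)
  expression_matrix(rbind(X = x, Y = y, Z = z))
}

# identifiable 5-gene signed system: 2 regulators, 3 single-regulator
# targets, weights of magnitude ~2 and random sign
make_star5 <- function(seed) {
  set.seed(seed)
  regs <- c("G1", "G2"); tgts <- c("G3", "G4", "G5")
  df <- data.frame(regulator = sample(regs, 3, replace = TRUE), target = tgts,
                   weight = sample(c(-1, 1), 3, replace = TRUE) *
                     stats::runif(3, 1.8, 2.2),
                   stringsAsFactors = FALSE)
  signed_network(df, nodes = c(regs, tgts))
}

# seeded random signed directed network on n nodes
rand_signed_network <- function(seed, n = 10, n_edges = 15) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(regulator = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  pick <- pairs[sample.int(nrow(pairs), n_edges), ]
  pick$weight <- stats::runif(n_edges, -2, 2)
  pick$weight[pick$weight == 0] <- 1
  signed_network(pick, nodes = nodes)
}

# positive-valued expression with an optional planted fold change
sim_lognormal_expr <- function(seed, n_genes = 500, n_per_group = 40,
                               planted = integer(0), fold = 4) {
  set.seed(seed)
  m <- 2L * n_per_group
  vals <- 2^matrix(stats::rnorm(n_genes * m, mean = log2(100), sd = 1),
                   n_genes, m)
  labels <- phenotype_labels(paste0("S", seq_len(m)),
                             rep(c(0L, 1L), each = n_per_group))
  tumor <- labels$label == 1L
  if (length(planted) > 0) vals[planted, tumor] <- vals[planted, tumor] * fold
  list(expr = expression_matrix(vals,
                                gene_ids = sprintf("gene%03d", seq_len(n_genes)),
                                sample_ids = labels$sample_id),
       labels = labels)
}
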