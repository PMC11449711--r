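# Independent brute-force oracles: explicit nested-loop implementations that
# share no code with the package internals.

# seeded random strictly-positive probability table
rand_joint_table <- function(dims, seed) {
  set.seed(seed)
  p <- array(stats::rexp(prod(dims)), dim = dims)
  p / sum(p)
}

oracle_kl <- function(p, q) {
  tot <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] == 0) return(Inf)
      tot <- tot + p[i] * log(p[i] / q[i])
    }
  }
  tot
}

# Intervention distribution q(a,b,c) = p(a,c) * sum_a' p(b|c,a') p(a'),
# cell by cell.
oracle_intervention <- function(p, direction = "A->B") {
  d <- dim(p)
  q <- array(0, dim = d)
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
    if (direction == "A->B") {
      pac <- 0
      for (b2 in seq_len(d[2])) pac <- pac + p[a, b2, cc]
      g <- 0
      for (a2 in seq_len(d[1])) {
        pa2 <- 0
        for (b2 in seq_len(d[2])) for (c2 in seq_len(d[3])) pa2 <- pa2 + p[a2, b2, c2]
        pa2c <- 0
        for (b2 in seq_len(d[2])) pa2c <- pa2c + p[a2, b2, cc]
        if (pa2c > 0) g <- g + p[a2, b, cc] / pa2c * pa2
      }
      q[a, b, cc] <- pac * g
    } else {
      pbc <- 0
      for (a2 in seq_len(d[1])) pbc <- pbc + p[a2, b, cc]
      h <- 0
      for (b2 in seq_len(d[2])) {
        pb2 <- 0
        for (a2 in seq_len(d[1])) for (c2 in seq_len(d[3])) pb2 <- pb2 + p[a2, b2, c2]
        pb2c <- 0
        for (a2 in seq_len(d[1])) pb2c <- pb2c + p[a2, b2, cc]
        if (pb2c > 0) h <- h + p[a, b2, cc] / pb2c * pb2
      }
      q[a, b, cc] <- pbc * h
    }
  }
  q
}

oracle_cmi2 <- function(p) {
  (oracle_kl(p, oracle_intervention(p, "A->B")) +
     oracle_kl(p, oracle_intervention(p, "B->A"))) / 2
}

oracle_mi <- function(p) {
  d <- dim(p)
  tot <- 0
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) {
    if (p[a, b] > 0) {
      pa <- sum(p[a, ]); pb <- sum(p[, b])
      tot <- tot + p[a, b] * log(p[a, b] / (pa * pb))
    }
  }
  tot
}

oracle_cmi <- function(p) {
  d <- dim(p)
  tot <- 0
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
    if (p[a, b, cc] > 0) {
      pc <- sum(p[, , cc]); pac <- sum(p[a, , cc]); pbc <- sum(p[, b, cc])
      tot <- tot + p[a, b, cc] * log(pc * p[a, b, cc] / (pac * pbc))
    }
  }
  tot
}

# Right-hand side of the CMI2 decomposition:
# CMI + (1/2) KL(p(B|C) || q_{A->B}(B|C)) + (1/2) KL(p(A|C) || q_{B->A}(A|C))
oracle_decomposition_rhs <- function(p) {
  d <- dim(p)
  qab <- oracle_intervention(p, "A->B")
  qba <- oracle_intervention(p, "B->A")
  t1 <- 0
  for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
    pbc <- sum(p[, b, cc]); pc <- sum(p[, , cc])
    qbc <- sum(qab[, b, cc]); qc <- sum(qab[, , cc])
    if (pbc > 0) t1 <- t1 + pbc * log((pbc / pc) / (qbc / qc))
  }
  t2 <- 0
  for (a in seq_len(d[1])) for (cc in seq_len(d[3])) {
    pac <- sum(p[a, , cc]); pc <- sum(p[, , cc])
    qac <- sum(qba[a, , cc]); qc <- sum(qba[, , cc])
    if (pac > 0) t2 <- t2 + pac * log((pac / pc) / (qac / qc))
  }
  oracle_cmi(p) + t1 / 2 + t2 / 2
}

# Exhaustive maximal-clique MCC: enumerate all vertex subsets of size >= 2,
# keep cliques with no clique superset, and sum (size-1)! per member node.
oracle_mcc <- function(nodes, edge1, edge2) {
  has_edge <- function(u, v) any((edge1 == u & edge2 == v) | (edge1 == v & edge2 == u))
  n <- length(nodes)
  subsets <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(members) < 2) next
    is_clique <- TRUE
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (i < j && !has_edge(members[i], members[j])) is_clique <- FALSE
    }
    if (is_clique) subsets[[length(subsets) + 1]] <- members
  }
  maximal <- Filter(function(s) {
    !any(vapply(subsets, function(t) length(t) > length(s) && all(s %in% t), TRUE))
  }, subsets)
  score <- stats::setNames(numeric(n), nodes)
  for (cl in maximal) {
    for (v in cl) score[v] <- score[v] + factorial(length(cl) - 1)
  }
  score
}
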