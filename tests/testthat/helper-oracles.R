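# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: distances come from boolean matrix powers, Fisher
# p-values from explicit hypergeometric enumeration, enrichment scores from
# a literal prefix walk.

# all-pairs hop distances by repeated boolean "relaxation" of the adjacency
oracle_all_pairs <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    d[a, b] <- 1; d[b, a] <- 1
  }
  repeat {
    changed <- FALSE
    for (u in nodes) for (v in nodes) {
      via <- min(d[u, ] + d[, v])
      if (via < d[u, v]) { d[u, v] <- via; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

oracle_closest_distance <- function(edges, nodes, S, T) {
  d <- oracle_all_pairs(edges, nodes)
  mean(vapply(S, function(u) min(d[u, T]), numeric(1)))
}

# hypergeometric enumeration over all 2x2 tables with the observed margins
oracle_fisher <- function(both, only_a, only_b, neither,
                          alternative = "two.sided") {
  m <- both + only_b            # elements of set b (column margin)
  n <- only_a + neither         # elements outside b
  k <- both + only_a            # elements of set a (row margin)
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(both, m, n, k)
  if (alternative == "greater") {
    sum(probs[xs >= both])
  } else {
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
}

# literal prefix walk over a 0/1 hit vector
oracle_es <- function(hits) {
  n_d <- length(hits)
  n_c <- sum(hits)
  best <- 0
  run <- 0
  for (i in seq_len(n_d)) {
    run <- run + if (hits[i]) (n_d - n_c) / n_c else -n_c / (n_d - n_c)
    if (run > best) best <- run
  }
  best
}

# exact permutation p by enumerating every placement of the hits
oracle_exact_perm_p <- function(n_d, n_c, es_obs) {
  placements <- combn(n_d, n_c)
  es_all <- apply(placements, 2, function(pos) {
    hits <- logical(n_d); hits[pos] <- TRUE
    oracle_es(hits)
  })
  mean(es_all > es_obs)
}

# small named path graph a-b-c-d-... for distance tests
path_graph <- function(k) {
  nodes <- letters[seq_len(k)]
  igraph::make_graph(rbind(nodes[-k], nodes[-1]), directed = FALSE)
}
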