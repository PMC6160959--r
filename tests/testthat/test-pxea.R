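test_that("running sum matches closed forms", {
  D <- paste0("p", 1:10)
  # all hits on top: ES reaches |D| - |C|
  expect_equal(running_sum_es(D, paste0("p", 1:3)), 7)
  # hits at the bottom of a 4-ranking: prefix sums -1, -2, -1, 0
  expect_equal(running_sum_es(paste0("p", 1:4), c("p3", "p4")), 0)
  expect_error(running_sum_es(D, character(0)), "0 < \\|C\\|")
  expect_error(running_sum_es(D, D), "0 < \\|C\\|")
  expect_error(running_sum_es(D, "nope"), "subset")
})

test_that("running sum agrees with the prefix-walk oracle everywhere", {
  for (n_d in 2:8) {
    for (n_c in 1:(n_d - 1)) {
      placements <- combn(n_d, n_c)
      for (j in seq_len(ncol(placements))) {
        hits <- logical(n_d)
        hits[placements[, j]] <- TRUE
        ids <- paste0("p", seq_len(n_d))
        expect_equal(running_sum_es(ids, ids[hits]), oracle_es(hits))
      }
    }
  }
})

test_that("ES is bounded, maximal only for top placement, and increments
           sum to |D| - 2|C|", {
  withr::local_seed(51)
  for (i in 1:40) {
    n_d <- sample(3:12, 1)
    n_c <- sample(seq_len(n_d - 1), 1)
    ids <- paste0("p", seq_len(n_d))
    C <- sample(ids, n_c)
    es <- running_sum_es(sample(ids), C)
    expect_gte(es, 0)
    expect_lte(es, n_d - n_c)
    x <- pxea:::pxea_increments(n_d, n_c, seq_len(n_d) <= n_c)
    expect_equal(sum(x), n_d - 2 * n_c)
    # maximal iff C occupies the top ranks
    top <- c(C, setdiff(ids, C))
    expect_equal(running_sum_es(top, C), n_d - n_c)
    if (es == n_d - n_c) next
  }
})

test_that("permutation p matches exhaustive enumeration", {
  ids <- paste0("p", 1:6)
  for (pos in list(c(1, 2), c(2, 5), c(5, 6))) {
    C <- ids[pos]
    res <- permutation_p(ids, C, n_perm = 10000, seed = 61)
    exact <- oracle_exact_perm_p(6, 2, running_sum_es(ids, C))
    se <- sqrt(exact * (1 - exact) / 10000)
    expect_lte(abs(res$p - exact), 3 * se + 1e-12)
  }
  # top placement is unbeatable: p is exactly zero, printed as a bound
  res0 <- permutation_p(ids, ids[1:2], n_perm = 500, seed = 62)
  expect_equal(res0$p, 0)
  expect_output(print(res0), "< 0.002")
  expect_error(permutation_p(ids, ids[1:2], n_perm = 0), "n_perm")
})

test_that("null ES distribution matches enumeration in expectation", {
  ids <- paste0("p", 1:8)
  res <- permutation_p(ids, ids[c(1, 5, 7)], n_perm = 10000, seed = 63)
  placements <- combn(8, 3)
  es_all <- apply(placements, 2, function(pos) {
    hits <- logical(8); hits[pos] <- TRUE
    oracle_es(hits)
  })
  expect_equal(mean(res$es_null), mean(es_all),
               tolerance = 3 * sd(es_all) / sqrt(10000) / mean(es_all))
})

test_that("rank_pathways_for_drug orders by independently recomputed z", {
  g <- toy_interactome(300, "barabasi_albert", 2, seed = 71)
  withr::local_seed(72)
  targets <- plant_disease_module(g, 5)
  pathways <- c(
    list(self = targets),
    setNames(lapply(1:9, function(i) sample(igraph::V(g)$name, 8)),
             paste0("rnd", 1:9)))
  D <- rank_pathways_for_drug(g, targets, pathways, n_random = 100,
                              seed = 73)
  expect_equal(nrow(D), 10)           # the full collection is ranked
  expect_equal(D$pathway_id[1], "self")
  expect_equal(D$d_obs[1], 0)
  # ranking equals sorting of the reported z values
  expect_equal(D$pathway_id,
               D$pathway_id[order(D$z, D$d_obs, D$pathway_id)])
  # determinism under the same seed
  D2 <- rank_pathways_for_drug(g, targets, pathways, n_random = 100,
                               seed = 73)
  expect_identical(D$pathway_id, D2$pathway_id)
  expect_error(
    suppressWarnings(rank_pathways_for_drug(g, "absent_gene", pathways)),
    "no drug target")
})

test_that("common_span intersects pathway ids", {
  a <- data.frame(pathway_id = paste0("p", 1:5))
  b <- data.frame(pathway_id = paste0("p", 4:8))
  expect_equal(common_span(a, b), c("p4", "p5"))
  expect_equal(common_span(a, a), paste0("p", 1:5))
  expect_equal(common_span(a, data.frame(pathway_id = "q")), character(0))
  # sizes mirroring the two spans of 170 and 82 with 35 shared ids
  big_a <- paste0("pw", 1:170)
  big_b <- paste0("pw", c(1:35, 200:246))
  expect_length(common_span(big_a, big_b), 35)
})

test_that("pxea_screen recovers a planted drug and groups ties sanely", {
  g <- toy_interactome(300, "barabasi_albert", 2, seed = 81)
  withr::local_seed(82)
  pool <- sample(igraph::V(g)$name, 180)
  pathways <- setNames(split(pool, rep(1:30, each = 6)),
                       sprintf("pw%02d", 1:30))
  C <- names(pathways)[sort(sample(30, 3))]
  targets <- unname(unlist(lapply(C, function(p) sample(pathways[[p]], 4))))
  drugs <- c(list(planted = targets),
             setNames(lapply(1:4, function(i)
               sample(igraph::V(g)$name, 12)), paste0("decoy", 1:4)))
  res <- pxea_screen(g, drugs, pathways, C = C, n_random = 200,
                     n_perm = 2000, min_bin_size = 25, seed = 83)
  expect_equal(res$drug_id[1], "planted")
  expect_equal(nrow(res), 5)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))

  # identical target sets give identical scores
  twins <- list(t1 = targets, t2 = targets)
  res2 <- pxea_screen(g, twins, pathways, C = C,
                      n_random = 50, n_perm = 500, seed = 84)
  expect_equal(res2$es[1], res2$es[2])

  # drugs with no usable target are reported, not scored
  res3 <- pxea_screen(g, list(ghost = "not_a_gene"), pathways,
                      C = C, n_random = 10, n_perm = 10)
  expect_true(is.na(res3$es))
  expect_equal(res3$n_targets_used, 0L)

  # empty drug table gives an empty result
  expect_equal(nrow(pxea_screen(g, list(), pathways, C)), 0)
})
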