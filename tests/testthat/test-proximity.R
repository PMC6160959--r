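test_that("closest_distance matches hand values and is asymmetric", {
  g <- path_graph(4)
  expect_equal(closest_distance(g, c("a", "b"), "d"), 2.5)
  expect_equal(closest_distance(g, "d", c("a", "b")), 2)
  # S inside T gives zero
  expect_equal(closest_distance(g, c("a", "b"), c("a", "b", "c")), 0)
  expect_error(closest_distance(g, character(0), "a"), "nonempty")
  expect_error(closest_distance(g, "z", "a"), "z")
})

test_that("closest_distance agrees with the all-pairs oracle", {
  withr::local_seed(31)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    g <- igraph::sample_gnp(n, 0.5)
    igraph::V(g)$name <- paste0("n", seq_len(n))
    g <- largest_connected_component(g)
    nodes <- igraph::V(g)$name
    if (length(nodes) < 3) next
    S <- sample(nodes, sample(1:2, 1))
    T <- sample(nodes, sample(1:3, 1))
    edges <- igraph::as_edgelist(g)
    expect_equal(closest_distance(g, S, T),
                 oracle_closest_distance(edges, nodes, S, T))
  }
})

test_that("zero closest distance happens exactly when S is inside T", {
  g <- toy_interactome(60, "erdos_renyi", 0.1, seed = 5)
  nodes <- igraph::V(g)$name
  withr::local_seed(6)
  for (i in 1:20) {
    S <- sample(nodes, 4)
    T <- sample(nodes, 10)
    d <- closest_distance(g, S, T)
    expect_equal(d == 0, all(S %in% T))
  }
})

test_that("proximity z is near zero under the null and reproducible", {
  g <- toy_interactome(200, "erdos_renyi", 0.05, seed = 13)
  nodes <- igraph::V(g)$name
  bins <- degree_bins(g, 50)
  withr::local_seed(14)
  zs <- vapply(1:20, function(i) {
    S <- sample(nodes, 8)
    T <- sample(nodes, 8)
    proximity_z(g, S, T, n_random = 100, bins = bins)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.5)

  S <- sample(nodes, 6); T <- sample(nodes, 6)
  p1 <- proximity_z(g, S, T, n_random = 50, bins = bins, seed = 99)
  p2 <- proximity_z(g, S, T, n_random = 50, bins = bins, seed = 99)
  expect_identical(p1$z, p2$z)
  expect_equal(p1$z, (p1$d_obs - p1$mu) / p1$sigma)
})

test_that("planted modules are significantly proximal", {
  g <- toy_interactome(500, "barabasi_albert", 2, seed = 17)
  S <- plant_disease_module(g, 8, seed = 18)
  nb <- setdiff(igraph::V(g)$name[unlist(lapply(
    igraph::adjacent_vertices(g, S), as.integer))], S)
  T <- c(S, nb[1])
  pr <- proximity_z(g, S, T, n_random = 200, seed = 19)
  expect_lte(pr$z, -2)
})

test_that("degenerate null (constant distances) flags z as undefined", {
  # star graph, S = the hub (alone in its degree bin): every resampled
  # pair sits at distance 1, so the null has zero spread
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", paste0("leaf", 1:4))
  pr <- proximity_z(g, "hub", "leaf1", n_random = 20,
                    min_bin_size = 1, seed = 1)
  expect_equal(pr$d_obs, 1)
  expect_equal(pr$sigma, 0)
  expect_true(is.na(pr$z))
})

test_that("genes absent from the interactome are dropped and recorded", {
  g <- path_graph(5)
  expect_warning(
    pr <- proximity_z(g, c("a", "zz"), c("d", "e"), n_random = 20,
                      min_bin_size = 1, seed = 2),
    "absent")
  expect_true("zz" %in% pr$dropped_genes)
  expect_error(
    suppressWarnings(proximity_z(g, c("q1", "q2"), "a", n_random = 5,
                                 min_bin_size = 1)),
    "empty after dropping")
})

test_that("pathway_span keeps planted pathways and drops random ones", {
  g <- toy_interactome(400, "barabasi_albert", 2, seed = 23)
  disease <- plant_disease_module(g, 10, seed = 24)
  withr::local_seed(25)
  pathways <- list(
    planted = c(disease, sample(setdiff(igraph::V(g)$name, disease), 2)),
    random1 = sample(igraph::V(g)$name, 12),
    random2 = sample(igraph::V(g)$name, 12))
  sp <- pathway_span(g, disease, pathways, n_random = 200, seed = 26,
                     disease_id = "toy")
  expect_s3_class(sp, "pathway_span")
  expect_true("planted" %in% sp$pathway_id)
  expect_true(all(sp$z <= -2))
  expect_false(is.unsorted(sp$z))
  # empty collection gives an empty span
  expect_equal(nrow(pathway_span(g, disease, list(), n_random = 10)), 0)
})

test_that("pathways with no gene in the graph are skipped with a warning", {
  g <- path_graph(6)
  expect_warning(
    sp <- pathway_span(g, c("a", "b"), list(gone = c("x1", "x2")),
                       n_random = 10, min_bin_size = 1, keep_all = TRUE),
    "skipped")
  expect_equal(nrow(sp), 0)
})

test_that("rwr_scores matches the K2 fixed point and conserves mass", {
  k2 <- igraph::make_graph(~ a - b)
  s <- rwr_scores(k2, "a", restart = 0.5)
  expect_equal(unname(s["a"]), 2 / 3, tolerance = 1e-4)
  expect_equal(unname(s["b"]), 1 / 3, tolerance = 1e-4)
  expect_equal(sum(s), 1)

  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("r", 1:6)
  s2 <- rwr_scores(ring, igraph::V(ring)$name)
  expect_equal(unname(s2), rep(1 / 6, 6), tolerance = 1e-6)

  g <- toy_interactome(100, "barabasi_albert", 2, seed = 3)
  s3 <- rwr_scores(g, igraph::V(g)$name[1:5])
  expect_equal(sum(s3), 1)
  expect_error(rwr_scores(k2, "a", max_iter = 1), "converge")
})

test_that("rwr proximity uses the shortest-path sign convention", {
  g <- toy_interactome(300, "barabasi_albert", 2, seed = 27)
  S <- plant_disease_module(g, 8, seed = 28)
  T <- gold_standard_pathways(S, 50, n_reps = 1, seed = 29)[[1]]
  pr <- rwr_proximity_z(g, S, T, n_random = 100, seed = 30)
  expect_equal(pr$engine, "rwr")
  expect_lte(pr$z, -2)

  # random target sets score near zero on average
  withr::local_seed(31)
  bins <- degree_bins(g, 100)
  zs <- vapply(1:8, function(i) {
    rwr_proximity_z(g, sample(igraph::V(g)$name, 6),
                    sample(igraph::V(g)$name, 6),
                    n_random = 60, bins = bins)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 1)
})
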