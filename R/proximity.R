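#' Closest-distance proximity between two gene sets
#'
#' The proximity from a set `S` to a set `T` in a network is the average,
#' over genes `u` in `S`, of the hop distance from `u` to the nearest gene
#' of `T`:
#' \deqn{d(S,T) = \frac{1}{|S|} \sum_{u \in S} \min_{v \in T} d(u,v)}
#' The measure is asymmetric in `(S, T)` by design; callers pass the sets in
#' the direction of interest (e.g. disease genes to pathway genes, or drug
#' targets to pathway genes).
#'
#' @param g An undirected igraph object (typically an interactome LCC).
#' @param S,T Character vectors of gene ids; must be nonempty subsets of
#'   the graph's vertex names.
#' @param dist_mat Optional precomputed all-pairs hop-distance matrix with
#'   vertex names on both dimensions (see [precompute_distances()]);
#'   indexing it is much faster than repeated breadth-first searches when
#'   many set pairs are scored on the same graph.
#' @return The closest distance, a non-negative number of hops.
#' @examples
#' g <- igraph::make_graph(~ a - b - c - d)
#' closest_distance(g, c("a", "b"), "d")  # (3 + 2)/2 = 2.5
#' closest_distance(g, "d", c("a", "b"))  # 2: asymmetric
#' @export
closest_distance <- function(g, S, T, dist_mat = NULL) {
  S <- unique(as.character(S)); T <- unique(as.character(T))
  nodes <- igraph::V(g)$name
  if (length(S) == 0L || length(T) == 0L) stop("S and T must be nonempty")
  missing <- setdiff(c(S, T), nodes)
  if (length(missing) > 0L) {
    stop("gene(s) not in graph: ", paste(missing, collapse = ", "))
  }
  d <- if (is.null(dist_mat)) {
    igraph::distances(g, v = S, to = T)
  } else {
    dist_mat[S, T, drop = FALSE]
  }
  nearest <- apply(d, 1L, min)
  if (any(!is.finite(nearest))) {
    stop("some source genes cannot reach any target gene")
  }
  mean(nearest)
}

#' Precompute all-pairs hop distances
#'
#' Dense all-pairs shortest-path matrix for a (desk-scale) graph, used to
#' accelerate repeated proximity calculations. Memory grows as n^2, so this
#' is worthwhile for graphs up to a few thousand nodes; for genome-scale
#' interactomes the streaming BFS path is used instead.
#'
#' @param g Undirected igraph object with named vertices.
#' @return Numeric matrix of hop distances, vertex names as dimnames.
#' @export
precompute_distances <- function(g) {
  d <- igraph::distances(g)
  dimnames(d) <- list(igraph::V(g)$name, igraph::V(g)$name)
  d
}

# reuse a caller-supplied distance matrix, or build one when the graph is
# small enough that n^2 doubles are cheap; NULL means "stream BFS"
maybe_dist_mat <- function(g, dist_mat) {
  if (!is.null(dist_mat)) return(dist_mat)
  if (igraph::vcount(g) <= 5000L) precompute_distances(g) else NULL
}

# n_random degree-matched null values of the closest distance. With a
# distance matrix the whole loop runs on integer vertex indices; without
# one (genome-scale graphs) it falls back to per-realization BFS.
null_closest_distances <- function(g, S, T, bins, dist_mat, n_random) {
  counts_S <- tabulate(bin_of(bins, S), nbins = length(bins$bins))
  counts_T <- tabulate(bin_of(bins, T), nbins = length(bins$bins))
  pool_sizes <- vapply(bins$vidx, length, 1L)
  fast_ok <- !is.null(dist_mat) && all(counts_S <= pool_sizes) &&
    all(counts_T <= pool_sizes)
  if (!fast_ok) {
    return(vapply(seq_len(n_random), function(i) {
      closest_distance(g,
                       sample_degree_matched(g, S, bins),
                       sample_degree_matched(g, T, bins),
                       dist_mat)
    }, numeric(1L)))
  }
  active_S <- which(counts_S > 0L)
  active_T <- which(counts_T > 0L)
  draw <- function(active, counts) {
    unlist(lapply(active, function(b) {
      bins$vidx[[b]][sample.int(pool_sizes[b], counts[b])]
    }), use.names = FALSE)
  }
  vapply(seq_len(n_random), function(i) {
    Sr <- draw(active_S, counts_S)
    Tr <- draw(active_T, counts_T)
    d <- dist_mat[Sr, Tr, drop = FALSE]
    mean(d[cbind(seq_along(Sr), max.col(-d, ties.method = "first"))])
  }, numeric(1L))
}

# drop genes not in the graph, with a warning naming the set
drop_absent <- function(g, genes, label) {
  genes <- unique(as.character(genes))
  absent <- setdiff(genes, igraph::V(g)$name)
  if (length(absent) > 0L) {
    warning(length(absent), " gene(s) of ", label, " absent from interactome")
  }
  list(kept = setdiff(genes, absent), dropped = absent)
}

new_proximity_result <- function(d_obs, null_values, n_random, seed,
                                 dropped, engine) {
  mu <- mean(null_values)
  sigma <- stats::sd(null_values)
  z <- if (sigma > 0) (d_obs - mu) / sigma else NA_real_
  structure(list(d_obs = d_obs, mu = mu, sigma = sigma, z = z,
                 n_random = n_random, seed = seed,
                 dropped_genes = dropped, engine = engine),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("proximity (%s): d_obs = %.4g, null mu = %.4g, sigma = %.4g\n",
              x$engine, x$d_obs, x$mu, x$sigma))
  if (is.na(x$z)) {
    cat("z undefined (sigma = 0); treated as not significant\n")
  } else {
    cat(sprintf("z = %.3f (n_random = %d)\n", x$z, x$n_random))
  }
  invisible(x)
}

#' Proximity z-score against a degree-matched null model
#'
#' Compares the observed closest distance `d(S, T)` to its distribution over
#' random gene-set pairs that match `S` and `T` in size and degree. Both
#' endpoints are resampled in every realization, and
#' \deqn{z(S,T) = \frac{d(S,T) - \mu_{d_{random}}}{\sigma_{d_{random}}}}
#' Negative z means the sets are closer in the interactome than expected by
#' chance; z <= -2 is the conventional significance cut. Genes absent from
#' the interactome are dropped (and recorded) before scoring.
#'
#' @inheritParams closest_distance
#' @param n_random Number of random realizations (default 1000).
#' @param min_bin_size Minimum degree-bin occupancy for the null model.
#' @param seed Optional integer seed for reproducibility.
#' @param bins Optional precomputed [degree_bins()]; pass when scoring many
#'   set pairs on the same graph to avoid recomputation.
#' @param dist_mat Optional all-pairs distance matrix from
#'   [precompute_distances()]; built automatically for graphs up to 5000
#'   nodes.
#' @return A `proximity_result`: list with `d_obs`, `mu`, `sigma`, `z`
#'   (`NA` when sigma is 0, i.e. a degenerate null), `n_random`, `seed`,
#'   `dropped_genes`.
#' @export
proximity_z <- function(g, S, T, n_random = 1000L, min_bin_size = 100L,
                        seed = NULL, bins = NULL, dist_mat = NULL) {
  n_random <- as.integer(n_random)
  if (n_random < 1L) stop("n_random must be >= 1")
  ds <- drop_absent(g, S, "S"); dt <- drop_absent(g, T, "T")
  if (length(ds$kept) == 0L || length(dt$kept) == 0L) {
    stop("S or T empty after dropping genes absent from the interactome")
  }
  if (is.null(bins)) bins <- degree_bins(g, min_bin_size)
  dist_mat <- maybe_dist_mat(g, dist_mat)
  d_obs <- closest_distance(g, ds$kept, dt$kept, dist_mat)
  if (!is.null(seed)) withr::local_seed(seed)
  null_values <- null_closest_distances(g, ds$kept, dt$kept, bins,
                                        dist_mat, n_random)
  new_proximity_result(d_obs, null_values, n_random, seed,
                       dropped = c(ds$dropped, dt$dropped),
                       engine = "shortest_path")
}

#' Pathway span of a disease
#'
#' Scores every pathway in a collection for proximity to a set of disease
#' genes (direction: disease genes to pathway genes) and keeps the pathways
#' significantly proximal at `z <= z_cut`. The retained set is the disease's
#' *pathway span*. Pathways with no gene in the interactome are skipped with
#' a warning.
#'
#' @param g Interactome (undirected igraph, typically the LCC).
#' @param disease_genes Character vector of disease gene ids.
#' @param pathways A named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param z_cut Significance cut on the proximity z (default -2).
#' @param n_random,min_bin_size,seed,dist_mat Passed to [proximity_z()];
#'   the distance matrix and degree bins are computed once and shared
#'   across pathways.
#' @param disease_id Optional label stored on the result.
#' @param keep_all If `TRUE`, return every pathway's score (column
#'   `in_span` flags the span) rather than only the span.
#' @return A data.frame of class `pathway_span` with columns `pathway_id`,
#'   `d_obs`, `mu`, `sigma`, `z`, sorted ascending by `z`; attributes
#'   `disease_id` and `z_cut`.
#' @export
pathway_span <- function(g, disease_genes, pathways, z_cut = -2,
                         n_random = 1000L, min_bin_size = 100L, seed = NULL,
                         disease_id = NA_character_, keep_all = FALSE,
                         dist_mat = NULL) {
  stopifnot(is.list(pathways))
  bins <- degree_bins(g, min_bin_size)
  dist_mat <- maybe_dist_mat(g, dist_mat)
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- names(pathways)
  rows <- lapply(ids, function(pid) {
    genes <- intersect(unique(as.character(pathways[[pid]])),
                       igraph::V(g)$name)
    if (length(genes) == 0L) {
      warning("pathway '", pid, "' has no gene in the interactome; skipped")
      return(NULL)
    }
    pr <- suppressWarnings(
      proximity_z(g, disease_genes, genes, n_random = n_random,
                  min_bin_size = min_bin_size, bins = bins,
                  dist_mat = dist_mat))
    data.frame(pathway_id = pid, d_obs = pr$d_obs, mu = pr$mu,
               sigma = pr$sigma, z = pr$z, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    res <- data.frame(pathway_id = character(0L), d_obs = numeric(0L),
                      mu = numeric(0L), sigma = numeric(0L), z = numeric(0L))
  } else {
    res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  res <- res[order(res$z, res$d_obs, res$pathway_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(res) <- NULL
  res$in_span <- !is.na(res$z) & res$z <= z_cut
  if (!keep_all) {
    res <- res[res$in_span, , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, disease_id = disease_id, z_cut = z_cut,
            class = c("pathway_span", "data.frame"))
}

#' Random walk with restart scores
#'
#' Propagates a unit of probability from a seed gene set over the network:
#' iterate \eqn{s \leftarrow r e + (1-r) W^T s} where `W` is the
#' column-normalized adjacency matrix, `e` the uniform restart vector over
#' the seeds, and `r` the restart probability. Iteration stops when the L1
#' change drops below `tol`; the converged vector is normalized to sum to 1.
#'
#' @param g Undirected igraph object.
#' @param seed_set Character vector of seed gene ids in `g`.
#' @param restart Restart probability in (0, 1]; default 0.5.
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum iterations; exceeding it is an error.
#' @return Named numeric vector of visit probabilities over all nodes.
#' @export
rwr_scores <- function(g, seed_set, restart = 0.5, tol = 1e-6,
                       max_iter = 1000L) {
  seed_set <- unique(as.character(seed_set))
  nodes <- igraph::V(g)$name
  missing <- setdiff(seed_set, nodes)
  if (length(missing) > 0L) {
    stop("seed gene(s) not in graph: ", paste(missing, collapse = ", "))
  }
  if (length(seed_set) == 0L) stop("seed_set must be nonempty")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::colSums(A)
  deg[deg == 0] <- 1              # isolated nodes keep zero score anyway
  # W column-normalized => W^T s = D^{-1} A s for a symmetric adjacency
  M <- Matrix::Diagonal(x = 1 / deg) %*% A
  e <- numeric(length(nodes))
  names(e) <- nodes
  e[seed_set] <- 1 / length(seed_set)
  s <- e
  for (it in seq_len(max_iter)) {
    s_new <- restart * e + (1 - restart) * as.numeric(M %*% s)
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < tol) {
      s <- s / sum(s)
      names(s) <- nodes
      return(s)
    }
  }
  stop("random walk did not converge after ", max_iter,
       " iterations (last L1 residual ", signif(delta, 3), ")")
}

#' Random-walk proximity z-score
#'
#' Alternative proximity engine: the statistic is the mean random-walk
#' visit probability over the target set `T` when the walk restarts from
#' `S`. The z-score is computed against the same degree-matched null as
#' [proximity_z()] (both sets resampled) and then negated, so that "more
#' proximal" means more negative and the z <= -2 significance convention of
#' the shortest-path engine applies unchanged.
#'
#' @inheritParams proximity_z
#' @param restart,tol,max_iter Passed to [rwr_scores()].
#' @return A `proximity_result` with `engine = "rwr"`; `d_obs` holds the
#'   observed mean visit probability.
#' @export
rwr_proximity_z <- function(g, S, T, n_random = 1000L, min_bin_size = 100L,
                            seed = NULL, bins = NULL, restart = 0.5,
                            tol = 1e-6, max_iter = 1000L) {
  n_random <- as.integer(n_random)
  if (n_random < 1L) stop("n_random must be >= 1")
  ds <- drop_absent(g, S, "S"); dt <- drop_absent(g, T, "T")
  if (length(ds$kept) == 0L || length(dt$kept) == 0L) {
    stop("S or T empty after dropping genes absent from the interactome")
  }
  if (is.null(bins)) bins <- degree_bins(g, min_bin_size)
  stat <- function(Sx, Tx) {
    mean(rwr_scores(g, Sx, restart = restart, tol = tol,
                    max_iter = max_iter)[Tx])
  }
  x_obs <- stat(ds$kept, dt$kept)
  if (!is.null(seed)) withr::local_seed(seed)
  null_values <- vapply(seq_len(n_random), function(i) {
    stat(sample_degree_matched(g, ds$kept, bins),
         sample_degree_matched(g, dt$kept, bins))
  }, numeric(1L))
  res <- new_proximity_result(x_obs, null_values, n_random, seed,
                              dropped = c(ds$dropped, dt$dropped),
                              engine = "rwr")
  # high visit probability = proximal; flip so z <= -2 still means "close"
  if (!is.na(res$z)) res$z <- -res$z
  res
}
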