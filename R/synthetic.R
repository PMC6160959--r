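#' Generate a toy interactome
#'
#' Random connected graphs for desk-scale benchmarking: scale-free
#' Barabasi-Albert graphs (heavy-tailed degrees, like real interactomes) or
#' Erdos-Renyi graphs (the structureless null). Generation is repeated
#' until the graph is connected, so the result is its own LCC.
#'
#' @param n_nodes Number of nodes (>= 3).
#' @param model `"barabasi_albert"` or `"erdos_renyi"`.
#' @param param Model parameter: edges per new node `m` for
#'   Barabasi-Albert (default 2), edge probability `p` for Erdos-Renyi
#'   (default 0.05).
#' @param seed Optional integer seed; generation is bit-reproducible.
#' @return Undirected connected igraph with vertex names `g1..gn`.
#' @export
toy_interactome <- function(n_nodes,
                            model = c("barabasi_albert", "erdos_renyi"),
                            param = NULL, seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  model <- match.arg(model)
  if (!is.null(seed)) withr::local_seed(seed)
  for (attempt in 1:100) {
    g <- switch(model,
      barabasi_albert = igraph::sample_pa(
        n_nodes, m = if (is.null(param)) 2L else as.integer(param),
        directed = FALSE),
      erdos_renyi = igraph::sample_gnp(
        n_nodes, p = if (is.null(param)) 0.05 else param))
    g <- igraph::simplify(g)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("g", seq_len(n_nodes))
      return(g)
    }
  }
  stop("failed to generate a connected graph in 100 attempts; ",
       "increase the edge density")
}

#' Plant a connected disease module
#'
#' Grows a connected node set by snowball sampling from a random start: at
#' each step a random frontier neighbor of the current set is added. The
#' induced subgraph on the result is always connected, emulating the
#' disease-module hypothesis that disease genes aggregate in interactome
#' neighborhoods.
#'
#' @param g Connected undirected igraph.
#' @param size Module size (<= number of nodes).
#' @param seed Optional integer seed.
#' @return Character vector of gene ids.
#' @export
plant_disease_module <- function(g, size, seed = NULL) {
  size <- as.integer(size)
  n <- igraph::vcount(g)
  if (size > n) stop("module size exceeds graph size")
  if (size < 1L) stop("module size must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  nodes <- sort(igraph::V(g)$name)
  module <- sample(nodes, 1L)
  while (length(module) < size) {
    nb_idx <- unique(unlist(lapply(igraph::adjacent_vertices(g, module),
                                   as.integer)))
    frontier <- setdiff(sort(igraph::V(g)$name[nb_idx]), module)
    if (length(frontier) == 0L) stop("graph is not connected")
    module <- c(module, sample(frontier, 1L))
  }
  sort(module)
}

#' Gold-standard pathways from noisy disease genes
#'
#' Builds synthetic "gold standard" pathways as random subsamples holding
#' `k` percent of a disease's genes — pathways that are true to the disease
#' but incomplete, emulating annotation noise. Set sizes are rounded half
#' up with a floor of one gene.
#'
#' @param disease_genes Character vector of disease gene ids.
#' @param k_percent Percentage of genes per pathway, in (0, 100].
#' @param n_reps Number of independent pathways (default 10).
#' @param seed Optional integer seed.
#' @return Named list of `n_reps` gene-id vectors.
#' @export
gold_standard_pathways <- function(disease_genes, k_percent, n_reps = 10L,
                                   seed = NULL) {
  disease_genes <- unique(as.character(disease_genes))
  if (length(disease_genes) == 0L) stop("disease_genes is empty")
  if (k_percent <= 0 || k_percent > 100) stop("k_percent must be in (0, 100]")
  if (!is.null(seed)) withr::local_seed(seed)
  size <- max(1L, as.integer(floor(k_percent / 100 * length(disease_genes)
                                   + 0.5)))
  out <- lapply(seq_len(n_reps), function(i) {
    sort(sample(disease_genes, size))
  })
  names(out) <- paste0("gold_k", k_percent, "_r", seq_len(n_reps))
  out
}

#' Size-matched random control pathways
#'
#' Uniform random node sets matching given sizes — the controls paired with
#' gold-standard pathways in the noise experiment. Plain random sampling,
#' no degree matching.
#'
#' @param g Undirected igraph.
#' @param sizes Integer vector of set sizes.
#' @param seed Optional integer seed.
#' @return Named list of gene-id vectors, one per size.
#' @export
control_pathways <- function(g, sizes, seed = NULL) {
  sizes <- as.integer(sizes)
  if (any(sizes > igraph::vcount(g))) stop("control size exceeds graph size")
  if (!is.null(seed)) withr::local_seed(seed)
  nodes <- sort(igraph::V(g)$name)
  out <- lapply(sizes, function(s) sort(sample(nodes, s)))
  names(out) <- paste0("control_", seq_along(sizes))
  out
}

#' Pathway-noise robustness experiment
#'
#' For each disease gene set and each noise level `k`, generates `n_reps`
#' gold-standard pathways (random `k`% subsets of the disease genes) and
#' size-matched random controls, then scores the proximity of the disease
#' genes to every pathway with the requested engines. With 2 diseases, 5
#' values of `k` and 10 replicates this yields 100 gold-standard pathways
#' (and 100 paired controls) per engine. Gold pathways should be strongly
#' proximal (z <= -2) while controls hover near z = 0, and the
#' shortest-path z should decrease as `k` grows (less noise).
#'
#' @param g Connected undirected igraph.
#' @param disease_gene_sets Named list of disease gene-id vectors.
#' @param k_values Noise levels (percent), default `c(10, 25, 50, 75, 90)`.
#' @param n_reps Replicates per (disease, k), default 10.
#' @param engines Subset of `c("shortest_path", "rwr")`.
#' @param n_random Null realizations per proximity z.
#' @param min_bin_size Degree-bin occupancy.
#' @param seed Optional integer seed for the full experiment.
#' @return data.frame with columns `disease_id`, `k`, `replicate`,
#'   `pathway_kind` (`"gold"`/`"control"`), `engine`, `d_obs`, `z`.
#' @export
noise_experiment <- function(g, disease_gene_sets,
                             k_values = c(10, 25, 50, 75, 90),
                             n_reps = 10L,
                             engines = "shortest_path",
                             n_random = 1000L, min_bin_size = 100L,
                             seed = NULL) {
  stopifnot(is.list(disease_gene_sets), length(disease_gene_sets) > 0L)
  engines <- match.arg(engines, c("shortest_path", "rwr"),
                       several.ok = TRUE)
  bins <- degree_bins(g, min_bin_size)
  dist_mat <- maybe_dist_mat(g, NULL)
  if (!is.null(seed)) withr::local_seed(seed)
  rows <- list()
  for (disease in sort(names(disease_gene_sets))) {
    genes <- intersect(unique(as.character(disease_gene_sets[[disease]])),
                       igraph::V(g)$name)
    if (length(genes) == 0L) stop("disease '", disease,
                                  "' has no gene in the graph")
    for (k in k_values) {
      gold <- gold_standard_pathways(genes, k, n_reps = n_reps)
      ctrl <- control_pathways(g, vapply(gold, length, 1L))
      for (rep_i in seq_len(n_reps)) {
        for (kind in c("gold", "control")) {
          pw <- if (kind == "gold") gold[[rep_i]] else ctrl[[rep_i]]
          for (engine in engines) {
            pr <- if (engine == "shortest_path") {
              proximity_z(g, genes, pw, n_random = n_random, bins = bins,
                          dist_mat = dist_mat)
            } else {
              rwr_proximity_z(g, genes, pw, n_random = n_random,
                              bins = bins)
            }
            rows[[length(rows) + 1L]] <- data.frame(
              disease_id = disease, k = k, replicate = rep_i,
              pathway_kind = kind, engine = engine,
              d_obs = pr$d_obs, z = pr$z, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
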