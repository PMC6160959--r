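#' Load an interactome from a two-column edge table
#'
#' Reads a plain TSV with one interaction per row (two tab-separated gene
#' identifiers). Lines starting with `#` and blank lines are skipped.
#' Self-loops are dropped (with a warning) and duplicate edges, including
#' reversed duplicates, are collapsed, so the result is a simple undirected
#' graph.
#'
#' @param path Path to a two-column tab-separated edge file.
#' @param quiet If `TRUE`, suppress the node/edge count message.
#' @return An undirected simple [igraph::igraph] object whose vertex names
#'   are the gene identifiers.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\ta", "b\tc"), f)
#' g <- load_interactome(f, quiet = TRUE)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @export
load_interactome <- function(path, quiet = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no parseable rows in edge table '", path, "'")
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop("edge table '", path, "': line ", idx[bad[1L]],
         " does not have exactly 2 tab-separated columns")
  }
  el <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  if (any(el == "")) stop("edge table '", path, "' contains empty identifiers")
  n_loops <- sum(el[, 1L] == el[, 2L])
  if (n_loops > 0L) {
    warning(n_loops, " self-loop(s) dropped from '", path, "'")
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!quiet) {
    message("interactome: ", igraph::vcount(g), " nodes, ",
            igraph::ecount(g), " edges")
  }
  g
}

#' Extract the largest connected component
#'
#' All network distances are computed on the largest connected component
#' (LCC) of the interactome so every gene can reach every other. Ties in
#' component size are broken deterministically by the lexicographically
#' smallest vertex name contained in the component.
#'
#' @param g An undirected igraph object with named vertices.
#' @return The induced subgraph on the largest component.
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # deterministic tie-break: component holding the smallest vertex name
    min_name <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1L))
    best <- best[order(min_name)][1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Hop distances from a set of source genes
#'
#' Breadth-first shortest path lengths (unweighted hop counts) from a set of
#' sources to every node of the graph; each node is assigned its distance to
#' the nearest source. Nodes unreachable from every source are omitted.
#'
#' @param g An undirected igraph object.
#' @param sources Character vector of source gene ids; must all be in `g`.
#' @return Named numeric vector mapping node id to hop distance.
#' @export
shortest_path_lengths <- function(g, sources) {
  sources <- unique(as.character(sources))
  missing <- setdiff(sources, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("source gene(s) not in graph: ", paste(missing, collapse = ", "))
  }
  d <- igraph::distances(g, v = sources, to = igraph::V(g))
  nearest <- apply(d, 2L, min)
  names(nearest) <- igraph::V(g)$name
  nearest[is.finite(nearest)]
}

#' Bin interactome nodes by degree
#'
#' Groups nodes by exact degree, then merges adjacent degree groups (in
#' ascending degree order) until every bin holds at least `min_bin_size`
#' nodes; a short final bin is merged backwards into its predecessor. The
#' bins drive the degree-matched random sampling used by the proximity
#' null model: a random counterpart of a gene is drawn from the gene's bin,
#' so random sets preserve the size and approximate degree profile of the
#' original set.
#'
#' @param g An undirected igraph object.
#' @param min_bin_size Minimum number of nodes per bin (default 100, the
#'   convention of the closest-distance proximity method).
#' @return An object of class `degree_bins`: a list with `bins` (each a list
#'   with `degrees = c(lo, hi)` and sorted `nodes`) and `min_bin_size`.
#' @export
degree_bins <- function(g, min_bin_size = 100L) {
  min_bin_size <- as.integer(min_bin_size)
  if (min_bin_size < 1L) stop("min_bin_size must be >= 1")
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  by_deg <- split(names(deg), deg)                # names are degree values
  degs <- sort(as.integer(names(by_deg)))
  bins <- list()
  cur_nodes <- character(0L)
  cur_lo <- NA_integer_
  for (d in degs) {
    if (length(cur_nodes) == 0L) cur_lo <- d
    cur_nodes <- c(cur_nodes, by_deg[[as.character(d)]])
    if (length(cur_nodes) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- list(degrees = c(cur_lo, d),
                                        nodes = sort(cur_nodes))
      cur_nodes <- character(0L)
    }
  }
  if (length(cur_nodes) > 0L) {
    if (length(bins) > 0L) {
      # merge trailing short bin backwards
      last <- bins[[length(bins)]]
      bins[[length(bins)]] <- list(
        degrees = c(last$degrees[1L], max(degs)),
        nodes = sort(c(last$nodes, cur_nodes)))
    } else {
      bins[[1L]] <- list(degrees = c(cur_lo, max(degs)),
                         nodes = sort(cur_nodes))
    }
  }
  lookup <- rep(seq_along(bins),
                vapply(bins, function(b) length(b$nodes), 1L))
  names(lookup) <- unlist(lapply(bins, `[[`, "nodes"))
  # vertex positions per bin (same order as the graph), for fast
  # integer-indexed resampling against a precomputed distance matrix
  vname <- igraph::V(g)$name
  vidx <- lapply(bins, function(b) match(b$nodes, vname))
  structure(list(bins = bins, min_bin_size = min_bin_size,
                 lookup = lookup, vidx = vidx),
            class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  cat("degree_bins:", length(x$bins), "bins (min_bin_size =",
      x$min_bin_size, ")\n")
  for (b in x$bins) {
    cat(sprintf("  degree %d-%d: %d nodes\n",
                b$degrees[1L], b$degrees[2L], length(b$nodes)))
  }
  invisible(x)
}

# bin index for each node id; internal
bin_of <- function(bins, nodes) {
  unname(bins$lookup[nodes])
}

#' Sample a degree-matched random gene set
#'
#' Draws, for every gene in `node_set`, a random gene from the same degree
#' bin, without replacement, yielding a random set of identical size and
#' matched degree profile. If a bin is exhausted (the set needs more genes
#' of a given degree class than the bin holds) the pool is widened to
#' adjacent bins with a warning.
#'
#' @param g An undirected igraph object.
#' @param node_set Character vector of gene ids in `g`.
#' @param bins Precomputed [degree_bins()] for `g`.
#' @param seed Optional integer seed; when supplied, sampling is
#'   reproducible and the caller's RNG state is left untouched.
#' @return Character vector of gene ids, same length as `unique(node_set)`.
#' @export
sample_degree_matched <- function(g, node_set, bins, seed = NULL) {
  node_set <- unique(as.character(node_set))
  missing <- setdiff(node_set, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  idx <- bin_of(bins, node_set)
  counts <- tabulate(idx, nbins = length(bins$bins))
  chosen <- vector("list", length(bins$bins))
  for (b in which(counts > 0L)) {
    m <- counts[b]
    pool <- bins$bins[[b]]$nodes
    if (m <= length(pool)) {
      # bins are disjoint, so cross-bin picks can never collide
      chosen[[b]] <- pool[sample.int(length(pool), m)]
      next
    }
    # bin exhausted: widen to adjacent bins (rare; only when node_set is
    # not itself a subset of the bin, e.g. after external deduplication)
    taken <- unlist(chosen)
    width <- 0L
    repeat {
      width <- width + 1L
      lo <- max(1L, b - width)
      hi <- min(length(bins$bins), b + width)
      pool <- setdiff(sort(unique(unlist(
        lapply(bins$bins[lo:hi], `[[`, "nodes")))), taken)
      if (length(pool) >= m) {
        warning("degree bin ", b, " exhausted; widened to adjacent bins")
        break
      }
      if (lo == 1L && hi == length(bins$bins)) {
        stop("cannot sample ", m, " nodes: graph too small")
      }
    }
    chosen[[b]] <- sample(pool, m)
  }
  unlist(chosen)
}
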