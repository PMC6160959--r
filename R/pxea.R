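#' Rank a pathway collection by proximity to a drug's targets
#'
#' Scores every pathway in the collection with the shortest-path proximity
#' z (direction: drug targets to pathway genes) and returns the full
#' collection ranked ascending by z — most proximal first. Ties are broken
#' by observed distance, then pathway id, so rankings are reproducible.
#'
#' @param g Interactome (undirected igraph LCC).
#' @param drug_targets Character vector of target gene ids; at least one
#'   must be in the interactome.
#' @param pathways Named list of gene-id vectors.
#' @param n_random,min_bin_size,seed,dist_mat Passed to [proximity_z()].
#' @return data.frame of class `ranked_pathways` with columns `rank`,
#'   `pathway_id`, `d_obs`, `mu`, `sigma`, `z`.
#' @export
rank_pathways_for_drug <- function(g, drug_targets, pathways,
                                   n_random = 1000L, min_bin_size = 100L,
                                   seed = NULL, dist_mat = NULL) {
  dt <- drop_absent(g, drug_targets, "drug targets")
  if (length(dt$kept) == 0L) stop("no drug target in the interactome")
  res <- pathway_span(g, dt$kept, pathways, z_cut = Inf,
                      n_random = n_random, min_bin_size = min_bin_size,
                      seed = seed, keep_all = TRUE, dist_mat = dist_mat)
  res <- as.data.frame(res)[, c("pathway_id", "d_obs", "mu", "sigma", "z")]
  res <- cbind(rank = seq_len(nrow(res)), res)
  class(res) <- c("ranked_pathways", "data.frame")
  res
}

#' Pathways shared by two disease spans
#'
#' Intersection of the pathway ids of two pathway spans (computed on the
#' same collection). This intersection is the usual pathway set of interest
#' `C` for scoring drugs against a disease pair; for a single disease pass
#' the same span twice.
#'
#' @param span_a,span_b [pathway_span()] results, or data.frames with a
#'   `pathway_id` column, or plain character vectors of pathway ids.
#' @return Sorted character vector of shared pathway ids (possibly empty;
#'   scoring an empty set is an error downstream).
#' @export
common_span <- function(span_a, span_b) {
  ids <- function(x) {
    if (is.character(x)) unique(x) else unique(as.character(x$pathway_id))
  }
  sort(intersect(ids(span_a), ids(span_b)))
}

# ids of a ranking, in rank order; internal
ranking_ids <- function(D) {
  if (is.character(D)) D else as.character(D$pathway_id)
}

# per-position increments of the running sum; internal
pxea_increments <- function(n_d, n_c, hit) {
  x <- rep(-n_c / (n_d - n_c), n_d)
  x[hit] <- (n_d - n_c) / n_c
  x
}

#' PxEA running-sum enrichment score
#'
#' Walks down the proximity-ranked pathway list `D` and accumulates
#' `(|D| - |C|)/|C|` whenever the pathway belongs to the set of interest
#' `C` and `-|C|/(|D| - |C|)` otherwise. The enrichment score is the
#' maximum of the running sum over all prefixes (floored at 0 by the empty
#' prefix), so it is large when the members of `C` concentrate at the
#' proximal top of the ranking. The score lies in `[0, |D| - |C|]` and
#' attains the maximum exactly when all of `C` occupies the top `|C|`
#' ranks.
#'
#' @param D A [rank_pathways_for_drug()] result, or a character vector of
#'   pathway ids already in rank order.
#' @param C Character vector of pathway ids of interest; must be a
#'   nonempty proper subset of `D`'s ids.
#' @return The enrichment score.
#' @examples
#' running_sum_es(paste0("p", 1:10), paste0("p", 1:3))  # 7: C on top
#' @export
running_sum_es <- function(D, C) {
  ids <- ranking_ids(D)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in ranking")
  C <- unique(as.character(C))
  n_d <- length(ids); n_c <- length(C)
  if (n_c == 0L || n_c >= n_d) {
    stop("need 0 < |C| < |D| (increments undefined otherwise)")
  }
  if (!all(C %in% ids)) stop("C must be a subset of the ranked pathway ids")
  x <- pxea_increments(n_d, n_c, ids %in% C)
  max(0, cumsum(x))
}

#' Permutation significance of a PxEA score
#'
#' Shuffles the ranking uniformly at random `n_perm` times (equivalently,
#' places the members of `C` uniformly among the `|D|` ranks), recomputes
#' the enrichment score for each shuffle, and reports
#' `p = #\{ES_random > ES_obs\} / n_perm` (strict inequality). A p of 0 is
#' stored as 0 and printed as `< 1/n_perm`; with the default 10,000
#' permutations the smallest reportable nonzero p is 1e-4.
#'
#' @inheritParams running_sum_es
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `pxea_result`: list with `es`, `p`, `n_perm`,
#'   `seed` and the null sample `es_null`.
#' @export
permutation_p <- function(D, C, n_perm = 10000L, seed = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  es_obs <- running_sum_es(D, C)
  ids <- ranking_ids(D)
  n_d <- length(ids); n_c <- length(unique(as.character(C)))
  if (!is.null(seed)) withr::local_seed(seed)
  base <- rep(-n_c / (n_d - n_c), n_d)
  x_hit <- (n_d - n_c) / n_c
  es_null <- vapply(seq_len(n_perm), function(b) {
    x <- base
    x[sample.int(n_d, n_c)] <- x_hit
    max(0, cumsum(x))
  }, numeric(1L))
  structure(list(es = es_obs, p = sum(es_null > es_obs) / n_perm,
                 n_perm = n_perm, seed = seed, es_null = es_null),
            class = "pxea_result")
}

#' @export
print.pxea_result <- function(x, ...) {
  p_txt <- if (x$p == 0) paste0("< ", format(1 / x$n_perm)) else
    format(x$p)
  cat(sprintf("PxEA: ES = %.4g, permutation p %s (n_perm = %d)\n",
              x$es, ifelse(x$p == 0, p_txt, paste("=", p_txt)), x$n_perm))
  invisible(x)
}

#' Screen a drug library against a pathway set of interest
#'
#' Runs the full PxEA pipeline for every drug in a target table: rank the
#' pathway collection by proximity to the drug's targets, score the
#' ranking against the pathway set of interest `C` (e.g. the common span
#' of two comorbid diseases), attach permutation significance, and adjust
#' p-values across drugs with Benjamini-Hochberg. Drugs with no target in
#' the interactome are reported but not scored.
#'
#' @param g Interactome (undirected igraph LCC).
#' @param drug_targets Named list mapping drug id to a character vector of
#'   target gene ids (e.g. from [read_pairs_tsv()]).
#' @param pathways Named list of gene-id vectors (the ranked collection D).
#' @param C Character vector of pathway ids of interest (nonempty, proper
#'   subset of the collection).
#' @param n_random Null-model realizations per proximity score.
#' @param n_perm Permutations per drug.
#' @param min_bin_size Degree-bin occupancy for the null model.
#' @param seed Optional integer seed covering the whole screen.
#' @return data.frame sorted by `es` descending (ties by drug id):
#'   `drug_id`, `es`, `p`, `p_adj`, `n_targets_used`, `dropped_targets`.
#' @export
pxea_screen <- function(g, drug_targets, pathways, C, n_random = 1000L,
                        n_perm = 10000L, min_bin_size = 100L, seed = NULL) {
  stopifnot(is.list(drug_targets))
  C <- unique(as.character(C))
  if (length(drug_targets) == 0L) {
    return(data.frame(drug_id = character(0), es = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      n_targets_used = integer(0),
                      dropped_targets = character(0)))
  }
  if (length(C) == 0L) stop("pathway set of interest C is empty")
  dist_mat <- maybe_dist_mat(g, NULL)
  if (!is.null(seed)) withr::local_seed(seed)
  score_cache <- new.env(parent = emptyenv())
  rows <- lapply(sort(names(drug_targets)), function(drug) {
    targets <- unique(as.character(drug_targets[[drug]]))
    kept <- intersect(targets, igraph::V(g)$name)
    dropped <- setdiff(targets, kept)
    if (length(kept) == 0L) {
      return(data.frame(drug_id = drug, es = NA_real_, p = NA_real_,
                        n_targets_used = 0L,
                        dropped_targets = paste(dropped, collapse = ","),
                        stringsAsFactors = FALSE))
    }
    # drugs sharing an identical target set share one ranking and score
    key <- paste(sort(kept), collapse = "\r")
    if (is.null(score_cache[[key]])) {
      D <- rank_pathways_for_drug(g, kept, pathways, n_random = n_random,
                                  min_bin_size = min_bin_size,
                                  dist_mat = dist_mat)
      score_cache[[key]] <- permutation_p(D, C, n_perm = n_perm)
    }
    pr <- score_cache[[key]]
    data.frame(drug_id = drug, es = pr$es, p = pr$p,
               n_targets_used = length(kept),
               dropped_targets = paste(dropped, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  scored <- !is.na(res$p)
  res$p_adj[scored] <- bh_adjust(res$p[scored])
  res <- res[order(-res$es, res$drug_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("drug_id", "es", "p", "p_adj", "n_targets_used",
          "dropped_targets")]
}
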