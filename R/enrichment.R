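#' Fisher's exact test on a 2x2 overlap table
#'
#' Thin, validated front-end to [stats::fisher.test()] for the 2x2
#' contingency tables used throughout the package (gene-set overlaps,
#' shared symptoms, shared pathways). The two-sided p sums the
#' probabilities of all tables with the same margins whose point
#' probability does not exceed the observed one; the one-sided alternative
#' is the upper hypergeometric tail (enrichment).
#'
#' @param both,only_a,only_b,neither Non-negative integer cells: elements in
#'   both sets, in only the first, in only the second, and in neither.
#' @param alternative `"greater"` (one-sided enrichment) or `"two.sided"`.
#' @return The p-value.
#' @examples
#' fisher_exact(35, 135, 47, 457, alternative = "two.sided")  # 2.2e-4
#' @export
fisher_exact <- function(both, only_a, only_b, neither,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  cells <- c(both, only_a, only_b, neither)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  if (sum(cells) == 0) stop("contingency table is empty")
  m <- matrix(as.integer(cells), nrow = 2L, byrow = TRUE)
  stats::fisher.test(m, alternative = alternative)$p.value
}

# 2x2 table of two sets within a universe; internal
overlap_table <- function(a, b, universe) {
  a <- intersect(unique(a), universe)
  b <- intersect(unique(b), universe)
  both <- length(intersect(a, b))
  c(both = both, only_a = length(a) - both, only_b = length(b) - both,
    neither = length(universe) - length(union(a, b)))
}

#' Overlap-based pathway enrichment
#'
#' The conventional enrichment approach: for each pathway, test the overlap
#' between the query gene set and the pathway genes (both restricted to a
#' gene universe) with a one-tailed Fisher's exact test, then adjust across
#' pathways with Benjamini-Hochberg.
#'
#' @param query Character vector of query gene ids (e.g. disease genes).
#'   Genes outside the universe are dropped with a warning.
#' @param pathways Named list of gene-id vectors.
#' @param universe Character vector: the gene universe. A sensible default
#'   is all genes of the pathway collection intersected with the
#'   interactome.
#' @param alpha Significance threshold recorded in the `significant` column.
#' @return data.frame with columns `set_id`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `p_adj`, `significant`, sorted by
#'   `p` then `set_id`.
#' @export
overlap_enrichment <- function(query, pathways, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  rows <- lapply(names(pathways), function(pid) {
    genes <- intersect(unique(as.character(pathways[[pid]])), universe)
    tab <- overlap_table(query, genes, universe)
    data.frame(set_id = pid, overlap = tab[["both"]],
               set_size = length(genes), query_size = length(query),
               universe_size = length(universe),
               p = fisher_exact(tab[["both"]], tab[["only_a"]],
                                tab[["only_b"]], tab[["neither"]],
                                alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(set_id = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0))
  }
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res$significant <- res$p <= alpha
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate correction with monotonicity enforcement,
#' values capped at 1, output in input order (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
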