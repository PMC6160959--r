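#' Construct a disease profile
#'
#' Bundles the per-disease inputs of the diseasome builder: the disease's
#' gene set, optionally its symptom scores (TF-IDF weighted associations
#' from literature mining) and optionally its pathway span.
#'
#' @param disease_id Disease identifier.
#' @param genes Nonempty character vector of gene ids.
#' @param symptoms Optional data.frame with columns `symptom_id`, `tfidf`.
#' @param pathway_span Optional [pathway_span()] result (or any data.frame
#'   with a `pathway_id` column).
#' @return An object of class `disease_profile`.
#' @export
disease_profile <- function(disease_id, genes, symptoms = NULL,
                            pathway_span = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("disease profile needs at least one gene")
  if (!is.null(symptoms)) {
    stopifnot(is.data.frame(symptoms),
              all(c("symptom_id", "tfidf") %in% names(symptoms)))
    if (any(symptoms$tfidf < 0)) stop("TF-IDF scores must be >= 0")
  }
  structure(list(disease_id = disease_id, genes = genes,
                 symptoms = symptoms, pathway_span = pathway_span),
            class = "disease_profile")
}

#' Significance of a shared-element link between two sets
#'
#' Two-sided Fisher's exact test on the overlap of two sets within a
#' universe; the building block for the shared-gene and shared-symptom
#' evidence channels of the diseasome.
#'
#' @param a,b Character vectors, subsets of `universe`.
#' @param universe Character vector of all possible elements.
#' @param alpha Significance level (link deemed present when p <= alpha).
#' @return List with `significant` (logical) and `p`.
#' @export
shared_set_link <- function(a, b, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty")
  tab <- overlap_table(a, b, universe)
  p <- fisher_exact(tab[["both"]], tab[["only_a"]], tab[["only_b"]],
                    tab[["neither"]], alternative = "two.sided")
  list(significant = p <= alpha, p = p)
}

#' Filter symptoms by TF-IDF score
#'
#' Keeps disease-symptom associations with TF-IDF score strictly above the
#' threshold (default 3.5), the quality filter applied to literature-mined
#' symptom data.
#'
#' @param profile A [disease_profile()] carrying a symptom table.
#' @param tfidf_min Threshold; associations must score strictly higher.
#' @return Character vector of retained symptom ids.
#' @export
symptom_filter <- function(profile, tfidf_min = 3.5) {
  if (is.null(profile$symptoms)) stop("profile has no symptom table")
  s <- profile$symptoms
  unique(as.character(s$symptom_id[s$tfidf > tfidf_min]))
}

#' Comorbidity relative risk
#'
#' Observed co-occurrence of two diagnoses in the same patients relative to
#' the expectation under independence given the diseases' prevalences:
#' \deqn{RR_{ij} = \frac{C_{ij} N}{P_i P_j}}
#' where `C_ij` patients have both diseases, `P_i` and `P_j` are the
#' prevalences and `N` the cohort size. A comorbidity link is called when
#' RR is strictly greater than 1.
#'
#' @param c_ij Patients with both diseases.
#' @param p_i,p_j Patients with each disease (must be positive).
#' @param n Total patients.
#' @return The relative risk.
#' @export
relative_risk <- function(c_ij, p_i, p_j, n) {
  if (p_i <= 0 || p_j <= 0) stop("disease prevalences must be positive")
  if (c_ij < 0 || c_ij > min(p_i, p_j) || max(p_i, p_j) > n) {
    stop("inconsistent comorbidity counts")
  }
  (c_ij * n) / (p_i * p_j)
}

#' Build the multi-evidence disease-disease network (diseasome)
#'
#' Evaluates, for every unordered disease pair, up to four independent
#' evidence channels and emits an edge whenever at least one fires:
#' \itemize{
#'   \item \strong{shared_genes}: two-sided Fisher on the gene overlap
#'     (p <= alpha);
#'   \item \strong{shared_symptoms}: two-sided Fisher on the overlap of
#'     TF-IDF-filtered symptoms (p <= alpha);
#'   \item \strong{comorbidity}: relative risk > 1 from a co-occurrence
#'     count table;
#'   \item \strong{shared_pathways}: two-sided Fisher on the overlap of the
#'     diseases' pathway spans over the pathway universe (p < alpha,
#'     strict).
#' }
#' A channel is evaluated only for pairs whose inputs exist (e.g. both
#' profiles carry symptom tables).
#'
#' @param profiles List of [disease_profile()] objects (>= 2).
#' @param gene_universe Character vector for the shared-gene tests.
#' @param symptom_universe Optional; defaults to the union of all
#'   post-filter symptoms across profiles.
#' @param comorbidity Optional data.frame with columns `disease_a`,
#'   `disease_b`, `c_ij`, `p_i`, `p_j`, `n`.
#' @param n_pathways Size of the pathway universe (number of pathways in
#'   the collection the spans were computed on); required when profiles
#'   carry pathway spans.
#' @param alpha Significance level for the Fisher channels.
#' @param tfidf_min Symptom score filter threshold.
#' @return data.frame with one row per connected pair: `disease_a`,
#'   `disease_b`, `evidence` (comma-joined channel names), `p_genes`,
#'   `p_symptoms`, `rr`, `p_pathways` (NA where a channel was not
#'   evaluated).
#' @export
build_diseasome <- function(profiles, gene_universe,
                            symptom_universe = NULL, comorbidity = NULL,
                            n_pathways = NULL, alpha = 0.05,
                            tfidf_min = 3.5) {
  if (length(profiles) < 2L) stop("need at least two disease profiles")
  ids <- vapply(profiles, `[[`, character(1L), "disease_id")
  if (anyDuplicated(ids)) stop("duplicate disease ids in profiles")
  names(profiles) <- ids

  has_sym <- vapply(profiles, function(p) !is.null(p$symptoms), logical(1L))
  sym_sets <- lapply(profiles[has_sym], symptom_filter, tfidf_min = tfidf_min)
  if (is.null(symptom_universe)) {
    symptom_universe <- sort(unique(unlist(sym_sets)))
  }
  span_ids <- lapply(profiles, function(p) {
    if (is.null(p$pathway_span)) NULL else
      unique(as.character(p$pathway_span$pathway_id))
  })
  rr_lookup <- NULL
  if (!is.null(comorbidity)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    rr_lookup <- stats::setNames(
      mapply(relative_risk, comorbidity$c_ij, comorbidity$p_i,
             comorbidity$p_j, comorbidity$n),
      key(comorbidity$disease_a, comorbidity$disease_b))
  }

  pairs <- utils::combn(sort(ids), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    evid <- character(0L)
    p_genes <- p_symptoms <- rr <- p_pathways <- NA_real_

    link <- shared_set_link(profiles[[a]]$genes, profiles[[b]]$genes,
                            gene_universe, alpha)
    p_genes <- link$p
    if (link$significant) evid <- c(evid, "shared_genes")

    if (has_sym[[a]] && has_sym[[b]] && length(symptom_universe) > 0L) {
      link <- shared_set_link(sym_sets[[a]], sym_sets[[b]],
                              symptom_universe, alpha)
      p_symptoms <- link$p
      if (link$significant) evid <- c(evid, "shared_symptoms")
    }

    if (!is.null(rr_lookup)) {
      k2 <- paste(min(a, b), max(a, b), sep = "\r")
      if (k2 %in% names(rr_lookup)) {
        rr <- rr_lookup[[k2]]
        if (rr > 1) evid <- c(evid, "comorbidity")
      }
    }

    if (!is.null(span_ids[[a]]) && !is.null(span_ids[[b]])) {
      if (is.null(n_pathways)) {
        stop("n_pathways required when profiles carry pathway spans")
      }
      sa <- span_ids[[a]]; sb <- span_ids[[b]]
      all_ids <- unique(c(sa, sb))
      if (length(all_ids) > n_pathways) {
        stop("pathway spans contain more ids than n_pathways")
      }
      tab <- c(both = length(intersect(sa, sb)),
               only_a = length(setdiff(sa, sb)),
               only_b = length(setdiff(sb, sa)))
      tab <- c(tab, neither = n_pathways - sum(tab))
      p_pathways <- fisher_exact(tab[["both"]], tab[["only_a"]],
                                 tab[["only_b"]], tab[["neither"]],
                                 alternative = "two.sided")
      if (p_pathways < alpha) evid <- c(evid, "shared_pathways")
    }

    if (length(evid) == 0L) return(NULL)
    data.frame(disease_a = a, disease_b = b,
               evidence = paste(evid, collapse = ","),
               p_genes = p_genes, p_symptoms = p_symptoms, rr = rr,
               p_pathways = p_pathways, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(disease_a = character(0), disease_b = character(0),
                      evidence = character(0), p_genes = numeric(0),
                      p_symptoms = numeric(0), rr = numeric(0),
                      p_pathways = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Summary metrics of a disease network
#'
#' Average degree (2|E|/n) and average local clustering coefficient over a
#' node set, where nodes of degree below 2 contribute a clustering of 0.
#'
#' @param edges Two-column data.frame (or matrix) of node-id pairs.
#' @param n_nodes Total number of nodes (isolated nodes included).
#' @return List with `avg_degree` and `avg_clustering`.
#' @examples
#' tri <- data.frame(a = c("x", "y", "z"), b = c("y", "z", "x"))
#' network_metrics(tri, 3)  # degree 2, clustering 1
#' @export
network_metrics <- function(edges, n_nodes) {
  if (n_nodes < 1L) stop("n_nodes must be >= 1")
  el <- as.matrix(edges[, 1:2, drop = FALSE])
  mode(el) <- "character"
  if (nrow(el) == 0L) return(list(avg_degree = 0, avg_clustering = 0))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  extra <- n_nodes - igraph::vcount(g)
  if (extra < 0L) stop("edges mention more nodes than n_nodes")
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(avg_degree = 2 * igraph::ecount(g) / n_nodes,
       avg_clustering = sum(local_cc) / n_nodes)
}
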