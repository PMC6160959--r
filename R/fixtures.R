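# Curated disease-gene associations for nine autoimmune disorders and the
# topology of their multi-evidence disease network. Gene symbols are kept
# as plain strings; no registry validation is attempted.

autoimmune_genes <- list(
  celiac_disease = c(
    "IL21", "CCR4", "HLA-DQA1", "BACH2", "RUNX3", "ICOSLG", "SH2B3",
    "CTLA4", "MYO9B", "ZMIZ1", "ETS1"),
  crohns_disease = c(
    "DNMT3A", "IL12B", "IRGM", "IL10", "CCL2", "FUT2", "SMAD3", "TYK2",
    "ATG16L1", "BACH2", "IL2RA", "NKX2-3", "PTPN2", "NOD2", "TAGAP",
    "MST1", "DENND1B", "IL23R", "ERAP2"),
  diabetes_mellitus_insulin_dependent = c(
    "IL10", "GLIS3", "HLA-DQA1", "HLA-DRB1", "PTPN22", "SLC29A3", "INS",
    "BACH2", "CLEC16A", "PAX4", "HLA-DQB1", "IL2RA", "CD69", "IL27",
    "HNF1A", "CTSH", "SH2B3", "C1QTNF6"),
  graves_disease = c("RNASET2", "CTLA4", "FCRL3", "TSHR"),
  lupus_erythematosus_systemic = c(
    "IKZF1", "CFB", "RASGRP3", "PDCD1", "RASGRP1", "DNASE1", "HLA-DRB1",
    "PTPN22", "ETS1", "TNIP1", "FCGR2B", "TNFSF4", "IRF5", "C2", "PRDM1",
    "PXK", "TLR5", "TREX1", "TNFAIP3", "SLC15A4", "PHRF1", "HLA-DQA1",
    "STAT4", "ITGAX", "ITGAM", "BLK", "C4A", "BANK1", "CR2"),
  multiple_sclerosis = c(
    "CD58", "CD6", "IRF8", "HLA-DQB1", "CBLB", "HLA-DRA", "KIF1B",
    "IL2RA", "TNFSF14", "VCAM1", "IL7R", "HLA-DRB1", "CD24", "TNFRSF1A",
    "PTPRC"),
  psoriasis = c(
    "IL12B", "TNIP1", "LCE3D", "IL13", "IL23R", "TYK2", "HLA-DQB1",
    "HLA-C", "FBXL19", "ERAP1", "TRAF3IP2", "TNFAIP3", "TNF", "REL",
    "NOS2"),
  rheumatoid_arthritis = c(
    "MIF", "CD40", "ANKRD55", "HLA-DRB1", "PTPN22", "RBPJ", "IL2RA",
    "AFF3", "CCL21", "REL", "SLC22A4", "CCR6", "IRF5", "SPRED2", "CTLA4",
    "PADI4", "TNFAIP3", "NFKBIL1", "HLA-DQA2", "STAT4", "IL6", "BLK",
    "TRAF1"),
  ulcerative_colitis = c(
    "IL12B", "JAK2", "ICOSLG", "IL1R2", "LSP1", "CXCR2", "IL10", "IL7R",
    "CXCR1", "DAP", "NKX2-3", "CARD9", "GNA12", "IRF5", "PRDM1", "HNF4A",
    "CCNY", "SLC26A3", "FCGR2A", "IL23R", "IL17REL", "MST1", "TNFSF15",
    "CDH3")
)

# disease pairs that carry no evidence in the autoimmune diseasome
autoimmune_missing_links <- list(
  c("ulcerative_colitis", "rheumatoid_arthritis"),
  c("ulcerative_colitis", "graves_disease"),
  c("graves_disease", "diabetes_mellitus_insulin_dependent")
)

#' Built-in autoimmune disorder fixtures
#'
#' Returns the curated gene sets of nine autoimmune disorders and the
#' topology of their multi-evidence diseasome: the complete graph over the
#' nine diseases minus the three unsupported pairs (ulcerative colitis -
#' rheumatoid arthritis, ulcerative colitis - Graves' disease, Graves'
#' disease - type 1 diabetes), i.e. 33 of the 36 possible links.
#'
#' @return List with `disease_genes` (named list of 9 gene-symbol vectors,
#'   sizes 11, 19, 18, 4, 29, 15, 15, 23, 24) and `diseasome_edges`
#'   (data.frame `disease_a`, `disease_b`, 33 rows).
#' @examples
#' fx <- autoimmune_fixtures()
#' length(fx$disease_genes$graves_disease)  # 4
#' nrow(fx$diseasome_edges)                 # 33
#' @export
autoimmune_fixtures <- function() {
  ids <- sort(names(autoimmune_genes))
  pairs <- utils::combn(ids, 2L)
  drop_key <- vapply(autoimmune_missing_links, function(p) {
    paste(sort(p), collapse = "\r")
  }, character(1L))
  keep <- !(paste(pairs[1L, ], pairs[2L, ], sep = "\r") %in% drop_key)
  edges <- data.frame(disease_a = pairs[1L, keep],
                      disease_b = pairs[2L, keep],
                      stringsAsFactors = FALSE)
  list(disease_genes = autoimmune_genes, diseasome_edges = edges)
}

#' Export the built-in fixtures to plain-text files
#'
#' Writes the autoimmune disease-gene table as a two-column TSV
#' (`disease_genes.tsv`, readable by [read_pairs_tsv()]) and the diseasome
#' topology as an edge list (`diseasome_edges.tsv`).
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- autoimmune_fixtures()
  genes_path <- file.path(dir, "disease_genes.tsv")
  write_pairs_tsv(fx$disease_genes, genes_path)
  edges_path <- file.path(dir, "diseasome_edges.tsv")
  utils::write.table(fx$diseasome_edges, edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(genes_path, edges_path))
}
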