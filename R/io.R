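#' Read a GMT pathway collection
#'
#' Parses the tab-separated GMT gene-set format (set name, description,
#' then one gene per field). Blank lines are skipped; duplicate genes
#' within a set are removed with a warning, preserving first-seen order.
#' Duplicate set ids or lines with fewer than three fields are errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene-id vectors of class `gmt_collection`, with
#'   a named `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*$", lines))
  sets <- list()
  descs <- character(0L)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT '", path, "': line ", i, " has fewer than 3 fields")
    }
    id <- fields[1L]
    if (id %in% names(sets)) {
      stop("GMT '", path, "': duplicate set id '", id, "'")
    }
    genes <- fields[-(1:2)]
    genes <- genes[genes != ""]
    if (anyDuplicated(genes)) {
      warning("GMT set '", id, "': duplicate genes removed")
      genes <- genes[!duplicated(genes)]
    }
    sets[[id]] <- genes
    descs[[id]] <- fields[2L]
  }
  structure(sets, description = descs, class = "gmt_collection")
}

#' Write a GMT pathway collection
#'
#' @param sets Named list of gene-id vectors; descriptions taken from a
#'   `description` attribute when present (empty otherwise).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "description")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descs) && id %in% names(descs)) descs[[id]] else ""
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column association table
#'
#' Reads id-gene pairs (disease-gene or drug-target associations) from a
#' two-column TSV and groups them by the first column. Lines starting with
#' `#` and blank lines are skipped; duplicate pairs are counted once.
#'
#' @param path Path to a two-column tab-separated file.
#' @return Named list mapping each id to its unique gene-id vector.
#' @export
read_pairs_tsv <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*$", lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) return(list())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop("pairs table '", path, "': line ", keep[bad[1L]],
         " does not have exactly 2 tab-separated columns")
  }
  id <- vapply(fields, `[[`, character(1L), 1L)
  gene <- vapply(fields, `[[`, character(1L), 2L)
  lapply(split(gene, id), unique)
}

#' Write a two-column association table
#'
#' Inverse of [read_pairs_tsv()]: one `id<TAB>gene` row per association,
#' ids in the list's order.
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs_tsv <- function(sets, path) {
  lines <- unlist(lapply(names(sets), function(id) {
    paste(id, sets[[id]], sep = "\t")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write proximity or screen results as TSV
#'
#' Deterministic tab-separated export for the data.frame results of
#' [pathway_span()], [rank_pathways_for_drug()], [pxea_screen()] and
#' [build_diseasome()].
#'
#' @param x A data.frame result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a diseasome as SIF
#'
#' Simple interaction format for network viewers: one
#' `source<TAB>relation<TAB>target` row per edge, the relation being the
#' comma-joined evidence string.
#'
#' @param diseasome A [build_diseasome()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diseasome_sif <- function(diseasome, path) {
  lines <- paste(diseasome$disease_a, diseasome$evidence,
                 diseasome$disease_b, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
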