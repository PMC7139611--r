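#' Parse a miRNA-target prediction table
#'
#' Reads one prediction algorithm's output: a TSV with header columns `mirna`
#' and `gene` (an optional `score` column is carried along). Every row is
#' stamped with the supplied source name; duplicate rows are kept — the
#' consensus step deduplicates by distinct source.
#'
#' @param path Path to a TSV file.
#' @param source Name of the prediction algorithm (nonempty).
#' @return Tibble with columns `mirna_id`, `gene_symbol`, `source`, `score`.
#' @export
parse_prediction_table <- function(path, source) {
  if (!nzchar(trimws(source))) stop_cf("parse_prediction_table(): empty source name")
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("mirna", "gene")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_cf("parse_prediction_table(): '", path, "' lacks column(s): ",
            paste(missing_cols, collapse = ", "),
            class = "counterflow_schema_error")
  }
  tibble::tibble(
    mirna_id = tab$mirna,
    gene_symbol = tab$gene,
    source = source,
    score = if ("score" %in% names(tab)) suppressWarnings(as.numeric(tab$score))
            else NA_real_
  )
}

#' Aggregate per-algorithm predictions into a consensus target map
#'
#' Pools prediction records from several algorithms, restricts them to the
#' miRNAs of interest, and keeps a (miRNA, gene) pair iff the number of
#' *distinct* sources predicting it is at least `min_sources`. miRNA ids are
#' matched exactly but case-insensitively after whitespace trimming; species
#' prefixes (`mmu-`, `hsa-`) are preserved and never translated. Gene symbols
#' are canonicalized to uppercase.
#'
#' @param tables A tibble of prediction records (rows from one or more
#'   [parse_prediction_table()] calls, row-bound), or a list of such tibbles.
#' @param mirnas Character vector of miRNA ids to keep (nonempty).
#' @param min_sources Minimum number of distinct predicting algorithms
#'   (default 1).
#' @return An object of class `TargetMap`: list with `pairs` (tibble
#'   `mirna_id`, `gene_symbol`, `evidence`), and `mirnas` (ordered unique
#'   miRNA ids present in the pairs).
#' @export
consensus_targets <- function(tables, mirnas, min_sources = 1L) {
  if (is.data.frame(tables)) tables <- list(tables)
  rec <- dplyr::bind_rows(tables)
  if (length(mirnas) == 0L) {
    stop_cf("consensus_targets(): empty miRNA list",
            class = "counterflow_validation_error")
  }
  stopifnot(min_sources >= 1L)
  mir_keep <- canonical_mirna(mirnas)
  # first-seen display form of each miRNA id, from the filter list
  mir_display <- stats::setNames(trimws(mirnas)[!duplicated(mir_keep)],
                                 unique(mir_keep))
  if (nrow(rec)) {
    rec$mirna_key <- canonical_mirna(rec$mirna_id)
    rec$gene_symbol <- canonical_symbol(rec$gene_symbol)
    rec <- rec[rec$mirna_key %in% mir_keep, , drop = FALSE]
  }
  pairs <- if (nrow(rec)) {
    rec |>
      dplyr::distinct(.data$mirna_key, .data$gene_symbol, .data$source) |>
      dplyr::count(.data$mirna_key, .data$gene_symbol, name = "evidence") |>
      dplyr::filter(.data$evidence >= min_sources) |>
      dplyr::mutate(mirna_id = unname(mir_display[.data$mirna_key])) |>
      dplyr::select("mirna_id", "gene_symbol", "evidence") |>
      dplyr::arrange(.data$mirna_id, .data$gene_symbol)
  } else {
    tibble::tibble(mirna_id = character(), gene_symbol = character(),
                   evidence = integer())
  }
  new_target_map(pairs)
}

new_target_map <- function(pairs) {
  structure(
    list(pairs = pairs, mirnas = sort_c(unique(pairs$mirna_id))),
    class = "TargetMap"
  )
}

#' @export
print.TargetMap <- function(x, ...) {
  cat(sprintf("<TargetMap: %d pairs, %d miRNAs, %d genes>\n",
              nrow(x$pairs), length(x$mirnas),
              length(unique(x$pairs$gene_symbol))))
  invisible(x)
}

#' Unique predicted targets of a target map
#'
#' @param map A `TargetMap`.
#' @param name Name for the resulting `GeneSet` (default "targets").
#' @return A `GeneSet` of the sorted unique gene symbols over all pairs.
#' @export
unique_target_set <- function(map, name = "targets") {
  stopifnot(inherits(map, "TargetMap"))
  if (!nrow(map$pairs)) return(gene_set(name = name))
  gs <- gene_set(map$pairs$gene_symbol, name = name)
  gs$provenance <- sprintf("%d unique targets over %d (miRNA, gene) pairs from %d miRNAs",
                           length(gs), nrow(map$pairs), length(map$mirnas))
  gs
}

#' Write / read a target map as TSV (mirna, gene, evidence)
#'
#' @param map A `TargetMap`.
#' @param path File path.
#' @return `path` invisibly (writer); a `TargetMap` (reader).
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "TargetMap"))
  out <- map$pairs
  names(out) <- c("mirna", "gene", "evidence")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_target_map
#' @export
read_target_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cci", progress = FALSE)
  new_target_map(tibble::tibble(mirna_id = tab$mirna,
                                gene_symbol = canonical_symbol(tab$gene),
                                evidence = tab$evidence))
}

#' Read a prediction manifest (source name -> table path)
#'
#' The manifest is a two-column TSV (`source`, `path`); relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return Tibble of pooled prediction records across all listed sources.
#' @export
read_prediction_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("source", "path") %in% names(man))) {
    stop_cf("read_prediction_manifest(): manifest needs columns source, path",
            class = "counterflow_schema_error")
  }
  base <- dirname(path)
  dplyr::bind_rows(lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    parse_prediction_table(p, man$source[i])
  }))
}
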