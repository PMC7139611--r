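#' Read / write a differential-expression table
#'
#' The counter-expression filter consumes precompiled differential-expression
#' lists (for miRNAs and for mRNAs) as TSVs with columns `feature_id`,
#' `fold_change_abs` (absolute scale, >= 1), `direction` (`up`/`down`),
#' `p_value`, and optionally `refseq` and `contrast`. Direction is an
#' explicit column rather than a signed fold change, matching the convention
#' of tables that print absolute fold changes under "up-/downregulated"
#' section headers. `fold_change_abs` and `p_value` may be `NA` when a list
#' is published without magnitudes.
#'
#' @param path File path.
#' @param de Tibble of DE records (writer).
#' @return Tibble of DE records (reader); `path` invisibly (writer).
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    fold_change_abs = readr::col_double(),
    direction = readr::col_character(),
    p_value = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_de_table(tab)
  tab
}

#' @rdname read_de_table
#' @export
write_de_table <- function(de, path) {
  validate_de_table(de)
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}

validate_de_table <- function(de) {
  need <- c("feature_id", "fold_change_abs", "direction", "p_value")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols)) {
    stop_cf("DE table lacks column(s): ", paste(missing_cols, collapse = ", "),
            class = "counterflow_schema_error")
  }
  if (any(!de$direction %in% c("up", "down"))) {
    stop_cf("DE table: direction must be 'up' or 'down'",
            class = "counterflow_validation_error")
  }
  fc <- de$fold_change_abs
  if (any(!is.na(fc) & fc < 1)) {
    stop_cf("DE table: fold_change_abs is on the absolute scale and must be >= 1",
            class = "counterflow_validation_error")
  }
  p <- de$p_value
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop_cf("DE table: p_value must lie in (0, 1]",
            class = "counterflow_validation_error")
  }
  invisible(de)
}

#' Counter-expressed miRNA/target pairs
#'
#' The core validation rule: a predicted (miRNA, gene) pair is biologically
#' plausible only if the two change in *opposite* directions in the same
#' contrast (an upregulated miRNA represses its target, so a true target of
#' an upregulated miRNA should appear among the downregulated mRNAs). This
#' function keeps a pair of `map` iff the gene lies in `restrict_to` (when
#' given), the gene appears in `mrna_de`, and the miRNA's and the gene's
#' directions differ.
#'
#' @param map A `TargetMap` of predicted pairs.
#' @param mirna_de DE tibble for miRNAs; every miRNA of `map` must appear
#'   (ids matched case-insensitively), otherwise a validation error lists the
#'   missing ids.
#' @param mrna_de DE tibble for mRNAs; genes absent from it are simply not
#'   validated (the DE list defines which genes changed at all).
#' @param restrict_to Optional `GeneSet` (e.g., the oxidative-stress set);
#'   pairs whose gene is outside it are dropped before the direction check.
#' @param p_max Optional p-value ceiling applied to both DE tables before
#'   filtering (default `NULL`: the DE tables are taken as already
#'   significant).
#' @return Tibble of validated pairs, sorted by gene then miRNA, with columns
#'   `mirna_id`, `gene_symbol`, `mirna_direction`, `gene_direction`,
#'   `evidence`. By construction `mirna_direction != gene_direction` on
#'   every row.
#' @export
counter_expressed_pairs <- function(map, mirna_de, mrna_de, restrict_to = NULL,
                                    p_max = NULL) {
  stopifnot(inherits(map, "TargetMap"))
  validate_de_table(mirna_de)
  validate_de_table(mrna_de)
  if (!is.null(p_max)) {
    mirna_de <- mirna_de[is.na(mirna_de$p_value) | mirna_de$p_value <= p_max, ]
    mrna_de <- mrna_de[is.na(mrna_de$p_value) | mrna_de$p_value <= p_max, ]
  }
  mir_dir <- stats::setNames(mirna_de$direction, canonical_mirna(mirna_de$feature_id))
  gene_dir <- stats::setNames(mrna_de$direction, canonical_symbol(mrna_de$feature_id))

  pairs <- map$pairs
  missing_mirnas <- setdiff(canonical_mirna(pairs$mirna_id), names(mir_dir))
  if (length(missing_mirnas)) {
    stop_cf("counter_expressed_pairs(): miRNA(s) in target map absent from mirna_de: ",
            paste(sort_c(missing_mirnas), collapse = ", "),
            class = "counterflow_validation_error")
  }
  if (!is.null(restrict_to)) {
    restrict_to <- as_gene_set(restrict_to)
    pairs <- pairs[pairs$gene_symbol %in% restrict_to$symbols, , drop = FALSE]
  }
  pairs$mirna_direction <- unname(mir_dir[canonical_mirna(pairs$mirna_id)])
  pairs$gene_direction <- unname(gene_dir[pairs$gene_symbol])
  keep <- !is.na(pairs$gene_direction) &
    pairs$mirna_direction != pairs$gene_direction
  out <- pairs[keep, c("mirna_id", "gene_symbol", "mirna_direction",
                       "gene_direction", "evidence")]
  out[order(out$gene_symbol, out$mirna_id, method = "radix"), , drop = FALSE]
}

#' Gene set of validated counter-expressed targets
#'
#' @param pairs Tibble of validated pairs from [counter_expressed_pairs()].
#' @param name Name for the resulting `GeneSet`.
#' @return A `GeneSet` of the sorted unique gene symbols of `pairs`.
#' @export
validated_gene_set <- function(pairs, name = "validated") {
  if (!nrow(pairs)) return(gene_set(name = name))
  gs <- gene_set(pairs$gene_symbol, name = name)
  gs$provenance <- sprintf("%d validated gene(s) from %d counter-expressed pair(s)",
                           length(gs), nrow(pairs))
  gs
}
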