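#' Read a long-format qPCR Ct table
#'
#' Expected columns: `sample`, `group`, `gene`, `replicate`, `ct`. The token
#' `Undetermined` (any case) and empty cells are read as missing Ct; present
#' Ct values must lie in (0, 45) cycles. Gene symbols are canonicalized to
#' uppercase.
#'
#' @param path Path to a TSV file.
#' @return Tibble of Ct measurements.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    group = readr::col_character(),
    gene = readr::col_character(),
    replicate = readr::col_integer(),
    ct = readr::col_character()
  ), progress = FALSE)
  ct <- suppressWarnings(as.numeric(tab$ct))
  undet <- grepl("^\\s*undetermined\\s*$", tab$ct, ignore.case = TRUE) |
    is.na(tab$ct) | !nzchar(trimws(tab$ct))
  ct[undet] <- NA_real_
  if (any(!is.na(ct) & (ct <= 0 | ct >= 45))) {
    stop_cf("read_ct_table(): Ct values must lie in (0, 45) cycles",
            class = "counterflow_validation_error")
  }
  if (any(tab$replicate < 1L)) {
    stop_cf("read_ct_table(): replicate indices start at 1",
            class = "counterflow_validation_error")
  }
  tibble::tibble(sample = tab$sample, group = tab$group,
                 gene = canonical_symbol(tab$gene),
                 replicate = tab$replicate, ct = ct)
}

#' Collapse technical replicates to mean Ct
#'
#' Averages the present replicate Cts per (sample, gene). Wells whose
#' replicate spread (max - min of present values) exceeds `max_spread`, and
#' wells with no present value at all, are excluded and reported; wells with
#' some missing replicates are flagged but kept.
#'
#' @param ms Tibble of Ct measurements ([read_ct_table()] shape).
#' @param max_spread Maximum tolerated replicate spread in cycles. The
#'   default of 1.0 is about 2.4 standard deviations of a duplicate
#'   difference at 0.3-cycle per-well noise: it drops genuine outliers
#'   (pipetting failures, partial evaporation) without discarding ordinary
#'   technical variation.
#' @return Tibble with columns `sample`, `group`, `gene`, `ct` (mean),
#'   `n_replicates`, `flagged` (partial missingness), plus an attribute
#'   `"excluded"` holding the excluded rows with an `exclusion_reason`.
#' @export
collapse_replicates <- function(ms, max_spread = 1.0) {
  grp <- ms |>
    dplyr::group_by(.data$sample, .data$group, .data$gene) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_present = sum(!is.na(.data$ct)),
      spread = if (sum(!is.na(.data$ct)) >= 2)
        max(.data$ct, na.rm = TRUE) - min(.data$ct, na.rm = TRUE) else 0,
      ct = if (sum(!is.na(.data$ct))) mean(.data$ct, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  excluded <- grp[grp$n_present == 0L | grp$spread > max_spread, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$exclusion_reason <- ifelse(excluded$n_present == 0L,
                                        "all replicates missing",
                                        sprintf("replicate spread %.2f > %.2f",
                                                excluded$spread, max_spread))
    message(sprintf("collapse_replicates(): excluded %d well(s): %s",
                    nrow(excluded),
                    paste(excluded$sample, excluded$gene, collapse = ", ")))
  }
  kept <- grp[grp$n_present > 0L & grp$spread <= max_spread, , drop = FALSE]
  out <- tibble::tibble(sample = kept$sample, group = kept$group,
                        gene = kept$gene, ct = kept$ct,
                        n_replicates = kept$n_present,
                        flagged = kept$n_present < kept$n_total)
  attr(out, "excluded") <- excluded
  out
}

#' Per-sample delta-Ct against a reference gene
#'
#' `dCt(s, g) = Ct(s, g) - Ct(s, reference)`: expression of `g` relative to
#' the endogenous control, per sample. Samples in which the reference was
#' not measured are excluded with a warning; reference rows are dropped from
#' the output. Because each sample is normalized by its own reference,
#' adding a constant to every Ct of a sample leaves all dCt unchanged.
#'
#' @param ct Collapsed Ct tibble from [collapse_replicates()].
#' @param reference Reference (housekeeping) gene symbol, e.g., `"ACTB"`.
#' @return Tibble with columns `sample`, `group`, `gene`, `delta_ct`.
#' @export
delta_ct <- function(ct, reference) {
  reference <- canonical_symbol(reference)
  ref <- ct[ct$gene == reference, c("sample", "ct")]
  names(ref)[2] <- "ref_ct"
  if (!nrow(ref)) {
    stop_cf("delta_ct(): reference gene '", reference, "' not measured",
            class = "counterflow_validation_error")
  }
  missing_ref <- setdiff(unique(ct$sample), ref$sample)
  if (length(missing_ref)) {
    warning("delta_ct(): excluding sample(s) without reference measurement: ",
            paste(missing_ref, collapse = ", "))
  }
  out <- dplyr::inner_join(ct[ct$gene != reference, ], ref, by = "sample")
  tibble::tibble(sample = out$sample, group = out$group, gene = out$gene,
                 delta_ct = out$ct - out$ref_ct)
}

#' Group-wise delta-delta-Ct fold changes with rank-sum tests
#'
#' The comparative Ct method on independent groups:
#' `ddCt(g) = mean dCt(case) - mean dCt(control)`, relative fold change
#' `2^-ddCt`, `log2 FC = -ddCt`. A positive ddCt (case needs more cycles
#' relative to the reference) therefore reports *downregulation* in the case
#' group. Per-gene significance comes from the Mann-Whitney rank-sum test on
#' the per-sample dCt values of the two groups.
#'
#' @param dct Tibble from [delta_ct()].
#' @param case_group,control_group Group labels (e.g., `"CAD"`, `"nonCAD"`).
#' @param exact_max_n Passed to [rank_sum_test()].
#' @return Tibble with one row per gene: `gene`, `delta_delta_ct`,
#'   `fold_change`, `log2_fc`, `p_value`, `n_case`, `n_control`. Genes
#'   absent from one of the groups are skipped with a warning.
#' @export
delta_delta_ct <- function(dct, case_group, control_group, exact_max_n = 16L) {
  genes <- sort_c(unique(dct$gene))
  rows <- lapply(genes, function(g) {
    x <- dct$delta_ct[dct$gene == g & dct$group == case_group]
    y <- dct$delta_ct[dct$gene == g & dct$group == control_group]
    if (!length(x) || !length(y)) {
      warning("delta_delta_ct(): gene ", g, " absent from one group; skipped")
      return(NULL)
    }
    ddct <- mean(x) - mean(y)
    ts <- rank_sum_test(x, y, exact_max_n = exact_max_n)
    tibble::tibble(gene = g, delta_delta_ct = ddct,
                   fold_change = 2^(-ddct), log2_fc = -ddct,
                   p_value = ts$p_value, n_case = length(x),
                   n_control = length(y))
  })
  dplyr::bind_rows(rows)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided test of location shift between two independent samples, with
#' midranks for ties. When the pooled size is at most `exact_max_n` and
#' there are no ties, the exact null distribution of U is used (two-sided p
#' = doubled smaller tail, capped at 1); otherwise the normal approximation
#' with tie correction and continuity correction. If every value across both
#' groups is identical the test is degenerate and p = 1 is returned, flagged.
#' Computation delegates to [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param exact_max_n Largest pooled sample size for the exact path
#'   (default 16).
#' @return List of class `rank_sum_test` with `statistic` (U for `x`, i.e.,
#'   the count of (x, y) pairs with x > y plus half-ties), `p_value`,
#'   `method` (`"exact"`, `"normal-approximation"` or `"degenerate"`),
#'   `tie_corrected`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y, exact_max_n = 16L) {
  if (!length(x) || !length(y)) stop_cf("rank_sum_test(): both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(statistic = u, p_value = 1, method = "degenerate",
                          tie_corrected = FALSE, n_x = nx, n_y = ny),
                     class = "rank_sum_test"))
  }
  use_exact <- !has_ties && (nx + ny) <= exact_max_n
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  structure(
    list(statistic = unname(res$statistic), p_value = min(res$p.value, 1),
         method = if (use_exact) "exact" else "normal-approximation",
         tie_corrected = has_ties, n_x = nx, n_y = ny),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum: U = %g, p = %.4g (%s%s), n = %d vs %d\n",
              x$statistic, x$p_value, x$method,
              if (x$tie_corrected) ", tie-corrected" else "",
              x$n_x, x$n_y))
  invisible(x)
}

#' Volcano table of fold changes vs significance
#'
#' @param rows Tibble from [delta_delta_ct()].
#' @param alpha Significance level; `significant` is `p_value < alpha`
#'   (strict, so p exactly equal to alpha is not significant).
#' @return Tibble with `gene`, `log2_fc`, `neg_log10_p`, `significant`,
#'   `direction` (`"up"` iff `log2_fc > 0`, else `"down"`; a fold change of
#'   exactly 1 is reported as `"down"` by this tie-break).
#' @export
volcano_table <- function(rows, alpha = 0.05) {
  tibble::tibble(
    gene = rows$gene,
    log2_fc = rows$log2_fc,
    neg_log10_p = -log10(rows$p_value),
    significant = rows$p_value < alpha,
    direction = ifelse(rows$log2_fc > 0, "up", "down")
  )
}
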