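#' Packaged atherosclerosis-progression (ATHp) reference data
#'
#' The package ships the published core of an integrated miRNA/mRNA
#' counter-expression study of atherosclerosis progression in the
#' ApoE-deficient mouse: the 14 validated oxidative-stress ("Oxstress")
#' transcripts with their absolute fold changes and p-values in the
#' progression contrast (scrambled-siRNA week 24 vs. baseline week 8,
#' `SC24W_vs_B8W`), the 13 miRNAs upregulated in the same contrast, and the
#' 68 predicted (miRNA, gene) targeting relationships linking them.
#'
#' Curation notes: one printed p-value (`Atp2a2`, "0011") is stored as
#' 0.011, and one miRNA id printed once without its species prefix
#' (`miR-27a-3p`, in the Mapk9 row of the published pair table) is stored as
#' `mmu-miR-27a-3p` — the published diagram counts 13 distinct miRNAs, which
#' requires the prefix.
#'
#' @return `athp_mrna_de()`: DE tibble of the 14 validated transcripts
#'   (direction `"down"`). `athp_other_de()`: the remaining published DE
#'   rows (the upregulated `Pnkd` transcript and the treatment-contrast
#'   rows). `athp_mirna_de()`: DE tibble of the 13 upregulated miRNAs (the
#'   study publishes their identities and direction; magnitudes are `NA`).
#'   `athp_target_map()`: the 68-pair `TargetMap` (14 genes, 13 miRNAs).
#' @name athp_fixtures
NULL

athp_extdata <- function(file) {
  system.file("extdata", file, package = "counterflow", mustWork = TRUE)
}

#' @rdname athp_fixtures
#' @export
athp_mrna_de <- function() {
  read_de_table(athp_extdata("athp_mrna_de.tsv"))
}

#' @rdname athp_fixtures
#' @export
athp_other_de <- function() {
  read_de_table(athp_extdata("athp_other_de.tsv"))
}

#' @rdname athp_fixtures
#' @export
athp_mirna_de <- function() {
  map <- athp_target_map()
  tibble::tibble(feature_id = map$mirnas,
                 fold_change_abs = NA_real_,
                 direction = "up",
                 p_value = NA_real_,
                 contrast = "SC24W_vs_B8W")
}

#' @rdname athp_fixtures
#' @export
athp_target_map <- function() {
  tab <- readr::read_tsv(athp_extdata("athp_pairs.tsv"), col_types = "cc",
                         progress = FALSE)
  pairs <- tibble::tibble(mirna_id = tab$mirna,
                          gene_symbol = canonical_symbol(tab$gene),
                          evidence = 1L)
  pairs <- pairs[order(pairs$mirna_id, pairs$gene_symbol, method = "radix"), ]
  new_target_map(pairs)
}

#' Write the packaged reference data as pipeline-ready files
#'
#' Copies the packaged ATHp tables into `outdir` in the dialects the
#' pipeline reads: the validated-transcript DE TSV, the additional DE rows,
#' the miRNA DE TSV, and the (miRNA, gene) pair TSV.
#'
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_athp_fixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mrna_de = file.path(outdir, "athp_mrna_de.tsv"),
    other_de = file.path(outdir, "athp_other_de.tsv"),
    mirna_de = file.path(outdir, "athp_mirna_de.tsv"),
    pairs = file.path(outdir, "athp_pairs.tsv")
  )
  file.copy(athp_extdata("athp_mrna_de.tsv"), paths[["mrna_de"]], overwrite = TRUE)
  file.copy(athp_extdata("athp_other_de.tsv"), paths[["other_de"]], overwrite = TRUE)
  readr::write_tsv(athp_mirna_de(), paths[["mirna_de"]], progress = FALSE)
  file.copy(athp_extdata("athp_pairs.tsv"), paths[["pairs"]], overwrite = TRUE)
  invisible(paths)
}
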