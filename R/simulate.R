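# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth, so the whole analysis is testable without any download.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic bundle. The defaults encode the study
#' conditions the pipeline was built around: 13 upregulated miRNAs, a
#' 10-case vs 12-control qPCR contrast, a planted 2-cycle Ct shift with
#' 0.3-cycle measurement noise, and a desk-scale counter-expression funnel
#' of 100 oxidative-stress genes, 40 of them predicted targets, 10 of those
#' downregulated (hence validated).
#'
#' @param seed Integer; drives every random draw of the bundle.
#' @param n_genes Size of the gene universe.
#' @param n_mirnas Number of (upregulated) miRNAs.
#' @param n_oxstress Number of oxidative-stress genes (annotated to the
#'   synthetic oxstress terms).
#' @param n_targeted Number of oxstress genes carrying at least one planted
#'   (miRNA, gene) pair.
#' @param n_validated Number of targeted oxstress genes planted as
#'   downregulated (the counter-expressed ground truth).
#' @param planted_pairs Total number of true (miRNA, gene) pairs over the
#'   targeted genes (each targeted gene gets at least one).
#' @param n_offtarget Number of non-oxstress genes given predicted pairs, so
#'   the unique-target list is larger than its oxstress intersection.
#' @param decoy_same_direction Number of targeted-but-not-validated oxstress
#'   genes written to the mRNA DE table as *up*regulated — decoys that the
#'   counter-expression rule must exclude (miRNAs are up).
#' @param n_extra_down Downregulated DE genes that are not predicted targets.
#' @param n_sources Number of prediction algorithms emulated.
#' @param source_sensitivity Probability that a given source reports a true
#'   pair.
#' @param source_fpr Probability that a given source reports any given false
#'   pair.
#' @param ct_effect_cycles Planted case-group Ct shift (cycles) for the
#'   planted qPCR genes; positive = downregulated in cases.
#' @param ct_noise_sd Gaussian measurement noise per Ct well (cycles).
#' @param n_case,n_control qPCR group sizes.
#' @param taxon Taxon id stamped into the synthetic GAF.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 300L,
                              n_mirnas = 13L,
                              n_oxstress = 100L,
                              n_targeted = 40L,
                              n_validated = 10L,
                              planted_pairs = 60L,
                              n_offtarget = 60L,
                              decoy_same_direction = 10L,
                              n_extra_down = 30L,
                              n_sources = 5L,
                              source_sensitivity = 1,
                              source_fpr = 0,
                              ct_effect_cycles = 2,
                              ct_noise_sd = 0.3,
                              n_case = 10L,
                              n_control = 12L,
                              taxon = 10090L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_oxstress = as.integer(n_oxstress),
              n_targeted = as.integer(n_targeted),
              n_validated = as.integer(n_validated),
              planted_pairs = as.integer(planted_pairs),
              n_offtarget = as.integer(n_offtarget),
              decoy_same_direction = as.integer(decoy_same_direction),
              n_extra_down = as.integer(n_extra_down),
              n_sources = as.integer(n_sources),
              source_sensitivity = source_sensitivity,
              source_fpr = source_fpr,
              ct_effect_cycles = ct_effect_cycles,
              ct_noise_sd = ct_noise_sd,
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              taxon = as.integer(taxon))
  with(cfg, {
    if (source_sensitivity < 0 || source_sensitivity > 1 ||
        source_fpr < 0 || source_fpr > 1) {
      stop_cf("simulation_config(): probabilities must lie in [0, 1]",
              class = "counterflow_validation_error")
    }
    if (n_validated > n_targeted || n_targeted > n_oxstress ||
        n_oxstress + n_offtarget > n_genes ||
        planted_pairs < n_targeted ||
        planted_pairs > n_targeted * n_mirnas ||
        decoy_same_direction > n_targeted - n_validated ||
        any(c(n_genes, n_mirnas, n_sources, n_case, n_control) < 1L) ||
        ct_noise_sd < 0) {
      stop_cf("simulation_config(): inconsistent configuration",
              class = "counterflow_validation_error")
    }
  })
  structure(cfg, class = "simulation_config")
}

synthetic_terms <- function() {
  tibble::tibble(
    id = c("GO:0006979", "GO:1902882", "GO:1902883", "GO:1902884",
           "GO:0008150"),
    name = c("response to oxidative stress",
             "regulation of response to oxidative stress",
             "negative regulation of response to oxidative stress",
             "positive regulation of response to oxidative stress",
             "biological_process"),
    parent = c("GO:0008150", "GO:0006979", "GO:1902882", "GO:1902882", NA)
  )
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Writes every file the pipeline reads — OBO ontology, GAF annotations,
#' per-source prediction tables with a manifest, miRNA and mRNA DE tables,
#' and a long-format qPCR Ct table — into `outdir`, and returns the planted
#' ground truth (oxstress set, true pairs, validated pairs, expected funnel
#' counts). With `source_sensitivity = 1` and `source_fpr = 0` the pipeline
#' recovers the ground truth exactly; re-running with the same config yields
#' byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return List with `paths` (named character vector of written files),
#'   `config`, and `ground_truth` (list: `oxstress_genes` (`GeneSet`),
#'   `true_pairs`, `validated_pairs` (tibbles), `downregulated_genes`,
#'   `ct_planted_genes`, and `expected_funnel` — the stage counts a
#'   noiseless run must report).
#' @export
generate_bundle <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    genes <- sprintf("Gene%04d", seq_len(config$n_genes))
    mirnas <- sprintf("mmu-miR-%d-5p", 100L + seq_len(config$n_mirnas))
    oxstress <- genes[seq_len(config$n_oxstress)]
    targeted <- oxstress[seq_len(config$n_targeted)]
    validated <- targeted[seq_len(config$n_validated)]
    decoys <- if (config$decoy_same_direction)
      targeted[config$n_validated + seq_len(config$decoy_same_direction)]
      else character()
    offtarget <- genes[config$n_oxstress + seq_len(config$n_offtarget)]
    background <- setdiff(genes, oxstress)

    # --- ontology + annotations -------------------------------------------
    terms <- synthetic_terms()
    obo_path <- file.path(outdir, "ontology.obo")
    write_obo(terms, obo_path)
    ox_terms <- terms$id[1:4]
    # every oxstress gene annotated to >= 1 oxstress term; extra multi-term
    # annotations create the overlap a curated ontology shows
    primary <- sample(ox_terms, config$n_oxstress, replace = TRUE,
                      prob = c(0.7, 0.15, 0.1, 0.05))
    ann <- tibble::tibble(gene_symbol = oxstress, term_id = primary)
    extra_idx <- which(stats::runif(config$n_oxstress) < 0.2)
    if (length(extra_idx)) {
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        gene_symbol = oxstress[extra_idx],
        term_id = sample(ox_terms, length(extra_idx), replace = TRUE)))
      ann <- dplyr::distinct(ann)
    }
    ann <- dplyr::bind_rows(ann, tibble::tibble(gene_symbol = background,
                                                term_id = "GO:0008150"))
    ann$taxon <- as.character(config$taxon)
    gaf_path <- file.path(outdir, "annotations.gaf")
    write_gaf(ann, gaf_path)

    # --- true pairs + prediction tables -----------------------------------
    base_pairs <- tibble::tibble(
      mirna_id = sample(mirnas, config$n_targeted, replace = TRUE),
      gene_symbol = targeted)
    extra_n <- config$planted_pairs - config$n_targeted
    all_combo <- tidyr::expand_grid(mirna_id = mirnas, gene_symbol = targeted)
    pool <- dplyr::anti_join(all_combo, base_pairs,
                             by = c("mirna_id", "gene_symbol"))
    extra_pairs <- pool[sample.int(nrow(pool), extra_n), ]
    off_pairs <- tibble::tibble(
      mirna_id = sample(mirnas, config$n_offtarget, replace = TRUE),
      gene_symbol = offtarget)
    true_pairs <- dplyr::bind_rows(base_pairs, extra_pairs, off_pairs)
    true_pairs <- true_pairs[order(true_pairs$mirna_id, true_pairs$gene_symbol,
                                   method = "radix"), ]

    sources <- sprintf("algo%d", seq_len(config$n_sources))
    false_pool <- dplyr::anti_join(
      tidyr::expand_grid(mirna_id = mirnas, gene_symbol = genes),
      true_pairs, by = c("mirna_id", "gene_symbol"))
    pred_paths <- character()
    for (s in sources) {
      keep_true <- stats::runif(nrow(true_pairs)) < config$source_sensitivity
      keep_false <- stats::runif(nrow(false_pool)) < config$source_fpr
      tab <- dplyr::bind_rows(true_pairs[keep_true, ],
                              false_pool[keep_false, ])
      out <- tibble::tibble(mirna = tab$mirna_id, gene = tab$gene_symbol)
      p <- file.path(outdir, paste0("predictions_", s, ".tsv"))
      readr::write_tsv(out, p, progress = FALSE)
      pred_paths[s] <- p
    }
    manifest_path <- file.path(outdir, "predictions_manifest.tsv")
    readr::write_tsv(tibble::tibble(source = sources,
                                    path = basename(pred_paths)),
                     manifest_path, progress = FALSE)

    # --- DE tables ---------------------------------------------------------
    mirna_de <- tibble::tibble(
      feature_id = mirnas,
      fold_change_abs = round(stats::runif(config$n_mirnas, 1.5, 20), 2),
      direction = "up",
      p_value = round(stats::runif(config$n_mirnas, 0.001, 0.04), 4))
    mirna_de_path <- file.path(outdir, "mirna_de.tsv")
    write_de_table(mirna_de, mirna_de_path)

    extra_down <- setdiff(genes, c(targeted, offtarget))
    extra_down <- sample(extra_down, config$n_extra_down)
    down_genes <- c(validated, extra_down)
    mrna_de <- tibble::tibble(
      feature_id = c(down_genes, decoys),
      fold_change_abs = round(stats::runif(length(down_genes) + length(decoys),
                                           1.5, 35), 2),
      direction = c(rep("down", length(down_genes)),
                    rep("up", length(decoys))),
      p_value = round(stats::runif(length(down_genes) + length(decoys),
                                   0.001, 0.04), 4))
    mrna_de_path <- file.path(outdir, "mrna_de.tsv")
    write_de_table(mrna_de, mrna_de_path)

    # --- qPCR Ct table -----------------------------------------------------
    ct <- simulate_ct_table(
      seed = config$seed + 1L, effect_cycles = config$ct_effect_cycles,
      noise_sd = config$ct_noise_sd, n_case = config$n_case,
      n_control = config$n_control)
    ct_path <- file.path(outdir, "ct.tsv")
    readr::write_tsv(dplyr::mutate(ct$table, ct = ifelse(is.na(.data$ct),
                                                         "Undetermined",
                                                         format(.data$ct))),
                     ct_path, progress = FALSE)

    truth <- list(
      oxstress_genes = gene_set(oxstress, name = "oxstress_truth"),
      true_pairs = true_pairs,
      validated_pairs = true_pairs[true_pairs$gene_symbol %in% validated, ],
      downregulated_genes = canonical_symbol(down_genes),
      ct_planted_genes = ct$planted_genes,
      expected_funnel = c(
        oxstress = config$n_oxstress,
        unique_targets = config$n_targeted + config$n_offtarget,
        oxstress_targeted = config$n_targeted,
        validated = config$n_validated)
    )
    list(
      paths = c(obo = obo_path, gaf = gaf_path, manifest = manifest_path,
                mirna_de = mirna_de_path, mrna_de = mrna_de_path,
                ct = ct_path, pred_paths),
      config = config,
      ground_truth = truth
    )
  })
}

#' Simulate a long-format qPCR Ct table with planted group shifts
#'
#' Emulates a TLDA-style duplicate-well experiment: a flat reference gene
#' (`ACTB`), null panel genes identical across groups, and planted genes
#' whose Ct is shifted by `effect_cycles` in the case group (a positive
#' shift = fewer transcripts = downregulation in cases). Every well gets a
#' sample-specific offset (shared by all genes of the sample, removed by
#' delta-Ct normalization) plus Gaussian noise.
#'
#' @param seed Integer seed.
#' @param planted_genes Genes carrying the shift (default CCR7, FOXO1).
#' @param null_genes Unshifted panel genes.
#' @param reference Reference gene symbol.
#' @param effect_cycles,noise_sd Shift and per-well noise, in cycles.
#' @param n_case,n_control Group sizes (groups `"CAD"` / `"nonCAD"`).
#' @param n_replicates Technical replicates per well (default 2).
#' @return List with `table` (tibble: sample, group, gene, replicate, ct),
#'   `planted_genes`, and `true_ddct` (named vector of planted
#'   delta-delta-Ct values, case minus control).
#' @export
simulate_ct_table <- function(seed = 1L,
                              planted_genes = c("CCR7", "FOXO1"),
                              null_genes = c("FOS", "MAP2K1", "MAPK1",
                                             "MAPK9", "EGFR", "GATA4",
                                             "RNF7"),
                              reference = "ACTB",
                              effect_cycles = 2, noise_sd = 0.3,
                              n_case = 10L, n_control = 12L,
                              n_replicates = 2L) {
  with_seed(seed, {
    samples <- tibble::tibble(
      sample = c(sprintf("CAD%02d", seq_len(n_case)),
                 sprintf("CTL%02d", seq_len(n_control))),
      group = c(rep("CAD", n_case), rep("nonCAD", n_control)),
      offset = stats::rnorm(n_case + n_control, 0, 1))
    genes <- c(reference, planted_genes, null_genes)
    base <- stats::setNames(c(18, stats::runif(length(genes) - 1L, 22, 28)),
                            genes)
    grid <- tidyr::expand_grid(samples, gene = genes,
                               replicate = seq_len(n_replicates))
    effect <- ifelse(grid$gene %in% planted_genes & grid$group == "CAD",
                     effect_cycles, 0)
    grid$ct <- base[grid$gene] + grid$offset + effect +
      stats::rnorm(nrow(grid), 0, noise_sd)
    grid$ct <- round(grid$ct, 4)
    list(
      table = grid[, c("sample", "group", "gene", "replicate", "ct")],
      planted_genes = planted_genes,
      true_ddct = stats::setNames(rep(effect_cycles, length(planted_genes)),
                                  planted_genes)
    )
  })
}

#' Simulate a planted two-block bipartite network
#'
#' Two dense miRNA-gene blocks with sparse inter-block edges: the planted
#' two-community structure used to exercise [detect_communities()]. Every
#' node is guaranteed at least one within-block edge so that all planted
#' nodes appear in the network.
#'
#' The default within-block density of 0.85 is chosen for identifiability:
#' at these block sizes, sparser blocks (e.g., 0.6) frequently produce
#' realizations whose Barber-modularity optimum is *not* the planted
#' bipartition, so exact recovery would be ill-posed regardless of the
#' optimizer. At 0.85 the planted partition is the optimum in essentially
#' every realization.
#'
#' @param seed Integer seed.
#' @param genes_per_block,mirnas_per_block Block side sizes.
#' @param p_within Within-block edge probability (default 0.85).
#' @param p_between Inter-block edge probability (default 0.05).
#' @return List with `network` (a `BipartiteNetwork`) and `block_of` (named
#'   integer vector: node -> planted block, 1 or 2).
#' @export
simulate_two_block_network <- function(seed = 1L, genes_per_block = 8L,
                                       mirnas_per_block = 7L,
                                       p_within = 0.85, p_between = 0.05) {
  with_seed(seed, {
    gene_block <- rep(1:2, each = genes_per_block)
    mir_block <- rep(1:2, each = mirnas_per_block)
    genes <- sprintf("GB%d_G%02d", gene_block, seq_along(gene_block))
    mirnas <- sprintf("mmu-miR-b%d-%02d", mir_block, seq_along(mir_block))
    grid <- tidyr::expand_grid(gi = seq_along(genes), mi = seq_along(mirnas))
    same <- gene_block[grid$gi] == mir_block[grid$mi]
    keep <- stats::runif(nrow(grid)) < ifelse(same, p_within, p_between)
    # guarantee every node one within-block edge
    for (gi in seq_along(genes)) {
      inb <- which(grid$gi == gi & same)
      if (!any(keep[inb])) keep[inb[sample.int(length(inb), 1L)]] <- TRUE
    }
    for (mi in seq_along(mirnas)) {
      inb <- which(grid$mi == mi & same)
      if (!any(keep[inb])) keep[inb[sample.int(length(inb), 1L)]] <- TRUE
    }
    edges <- tibble::tibble(mirna_id = mirnas[grid$mi[keep]],
                            gene_symbol = genes[grid$gi[keep]])
    net <- build_bipartite(edges)
    block_of <- stats::setNames(c(gene_block, mir_block),
                                canonical_symbol(c(genes, mirnas)))
    # gene nodes were canonicalized to uppercase by build_bipartite;
    # miRNA ids keep their case
    names(block_of) <- c(canonical_symbol(genes), mirnas)
    list(network = net, block_of = block_of)
  })
}
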