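# Workflow orchestration: configuration, staged execution, provenance.

config_defaults <- function() {
  list(
    obo = NULL, gaf = NULL, predictions_manifest = NULL,
    mirna_de = NULL, mrna_de = NULL, ct = NULL,
    outdir = NULL,
    terms = c("GO:0006979", "GO:1902882", "GO:1902883", "GO:1902884"),
    descend = FALSE, taxon = NULL, exclude_evidence = character(),
    min_sources = 1L, p_max = NULL,
    min_k = 2L, top = 20L, alpha = 0.05,
    reference = "ACTB", case_group = "CAD", control_group = "nonCAD",
    seed = 0L
  )
}

required_config_keys <- c("obo", "gaf", "predictions_manifest",
                          "mirna_de", "mrna_de", "outdir")

#' Load and validate a pipeline configuration
#'
#' Reads a configuration file — YAML (`.yml`/`.yaml`) or flat `key = value`
#' lines — applies defaults (`min_sources = 1`, `alpha = 0.05`, `top = 20`,
#' the four oxidative-stress GO terms, ...), rejects unknown keys by name,
#' and checks that the required input paths are present. Relative paths are
#' resolved against the config file's directory. `as_config()` performs the
#' same validation on an in-memory list.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of values overriding the file.
#' @return A validated list of class `counterflow_config`, with a
#'   `config_hash` attribute.
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_cf("load_config(): no such file: ", path,
                                  class = "counterflow_config_error")
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- lengths(kv) != 2L
    if (any(bad)) stop_cf("load_config(): malformed line: ", lines[bad][1],
                          class = "counterflow_config_error")
    stats::setNames(lapply(kv, function(x) {
      v <- x[2]
      if (grepl(",", v)) trimws(strsplit(v, ",")[[1]])
      else if (!is.na(suppressWarnings(as.numeric(v)))) as.numeric(v)
      else if (v %in% c("true", "false")) v == "true"
      else v
    }), vapply(kv, `[`, character(1), 1L))
  }
  raw[names(overrides)] <- overrides
  base <- dirname(path)
  for (k in intersect(names(raw), c(required_config_keys[-6], "ct"))) {
    if (is.character(raw[[k]]) && !file.exists(raw[[k]]) &&
        file.exists(file.path(base, raw[[k]]))) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  if (!is.null(raw$outdir) && !grepl("^(/|[A-Za-z]:)", raw$outdir)) {
    raw$outdir <- file.path(base, raw$outdir)
  }
  as_config(raw)
}

#' @rdname load_config
#' @param x Named list of configuration values.
#' @export
as_config <- function(x) {
  defaults <- config_defaults()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    stop_cf("configuration: unknown key(s): ", paste(unknown, collapse = ", "),
            class = "counterflow_config_error")
  }
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  missing_keys <- required_config_keys[vapply(cfg[required_config_keys],
                                              is.null, logical(1))]
  if (length(missing_keys)) {
    stop_cf("configuration: missing required key(s): ",
            paste(missing_keys, collapse = ", "),
            class = "counterflow_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_sources <- as.integer(cfg$min_sources)
  canonical <- cfg[order(names(cfg), method = "radix")]
  structure(cfg, class = "counterflow_config",
            config_hash = object_digest(canonical))
}

#' Run the full counter-expression pipeline
#'
#' Executes the staged workflow: (1) reverse-GO gene-set compilation from
#' the ontology and annotations, (2) consensus miRNA-target aggregation,
#' (3) intersection of the oxstress set with the unique predicted targets,
#' (4) counter-expression validation against the DE tables, (5) GO
#' enrichment of the validated set, (6) bipartite network construction with
#' community detection, and — when a Ct table is configured — (7) qPCR
#' delta-delta-Ct analysis. Every intermediate is written to
#' `config$outdir` as TSV; one log line per stage reports its item count (the
#' funnel); a machine-readable manifest is written even when a stage fails.
#'
#' @param config A `counterflow_config` from [load_config()]/[as_config()],
#'   or a named list coerced by [as_config()].
#' @return An object of class `PipelineReport`: list with `stage_counts`
#'   (tibble `stage`, `count`, in funnel order), `outputs` (paths),
#'   `results` (the in-memory stage objects) and `manifest_path`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "counterflow_config")) config <- as_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$stages <- list()
  state$outputs <- character()
  state$results <- list()
  state$config <- config
  state$inputs <- unlist(config[required_config_keys[-6]])
  if (!is.null(config$ct)) state$inputs <- c(state$inputs, ct = config$ct)
  state$failure <- NULL

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      state$failure <- list(stage = name, message = conditionMessage(e))
      write_manifest(state, file.path(config$outdir, "manifest.json"))
      stop_cf("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "counterflow_stage_error")
    })
    res
  }
  log_stage <- function(name, count) {
    state$stages[[length(state$stages) + 1L]] <-
      list(stage = name, count = as.integer(count))
    message(sprintf("[%s] %d item(s)", name, count))
  }
  emit <- function(key, path) {
    state$outputs[key] <- path
    path
  }

  # 1 -- reverse-GO gene set
  oxstress <- run_stage("oxstress", function() {
    ontology <- parse_obo(config$obo)
    ann <- parse_gaf(config$gaf, taxon_filter = config$taxon,
                     exclude_evidence = config$exclude_evidence)
    terms <- config$terms
    if (isTRUE(config$descend)) {
      terms <- descendant_terms(ontology, terms)
    }
    gs <- compile_gene_set(ann, terms, name = "oxstress", ontology = ontology)
    state$results$ontology <- ontology
    state$results$annotations <- ann
    write_gene_set(gs, emit("oxstress", file.path(config$outdir, "oxstress_genes.tsv")))
    gs
  })
  log_stage("oxstress", length(oxstress))
  state$results$oxstress <- oxstress

  # 2 -- consensus targets
  map <- run_stage("targets", function() {
    mirna_de <- read_de_table(config$mirna_de)
    state$results$mirna_de <- mirna_de
    if (!nrow(mirna_de)) {
      return(new_target_map(tibble::tibble(mirna_id = character(),
                                           gene_symbol = character(),
                                           evidence = integer())))
    }
    records <- read_prediction_manifest(config$predictions_manifest)
    m <- consensus_targets(records, mirnas = mirna_de$feature_id,
                           min_sources = config$min_sources)
    write_target_map(m, emit("target_map", file.path(config$outdir, "target_map.tsv")))
    m
  })
  targets <- unique_target_set(map)
  log_stage("unique_targets", length(targets))
  state$results$target_map <- map
  state$results$unique_targets <- targets

  # 3 -- oxstress genes among predicted targets
  targeted <- run_stage("oxstress_targeted", function() {
    gs <- intersect_gene_sets(oxstress, targets, name = "oxstress_targeted")
    write_gene_set(gs, emit("oxstress_targeted",
                            file.path(config$outdir, "oxstress_targeted.tsv")))
    gs
  })
  log_stage("oxstress_targeted", length(targeted))
  state$results$oxstress_targeted <- targeted

  # 4 -- counter-expression validation
  pairs <- run_stage("validated", function() {
    mrna_de <- read_de_table(config$mrna_de)
    state$results$mrna_de <- mrna_de
    p <- counter_expressed_pairs(map, state$results$mirna_de, mrna_de,
                                 restrict_to = oxstress, p_max = config$p_max)
    readr::write_tsv(p, emit("validated_pairs",
                             file.path(config$outdir, "validated_pairs.tsv")),
                     progress = FALSE)
    p
  })
  validated <- validated_gene_set(pairs)
  write_gene_set(validated, emit("validated_genes",
                                 file.path(config$outdir, "validated_genes.tsv")))
  log_stage("validated", length(validated))
  state$results$validated_pairs <- pairs
  state$results$validated <- validated

  # 5 -- enrichment of the validated set
  enr <- run_stage("enrichment", function() {
    if (!length(validated)) return(empty_enrichment())
    e <- enrich(validated, state$results$annotations, min_k = config$min_k,
                top = config$top, ontology = state$results$ontology)
    write_enrichment(e, emit("enrichment",
                             file.path(config$outdir, "enrichment.tsv")))
    e
  })
  log_stage("enrichment_terms", nrow(enr))
  state$results$enrichment <- enr

  # 6 -- bipartite network
  net <- run_stage("network", function() {
    n <- build_bipartite(pairs)
    part <- if (nrow(n$edges)) detect_communities(n, seed = config$seed) else NULL
    paths <- write_network(n, file.path(config$outdir, "network"),
                           partition = part)
    for (p in paths) emit(basename(p), p)
    state$results$partition <- part
    n
  })
  log_stage("network_edges", nrow(net$edges))
  state$results$network <- net

  # 7 -- optional qPCR analysis
  if (!is.null(config$ct)) {
    fc <- run_stage("qpcr", function() {
      ct <- read_ct_table(config$ct)
      collapsed <- collapse_replicates(ct)
      dct <- delta_ct(collapsed, config$reference)
      readr::write_tsv(dct, emit("delta_ct",
                                 file.path(config$outdir, "delta_ct.tsv")),
                       progress = FALSE)
      rows <- delta_delta_ct(dct, config$case_group, config$control_group)
      readr::write_tsv(volcano_table(rows, alpha = config$alpha),
                       emit("volcano", file.path(config$outdir, "volcano.tsv")),
                       progress = FALSE)
      rows
    })
    log_stage("qpcr_genes", nrow(fc))
    state$results$fold_changes <- fc
  }

  manifest_path <- write_manifest(state, file.path(config$outdir, "manifest.json"))
  stage_counts <- tibble::tibble(
    stage = vapply(state$stages, `[[`, character(1), "stage"),
    count = vapply(state$stages, `[[`, integer(1), "count"))
  structure(
    list(stage_counts = stage_counts, outputs = state$outputs,
         results = as.list(state$results), manifest_path = manifest_path),
    class = "PipelineReport"
  )
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("<PipelineReport>\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-18s %d\n", x$stage_counts$stage[i], x$stage_counts$count[i]))
  }
  invisible(x)
}

#' Write a machine-readable run manifest
#'
#' Records tool version, the configuration (with its hash and seed), md5
#' digests of every consumed input file, the ordered stage log, and — for a
#' failed run — the failing stage and message. Together with the config the
#' manifest suffices to re-run the pipeline bit-identically.
#'
#' @param state Internal pipeline state (or a list with elements `config`,
#'   `inputs`, `stages`, `outputs`, `failure`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(state, path) {
  cfg <- state$config
  digests <- vapply(state$inputs, function(p)
    if (file.exists(p)) file_digest(p) else NA_character_, character(1))
  manifest <- list(
    tool = "counterflow",
    version = as.character(utils::packageVersion("counterflow")),
    config = cfg[order(names(cfg), method = "radix")],
    config_hash = attr(cfg, "config_hash"),
    seed = cfg$seed,
    input_digests = as.list(digests),
    stage_log = state$stages,
    outputs = as.list(state$outputs),
    failure = state$failure
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
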