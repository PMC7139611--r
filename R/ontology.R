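#' Parse an OBO ontology file
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 file into a lightweight
#' ontology graph: term ids, labels, directed child-to-parent edges tagged
#' with their relation kind (`is_a` or `part_of`), and the set of obsolete
#' terms. Obsolete terms are flagged and carry no edges. Other stanza types
#' (`[Typedef]`, `[Instance]`) are ignored.
#'
#' @param path Path to an OBO file.
#' @return An object of class `OntologyGraph`: list with `terms` (character),
#'   `name_of` (named character, term id -> label), `edges` (tibble with
#'   columns `child`, `parent`, `relation`) and `obsolete` (character).
#' @details The graph restricted to `is_a` edges must be acyclic; a cycle
#'   raises a validation error. A `[Term]` stanza without an `id:` line is a
#'   parse error reporting the offending line number.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character()
  name_of <- character()
  obsolete <- character()
  edges <- list()
  in_term <- FALSE
  cur_id <- NA_character_
  stanza_line <- 0L

  flush_check <- function() {
    if (in_term && is.na(cur_id)) {
      stop_cf("parse_obo(): [Term] stanza starting at line ", stanza_line,
              " has no id:", class = "counterflow_parse_error")
    }
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (startsWith(ln, "[")) {
      flush_check()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_
      stanza_line <- i
      next
    }
    if (!in_term) next
    if (startsWith(ln, "id:")) {
      cur_id <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur_id)
    } else if (startsWith(ln, "name:")) {
      if (is.na(cur_id)) {
        stop_cf("parse_obo(): name: before id: at line ", i,
                class = "counterflow_parse_error")
      }
      name_of[cur_id] <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_obsolete:")) {
      if (grepl("true", ln, fixed = TRUE)) obsolete <- c(obsolete, cur_id)
    } else if (startsWith(ln, "is_a:")) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- c(cur_id, parent, "is_a")
    } else if (startsWith(ln, "relationship:")) {
      body <- trimws(sub("!.*$", "", sub("^relationship:", "", ln)))
      parts <- strsplit(body, "[[:space:]]+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% c("part_of")) {
        edges[[length(edges) + 1L]] <- c(cur_id, parts[2], parts[1])
      }
    }
  }
  flush_check()

  edges <- if (length(edges)) {
    m <- do.call(rbind, edges)
    tibble::tibble(child = m[, 1], parent = m[, 2], relation = m[, 3])
  } else {
    tibble::tibble(child = character(), parent = character(),
                   relation = character())
  }
  # obsolete terms are not linked
  edges <- edges[!(edges$child %in% obsolete), , drop = FALSE]
  terms <- unique(terms)
  # edge endpoints must be known terms; parents referenced but never defined
  # are added as bare terms (common in term-subset extracts)
  extra <- setdiff(edges$parent, terms)
  terms <- c(terms, extra)

  graph <- structure(
    list(terms = terms, name_of = name_of, edges = edges,
         obsolete = unique(obsolete)),
    class = "OntologyGraph"
  )
  assert_isa_acyclic(graph)
  graph
}

# Kahn topological check on the is_a subgraph.
assert_isa_acyclic <- function(graph) {
  e <- graph$edges[graph$edges$relation == "is_a", , drop = FALSE]
  if (!nrow(e)) return(invisible(TRUE))
  nodes <- unique(c(e$child, e$parent))
  indeg <- table(factor(e$parent, levels = nodes))
  queue <- nodes[indeg == 0]
  removed <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  adj <- split(e$parent, e$child)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; removed <- removed + 1L
    for (p in adj[[v]] %||% character()) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (removed < length(nodes)) {
    stop_cf("parse_obo(): cycle detected in is_a edges",
            class = "counterflow_validation_error")
  }
  invisible(TRUE)
}

#' @export
print.OntologyGraph <- function(x, ...) {
  cat(sprintf("<OntologyGraph: %d terms, %d edges, %d obsolete>\n",
              length(x$terms), nrow(x$edges), length(x$obsolete)))
  invisible(x)
}

#' Descendant terms of a set of roots
#'
#' Returns the roots together with every term from which a root is reachable
#' by following child-to-parent edges of the selected relation kinds — i.e.,
#' the ontology descendants. Obsolete terms are excluded from the result.
#'
#' @param ontology An `OntologyGraph` from [parse_obo()].
#' @param roots Character vector of term ids; all must exist in the ontology.
#' @param relations Relation kinds to traverse; default `"is_a"` only.
#' @return Character vector of term ids (roots plus descendants), sorted.
#' @export
descendant_terms <- function(ontology, roots, relations = "is_a") {
  stopifnot(inherits(ontology, "OntologyGraph"))
  missing_roots <- setdiff(roots, ontology$terms)
  if (length(missing_roots)) {
    stop_cf("descendant_terms(): unknown root term(s): ",
            paste(missing_roots, collapse = ", "),
            class = "counterflow_lookup_error")
  }
  e <- ontology$edges[ontology$edges$relation %in% relations, , drop = FALSE]
  children_of <- split(e$child, e$parent)
  seen <- character()
  queue <- unique(roots)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, setdiff(children_of[[v]] %||% character(), seen))
  }
  sort_c(setdiff(seen, ontology$obsolete))
}

#' Parse a GAF gene-association file
#'
#' Reads GAF 2.1/2.2 (17 tab-separated columns, `!`-prefixed comment lines)
#' into a tibble of annotation records, with optional taxon filtering,
#' evidence-code exclusion, and dropping of NOT-qualified (negated)
#' annotations.
#'
#' @param path Path to a GAF file.
#' @param taxon_filter Optional NCBI taxon id (e.g., `10090` for mouse); only
#'   records whose first listed taxon matches are kept. `NULL` keeps all.
#' @param exclude_evidence Character vector of GAF evidence codes to drop
#'   (default none: all evidence, including IEA, is kept).
#' @param drop_negated If `TRUE` (default), records whose qualifier contains
#'   `NOT` are dropped.
#' @return A tibble with columns `gene_symbol`, `term_id`, `taxon`,
#'   `evidence_code`, `qualifier`.
#' @export
parse_gaf <- function(path, taxon_filter = NULL, exclude_evidence = character(),
                      drop_negated = TRUE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(tibble::tibble(gene_symbol = character(), term_id = character(),
                          taxon = character(), evidence_code = character(),
                          qualifier = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- nfield < 15L | nfield > 17L
  if (any(bad)) {
    stop_cf("parse_gaf(): line ", idx[which(bad)[1]], " has ",
            nfield[which(bad)[1]], " columns (expected 17)",
            class = "counterflow_parse_error")
  }
  get <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else "",
                            character(1))
  rec <- tibble::tibble(
    gene_symbol = get(3L),
    term_id = get(5L),
    taxon = sub("^taxon:", "", vapply(strsplit(get(13L), "|", fixed = TRUE),
                                      `[`, character(1), 1L)),
    evidence_code = get(7L),
    qualifier = get(4L)
  )
  if (any(!nzchar(rec$gene_symbol))) {
    stop_cf("parse_gaf(): empty gene symbol at line ",
            idx[which(!nzchar(rec$gene_symbol))[1]],
            class = "counterflow_parse_error")
  }
  if (!is.null(taxon_filter)) {
    rec <- rec[rec$taxon == as.character(taxon_filter), , drop = FALSE]
  }
  if (length(exclude_evidence)) {
    rec <- rec[!(rec$evidence_code %in% exclude_evidence), , drop = FALSE]
  }
  if (isTRUE(drop_negated)) {
    rec <- rec[!grepl("(^|\\|)NOT($|\\|)", rec$qualifier), , drop = FALSE]
  }
  rec
}

#' Compile a gene set from annotations ("reverse GO")
#'
#' The reverse Gene Ontology step: given annotation records and a set of GO
#' term ids, collect every gene symbol annotated to any of the terms,
#' canonicalize (uppercase), drop duplicates and sort — turning GO terms into
#' a gene list rather than annotating a gene list. The provenance records the
#' per-term raw annotation counts and the final unique count, the audit trail
#' a curator would keep when merging per-term query results.
#'
#' @param annotations Tibble of annotation records from [parse_gaf()].
#' @param terms Character vector of term ids to collect genes for.
#' @param name Name for the resulting `GeneSet`.
#' @param ontology Optional `OntologyGraph`; when given, annotations to
#'   obsolete terms are dropped with a warning.
#' @return A `GeneSet`.
#' @export
compile_gene_set <- function(annotations, terms, name = "gene_set",
                             ontology = NULL) {
  if (!is.null(ontology)) {
    obs <- annotations$term_id %in% ontology$obsolete
    if (any(obs)) {
      warning(sprintf("compile_gene_set(): dropping %d annotation(s) to obsolete terms",
                      sum(obs)))
      annotations <- annotations[!obs, , drop = FALSE]
    }
  }
  hits <- annotations[annotations$term_id %in% terms, , drop = FALSE]
  per_term <- vapply(terms, function(t) sum(hits$term_id == t), integer(1))
  gs <- gene_set(hits$gene_symbol, name = name)
  gs$provenance <- c(
    sprintf("term %s: %d annotation(s)", terms, per_term),
    sprintf("unique symbols after case-fold dedup: %d", length(gs))
  )
  gs
}

# --- writers used by the synthetic-data generator ------------------------

#' Write a minimal OBO file
#'
#' Serializes an ontology description (as built by the synthetic-data
#' generator) in OBO 1.2 dialect readable by [parse_obo()].
#'
#' @param terms Tibble with columns `id`, `name`, and optionally `parent`
#'   (NA for roots) and `obsolete` (logical).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(terms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: synthetic"), con)
  for (i in seq_len(nrow(terms))) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", terms$id[i]), con)
    writeLines(paste0("name: ", terms$name[i]), con)
    if ("parent" %in% names(terms) && !is.na(terms$parent[i])) {
      writeLines(paste0("is_a: ", terms$parent[i]), con)
    }
    if ("obsolete" %in% names(terms) && isTRUE(terms$obsolete[i])) {
      writeLines("is_obsolete: true", con)
    }
  }
  invisible(path)
}

#' Write a GAF 2.1 file
#'
#' @param annotations Tibble with columns `gene_symbol`, `term_id`, `taxon`,
#'   and optionally `evidence_code` and `qualifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  n <- nrow(annotations)
  ev <- if ("evidence_code" %in% names(annotations)) annotations$evidence_code
        else rep("IEA", n)
  qual <- if ("qualifier" %in% names(annotations)) annotations$qualifier
          else rep("", n)
  rows <- vapply(seq_len(n), function(i) {
    paste(c("SYN", paste0("SYN:", annotations$gene_symbol[i]),
            annotations$gene_symbol[i], qual[i], annotations$term_id[i],
            "SYN:ref", ev[i], "", "P", "", "", "protein",
            paste0("taxon:", annotations$taxon[i]), "20200101", "SYN", "", ""),
          collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}
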