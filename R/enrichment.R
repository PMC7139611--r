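#' Upper tail of the hypergeometric distribution
#'
#' Returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are sampled without
#' replacement from a universe of `N` genes of which `K` carry the
#' annotation — the standard over-representation p-value. Computed in log
#' space (`lchoose` + log-sum-exp) so that tiny tails at large `N` do not
#' underflow term by term.
#'
#' @param k Observed overlap count, `0 <= k <= min(K, n)`.
#' @param K Category size in the universe.
#' @param n Query list size.
#' @param N Universe size; `K <= N`, `n <= N`.
#' @return A probability in `[0, 1]`; `k = 0` gives exactly 1.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (length(k) != 1L || length(K) != 1L || length(n) != 1L || length(N) != 1L ||
      anyNA(c(k, K, n, N)) || k < 0 || K > N || n > N || k > min(K, n)) {
    stop_cf("hypergeom_tail(): need 0 <= k <= min(K, n) and K, n <= N",
            class = "counterflow_domain_error")
  }
  hypergeom_tail_all(K, n, N)[k + 1L]
}

# Tail probabilities P(X >= k) for all k = 0..min(K, n) at once.
hypergeom_tail_all <- function(K, n, N) {
  upper <- min(K, n)
  i <- 0:upper
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  tails <- vapply(seq_along(i), function(j) exp(logsumexp(lp[j:length(lp)])),
                  numeric(1))
  pmin(tails, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, mapped back to the input
#' order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop_cf("bh_adjust(): p-values must lie in (0, 1]",
            class = "counterflow_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric GO over-representation analysis
#'
#' For every term annotating at least `min_k` query genes, tests whether the
#' query list is enriched in that term's genes relative to the universe,
#' using the one-sided hypergeometric tail, then adjusts across the tested
#' terms by Benjamini-Hochberg. Term-to-gene mapping is direct annotation
#' only by default; set `propagate = TRUE` to also count genes annotated to
#' descendants of each term (requires `ontology`).
#'
#' @param query A `GeneSet` (or character vector) of genes to test; nonempty.
#' @param annotations Annotation tibble from [parse_gaf()].
#' @param universe Optional `GeneSet`/character vector of background genes;
#'   default: every distinct annotated symbol in `annotations`.
#' @param min_k Minimum in-list count for a term to be tested (default 2).
#' @param top Keep the first `top` rows after sorting (default 20); `Inf`
#'   keeps all.
#' @param ontology Optional `OntologyGraph`, used for term labels and for
#'   ancestor propagation.
#' @param propagate If `TRUE`, a gene annotated to a term also counts for all
#'   of that term's ancestors (is_a only). Default `FALSE`.
#' @return Tibble with one row per tested term: `term_id`, `label`, `k`
#'   (genes in list), `K` (category size in universe), `n` (query size in
#'   universe), `N` (universe size), `p_raw`, `q_fdr`, `hit_symbols`
#'   (semicolon-joined), sorted by `q_fdr`, then `p_raw`, then `term_id`.
#' @export
enrich <- function(query, annotations, universe = NULL, min_k = 2L, top = 20L,
                   ontology = NULL, propagate = FALSE) {
  query <- as_gene_set(query, name = "query")
  if (!length(query)) stop_cf("enrich(): empty query gene set")
  ann <- tibble::tibble(
    gene_symbol = canonical_symbol(annotations$gene_symbol),
    term_id = annotations$term_id
  )
  if (isTRUE(propagate)) {
    if (is.null(ontology)) stop_cf("enrich(): propagate = TRUE needs an ontology")
    e <- ontology$edges[ontology$edges$relation == "is_a", , drop = FALSE]
    parents_of <- split(e$parent, e$child)
    ancestors <- function(t) {
      seen <- character(); queue <- t
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nxt <- setdiff(parents_of[[v]] %||% character(), seen)
        seen <- c(seen, nxt); queue <- c(queue, nxt)
      }
      seen
    }
    extra <- lapply(unique(ann$term_id), function(t) {
      anc <- ancestors(t)
      if (!length(anc)) return(NULL)
      g <- ann$gene_symbol[ann$term_id == t]
      tidyr::expand_grid(gene_symbol = g, term_id = anc)
    })
    ann <- dplyr::bind_rows(c(list(ann), extra))
    message("enrich(): ancestor propagation enabled (is_a)")
  }
  ann <- dplyr::distinct(ann)

  uni <- if (is.null(universe)) sort_c(unique(ann$gene_symbol))
         else as_gene_set(universe)$symbols
  ann <- ann[ann$gene_symbol %in% uni, , drop = FALSE]
  q_in <- intersect(query$symbols, uni)
  if (!length(q_in)) {
    warning("enrich(): query is disjoint from the universe; empty result")
    return(empty_enrichment())
  }
  N <- length(uni)
  n <- length(q_in)

  by_term <- split(ann$gene_symbol, ann$term_id)
  rows <- lapply(names(by_term), function(t) {
    genes <- by_term[[t]]
    hits <- intersect(q_in, genes)
    k <- length(hits)
    if (k < min_k) return(NULL)
    tibble::tibble(term_id = t, k = k, K = length(genes), n = n, N = N,
                   p_raw = hypergeom_tail(k, length(genes), n, N),
                   hit_symbols = paste(sort_c(hits), collapse = ";"))
  })
  rows <- dplyr::bind_rows(rows)
  if (!nrow(rows)) return(empty_enrichment())
  rows$q_fdr <- bh_adjust(rows$p_raw)
  rows$label <- if (!is.null(ontology)) {
    unname(ontology$name_of[rows$term_id])
  } else NA_character_
  rows <- rows[order(rows$q_fdr, rows$p_raw, rows$term_id, method = "radix"), ]
  rows <- utils::head(rows, top)
  rows[, c("term_id", "label", "k", "K", "n", "N", "p_raw", "q_fdr",
           "hit_symbols")]
}

empty_enrichment <- function() {
  tibble::tibble(term_id = character(), label = character(), k = integer(),
                 K = integer(), n = integer(), N = integer(),
                 p_raw = numeric(), q_fdr = numeric(),
                 hit_symbols = character())
}

#' Write an enrichment table as TSV
#'
#' Columns mirror a published enrichment report: term id, label, FDR,
#' genes-in-list, category size, and the hit symbols.
#'
#' @param rows Tibble from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path) {
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}
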