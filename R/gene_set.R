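#' Construct a gene set
#'
#' A `GeneSet` is a named, duplicate-free, lexicographically sorted collection
#' of gene symbols. Symbols are canonicalized to uppercase for identity (so
#' the murine symbol `Ccr7` and the human symbol `CCR7` collapse to one
#' entry), while the first-seen display form of each symbol is preserved for
#' reporting.
#'
#' @param symbols Character vector of gene symbols, any case, duplicates
#'   allowed. Empty strings and `NA` are rejected.
#' @param name Short label for the set (e.g., `"oxstress"`).
#' @param provenance Character vector: free-text audit trail (how the set was
#'   built, per-source counts, ...). Carried along by set operations.
#' @return An object of class `GeneSet` with fields `name`, `symbols`
#'   (canonical, sorted, unique), `display` (named map canonical -> first-seen
#'   form) and `provenance`.
#' @examples
#' gs <- gene_set(c("Ccr7", "Foxo1", "CCR7"), name = "demo")
#' gs$symbols  # "CCR7" "FOXO1"
#' @export
gene_set <- function(symbols = character(), name = "", provenance = character()) {
  symbols <- as.character(symbols)
  if (anyNA(symbols) || any(!nzchar(trimws(symbols)))) {
    stop_cf("gene_set(): symbols must be nonempty and non-NA")
  }
  display <- trimws(symbols)
  canon <- canonical_symbol(display)
  keep <- !duplicated(canon)
  display <- display[keep]
  canon <- canon[keep]
  ord <- order(canon, method = "radix")
  structure(
    list(
      name = name,
      symbols = canon[ord],
      display = stats::setNames(display[ord], canon[ord]),
      provenance = as.character(provenance)
    ),
    class = "GeneSet"
  )
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("<GeneSet '%s': %d symbols>\n", x$name, length(x$symbols)))
  if (length(x$symbols)) {
    shown <- utils::head(x$symbols, 10L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$symbols) > 10L) ", ..." else "", "\n", sep = "")
  }
  for (p in x$provenance) cat("  # ", p, "\n", sep = "")
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$symbols)

#' Intersect two gene sets
#'
#' Symbols are compared on their canonical (uppercase) form; the result is a
#' sorted, duplicate-free `GeneSet`. Commutative up to display forms (the
#' first argument's display form wins).
#'
#' @param a,b `GeneSet` objects (or character vectors, which are coerced).
#' @param name Name for the resulting set; default joins the input names.
#' @return A `GeneSet` containing the symbols present in both inputs.
#' @export
intersect_gene_sets <- function(a, b, name = NULL) {
  a <- as_gene_set(a)
  b <- as_gene_set(b)
  common <- intersect(a$symbols, b$symbols)
  out <- gene_set(unname(a$display[common]),
                  name = name %||% paste0(a$name, "&", b$name))
  out$provenance <- c(
    a$provenance, b$provenance,
    sprintf("intersection of '%s' (n=%d) and '%s' (n=%d): %d common symbols",
            a$name, length(a), b$name, length(b), length(out))
  )
  out
}

#' @rdname gene_set
#' @param x Object to coerce: a `GeneSet` (returned as is) or a character
#'   vector of symbols.
#' @export
as_gene_set <- function(x, name = "") {
  if (inherits(x, "GeneSet")) return(x)
  gene_set(x, name = name)
}

#' Write / read a gene set as TSV
#'
#' The TSV has columns `symbol` (canonical form) and `display` (first-seen
#' form); provenance lines are stored as `#`-prefixed header comments. A
#' plain one-symbol-per-line text format is also supported via
#' `write_gene_set_txt()`.
#'
#' @param gs A `GeneSet`.
#' @param path Output file path.
#' @return `path`, invisibly (writers); a `GeneSet` (reader).
#' @export
write_gene_set <- function(gs, path) {
  gs <- as_gene_set(gs)
  hdr <- c(sprintf("# gene_set: %s", gs$name),
           sprintf("# %s", gs$provenance))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("symbol\tdisplay", con)
  if (length(gs$symbols)) {
    writeLines(paste(gs$symbols, unname(gs$display[gs$symbols]), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_gene_set
#' @export
write_gene_set_txt <- function(gs, path) {
  gs <- as_gene_set(gs)
  writeLines(gs$symbols, path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  name <- sub("^# gene_set: ", "", meta[startsWith(meta, "# gene_set:")])
  prov <- sub("^# ", "", meta[!startsWith(meta, "# gene_set:")])
  if (!length(body) || body[1] != "symbol\tdisplay") {
    stop_cf("read_gene_set(): '", path, "' lacks the 'symbol\\tdisplay' header")
  }
  body <- body[-1]
  display <- if (length(body)) vapply(strsplit(body, "\t", fixed = TRUE),
                                      `[`, character(1), 2L) else character()
  gene_set(display, name = if (length(name)) name else "", provenance = prov)
}
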