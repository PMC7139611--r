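# Internal helpers shared across modules.

# Locale-independent lexicographic sort (C collation via radix method),
# so GeneSet ordering is identical across platforms.
sort_c <- function(x) sort(x, method = "radix")

#' @noRd
canonical_symbol <- function(x) toupper(trimws(x))

#' @noRd
canonical_mirna <- function(x) tolower(trimws(x))

# log(sum(exp(lx))) without overflow; lx may contain -Inf.
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cf <- function(..., class = "counterflow_error") {
  rlang::abort(paste0(...), class = class)
}

# md5 digest of a file; base tools only.
file_digest <- function(path) unname(tools::md5sum(path))

# md5 digest of an arbitrary R object, via a temporary serialized file.
object_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  file_digest(tf)
}
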