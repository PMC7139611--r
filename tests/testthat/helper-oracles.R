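# Independent oracles used across the suite. Each re-derives the quantity
# by brute force or via a different library route than the implementation.

# Hypergeometric upper tail by explicit pmf enumeration (stats::dhyper sum).
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(stats::dhyper(i, K, N - K, n))
}

# Benjamini-Hochberg by the literal step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact two-sided Mann-Whitney p by full enumeration of rank splits
# (valid only without ties).
oracle_exact_rank_sum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- utils::combn(length(pooled), nx,
                        function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

# All terms reachable from roots via child->parent edges, by iterated
# expansion over the full edge list (transitive-closure brute force).
oracle_descendants <- function(edges, roots) {
  reach <- roots
  repeat {
    nxt <- unique(c(reach, edges$child[edges$parent %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  sort(reach)
}

# Random DAG as an OntologyGraph: edges only from higher- to lower-indexed
# terms, so acyclicity holds by construction.
random_dag_ontology <- function(n_terms, p_edge = 0.15) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  pairs <- which(upper.tri(matrix(0, n_terms, n_terms)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(child = ids[pairs[keep, 2]],
                          parent = ids[pairs[keep, 1]],
                          relation = "is_a")
  structure(list(terms = ids,
                 name_of = stats::setNames(ids, ids),
                 edges = edges, obsolete = character()),
            class = "OntologyGraph")
}

# Barber bipartite modularity by the raw definition (double loop).
oracle_barber_modularity <- function(net, membership) {
  m <- nrow(net$edges)
  gdeg <- table(factor(net$edges$gene_symbol, levels = net$gene_nodes))
  mdeg <- table(factor(net$edges$mirna_id, levels = net$mirna_nodes))
  q <- 0
  for (g in net$gene_nodes) {
    for (mi in net$mirna_nodes) {
      if (membership[[g]] != membership[[mi]]) next
      a <- as.numeric(any(net$edges$gene_symbol == g & net$edges$mirna_id == mi))
      q <- q + a - gdeg[[g]] * mdeg[[mi]] / m
    }
  }
  q / m
}

# Small OBO text used by several parser tests.
write_chain_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: A", "",
    "[Term]", "id: GO:0000002", "name: B", "is_a: GO:0000001 ! A", "",
    "[Term]", "id: GO:0000003", "name: C", "is_a: GO:0000002 ! B"
  ), path)
  path
}

# Minimal GAF writer for parser tests (17 columns, via the package writer).
tiny_gaf <- function(path, symbols, terms, taxa,
                     qualifiers = rep("", length(symbols)),
                     evidence = rep("IEA", length(symbols))) {
  write_gaf(tibble::tibble(gene_symbol = symbols, term_id = terms,
                           taxon = taxa, evidence_code = evidence,
                           qualifier = qualifiers), path)
}
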