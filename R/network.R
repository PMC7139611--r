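#' Build a bipartite miRNA-gene network
#'
#' One side holds miRNA nodes, the other gene nodes; an edge means the miRNA
#' is predicted (or validated) to target the gene. Node sets are exactly the
#' endpoints of the supplied pairs; duplicate pairs collapse to one edge.
#'
#' @param pairs A `TargetMap`, or a tibble with columns `mirna_id` and
#'   `gene_symbol` (e.g., the output of [counter_expressed_pairs()]).
#' @return An object of class `BipartiteNetwork`: list with `gene_nodes`,
#'   `mirna_nodes` (sorted character vectors) and `edges` (tibble `mirna_id`,
#'   `gene_symbol`, deduplicated, sorted).
#' @export
build_bipartite <- function(pairs) {
  if (inherits(pairs, "TargetMap")) pairs <- pairs$pairs
  edges <- tibble::tibble(mirna_id = trimws(pairs$mirna_id),
                          gene_symbol = canonical_symbol(pairs$gene_symbol))
  edges <- dplyr::distinct(edges)
  edges <- edges[order(edges$mirna_id, edges$gene_symbol, method = "radix"), ]
  structure(
    list(gene_nodes = sort_c(unique(edges$gene_symbol)),
         mirna_nodes = sort_c(unique(edges$mirna_id)),
         edges = edges),
    class = "BipartiteNetwork"
  )
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("<BipartiteNetwork: %d genes, %d miRNAs, %d edges>\n",
              length(x$gene_nodes), length(x$mirna_nodes), nrow(x$edges)))
  invisible(x)
}

#' Degree profile of a bipartite network
#'
#' @param net A `BipartiteNetwork`.
#' @return Tibble with columns `node`, `side` (`"gene"`/`"mirna"`), `degree`.
#'   The gene-side degrees and the miRNA-side degrees each sum to the edge
#'   count (handshake identity).
#' @export
degree_profile <- function(net) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  gdeg <- table(factor(net$edges$gene_symbol, levels = net$gene_nodes))
  mdeg <- table(factor(net$edges$mirna_id, levels = net$mirna_nodes))
  tibble::tibble(
    node = c(net$gene_nodes, net$mirna_nodes),
    side = c(rep("gene", length(net$gene_nodes)),
             rep("mirna", length(net$mirna_nodes))),
    degree = as.integer(c(gdeg, mdeg))
  )
}

#' miRNAs shared by two genes
#'
#' The intersection of two genes' miRNA neighborhoods: the regulators
#' predicted to target both. Symmetric in its gene arguments;
#' `shared_regulators(net, g, g)` is g's full neighborhood.
#'
#' @param net A `BipartiteNetwork`.
#' @param gene_a,gene_b Gene symbols (any case); both must be nodes.
#' @return Sorted character vector of miRNA ids.
#' @export
shared_regulators <- function(net, gene_a, gene_b) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  a <- canonical_symbol(gene_a)
  b <- canonical_symbol(gene_b)
  unknown <- setdiff(c(a, b), net$gene_nodes)
  if (length(unknown)) {
    stop_cf("shared_regulators(): unknown gene(s): ",
            paste(unique(unknown), collapse = ", "),
            class = "counterflow_lookup_error")
  }
  nb <- function(g) net$edges$mirna_id[net$edges$gene_symbol == g]
  sort_c(intersect(nb(a), nb(b)))
}

#' Barber bipartite modularity of a partition
#'
#' Modularity with a bipartite-aware null model: only (miRNA, gene) slots can
#' hold edges, so the expected co-membership weight of miRNA `j` and gene `i`
#' is `d_i e_j / m` (degrees over edge count), not the unipartite `k_i k_j / 2m`.
#' `Q = (1/m) * sum_{i,j} (A_ij - d_i e_j / m) * [c(i) == c(j)]`.
#'
#' @param net A `BipartiteNetwork`.
#' @param membership Named integer vector: node (gene symbol or miRNA id) ->
#'   module index; must cover every node of `net`.
#' @return Scalar modularity in `[-1, 1]`.
#' @export
barber_modularity <- function(net, membership) {
  B <- barber_matrix(net)
  m <- nrow(net$edges)
  cg <- membership[rownames(B)]
  cm <- membership[colnames(B)]
  if (anyNA(cg) || anyNA(cm)) {
    stop_cf("barber_modularity(): membership must cover every node")
  }
  same <- outer(cg, cm, "==")
  sum(B[same]) / m
}

# B = A - d e^T / m on genes (rows) x miRNAs (cols); dimnames set.
barber_matrix <- function(net) {
  g <- net$gene_nodes
  mir <- net$mirna_nodes
  A <- matrix(0, length(g), length(mir), dimnames = list(g, mir))
  A[cbind(net$edges$gene_symbol, net$edges$mirna_id)] <- 1
  m <- nrow(net$edges)
  A - (rowSums(A) %o% colSums(A)) / m
}

#' Community detection by greedy Barber-modularity maximization
#'
#' Three deterministic phases on the bipartite graph. (1) Agglomeration:
#' every node starts in its own module and the merge with the largest
#' positive Barber-modularity gain is applied repeatedly (ties broken by
#' lexicographic order of the module pair's smallest node labels).
#' (2) Refinement: nodes are swept in lexicographic order and moved to the
#' module that strictly increases modularity, until a full sweep makes no
#' move — the alternating reassignment step of bipartite modularity
#' maximization, which repairs the local maxima plain agglomeration is
#' prone to. (3) Coalescence: connected module pairs whose merge leaves
#' modularity unchanged are merged, resolving modularity ties toward fewer
#' modules (so a lone edge reports one module, not two). The procedure is
#' fully deterministic; the `seed` is recorded in the result for provenance
#' but does not influence the outcome.
#'
#' @param net A nonempty `BipartiteNetwork`.
#' @param seed Integer recorded in the result.
#' @return An object of class `PartitionResult`: list with `module_of`
#'   (named integer, 0-based contiguous module indices), `modularity`
#'   (Barber modularity of the returned partition), `method`, `seed`.
#' @export
detect_communities <- function(net, seed = 0L) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  if (!nrow(net$edges)) stop_cf("detect_communities(): empty network")
  B <- barber_matrix(net)
  m <- nrow(net$edges)
  nodes <- c(rownames(B), colnames(B))
  ng <- nrow(B)
  # C[x, y] = sum of B over (genes of module x) x (miRNAs of module y).
  # Initially every node is its own module; gene singletons have empty
  # miRNA content and vice versa, so C starts as B embedded in a K x K frame.
  K <- length(nodes)
  C <- matrix(0, K, K)
  C[seq_len(ng), ng + seq_len(K - ng)] <- B
  comm <- as.list(seq_len(K))           # module -> member node indices
  anchor <- nodes                       # module -> lexicographic anchor label
  repeat {
    G <- C + t(C)                       # gain(x, y) * m for merging x, y
    diag(G) <- -Inf
    best <- max(G)
    if (best <= 1e-12) break
    hits <- which(G == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (anchor_a, anchor_b) pair
    key <- paste(pmin(anchor[hits[, 1]], anchor[hits[, 2]]),
                 pmax(anchor[hits[, 1]], anchor[hits[, 2]]), sep = "\r")
    pick <- hits[order(key, method = "radix")[1], ]
    a <- pick[1]; b <- pick[2]
    C[a, ] <- C[a, ] + C[b, ]
    C[, a] <- C[, a] + C[, b]
    C <- C[-b, -b, drop = FALSE]
    comm[[a]] <- c(comm[[a]], comm[[b]])
    comm[[b]] <- NULL
    anchor[a] <- min(anchor[a], anchor[b])
    anchor <- anchor[-b]
  }
  membership <- integer(length(nodes))
  names(membership) <- nodes
  for (x in seq_along(comm)) membership[comm[[x]]] <- x
  # full B in node x node frame: rows genes then miRNAs, cross-side blocks
  Bfull <- matrix(0, K, K, dimnames = list(nodes, nodes))
  Bfull[seq_len(ng), ng + seq_len(K - ng)] <- B
  Bfull[ng + seq_len(K - ng), seq_len(ng)] <- t(B)

  # refinement sweeps: move single nodes to strictly better modules
  sweep_order <- order(nodes, method = "radix")
  refine <- function(membership) {
    repeat {
      moved <- FALSE
      for (v in sweep_order) {
        s <- tapply(Bfull[v, ], membership, sum)        # gain per module
        cur <- as.character(membership[v])
        gains <- s - s[[cur]]
        best <- names(gains)[which.max(gains)]
        if (gains[[best]] > 1e-12) {
          membership[v] <- as.integer(best)
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    membership
  }
  q_of <- function(membership) {
    sum(Bfull[outer(membership, membership, "==")]) / (2 * m)
  }
  membership <- refine(membership)

  # escape agglomeration maxima: try every module-pair merge followed by a
  # resweep, accept the best strict improvement, repeat to convergence
  repeat {
    mods <- sort(unique(membership))
    if (length(mods) < 2L) break
    cur_q <- q_of(membership)
    best_q <- cur_q
    best_mem <- NULL
    for (i in seq_along(mods)[-length(mods)]) {
      for (j in (i + 1L):length(mods)) {
        trial <- membership
        trial[trial == mods[j]] <- mods[i]
        trial <- refine(trial)
        tq <- q_of(trial)
        if (tq > best_q + 1e-12) {
          best_q <- tq
          best_mem <- trial
        }
      }
    }
    if (is.null(best_mem)) break
    membership <- best_mem
  }

  # coalesce connected modules whose merge does not lower modularity
  repeat {
    mods <- sort(unique(membership))
    if (length(mods) < 2L) break
    adj <- outer(mods, mods, Vectorize(function(a, b) {
      if (a >= b) return(FALSE)
      va <- names(membership)[membership == a]
      vb <- names(membership)[membership == b]
      any(net$edges$gene_symbol %in% va & net$edges$mirna_id %in% vb) ||
        any(net$edges$gene_symbol %in% vb & net$edges$mirna_id %in% va)
    }))
    gain <- outer(mods, mods, Vectorize(function(a, b) {
      va <- membership == a
      vb <- membership == b
      sum(Bfull[va, vb])
    }))
    cand <- which(adj & gain > -1e-12, arr.ind = TRUE)
    if (!nrow(cand)) break
    pick <- cand[order(-gain[cand], cand[, 1], cand[, 2])[1], ]
    membership[membership == mods[pick[2]]] <- mods[pick[1]]
  }

  # contiguous 0-based ids, modules ordered by their lexicographic anchor
  anchors <- tapply(names(membership), membership, min)
  ord <- order(anchors, method = "radix")
  relabel <- stats::setNames(seq_along(ord) - 1L, names(anchors)[ord])
  module_of <- unname(relabel[as.character(membership)])
  names(module_of) <- names(membership)
  structure(
    list(module_of = module_of,
         modularity = barber_modularity(net, module_of),
         method = "greedy_barber_refined",
         seed = as.integer(seed)),
    class = "PartitionResult"
  )
}

#' @export
print.PartitionResult <- function(x, ...) {
  cat(sprintf("<PartitionResult: %d modules, Q_B = %.4f, method = %s>\n",
              length(unique(x$module_of)), x$modularity, x$method))
  invisible(x)
}

#' Convert a bipartite network to an igraph object
#'
#' Nodes carry a logical `type` attribute (`TRUE` for miRNAs, `FALSE` for
#' genes), igraph's bipartite convention, plus a readable `side` attribute.
#'
#' @param net A `BipartiteNetwork`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna_id", "gene_symbol")],
    directed = FALSE,
    vertices = data.frame(
      name = c(net$mirna_nodes, net$gene_nodes),
      type = c(rep(TRUE, length(net$mirna_nodes)),
               rep(FALSE, length(net$gene_nodes))),
      side = c(rep("mirna", length(net$mirna_nodes)),
               rep("gene", length(net$gene_nodes)))
    )
  )
  g
}

#' Export a bipartite network
#'
#' Writes the edge list as TSV (`mirna`, `gene`), the graph as GML with the
#' bipartite side stored as a node attribute, the degree table, and (when a
#' partition is supplied) the module assignment.
#'
#' @param net A `BipartiteNetwork`.
#' @param prefix Output path prefix; files `<prefix>_edges.tsv`,
#'   `<prefix>.gml`, `<prefix>_degrees.tsv` and optionally
#'   `<prefix>_modules.tsv` are written.
#' @param partition Optional `PartitionResult`.
#' @return Character vector of written paths, invisibly.
#' @export
write_network <- function(net, prefix, partition = NULL) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  edges_path <- paste0(prefix, "_edges.tsv")
  out <- net$edges
  names(out) <- c("mirna", "gene")
  readr::write_tsv(out, edges_path, progress = FALSE)
  gml_path <- paste0(prefix, ".gml")
  # igraph downcasts the logical bipartite `type` attribute to numeric in
  # GML; that is the intended on-disk encoding, so silence the note
  suppressWarnings(igraph::write_graph(as_igraph(net), gml_path, format = "gml"))
  # drop the timestamped Creator comment so identical networks yield
  # byte-identical files (the manifest's reproducibility contract)
  gml <- readLines(gml_path)
  gml[startsWith(gml, "Creator")] <- "Creator \"counterflow\""
  writeLines(gml, gml_path)
  deg_path <- paste0(prefix, "_degrees.tsv")
  readr::write_tsv(degree_profile(net), deg_path, progress = FALSE)
  paths <- c(edges_path, gml_path, deg_path)
  if (!is.null(partition)) {
    mod_path <- paste0(prefix, "_modules.tsv")
    readr::write_tsv(
      tibble::tibble(node = names(partition$module_of),
                     module = unname(partition$module_of)),
      mod_path, progress = FALSE)
    paths <- c(paths, mod_path)
  }
  invisible(paths)
}
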