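test_that("the packaged map builds the published bipartite network", {
  net <- build_bipartite(athp_target_map())
  expect_length(net$gene_nodes, 14)
  expect_length(net$mirna_nodes, 13)
  expect_equal(nrow(net$edges), 68)
  deg <- degree_profile(net)
  expect_equal(deg$degree[deg$node == "FOS"], 1)
  # handshake identity
  expect_equal(sum(deg$degree[deg$side == "gene"]), 68)
  expect_equal(sum(deg$degree[deg$side == "mirna"]), 68)
})

test_that("duplicate pairs collapse and empty input yields an empty network", {
  dup <- build_bipartite(tibble::tibble(mirna_id = c("m1", "m1"),
                                        gene_symbol = c("G1", "g1")))
  expect_equal(nrow(dup$edges), 1)
  empty <- build_bipartite(tibble::tibble(mirna_id = character(),
                                          gene_symbol = character()))
  expect_length(empty$gene_nodes, 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("degree handshake holds on random networks; star degree is its size", {
  star <- build_bipartite(tibble::tibble(mirna_id = "m1",
                                         gene_symbol = sprintf("G%d", 1:5)))
  deg <- degree_profile(star)
  expect_equal(deg$degree[deg$node == "m1"], 5)
  set.seed(2)
  for (rep in 1:10) {
    net <- build_bipartite(tibble::tibble(
      mirna_id = sample(sprintf("m%d", 1:8), 40, replace = TRUE),
      gene_symbol = sample(sprintf("G%d", 1:15), 40, replace = TRUE)))
    deg <- degree_profile(net)
    expect_equal(sum(deg$degree[deg$side == "gene"]), nrow(net$edges))
    expect_equal(sum(deg$degree[deg$side == "mirna"]), nrow(net$edges))
  }
})

test_that("shared regulators of Ccr7 and Foxo1 are the two published miRNAs", {
  net <- build_bipartite(athp_target_map())
  expect_equal(shared_regulators(net, "Ccr7", "Foxo1"),
               c("mmu-miR-30a-5p", "mmu-miR-465a-5p"))
  # symmetry, identity, and failure on unknown genes
  expect_equal(shared_regulators(net, "Foxo1", "Ccr7"),
               shared_regulators(net, "Ccr7", "Foxo1"))
  expect_equal(shared_regulators(net, "Fos", "Fos"), "mmu-miR-543-3p")
  expect_length(shared_regulators(net, "Fos", "Kcnh3"), 0)
  expect_error(shared_regulators(net, "Ccr7", "Nope"),
               class = "counterflow_lookup_error")
})

test_that("Barber modularity matches the raw-definition oracle", {
  set.seed(13)
  for (rep in 1:5) {
    net <- build_bipartite(tibble::tibble(
      mirna_id = sample(sprintf("m%d", 1:5), 20, replace = TRUE),
      gene_symbol = sample(sprintf("G%d", 1:8), 20, replace = TRUE)))
    nodes <- c(net$gene_nodes, net$mirna_nodes)
    membership <- stats::setNames(sample(0:2, length(nodes), replace = TRUE),
                                  nodes)
    expect_equal(barber_modularity(net, membership),
                 oracle_barber_modularity(net, membership),
                 tolerance = 1e-12)
  }
})

test_that("two disjoint complete blocks are recovered as exactly two modules", {
  blocks <- dplyr::bind_rows(
    tidyr::expand_grid(mirna_id = sprintf("mA%d", 1:3),
                       gene_symbol = sprintf("GA%d", 1:4)),
    tidyr::expand_grid(mirna_id = sprintf("mB%d", 1:3),
                       gene_symbol = sprintf("GB%d", 1:4)))
  net <- build_bipartite(blocks)
  part <- detect_communities(net, seed = 1)
  expect_length(unique(part$module_of), 2)
  # modules coincide with the graph components (independent igraph check)
  comp <- igraph::components(as_igraph(net))$membership
  expect_equal(length(unique(paste(part$module_of[names(comp)], comp))), 2)
  expect_gt(part$modularity, 0.4)
})

test_that("a single edge joins both endpoints in one module", {
  net <- build_bipartite(tibble::tibble(mirna_id = "m1", gene_symbol = "G1"))
  part <- detect_communities(net, seed = 5)
  expect_equal(unname(part$module_of["G1"]), unname(part$module_of["m1"]))
})

test_that("community detection is bit-identical across repeated runs", {
  net <- build_bipartite(athp_target_map())
  a <- detect_communities(net, seed = 17)
  b <- detect_communities(net, seed = 17)
  expect_identical(a, b)
  expect_equal(a$method, "greedy_barber_refined")
  expect_equal(barber_modularity(net, a$module_of), a$modularity)
})

test_that("network export writes edge list, GML, degrees and modules", {
  net <- build_bipartite(athp_target_map())
  part <- detect_communities(net, seed = 1)
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_network(net, prefix, partition = part)
  expect_true(all(file.exists(paths)))
  edges <- readr::read_tsv(paste0(prefix, "_edges.tsv"), col_types = "cc",
                           progress = FALSE)
  expect_equal(nrow(edges), 68)
  g <- igraph::read_graph(paste0(prefix, ".gml"), format = "gml")
  expect_equal(igraph::gorder(g), 27)
  expect_equal(igraph::gsize(g), 68)
  mods <- readr::read_tsv(paste0(prefix, "_modules.tsv"), col_types = "ci",
                          progress = FALSE)
  expect_equal(nrow(mods), 27)
})
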