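test_that("parse_obo reads term stanzas, labels and transitivity", {
  p <- write_chain_obo(withr::local_tempfile(fileext = ".obo"))
  g <- parse_obo(p)
  expect_setequal(g$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(unname(g$name_of["GO:0000002"]), "B")
  expect_true(all(c("GO:0000001", "GO:0000002", "GO:0000003") %in%
                    descendant_terms(g, "GO:0000001")))
})

test_that("parse_obo recognizes the oxidative-stress root term by label", {
  p <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0006979", "name: response to oxidative stress"), p)
  g <- parse_obo(p)
  expect_true("GO:0006979" %in% g$terms)
  expect_equal(unname(g$name_of["GO:0006979"]), "response to oxidative stress")
})

test_that("parse_obo handles empty files, obsolete terms, and rejects bad input", {
  empty <- withr::local_tempfile(fileext = ".obo")
  writeLines(character(), empty)
  g <- parse_obo(empty)
  expect_length(g$terms, 0)

  p <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0000001", "name: A", "",
               "[Term]", "id: GO:0000009", "name: gone",
               "is_a: GO:0000001", "is_obsolete: true"), p)
  g <- parse_obo(p)
  expect_equal(g$obsolete, "GO:0000009")
  expect_equal(nrow(g$edges), 0)  # obsolete terms are not linked
  expect_equal(descendant_terms(g, "GO:0000001"), "GO:0000001")

  noid <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "name: orphan"), noid)
  expect_error(parse_obo(noid), "line")

  cyc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "is_a: B", "",
               "[Term]", "id: B", "name: b", "is_a: A"), cyc)
  expect_error(parse_obo(cyc), "cycle")
})

test_that("descendant_terms counts diamond nodes once and rejects unknown roots", {
  p <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "",
               "[Term]", "id: B", "name: b", "is_a: A", "",
               "[Term]", "id: C", "name: c", "is_a: A", "",
               "[Term]", "id: D", "name: d", "is_a: B", "is_a: C"), p)
  g <- parse_obo(p)
  expect_equal(descendant_terms(g, "A"), c("A", "B", "C", "D"))
  expect_equal(descendant_terms(g, "D"), "D")  # leaf: identity
  expect_error(descendant_terms(g, "Z"), "unknown root")
})

test_that("descendant_terms agrees with transitive-closure oracle on random DAGs", {
  set.seed(11)
  for (rep in 1:20) {
    g <- random_dag_ontology(sample(5:50, 1))
    roots <- sample(g$terms, sample(1:3, 1))
    expect_equal(descendant_terms(g, roots),
                 oracle_descendants(g$edges, roots))
  }
})

test_that("parse_gaf applies taxon, negation and evidence filters", {
  p <- withr::local_tempfile(fileext = ".gaf")
  tiny_gaf(p,
           symbols = c("Sod1", "Cat", "GPX1", "Foxo1", "Nfe2l2"),
           terms = rep("GO:0006979", 5),
           taxa = c("10090", "10090", "9606", "10090", "9606"),
           qualifiers = c("", "NOT|involved_in", "", "", ""),
           evidence = c("IDA", "IDA", "IEA", "IEA", "ISS"))
  rec <- parse_gaf(p, taxon_filter = 10090, drop_negated = FALSE)
  expect_equal(nrow(rec), 3)
  rec <- parse_gaf(p, taxon_filter = 10090, drop_negated = TRUE)
  expect_setequal(rec$gene_symbol, c("Sod1", "Foxo1"))
  rec <- parse_gaf(p, exclude_evidence = "IEA", drop_negated = FALSE)
  expect_setequal(rec$gene_symbol, c("Sod1", "Cat", "Nfe2l2"))

  hdr <- withr::local_tempfile(fileext = ".gaf")
  writeLines("!gaf-version: 2.1", hdr)
  expect_equal(nrow(parse_gaf(hdr)), 0)

  bad <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", "only\tfour\tcolumns\there"), bad)
  expect_error(parse_gaf(bad), "line 2")
})

test_that("compile_gene_set deduplicates case-insensitively with audit provenance", {
  ann <- tibble::tibble(
    gene_symbol = c("GeneA", "genea", "GeneB", "GeneC"),
    term_id = c("T1", "T1", "T2", "T9"),
    taxon = "10090", evidence_code = "IEA", qualifier = "")
  gs <- compile_gene_set(ann, c("T1", "T2"), name = "ox")
  expect_equal(gs$symbols, c("GENEA", "GENEB"))
  expect_match(gs$provenance, "term T1: 2", all = FALSE)
  expect_match(gs$provenance, "unique symbols after case-fold dedup: 2",
               all = FALSE)
  # disjoint terms: empty set is permitted
  expect_length(compile_gene_set(ann, "T7"), 0)
})

test_that("multi-term union equals the brute-force set union, bounded by count sums", {
  # four terms with planted overlap, emulating per-term query counts that
  # exceed the final unique total
  set.seed(23)
  pool <- sprintf("Gene%03d", 1:450)
  sizes <- c(400, 94, 56, 23)
  terms <- paste0("T", 1:4)
  ann <- dplyr::bind_rows(lapply(1:4, function(i) tibble::tibble(
    gene_symbol = sample(pool, sizes[i]), term_id = terms[i])))
  gs <- compile_gene_set(ann, terms, name = "ox")
  brute_union <- unique(toupper(ann$gene_symbol))
  expect_equal(length(gs), length(brute_union))
  expect_setequal(gs$symbols, brute_union)
  expect_lte(length(gs), sum(sizes))

  # disjoint per-term sets: union size equals the sum of counts
  ann2 <- tibble::tibble(gene_symbol = sprintf("D%03d", 1:60),
                         term_id = rep(terms, each = 15))
  expect_length(compile_gene_set(ann2, terms), 60)
})

test_that("compile_gene_set is idempotent and order-invariant", {
  set.seed(5)
  ann <- tibble::tibble(
    gene_symbol = sample(c(sprintf("g%02d", 1:30), sprintf("G%02d", 1:30))),
    term_id = sample(c("T1", "T2"), 60, replace = TRUE))
  gs <- compile_gene_set(ann, c("T1", "T2"))
  # re-annotate the output and recompile: nothing changes
  gs2 <- compile_gene_set(tibble::tibble(gene_symbol = gs$symbols,
                                         term_id = "T1"), "T1")
  expect_equal(gs2$symbols, gs$symbols)
  # permutation invariance
  perm <- ann[sample(nrow(ann)), ]
  expect_equal(compile_gene_set(perm, c("T1", "T2"))$symbols, gs$symbols)
})

test_that("annotations to obsolete terms are dropped with a warning", {
  p <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T1", "name: live", "",
               "[Term]", "id: T9", "name: dead", "is_obsolete: true"), p)
  g <- parse_obo(p)
  ann <- tibble::tibble(gene_symbol = c("A", "B"), term_id = c("T1", "T9"))
  expect_warning(gs <- compile_gene_set(ann, c("T1", "T9"), ontology = g),
                 "obsolete")
  expect_equal(gs$symbols, "A")
})
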