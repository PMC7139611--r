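test_that("hypergeometric tail handles boundary cases and rejects bad input", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)       # whole support
  expect_equal(hypergeom_tail(4, 4, 4, 4), 1)        # forced full overlap
  expect_equal(hypergeom_tail(2, 5, 5, 20),
               oracle_hyper_tail(2, 5, 5, 20), tolerance = 1e-12)
  expect_error(hypergeom_tail(6, 5, 5, 20), class = "counterflow_domain_error")
  expect_error(hypergeom_tail(1, 25, 5, 20), class = "counterflow_domain_error")
})

test_that("tail is non-increasing in k and exact at extreme depletion/enrichment", {
  tails <- vapply(0:10, hypergeom_tail, numeric(1), K = 15, n = 10, N = 40)
  expect_true(all(diff(tails) <= 1e-15))
  # full-overlap probability equals the single-term closed form
  expect_equal(hypergeom_tail(5, 10, 5, 100),
               choose(10, 5) / choose(100, 5), tolerance = 1e-12)
})

test_that("log-space tail matches pmf enumeration across a parameter sweep", {
  set.seed(3)
  for (rep in 1:200) {
    N <- sample(2:200, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N), oracle_hyper_tail(k, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)                     # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))       # tie case
  set.seed(4)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q > 0 & q <= 1))
    # permutation invariance after mapping back
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], q)
  }
  expect_error(bh_adjust(c(0.5, 0)), class = "counterflow_domain_error")
})

test_that("enrich reports k, K, n, N against the annotation universe", {
  # a 13-gene category holding 2 genes of a 14-gene query, inside a larger
  # annotated universe
  set.seed(8)
  universe <- sprintf("U%03d", 1:200)
  cat_genes <- universe[1:13]
  query <- c(cat_genes[1:2], universe[100:111])          # 14 genes, 2 hits
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_symbol = cat_genes, term_id = "GO:KK"),
    tibble::tibble(gene_symbol = universe, term_id = "GO:ALL"))
  rows <- enrich(gene_set(query), ann, min_k = 2, top = 20)
  kk <- rows[rows$term_id == "GO:KK", ]
  expect_equal(kk$k, 2L)
  expect_equal(kk$K, 13L)
  expect_equal(kk$n, 14L)
  expect_equal(kk$N, 200L)
  expect_equal(kk$p_raw, oracle_hyper_tail(2, 13, 14, 200), tolerance = 1e-12)
  expect_equal(sort(strsplit(kk$hit_symbols, ";")[[1]]), sort(cat_genes[1:2]))
})

test_that("a query equal to a whole category attains the enumeration minimum", {
  universe <- sprintf("U%03d", 1:100)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_symbol = universe[1:10], term_id = "GO:T"),
    tibble::tibble(gene_symbol = universe, term_id = "GO:ALL"))
  rows <- enrich(gene_set(universe[1:10]), ann)
  expect_equal(rows$p_raw[rows$term_id == "GO:T"],
               oracle_hyper_tail(10, 10, 10, 100), tolerance = 1e-12)
})

test_that("a disjoint query warns and returns an empty table", {
  ann <- tibble::tibble(gene_symbol = c("A", "B"), term_id = "T1")
  expect_warning(rows <- enrich(gene_set("ZZZ"), ann), "disjoint")
  expect_equal(nrow(rows), 0)
})

test_that("random queries are enriched at roughly the nominal rate", {
  # type-I behavior: drawing the query uniformly from the universe, the
  # fraction of term tests with p_raw < 0.05 should sit near 0.05
  set.seed(77)
  universe <- sprintf("U%03d", 1:500)
  ann <- dplyr::bind_rows(lapply(1:30, function(i) tibble::tibble(
    gene_symbol = sample(universe, 50), term_id = sprintf("GO:%04d", i))))
  ann <- dplyr::bind_rows(ann, tibble::tibble(gene_symbol = universe,
                                              term_id = "GO:ALL"))
  hits <- 0L; tests <- 0L
  for (rep in 1:40) {
    q <- sample(universe, 50)
    rows <- enrich(gene_set(q), ann, min_k = 0, top = Inf)
    rows <- rows[rows$term_id != "GO:ALL", ]
    hits <- hits + sum(rows$p_raw < 0.05)
    tests <- tests + nrow(rows)
  }
  expect_gt(hits / tests, 0.02)
  expect_lt(hits / tests, 0.08)
})

test_that("ancestor propagation adds counts up the is_a chain when enabled", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: P", "name: parent", "",
               "[Term]", "id: C", "name: child", "is_a: P"), obo)
  ont <- parse_obo(obo)
  ann <- tibble::tibble(gene_symbol = c("A", "B", "C", "D"),
                        term_id = c("C", "C", "P", "P"))
  direct <- enrich(gene_set(c("A", "B")), ann, min_k = 1, ontology = ont)
  expect_false("P" %in% direct$term_id)  # no direct hits: P is not tested
  suppressMessages(
    prop <- enrich(gene_set(c("A", "B")), ann, min_k = 1, ontology = ont,
                   propagate = TRUE))
  expect_equal(prop$K[prop$term_id == "P"], 4L)  # children count for parents
  expect_equal(prop$label[prop$term_id == "P"], "parent")
})
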