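ct_long <- function(sample, group, gene, replicate, ct) {
  tibble::tibble(sample = sample, group = group, gene = gene,
                 replicate = replicate, ct = ct)
}

test_that("replicates collapse to means; spread and missingness are policed", {
  ms <- ct_long(rep("S1", 6), "CAD",
                rep(c("ACTB", "CCR7", "FOXO1"), each = 2),
                rep(1:2, 3),
                c(24.1, 24.3, 30.0, 30.1, 28.0, NA))
  got <- collapse_replicates(ms)
  expect_equal(got$ct[got$gene == "ACTB"], 24.2)
  foxo <- got[got$gene == "FOXO1", ]
  expect_equal(foxo$ct, 28.0)          # single present value used...
  expect_true(foxo$flagged)            # ...but flagged

  wide <- ct_long(rep("S1", 2), "CAD", "EGFR", 1:2, c(25, 27))
  expect_message(got <- collapse_replicates(wide, max_spread = 0.5), "excluded")
  expect_equal(nrow(got), 0)
  expect_match(attr(got, "excluded")$exclusion_reason, "spread")

  allmiss <- ct_long(rep("S1", 2), "CAD", "FOS", 1:2, c(NA_real_, NA_real_))
  expect_message(got <- collapse_replicates(allmiss), "excluded")
  expect_match(attr(got, "excluded")$exclusion_reason, "missing")
})

test_that("read_ct_table accepts Undetermined and enforces the Ct range", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup\tgene\treplicate\tct",
               "S1\tCAD\tccr7\t1\t30.5",
               "S1\tCAD\tccr7\t2\tUndetermined"), p)
  tab <- read_ct_table(p)
  expect_equal(tab$gene, c("CCR7", "CCR7"))
  expect_equal(tab$ct, c(30.5, NA))
  writeLines(c("sample\tgroup\tgene\treplicate\tct",
               "S1\tCAD\tccr7\t1\t50"), p)
  expect_error(read_ct_table(p), class = "counterflow_validation_error")
})

test_that("delta-Ct normalizes to the reference and drops it from output", {
  collapsed <- tibble::tibble(
    sample = c("S1", "S1", "S2", "S2", "S3"),
    group = c("CAD", "CAD", "nonCAD", "nonCAD", "CAD"),
    gene = c("ACTB", "CCR7", "ACTB", "CCR7", "CCR7"),
    ct = c(20, 30, 21, 28, 33), n_replicates = 2L, flagged = FALSE)
  expect_warning(dct <- delta_ct(collapsed, "ACTB"), "S3")
  expect_equal(dct$delta_ct[dct$sample == "S1"], 10)
  expect_equal(dct$delta_ct[dct$sample == "S2"], 7)
  expect_false("ACTB" %in% dct$gene)
  expect_false("S3" %in% dct$sample)
})

test_that("delta-delta-Ct: null case, direction convention, antisymmetry", {
  dct <- tibble::tibble(
    sample = sprintf("S%d", 1:8),
    group = rep(c("CAD", "nonCAD"), each = 4),
    gene = "CCR7",
    delta_ct = c(7, 7.2, 6.8, 7.1, 5, 5.2, 4.9, 5.1))
  rows <- delta_delta_ct(dct, "CAD", "nonCAD")
  # case mean 7.025, control mean 5.05: ddCt ~ +2 => ~4-fold DOWN in case
  expect_equal(rows$delta_delta_ct, 1.975)
  expect_equal(rows$fold_change, 2^-1.975, tolerance = 1e-12)
  expect_equal(rows$log2_fc, -rows$delta_delta_ct)

  swapped <- delta_delta_ct(dct, "nonCAD", "CAD")
  expect_equal(swapped$delta_delta_ct, -rows$delta_delta_ct)
  expect_equal(swapped$fold_change, 1 / rows$fold_change, tolerance = 1e-12)

  ident <- dct
  ident$delta_ct <- rep(c(5, 5.5, 6, 6.5), 2)
  null_rows <- delta_delta_ct(ident, "CAD", "nonCAD")
  expect_equal(null_rows$delta_delta_ct, 0)
  expect_equal(null_rows$fold_change, 1)
})

test_that("per-sample Ct offsets cancel in delta-Ct (normalization invariance)", {
  sim <- simulate_ct_table(seed = 42)
  base <- suppressWarnings(delta_ct(collapse_replicates(sim$table), "ACTB"))
  shifted_tab <- sim$table
  bump <- stats::setNames(seq_along(unique(sim$table$sample)),
                          unique(sim$table$sample))
  shifted_tab$ct <- shifted_tab$ct + bump[shifted_tab$sample]
  shifted <- suppressWarnings(delta_ct(collapse_replicates(shifted_tab), "ACTB"))
  expect_equal(shifted$delta_ct, base$delta_ct, tolerance = 1e-9)
})

test_that("rank-sum exact p matches the published toy example and degenerates safely", {
  ts <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(ts$statistic, 0)
  expect_equal(ts$p_value, 1 / 3, tolerance = 1e-12)  # 2 / choose(4, 2)
  expect_equal(ts$method, "exact")

  same <- rank_sum_test(c(5, 5, 5), c(5, 5))
  expect_equal(same$p_value, 1)
  expect_equal(same$method, "degenerate")

  big <- rank_sum_test(stats::rnorm(12), stats::rnorm(12))
  expect_equal(big$method, "normal-approximation")
  expect_true(big$statistic >= 0 && big$statistic <= 144)
})

test_that("exact mode agrees with full enumeration for all group sizes <= 8", {
  set.seed(19)
  for (nx in 1:8) {
    for (ny in nx:8) {
      x <- stats::rnorm(nx)
      y <- stats::rnorm(ny, mean = sample(c(0, 2), 1))
      ts <- rank_sum_test(x, y, exact_max_n = 16)
      expect_equal(ts$method, "exact")
      expect_equal(ts$p_value, oracle_exact_rank_sum_p(x, y),
                   tolerance = 1e-12,
                   label = sprintf("p at nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("ties fall back to the corrected normal approximation", {
  ts <- rank_sum_test(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_equal(ts$method, "normal-approximation")
  expect_true(ts$tie_corrected)
  expect_true(ts$p_value > 0 && ts$p_value <= 1)
})

test_that("volcano table applies strict alpha and the fold-change-1 tie-break", {
  rows <- tibble::tibble(gene = c("A", "B", "C"),
                         delta_delta_ct = c(2, 0, -1),
                         fold_change = c(0.25, 1, 2),
                         log2_fc = c(-2, 0, 1),
                         p_value = c(0.01, 0.05, 0.2),
                         n_case = 10L, n_control = 12L)
  v <- volcano_table(rows, alpha = 0.05)
  expect_equal(v$significant, c(TRUE, FALSE, FALSE))  # p = alpha is NOT significant
  expect_equal(v$direction, c("down", "down", "up"))  # FC 1 reports down
  expect_equal(v$neg_log10_p[1], 2)
})

test_that("planted Ct shifts are recovered and flagged significant-down", {
  sim <- simulate_ct_table(seed = 7)
  dct <- delta_ct(collapse_replicates(sim$table), "ACTB")
  rows <- delta_delta_ct(dct, "CAD", "nonCAD")
  v <- volcano_table(rows)
  planted <- v$gene %in% sim$planted_genes
  expect_true(all(v$significant[planted]))
  expect_true(all(v$direction[planted] == "down"))
  expect_equal(rows$delta_delta_ct[match(sim$planted_genes, rows$gene)],
               unname(sim$true_ddct), tolerance = 0.5)
})
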