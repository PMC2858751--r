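# Hand-traceable fixture: two genes on chr1 (+), each with an annotated
# primary probe set and an unannotated downstream probe set. GeneA's pair is
# co-expressed; geneB's is independent.
detect_fixture <- function(r_b = NULL, seed = 8, n = 30) {
  set.seed(seed)
  tx <- tx_tbl(c("TA", "TB"), c("geneA", "geneB"), "chr1",
               c(1000, 50000), c(5000, 56000), "+")
  ps <- ps_tbl(c("PA", "XA", "PB", "XB"), "chr1",
               c(4700, 5400, 55700, 56600),
               c(4800, 5500, 55800, 56700), "+")
  ann <- list(PA = "TA", XA = character(0), PB = "TB", XB = character(0))
  shared <- rnorm(n, 9, 2)
  expr <- rbind(PA = shared + rnorm(n, 0, 0.3),
                XA = shared - 0.8 + rnorm(n, 0, 0.3),
                PB = rnorm(n, 9, 2),
                XB = rnorm(n, 8, 2))
  colnames(expr) <- sprintf("s%02d", 1:n)
  list(tx = tx, ps = ps, ann = ann, expr = expr)
}

test_that("the screen recovers a planted pair and drops an uncorrelated one", {
  f <- detect_fixture()
  scr <- detect_extensions(f$tx, f$ps, f$ann, f$expr)
  expect_s3_class(scr, "utrx_screen")
  expect_equal(nrow(scr$predictions), 1)
  expect_equal(scr$predictions$gene_symbol, "geneA")
  expect_equal(scr$predictions$primary_probeset, "PA")
  expect_equal(scr$predictions$extended_probeset, "XA")
  expect_gt(scr$predictions$pearson_r, 0.9)
  expect_equal(scr$predictions$distance_bp, 600)   # 5400 - 4800
  # both pairs visible before the correlation cutoff
  expect_equal(unname(scr$stage_counts["probe_set_pairs"]), 2)
  expect_equal(unname(scr$stage_counts["above_noise"]), 2)
  expect_equal(unname(scr$stage_counts["correlated"]), 1)
  expect_true(all(diff(scr$stage_counts) <= 0))
  expect_equal(unname(scr$stage_counts["genes"]), nrow(scr$predictions))
})

test_that("an empty probe-set table yields an empty funnel", {
  f <- detect_fixture()
  empty <- f$ps[0, , drop = FALSE]
  scr <- detect_extensions(f$tx, empty, list(), f$expr)
  expect_equal(nrow(scr$predictions), 0)
  expect_equal(unname(scr$stage_counts[c("probe_set_pairs", "above_noise",
                                         "correlated", "genes")]),
               c(0L, 0L, 0L, 0L))
})

test_that("a weakly correlated pair is counted pre-cutoff but not predicted", {
  f <- detect_fixture(seed = 13)
  # decorrelate geneA's pair almost entirely (r ~ 0.15)
  set.seed(77)
  f$expr["XA", ] <- 0.3 * scale(f$expr["PA", ])[, 1] + rnorm(30, 8, 2)
  scr <- detect_extensions(f$tx, f$ps, f$ann, f$expr)
  expect_equal(unname(scr$stage_counts["above_noise"]), 2)
  expect_lt(abs(scr$pairs$pearson_r[scr$pairs$gene_symbol == "geneA"]),
            0.6)
  expect_false("geneA" %in% scr$predictions$gene_symbol)
})

test_that("a pair with a missing expression row is dropped with a warning", {
  f <- detect_fixture()
  expr <- f$expr[rownames(f$expr) != "XB", , drop = FALSE]
  expect_warning(scr <- detect_extensions(f$tx, f$ps, f$ann, expr),
                 "missing from expression")
  expect_equal(unname(scr$stage_counts["probe_set_pairs"]), 1)
  expect_equal(scr$dropped$missing_expression, 1)
  expect_equal(scr$predictions$gene_symbol, "geneA")
})

test_that("predictions are invariant under a common sample permutation", {
  f <- detect_fixture()
  scr1 <- detect_extensions(f$tx, f$ps, f$ann, f$expr)
  set.seed(99)
  perm <- sample(ncol(f$expr))
  scr2 <- detect_extensions(f$tx, f$ps, f$ann, f$expr[, perm])
  expect_equal(scr1$predictions, scr2$predictions)
  expect_equal(scr1$pairs$pearson_r, scr2$pairs$pearson_r)
})

test_that("isoforms collapse to one prediction for the most-3' transcript", {
  f <- detect_fixture()
  # second, 3'-shorter isoform of geneA annotated to the same probe set
  tx <- rbind(f$tx, tx_tbl("TA0", "geneA", "chr1", 1000, 4600, "+"))
  ann <- f$ann
  ann$PA <- c("TA", "TA0")
  scr <- detect_extensions(tx, f$ps, ann, f$expr)
  expect_equal(unname(scr$stage_counts["correlated"]), 2) # both isoforms
  expect_equal(nrow(scr$predictions), 1)                  # one per gene
  expect_equal(scr$predictions$transcript_id, "TA")       # most 3'
})

test_that("rescue pairs require a below-noise primary and high correlation", {
  f <- detect_fixture()
  # push geneA's primary below the noise floor, keep correlation
  f$expr["PA", ] <- 4 + 0.15 * scale(f$expr["XA", ])[, 1]
  scr <- detect_extensions(f$tx, f$ps, f$ann, f$expr)
  res <- rescue_low_primary_pairs(scr)
  expect_equal(res$gene_symbol, "geneA")
  expect_gt(res$pearson_r, 0.6)
  # never merged into the main predictions
  expect_false("geneA" %in% scr$predictions$gene_symbol)
  expect_equal(length(intersect(res$transcript_id,
                                scr$predictions$transcript_id)), 0)
})

test_that("pairs with both members above noise never appear in the rescue set", {
  f <- detect_fixture()
  scr <- detect_extensions(f$tx, f$ps, f$ann, f$expr)
  expect_equal(nrow(rescue_low_primary_pairs(scr)), 0)
})
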