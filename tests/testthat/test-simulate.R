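small_cfg <- function(...) {
  synthetic_config(n_genes = 40, rng_seed = 5, ...)
}

test_that("the generator is deterministic and structurally stable", {
  b1 <- simulate_bundle(small_cfg())
  b2 <- simulate_bundle(small_cfg())
  expect_identical(b1$probesets, b2$probesets)
  expect_identical(b1$expr, b2$expr)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$truth, b2$truth)
  # a different seed changes data but not structure
  b3 <- simulate_bundle(synthetic_config(n_genes = 40, rng_seed = 6))
  expect_false(identical(b1$expr, b3$expr))
  expect_identical(dim(b1$expr), dim(b3$expr))
  expect_identical(nrow(b1$probesets), nrow(b3$probesets))
  expect_identical(table(b1$truth$class), table(b3$truth$class))
})

test_that("planted extension counts follow the configured fractions exactly", {
  b0 <- simulate_bundle(synthetic_config(n_genes = 30, rng_seed = 2,
                                         fraction_with_extension = 0,
                                         fraction_rescue = 0))
  expect_equal(sum(b0$truth$class != "decoy"), 0)
  b30 <- simulate_bundle(synthetic_config(n_genes = 100, rng_seed = 2,
                                          fraction_with_extension = 0.3,
                                          fraction_rescue = 0))
  expect_equal(sum(b30$truth$class == "extension"), 30)
})

test_that("samples form 22 tissue blocks of 3-5 replicates totalling 70", {
  b <- simulate_bundle(small_cfg())
  expect_equal(nrow(b$tissues), 70)
  reps <- table(b$tissues$tissue)
  expect_length(reps, 22)
  expect_true(all(reps >= 3 & reps <= 5))
  expect_identical(colnames(b$expr), b$tissues$sample_id)
})

test_that("planted pairs reach the target correlation, decoys stay near zero", {
  b <- simulate_bundle(synthetic_config(n_genes = 120, rng_seed = 9))
  tr <- b$truth
  r_planted <- vapply(which(tr$class == "extension"), function(i)
    cor(b$expr[tr$primary_id[i], ], b$expr[tr$extended_id[i], ]),
    numeric(1))
  expect_gt(mean(r_planted >= 0.8 & r_planted <= 0.97), 0.9)
  expect_equal(median(r_planted), 0.9, tolerance = 0.05)
  r_decoy <- vapply(which(tr$class == "decoy"), function(i)
    cor(b$expr[tr$primary_id[i], ], b$expr[tr$extended_id[i], ]),
    numeric(1))
  expect_lt(abs(mean(r_decoy)), 0.15)
})

test_that("noise-free planted pairs are perfectly correlated", {
  b <- simulate_bundle(synthetic_config(n_genes = 20, rng_seed = 3,
                                        replicate_noise_sd = 0,
                                        planted_pair_correlation = 1))
  tr <- b$truth
  i <- which(tr$class == "extension")[1]
  r <- cor(b$expr[tr$primary_id[i], ], b$expr[tr$extended_id[i], ])
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("an unreachable planted correlation is refused", {
  expect_error(simulate_bundle(synthetic_config(
    n_genes = 10, tissue_effect_sd = 0.3, replicate_noise_sd = 2,
    planted_pair_correlation = 0.9)), "unreachable")
})

test_that("conservation classes hit their configured means", {
  set.seed(1)
  b <- simulate_bundle(synthetic_config(n_genes = 80, rng_seed = 12))
  tr <- b$truth
  planted <- tr[tr$class != "decoy", ]
  regs <- iv(planted$chrom, planted$region_start, planted$region_end,
             planted$strand)
  total_bp <- sum(regs$end - regs$start)
  expect_gt(total_bp, 10000)
  means <- vapply(seq_len(nrow(regs)), function(i)
    mean_conservation(b$track, regs[i, ]), numeric(1))
  wmean <- sum(means * (regs$end - regs$start)) / total_bp
  expect_equal(wmean, 0.26, tolerance = 0.02)
  utr_mean <- mean(vapply(sample(nrow(b$pools$utr), 30), function(i)
    mean_conservation(b$track, b$pools$utr[i, ]), numeric(1)))
  ig_mean <- mean(vapply(sample(nrow(b$pools$intergenic), 30), function(i)
    mean_conservation(b$track, b$pools$intergenic[i, ]), numeric(1)))
  expect_equal(utr_mean, 0.233, tolerance = 0.02)
  expect_equal(ig_mean, 0.124, tolerance = 0.02)
})

test_that("rescue genes have a below-noise primary but expressed extension", {
  b <- simulate_bundle(synthetic_config(n_genes = 100, rng_seed = 4,
                                        fraction_rescue = 0.1))
  tr <- b$truth
  res <- tr[tr$class == "rescue", ]
  expect_gt(nrow(res), 0)
  pri_max <- apply(b$expr[res$primary_id, , drop = FALSE], 1, max)
  ext_max <- apply(b$expr[res$extended_id, , drop = FALSE], 1, max)
  expect_true(all(pri_max <= 6))
  expect_true(all(ext_max > 6))
})

test_that("with tag fraction 1 every planted extension is tag-confirmed", {
  b <- simulate_bundle(synthetic_config(n_genes = 40, rng_seed = 8,
                                        tag_fraction = 1))
  tr <- b$truth
  planted <- tr[tr$class != "decoy", ]
  ps1 <- remove_multimapping(b$probesets)
  conf <- vapply(seq_len(nrow(planted)), function(i) {
    tgt <- ps1[ps1$probeset_id == planted$extended_id[i], , drop = FALSE]
    confirm_by_tags(tgt, b$tags)
  }, logical(1))
  expect_true(all(conf))
  expect_true(all(planted$has_tag))
})

test_that("motif planting enriches polyA hexamers in extension sequence", {
  b <- simulate_bundle(synthetic_config(n_genes = 60, rng_seed = 14,
                                        motif_plant_rate = 10))
  tr <- b$truth
  planted <- tr[tr$class != "decoy", ]
  ext_seq <- extract_region_sequences(
    b$genome, iv(planted$chrom, planted$region_start, planted$region_end,
                 "+"))
  ig_seq <- extract_region_sequences(
    b$genome, iv(b$pools$intergenic$chrom, b$pools$intergenic$start,
                 b$pools$intergenic$end, "+"))
  rate <- function(seqs) {
    hits <- sum(vapply(seqs, function(s)
      o_count_occ(s, "AATAAA"), numeric(1)))
    1000 * hits / sum(nchar(seqs))
  }
  expect_gt(rate(ext_seq), 3 * rate(ig_seq))
})

test_that("end-to-end recovery on a small bundle is near perfect", {
  b <- simulate_bundle(synthetic_config(n_genes = 60, rng_seed = 21))
  scr <- detect_extensions(b$transcripts, b$probesets, b$annotation,
                           b$expr)
  planted <- b$truth$gene_symbol[b$truth$class == "extension"]
  expect_gte(mean(planted %in% scr$predictions$gene_symbol), 0.95)
  decoys <- b$truth$gene_symbol[b$truth$class == "decoy"]
  expect_lte(mean(decoys %in% scr$predictions$gene_symbol), 0.05)
})
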