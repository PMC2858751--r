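test_that("pair distance is the strand-aware gap between facing edges", {
  expect_equal(pair_distance(iv("chr1", 1000, 1025, "+"),
                             iv("chr1", 1200, 1225, "+")), 175)
  expect_equal(pair_distance(iv("chr1", 1200, 1225, "-"),
                             iv("chr1", 1000, 1025, "-")), 175)
  expect_equal(pair_distance(iv("chr1", 1000, 1025, "+"),
                             iv("chr1", 1025, 1050, "+")), 0)  # abutting
  expect_error(pair_distance(iv("chr1", 1000, 1025, "+"),
                             iv("chr1", 900, 925, "+")),
               "not strictly downstream")
  expect_error(pair_distance(iv("chr1", 1000, 1025, "+"),
                             iv("chr2", 1200, 1225, "+")),
               "share chromosome")
})

test_that("extension regions run from the annotated 3' end to the far target edge", {
  tp <- tx_tbl("T", "g", "chr1", 0, 1000, "+")
  r <- extension_region(tp, iv("chr1", 1200, 1225, "+"))
  expect_equal(c(r$start, r$end, r$length), c(1000, 1225, 225))
  tm <- tx_tbl("T", "g", "chr1", 1000, 2000, "-")
  r2 <- extension_region(tm, iv("chr1", 800, 825, "-"))
  expect_equal(c(r2$start, r2$end, r2$length), c(800, 1000, 200))
  expect_error(extension_region(tp, iv("chr1", 900, 1100, "+")),
               "not downstream")
})

test_that("mean conservation averages per base, absent bases scoring 0", {
  tr <- conservation_track("chr1", 0, 100, 0.5)
  expect_equal(mean_conservation(tr, iv("chr1", 0, 100, "+")), 0.5)
  tr2 <- conservation_track(c("chr1", "chr1"), c(0, 50), c(50, 100),
                            c(1, 0))
  expect_equal(mean_conservation(tr2, iv("chr1", 0, 100, "+")), 0.5)
  # 10-bp region, 4 bp scored 0.8, 6 bp absent -> 0.32
  tr3 <- conservation_track("chr1", 3, 7, 0.8)
  expect_equal(mean_conservation(tr3, iv("chr1", 0, 10, "+")), 0.32)
  # region on an unscored chromosome
  expect_equal(mean_conservation(tr3, iv("chr2", 0, 10, "+")), 0)
})

test_that("mean conservation recombines from sub-regions by bp weighting", {
  set.seed(20)
  pos <- 0:499
  tr <- conservation_track("chr1", pos, pos + 1, runif(500))
  for (k in 1:10) {
    a <- sort(sample(0:500, 3))
    if (a[1] == a[2] || a[2] == a[3]) next
    whole <- mean_conservation(tr, iv("chr1", a[1], a[3], "+"))
    left <- mean_conservation(tr, iv("chr1", a[1], a[2], "+"))
    right <- mean_conservation(tr, iv("chr1", a[2], a[3], "+"))
    w <- (a[2] - a[1]) / (a[3] - a[1])
    expect_equal(whole, w * left + (1 - w) * right)
  }
})

test_that("matched random sets honour lengths, totals and determinism", {
  pool <- iv(rep("chr1", 3), c(0, 5000, 9000), c(3000, 7000, 9400), "+")
  lens <- c(250, 400, 120, 400)
  sets <- sample_matched_region_sets(pool, lens, n_sets = 20, seed = 5)
  expect_length(sets, 20)
  for (s in sets) {
    expect_equal(s$end - s$start, lens)
    expect_equal(sum(s$end - s$start), sum(lens))
  }
  sets2 <- sample_matched_region_sets(pool, lens, n_sets = 20, seed = 5)
  expect_identical(sets, sets2)
  # a pool interval of exactly the target length is forced
  one <- iv("chr1", 100, 350, "+")
  forced <- sample_matched_region_sets(one, 250, n_sets = 3, seed = 1)
  expect_true(all(vapply(forced, function(s)
    s$start == 100 && s$end == 350, logical(1))))
  expect_error(sample_matched_region_sets(pool, 5000, n_sets = 2, seed = 1),
               "length >= 5000")
})

test_that("conserved extensions separate sharply from the intergenic null", {
  f <- cons_fixture()
  cmp <- conservation_comparison(f$ext, f$utr_pool, f$ig_pool, f$track,
                                 n_sets = 100, seed = 3)
  expect_gt(cmp$z, 3.72)
  expect_lt(cmp$p, 1e-4)
  expect_length(cmp$utr_set_means, 100)
  expect_length(cmp$intergenic_set_means, 100)
  expect_true(all(cmp$intergenic_set_means >= 0 &
                    cmp$intergenic_set_means <= 1))
  # extension mean sits inside the UTR set range, above the intergenic one
  expect_gt(cmp$ext_mean, max(cmp$intergenic_set_means))
})

test_that("self-draws from the intergenic pool give a small Z", {
  f <- cons_fixture()
  lens <- rep(400, 20)
  self <- sample_matched_region_sets(f$ig_pool, lens, n_sets = 1,
                                     seed = 71)[[1]]
  cmp <- conservation_comparison(self, f$utr_pool, f$ig_pool, f$track,
                                 n_sets = 100, seed = 4)
  expect_lt(abs(cmp$z), 3)
})

test_that("a constant-score track makes the Z undefined", {
  tr <- conservation_track("chr1", 0:999, 1:1000, 0.5)
  pool <- iv("chr1", 0, 1000, "+")
  expect_error(conservation_comparison(iv("chr1", 10, 60, "+"), pool, pool,
                                       tr, n_sets = 10, seed = 1),
               "zero spread")
})

test_that("tag confirmation accepts in-target and downstream 3' ends only", {
  target <- iv("chr1", 5000, 5100, "+")
  inside <- iv("chr1", 5030, 5050, "+")
  upstream <- iv("chr1", 4000, 4020, "+")
  downstream <- iv("chr1", 10050, 10070, "+")
  wrong_strand <- iv("chr1", 5030, 5050, "-")
  expect_true(confirm_by_tags(target, inside))
  expect_false(confirm_by_tags(target, upstream))
  expect_true(confirm_by_tags(target, downstream))  # "even further downstream"
  expect_false(confirm_by_tags(target, wrong_strand))
  expect_false(confirm_by_tags(target, upstream[0, ]))
  # minus strand: downstream means lower coordinates
  targetm <- iv("chr1", 5000, 5100, "-")
  expect_true(confirm_by_tags(targetm, iv("chr1", 1000, 1020, "-")))
  expect_false(confirm_by_tags(targetm, iv("chr1", 8000, 8020, "-")))
})
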