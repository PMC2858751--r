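test_that("the four built-in patterns parse into the expected elements", {
  m <- utrx_motifs()
  expect_named(m, c("c_rich", "au_rich", "cyto_polyA", "mammalian_polyA"))
  cr <- m$c_rich$elements
  expect_equal(vapply(cr, `[[`, character(1), "type"),
               c("word", "gap", "word", "repeat", "word"))
  expect_equal(cr[[2]]$min, 0); expect_equal(cr[[2]]$max, 5)
  expect_equal(cr[[4]]$min, 0); expect_equal(cr[[4]]$max, 4)
  expect_length(m$au_rich$elements, 1)
  expect_length(m$au_rich$elements[[1]]$masks, 9)
  cp <- m$cyto_polyA$elements
  expect_equal(cp[[2]]$min, 1); expect_equal(cp[[2]]$max, 100)
  mp <- m$mammalian_polyA$elements
  expect_equal(mp[[2]]$min, 12); expect_equal(mp[[2]]$max, 40)
  expect_equal(mp[[3]]$subs, 5)
  expect_equal(mp[[3]]$ins, 0); expect_equal(mp[[3]]$del, 0)
  # A(A|U)UAAA: position 2 accepts A or U but not G
  w <- mp[[1]]$masks
  expect_length(w, 6)
  expect_true(bitwAnd(w[2], 1L) > 0)   # A
  expect_true(bitwAnd(w[2], 8L) > 0)   # U
  expect_false(bitwAnd(w[2], 4L) > 0)  # not G
})

test_that("malformed patterns fail with positional diagnostics", {
  expect_error(parse_motif_pattern("ACGJ"), "token 1, position 4")
  expect_error(parse_motif_pattern("[5,0,0] ACG"), "must follow a word")
  expect_error(parse_motif_pattern("AC 5...2 GG"), "min > max")
  expect_error(parse_motif_pattern("A(A|UU)G"), "single IUPAC")
  expect_error(parse_motif_pattern("A(AU G"), "unclosed")
  expect_error(parse_motif_pattern(""), "empty")
})

test_that("scanning matches the worked examples, DNA and RNA alike", {
  m <- utrx_motifs()
  expect_equal(scan_motif("UAUUUAUAA", m$au_rich)$start, 0)
  expect_equal(nrow(scan_motif("UAUUUAUGG", m$au_rich)), 0)  # W excludes G
  expect_equal(scan_motif("TATTTATAA", m$au_rich)$start, 0)  # T == U
  # C-rich: YCCA + gap0 + CCCW + zero Ys + TCYCC
  hit <- scan_motif("CCCACCCAUCUCC", m$c_rich)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(0, 13))
  # mammalian polyA: hexamer + 12-base gap + K-decamer, 0 mismatches
  s <- paste0("AAUAAA", "CCACCACCACCA", "GUGUGUGUGU")
  hit2 <- scan_motif(s, m$mammalian_polyA)
  expect_equal(c(hit2$start[1], hit2$end[1]), c(0, 28))
  # cytoplasmic polyA element needs a gap of at least 1
  expect_equal(nrow(scan_motif("UUUUAUAAUAAA", m$cyto_polyA)), 0)
  expect_equal(scan_motif("UUUUAUCAAUAAA", m$cyto_polyA)$start, 0)
})

test_that("sequence N matches only the pattern symbol N", {
  expect_equal(nrow(scan_motif("NAUUUAUAA", utrx_motifs()$au_rich)), 0)
  p <- parse_motif_pattern("ANG")
  expect_equal(scan_motif("ANG", p)$start, 0)
  expect_equal(scan_motif("ACG", p)$start, 0)
  expect_equal(nrow(scan_motif("NCG", p)), 0)
})

test_that("overlapping matches at distinct starts each count once", {
  hits <- scan_motif("UAUUUAUUUAUAA",
                     parse_motif_pattern("UAUUUAU"))
  expect_equal(hits$start, c(0, 4))
})

test_that("the scanner agrees with the naive enumerator on random sequences", {
  m <- utrx_motifs()
  o <- o_builtin_motifs()
  set.seed(33)
  for (nm in names(m)) {
    for (k in 1:25) {
      s <- random_dna(150)
      got <- scan_motif(s, m[[nm]])$start
      want <- o_motif_starts(s, o[[nm]])
      expect_equal(got, as.integer(want %||% integer(0)),
                   info = paste(nm, "seq", k))
    }
  }
  # enriched alphabet to exercise the edit-budget branch more often
  for (k in 1:25) {
    s <- paste(sample(c("A", "U", "G", "T", "K"), 120, replace = TRUE,
                      prob = c(0.3, 0.25, 0.25, 0.1, 0.1)), collapse = "")
    s <- gsub("K", "G", s)
    got <- scan_motif(s, m$mammalian_polyA)$start
    want <- o_motif_starts(s, o$mammalian_polyA)
    expect_equal(got, as.integer(want %||% integer(0)))
  }
})

test_that("seed sites are typed by the canonical 8mer/7mer hierarchy", {
  # let-7 style seed GAGGUAG: rc = CUACCUC
  r <- count_seed_sites("GGCUACCUCGG", "GAGGUAG")
  expect_equal(unlist(r[, -1], use.names = FALSE), c(0L, 1L, 0L))
  r2 <- count_seed_sites("GGCUACCUCAGG", "GAGGUAG")
  expect_equal(unlist(r2[, -1], use.names = FALSE), c(1L, 0L, 0L))
  # 7mer-A1: UACCUCA without the m8 match C before it
  r3 <- count_seed_sites("GGUACCUCAGG", "GAGGUAG")
  expect_equal(unlist(r3[, -1], use.names = FALSE), c(0L, 0L, 1L))
  expect_equal(sum(count_seed_sites("", "GAGGUAG")[, -1]), 0)
  expect_error(count_seed_sites("ACGU", "GAGG"), "7 bases")
  # DNA spelling of target and seed is equivalent
  r4 <- count_seed_sites("GGCTACCTCAGG", "GAGGTAG")
  expect_equal(unlist(r4[, -1], use.names = FALSE), c(1L, 0L, 0L))
})

test_that("seed-site counts match a sliding-window oracle on random sequences", {
  set.seed(44)
  for (k in 1:10) {
    txt <- chartr("T", "U", random_dna(300))
    seed <- paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE),
                  collapse = "")
    got <- count_seed_sites(txt, seed)
    rc7 <- paste(rev(strsplit(chartr("ACGU", "UGCA", seed), "")[[1]]),
                 collapse = "")
    rc6 <- paste(rev(strsplit(chartr("ACGU", "UGCA",
                                     substr(seed, 1, 6)), "")[[1]]),
                 collapse = "")
    n8 <- o_count_occ(txt, paste0(rc7, "A"))
    expect_equal(got$site_8mer, n8)
    expect_equal(got$site_7mer_m8, o_count_occ(txt, rc7) - n8)
    expect_equal(got$site_7mer_A1, o_count_occ(txt, paste0(rc6, "A")) - n8)
  }
})
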