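# Fixture builders and independent brute-force oracles used across tests.

ps_tbl <- function(id, chrom, start, end, strand) {
  data.frame(probeset_id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

tx_tbl <- function(id, symbol, chrom, start, end, strand) {
  data.frame(transcript_id = id, gene_symbol = symbol, chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

iv <- function(chrom, start, end, strand) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# --- correlation oracles (formula written out, no stats::cor) -------------

o_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# all-unordered-pairs tail fraction among above-noise rows
o_all_pairs_fpr <- function(m, cutoff, threshold = 6) {
  keep <- rownames(m)[apply(m, 1, max) > threshold]
  r <- c()
  for (i in seq_along(keep)) {
    for (j in seq_along(keep)) {
      if (j > i) r <- c(r, o_pearson(m[keep[i], ], m[keep[j], ]))
    }
  }
  list(fpr = mean(r > cutoff), n = length(r))
}

o_cross_chrom_fpr <- function(p, m, locations, cutoff) {
  others <- names(locations)[locations != locations[[p]]]
  others <- others[others %in% rownames(m)]
  r <- vapply(others, function(q) o_pearson(m[p, ], m[q, ]), numeric(1))
  list(fpr = mean(r > cutoff), n = length(r))
}

# --- naive motif-match oracle ---------------------------------------------
# Pattern elements are hand-built lists (independent of the package's
# parser): word  = list(kind="word", sets=list_of_char_vectors, s=, i=, d=)
#          gap   = list(kind="gap", min=, max=)
#          rep   = list(kind="rep", set=chars, min=, max=)
# The oracle enumerates every branch and reports whether ANY full match
# exists at a start position.

o_iupac <- list(
  A = "A", C = "C", G = "G", U = c("U", "T"), T = c("U", "T"),
  M = c("A", "C"), R = c("A", "G"), W = c("A", "U", "T"),
  S = c("C", "G"), Y = c("C", "U", "T"), K = c("G", "U", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "U", "T"),
  D = c("A", "G", "U", "T"), B = c("C", "G", "U", "T"),
  N = c("A", "C", "G", "U", "T", "N")
)

o_word <- function(pattern, s = 0, i = 0, d = 0) {
  list(kind = "word", sets = lapply(strsplit(pattern, "")[[1]],
                                    function(ch) o_iupac[[ch]]),
       s = s, i = i, d = d)
}
o_gap <- function(min, max) list(kind = "gap", min = min, max = max)
o_rep <- function(sym, min, max) list(kind = "rep", set = o_iupac[[sym]],
                                      min = min, max = max)

# can elements els match starting at 1-based position pos?
o_match_at <- function(chars, els, pos) {
  if (length(els) == 0) return(TRUE)
  el <- els[[1]]
  rest <- els[-1]
  n <- length(chars)
  if (el$kind == "gap") {
    for (g in el$min:el$max) {
      if (pos + g - 1 > n) break
      if (o_match_at(chars, rest, pos + g)) return(TRUE)
    }
    return(FALSE)
  }
  if (el$kind == "rep") {
    if (el$min > 1) {
      if (pos + el$min - 2 > n) return(FALSE)
      for (k0 in 1:(el$min - 1)) {
        if (!(chars[pos + k0 - 1] %in% el$set)) return(FALSE)
      }
    }
    for (k in el$min:el$max) {
      if (pos + k - 1 > n) break
      if (k > 0 && !(chars[pos + k - 1] %in% el$set)) break
      if (o_match_at(chars, rest, pos + k)) return(TRUE)
    }
    return(FALSE)
  }
  # word with edit budgets: enumerate all alignments
  w <- function(j, q, s, i, d) {
    if (j > length(el$sets)) return(o_match_at(chars, rest, pos + q))
    if (d > 0 && w(j + 1, q, s, i, d - 1)) return(TRUE)
    if (pos + q <= n) {
      if (chars[pos + q] %in% el$sets[[j]]) {
        if (w(j + 1, q + 1, s, i, d)) return(TRUE)
      } else if (s > 0 && w(j + 1, q + 1, s - 1, i, d)) return(TRUE)
      if (i > 0 && w(j, q + 1, s, i - 1, d)) return(TRUE)
    }
    FALSE
  }
  w(1, 0, el$s, el$i, el$d)
}

# 0-based start positions at which the element list matches
o_motif_starts <- function(seq, els) {
  chars <- strsplit(toupper(seq), "")[[1]]
  hits <- c()
  for (p in seq_along(chars)) {
    if (o_match_at(chars, els, p)) hits <- c(hits, p - 1)
  }
  hits
}

# hand-built element lists for the four built-in motifs
# (A(A|U)UAAA is spelled with IUPAC W at position 2)
o_builtin_motifs <- function() {
  list(
    c_rich = list(o_word("YCCA"), o_gap(0, 5), o_word("CCCW"),
                  o_rep("Y", 0, 4), o_word("TCYCC")),
    au_rich = list(o_word("UAUUUAUWW")),
    cyto_polyA = list(o_word("UUUUAU"), o_gap(1, 100), o_word("AAUAAA")),
    mammalian_polyA = list(o_word("AWUAAA"), o_gap(12, 40),
                           o_word("KKKKKKKKKK", s = 5))
  )
}

# small synthetic conservation landscape mirroring the UTR/intergenic split
cons_fixture <- function(seed = 17) {
  set.seed(seed)
  n_blocks <- 40
  utr_start <- seq(0, by = 5000, length.out = n_blocks)
  ig_start <- utr_start + 2500
  ext_start <- utr_start + 1500
  per_base <- function(starts, len, m) {
    pos <- unlist(lapply(starts, function(s) s:(s + len - 1)))
    data.frame(chrom = "chr1", start = pos, end = pos + 1,
               score = rbeta(length(pos), m * 8, (1 - m) * 8))
  }
  track <- conservation_track(rbind(
    per_base(utr_start, 1200, 0.233),
    per_base(ig_start, 1500, 0.124),
    per_base(ext_start, 600, 0.26)))
  list(track = track,
       utr_pool = iv("chr1", utr_start, utr_start + 1200, "+"),
       ig_pool = iv("chr1", ig_start, ig_start + 1500, "+"),
       ext = iv("chr1", ext_start[1:25], ext_start[1:25] + 600, "+"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sliding-window overlapping occurrence counter (for seed-site checks)
o_count_occ <- function(txt, pat) {
  n <- nchar(txt); k <- nchar(pat)
  if (n < k) return(0)
  hits <- 0
  for (p in 1:(n - k + 1)) {
    if (substr(txt, p, p + k - 1) == pat) hits <- hits + 1
  }
  hits
}
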