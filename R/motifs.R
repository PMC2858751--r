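# Transterm-style motif grammar and scanner, plus microRNA seed-site
# counting. Patterns are sequences of elements:
#   * an IUPAC word, possibly with single-base alternation groups "(A|U)"
#     and an optional trailing mismatch allowance "[s,i,d]" (substitutions,
#     insertions, deletions) that applies to that word only;
#   * a bounded gap "a...b" (also written "a.b" or "a..b") matching any
#     a..b bases;
#   * a bounded repeat "X{a,b}" of one IUPAC symbol.
# RNA and DNA are equivalent (T == U). Scanning is per start position: a
# start matches if some combination of gap lengths, repeat counts and edit
# operations lets the whole pattern match; the shortest such match is
# reported.

# base bitmasks: A=1 C=2 G=4 U/T=8; sequence N is 16 and matches only the
# pattern symbol N (whose mask includes 16)
.IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, M = 3L, R = 5L,
                 W = 9L, S = 6L, Y = 10L, K = 12L, V = 7L, H = 11L,
                 D = 13L, B = 14L, N = 31L)
.SEQ_CODE <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, N = 16L)

encode_sequence <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  code <- .SEQ_CODE[chars]
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop("unrecognized sequence character '", chars[bad], "' at position ",
         bad, call. = FALSE)
  }
  unname(code)
}

parse_word_token <- function(tok, tokno) {
  chars <- strsplit(tok, "", fixed = TRUE)[[1]]
  masks <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- toupper(chars[i])
    if (ch == "(") {
      j <- i
      while (j <= length(chars) && chars[j] != ")") j <- j + 1L
      if (j > length(chars))
        stop("motif parse error: unclosed '(' in token ", tokno, " ('",
             tok, "')", call. = FALSE)
      alts <- strsplit(paste(chars[(i + 1):(j - 1)], collapse = ""),
                       "|", fixed = TRUE)[[1]]
      if (length(alts) < 1 || any(nchar(alts) != 1))
        stop("motif parse error: alternation in token ", tokno,
             " must list single IUPAC symbols", call. = FALSE)
      am <- .IUPAC_MASK[toupper(alts)]
      if (anyNA(am))
        stop("motif parse error: unknown symbol in alternation, token ",
             tokno, call. = FALSE)
      masks <- c(masks, Reduce(bitwOr, am))
      i <- j + 1L
    } else {
      m <- .IUPAC_MASK[ch]
      if (is.na(m))
        stop("motif parse error: unknown IUPAC symbol '", chars[i],
             "' in token ", tokno, ", position ", i, call. = FALSE)
      masks <- c(masks, unname(m))
      i <- i + 1L
    }
  }
  list(type = "word", masks = masks, subs = 0L, ins = 0L, del = 0L,
       text = tok)
}

#' Parse a Transterm-style motif pattern
#'
#' Understands whitespace-separated tokens: IUPAC words with `(X|Y)`
#' alternations, bounded gaps `min...max` (one to three dots), bounded
#' repeats `X{min,max}`, and a mismatch allowance `[s,i,d]` that attaches to
#' the preceding word. DNA and RNA spellings are equivalent.
#'
#' @param text the pattern, e.g. `"UUUUAU 1.100 AAUAAA"`.
#' @param name optional motif name.
#' @return an object of class `motif_pattern`.
#' @examples
#' parse_motif_pattern("YCCA 0...5 CCCW Y{0,4} TCYCC", name = "c_rich")
#' @export
parse_motif_pattern <- function(text, name = NULL) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) == 0) stop("empty motif pattern", call. = FALSE)
  elements <- list()
  for (k in seq_along(toks)) {
    tok <- toks[k]
    if (grepl("^\\[[0-9]+,[0-9]+,[0-9]+\\]$", tok)) {
      nums <- as.integer(strsplit(gsub("[][]", "", tok), ",")[[1]])
      n <- length(elements)
      if (n == 0 || elements[[n]]$type != "word")
        stop("motif parse error: allowance '", tok, "' (token ", k,
             ") must follow a word", call. = FALSE)
      elements[[n]]$subs <- nums[1]
      elements[[n]]$ins <- nums[2]
      elements[[n]]$del <- nums[3]
    } else if (grepl("^[0-9]+\\.{1,3}[0-9]+$", tok)) {
      nums <- as.integer(strsplit(tok, "\\.+")[[1]])
      if (nums[1] > nums[2])
        stop("motif parse error: gap '", tok, "' (token ", k,
             ") has min > max", call. = FALSE)
      elements[[length(elements) + 1]] <-
        list(type = "gap", min = nums[1], max = nums[2], text = tok)
    } else if (grepl("^[A-Za-z]\\{[0-9]+,[0-9]+\\}$", tok)) {
      sym <- toupper(substr(tok, 1, 1))
      m <- .IUPAC_MASK[sym]
      if (is.na(m))
        stop("motif parse error: unknown repeat symbol '", sym,
             "' in token ", k, call. = FALSE)
      nums <- as.integer(strsplit(gsub("^.\\{|\\}$", "", tok), ",")[[1]])
      if (nums[1] > nums[2])
        stop("motif parse error: repeat '", tok, "' (token ", k,
             ") has min > max", call. = FALSE)
      elements[[length(elements) + 1]] <-
        list(type = "repeat", mask = unname(m), min = nums[1],
             max = nums[2], text = tok)
    } else {
      elements[[length(elements) + 1]] <- parse_word_token(tok, k)
    }
  }
  structure(list(elements = elements, text = text,
                 name = name %||% text),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("Motif pattern '%s': %s (%d element(s))\n", x$name, x$text,
              length(x$elements)))
  invisible(x)
}

#' Built-in 3'UTR regulatory motifs
#'
#' The four classic Transterm patterns used for 3'UTR characterization:
#' the C-rich and AU-rich stability elements and the cytoplasmic and
#' mammalian polyadenylation elements (the latter with a 5-substitution
#' allowance on its downstream U/G-rich decamer).
#'
#' @return named list of [parse_motif_pattern()] objects.
#' @export
utrx_motifs <- function() {
  list(
    c_rich = parse_motif_pattern("YCCA 0...5 CCCW Y{0,4} TCYCC",
                                 name = "c_rich"),
    au_rich = parse_motif_pattern("UAUUUAUWW", name = "au_rich"),
    cyto_polyA = parse_motif_pattern("UUUUAU 1.100 AAUAAA",
                                     name = "cyto_polyA"),
    mammalian_polyA = parse_motif_pattern(
      "A(A|U)UAAA 12.40 KKKKKKKKKK [5,0,0]", name = "mammalian_polyA")
  )
}

# all sequence lengths a word can consume starting at pos (1-based),
# within its substitution/insertion/deletion budgets; ascending order
word_match_lengths <- function(enc, L, masks, pos, subs, ins, del) {
  ends <- integer(0)
  k <- length(masks)
  rec <- function(j, q, s, i, d) {
    if (j > k) {
      ends <<- c(ends, q)
      return(invisible())
    }
    if (d > 0L) rec(j + 1L, q, s, i, d - 1L)       # skip pattern symbol
    if (pos + q <= L) {
      hit <- bitwAnd(enc[pos + q], masks[j]) > 0L
      if (hit) rec(j + 1L, q + 1L, s, i, d)
      else if (s > 0L) rec(j + 1L, q + 1L, s - 1L, i, d)
      if (i > 0L) rec(j, q + 1L, s, i - 1L, d)     # extra sequence base
    }
    invisible()
  }
  rec(1L, 0L, subs, ins, del)
  sort(unique(ends))
}

# try to match elements[ei..] at pos (1-based, next base to consume);
# returns the exclusive end position of the shortest match, or -1
match_elements <- function(enc, L, elements, ei, pos) {
  if (ei > length(elements)) return(pos)
  el <- elements[[ei]]
  if (el$type == "word") {
    k <- length(el$masks)
    if (el$subs == 0L && el$ins == 0L && el$del == 0L) {
      if (pos + k - 1L > L) return(-1L)
      idx <- pos:(pos + k - 1L)
      if (all(bitwAnd(enc[idx], el$masks) > 0L))
        return(match_elements(enc, L, elements, ei + 1L, pos + k))
      return(-1L)
    }
    for (cl in word_match_lengths(enc, L, el$masks, pos,
                                  el$subs, el$ins, el$del)) {
      r <- match_elements(enc, L, elements, ei + 1L, pos + cl)
      if (r > 0L) return(r)
    }
    return(-1L)
  }
  if (el$type == "gap") {
    for (g in el$min:el$max) {
      if (pos + g - 1L > L) break
      r <- match_elements(enc, L, elements, ei + 1L, pos + g)
      if (r > 0L) return(r)
    }
    return(-1L)
  }
  # bounded repeat of one symbol
  k <- 0L
  while (k < el$min) {
    if (pos + k > L || bitwAnd(enc[pos + k], el$mask) == 0L) return(-1L)
    k <- k + 1L
  }
  repeat {
    r <- match_elements(enc, L, elements, ei + 1L, pos + k)
    if (r > 0L) return(r)
    if (k >= el$max) return(-1L)
    if (pos + k > L || bitwAnd(enc[pos + k], el$mask) == 0L) return(-1L)
    k <- k + 1L
  }
}

#' Scan a sequence for a motif pattern
#'
#' Reports every start position at which the pattern can match (overlapping
#' matches at distinct starts each count once); per start, the shortest
#' match is reported. `T` and `U` are interchangeable; a sequence `N`
#' matches only the pattern symbol `N`, and gap elements match any bases.
#'
#' @param seq a character string (DNA or RNA) or anything coercible with
#'   `as.character()` (e.g. a `Biostrings` sequence).
#' @param pattern a [parse_motif_pattern()] object or a pattern string.
#' @return data frame of hits with 0-based half-open `start`, `end`.
#' @examples
#' scan_motif("UAUUUAUAA", utrx_motifs()$au_rich)
#' @export
scan_motif <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- parse_motif_pattern(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  enc <- encode_sequence(seq)
  L <- length(enc)
  elements <- pattern$elements
  if (L == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  # vectorized prefilter when the pattern opens with an exact word
  first <- elements[[1]]
  starts <- seq_len(L)
  if (first$type == "word" && first$subs == 0L && first$ins == 0L &&
      first$del == 0L) {
    k <- length(first$masks)
    if (L < k) return(data.frame(start = integer(0), end = integer(0)))
    ok <- rep(TRUE, L - k + 1L)
    for (j in seq_len(k))
      ok <- ok & bitwAnd(enc[j:(L - k + j)], first$masks[j]) > 0L
    starts <- which(ok)
  }
  hits_s <- integer(0)
  hits_e <- integer(0)
  for (s in starts) {
    e <- match_elements(enc, L, elements, 1L, s)
    if (e > 0L) {
      hits_s <- c(hits_s, s - 1L)
      hits_e <- c(hits_e, e - 1L)
    }
  }
  data.frame(start = hits_s, end = hits_e)
}

#' Count motif hits over sets of sequences
#'
#' Convenience wrapper scanning each pattern over each sequence and
#' totalling hit counts and scanned bases — the unit used to compare motif
#' density between region classes (e.g. predicted extensions vs known
#' 3'UTRs vs intergenic sequence).
#'
#' @param seqs character vector of sequences (or `Biostrings` set).
#' @param patterns list of patterns (default [utrx_motifs()]).
#' @return data frame with one row per motif: `motif`, `hits`, `total_bp`,
#'   `hits_per_kbp`.
#' @export
count_motifs <- function(seqs, patterns = utrx_motifs()) {
  seqs <- as.character(seqs)
  total_bp <- sum(nchar(seqs))
  rows <- lapply(names(patterns), function(nm) {
    n <- sum(vapply(seqs, function(s) nrow(scan_motif(s, patterns[[nm]])),
                    numeric(1)))
    data.frame(motif = nm, hits = n, total_bp = total_bp,
               hits_per_kbp = 1000 * n / total_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

rna_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGUT", "UGCAA", toupper(x)), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# overlapping-capable exact occurrence count
count_occurrences <- function(text, pat) {
  n <- nchar(text)
  k <- nchar(pat)
  if (n < k) return(0L)
  tc <- strsplit(text, "", fixed = TRUE)[[1]]
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) ok <- ok & tc[j:(n - k + j)] == pc[j]
  sum(ok)
}

#' Count microRNA seed-match sites in a 3'UTR sequence
#'
#' Seeds are the 7-mers at miRNA positions 2–8 (5'->3'). Site types follow
#' the canonical hierarchy, each occurrence assigned to exactly one type:
#' \describe{
#'   \item{8mer}{exact match to the reverse complement of the full seed,
#'     followed by an A opposite miRNA position 1.}
#'   \item{7mer-m8}{reverse complement of the full seed, not followed by A.}
#'   \item{7mer-A1}{reverse complement of miRNA positions 2–7 followed by
#'     A, not also qualifying as an 8mer.}
#' }
#'
#' @param utr_seq target sequence, 5'->3' (DNA or RNA).
#' @param seeds character vector of 7-base seeds over A/C/G/U (or T).
#' @return data frame with columns `seed`, `site_8mer`, `site_7mer_m8`,
#'   `site_7mer_A1`.
#' @examples
#' count_seed_sites("GGCUACCUCAGG", "GAGGUAG") # let-7 8mer site
#' @export
count_seed_sites <- function(utr_seq, seeds) {
  txt <- chartr("T", "U", toupper(as.character(utr_seq)))
  rows <- lapply(seeds, function(seed) {
    s <- chartr("T", "U", toupper(seed))
    if (nchar(s) != 7 || grepl("[^ACGU]", s))
      stop("seed must be 7 bases over A/C/G/U: '", seed, "'", call. = FALSE)
    rc7 <- rna_revcomp(s)
    site8 <- paste0(rc7, "A")
    siteA1 <- paste0(rna_revcomp(substr(s, 1, 6)), "A")
    n8 <- count_occurrences(txt, site8)
    data.frame(seed = seed,
               site_8mer = n8,
               site_7mer_m8 = count_occurrences(txt, rc7) - n8,
               site_7mer_A1 = count_occurrences(txt, siteA1) - n8,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
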