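# Extension regions, conservation scoring, matched random region sets, the
# conservation Z comparison, and 3'-end tag confirmation.

#' Distance between a primary and an extended probe set target
#'
#' The gap between facing edges in transcript orientation: from the primary
#' target's 3' coordinate to the extended target's 5'-most coordinate. The
#' extended target must not lie upstream of or overlap the primary target;
#' an abutting target gives 0 (such pairs are already excluded by pairing).
#'
#' @param primary_target,extended_target one-row interval data frames on
#'   the same chromosome and strand.
#' @return distance in bp (>= 0).
#' @export
pair_distance <- function(primary_target, extended_target) {
  validate_intervals(primary_target)
  validate_intervals(extended_target)
  if (primary_target$chrom != extended_target$chrom ||
      primary_target$strand != extended_target$strand)
    stop("probe set targets must share chromosome and strand", call. = FALSE)
  d <- if (primary_target$strand == "+") {
    extended_target$start - primary_target$end
  } else {
    primary_target$start - extended_target$end
  }
  if (d < 0)
    stop("extended target is not strictly downstream of the primary target",
         call. = FALSE)
  d
}

#' Extension region of a prediction
#'
#' The genomic region a predicted extension covers: from the transcript's
#' annotated 3' end to the far (3'-most in transcript orientation) edge of
#' the extended probe set target, so the region includes both the
#' inter-probe gap and the target itself.
#'
#' @param transcript one-row transcript table.
#' @param extended_target one-row interval table (the extended probe set's
#'   target), downstream of the transcript's 3' end.
#' @return one-row data frame `chrom`, `start`, `end`, `strand`, `length`.
#' @export
extension_region <- function(transcript, extended_target) {
  validate_intervals(transcript)
  validate_intervals(extended_target)
  if (transcript$chrom != extended_target$chrom)
    stop("extended target on a different chromosome", call. = FALSE)
  if (transcript$strand == "+") {
    if (extended_target$start < transcript$end)
      stop("extended target is not downstream of the transcript 3' end",
           call. = FALSE)
    reg <- data.frame(chrom = transcript$chrom, start = transcript$end,
                      end = extended_target$end, strand = "+",
                      stringsAsFactors = FALSE)
  } else {
    if (extended_target$end > transcript$start)
      stop("extended target is not downstream of the transcript 3' end",
           call. = FALSE)
    reg <- data.frame(chrom = transcript$chrom,
                      start = extended_target$start, end = transcript$start,
                      strand = "-", stringsAsFactors = FALSE)
  }
  reg$length <- reg$end - reg$start
  reg
}

#' Per-base conservation track
#'
#' A sparse per-base score track (e.g. phastCons posterior probabilities in
#' \[0, 1\]), stored as non-overlapping scored runs per chromosome. Bases
#' absent from the track score 0 — for phastCons-style tracks absence means
#' the base was unalignable, and treating it as unconserved is the
#' conservative choice.
#'
#' @param chrom,start,end run coordinates (0-based half-open), or a single
#'   data frame with columns `chrom`, `start`, `end`, `score`.
#' @param score per-run score in \[0, 1\].
#' @return an object of class `utrx_track`.
#' @export
conservation_track <- function(chrom, start = NULL, end = NULL,
                               score = NULL) {
  df <- if (is.data.frame(chrom)) chrom else
    data.frame(chrom = as.character(chrom), start = as.numeric(start),
               end = as.numeric(end), score = as.numeric(score),
               stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(df)))
  if (any(df$start >= df$end)) stop("track runs need start < end",
                                    call. = FALSE)
  if (any(df$score < 0 | df$score > 1))
    stop("conservation scores must lie in [0, 1]", call. = FALSE)
  by_chr <- lapply(split(df[c("start", "end", "score")], df$chrom),
    function(s) {
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping runs in conservation track", call. = FALSE)
      list(start = s$start, end = s$end, score = s$score,
           # cumulative score mass for O(log n) range queries
           cum = cumsum(s$score * (s$end - s$start)))
    })
  structure(list(runs = by_chr), class = "utrx_track")
}

#' @export
print.utrx_track <- function(x, ...) {
  nb <- sum(vapply(x$runs, function(r) sum(r$end - r$start), numeric(1)))
  cat(sprintf("Conservation track: %d chromosome(s), %.0f scored bases\n",
              length(x$runs), nb))
  invisible(x)
}

#' Mean conservation score over a region
#'
#' The per-base average over `[start, end)`; bases without a score in the
#' track contribute 0 to the average.
#'
#' @param track a [conservation_track()].
#' @param region one-row interval data frame (strand is ignored).
#' @return mean score in \[0, 1\].
#' @export
mean_conservation <- function(track, region) {
  stopifnot(inherits(track, "utrx_track"))
  region_conservation_sum(track, region) / (region$end - region$start)
}

# total score mass (score x overlap bp) of the track inside a region
region_conservation_sum <- function(track, region) {
  conservation_sums(track, region$chrom, region$start, region$end)
}

# vectorized score-mass query: runs are sorted and non-overlapping, so the
# mass over [a, b) is a cumulative-sum difference with boundary-run
# truncation corrections
conservation_sums <- function(track, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    r <- track$runs[[ch]]
    if (is.null(r)) next
    sel <- which(chrom == ch)
    a <- start[sel]
    b <- end[sel]
    lo <- findInterval(a, r$end, left.open = TRUE) + 1L
    hi <- findInterval(b - 1e-9, r$start)
    valid <- hi >= lo
    lo_v <- lo[valid]
    hi_v <- hi[valid]
    tot <- r$cum[hi_v] - ifelse(lo_v > 1L, r$cum[lo_v - 1L], 0)
    tot <- tot - pmax(0, a[valid] - r$start[lo_v]) * r$score[lo_v]
    tot <- tot - pmax(0, r$end[hi_v] - b[valid]) * r$score[hi_v]
    out[sel[valid]] <- tot
  }
  out
}

#' Draw length-matched random region sets from a pool
#'
#' For each target length L, one sub-interval of length L is drawn uniformly
#' over all possible placements in pool intervals of length >= L (an
#' interval is chosen with probability proportional to its number of valid
#' start positions, then the offset uniformly). Each of the `n_sets` sets
#' therefore contains exactly the same amount of sequence as the target
#' regions.
#'
#' @param pool data frame of intervals to draw from.
#' @param target_lengths numeric vector of region lengths (bp) to match.
#' @param n_sets number of sets.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list of `n_sets` data frames of intervals.
#' @export
sample_matched_region_sets <- function(pool, target_lengths, n_sets = 100,
                                       seed = 1L) {
  validate_intervals(pool)
  stopifnot(n_sets > 0, all(target_lengths > 0))
  lens <- pool$end - pool$start
  uniq <- sort(unique(target_lengths))
  elig <- lapply(uniq, function(L) {
    idx <- which(lens >= L)
    if (length(idx) == 0)
      stop("no pool interval of length >= ", L, " bp", call. = FALSE)
    list(idx = idx, w = lens[idx] - L + 1)
  })
  names(elig) <- as.character(uniq)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      k <- integer(length(target_lengths))
      off <- integer(length(target_lengths))
      for (L in uniq) {
        e <- elig[[as.character(L)]]
        at <- which(target_lengths == L)
        k[at] <- if (length(e$idx) == 1) rep(e$idx, length(at)) else
          sample(e$idx, length(at), replace = TRUE, prob = e$w)
        off[at] <- floor(runif(length(at)) * (lens[k[at]] - L + 1))
      }
      data.frame(chrom = pool$chrom[k], start = pool$start[k] + off,
                 end = pool$start[k] + off + target_lengths,
                 strand = pool$strand[k], stringsAsFactors = FALSE)
    })
  })
}

# bp-weighted mean conservation over a set of regions
set_mean_conservation <- function(track, regions) {
  sum(conservation_sums(track, regions$chrom, regions$start,
                        regions$end)) /
    sum(regions$end - regions$start)
}

#' Compare extension-region conservation to matched random sets
#'
#' Scores the predicted extension regions (bp-weighted mean conservation)
#' and `n_sets` length-matched random sets drawn from a known-3'UTR pool and
#' from an intergenic pool. The Z-statistic places the extension mean within
#' the intergenic set-mean distribution,
#' `z = (ext_mean - mean(intergenic)) / sd(intergenic)` (sample sd), with a
#' one-sided upper-tail normal p-value: a large z says the extensions are
#' conserved like UTRs, not like intergenic sequence.
#'
#' @param ext_regions data frame of extension regions.
#' @param utr_pool,intergenic_pool interval pools to draw matched sets from.
#' @param track a [conservation_track()].
#' @param n_sets number of matched sets per pool.
#' @param seed integer seed for the set draws.
#' @return object of class `utrx_conservation` with `ext_mean`,
#'   `utr_set_means`, `intergenic_set_means`, `z`, `p`.
#' @export
conservation_comparison <- function(ext_regions, utr_pool, intergenic_pool,
                                    track, n_sets = 100, seed = 1L) {
  validate_intervals(ext_regions)
  stopifnot(inherits(track, "utrx_track"))
  lens <- ext_regions$end - ext_regions$start
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2))
  utr_sets <- sample_matched_region_sets(utr_pool, lens, n_sets, seeds[1])
  ig_sets <- sample_matched_region_sets(intergenic_pool, lens, n_sets,
                                        seeds[2])
  ext_mean <- set_mean_conservation(track, ext_regions)
  utr_means <- vapply(utr_sets, set_mean_conservation, numeric(1),
                      track = track)
  ig_means <- vapply(ig_sets, set_mean_conservation, numeric(1),
                     track = track)
  s <- sd(ig_means)
  if (s == 0)
    stop("intergenic set means have zero spread; Z undefined", call. = FALSE)
  z <- (ext_mean - mean(ig_means)) / s
  structure(list(ext_mean = ext_mean, utr_set_means = utr_means,
                 intergenic_set_means = ig_means, z = z,
                 p = pnorm(z, lower.tail = FALSE), n_sets = n_sets),
            class = "utrx_conservation")
}

#' @export
print.utrx_conservation <- function(x, ...) {
  cat("Conservation of predicted extensions vs matched random sets\n")
  cat(sprintf("  extensions            : mean score %.3f\n", x$ext_mean))
  cat(sprintf("  known 3'UTR sets      : mean %.3f (range %.3f-%.3f)\n",
              mean(x$utr_set_means), min(x$utr_set_means),
              max(x$utr_set_means)))
  cat(sprintf("  intergenic sets       : mean %.3f (range %.3f-%.3f)\n",
              mean(x$intergenic_set_means), min(x$intergenic_set_means),
              max(x$intergenic_set_means)))
  cat(sprintf("  Z vs intergenic       : %.2f (one-sided p %s)\n", x$z,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Confirm a predicted extension with 3'-end sequence tags
#'
#' A prediction is confirmed when some tag on the same strand has its 3'
#' coordinate inside the extended probe set's target region or anywhere
#' downstream of it in transcript orientation (a transcript may well end
#' beyond the probe target).
#'
#' @param extended_target one-row interval table (the extended probe set
#'   target, carrying the transcript's strand).
#' @param tags data frame of tag intervals with strand.
#' @return logical flag.
#' @export
confirm_by_tags <- function(extended_target, tags) {
  validate_intervals(extended_target)
  if (nrow(tags) == 0) return(FALSE)
  validate_intervals(tags)
  same <- tags$chrom == extended_target$chrom &
    tags$strand == extended_target$strand
  if (!any(same)) return(FALSE)
  tag3 <- three_prime_coordinate(tags[same, , drop = FALSE])
  if (extended_target$strand == "+") any(tag3 > extended_target$start)
  else any(tag3 < extended_target$end)
}
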