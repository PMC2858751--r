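# Probe-set / transcript bookkeeping and the strand-aware pairing rules.
#
# A probe-set table has one row per genomic target alignment with columns
# probeset_id, chrom, start, end, strand; multi-mapping probe sets therefore
# occupy several rows. A transcript table has one row per transcript with
# columns transcript_id, gene_symbol, chrom, start, end, strand. The
# annotation table is a named list: probeset_id -> character vector of
# transcript ids (possibly empty = unannotated).

validate_probesets <- function(ps) {
  stopifnot(is.data.frame(ps), "probeset_id" %in% names(ps))
  validate_intervals(ps, "probe set alignment")
  invisible(ps)
}

validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx),
            all(c("transcript_id", "gene_symbol") %in% names(tx)))
  if (anyDuplicated(tx$transcript_id))
    stop("duplicated transcript ids", call. = FALSE)
  validate_intervals(tx, "transcript")
  invisible(tx)
}

validate_annotation <- function(annotation, probesets = NULL) {
  stopifnot(is.list(annotation))
  if (length(annotation) > 0 && is.null(names(annotation)))
    stop("annotation table must be a named list", call. = FALSE)
  if (!is.null(probesets)) {
    unknown <- setdiff(names(annotation), probesets$probeset_id)
    if (length(unknown) > 0) {
      stop("annotation table refers to unknown probe set id(s): ",
           paste(head(unknown, 10), collapse = ", "), call. = FALSE)
    }
  }
  invisible(annotation)
}

#' Drop probe sets that align to multiple genomic locations
#'
#' Probe sets whose sequence targets more than one genomic location cannot be
#' attributed to a single transcript 3' end and are removed before pairing.
#' The operation keeps exactly the probe sets with a single alignment, in the
#' original row order, and is idempotent.
#'
#' @param probesets probe-set alignment table (one row per alignment).
#' @return the subset of rows belonging to uniquely-mapping probe sets.
#' @export
remove_multimapping <- function(probesets) {
  validate_probesets(probesets)
  n <- table(probesets$probeset_id)
  keep <- probesets$probeset_id %in% names(n)[n == 1]
  probesets[keep, , drop = FALSE]
}

#' Select one representative transcript per gene symbol
#'
#' For genes with several transcript isoforms the representative is the one
#' whose annotated 3' end lies most 3' in transcript orientation (maximum
#' `end` on `+`, minimum `start` on `-`). Ties are broken by the
#' lexicographically smallest transcript id. Gene symbols whose transcripts
#' disagree on chromosome or strand are rejected with a warning and yield no
#' representative.
#'
#' @param transcripts transcript table.
#' @return subset of `transcripts`, one row per retained gene symbol.
#' @export
select_representative_transcripts <- function(transcripts) {
  validate_transcripts(transcripts)
  pick <- lapply(split(seq_len(nrow(transcripts)), transcripts$gene_symbol),
    function(idx) {
      sub <- transcripts[idx, , drop = FALSE]
      if (length(unique(sub$chrom)) > 1L || length(unique(sub$strand)) > 1L) {
        warning("gene symbol '", sub$gene_symbol[1],
                "': transcripts on different chromosomes/strands; skipped",
                call. = FALSE)
        return(NULL)
      }
      coord <- three_prime_coordinate(sub)
      # most 3' in transcript orientation
      score <- if (sub$strand[1] == "+") coord else -coord
      idx[order(-score, sub$transcript_id)][1]
    })
  rows <- sort(unlist(pick, use.names = FALSE))
  transcripts[rows, , drop = FALSE]
}

# probe set ids considered "annotated": non-empty entry in the annotation
# table; optionally also any probe set whose target overlaps a transcript
# span on the same strand (by_overlap mode).
annotated_probeset_ids <- function(annotation, probesets = NULL,
                                   transcripts = NULL, by_overlap = FALSE) {
  ids <- names(annotation)[lengths(annotation) > 0]
  if (by_overlap) {
    stopifnot(!is.null(probesets), !is.null(transcripts))
    ov <- vapply(seq_len(nrow(probesets)), function(i) {
      p <- probesets[i, ]
      any(transcripts$chrom == p$chrom & transcripts$strand == p$strand &
            transcripts$start < p$end & p$start < transcripts$end)
    }, logical(1))
    ids <- union(ids, probesets$probeset_id[ov])
  }
  ids
}

# reverse map transcript_id -> character vector of probe set ids
transcripts_to_probesets <- function(annotation) {
  if (length(annotation) == 0) return(list())
  flat <- data.frame(
    ps = rep(names(annotation), lengths(annotation)),
    tx = unlist(annotation, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  lapply(split(flat$ps, flat$tx), unique)
}

#' Find a transcript's primary probe set
#'
#' The primary probe set is the probe set annotated to the transcript whose
#' target region lies most 3' in the transcript's orientation. Ties are
#' broken by the lexicographically smallest probe set id.
#'
#' @param transcript a one-row transcript table.
#' @param annotation named list: probeset id -> transcript ids.
#' @param probesets uniquely-mapping probe-set alignment table.
#' @return the primary probe set id, or `NA_character_` if no probe set is
#'   annotated to the transcript (on its chromosome and strand).
#' @export
find_primary_probeset <- function(transcript, annotation, probesets) {
  stopifnot(nrow(transcript) == 1L)
  validate_probesets(probesets)
  ids <- names(annotation)[vapply(annotation, function(v)
    transcript$transcript_id %in% v, logical(1))]
  cand <- probesets[probesets$probeset_id %in% ids &
                      probesets$chrom == transcript$chrom &
                      probesets$strand == transcript$strand, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  coord <- three_prime_coordinate(cand)
  score <- if (transcript$strand == "+") coord else -coord
  cand$probeset_id[order(-score, cand$probeset_id)][1]
}

#' Find the next downstream unannotated probe set
#'
#' Among uniquely-mapping probe sets on the transcript's chromosome and
#' strand, the candidate is the single nearest one lying strictly downstream
#' of the primary probe set's target: its 5'-most edge (in transcript
#' orientation) must lie beyond the primary target's 3' coordinate, so
#' overlapping or abutting targets are never candidates. If that nearest
#' probe set is annotated to any transcript, the transcript yields no pair
#' (skipping further downstream is deliberately not done). Equal-distance
#' ties are broken by the smallest probe set id.
#'
#' @inheritParams find_primary_probeset
#' @param primary the primary probe set id for `transcript`.
#' @param annotated_ids optional precomputed character vector of probe set
#'   ids considered annotated; defaults to the non-empty entries of
#'   `annotation` (see `by_overlap`).
#' @param by_overlap if `TRUE`, a probe set overlapping any transcript span
#'   on the same strand also counts as annotated; requires `transcripts`.
#' @param transcripts full transcript table (only used with `by_overlap`).
#' @return the candidate ("extended") probe set id, or `NA_character_`.
#' @export
find_downstream_candidate <- function(transcript, primary, probesets,
                                      annotation, annotated_ids = NULL,
                                      by_overlap = FALSE, transcripts = NULL) {
  stopifnot(nrow(transcript) == 1L)
  validate_probesets(probesets)
  pr <- probesets[probesets$probeset_id == primary, , drop = FALSE]
  if (nrow(pr) != 1L)
    stop("primary probe set '", primary, "' not found or not unique",
         call. = FALSE)
  if (is.null(annotated_ids)) {
    annotated_ids <- annotated_probeset_ids(annotation, probesets,
                                            transcripts, by_overlap)
  }
  cand <- probesets[probesets$chrom == transcript$chrom &
                      probesets$strand == transcript$strand &
                      probesets$probeset_id != primary, , drop = FALSE]
  if (transcript$strand == "+") {
    p3 <- pr$end
    cand <- cand[cand$start > p3, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    cand <- cand[order(cand$start, cand$probeset_id), , drop = FALSE]
  } else {
    p3 <- pr$start
    cand <- cand[cand$end < p3, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    cand <- cand[order(-cand$end, cand$probeset_id), , drop = FALSE]
  }
  nearest <- cand$probeset_id[1]
  if (nearest %in% annotated_ids) return(NA_character_)
  nearest
}
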