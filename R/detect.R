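#' Screen for 3' UTR extensions
#'
#' The end-to-end detection pipeline. For every annotated transcript it finds
#' the primary (most-3' annotated) probe set, pairs it with the nearest
#' strictly-downstream co-oriented unannotated probe set, keeps pairs in
#' which both members are expressed above the noise floor, keeps pairs whose
#' expression profiles correlate above the Pearson cutoff, and finally
#' collapses surviving transcripts to one prediction per gene symbol by
#' choosing the isoform whose current annotation extends most 3'. The count
#' of transcripts surviving each stage is recorded.
#'
#' @param transcripts transcript table (`transcript_id`, `gene_symbol`,
#'   `chrom`, `start`, `end`, `strand`; 0-based half-open).
#' @param probesets probe-set alignment table (`probeset_id`, `chrom`,
#'   `start`, `end`, `strand`), one row per alignment.
#' @param annotation named list: probeset id -> character vector of
#'   transcript ids (empty vector = unannotated probe set).
#' @param expr numeric log2 expression matrix, probe sets x samples.
#' @param params a [utrx_params()] object.
#' @return an object of class `utrx_screen` with elements:
#'   \describe{
#'     \item{predictions}{one row per predicted gene: `gene_symbol`,
#'       `transcript_id`, `primary_probeset`, `extended_probeset`,
#'       `pearson_r`, `distance_bp`.}
#'     \item{pairs}{every candidate pair with noise flags and correlation,
#'       including pairs that failed later filters.}
#'     \item{stage_counts}{named vector of transcripts surviving each stage.}
#'   }
#' @seealso [rescue_low_primary_pairs()], [random_pair_null()]
#' @export
detect_extensions <- function(transcripts, probesets, annotation, expr,
                              params = utrx_params()) {
  validate_transcripts(transcripts)
  validate_probesets(probesets)
  validate_annotation(annotation, probesets)
  validate_expression(expr)
  stopifnot(inherits(params, "utrx_params"))

  ps1 <- remove_multimapping(probesets)
  n_multi_removed <- length(unique(probesets$probeset_id)) -
    length(unique(ps1$probeset_id))
  annotation <- annotation[intersect(names(annotation), ps1$probeset_id)]
  ann_ids <- annotated_probeset_ids(
    annotation, ps1, transcripts, by_overlap = params$annotate_by_overlap)
  tx2ps <- transcripts_to_probesets(annotation)

  # index probe sets by chrom/strand once; pairing loops over transcripts
  ps_rows <- split(seq_len(nrow(ps1)),
                   paste(ps1$chrom, ps1$strand, sep = "\r"))
  ps_by_id <- setNames(seq_len(nrow(ps1)), ps1$probeset_id)

  pairs <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    t1 <- transcripts[i, , drop = FALSE]
    cand_ps <- tx2ps[[t1$transcript_id]]
    if (is.null(cand_ps)) next
    sub <- ps1[ps_rows[[paste(t1$chrom, t1$strand, sep = "\r")]], ,
               drop = FALSE]
    pri_rows <- sub[sub$probeset_id %in% cand_ps, , drop = FALSE]
    if (nrow(pri_rows) == 0) next
    coord <- three_prime_coordinate(pri_rows)
    score <- if (t1$strand == "+") coord else -coord
    primary <- pri_rows$probeset_id[order(-score, pri_rows$probeset_id)][1]
    ext <- find_downstream_candidate(t1, primary, sub, annotation,
                                     annotated_ids = ann_ids)
    if (is.na(ext)) next
    pr <- ps1[ps_by_id[[primary]], , drop = FALSE]
    ex <- ps1[ps_by_id[[ext]], , drop = FALSE]
    pairs[[i]] <- data.frame(
      transcript_id = t1$transcript_id, gene_symbol = t1$gene_symbol,
      strand = t1$strand, primary_probeset = primary,
      extended_probeset = ext,
      distance_bp = pair_distance(pr, ex),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(transcript_id = character(), gene_symbol = character(),
                        strand = character(), primary_probeset = character(),
                        extended_probeset = character(),
                        distance_bp = numeric(), stringsAsFactors = FALSE)
  }

  # expression stages
  n_missing_expr <- 0L
  n_zero_var <- 0L
  if (nrow(pairs) > 0) {
    present <- pairs$primary_probeset %in% rownames(expr) &
      pairs$extended_probeset %in% rownames(expr)
    n_missing_expr <- sum(!present)
    if (n_missing_expr > 0) {
      warning(n_missing_expr,
              " pair(s) dropped: probe set missing from expression matrix",
              call. = FALSE)
      pairs <- pairs[present, , drop = FALSE]
    }
  }
  thr <- params$expression_threshold
  if (nrow(pairs) > 0) {
    pmax_ <- apply(expr[pairs$primary_probeset, , drop = FALSE], 1, max)
    emax_ <- apply(expr[pairs$extended_probeset, , drop = FALSE], 1, max)
    pairs$primary_above_noise <- unname(pmax_ > thr)
    pairs$extended_above_noise <- unname(emax_ > thr)
    psd <- apply(expr[pairs$primary_probeset, , drop = FALSE], 1, sd)
    esd <- apply(expr[pairs$extended_probeset, , drop = FALSE], 1, sd)
    ok_var <- psd > 0 & esd > 0
    n_zero_var <- sum(!ok_var)
    if (n_zero_var > 0) {
      message(n_zero_var,
              " pair(s) excluded: zero-variance expression profile")
      pairs <- pairs[ok_var, , drop = FALSE]
    }
    pairs$pearson_r <- vapply(seq_len(nrow(pairs)), function(k) {
      pearson(expr[pairs$primary_probeset[k], ],
              expr[pairs$extended_probeset[k], ])
    }, numeric(1))
  } else {
    pairs$primary_above_noise <- logical(0)
    pairs$extended_above_noise <- logical(0)
    pairs$pearson_r <- numeric(0)
  }

  noise_ok <- pairs$primary_above_noise & pairs$extended_above_noise
  corr_ok <- noise_ok & pairs$pearson_r > params$correlation_cutoff

  # collapse to one prediction per gene symbol
  surv_tx <- transcripts[transcripts$transcript_id %in%
                           pairs$transcript_id[corr_ok], , drop = FALSE]
  rep_tx <- if (nrow(surv_tx) > 0)
    select_representative_transcripts(surv_tx) else surv_tx
  predictions <- pairs[corr_ok & pairs$transcript_id %in%
                         rep_tx$transcript_id,
                       c("gene_symbol", "transcript_id", "primary_probeset",
                         "extended_probeset", "pearson_r", "distance_bp"),
                       drop = FALSE]
  predictions <- predictions[order(predictions$gene_symbol,
                                   predictions$transcript_id), , drop = FALSE]
  rownames(predictions) <- NULL

  stage_counts <- c(
    transcripts = nrow(transcripts),
    probe_set_pairs = nrow(pairs),
    above_noise = sum(noise_ok),
    correlated = sum(corr_ok),
    genes = nrow(predictions)
  )

  structure(list(
    predictions = predictions,
    pairs = pairs,
    stage_counts = stage_counts,
    params = params,
    dropped = list(missing_expression = n_missing_expr,
                   zero_variance = n_zero_var,
                   multimapping_probesets = n_multi_removed)
  ), class = "utrx_screen")
}

#' Rescue pairs whose primary probe set falls below the noise floor
#'
#' When a transcript's real 3' end lies further downstream than annotated,
#' the annotated probe set sits farther from the polyA tail and its signal
#' is attenuated by the 3'-biased labeling protocol — possibly below the
#' noise threshold. This companion screen collects consecutive pairs in
#' which only the downstream member passes the expression criterion while
#' the correlation still exceeds the cutoff. Because the primary profile is
#' noisier, the false-positive rate is higher here, so these pairs are
#' reported separately and never merged into the main predictions.
#'
#' @param x a `utrx_screen` object from [detect_extensions()], or a
#'   transcript table (in which case the remaining arguments are passed to
#'   [detect_extensions()] first).
#' @param ... arguments forwarded to [detect_extensions()].
#' @return data frame of rescue pairs (same columns as `x$pairs`).
#' @export
rescue_low_primary_pairs <- function(x, ...) {
  scr <- if (inherits(x, "utrx_screen")) x else detect_extensions(x, ...)
  p <- scr$pairs
  keep <- !p$primary_above_noise & p$extended_above_noise &
    p$pearson_r > scr$params$correlation_cutoff
  out <- p[keep, , drop = FALSE]
  out <- out[order(out$gene_symbol, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.utrx_screen <- function(x, ...) {
  cat("3'UTR extension screen\n")
  labels <- c(transcripts = "annotated transcripts",
              probe_set_pairs = "with downstream probe set pair",
              above_noise = "both members above noise",
              correlated = sprintf("Pearson r > %g",
                                   x$params$correlation_cutoff),
              genes = "unique gene symbols (predictions)")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-36s %6d\n", labels[[nm]], x$stage_counts[[nm]]))
  }
  invisible(x)
}

#' @method summary utrx_screen
#' @export
summary.utrx_screen <- function(object, ...) {
  print(object)
  if (nrow(object$predictions) > 0) {
    cat("\nPrediction correlations:\n")
    print(summary(object$predictions$pearson_r))
    cat("\nDistance to extended probe set (bp):\n")
    print(summary(object$predictions$distance_bp))
  }
  if (object$dropped$multimapping_probesets > 0)
    cat(sprintf("\n%d multi-mapping probe set(s) removed before pairing\n",
                object$dropped$multimapping_probesets))
  invisible(object)
}

#' Histogram of pair correlations, optionally against a null
#'
#' Plots the distribution of Pearson correlations of all candidate pairs
#' (red) and, when given, of the random-pair null (blue), with the cutoff
#' marked — the standard diagnostic for choosing/validating the cutoff.
#'
#' @param x a `utrx_screen` object.
#' @param null optional `utrx_null` object (from [random_pair_null()]).
#' @param ... passed to [graphics::hist()].
#' @return invisibly, `x`.
#' @method plot utrx_screen
#' @export
plot.utrx_screen <- function(x, null = NULL, ...) {
  r <- x$pairs$pearson_r[x$pairs$primary_above_noise &
                           x$pairs$extended_above_noise]
  breaks <- seq(-1, 1, by = 0.05)
  h <- hist(r, breaks = breaks, plot = FALSE)
  plot(h$mids, h$density, type = "h", col = "red", lwd = 3,
       xlab = "Pearson correlation", ylab = "density",
       main = "Candidate pairs vs random-pair null", ...)
  if (!is.null(null)) {
    hn <- hist(null$r_values, breaks = breaks, plot = FALSE)
    points(hn$mids, hn$density, type = "l", col = "blue", lwd = 2)
    legend("topleft", legend = c("probe set pairs", "random pairs"),
           col = c("red", "blue"), lwd = 2, bty = "n")
  }
  abline(v = x$params$correlation_cutoff, lty = 2)
  invisible(x)
}
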