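#' Screening pipeline parameters
#'
#' Collects the tunable thresholds of the extension screen. Defaults follow
#' standard practice for multi-tissue 3' expression compendia: a log2 signal
#' of 6 (raw 64) as the noise floor, a one-sided Pearson cutoff of 0.6, motif
#' and conservation characterization restricted to extension regions shorter
#' than 1 kb, 100 matched random region sets, and 100,000 random pairs for
#' the empirical null.
#'
#' @param expression_threshold log2 signal units; a probe set is "above
#'   noise" when its maximum over all samples is strictly greater than this.
#' @param correlation_cutoff one-sided Pearson r cutoff (strictly greater).
#' @param motif_max_region_len bp; only extension regions strictly shorter
#'   than this enter motif/conservation characterization.
#' @param n_random_sets number of matched random region sets.
#' @param n_random_pairs number of random probe-set pairs for the null.
#' @param rng_seed integer seed used by the seeded operations.
#' @param annotate_by_overlap logical; if `TRUE`, probe sets overlapping any
#'   transcript span on the same strand are also treated as annotated when
#'   screening downstream candidates.
#' @return an object of class `utrx_params`.
#' @export
utrx_params <- function(expression_threshold = 6,
                        correlation_cutoff = 0.6,
                        motif_max_region_len = 1000,
                        n_random_sets = 100,
                        n_random_pairs = 100000,
                        rng_seed = 1L,
                        annotate_by_overlap = FALSE) {
  stopifnot(is.finite(expression_threshold),
            correlation_cutoff >= -1, correlation_cutoff <= 1,
            motif_max_region_len > 0, n_random_sets > 0, n_random_pairs > 0,
            is.logical(annotate_by_overlap))
  structure(list(
    expression_threshold = expression_threshold,
    correlation_cutoff = correlation_cutoff,
    motif_max_region_len = as.integer(motif_max_region_len),
    n_random_sets = as.integer(n_random_sets),
    n_random_pairs = as.integer(n_random_pairs),
    rng_seed = as.integer(rng_seed),
    annotate_by_overlap = annotate_by_overlap
  ), class = "utrx_params")
}

#' @export
print.utrx_params <- function(x, ...) {
  cat("3'UTR extension screen parameters\n")
  cat(sprintf("  expression threshold : log2 signal > %g\n",
              x$expression_threshold))
  cat(sprintf("  correlation cutoff   : Pearson r > %g (one-sided)\n",
              x$correlation_cutoff))
  cat(sprintf("  motif region length  : < %d bp\n", x$motif_max_region_len))
  cat(sprintf("  random sets / pairs  : %d / %d\n",
              x$n_random_sets, x$n_random_pairs))
  cat(sprintf("  annotate by overlap  : %s\n", x$annotate_by_overlap))
  invisible(x)
}
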