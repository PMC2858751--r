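# Expression-side operations: noise filter, correlation, and the two
# empirical null models for the false-positive rate.

validate_expression <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m))) stop("expression matrix needs row names",
                                 call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicated probe set row ids",
                                       call. = FALSE)
  if (ncol(m) < 2) stop("expression matrix needs >= 2 samples",
                        call. = FALSE)
  if (any(!is.finite(m))) stop("expression matrix has non-finite values",
                               call. = FALSE)
  invisible(m)
}

#' Pearson correlation between two expression profiles
#'
#' The sample product-moment correlation. Zero-variance input is an error,
#' never a silent 0: degenerate profiles must be excluded upstream.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return r in \[-1, 1\].
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero-variance input", call. = FALSE)
  cor(x, y)
}

#' Above-noise expression filter
#'
#' A probe set is considered expressed above the noise floor when its log2
#' signal is strictly greater than `threshold` in at least one sample.
#'
#' @param row numeric vector of log2 signals.
#' @param threshold log2 signal threshold (default 6, i.e. raw signal 64).
#' @return logical flag.
#' @export
above_noise <- function(row, threshold = 6) {
  stopifnot(all(is.finite(row)))
  max(row) > threshold
}

# rows of m eligible for correlation work: above noise (optionally) and with
# nonzero variance. Returns list(ids, n_zero_variance).
eligible_rows <- function(m, threshold, require_above_noise = TRUE) {
  keep <- rownames(m)
  if (require_above_noise) {
    above <- apply(m, 1, max) > threshold
    keep <- keep[above]
  }
  v <- apply(m[keep, , drop = FALSE], 1, sd)
  nzero <- sum(v == 0)
  list(ids = keep[v > 0], n_zero_variance = nzero)
}

# center and scale rows to unit norm so r = rowSums(Z[i,] * Z[j,])
unit_rows <- function(m) {
  c0 <- m - rowMeans(m)
  c0 / sqrt(rowSums(c0^2))
}

new_null_estimate <- function(method, cutoff, fpr, n_comparisons,
                              r_values = NULL, extra = list()) {
  structure(c(list(method = method, cutoff = cutoff, fpr = fpr,
                   n_comparisons = n_comparisons, r_values = r_values),
              extra),
            class = "utrx_null")
}

#' @export
print.utrx_null <- function(x, ...) {
  cat(sprintf("Empirical null (%s): FPR = %.4g%% at r > %g (%d comparisons)\n",
              x$method, 100 * x$fpr, x$cutoff, x$n_comparisons))
  invisible(x)
}

#' Random-pair empirical null for the correlation cutoff
#'
#' Estimates the false-positive rate of the correlation screen as the tail
#' fraction of Pearson correlations between randomly picked probe-set pairs
#' that exceed the cutoff. By default only probe sets expressed above the
#' noise floor are eligible, matching the eligibility rule of the real
#' screen. Pairs are drawn uniformly (a probe set never pairs with itself;
#' the same pair may recur across draws); `exhaustive = TRUE` enumerates all
#' unordered pairs instead, which is the brute-force reference on small
#' matrices.
#'
#' @param m numeric expression matrix, probe sets x samples, with row names.
#' @param n_pairs number of random pairs to draw (ignored when exhaustive).
#' @param cutoff Pearson r cutoff (strict, one-sided).
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @param threshold above-noise threshold (log2 units).
#' @param require_above_noise restrict eligibility to above-noise rows.
#' @param exhaustive enumerate all unordered pairs instead of sampling.
#' @return an object of class `utrx_null` with elements `method`, `cutoff`,
#'   `fpr`, `n_comparisons` and the sampled `r_values`.
#' @export
random_pair_null <- function(m, n_pairs = 100000, cutoff = 0.6, seed = 1L,
                             threshold = 6, require_above_noise = TRUE,
                             exhaustive = FALSE) {
  validate_expression(m)
  el <- eligible_rows(m, threshold, require_above_noise)
  if (el$n_zero_variance > 0)
    message(el$n_zero_variance,
            " zero-variance probe set(s) excluded from the null")
  n <- length(el$ids)
  if (n < 2) stop("fewer than 2 eligible probe sets for the random-pair null",
                  call. = FALSE)
  z <- unit_rows(m[el$ids, , drop = FALSE])
  if (exhaustive) {
    rmat <- tcrossprod(z)
    r <- rmat[upper.tri(rmat)]
  } else {
    stopifnot(n_pairs > 0)
    r <- with_seed(seed, {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n - 1L, n_pairs, replace = TRUE)
      j <- j + (j >= i)
      rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE])
    })
  }
  new_null_estimate("random_pair", cutoff, mean(r > cutoff), length(r),
                    r_values = r,
                    extra = list(n_eligible = n,
                                 n_zero_variance = el$n_zero_variance,
                                 exhaustive = exhaustive))
}

#' Cross-chromosome per-probe-set false-positive rate
#'
#' Correlates one probe set's expression profile against every
#' uniquely-mapping probe set located on a different chromosome. Under the
#' (stringent) assumption that a transcript never extends across
#' chromosomes, any correlation above the cutoff in this comparison is a
#' false positive, so the tail fraction estimates the per-probe-set FPR.
#'
#' @param probeset_id the probe set to evaluate.
#' @param m expression matrix (probe sets x samples).
#' @param locations named character vector mapping uniquely-mapping probe
#'   set ids to their chromosome.
#' @param cutoff Pearson r cutoff (strict).
#' @return an object of class `utrx_null`.
#' @export
cross_chromosome_fpr <- function(probeset_id, m, locations, cutoff = 0.6) {
  validate_expression(m)
  if (!probeset_id %in% rownames(m) || !probeset_id %in% names(locations))
    stop("probe set '", probeset_id, "' not present in matrix and locations",
         call. = FALSE)
  own <- locations[[probeset_id]]
  others <- names(locations)[locations != own]
  others <- intersect(others, rownames(m))
  if (length(others) > 0) {
    v <- apply(m[others, , drop = FALSE], 1, sd)
    others <- others[v > 0]
  }
  if (length(others) == 0)
    stop("no eligible comparison probe sets on other chromosomes",
         call. = FALSE)
  x <- as.numeric(m[probeset_id, ])
  if (sd(x) == 0) stop("undefined correlation: zero-variance input",
                       call. = FALSE)
  r <- as.numeric(cor(x, t(m[others, , drop = FALSE])))
  new_null_estimate("cross_chromosome", cutoff, mean(r > cutoff), length(r),
                    r_values = r, extra = list(probeset_id = probeset_id))
}

#' Expected number of false positives among the predictions
#'
#' `floor(n_predictions * fpr)`: with 845 predictions and the two null
#' estimates of 1.84% and 2.18% this yields the 15–18 false-positive range.
#'
#' @param n_predictions number of predictions.
#' @param fpr estimated false-positive rate in \[0, 1\].
#' @return integer count.
#' @examples
#' expected_false_positives(845, 0.0184) # 15
#' expected_false_positives(845, 0.0218) # 18
#' @export
expected_false_positives <- function(n_predictions, fpr) {
  stopifnot(n_predictions >= 0, fpr >= 0, fpr <= 1)
  as.integer(floor(n_predictions * fpr))
}
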