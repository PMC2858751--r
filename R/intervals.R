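#' Build a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand`, using 0-based half-open coordinates. The Unicode minus sign is
#' normalized to ASCII `-`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`, half-open.
#' @param strand character vector of `"+"` or `"-"`.
#' @return a data frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200, "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = normalize_strand(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

normalize_strand <- function(strand) {
  s <- chartr("−", "-", as.character(strand))
  bad <- !(s %in% c("+", "-"))
  if (any(bad)) {
    stop("invalid strand symbol(s): ",
         paste(unique(s[bad]), collapse = ", "), call. = FALSE)
  }
  s
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop(what, ": non-finite coordinates", call. = FALSE)
  if (any(df$start < 0))
    stop(what, ": negative start coordinate", call. = FALSE)
  if (any(df$start >= df$end))
    stop(what, ": start must be < end (0-based half-open)", call. = FALSE)
  normalize_strand(df$strand)
  invisible(df)
}

#' Strand-aware 3' and 5' coordinates of intervals
#'
#' With half-open coordinates the 3' coordinate of an interval is its `end`
#' on the `+` strand and its `start` on the `-` strand; the 5' coordinate is
#' the opposite edge.
#'
#' @param iv a data frame of intervals (see [genomic_intervals()]).
#' @return numeric vector of coordinates, one per row of `iv`.
#' @examples
#' three_prime_coordinate(genomic_intervals("chr1", 100, 200, "+")) # 200
#' three_prime_coordinate(genomic_intervals("chr1", 100, 200, "-")) # 100
#' @export
three_prime_coordinate <- function(iv) {
  validate_intervals(iv)
  ifelse(iv$strand == "+", iv$end, iv$start)
}

#' @rdname three_prime_coordinate
#' @export
five_prime_coordinate <- function(iv) {
  validate_intervals(iv)
  ifelse(iv$strand == "+", iv$start, iv$end)
}
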