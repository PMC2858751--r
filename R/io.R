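# Readers/writers for the interchange formats and bundle assembly.
# BED semantics (0-based half-open) are preserved bit-for-bit; BED12,
# bedGraph, WIG and GTF go through rtracklayer, FASTA through Biostrings.
# BED6 is read with a validating tabular reader so malformed lines can be
# reported with their line number.

read_bed6 <- function(path, what = "feature") {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 6)
    stop(path, ": expected BED6 (6+ columns), got ", ncol(df),
         call. = FALSE)
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                 start >= end)
  if (length(bad) > 0)
    stop(path, " line ", bad[1], ": invalid ", what,
         " interval (need 0 <= start < end)", call. = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = start, end = end,
             name = as.character(df[[4]]),
             strand = normalize_strand(df[[6]]), stringsAsFactors = FALSE)
}

#' Read probe-set target alignments from BED6
#'
#' One line per alignment; the BED name field is the probe set id, so
#' multi-mapping probe sets occupy several lines.
#'
#' @param path BED6 file.
#' @return probe-set alignment table.
#' @export
read_probesets <- function(path) {
  b <- read_bed6(path, "probe set alignment")
  data.frame(probeset_id = b$name, chrom = b$chrom, start = b$start,
             end = b$end, strand = b$strand, stringsAsFactors = FALSE)
}

#' Read 3'-end tag intervals from BED6
#' @param path BED6 file of tag alignments (strand required).
#' @return tag interval table.
#' @export
read_tags <- function(path) {
  b <- read_bed6(path, "tag")
  data.frame(chrom = b$chrom, start = b$start, end = b$end,
             strand = b$strand, tag_id = b$name, stringsAsFactors = FALSE)
}

#' Read transcript models
#'
#' BED12 (name = transcript id) with a 2-column id->symbol TSV, or GTF with
#' `transcript_id` / `gene_name` attributes.
#'
#' @param path BED12 or GTF file (by extension: `.gtf`/`.gff` = GTF).
#' @param symbols_path 2-column TSV (transcript id, gene symbol); required
#'   for BED12 input.
#' @return transcript table.
#' @export
read_transcripts <- function(path, symbols_path = NULL) {
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[gr$type == "transcript"]
    tx <- data.frame(transcript_id = gr$transcript_id,
                     gene_symbol = gr$gene_name,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1,
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    tx <- data.frame(transcript_id = gr$name,
                     gene_symbol = NA_character_,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1,
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     stringsAsFactors = FALSE)
    if (is.null(symbols_path))
      stop("BED12 transcripts need a transcript->symbol TSV", call. = FALSE)
    sym <- read.delim(symbols_path, header = FALSE,
                      stringsAsFactors = FALSE)
    map <- setNames(as.character(sym[[2]]), as.character(sym[[1]]))
    missing <- setdiff(tx$transcript_id, names(map))
    if (length(missing) > 0)
      stop(symbols_path, ": no gene symbol for transcript id(s): ",
           paste(head(missing, 10), collapse = ", "), call. = FALSE)
    tx$gene_symbol <- unname(map[tx$transcript_id])
  }
  validate_transcripts(tx)
  tx
}

#' Read the probe-set annotation table
#'
#' 2-column TSV: probe set id, comma-separated transcript ids (empty second
#' field = unannotated probe set).
#'
#' @param path TSV file.
#' @return named list probeset id -> character vector of transcript ids.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  vals <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(p[2])) character(0)
    else strsplit(p[2], ",", fixed = TRUE)[[1]]
  })
  setNames(vals, ids)
}

#' Read a log2 expression matrix
#'
#' TSV with a header row of sample ids; first column = probe set id.
#'
#' @param path TSV file.
#' @return numeric matrix, probe sets x samples.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric expression values",
                           call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  validate_expression(m)
  m
}

#' Read the sample-to-tissue map (2-column TSV with header)
#' @param path TSV file with columns `sample_id`, `tissue`.
#' @return data frame.
#' @export
read_tissues <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "tissue") %in% names(df)))
  df
}

#' Read a per-base conservation track (bedGraph or fixed-step WIG)
#' @param path file; `.wig` is read as WIG, anything else as bedGraph.
#' @return a [conservation_track()].
#' @export
read_track <- function(path) {
  fmt <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) "WIG"
  else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  conservation_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    score = gr$score, stringsAsFactors = FALSE))
}

#' Load a full input bundle from a directory
#'
#' Expects the file layout written by [write_bundle()]: `probesets.bed`,
#' `transcripts.bed12`, `symbols.tsv`, `annotation.tsv`, `expr.tsv`,
#' `tissues.tsv` and optionally `cons.bedGraph`, `genome.fa`, `tags.bed`,
#' `truth.tsv`. Cross-references are validated: annotation keys must be
#' known probe sets and tissue-map samples must match the matrix.
#'
#' @param dir directory path.
#' @return object of class `utrx_bundle`.
#' @export
load_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  probesets <- read_probesets(p("probesets.bed"))
  transcripts <- read_transcripts(p("transcripts.bed12"), p("symbols.tsv"))
  annotation <- read_annotation(p("annotation.tsv"))
  validate_annotation(annotation, probesets)
  expr <- read_expression(p("expr.tsv"))
  tissues <- read_tissues(p("tissues.tsv"))
  if (!identical(tissues$sample_id, colnames(expr)))
    stop("tissue map samples do not match expression matrix columns",
         call. = FALSE)
  out <- list(probesets = probesets, transcripts = transcripts,
              annotation = annotation, expr = expr, tissues = tissues)
  if (file.exists(p("cons.bedGraph"))) out$track <- read_track(p("cons.bedGraph"))
  if (file.exists(p("genome.fa")))
    out$genome <- Biostrings::readDNAStringSet(p("genome.fa"))
  if (file.exists(p("tags.bed"))) out$tags <- read_tags(p("tags.bed"))
  if (file.exists(p("truth.tsv")))
    out$truth <- read.delim(p("truth.tsv"), stringsAsFactors = FALSE)
  if (file.exists(p("pools.tsv"))) {
    pools <- read.delim(p("pools.tsv"), stringsAsFactors = FALSE)
    out$pools <- split(pools[c("chrom", "start", "end", "strand")],
                       pools$pool)
  }
  structure(out, class = "utrx_bundle")
}

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path, col.names = TRUE) {
  old <- options(scipen = 15)   # never write coordinates in E notation
  on.exit(options(old))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
}

#' Write a synthetic bundle to a directory of interchange files
#'
#' Writes `probesets.bed`, `transcripts.bed12`, `symbols.tsv`,
#' `annotation.tsv`, `expr.tsv`, `tissues.tsv`, `cons.bedGraph`,
#' `genome.fa`, `tags.bed`, `truth.tsv`, `pools.tsv` and `config.yaml`.
#' Numeric values are serialized at full precision so a load/write cycle is
#' lossless and byte-reproducible.
#'
#' @param bundle a `utrx_bundle` (from [simulate_bundle()] or
#'   [load_bundle()]).
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  ps <- bundle$probesets
  write_tsv(data.frame(ps$chrom, ps$start, ps$end, ps$probeset_id, 0,
                       ps$strand), p("probesets.bed"), col.names = FALSE)
  tx <- bundle$transcripts
  len <- tx$end - tx$start
  write_tsv(data.frame(tx$chrom, tx$start, tx$end, tx$transcript_id, 0,
                       tx$strand, tx$start, tx$end, 0, 1,
                       paste0(len, ","), "0,"),
            p("transcripts.bed12"), col.names = FALSE)
  write_tsv(data.frame(tx$transcript_id, tx$gene_symbol), p("symbols.tsv"),
            col.names = FALSE)
  ann <- bundle$annotation
  writeLines(paste0(names(ann), "\t",
                    vapply(ann, paste, character(1), collapse = ",")),
             p("annotation.tsv"))
  em <- bundle$expr
  edf <- data.frame(probeset_id = rownames(em),
                    matrix(fmt_num(em), nrow = nrow(em),
                           dimnames = list(NULL, colnames(em))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(edf, p("expr.tsv"))
  write_tsv(bundle$tissues, p("tissues.tsv"))
  if (!is.null(bundle$track)) {
    runs <- do.call(rbind, lapply(names(bundle$track$runs), function(ch) {
      r <- bundle$track$runs[[ch]]
      data.frame(chrom = ch, start = r$start, end = r$end,
                 score = fmt_num(r$score), stringsAsFactors = FALSE)
    }))
    write_tsv(runs, p("cons.bedGraph"), col.names = FALSE)
  }
  if (!is.null(bundle$genome))
    Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  if (!is.null(bundle$tags) && nrow(bundle$tags) > 0) {
    tg <- bundle$tags
    write_tsv(data.frame(tg$chrom, tg$start, tg$end, tg$tag_id, 0,
                         tg$strand), p("tags.bed"), col.names = FALSE)
  }
  if (!is.null(bundle$truth)) write_tsv(bundle$truth, p("truth.tsv"))
  if (!is.null(bundle$pools)) {
    pools <- do.call(rbind, lapply(names(bundle$pools), function(nm)
      cbind(pool = nm, bundle$pools[[nm]])))
    write_tsv(pools, p("pools.tsv"))
  }
  if (!is.null(bundle$config))
    yaml::write_yaml(unclass(bundle$config), p("config.yaml"))
  invisible(dir)
}

#' Write predictions and stage counts
#'
#' Deterministic output: rows ordered by gene symbol then transcript id,
#' correlations serialized with 6 decimals. A companion file records the
#' count of transcripts surviving each pipeline stage.
#'
#' @param screen a `utrx_screen` from [detect_extensions()].
#' @param path output TSV for the predictions.
#' @param counts_path optional TSV for the stage counts.
#' @return invisibly, `path`.
#' @export
write_predictions <- function(screen, path, counts_path = NULL) {
  stopifnot(inherits(screen, "utrx_screen"))
  pred <- screen$predictions
  pred <- pred[order(pred$gene_symbol, pred$transcript_id), , drop = FALSE]
  out <- data.frame(gene_symbol = pred$gene_symbol,
                    transcript_id = pred$transcript_id,
                    primary_probeset = pred$primary_probeset,
                    extended_probeset = pred$extended_probeset,
                    pearson_r = sprintf("%.6f", pred$pearson_r),
                    distance_bp = pred$distance_bp,
                    stringsAsFactors = FALSE)
  if (nrow(pred) == 0) out <- out[0, , drop = FALSE]
  write_tsv(out, path)
  if (!is.null(counts_path)) {
    write_tsv(data.frame(stage = names(screen$stage_counts),
                         count = as.integer(screen$stage_counts)),
              counts_path)
  }
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#' @param path TSV file.
#' @return data frame of predictions.
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0) df$pearson_r <- as.numeric(df$pearson_r)
  df
}

#' Write a machine-readable run manifest
#'
#' Records parameters, seed and input-file checksums so a run can be
#' reproduced bit-for-bit.
#'
#' @param path output JSON path.
#' @param params named list (or `utrx_params`) of run parameters.
#' @param inputs character vector of input file paths to checksum.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(path, params, inputs = character(0)) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "utrx",
    version = as.character(utils::packageVersion("utrx")),
    parameters = unclass(params),
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Strand-aware region sequences from a genome
#'
#' Extracts each region's sequence, reverse-complemented for `-` strand
#' regions so sequences read 5'->3' in transcript orientation.
#'
#' @param genome a `Biostrings::DNAStringSet` keyed by chromosome.
#' @param regions interval data frame.
#' @return character vector of sequences.
#' @export
extract_region_sequences <- function(genome, regions) {
  validate_intervals(regions)
  vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    s <- Biostrings::subseq(genome[[r$chrom]], start = r$start + 1,
                            end = r$end)
    if (r$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
}
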