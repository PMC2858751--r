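# Synthetic multi-tissue expression bundles with planted 3'UTR extensions.
# The generator emulates the structure of a 3' expression array compendium:
# tissue-replicate sample blocks, an above-noise log2 signal floor, planted
# correlated probe-set pairs downstream of a subset of genes, decoy
# downstream probe sets with independent profiles, a conservation track
# whose per-base score distribution differs between UTR, extension and
# intergenic sequence, random genomic sequence with optional planted
# motifs, and 3'-end tags at a fraction of planted extension ends.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate a 70-array compendium over 22 tissues with 3–5
#' replicates per tissue, planted pair correlation 0.9, a log2 noise floor
#' at 6, and per-base conservation means of 0.233 (known 3'UTR), 0.26
#' (planted extension) and 0.124 (intergenic).
#'
#' @param n_genes number of simulated genes.
#' @param fraction_with_extension fraction of genes with a planted,
#'   co-expressed downstream probe set (a true 3'UTR extension).
#' @param fraction_rescue fraction of genes whose planted extension has an
#'   attenuated primary probe set (below the noise floor) — detectable only
#'   by the rescue screen.
#' @param fraction_isoforms fraction of genes carrying a second, 3'-shorter
#'   transcript isoform.
#' @param n_tissues,n_samples tissue count and total sample count; samples
#'   are distributed 3–5 replicates per tissue.
#' @param tissue_effect_sd,replicate_noise_sd log2-scale standard
#'   deviations of the shared per-tissue effect and the residual noise.
#' @param planted_pair_correlation target Pearson correlation of planted
#'   pairs; the shared tissue component of the extended member is rescaled
#'   so the expected sample correlation equals this value.
#' @param background_signal_mean,background_signal_sd log2-scale baseline
#'   distribution of expressed genes.
#' @param utr_conservation_mean,intergenic_conservation_mean,extension_conservation_mean
#'   per-base conservation score means (beta-distributed, in \[0, 1\]).
#' @param conservation_concentration beta concentration (a+b) of per-base
#'   scores; larger = tighter around the class mean.
#' @param motif_plant_rate expected planted polyA-signal motifs per kbp of
#'   extension sequence (0 = none; motif content then matches intergenic
#'   background).
#' @param tag_fraction fraction of planted extensions that receive a
#'   confirming 3'-end tag.
#' @param n_multimapping number of decoy multi-mapping probe sets.
#' @param utr_len annotated 3'UTR length (bp).
#' @param rng_seed integer seed; the full bundle is deterministic given it.
#' @return object of class `utrx_sim_config`.
#' @export
synthetic_config <- function(n_genes = 200,
                             fraction_with_extension = 0.3,
                             fraction_rescue = 0.05,
                             fraction_isoforms = 0.1,
                             n_tissues = 22,
                             n_samples = 70,
                             tissue_effect_sd = 1.5,
                             replicate_noise_sd = 0.5,
                             planted_pair_correlation = 0.9,
                             background_signal_mean = 8,
                             background_signal_sd = 1,
                             utr_conservation_mean = 0.233,
                             intergenic_conservation_mean = 0.124,
                             extension_conservation_mean = 0.26,
                             conservation_concentration = 8,
                             motif_plant_rate = 0,
                             tag_fraction = 0.4,
                             n_multimapping = 6,
                             utr_len = 1200,
                             rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              fraction_with_extension = fraction_with_extension,
              fraction_rescue = fraction_rescue,
              fraction_isoforms = fraction_isoforms,
              n_tissues = as.integer(n_tissues),
              n_samples = as.integer(n_samples),
              tissue_effect_sd = tissue_effect_sd,
              replicate_noise_sd = replicate_noise_sd,
              planted_pair_correlation = planted_pair_correlation,
              background_signal_mean = background_signal_mean,
              background_signal_sd = background_signal_sd,
              utr_conservation_mean = utr_conservation_mean,
              intergenic_conservation_mean = intergenic_conservation_mean,
              extension_conservation_mean = extension_conservation_mean,
              conservation_concentration = conservation_concentration,
              motif_plant_rate = motif_plant_rate,
              tag_fraction = tag_fraction,
              n_multimapping = as.integer(n_multimapping),
              utr_len = as.integer(utr_len),
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_tissues > 0,
              fraction_with_extension >= 0, fraction_with_extension <= 1,
              fraction_rescue >= 0, fraction_rescue <= 1,
              fraction_isoforms >= 0, fraction_isoforms <= 1,
              tissue_effect_sd >= 0, replicate_noise_sd >= 0,
              planted_pair_correlation >= 0, planted_pair_correlation <= 1,
              utr_conservation_mean > 0, utr_conservation_mean < 1,
              intergenic_conservation_mean > 0,
              intergenic_conservation_mean < 1,
              extension_conservation_mean > 0,
              extension_conservation_mean < 1,
              motif_plant_rate >= 0, tag_fraction >= 0, tag_fraction <= 1,
              n_samples >= 3 * n_tissues, n_samples <= 5 * n_tissues)
  })
  structure(cfg, class = "utrx_sim_config")
}

# scale factor alpha on the shared tissue component of the extended member
# so that cor(T + e1, alpha*T + e2) has expectation r
solve_shared_scale <- function(r, sd_tissue, sd_noise) {
  if (r == 0) return(0)
  if (sd_noise == 0) return(1)       # noise-free: any alpha > 0 gives r = 1
  if (r == 1)
    stop("planted correlation 1 requires replicate_noise_sd = 0",
         call. = FALSE)
  vt <- sd_tissue^2
  ve <- sd_noise^2
  den <- vt^2 - r^2 * vt * (vt + ve)
  if (den <= 0)
    stop("planted correlation ", r, " unreachable with tissue sd ",
         sd_tissue, " and noise sd ", sd_noise, call. = FALSE)
  sqrt(r^2 * ve * (vt + ve) / den)
}

# gene geometry: one slot per gene holding transcript, downstream zone for
# the extension target, and an intergenic block; minus-strand genes are the
# mirror image within the slot
sim_geometry <- function(cfg) {
  n <- cfg$n_genes
  per_chrom <- 55L
  gene_chrom <- sprintf("chrS%d", (seq_len(n) - 1L) %/% per_chrom + 1L)
  glen <- round(runif(n, 2000, 6000))
  down_zone <- 4000L
  ig_block <- 3000L
  spacer <- 500L
  slot <- glen + down_zone + ig_block + spacer
  start <- numeric(n)
  for (ch in unique(gene_chrom)) {
    idx <- which(gene_chrom == ch)
    start[idx] <- 1000 + cumsum(c(0, slot[idx][-length(idx)]))
  }

  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_ext <- round(n * cfg$fraction_with_extension)
  n_res <- round(n * cfg$fraction_rescue)
  class <- sample(c(rep("extension", n_ext), rep("rescue", n_res),
                    rep("decoy", n - n_ext - n_res)))
  gap <- round(ifelse(runif(n) < 0.8, runif(n, 100, 800),
                      runif(n, 1000, 2800)))
  target_len <- 100L

  g <- data.frame(gene_symbol = sprintf("Gene%04d", seq_len(n)),
                  transcript_id = sprintf("TX%04d", seq_len(n)),
                  chrom = gene_chrom, strand = strand, class = class,
                  stringsAsFactors = FALSE)
  plus <- strand == "+"
  # transcript span
  g$tx_start <- ifelse(plus, start, start + ig_block + down_zone)
  g$tx_end <- g$tx_start + glen
  end3 <- ifelse(plus, g$tx_end, g$tx_start)       # annotated 3' end
  # primary probe target inside the annotated 3'UTR
  g$pri_start <- ifelse(plus, g$tx_end - 300, g$tx_start + 200)
  g$pri_end <- g$pri_start + target_len
  # downstream (extension/decoy) probe target
  g$ext_start <- ifelse(plus, end3 + gap, end3 - gap - target_len)
  g$ext_end <- g$ext_start + target_len
  # planted extension region: annotated 3' end -> far edge of target
  g$region_start <- ifelse(plus, end3, g$ext_start)
  g$region_end <- ifelse(plus, g$ext_end, end3)
  # annotated 3'UTR interval and intergenic pool block
  g$utr_start <- ifelse(plus, g$tx_end - cfg$utr_len, g$tx_start)
  g$utr_end <- g$utr_start + cfg$utr_len
  g$ig_start <- ifelse(plus, g$tx_end + down_zone, start)
  g$ig_end <- g$ig_start + 1500L
  g$distance_bp <- gap
  g$primary_id <- sprintf("PSP%04d", seq_len(n))
  g$extended_id <- sprintf("PSX%04d", seq_len(n))
  g
}

sim_transcripts <- function(g, cfg) {
  tx <- data.frame(transcript_id = g$transcript_id,
                   gene_symbol = g$gene_symbol, chrom = g$chrom,
                   start = g$tx_start, end = g$tx_end, strand = g$strand,
                   stringsAsFactors = FALSE)
  n_iso <- round(cfg$n_genes * cfg$fraction_isoforms)
  if (n_iso > 0) {
    pick <- sort(sample(cfg$n_genes, n_iso))
    iso <- tx[pick, , drop = FALSE]
    iso$transcript_id <- paste0(iso$transcript_id, "b")
    plus <- iso$strand == "+"
    iso$end <- ifelse(plus, iso$end - 300, iso$end)
    iso$start <- ifelse(plus, iso$start, iso$start + 300)
    tx <- rbind(tx, iso)
  }
  tx <- tx[order(tx$transcript_id), , drop = FALSE]
  rownames(tx) <- NULL
  tx
}

sim_probesets <- function(g, tx, cfg) {
  ps <- rbind(
    data.frame(probeset_id = g$primary_id, chrom = g$chrom,
               start = g$pri_start, end = g$pri_end, strand = g$strand,
               stringsAsFactors = FALSE),
    data.frame(probeset_id = g$extended_id, chrom = g$chrom,
               start = g$ext_start, end = g$ext_end, strand = g$strand,
               stringsAsFactors = FALSE)
  )
  if (cfg$n_multimapping > 0) {
    host <- sample(cfg$n_genes, 2 * cfg$n_multimapping, replace = TRUE)
    mm <- data.frame(
      probeset_id = rep(sprintf("PSM%03d", seq_len(cfg$n_multimapping)),
                        each = 2),
      chrom = g$chrom[host],
      start = g$ig_end[host] + 200 + round(runif(2 * cfg$n_multimapping,
                                                 0, 800)),
      end = NA_real_,
      strand = sample(c("+", "-"), 2 * cfg$n_multimapping, replace = TRUE),
      stringsAsFactors = FALSE)
    mm$end <- mm$start + 100
    ps <- rbind(ps, mm)
  }
  ps <- ps[order(ps$probeset_id, ps$chrom, ps$start), , drop = FALSE]
  rownames(ps) <- NULL
  ps
}

sim_annotation <- function(g, tx, ps) {
  ann <- setNames(vector("list", length(unique(ps$probeset_id))),
                  sort(unique(ps$probeset_id)))
  ann[] <- list(character(0))
  by_gene <- split(tx$transcript_id, tx$gene_symbol)
  for (i in seq_len(nrow(g)))
    ann[[g$primary_id[i]]] <- sort(by_gene[[g$gene_symbol[i]]])
  ann
}

sim_tissue_map <- function(cfg) {
  reps <- rep(3L, cfg$n_tissues)
  extra <- cfg$n_samples - sum(reps)
  if (extra > 0) {
    add <- rep(seq_len(cfg$n_tissues), length.out = extra)
    for (t in add) reps[t] <- reps[t] + 1L
  }
  tissue <- rep(sprintf("tissue%02d", seq_len(cfg$n_tissues)), reps)
  data.frame(sample_id = sprintf("S%03d", seq_along(tissue)),
             tissue = tissue, stringsAsFactors = FALSE)
}

#' Simulated expression matrix for a planted-truth geometry
#'
#' Every probe set's profile is a gene-level per-tissue effect (shared by
#' all replicates of a tissue) plus a probe-set baseline offset and
#' replicate noise. Planted pairs share the tissue effect (the extended
#' member's copy rescaled so the expected pair correlation equals the
#' configured target) and differ by a consistent additive offset, emulating
#' the 3' labeling-efficiency shift; decoy downstream probe sets draw
#' independent tissue effects. Rescue-class primaries get an attenuated,
#' low-baseline profile that stays below the noise floor.
#'
#' @param truth geometry/truth table from [simulate_bundle()] (its `truth`
#'   element) or from the internal geometry generator.
#' @param cfg a [synthetic_config()].
#' @param tissues optional tissue map (regenerated from `cfg` if missing).
#' @return list with `expr` (matrix) and `tissues` (sample map).
#' @export
simulate_expression <- function(truth, cfg, tissues = NULL) {
  stopifnot(inherits(cfg, "utrx_sim_config"))
  tissues <- tissues %||% sim_tissue_map(cfg)
  nt <- cfg$n_tissues
  tix <- as.integer(factor(tissues$tissue,
                           levels = sprintf("tissue%02d", seq_len(nt))))
  ns <- nrow(tissues)
  st <- cfg$tissue_effect_sd
  se <- cfg$replicate_noise_sd
  alpha <- solve_shared_scale(cfg$planted_pair_correlation, st,
                              if (se == 0) 0 else se)
  n <- nrow(truth)
  rows <- vector("list", 2L * n)
  ids <- character(2L * n)
  for (i in seq_len(n)) {
    Tg <- rnorm(nt, 0, st)[tix]
    b <- rnorm(1, cfg$background_signal_mean, cfg$background_signal_sd)
    cls <- truth$class[i]
    if (cls %in% c("extension", "rescue")) {
      shift <- runif(1, 0.3, 1.2)
      if (cls == "rescue") {
        # attenuated primary: weak baseline + damped tissue effect
        bp <- rnorm(1, 4, 0.3)
        x <- bp + 0.25 * Tg + rnorm(ns, 0, 0.25)
      } else {
        x <- b + Tg + rnorm(ns, 0, se)
      }
      y <- (b - shift) + alpha * Tg + rnorm(ns, 0, se)
    } else {
      x <- b + Tg + rnorm(ns, 0, se)
      Td <- rnorm(nt, 0, st)[tix]
      bd <- rnorm(1, cfg$background_signal_mean - 0.5,
                  cfg$background_signal_sd)
      y <- bd + Td + rnorm(ns, 0, se)
    }
    rows[[2L * i - 1L]] <- x
    rows[[2L * i]] <- y
    ids[2L * i - 1L] <- truth$primary_id[i]
    ids[2L * i] <- truth$extended_id[i]
  }
  expr <- do.call(rbind, rows)
  rownames(expr) <- ids
  colnames(expr) <- tissues$sample_id
  if (cfg$n_multimapping > 0) {
    mm <- t(vapply(seq_len(cfg$n_multimapping), function(i) {
      rnorm(1, cfg$background_signal_mean, cfg$background_signal_sd) +
        rnorm(nt, 0, st)[tix] + rnorm(ns, 0, se)
    }, numeric(ns)))
    rownames(mm) <- sprintf("PSM%03d", seq_len(cfg$n_multimapping))
    colnames(mm) <- tissues$sample_id
    expr <- rbind(expr, mm)
  }
  list(expr = expr, tissues = tissues)
}

# per-base beta scores with class-specific means over UTR / extension /
# intergenic intervals
sim_conservation <- function(g, cfg) {
  conc <- cfg$conservation_concentration
  draw <- function(chrom, start, end, m) {
    n <- sum(end - start)
    pos <- unlist(lapply(seq_along(start), function(i)
      seq.int(start[i], end[i] - 1L)), use.names = FALSE)
    data.frame(chrom = rep(chrom, end - start), start = pos,
               end = pos + 1, score = rbeta(n, m * conc, (1 - m) * conc),
               stringsAsFactors = FALSE)
  }
  planted <- g$class %in% c("extension", "rescue")
  parts <- list(
    draw(g$chrom, g$utr_start, g$utr_end, cfg$utr_conservation_mean),
    draw(g$chrom, g$ig_start, g$ig_end,
         cfg$intergenic_conservation_mean)
  )
  if (any(planted)) {
    parts[[3]] <- draw(g$chrom[planted], g$region_start[planted],
                       g$region_end[planted],
                       cfg$extension_conservation_mean)
  }
  conservation_track(do.call(rbind, parts))
}

sim_genome <- function(g, cfg) {
  lens <- vapply(split(pmax(g$tx_end, g$ig_end, g$ext_end), g$chrom), max,
                 numeric(1)) + 1000
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  if (cfg$motif_plant_rate > 0) {
    planted <- which(g$class %in% c("extension", "rescue"))
    for (i in planted) {
      L <- g$region_end[i] - g$region_start[i]
      k <- rpois(1, cfg$motif_plant_rate * L / 1000)
      if (k == 0) next
      pos <- g$region_start[i] +
        sort(sample.int(max(L - 6L, 1L), min(k, max(L %/% 12L, 1L))))
      s <- seqs[[g$chrom[i]]]
      for (p in pos) substr(s, p + 1, p + 6) <- "AATAAA"
      seqs[[g$chrom[i]]] <- s
    }
  }
  Biostrings::DNAStringSet(seqs)
}

sim_tags <- function(g, cfg) {
  planted <- which(g$class %in% c("extension", "rescue"))
  take <- planted[runif(length(planted)) < cfg$tag_fraction]
  if (length(take) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      tag_id = character(), stringsAsFactors = FALSE))
  off <- round(runif(length(take), 10, 250))
  plus <- g$strand[take] == "+"
  end3 <- ifelse(plus, g$ext_start[take] + off, g$ext_end[take] - off)
  tags <- data.frame(chrom = g$chrom[take],
                     start = ifelse(plus, end3 - 20, end3),
                     end = ifelse(plus, end3, end3 + 20),
                     strand = g$strand[take],
                     tag_id = sprintf("tag%04d", seq_along(take)),
                     stringsAsFactors = FALSE)
  list(tags = tags, genes = g$gene_symbol[take])
}

#' Generate a complete synthetic input bundle with planted truth
#'
#' Builds non-overlapping gene models on synthetic chromosomes, an
#' annotated primary probe set in each gene's 3'UTR, an unannotated
#' downstream probe set per gene (co-expressed for extension genes,
#' independent decoy otherwise), decoy multi-mapping probe sets, the
#' multi-tissue expression matrix, the per-base conservation track, random
#' genome sequence, 3'-end tags, and the ground-truth table. Everything is
#' deterministic given `cfg$rng_seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `utrx_bundle`: a list with `probesets`,
#'   `transcripts`, `annotation`, `expr`, `tissues`, `track`, `genome`,
#'   `tags`, `truth`, `pools` (the 3'UTR and intergenic interval pools) and
#'   `config`.
#' @export
simulate_bundle <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "utrx_sim_config"))
  with_seed(cfg$rng_seed, {
    g <- sim_geometry(cfg)
    tx <- sim_transcripts(g, cfg)
    ps <- sim_probesets(g, tx, cfg)
    ann <- sim_annotation(g, tx, ps)
    tissues <- sim_tissue_map(cfg)
    ex <- simulate_expression(g, cfg, tissues)
    track <- sim_conservation(g, cfg)
    genome <- sim_genome(g, cfg)
    tg <- sim_tags(g, cfg)
    truth <- data.frame(
      gene_symbol = g$gene_symbol, class = g$class, chrom = g$chrom,
      strand = g$strand, transcript_id = g$transcript_id,
      primary_id = g$primary_id, extended_id = g$extended_id,
      distance_bp = g$distance_bp, region_start = g$region_start,
      region_end = g$region_end,
      planted_r = ifelse(g$class == "decoy", 0,
                         cfg$planted_pair_correlation),
      has_tag = if (is.data.frame(tg)) FALSE else
        g$gene_symbol %in% tg$genes,
      stringsAsFactors = FALSE)
    pools <- list(
      utr = data.frame(chrom = g$chrom, start = g$utr_start,
                       end = g$utr_end, strand = g$strand,
                       stringsAsFactors = FALSE),
      intergenic = data.frame(chrom = g$chrom, start = g$ig_start,
                              end = g$ig_end, strand = g$strand,
                              stringsAsFactors = FALSE))
    structure(list(probesets = ps, transcripts = tx, annotation = ann,
                   expr = ex$expr, tissues = ex$tissues, track = track,
                   genome = genome,
                   tags = if (is.data.frame(tg)) tg else tg$tags,
                   truth = truth, pools = pools, config = cfg),
              class = "utrx_bundle")
  })
}

#' @export
print.utrx_bundle <- function(x, ...) {
  cat(sprintf(paste0("Synthetic 3' expression bundle: %d genes, ",
                     "%d probe set alignments, %d x %d expression matrix\n"),
              length(unique(x$transcripts$gene_symbol)), nrow(x$probesets),
              nrow(x$expr), ncol(x$expr)))
  if (!is.null(x$truth))
    print(table(x$truth$class))
  invisible(x)
}
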