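---
title: "Screening 3' expression arrays for 3'UTR extensions"
author: "utrx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening 3' expression arrays for 3'UTR extensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrx)
```

## The problem and the model

3' expression arrays (Affymetrix-style) summarize ~11 probe pairs into one
probe set per transcript target, and because the labeling protocol primes
from the polyA tail, probe sets were designed against transcript 3' ends as
known from EST evidence. Annotation has moved on: many probe sets that were
intergenic at design time actually sit inside 3' untranslated regions (UTRs)
that extend beyond the annotated transcript end. When such an unannotated
probe set is located immediately downstream of a gene, on the same strand,
and its expression profile across many tissues tracks the gene's most-3'
annotated probe set, the parsimonious explanation is a 3'UTR extension that
covers both targets.

`detect_extensions()` implements that inference as a filtering funnel:

1. discard probe sets with multiple genomic alignments (their signal cannot
   be attributed to one locus);
2. per transcript, find the *primary* probe set — the annotated probe set
   whose target is most 3' in transcript orientation;
3. pair it with the single nearest strictly-downstream, co-oriented,
   unannotated probe set (if that nearest probe set is annotated to any
   transcript, the transcript yields no pair — we deliberately do not skip
   further downstream, because the biological question is about the probe
   set adjacent to the gene);
4. require both members to exceed the noise floor (log2 signal > 6 in at
   least one array, strict);
5. require the Pearson correlation of the two profiles over all samples to
   exceed 0.6 (strict, one-sided — anti-correlation is not evidence of a
   shared transcript);
6. collapse transcript-level survivors to one prediction per gene symbol,
   keeping the isoform whose annotation already extends most 3'.

The count surviving each stage is recorded (`stage_counts`), because the
funnel shape itself is a diagnostic: a collapse between stages 4 and 5
indicates noisy profiles rather than absent extensions.

Because correlation is computed over all samples, the screen requires broad
multi-tissue designs; extensions used in only a few tissues are expected to
be missed. That is a sensitivity limitation, not a specificity one.

## False-positive rates instead of per-pair p-values

The screen controls errors with two empirical nulls rather than
per-correlation tests:

* **Random-pair null** (`random_pair_null()`): Pearson correlations of
  randomly drawn pairs of above-noise probe sets. The fraction of the null
  above the cutoff estimates the screen's false-positive rate. The
  eligibility rule (above-noise only) matches the real screen, since that
  is the population candidates are drawn from. 100,000 seeded draws by
  default; an exhaustive mode enumerates all pairs and is the brute-force
  reference the test suite compares against.
* **Cross-chromosome null** (`cross_chromosome_fpr()`): a per-probe-set
  rate, from correlating one profile against every uniquely-mapping probe
  set on *other* chromosomes, under the stringent assumption that a
  transcript never spans chromosomes, so every exceedance is a false
  positive.

`expected_false_positives(n, fpr)` converts a rate into an expected count
with `floor()` — the conservative integer bound for "how many of these
predictions should I distrust".

Profiles with zero variance are excluded from pairing and from both nulls
(with a logged count) rather than silently scored 0: an undefined
correlation is an eligibility problem, not evidence.

### The rescue screen

An extension moves the true polyA tail away from the annotated probe set,
attenuating its signal (labeling efficiency decays with distance from the
tail). Pairs in which only the downstream member clears the noise floor
while the correlation still exceeds the cutoff are therefore collected by
`rescue_low_primary_pairs()` — but kept strictly separate from the main
predictions, because a below-noise primary profile is dominated by noise
and its correlations are less trustworthy.

## Characterizing predicted extensions

**Conservation.** A real UTR extension should be conserved like a UTR, not
like intergenic sequence. `conservation_comparison()` scores the predicted
extension regions (bp-weighted mean of a per-base track, e.g. phastCons)
and 100 length-matched random region sets drawn from a known-3'UTR pool and
an intergenic pool. Matching is per region length (hence equal totals per
set); intervals are chosen with probability proportional to their number of
valid placements, so every possible sub-interval is equally likely. The
extension mean is placed in the intergenic set-mean distribution with a
normal Z-statistic (sample sd, n−1) and a one-sided upper-tail p-value.
Bases absent from the track score 0: per-base conservation tracks omit
unalignable bases, and treating absence as non-conservation is the
conservative choice. A constant track makes the Z undefined and is an
error, not a 0.

The *extension region* runs from the annotated 3' end to the far (3'-most)
edge of the extended probe set target, so it contains both the inter-probe
gap and the target itself. Regions of 1 kb or more are excluded from
characterization (strict `< 1000` bp): long gaps increasingly reflect
spliced-out intronic sequence or unrelated downstream transcription, which
would dilute both conservation and motif signals.

**Motifs.** `scan_motif()` evaluates Transterm-style patterns — IUPAC words
with single-base alternations, bounded gaps (`a...b`), bounded single-symbol
repeats (`X{a,b}`), and a per-word mismatch allowance `[s,i,d]` read as
substitutions / insertions / deletions, applied only to the word it
follows. Four classic 3'UTR elements ship built in (`utrx_motifs()`): the
C-rich and AU-rich stability elements and the cytoplasmic and mammalian
polyadenylation elements. Matching is per start position: a start counts
once no matter how many gap/edit combinations realize it, and the shortest
realization is reported. `T` and `U` are interchangeable; an `N` in the
sequence matches only the pattern symbol `N`. The scanner is validated
against a naive enumerator that tries every gap length, repeat count and
edit alignment.

**microRNA seed sites.** `count_seed_sites()` counts canonical seed
matches for 7-mer seeds (miRNA positions 2–8) with the standard hierarchy —
8mer > 7mer-m8 > 7mer-A1, each genomic occurrence assigned to exactly one
type. No conservation weighting or context scoring is applied; the counts
are a composition descriptor, not a target prediction.

**3'-end tags.** `confirm_by_tags()` accepts a prediction when any
same-strand tag has its 3' coordinate inside the extended probe set target
or anywhere downstream of it in transcript orientation (transcripts may end
beyond the probe target). Note the downstream clause is unbounded: in dense
gene neighbourhoods a tag belonging to a downstream gene can also satisfy
it, so the confirmation rate is an upper bound.

## The synthetic data generator

`simulate_bundle()` produces a complete, structurally faithful input bundle
with known truth, so the whole pipeline is testable without external data.
It emulates a 70-array compendium over 22 tissues with 3–5 replicates per
tissue — the canonical shape of public multi-tissue 3' expression sets —
with:

* non-overlapping gene models on synthetic chromosomes, each with an
  annotated primary probe set inside its 3'UTR and an unannotated
  downstream probe set (planted co-expressed pair for extension genes,
  independent decoy otherwise), plus multi-mapping decoy probe sets;
* expression built from a shared per-gene, per-tissue latent effect
  (log2-scale sd 1.5) plus replicate noise (sd 0.5) and a constant
  probe-set offset. Planted pairs share the latent effect, with the
  extended member's copy rescaled so the *expected* sample correlation
  equals the configured target (0.9 by default; with the default sds the
  scale factor is exactly 1). Sharing a latent effect rather than copying
  profiles keeps the random-pair null realistically heavy-tailed, because
  replicates of one tissue are correlated across all genes;
* a "rescue" class (5% of genes by default) whose primary probe set has a
  weak baseline and damped tissue effect, staying below the noise floor
  while still correlating with its extension;
* per-base conservation drawn from beta distributions with means 0.233
  (known UTR), 0.26 (planted extension) and 0.124 (intergenic) and
  concentration 8 — values typical of placental-mammal phastCons averages
  for these region classes. Scores are i.i.d. per base; real conservation
  is spatially autocorrelated, which the matched-set comparison does not
  require but which makes synthetic set-mean spreads narrower (and Z
  values larger) than on real tracks;
* random genomic sequence, with polyA hexamers optionally planted in
  extensions (`motif_plant_rate`, default 0 — so by default extension,
  UTR and intergenic sequence are compositionally indistinguishable, and
  motif counts cannot separate them);
* 3'-end tags at a configurable fraction of planted extension ends
  (default 0.4).

The annotated 3'UTRs are 1200 bp, so the known-UTR pool can always supply
length-matched draws for sub-kilobase extension regions. Everything is
deterministic given `rng_seed`; changing only the seed changes data but no
structural counts.

What passing tests on this generator do **not** show: robustness to
cross-hybridization, GC and probe-affinity effects, RMA artefacts,
tissue-specific 3'UTR length variation, or spatially structured
conservation. The generator is a contract check for the algorithmic
pipeline, not a biological benchmark.

## Numerical and design choices

* Coordinates are 0-based half-open (BED) throughout; the 3' coordinate of
  an interval is `end` on `+` and `start` on `-`.
* All threshold comparisons are strict (`> 6`, `r > 0.6`, region
  `< 1000` bp).
* Ties (equal 3' coordinates, equal distances) are broken by
  lexicographically smallest id, making every output deterministic.
* A candidate probe set overlapping or abutting the primary target is not
  "strictly downstream" and is ignored; distances are gaps between facing
  edges, so an abutting pair would have distance 0.
* "Annotated" means a non-empty entry in the annotation table; an optional
  overlap mode additionally treats any probe set overlapping a transcript
  span on the same strand as annotated. A between-lying probe set annotated
  to a *different* gene blocks the pair (the transcript is dropped) rather
  than being skipped — the conservative reading of "the next downstream
  probe set".
* The random-pair null draws from above-noise rows only; the
  cross-chromosome null uses all uniquely-mapping rows. Both rules are
  explicit arguments.
* Seeds: every stochastic operation takes a seed and restores the caller's
  RNG state; composite operations derive sub-seeds below 2^31.
* Output files are byte-reproducible: fixed row order (gene symbol, then
  transcript id), correlations at 6 decimals, coordinates never in
  scientific notation, full-precision (`%.17g`) serialization for values
  that must round-trip losslessly.

## Problem sizes used in the validation suite

The test suite runs the full screen on 200-gene bundles (70 samples),
oracle comparisons on matrices of up to 20 probe sets and sequences of up
to 200 bp, 100 matched random sets per conservation comparison with 100
self-draw replicates for Z calibration, and 100,000-draw (or exhaustive)
nulls. These sizes give stable statistics while keeping the suite quick to
run on a laptop.

## A worked run

```{r example}
bundle <- simulate_bundle(synthetic_config(n_genes = 100, rng_seed = 7))
screen <- detect_extensions(bundle$transcripts, bundle$probesets,
                            bundle$annotation, bundle$expr)
screen
head(screen$predictions, 3)
null <- random_pair_null(bundle$expr, n_pairs = 20000, seed = 7)
null
expected_false_positives(nrow(screen$predictions), null$fpr)
```

```{r conservation}
regions <- prediction_regions(screen$predictions, bundle$transcripts,
                              bundle$probesets)
conservation_comparison(regions[regions$length < 1000, ],
                        bundle$pools$utr, bundle$pools$intergenic,
                        bundle$track, n_sets = 100, seed = 7)
```
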