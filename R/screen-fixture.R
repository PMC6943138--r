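# Synthetic two-cell-line methylation screen fixture with planted truth.
# Emulates the shape of real WGBS methylomes overlaid on a cohort of
# i-motif forming sequences: sequences on a toy chromosome, per-cytosine
# beta values for two cell lines, and per-sequence transitional pH values.

#' Generate a synthetic methylation-screen fixture
#'
#' Builds `n` C-rich sequences (four C-tracts of 3-5 cytosines separated by
#' short A/T/G loops) on a toy chromosome, plants sequence-level truth, and
#' emits per-cytosine beta values for two cell lines plus per-sequence
#' transitional pH values:
#'
#' * exactly `k_methylated` sequences carry one cytosine with beta 0.9 in
#'   at least one cell line (>= the 0.5 call threshold); all other betas
#'   are background draws below 0.3;
#' * `k_loop_adjacent` of the methylated sequences have their planted
#'   cytosine adjacent to loop 1 or loop 3 (tract-terminal); the rest are
#'   tract-internal;
#' * `k_differential` of the methylated sequences are methylated in line A
#'   only; the rest carry identical beta 0.9 in both lines. Background
#'   betas differ by < 0.05 between lines so no spurious differential
#'   calls arise at the 0.2 delta-beta threshold;
#' * `k_neutral` sequences receive a transitional pH in 7.0-7.5 (neutral),
#'   the rest 5.8-6.6 (acidic); `k_methylated_neutral` of the methylated
#'   sequences fall in the neutral class.
#'
#' Defaults mirror a reference screen cohort structure
#' (44 sequences, 12 methylated of which 10 differential and 8
#' loop-adjacent, 13 neutral formers).
#'
#' @param n number of sequences.
#' @param k_methylated number of methylated sequences.
#' @param k_neutral number of neutral-stability sequences (default 13).
#' @param seed integer RNG seed; the fixture is a pure function of its
#'   arguments and this seed.
#' @param k_differential,k_loop_adjacent,k_methylated_neutral planted
#'   counts among the methylated sequences; `NULL` scales the reference
#'   proportions (10/12, 8/12, 10/12) to `k_methylated`.
#' @param min_tract_len minimum C-tract length in generated sequences.
#' @param dir if non-NULL, write `sequences.fasta`, `sequences.bed`,
#'   `lineA.bedGraph`, `lineB.bedGraph` and `pht.csv` into this directory.
#' @return object of class `screen_fixture`: list with `sequences` (list of
#'   [imotif_sequence()]), `calls_A`, `calls_B` (call data.frames),
#'   `pht` (data.frame `id`, `pHT`), `truth` (planted id sets and counts)
#'   and `files` (paths, when written).
#' @export
make_screen_fixture <- function(n = 44, k_methylated = 12, k_neutral = 13,
                                seed = 1L, k_differential = NULL,
                                k_loop_adjacent = NULL,
                                k_methylated_neutral = NULL,
                                min_tract_len = 3, dir = NULL) {
  if (k_methylated > n) stop_em("invalid_params", "k_methylated must be <= n")
  if (k_neutral > n) stop_em("invalid_params", "k_neutral must be <= n")
  scale_k <- function(k) min(k_methylated, round(k / 12 * k_methylated))
  if (is.null(k_differential)) k_differential <- scale_k(10)
  if (is.null(k_loop_adjacent)) k_loop_adjacent <- scale_k(8)
  if (is.null(k_methylated_neutral))
    k_methylated_neutral <- min(scale_k(10), k_neutral)
  if (k_differential > k_methylated || k_loop_adjacent > k_methylated ||
      k_methylated_neutral > k_methylated)
    stop_em("invalid_params", "planted sub-counts cannot exceed k_methylated")
  if (k_methylated_neutral > k_neutral ||
      (k_methylated - k_methylated_neutral) > (n - k_neutral))
    stop_em("invalid_params", "stability split incompatible with k_neutral")

  set.seed(seed)
  loop_alpha <- c("A", "T", "G")
  make_seq <- function() {
    tract <- function() strrep("C", sample(min_tract_len:(min_tract_len + 2), 1))
    loop <- function() paste(sample(loop_alpha, sample(1:4, 1), replace = TRUE),
                             collapse = "")
    flank <- function() if (runif(1) < 0.5) "" else
      paste(sample(loop_alpha, sample(1:3, 1), replace = TRUE), collapse = "")
    paste0(flank(), tract(), loop(), tract(), loop(), tract(), loop(),
           tract(), flank())
  }
  ids <- sprintf("IM%03d", seq_len(n))
  seq_strings <- vapply(seq_len(n), function(i) make_seq(), character(1))

  # toy chromosome layout: consecutive intervals with 100 bp gaps
  starts <- integer(n)
  cur <- 1000L
  for (i in seq_len(n)) {
    starts[i] <- cur
    cur <- cur + nchar(seq_strings[i]) + 100L
  }

  meth_ids <- sample(seq_len(n), k_methylated)
  loop_adj_ids <- meth_ids[seq_len(k_loop_adjacent)]
  diff_ids <- meth_ids[seq_len(k_differential)]
  # neutral class: prefer the designated methylated sequences, fill up with
  # unmethylated ones
  neutral_ids <- c(meth_ids[seq_len(k_methylated_neutral)],
                   sample(setdiff(seq_len(n), meth_ids),
                          k_neutral - k_methylated_neutral))
  pht <- round(runif(n, 5.8, 6.6), 2)
  if (length(neutral_ids))
    pht[neutral_ids] <- round(runif(k_neutral, 7.0, 7.5), 2)

  seqs <- vector("list", n)
  rows_A <- vector("list", n)
  rows_B <- vector("list", n)
  for (i in seq_len(n)) {
    sq <- imotif_sequence(ids[i], seq_strings[i], chrom = "chrS",
                          start = starts[i],
                          end = starts[i] + nchar(seq_strings[i]),
                          strand = "+", pHT = pht[i])
    seqs[[i]] <- sq
    ann <- annotate_cytosines(sq$sequence, min_tract_len = min_tract_len)
    # background betas: low and nearly identical between lines
    bg <- round(runif(nrow(ann), 0, 0.30), 3)
    beta_A <- bg
    beta_B <- pmin(pmax(bg + round(runif(nrow(ann), -0.04, 0.04), 3), 0), 0.3)
    if (i %in% meth_ids) {
      cand <- if (i %in% loop_adj_ids)
        which(!is.na(ann$adjacent_loop) & ann$adjacent_loop %in% c(1, 3) &
                ann$role %in% c("tract_5prime_terminal", "tract_3prime_terminal"))
      else which(ann$role == "tract_internal")
      planted <- cand[sample.int(length(cand), 1)]
      beta_A[planted] <- 0.9
      beta_B[planted] <- if (i %in% diff_ids) 0.05 else 0.9
    }
    g0 <- genomic_positions0(sq, ann$position)
    rows_A[[i]] <- data.frame(chrom = "chrS", start = g0, end = g0 + 1L,
                              beta = beta_A, coverage = 30L)
    rows_B[[i]] <- data.frame(chrom = "chrS", start = g0, end = g0 + 1L,
                              beta = beta_B, coverage = 30L)
  }
  calls_A <- do.call(rbind, rows_A)
  calls_B <- do.call(rbind, rows_B)
  fixture <- structure(list(
    sequences = seqs,
    calls_A = calls_A, calls_B = calls_B,
    pht = data.frame(id = ids, pHT = pht),
    truth = list(methylated = sort(ids[meth_ids]),
                 differential = sort(ids[diff_ids]),
                 loop_adjacent = sort(ids[loop_adj_ids]),
                 neutral = sort(ids[neutral_ids]),
                 k_methylated = k_methylated,
                 k_differential = k_differential,
                 k_loop_adjacent = k_loop_adjacent,
                 k_neutral = k_neutral,
                 k_methylated_neutral = k_methylated_neutral),
    files = NULL), class = "screen_fixture")
  if (!is.null(dir)) fixture$files <- write_screen_fixture(fixture, dir)
  fixture
}

#' Write a screen fixture to disk
#'
#' Emits the fixture as standard plain-text formats: FASTA (sequences),
#' BED6 (intervals, 0-based half-open, name = sequence id), one bedGraph
#' per cell line (`chrom start end beta coverage`) and a CSV of
#' transitional pH per sequence. Output is byte-deterministic for a given
#' fixture.
#'
#' @param fixture a [make_screen_fixture()] result.
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_screen_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "screen_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "sequences.fasta"),
                bed = file.path(dir, "sequences.bed"),
                bedgraph_A = file.path(dir, "lineA.bedGraph"),
                bedgraph_B = file.path(dir, "lineB.bedGraph"),
                pht = file.path(dir, "pht.csv"))
  seqs <- fixture$sequences
  dss <- Biostrings::DNAStringSet(
    setNames(vapply(seqs, `[[`, character(1), "sequence"),
             vapply(seqs, `[[`, character(1), "id")))
  Biostrings::writeXStringSet(dss, paths$fasta)
  bed <- vapply(seqs, function(sq)
    sprintf("%s\t%d\t%d\t%s\t0\t%s", sq$chrom, sq$start, sq$end, sq$id,
            sq$strand), character(1))
  writeLines(bed, paths$bed)
  write_bg <- function(calls, path) {
    writeLines(sprintf("%s\t%d\t%d\t%.3f\t%d", calls$chrom, calls$start,
                       calls$end, calls$beta, calls$coverage), path)
  }
  write_bg(fixture$calls_A, paths$bedgraph_A)
  write_bg(fixture$calls_B, paths$bedgraph_B)
  writeLines(c("id,pHT", sprintf("%s,%.2f", fixture$pht$id, fixture$pht$pHT)),
             paths$pht)
  paths
}
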