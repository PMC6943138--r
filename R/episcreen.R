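# In-silico methylation screen of i-motif forming sequences: C-tract/loop
# decomposition, per-cytosine role annotation, methylome overlap for two
# cell lines, acidic/neutral stability classes and a cohort summary with a
# pooled two-proportion z-test.

#' Decompose a C-rich sequence into C-tracts, loops and flanks
#'
#' Finds maximal runs of C of length >= `min_tract_len` (tracts), the
#' inter-tract segments (loops, indexed 1..k-1 between consecutive tracts)
#' and the flanking sequence outside the first/last tract. A sequence needs
#' at least four tracts to be screenable as an intramolecular i-motif; with
#' fewer, the decomposition is returned with `screenable = FALSE`.
#'
#' @param seq uppercase DNA string (the C-rich strand, 5'->3').
#' @param min_tract_len minimum tract length (default 3, the hTeloC tract
#'   length; genomic i-motifs such as MSMO1/PLCB2 have tracts of five).
#' @return list with `tracts` (data.frame `start`, `end`, `length`; 1-based
#'   inclusive), `loops` (data.frame `index`, `start`, `end`, `seq`),
#'   `flank5`, `flank3` (strings) and `screenable` (logical).
#' @export
find_c_tracts <- function(seq, min_tract_len = 3) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (grepl("[^ACGT]", seq))
    stop_em("invalid_sequence", "sequence must be uppercase ACGT")
  m <- gregexpr(sprintf("C{%d,}", min_tract_len), seq)[[1]]
  if (m[1] == -1) {
    tracts <- data.frame(start = integer(), end = integer(), length = integer())
  } else {
    tracts <- data.frame(start = as.integer(m),
                         length = attr(m, "match.length"))
    tracts$end <- tracts$start + tracts$length - 1L
    tracts <- tracts[, c("start", "end", "length")]
  }
  k <- nrow(tracts)
  loops <- data.frame(index = integer(), start = integer(), end = integer(),
                      seq = character())
  if (k >= 2) {
    loops <- data.frame(
      index = seq_len(k - 1L),
      start = tracts$end[-k] + 1L,
      end = tracts$start[-1L] - 1L)
    loops$seq <- substring(seq, loops$start, loops$end)
  }
  list(tracts = tracts, loops = loops,
       flank5 = if (k >= 1) substring(seq, 1, tracts$start[1] - 1L) else seq,
       flank3 = if (k >= 1) substring(seq, tracts$end[k] + 1L, nchar(seq)) else "",
       screenable = k >= 4)
}

#' Annotate every cytosine of a C-rich sequence
#'
#' Assigns each cytosine a 1-based ordinal (counted 5'->3' over all
#' cytosines, the convention used to number modification positions), a
#' role, and the index of the adjacent loop where applicable:
#'
#' * `tract_5prime_terminal` / `tract_3prime_terminal`: first/last cytosine
#'   of a tract; adjacent to the loop it touches (the 3' end of tract *i*
#'   touches loop *i*, the 5' end of tract *i* touches loop *i - 1*).
#' * `tract_internal`: inside a tract.
#' * `loop_cytosine`: a cytosine within a loop (runs shorter than the tract
#'   minimum); adjacent to that loop.
#' * `flank_cytosine`: outside the tract core.
#'
#' @param seq uppercase DNA string.
#' @param tracts a [find_c_tracts()] result (computed if omitted).
#' @param min_tract_len used when `tracts` is omitted.
#' @return data.frame with `cytosine_ordinal`, `position` (1-based in the
#'   sequence), `role`, `adjacent_loop` (integer, NA when none).
#' @export
annotate_cytosines <- function(seq, tracts = NULL, min_tract_len = 3) {
  if (is.null(tracts)) tracts <- find_c_tracts(seq, min_tract_len)
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars == "C")
  n <- length(pos)
  role <- character(n)
  loop_idx <- rep(NA_integer_, n)
  tr <- tracts$tracts
  lp <- tracts$loops
  k <- nrow(tr)
  for (i in seq_len(n)) {
    p <- pos[i]
    ti <- if (k > 0) which(tr$start <= p & p <= tr$end) else integer()
    if (length(ti) == 1) {
      if (p == tr$start[ti] && p == tr$end[ti]) {
        # single-cytosine tract (only possible when min_tract_len == 1)
        role[i] <- "tract_5prime_terminal"
        if (ti > 1) loop_idx[i] <- ti - 1L
      } else if (p == tr$start[ti]) {
        role[i] <- "tract_5prime_terminal"
        if (ti > 1) loop_idx[i] <- ti - 1L
      } else if (p == tr$end[ti]) {
        role[i] <- "tract_3prime_terminal"
        if (ti <= nrow(lp)) loop_idx[i] <- ti
      } else {
        role[i] <- "tract_internal"
      }
    } else {
      li <- if (nrow(lp) > 0) which(lp$start <= p & p <= lp$end) else integer()
      if (length(li) == 1) {
        role[i] <- "loop_cytosine"
        loop_idx[i] <- lp$index[li]
      } else {
        role[i] <- "flank_cytosine"
      }
    }
  }
  data.frame(cytosine_ordinal = seq_len(n), position = pos,
             role = role, adjacent_loop = loop_idx)
}

#' i-motif sequence record
#'
#' @param id sequence identifier.
#' @param sequence uppercase ACGT string (C-rich strand, 5'->3').
#' @param chrom,start,end,strand optional genomic interval in BED
#'   conventions (0-based half-open; strand `"+"`, `"-"` or NA).
#' @param pHT optional transitional pH.
#' @return object of class `imotif_sequence`.
#' @export
imotif_sequence <- function(id, sequence, chrom = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            strand = NA_character_, pHT = NA_real_) {
  if (grepl("[^ACGT]", sequence))
    stop_em("invalid_sequence", "sequence must be uppercase ACGT")
  if (!is.na(start) && !is.na(end)) {
    if (end - start != nchar(sequence))
      stop_em("invalid_interval",
              "interval width (%d) does not match sequence length (%d)",
              end - start, nchar(sequence))
  }
  structure(list(id = id, sequence = sequence, chrom = chrom,
                 start = start, end = end, strand = strand, pHT = pHT),
            class = "imotif_sequence")
}

# Genomic positions (0-based) of the sequence's bases; minus-strand records
# have their coordinates mirrored (base i of the given C-rich strand maps to
# end - 1 - i on the reference).
genomic_positions0 <- function(seq_record, positions1) {
  p0 <- positions1 - 1L
  if (identical(seq_record$strand, "-"))
    seq_record$end - 1L - p0
  else
    seq_record$start + p0
}

#' Overlay methylation calls on a sequence's cytosines
#'
#' Maps per-interval methylation calls (bedGraph-style, 0-based half-open)
#' onto the cytosines of an [imotif_sequence()]. A call is assigned to a
#' cytosine when its interval covers the cytosine's genomic position on the
#' C-rich strand; minus-strand records have mirrored coordinates. Calls
#' with an explicit strand must match the sequence strand; strand `"*"`,
#' `"."` or NA matches either. The sequence is flagged methylated in a cell
#' line iff at least one cytosine has `beta >= beta_threshold` with
#' `coverage >= min_coverage`.
#'
#' @param seq_record an [imotif_sequence()] with a genomic interval.
#' @param calls data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `beta`, and optionally `strand`, `coverage`, `cell_line`.
#'   Beta values on a percent scale (max > 1) are rescaled to `[0, 1]` with
#'   a message.
#' @param beta_threshold,min_coverage call thresholds (defaults 0.5 and 1).
#' @param min_tract_len passed to [annotate_cytosines()].
#' @return list with `annotation` (the cytosine table plus `beta` and
#'   `coverage` per cell line) and `methylated` (named logical per cell
#'   line).
#' @export
overlap_methylation <- function(seq_record, calls, beta_threshold = 0.5,
                                min_coverage = 1, min_tract_len = 3) {
  stopifnot(inherits(seq_record, "imotif_sequence"))
  if (is.na(seq_record$start) || is.na(seq_record$end) ||
      is.na(seq_record$chrom))
    stop_em("no_interval", "sequence '%s' has no genomic interval", seq_record$id)
  if (!all(c("chrom", "start", "end", "beta") %in% names(calls)))
    stop_em("invalid_calls", "calls need chrom/start/end/beta columns")
  if (nrow(calls) > 0 && max(calls$beta, na.rm = TRUE) > 1) {
    message("beta values look like percentages (max > 1); rescaling by 1/100")
    calls$beta <- calls$beta / 100
  }
  if (is.null(calls$coverage)) calls$coverage <- 1L
  if (is.null(calls$strand)) calls$strand <- "*"
  if (is.null(calls$cell_line)) calls$cell_line <- "A"
  ann <- annotate_cytosines(seq_record$sequence, min_tract_len = min_tract_len)
  gpos0 <- genomic_positions0(seq_record, ann$position)
  cyt_gr <- GenomicRanges::GRanges(
    seqnames = seq_record$chrom,
    ranges = IRanges::IRanges(start = gpos0 + 1L, width = 1L))
  lines <- sort(unique(calls$cell_line))
  methylated <- setNames(logical(length(lines)), lines)
  for (ln in lines) {
    cl <- calls[calls$cell_line == ln, , drop = FALSE]
    strand_ok <- cl$strand %in% c("*", ".", NA_character_) |
      is.na(seq_record$strand) | cl$strand == seq_record$strand
    cl <- cl[strand_ok, , drop = FALSE]
    beta <- rep(NA_real_, nrow(ann))
    covg <- rep(NA_real_, nrow(ann))
    if (nrow(cl) > 0) {
      call_gr <- GenomicRanges::GRanges(
        seqnames = cl$chrom,
        ranges = IRanges::IRanges(start = cl$start + 1L, end = cl$end))
      hits <- GenomicRanges::findOverlaps(cyt_gr, call_gr)
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      beta[qi] <- cl$beta[si]
      covg[qi] <- cl$coverage[si]
    }
    ann[[paste0("beta_", ln)]] <- beta
    ann[[paste0("coverage_", ln)]] <- covg
    methylated[ln] <- any(!is.na(beta) & beta >= beta_threshold &
                            !is.na(covg) & covg >= min_coverage)
  }
  list(annotation = ann, methylated = methylated)
}

#' Classify i-motif stability from the transitional pH
#'
#' Sequences with a transitional pH at or above `threshold` (default 6.8,
#' the lower edge of "pH 7.0 +/- 0.2") are classed as neutral i-motif
#' formers, i.e. stable near physiological pH; lower pHT is acidic; a
#' missing pHT is unknown.
#'
#' @param pHT numeric (vectorized); NA allowed.
#' @param threshold neutral cutoff, pH units.
#' @return character vector in `{"acidic", "neutral", "unknown"}`.
#' @export
classify_stability <- function(pHT, threshold = 6.8) {
  out <- ifelse(is.na(pHT), "unknown",
                ifelse(pHT >= threshold, "neutral", "acidic"))
  as.character(out)
}

#' Call differential methylation between two cell lines
#'
#' A sequence is differentially methylated when its sequence-level
#' methylated flags differ between cell lines, or when any cytosine
#' measured in both lines changes beta by at least `delta_beta`. A
#' sequence methylated in neither line is never differential.
#'
#' @param methylated_A,methylated_B sequence-level flags.
#' @param beta_A,beta_B per-cytosine beta vectors (same cytosine order; NA
#'   where not covered).
#' @param delta_beta minimum beta change (default 0.2).
#' @return logical.
#' @export
call_differential <- function(methylated_A, methylated_B,
                              beta_A = numeric(), beta_B = numeric(),
                              delta_beta = 0.2) {
  if (!methylated_A && !methylated_B) return(FALSE)
  if (xor(methylated_A, methylated_B)) return(TRUE)
  shared <- !is.na(beta_A) & !is.na(beta_B)
  any(abs(beta_A[shared] - beta_B[shared]) >= delta_beta)
}

#' Pooled two-proportion z-test
#'
#' Compares k1/n1 against k2/n2 with the pooled-variance z statistic
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))`, `p = (k1+k2)/(n1+n2)`,
#' two-sided normal p-value. A continuity correction (Yates, halved and
#' capped at |p1 - p2|) can be enabled.
#'
#' @param k1,n1,k2,n2 successes and totals per group.
#' @param correct apply continuity correction (default FALSE).
#' @return list with `z`, `p_value`, `p1`, `p2` and the inputs.
#' @export
proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 < 1 || n2 < 1) stop_em("invalid_params", "n1 and n2 must be >= 1")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0)
    stop_em("invalid_params", "counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  p <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) {
    # all successes or all failures in both groups: no evidence of difference
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2,
                k1 = k1, n1 = n1, k2 = k2, n2 = n2, correct = correct))
  }
  diff <- p1 - p2
  if (correct) {
    cc <- min(0.5 * (1 / n1 + 1 / n2), abs(diff))
    z <- (abs(diff) - cc) / se * sign(diff)
    if (diff == 0) z <- 0
  } else {
    z <- diff / se
  }
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2,
       k1 = k1, n1 = n1, k2 = k2, n2 = n2, correct = correct)
}

#' Screen a set of i-motif sequences against two methylomes
#'
#' Runs [overlap_methylation()] per sequence for both cell lines, calls
#' differential and loop-adjacent methylation and the stability class, and
#' returns the per-sequence result table consumed by [summarize_screen()].
#'
#' Loop-adjacent methylation means a methylated cytosine (in either line)
#' whose annotation touches one of `loop_indices` — by default loops 1 and
#' 3, the first and last loops of the four-tract core, the positions most
#' sensitive to modification.
#'
#' @param seqs list of [imotif_sequence()] records.
#' @param calls_A,calls_B methylation call data.frames (see
#'   [overlap_methylation()]) for cell lines A and B.
#' @param beta_threshold,min_coverage,delta_beta,min_tract_len,loop_indices,
#'   neutral_threshold screen parameters (documented defaults).
#' @return data.frame of class `screen_result` with one row per sequence:
#'   `id`, `screenable`, `methylated_A`, `methylated_B`, `methylated`,
#'   `differential`, `loop_adjacent_methylation`, `stability_class`, `pHT`.
#' @export
screen_sequences <- function(seqs, calls_A, calls_B, beta_threshold = 0.5,
                             min_coverage = 1, delta_beta = 0.2,
                             min_tract_len = 3, loop_indices = c(1, 3),
                             neutral_threshold = 6.8) {
  calls_A$cell_line <- "A"
  calls_B$cell_line <- "B"
  rows <- lapply(seqs, function(sq) {
    tracts <- find_c_tracts(sq$sequence, min_tract_len)
    if (!tracts$screenable) {
      return(data.frame(id = sq$id, screenable = FALSE,
                        methylated_A = FALSE, methylated_B = FALSE,
                        methylated = FALSE, differential = FALSE,
                        loop_adjacent_methylation = FALSE,
                        stability_class = classify_stability(sq$pHT, neutral_threshold),
                        pHT = sq$pHT))
    }
    ovA <- overlap_methylation(sq, calls_A, beta_threshold, min_coverage,
                               min_tract_len)
    ovB <- overlap_methylation(sq, calls_B, beta_threshold, min_coverage,
                               min_tract_len)
    annA <- ovA$annotation; annB <- ovB$annotation
    mA <- unname(ovA$methylated["A"]); mB <- unname(ovB$methylated["B"])
    meth_cyt <- (!is.na(annA$beta_A) & annA$beta_A >= beta_threshold &
                   annA$coverage_A >= min_coverage) |
      (!is.na(annB$beta_B) & annB$beta_B >= beta_threshold &
         annB$coverage_B >= min_coverage)
    loop_adj <- any(meth_cyt & !is.na(annA$adjacent_loop) &
                      annA$adjacent_loop %in% loop_indices)
    data.frame(id = sq$id, screenable = TRUE,
               methylated_A = mA, methylated_B = mB,
               methylated = mA || mB,
               differential = call_differential(mA, mB, annA$beta_A,
                                                annB$beta_B, delta_beta),
               loop_adjacent_methylation = loop_adj,
               stability_class = classify_stability(sq$pHT, neutral_threshold),
               pHT = sq$pHT)
  })
  structure(do.call(rbind, rows), class = c("screen_result", "data.frame"))
}

#' Summarize a methylation screen cohort
#'
#' Counts and percentages of methylated, differentially methylated and
#' loop-adjacent-methylated sequences, the neutral/acidic split among
#' methylated sequences, and a pooled two-proportion z-test comparing the
#' methylation rate of neutral versus acidic i-motif formers. Percentages
#' are rounded to integers for the printed report; exact fractions are kept
#' in the returned object. With zero methylated sequences the downstream
#' percentages are undefined (NA) and flagged.
#'
#' @param results a [screen_sequences()] result (or a data.frame with the
#'   same columns).
#' @param correct continuity correction for the proportions test.
#' @return object of class `screen_summary`.
#' @export
summarize_screen <- function(results, correct = FALSE) {
  stopifnot(all(c("methylated", "differential", "loop_adjacent_methylation",
                  "stability_class") %in% names(results)))
  n_total <- nrow(results)
  n_screenable <- sum(results$screenable %||% rep(TRUE, n_total))
  k_meth <- sum(results$methylated)
  frac <- function(k, n) {
    if (n == 0) list(count = k, denominator = n, fraction = NA_real_,
                     percent = NA_real_)
    else list(count = k, denominator = n, fraction = k / n,
              percent = round(100 * k / n))
  }
  meth <- results[results$methylated, , drop = FALSE]
  n_neutral <- sum(results$stability_class == "neutral")
  n_acidic <- sum(results$stability_class == "acidic")
  k_meth_neutral <- sum(meth$stability_class == "neutral")
  k_meth_acidic <- sum(meth$stability_class == "acidic")
  prop <- if (n_neutral >= 1 && n_acidic >= 1 && k_meth > 0)
    proportion_test(k_meth_neutral, n_neutral, k_meth_acidic, n_acidic,
                    correct = correct)
  else NULL
  structure(list(
    n_total = n_total,
    n_screenable = n_screenable,
    methylated = frac(k_meth, n_total),
    differential = frac(sum(meth$differential), k_meth),
    loop_adjacent = frac(sum(meth$loop_adjacent_methylation), k_meth),
    stability_split = list(neutral = frac(k_meth_neutral, k_meth),
                           acidic = frac(k_meth_acidic, k_meth)),
    by_class = list(neutral = frac(k_meth_neutral, n_neutral),
                    acidic = frac(k_meth_acidic, n_acidic)),
    proportion_test = prop,
    flags = if (k_meth == 0) "no_methylated_sequences" else character()),
    class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  pc <- function(f) {
    if (is.na(f$percent)) sprintf("%d/%d (undefined)", f$count, f$denominator)
    else sprintf("%d/%d (%d%%)", f$count, f$denominator, f$percent)
  }
  cat("<screen_summary>\n")
  cat("  methylated:            ", pc(x$methylated), "\n")
  cat("  differential:          ", pc(x$differential), "\n")
  cat("  loop-adjacent:         ", pc(x$loop_adjacent), "\n")
  cat("  neutral among meth.:   ", pc(x$stability_split$neutral), "\n")
  cat("  acidic among meth.:    ", pc(x$stability_split$acidic), "\n")
  if (!is.null(x$proportion_test))
    cat(sprintf("  neutral vs acidic methylation: z = %.3f, p = %.4g\n",
                x$proportion_test$z, x$proportion_test$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
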