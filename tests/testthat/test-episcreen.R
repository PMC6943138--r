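# Sequence decomposition, cytosine annotation, methylation overlap,
# stability classes, proportions test and the cohort summary.

test_that("hTeloC decomposes into 4 CCC tracts with TAA loops and T/AA flanks", {
  tr <- find_c_tracts(HTELOC)
  expect_true(tr$screenable)
  expect_identical(nrow(tr$tracts), 4L)
  expect_identical(tr$tracts$length, rep(3L, 4))
  expect_identical(tr$loops$seq, rep("TAA", 3))
  expect_identical(tr$flank5, "T")
  expect_identical(tr$flank3, "AA")
})

test_that("MSMO1 decomposes into 4 five-cytosine tracts with G loops", {
  tr <- find_c_tracts(MSMO1_IM, min_tract_len = 5)
  expect_identical(tr$tracts$length, rep(5L, 4))
  expect_identical(tr$loops$seq, rep("G", 3))
  expect_identical(tr$flank5, "")
  expect_identical(tr$flank3, "")
})

test_that("sequences without four tracts are not screenable", {
  expect_false(find_c_tracts("AAAA")$screenable)
  expect_false(find_c_tracts("CCCTACCCTACCC")$screenable)  # 3 tracts
  expect_error(find_c_tracts("accc"), class = "invalid_sequence")
})

test_that("tracts, loops and flanks partition the sequence", {
  seqs <- c(HTELOC, MSMO1_IM, PLCB2_IM, "GGCCCATCCCTTACCCGGACCCTT")
  for (s in seqs) {
    tr <- find_c_tracts(s)
    k <- nrow(tr$tracts)
    pieces <- character(0)
    for (i in seq_len(k)) {
      pieces <- c(pieces, substring(s, tr$tracts$start[i], tr$tracts$end[i]))
      if (i < k) pieces <- c(pieces, tr$loops$seq[i])
    }
    expect_identical(paste0(tr$flank5, paste(pieces, collapse = ""), tr$flank3), s)
  }
})

test_that("hTeloC cytosines 3/4 and 9/10 are terminal next to loops 1 and 3", {
  ann <- annotate_cytosines(HTELOC)
  expect_identical(nrow(ann), 12L)
  expect_identical(ann$cytosine_ordinal, 1:12)
  get <- function(i) ann[ann$cytosine_ordinal == i, ]
  expect_identical(get(3)$role, "tract_3prime_terminal")
  expect_identical(get(3)$adjacent_loop, 1L)
  expect_identical(get(4)$role, "tract_5prime_terminal")
  expect_identical(get(4)$adjacent_loop, 1L)
  expect_identical(get(9)$adjacent_loop, 3L)
  expect_identical(get(10)$adjacent_loop, 3L)
  expect_identical(get(2)$role, "tract_internal")
  expect_true(is.na(get(1)$adjacent_loop))  # 5' end of tract 1 faces the flank
})

test_that("MSMO1 cytosine 15 and PLCB2 cytosines 5/14 are loop-adjacent tract ends", {
  m <- annotate_cytosines(MSMO1_IM, min_tract_len = 5)
  expect_identical(m[m$cytosine_ordinal == 15, ]$role, "tract_3prime_terminal")
  expect_identical(m[m$cytosine_ordinal == 15, ]$adjacent_loop, 3L)
  p <- annotate_cytosines(PLCB2_IM, min_tract_len = 5)
  r5 <- p[p$cytosine_ordinal == 5, ]; r14 <- p[p$cytosine_ordinal == 14, ]
  expect_true(r5$role %in% c("tract_5prime_terminal", "tract_3prime_terminal"))
  expect_true(r14$role %in% c("tract_5prime_terminal", "tract_3prime_terminal"))
  expect_false(is.na(r5$adjacent_loop))
  expect_false(is.na(r14$adjacent_loop))
  # PLCB2 has loop cytosines in its long first loop
  expect_true(any(p$role == "loop_cytosine"))
})

test_that("annotation is stable under the minus-strand convention", {
  # annotating the given C-rich strand is independent of which genomic
  # strand it lives on; the strand only affects coordinate mapping
  plus <- toy_screen_sequence("+")
  minus <- toy_screen_sequence("-")
  expect_identical(annotate_cytosines(plus$sequence),
                   annotate_cytosines(minus$sequence))
  # minus-strand genomic positions are mirrored within the interval
  ann <- annotate_cytosines(HTELOC)
  gp <- epimotif:::genomic_positions0(plus, ann$position)
  gm <- epimotif:::genomic_positions0(minus, ann$position)
  expect_identical(sort(gm), sort(plus$end - 1L - (gp - plus$start)))
  expect_identical(gm, minus$end - 1L - (ann$position - 1L))
})

test_that("methylation overlap maps calls to cytosines with thresholds", {
  sq <- toy_screen_sequence()
  # beta 0.9 on cytosine ordinal 4 (sequence position 8) -> methylated
  ann <- annotate_cytosines(HTELOC)
  pos4 <- ann$position[ann$cytosine_ordinal == 4]
  ov <- overlap_methylation(sq, toy_call(pos4, 0.9))
  expect_true(ov$methylated[["A"]])
  expect_equal(ov$annotation$beta_A[ann$cytosine_ordinal == 4], 0.9)
  # sub-threshold beta everywhere -> not methylated
  low <- do.call(rbind, lapply(ann$position, toy_call, beta = 0.4))
  expect_false(overlap_methylation(sq, low)$methylated[["A"]])
  # a call on a loop adenine maps to no cytosine
  loop_a <- toy_call(6, 0.95)  # position 6 is a loop A in hTeloC? (T A A)
  ovA <- overlap_methylation(sq, loop_a)
  expect_false(ovA$methylated[["A"]])
  expect_true(all(is.na(ovA$annotation$beta_A) |
                    ovA$annotation$beta_A != 0.95))
  # coverage gate
  thin <- toy_call(pos4, 0.9, coverage = 0L)
  expect_false(overlap_methylation(sq, thin, min_coverage = 5)$methylated[["A"]])
  # intervals are required
  noiv <- imotif_sequence("x", HTELOC)
  expect_error(overlap_methylation(noiv, toy_call(2, 0.9)), class = "no_interval")
})

test_that("minus-strand records map calls through mirrored coordinates", {
  sq <- toy_screen_sequence("-")
  ann <- annotate_cytosines(HTELOC)
  pos4 <- ann$position[ann$cytosine_ordinal == 4]
  g0 <- sq$end - 1L - (pos4 - 1L)
  call <- data.frame(chrom = "chrT", start = g0, end = g0 + 1L, beta = 0.9,
                     coverage = 30L, strand = "-", cell_line = "A")
  ov <- overlap_methylation(sq, call)
  expect_true(ov$methylated[["A"]])
  expect_equal(ov$annotation$beta_A[ann$cytosine_ordinal == 4], 0.9)
  # a plus-strand call does not map onto a minus-strand record
  call$strand <- "+"
  expect_false(overlap_methylation(sq, call)$methylated[["A"]])
})

test_that("stability classes follow the neutral pHT >= 6.8 rule", {
  expect_identical(classify_stability(6.2), "acidic")
  expect_identical(classify_stability(7.1), "neutral")
  expect_identical(classify_stability(6.8), "neutral")
  expect_identical(classify_stability(NA), "unknown")
  expect_identical(classify_stability(c(6.2, 7.1, NA)),
                   c("acidic", "neutral", "unknown"))
})

test_that("differential calls follow flag differences or beta shifts", {
  expect_true(call_differential(TRUE, FALSE))
  expect_false(call_differential(FALSE, FALSE, c(0.1, 0.9), c(0.7, 0.1)))
  b <- c(0.9, 0.2, 0.3)
  expect_false(call_differential(TRUE, TRUE, b, b))
  expect_true(call_differential(TRUE, TRUE, c(0.9, 0.2), c(0.9, 0.7)))
  expect_false(call_differential(TRUE, TRUE, c(0.9, 0.2), c(0.9, 0.3)))
})

test_that("proportion test matches the pooled z formula and prop.test", {
  # hand computation: p = 1/2, se = sqrt(1/4 * 2/13), z = (10/13 - 3/13)/se
  pt1 <- proportion_test(10, 13, 3, 13)
  z_hand <- (10 / 13 - 3 / 13) / sqrt(0.5 * 0.5 * (2 / 13))
  expect_equal(pt1$z, z_hand, tolerance = 1e-12)
  expect_equal(pt1$z, 2.7456, tolerance = 1e-4)
  expect_equal(pt1$p_value, 0.00604, tolerance = 1e-3)
  # cross-check against the chi-square equivalence in stats::prop.test
  ref <- prop.test(c(10, 3), c(13, 13), correct = FALSE)
  expect_equal(pt1$z^2, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(pt1$p_value, ref$p.value, tolerance = 1e-9)
  # equal proportions give z = 0, p = 1
  pt0 <- proportion_test(5, 10, 5, 10)
  expect_equal(pt0$z, 0)
  expect_equal(pt0$p_value, 1)
  # (0,5) vs (5,5): pooled z = -sqrt(10), p < 0.01
  pt2 <- proportion_test(0, 5, 5, 5)
  expect_equal(pt2$z, -1 / sqrt(0.25 * 0.4), tolerance = 1e-12)
  expect_lt(pt2$p_value, 0.01)
  expect_error(proportion_test(3, 0, 1, 5), class = "invalid_params")
})

test_that("proportion test is symmetric under group swap", {
  for (kk in list(c(10, 13, 3, 13), c(4, 9, 7, 21), c(0, 5, 5, 5))) {
    a <- proportion_test(kk[1], kk[2], kk[3], kk[4])
    b <- proportion_test(kk[3], kk[4], kk[1], kk[2])
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("screen round trip recovers the planted fixture truth across seeds", {
  for (s in c(1, 7, 23)) {
    fx <- make_screen_fixture(n = 44, k_methylated = 12, seed = s)
    res <- screen_sequences(fx$sequences, fx$calls_A, fx$calls_B)
    expect_identical(sort(res$id[res$methylated]), fx$truth$methylated)
    expect_identical(sort(res$id[res$differential]), fx$truth$differential)
    expect_identical(sort(res$id[res$loop_adjacent_methylation]),
                     fx$truth$loop_adjacent)
    summ <- summarize_screen(res)
    expect_identical(summ$methylated$count, 12L)
    expect_identical(summ$methylated$percent, 27)
  }
  # different (n, k)
  fx2 <- make_screen_fixture(n = 20, k_methylated = 5, k_neutral = 6, seed = 2)
  res2 <- screen_sequences(fx2$sequences, fx2$calls_A, fx2$calls_B)
  expect_identical(sum(res2$methylated), 5L)
})

test_that("a fixture with no methylation leaves downstream rates undefined", {
  fx <- make_screen_fixture(n = 10, k_methylated = 0, k_neutral = 3, seed = 4)
  res <- screen_sequences(fx$sequences, fx$calls_A, fx$calls_B)
  summ <- summarize_screen(res)
  expect_identical(summ$methylated$count, 0L)
  expect_true(is.na(summ$differential$percent))
  expect_true(is.na(summ$stability_split$neutral$percent))
  expect_null(summ$proportion_test)
  expect_identical(summ$flags, "no_methylated_sequences")
})

test_that("fixture files are byte-identical for the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_screen_fixture(n = 12, k_methylated = 4, k_neutral = 4,
                            seed = 5, dir = d1)
  f2 <- make_screen_fixture(n = 12, k_methylated = 4, k_neutral = 4,
                            seed = 5, dir = d2)
  for (nm in names(f1$files)) {
    expect_identical(readLines(f1$files[[nm]]), readLines(f2$files[[nm]]))
  }
  f3 <- make_screen_fixture(n = 12, k_methylated = 4, k_neutral = 4, seed = 6)
  expect_false(identical(f1$truth$methylated, f3$truth$methylated) &&
                 identical(vapply(f1$sequences, `[[`, "", "sequence"),
                           vapply(f3$sequences, `[[`, "", "sequence")))
})

test_that("the file round trip reproduces the in-memory screen", {
  d <- withr::local_tempdir()
  fx <- make_screen_fixture(n = 16, k_methylated = 5, k_neutral = 5,
                            seed = 8, dir = d)
  seqs <- read_sequences(fx$files$fasta, fx$files$bed, fx$files$pht)
  res_file <- screen_sequences(seqs,
                               read_bedgraph(fx$files$bedgraph_A, "A"),
                               read_bedgraph(fx$files$bedgraph_B, "B"))
  res_mem <- screen_sequences(fx$sequences, fx$calls_A, fx$calls_B)
  expect_identical(res_file$methylated, res_mem$methylated)
  expect_identical(res_file$differential, res_mem$differential)
  expect_identical(res_file$loop_adjacent_methylation,
                   res_mem$loop_adjacent_methylation)
  expect_identical(res_file$stability_class, res_mem$stability_class)
})
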