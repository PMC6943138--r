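# Shared test fixtures, built in code.

# Default control scenario: unmodified hTeloC-like melt (Tm 39.7 degC,
# dH -160 kJ/mol) on the standard 4-95 degC, 1 degC grid.
control_params <- function(...) two_state_params(...)

# A flat-baseline variant where theta(Tm) = midpoint exactly.
flat_params <- function(...) {
  two_state_params(baseline_folded = c(0.70, 0),
                   baseline_unfolded = c(0.54, 0), ...)
}

# theta series computed with the *true* generator baselines (exact route).
true_theta <- function(params, curve = simulate_melt_curve(params)) {
  fraction_folded(curve, list(folded = params$baseline_folded,
                              unfolded = params$baseline_unfolded,
                              resid_sd = 0))
}

# A minimal single-sequence methylation scenario: one i-motif with a known
# interval and one call table per line.
toy_screen_sequence <- function(strand = "+") {
  # hTeloC placed at chrT:1000-1024 (0-based half-open)
  imotif_sequence("toy", HTELOC, chrom = "chrT", start = 1000L,
                  end = 1000L + nchar(HTELOC), strand = strand, pHT = 6.2)
}

# Calls covering the cytosine at 1-based sequence position `pos` of a
# plus-strand toy sequence.
toy_call <- function(pos, beta, coverage = 30L, strand = "*",
                     cell_line = "A") {
  g0 <- 1000L + pos - 1L
  data.frame(chrom = "chrT", start = g0, end = g0 + 1L, beta = beta,
             coverage = coverage, strand = strand, cell_line = cell_line)
}
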