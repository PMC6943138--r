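# Single-position modification ledger for the hTeloC model i-motif.

# Modification codes used in the 'XXyCZZ' labelling scheme.
.MOD_CODES <- c("5mC" = "m", "5hmC" = "hm", "5fC" = "f", "5caC" = "ca")

#' Enumerate single-position epigenetic variants of hTeloC
#'
#' Builds the ledger of every single-cytosine variant of the hTeloC
#' sequence (5'-TCCCTAACCCTAACCCTAACCCAA-3', 12 cytosines) carrying one of
#' the four epigenetic modifications 5mC, 5hmC, 5fC or 5caC — 48 records.
#' Labels follow the 'XXyCZZ' scheme: XX is the oligonucleotide number
#' (01-48, ordered modification-major), y the modification code (m, hm, f
#' or ca) and ZZ the 1-based ordinal of the modified cytosine (01-12), e.g.
#' `01mC01`, `13hmC01`, `48caC12`.
#'
#' A companion set of the 12 thymine-substitution variants (`hTeloCT1` ..
#' `hTeloCT12`, the mutational screen) is returned separately; there the
#' cytosine is replaced by T in the backbone itself.
#'
#' @param sequence backbone sequence (default [HTELOC]).
#' @return list with two data.frames:
#'   * `modified`: `odn`, `label`, `modification`, `cytosine_ordinal`,
#'     `position` (1-based in the sequence), `sequence` (unmodified
#'     backbone), `display` (backbone with the modified cytosine in
#'     brackets, e.g. `...A[5mC]CC...`).
#'   * `thymine`: `label`, `cytosine_ordinal`, `position`, `sequence` (the
#'     substituted sequence).
#' @export
make_variant_ledger <- function(sequence = HTELOC) {
  ann <- annotate_cytosines(sequence)
  n_c <- nrow(ann)
  mods <- names(.MOD_CODES)
  odn <- 0L
  rows <- vector("list", length(mods) * n_c)
  for (mi in seq_along(mods)) {
    for (ci in seq_len(n_c)) {
      odn <- odn + 1L
      pos <- ann$position[ci]
      display <- paste0(substring(sequence, 1, pos - 1L),
                        "[", mods[mi], "]",
                        substring(sequence, pos + 1L, nchar(sequence)))
      rows[[odn]] <- data.frame(
        odn = odn,
        label = sprintf("%02d%sC%02d", odn, .MOD_CODES[[mi]], ci),
        modification = mods[mi],
        cytosine_ordinal = ci,
        position = pos,
        sequence = sequence,
        display = display)
    }
  }
  thy <- data.frame(
    label = sprintf("hTeloCT%d", seq_len(n_c)),
    cytosine_ordinal = seq_len(n_c),
    position = ann$position,
    sequence = vapply(seq_len(n_c), function(ci) {
      pos <- ann$position[ci]
      paste0(substring(sequence, 1, pos - 1L), "T",
             substring(sequence, pos + 1L, nchar(sequence)))
    }, character(1)))
  list(modified = do.call(rbind, rows), thymine = thy)
}
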