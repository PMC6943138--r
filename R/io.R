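# File readers/writers. Readers validate and reject malformed input rather
# than silently repairing it.

#' Read a UV melting curve from CSV
#'
#' Expects columns `temperature_C` and `absorbance_AU`; metadata is passed
#' by the caller (e.g. from a manifest or filename convention).
#'
#' @param path CSV file.
#' @param sequence_id,replicate_id,direction curve metadata.
#' @return a [melt_curve()].
#' @export
read_melt_csv <- function(path, sequence_id = "seq", replicate_id = 1L,
                          direction = c("melt", "anneal")) {
  direction <- match.arg(direction)
  d <- read.csv(path, check.names = TRUE)
  need <- c("temperature_C", "absorbance_AU")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_em("missing_columns", "missing column(s): %s",
            paste(miss, collapse = ", "))
  melt_curve(d$temperature_C, d$absorbance_AU, sequence_id = sequence_id,
             replicate_id = replicate_id, direction = direction)
}

#' Write a melting curve to CSV
#'
#' @param curve a [melt_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curve, path) {
  stopifnot(inherits(curve, "melt_curve"))
  write.csv(curve$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' Expects columns `wavelength_nm` and `signal`.
#'
#' @param path CSV file.
#' @param temperature_C,pH,blank_subtracted metadata.
#' @return a [spectrum()].
#' @export
read_spectrum_csv <- function(path, temperature_C = NA_real_, pH = NA_real_,
                              blank_subtracted = FALSE) {
  d <- read.csv(path, check.names = TRUE)
  miss <- setdiff(c("wavelength_nm", "signal"), names(d))
  if (length(miss))
    stop_em("missing_columns", "missing column(s): %s",
            paste(miss, collapse = ", "))
  spectrum(d$wavelength_nm, d$signal, temperature_C = temperature_C, pH = pH,
           blank_subtracted = blank_subtracted)
}

#' Read a bedGraph-style methylation track
#'
#' Tab-separated `chrom start end beta [coverage]` (0-based half-open).
#' Track/header lines starting with `track` or `#` are skipped. Beta values
#' on a percent scale (max > 1) are rescaled to `[0, 1]` with a message.
#'
#' @param path bedGraph file.
#' @param cell_line label attached to the calls.
#' @return data.frame with `chrom`, `start`, `end`, `beta`, `coverage`,
#'   `cell_line`.
#' @export
read_bedgraph <- function(path, cell_line = "A") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    stop_em("empty_file", "no data lines in %s", path)
  d <- read.table(text = lines, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(d) < 4)
    stop_em("missing_columns", "bedGraph needs >= 4 columns")
  names(d)[1:4] <- c("chrom", "start", "end", "beta")
  d$coverage <- if (ncol(d) >= 5) d[[5]] else 1L
  d <- d[, c("chrom", "start", "end", "beta", "coverage")]
  if (any(d$end <= d$start))
    stop_em("invalid_interval", "bedGraph intervals must have end > start")
  if (max(d$beta) > 1) {
    message("beta values look like percentages (max > 1); rescaling by 1/100")
    d$beta <- d$beta / 100
  }
  if (any(d$beta < 0 | d$beta > 1))
    stop_em("invalid_beta", "beta values outside [0, 1]")
  d$cell_line <- cell_line
  d
}

#' Read i-motif sequences with intervals and transitional pH
#'
#' Joins a FASTA of C-rich sequences with a BED6 of genomic intervals
#' (matched by BED name = FASTA id) and, optionally, a CSV of transitional
#' pH values (`id,pHT`). BED names absent from the FASTA (or vice versa
#' when `require_all = TRUE`) are an error listing every mismatch; a
#' missing pHT leaves the stability class unknown.
#'
#' @param fasta FASTA path.
#' @param bed optional BED6 path.
#' @param pht_csv optional CSV path.
#' @param require_all require an interval for every FASTA record.
#' @return list of [imotif_sequence()].
#' @export
read_sequences <- function(fasta, bed = NULL, pht_csv = NULL,
                           require_all = FALSE) {
  dss <- Biostrings::readDNAStringSet(fasta)
  ids <- names(dss)
  seqs <- unname(as.character(dss))
  iv <- NULL
  if (!is.null(bed)) {
    iv <- read.table(bed, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(iv) < 4)
      stop_em("missing_columns", "BED needs >= 4 columns (chrom start end name)")
    names(iv)[1:4] <- c("chrom", "start", "end", "name")
    iv$strand <- if (ncol(iv) >= 6) iv[[6]] else NA_character_
    unknown <- setdiff(iv$name, ids)
    if (length(unknown))
      stop_em("id_mismatch", "BED name(s) absent from FASTA: %s",
              paste(unknown, collapse = ", "))
    if (require_all) {
      missing <- setdiff(ids, iv$name)
      if (length(missing))
        stop_em("id_mismatch", "FASTA id(s) without interval: %s",
                paste(missing, collapse = ", "))
    }
  }
  pht <- NULL
  if (!is.null(pht_csv)) {
    pht <- read.csv(pht_csv, stringsAsFactors = FALSE)
    if (!all(c("id", "pHT") %in% names(pht)))
      stop_em("missing_columns", "pHT CSV needs id,pHT columns")
  }
  lapply(seq_along(ids), function(i) {
    id <- ids[i]
    row <- if (!is.null(iv)) iv[match(id, iv$name), ] else NULL
    p <- if (!is.null(pht)) pht$pHT[match(id, pht$id)] else NA_real_
    imotif_sequence(
      id, seqs[i],
      chrom = if (!is.null(row) && !is.na(row$name)) row$chrom else NA_character_,
      start = if (!is.null(row) && !is.na(row$name)) row$start else NA_integer_,
      end = if (!is.null(row) && !is.na(row$name)) row$end else NA_integer_,
      strand = if (!is.null(row) && !is.na(row$name)) row$strand else NA_character_,
      pHT = if (length(p)) p else NA_real_)
  })
}

#' Write a structured report as TSV + JSON twins
#'
#' The TSV is the human-readable table; the JSON twin carries the same
#' values machine-readably plus a provenance block (package version,
#' parameters used, timestamp omitted for reproducibility).
#'
#' @param table data.frame to report.
#' @param path_prefix files are written as `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param params named list of analysis parameters recorded in the JSON.
#' @return named list of the two paths, invisibly.
#' @export
write_report <- function(table, path_prefix, params = list()) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  write.table(table, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(results = table,
         provenance = list(
           package = "epimotif",
           version = as.character(utils::packageVersion("epimotif")),
           parameters = params)),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tsv = tsv, json = json))
}
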