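# Read1 parsing (UMI + cell barcode at fixed offsets), whitelist correction
# with unique Hamming-distance-<=2 assignment, and Read2 pre-trimming
# (5' handle and dA-tail removal).

#' Extract UMI and raw barcode from Read1
#'
#' Fixed-offset extraction: the first `umi_length` (8) bases are the UMI and
#' the next `barcode_length` (30) bases the cell barcode; any residual
#' poly(T) is ignored. Reads shorter than 38 nt are rejected with reason
#' `"too_short"` (counted, not fatal).
#'
#' @param r1 A read table as returned by [read_fastq()] (columns `id`,
#'   `seq`), or a character vector of sequences.
#' @param design A `bead_primer_design` (supplies the UMI and barcode
#'   lengths); defaults to 8 + 30.
#' @return A `data.table` with `read_id`, `umi`, `raw_barcode`, and `status`
#'   (`"ok"` or `"too_short"`); `umi`/`raw_barcode` are `NA` for rejected
#'   reads.
#' @export
parse_read1 <- function(r1, design = NULL) {
  umi_len <- if (is.null(design)) 8L else design$umi_length
  bc_len <- if (is.null(design)) 30L else design$barcode_length
  if (is.character(r1)) {
    r1 <- data.frame(id = as.character(seq_along(r1)), seq = r1,
                     stringsAsFactors = FALSE)
  }
  need <- umi_len + bc_len
  seqs <- toupper(r1$seq)
  ok <- nchar(seqs) >= need
  data.table::data.table(
    read_id = r1$id,
    umi = ifelse(ok, substr(seqs, 1L, umi_len), NA_character_),
    raw_barcode = ifelse(ok, substr(seqs, umi_len + 1L, need), NA_character_),
    status = ifelse(ok, "ok", "too_short"))
}

#' Correct raw barcodes against a whitelist
#'
#' A raw barcode is merged into a whitelist barcode if and only if exactly
#' one whitelist member lies within Hamming distance 2; zero candidates or
#' several (an ambiguous assignment) yield `NA` -- the read is discarded, not
#' repaired. The search enumerates the 4,006-sequence Hamming-<=2
#' neighbourhood of the observed 30-mer against a whitelist hash, which is
#' exactly equivalent to a nearest-neighbour scan over the whole whitelist.
#' When the whitelist's recorded minimum pairwise distance is >= 3 (true of
#' every whitelist this toolkit generates) an exact match is provably unique
#' and short-circuits the scan.
#'
#' @param raw Character vector of raw barcodes (`NA` passes through).
#' @param whitelist A `barcode_whitelist`.
#' @return Character vector: the corrected whitelist barcode, or `NA` when
#'   the assignment is absent or not unique.
#' @export
correct_barcode <- function(raw, whitelist) {
  stopifnot(inherits(whitelist, "barcode_whitelist"))
  idx <- match_barcodes_cpp(as.character(raw), whitelist$barcodes,
                            isTRUE(whitelist$min_distance >= 3))
  whitelist$barcodes[idx]
}

#' Trim the constant handle and dA tail from Read2
#'
#' Removes a leading exact match of `handle` (if present) and a trailing
#' A-homopolymer of length at least `min_tail` (extra bases generated by the
#' dA-tailing step). Never returns a negative-length sequence; reads empty
#' after trimming are flagged `"empty_after_trim"`.
#'
#' @param r2 A read table (columns `id`, `seq`, optionally `qual`) or a
#'   character vector of sequences.
#' @param handle Constant 5' handle sequence; `""` disables handle trimming.
#' @param min_tail Minimum trailing A-run length to trim (default 6).
#' @return A `data.table` with `read_id`, `seq`, `qual`, `status` (`"ok"` or
#'   `"empty_after_trim"`).
#' @export
trim_read2 <- function(r2, handle = "", min_tail = 6L) {
  if (is.character(r2)) {
    r2 <- data.frame(id = as.character(seq_along(r2)), seq = r2,
                     qual = strrep("I", nchar(r2)), stringsAsFactors = FALSE)
  }
  if (is.null(r2$qual)) r2$qual <- strrep("I", nchar(r2$seq))
  seqs <- toupper(r2$seq)
  from <- rep(1L, length(seqs))
  if (nzchar(handle)) {
    has_handle <- startsWith(seqs, toupper(handle))
    from[has_handle] <- nchar(handle) + 1L
  }
  to <- nchar(seqs)
  tail_len <- attr(regexpr("A*$", seqs), "match.length")
  trim_tail <- tail_len >= min_tail
  to[trim_tail] <- to[trim_tail] - tail_len[trim_tail]
  to <- pmax(to, from - 1L)
  out_seq <- substr(seqs, from, to)
  out_qual <- substr(r2$qual, from, to)
  data.table::data.table(
    read_id = r2$id, seq = out_seq, qual = out_qual,
    status = ifelse(nchar(out_seq) == 0L, "empty_after_trim", "ok"))
}

#' Demultiplex a paired-read library
#'
#' Runs [parse_read1()], [correct_barcode()] and [trim_read2()] over a read
#' pair set and reports rejected reads by reason. Only reads passing all
#' three stages appear in the tagged table.
#'
#' @param r1,r2 Read tables ([read_fastq()] output); must be paired in order.
#' @param whitelist A `barcode_whitelist`.
#' @param design Optional `bead_primer_design` for the Read1 layout.
#' @param handle Read2 5' handle to trim (`""` to disable).
#' @param min_tail Minimum dA-tail length to trim from Read2.
#' @return A list of class `demux_result`: `tagged` (`read_id`, `barcode`,
#'   `umi`), `r2_trimmed` (trimmed Read2 for tagged reads), and `rejects`
#'   (named counts: `too_short`, `barcode_unassigned`, `empty_after_trim`,
#'   plus `n_input` and `n_tagged`).
#' @export
demux_reads <- function(r1, r2, whitelist, design = NULL, handle = "",
                        min_tail = 6L) {
  stopifnot(nrow(r1) == nrow(r2))
  parsed <- parse_read1(r1, design)
  parsed[, barcode := NA_character_]
  ok <- parsed$status == "ok"
  parsed$barcode[ok] <- correct_barcode(parsed$raw_barcode[ok], whitelist)
  unassigned <- ok & is.na(parsed$barcode)
  trimmed <- trim_read2(r2, handle = handle, min_tail = min_tail)
  empty <- trimmed$status != "ok"
  keep <- ok & !is.na(parsed$barcode) & !empty
  rejects <- c(
    too_short = sum(!ok),
    barcode_unassigned = sum(unassigned),
    empty_after_trim = sum(ok & !is.na(parsed$barcode) & empty),
    n_input = nrow(r1),
    n_tagged = sum(keep))
  structure(list(
    tagged = parsed[keep, .(read_id, barcode, umi)],
    r2_trimmed = trimmed[keep],
    rejects = as.list(rejects)), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("Demux:", x$rejects$n_tagged, "of", x$rejects$n_input,
      "reads tagged (too_short:", x$rejects$too_short,
      ", barcode_unassigned:", x$rejects$barcode_unassigned,
      ", empty_after_trim:", x$rejects$empty_after_trim, ")\n")
  invisible(x)
}

#' Write a demultiplexing rejection summary as JSON
#'
#' @param demux A `demux_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_demux_summary <- function(demux, path) {
  jsonlite::write_json(demux$rejects, path, auto_unbox = TRUE)
  invisible(path)
}
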