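# Readers/writers for the standard formats the toolkit touches, plus run
# configuration. All other modules consume and produce through these contracts.
#
# Coordinate convention: everything user-visible is 1-based inclusive (GTF
# convention). Internal half-open arithmetic (coverage binning) never leaks
# into outputs.

#' Read a FASTQ file into a read table
#'
#' Parses 4-line FASTQ records into a data.frame with one row per read.
#' Gzip-compressed input is handled transparently (detected from the stream,
#' not the file extension). Sequences are uppercased.
#'
#' @param path Path to a FASTQ file, optionally gzip-compressed.
#' @return A `data.frame` with columns `id`, `seq`, `qual` (character).
#'   Zero-row for an empty file.
#' @details Malformed input (truncated final record, a record whose quality
#'   string length differs from its sequence length, or a missing `@`/`+`
#'   marker) raises an error naming the 1-based record index.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4L + 1L,
         " (file has ", length(lines), " lines, not a multiple of 4)")
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad_hdr <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad_hdr)) {
    stop("malformed FASTQ: record ", bad_hdr[1L], " does not start with '@'")
  }
  bad_plus <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad_plus)) {
    stop("malformed FASTQ: record ", bad_plus[1L], " separator line is not '+'")
  }
  bad_len <- which(nchar(qual) != nchar(seqs))
  if (length(bad_len)) {
    stop("malformed FASTQ: record ", bad_len[1L],
         " quality length (", nchar(qual[bad_len[1L]]),
         ") != sequence length (", nchar(seqs[bad_len[1L]]), ")")
  }
  data.frame(id = sub("^@", "", hdr), seq = seqs, qual = qual,
             stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ
#'
#' @param reads A data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path; written gzip-compressed when `gz = TRUE`.
#' @param gz Compress the output with gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, gz = FALSE) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  con <- if (gz) gzfile(path, open = "wb") else file(path, open = "wb")
  on.exit(close(con))
  n <- nrow(reads)
  if (n > 0L) {
    out <- character(4L * n)
    out[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$id)
    out[seq(2L, 4L * n, by = 4L)] <- reads$seq
    out[seq(3L, 4L * n, by = 4L)] <- "+"
    out[seq(4L, 4L * n, by = 4L)] <- reads$qual
    writeLines(out, con)
  }
  invisible(path)
}

.BIOTYPES <- c("mRNA", "rRNA", "tRNA", "ncRNA")

# Map annotation biotype vocabulary onto the four classes the toolkit reports.
.normalize_biotype <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% .BIOTYPES, x,
         ifelse(x %in% c("protein_coding", "CDS", "mrna"), "mRNA",
         ifelse(grepl("rRNA", x, ignore.case = TRUE), "rRNA",
         ifelse(grepl("tRNA", x, ignore.case = TRUE), "tRNA", "ncRNA"))))
  out
}

#' Build a gene-model table
#'
#' Constructor used by [read_gtf()] and the simulator. Validates the
#' invariants of the gene model: 1-based inclusive coordinates with
#' `start <= end`, biotype one of `mRNA`, `rRNA`, `tRNA`, `ncRNA`.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param biotype Biotype per gene (see Details for accepted synonyms).
#' @param contig Contig/chromosome name per gene.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_models` with an additional `length`
#'   column (`end - start + 1`).
#' @export
gene_models <- function(gene_id, biotype, contig, start, end, strand = "+") {
  n <- length(gene_id)
  biotype <- .normalize_biotype(rep_len(biotype, n))
  contig <- rep_len(as.character(contig), n)
  strand <- rep_len(as.character(strand), n)
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(gene_id)) stop("duplicated gene_id in gene models")
  if (any(is.na(start) | is.na(end))) stop("missing coordinates in gene models")
  bad <- which(end < start)
  if (length(bad)) {
    stop("gene ", gene_id[bad[1L]], ": end (", end[bad[1L]],
         ") < start (", start[bad[1L]], ")")
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  gm <- data.frame(gene_id = as.character(gene_id), biotype = biotype,
                   contig = contig, start = start, end = end, strand = strand,
                   length = end - start + 1L, stringsAsFactors = FALSE)
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Read gene models from a GTF or GFF3 annotation
#'
#' Imports `gene` features through \pkg{rtracklayer} and returns one row per
#' gene. GTF attributes `gene_id` and `gene_biotype`/`biotype`/`gene_type`
#' are honoured; in the GFF3 dialect `ID` substitutes for `gene_id`. Genes
#' lacking a biotype attribute default to `mRNA` (with a message).
#'
#' @param path Path to a GTF or GFF3 file.
#' @param format `"auto"` (sniff from content/extension), `"gtf"` or `"gff3"`.
#' @return A `gene_models` data.frame (see [gene_models()]).
#' @export
read_gtf <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    format <- if (any(grepl("gff-version\\s*3", head_lines)) ||
                  !any(grepl("gene_id", head_lines))) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  md <- as.data.frame(S4Vectors::mcols(gr))
  feature_type <- if ("type" %in% names(md)) as.character(md$type) else
    rep("gene", length(gr))
  keep <- feature_type == "gene"
  if (!any(keep)) stop("no 'gene' features in ", path)
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  ids <- if ("gene_id" %in% names(md) && !all(is.na(md$gene_id))) {
    as.character(md$gene_id)
  } else if ("ID" %in% names(md)) {
    as.character(md$ID)
  } else {
    stop("annotation records lack a gene_id (or ID) attribute: ", path)
  }
  if (anyNA(ids)) {
    stop("gene feature ", which(is.na(ids))[1L], " lacks a gene_id attribute")
  }
  bt_col <- intersect(c("gene_biotype", "biotype", "gene_type"), names(md))
  if (length(bt_col)) {
    bt <- as.character(md[[bt_col[1L]]])
    if (anyNA(bt)) {
      message(sum(is.na(bt)), " gene(s) lack a biotype attribute; ",
              "defaulting to mRNA")
      bt[is.na(bt)] <- "mRNA"
    }
  } else {
    message("annotation has no biotype attribute; defaulting all genes to mRNA")
    bt <- rep("mRNA", length(ids))
  }
  gene_models(gene_id = ids, biotype = bt,
              contig = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
              strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                              "-", "+"))
}

# gene_models -> GRanges, for overlap machinery
.genes_as_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand, gene_id = genes$gene_id, biotype = genes$biotype)
}

#' Write a UMI count matrix as a MatrixMarket trio
#'
#' Writes `matrix.mtx` (coordinate format), `barcodes.tsv` (one barcode per
#' line) and `features.tsv` (`gene_id`, `biotype`) into `dir`. Re-reading with
#' [read_mtx()] reproduces the matrix exactly.
#'
#' @param matrix A `umi_count_matrix` (see [count_umis()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(matrix, dir) {
  stopifnot(inherits(matrix, "umi_count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(matrix$counts, file.path(dir, "matrix.mtx"))
  writeLines(matrix$barcodes, file.path(dir, "barcodes.tsv"))
  write.table(matrix$genes[, c("gene_id", "biotype")],
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a MatrixMarket trio back into a UMI count matrix
#'
#' @param dir Directory holding `matrix.mtx`, `barcodes.tsv`, `features.tsv`
#'   as written by [write_mtx()].
#' @return A `umi_count_matrix`.
#' @export
read_mtx <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                      col.names = c("gene_id", "biotype"),
                      stringsAsFactors = FALSE)
  new_umi_count_matrix(m, genes = feats, barcodes = barcodes)
}

#' Run configuration
#'
#' A named list of stage parameters plus a master seed, round-trippable
#' through YAML. Every stochastic operation in the toolkit takes its seed from
#' this object (or an explicit `seed` argument).
#'
#' @param seed Integer master seed.
#' @param ... Named stage sections (arbitrary nested lists).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed), ...)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Serialize / deserialize a run configuration
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

# Structured log line to stderr; used sparingly by long-running stages.
.log <- function(...) {
  message(sprintf("[microdrops %s] ", format(Sys.time(), "%H:%M:%S")), ...)
}
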