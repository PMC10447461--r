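# Read -> gene assignment over gene intervals, UMI deduplication per
# (barcode, gene), and the sparse count matrix with biotype accounting.
# Bacterial genes are modelled as single intervals; only uniquely mapped
# reads are consumed.

#' Read an alignment interchange TSV
#'
#' The canonical alignment interchange is a TSV with columns `read_id`,
#' `contig`, `start`, `end` (1-based inclusive), `strand`, `unique` (0/1).
#' SAM is accepted via [read_sam_alignments()].
#'
#' @param path TSV path (with header).
#' @return A `data.table` of alignment records.
#' @export
read_alignments <- function(path) {
  al <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("read_id", "contig",
                                                          "strand")))
  need <- c("read_id", "contig", "start", "end", "strand", "unique")
  if (!all(need %in% names(al))) {
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(al$end < al$start)) stop("alignment with end < start")
  al
}

#' Read alignments from a SAM file (thin adapter)
#'
#' Maps mapped SAM records to alignment interchange rows; a record is
#' `unique` when its MAPQ exceeds `mapq_unique`.
#'
#' @param path SAM file path.
#' @param mapq_unique MAPQ threshold above which a record counts as uniquely
#'   mapped (default 3).
#' @return A `data.table` of alignment records.
#' @export
read_sam_alignments <- function(path, mapq_unique = 3L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.table::data.table(read_id = character(), contig = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), unique = integer()))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  flag <- as.integer(f[[2]])
  mapped <- bitwAnd(flag, 4L) == 0L
  start <- as.integer(f[[4]])
  seq_len_ <- nchar(f[[10]])
  data.table::data.table(
    read_id = f[[1]], contig = f[[3]], start = start,
    end = start + seq_len_ - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    unique = as.integer(as.integer(f[[5]]) > mapq_unique))[mapped]
}

#' Assign uniquely mapped reads to genes
#'
#' A read is assigned to a gene iff it is uniquely mapped and its interval
#' overlaps exactly one gene (overlap of at least 1 nt). Reads overlapping
#' zero or several genes are unassigned and counted by reason; strand is
#' ignored unless `mode = "stranded"`.
#'
#' @param alignments Alignment table (`read_id`, `contig`, `start`, `end`,
#'   `strand`, `unique`).
#' @param genes A `gene_models` table.
#' @param mode `"unstranded"` (default; random-primed bacterial cDNA has
#'   mixed read strands) or `"stranded"`.
#' @return A `data.table` with `read_id`, `gene_id` (`NA` when unassigned)
#'   and `status` in `{assigned, not_unique, unknown_contig, no_feature,
#'   ambiguous}`; attribute `"assignment_counts"` holds the per-status
#'   totals.
#' @export
assign_reads <- function(alignments, genes,
                         mode = c("unstranded", "stranded")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genes, "gene_models"))
  al <- data.table::as.data.table(alignments)
  status <- rep("assigned", nrow(al))
  gene_id <- rep(NA_character_, nrow(al))

  uniq <- al$unique == 1L
  status[!uniq] <- "not_unique"
  known <- al$contig %in% unique(genes$contig)
  status[uniq & !known] <- "unknown_contig"

  cand <- which(uniq & known)
  if (length(cand)) {
    gr_genes <- .genes_as_granges(genes)
    gr_reads <- GenomicRanges::GRanges(
      seqnames = al$contig[cand],
      ranges = IRanges::IRanges(start = al$start[cand], end = al$end[cand]),
      strand = al$strand[cand])
    hits <- GenomicRanges::findOverlaps(gr_reads, gr_genes,
                                        ignore.strand = mode == "unstranded")
    n_hits <- tabulate(S4Vectors::queryHits(hits), nbins = length(cand))
    one <- n_hits == 1L
    first_hit <- integer(length(cand))
    first_hit[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    gene_id[cand[one]] <- genes$gene_id[first_hit[one]]
    status[cand[!one & n_hits == 0L]] <- "no_feature"
    status[cand[n_hits >= 2L]] <- "ambiguous"
  }
  out <- data.table::data.table(read_id = al$read_id, gene_id = gene_id,
                                status = status)
  counts <- table(factor(status, levels = c("assigned", "not_unique",
                                            "unknown_contig", "no_feature",
                                            "ambiguous")))
  data.table::setattr(out, "assignment_counts", as.list(counts))
  out
}

# ---- UMI count matrix container -------------------------------------------

new_umi_count_matrix <- function(counts, genes, barcodes) {
  counts <- as(counts, "CsparseMatrix")
  stopifnot(nrow(counts) == nrow(genes), ncol(counts) == length(barcodes))
  dimnames(counts) <- list(genes$gene_id, barcodes)
  per_barcode <- data.table::data.table(
    barcode = barcodes,
    n_umis = Matrix::colSums(counts),
    n_genes = Matrix::colSums(counts > 0))
  structure(list(counts = counts,
                 genes = as.data.frame(genes)[, c("gene_id", "biotype")],
                 barcodes = barcodes,
                 per_barcode = per_barcode),
            class = "umi_count_matrix")
}

#' @export
print.umi_count_matrix <- function(x, ...) {
  cat("UMI count matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "barcodes;", sum(x$counts), "UMIs\n")
  invisible(x)
}

#' Per-barcode summary of a UMI count matrix
#'
#' @param matrix A `umi_count_matrix`.
#' @return A `data.table` with `barcode`, `n_umis`, `n_genes`.
#' @export
barcode_summary <- function(matrix) {
  stopifnot(inherits(matrix, "umi_count_matrix"))
  data.table::copy(matrix$per_barcode)
}

# directional UMI collapse within one (barcode, gene) group: merge a UMI at
# Hamming distance 1 into a more abundant neighbour when
# parent_count >= 2 * child_count - 1; returns the number of clusters.
.collapse_directional <- function(umis, counts) {
  k <- length(umis)
  if (k <= 1L) return(k)
  m <- .seq_int_matrix(umis)
  D <- matrix(0L, k, k)
  for (pos in seq_len(ncol(m))) {
    D <- D + outer(m[, pos], m[, pos], "!=")
  }
  ord <- order(-counts, umis)
  visited <- logical(k)
  clusters <- 0L
  for (i in ord) {
    if (visited[i]) next
    clusters <- clusters + 1L
    stack <- i
    visited[i] <- TRUE
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      nb <- which(D[x, ] == 1L & !visited & counts[x] >= 2L * counts - 1L)
      if (length(nb)) {
        visited[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  clusters
}

#' Deduplicate UMIs into a sparse count matrix
#'
#' Within each (barcode, gene) pair, identical UMIs count once
#' (`collapse = "exact"`, the default). With `collapse = "directional"`,
#' UMIs at Hamming distance 1 are additionally merged child-into-parent when
#' the parent's read count is at least `2 * child - 1` (the directional
#' network rule). Records whose UMI length is not 8 are rejected and
#' counted.
#'
#' @param tagged A table with columns `barcode`, `umi`, `gene_id` (demux
#'   output joined to gene assignments); rows with `NA` gene are ignored.
#' @param genes A `gene_models` table defining the feature space (all genes
#'   appear as matrix rows, including undetected ones).
#' @param collapse `"exact"` or `"directional"`.
#' @return A `umi_count_matrix`: sparse genes x barcodes integer counts,
#'   gene biotypes, and per-barcode totals (`n_umis`, `n_genes`). Attribute
#'   `"n_rejected_umi_length"` counts rejected records.
#' @export
count_umis <- function(tagged, genes, collapse = c("exact", "directional")) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(genes, "gene_models"))
  tg <- data.table::as.data.table(tagged)
  stopifnot(all(c("barcode", "umi", "gene_id") %in% names(tg)))
  tg <- tg[!is.na(gene_id) & !is.na(barcode)]
  bad_umi <- nchar(tg$umi) != 8L | is.na(tg$umi)
  n_rejected <- sum(bad_umi)
  tg <- tg[!bad_umi]

  if (nrow(tg)) {
    per_umi <- tg[, .(count = .N), by = .(barcode, gene_id, umi)]
    cnt <- if (collapse == "exact") {
      per_umi[, .(n = .N), by = .(barcode, gene_id)]
    } else {
      per_umi[, .(n = .collapse_directional(umi, count)),
              by = .(barcode, gene_id)]
    }
    barcodes <- sort(unique(cnt$barcode))
    gi <- match(cnt$gene_id, genes$gene_id)
    if (anyNA(gi)) {
      stop("tagged reads reference genes absent from the annotation: ",
           cnt$gene_id[is.na(gi)][1L])
    }
    m <- Matrix::sparseMatrix(i = gi, j = match(cnt$barcode, barcodes),
                              x = cnt$n,
                              dims = c(nrow(genes), length(barcodes)))
  } else {
    barcodes <- character()
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(genes), 0L))
  }
  out <- new_umi_count_matrix(m, genes, barcodes)
  attr(out, "n_rejected_umi_length") <- n_rejected
  out
}

#' Biotype composition report
#'
#' Proportions of reads (or UMIs) per biotype over
#' `{mRNA, rRNA, tRNA, ncRNA, unassigned}`; the five proportions sum to 1
#' (all zero for empty input).
#'
#' @param assigned Either an [assign_reads()] result (reads with `gene_id`,
#'   `NA` = unassigned) or a `umi_count_matrix` (UMI-level proportions).
#' @param genes A `gene_models` table (ignored for a matrix input).
#' @return A list with `counts` and `proportions`, both named over the five
#'   categories, and `total`.
#' @export
biotype_report <- function(assigned, genes = NULL) {
  cats <- c(.BIOTYPES, "unassigned")
  if (inherits(assigned, "umi_count_matrix")) {
    per_gene <- Matrix::rowSums(assigned$counts)
    counts <- vapply(.BIOTYPES, function(bt) {
      sum(per_gene[assigned$genes$biotype == bt])
    }, numeric(1))
    counts <- c(counts, unassigned = 0)
  } else {
    stopifnot(inherits(genes, "gene_models"))
    bt <- genes$biotype[match(assigned$gene_id, genes$gene_id)]
    bt[is.na(bt)] <- "unassigned"
    counts <- vapply(cats, function(x) sum(bt == x), numeric(1))
  }
  total <- sum(counts)
  proportions <- if (total > 0) counts / total else setNames(rep(0, 5), cats)
  list(counts = as.list(counts), proportions = as.list(proportions),
       total = total)
}

#' Write a biotype report as JSON
#'
#' @param report A [biotype_report()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_biotype_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
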