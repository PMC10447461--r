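# Species-mixing (barnyard) metrics, saturation analysis, gene-body
# coverage and pseudo-bulk correlation.

#' Barnyard (species-mixing) report
#'
#' Labels each called barcode by its majority species, or `"mixed"` when the
#' minor-species UMI fraction reaches `mixed_threshold` AND the top two
#' species each contribute at least `min_umis` UMIs. The doublet rate is
#' `mixed / total labelled barcodes`; per-species specificity is the median,
#' over that species' singlets, of the fraction of the barcode's UMIs coming
#' from its own species.
#'
#' @param matrix A `umi_count_matrix` restricted to called cells.
#' @param species_of_gene Named character vector mapping `gene_id` to
#'   species; at least two species are required.
#' @param min_umis Minimum UMIs from each of the top two species for a
#'   `"mixed"` call (default 10).
#' @param mixed_threshold Minor-species UMI fraction at or above which a
#'   barcode is `"mixed"` (default 0.2).
#' @return A list of class `barnyard_report`: `per_barcode` (`barcode`,
#'   per-species UMI columns, `major_species`, `minor_fraction`, `label`),
#'   `species_counts`, `mixed_count`, `doublet_rate`, `specificity` (named,
#'   per species).
#' @export
barnyard <- function(matrix, species_of_gene, min_umis = 10L,
                     mixed_threshold = 0.2) {
  stopifnot(inherits(matrix, "umi_count_matrix"))
  sp <- species_of_gene[matrix$genes$gene_id]
  if (anyNA(sp)) stop("species_of_gene does not cover all genes")
  species <- sort(unique(sp))
  if (length(species) < 2L) {
    stop("barnyard metrics need at least 2 species in the annotation")
  }
  # species x barcodes UMI totals
  ind <- Matrix::sparseMatrix(
    i = match(sp, species), j = seq_along(sp), x = 1,
    dims = c(length(species), nrow(matrix$counts)))
  sp_umis <- as.matrix(ind %*% matrix$counts)
  rownames(sp_umis) <- species

  total <- colSums(sp_umis)
  major_idx <- apply(sp_umis, 2L, which.max)
  major <- species[major_idx]
  major_umis <- sp_umis[cbind(major_idx, seq_along(total))]
  minor_fraction <- ifelse(total > 0, 1 - major_umis / total, 0)
  second_umis <- apply(sp_umis, 2L, function(v) sort(v, decreasing = TRUE)[2L])
  mixed <- minor_fraction >= mixed_threshold &
    major_umis >= min_umis & second_umis >= min_umis
  label <- ifelse(mixed, "mixed", major)

  per_barcode <- data.table::data.table(
    barcode = matrix$barcodes,
    t(sp_umis),
    major_species = major,
    minor_fraction = minor_fraction,
    label = label)
  specificity <- vapply(species, function(s) {
    sel <- label == s
    if (!any(sel)) return(NA_real_)
    median(sp_umis[s, sel] / total[sel])
  }, numeric(1))
  species_counts <- vapply(species, function(s) sum(label == s), integer(1))
  structure(list(per_barcode = per_barcode,
                 species_counts = species_counts,
                 mixed_count = sum(mixed),
                 doublet_rate = sum(mixed) / length(label),
                 specificity = specificity),
            class = "barnyard_report")
}

#' Doublet rate from per-species cell counts
#'
#' The inter-species doublet rate implied by a labelled barnyard table:
#' `mixed / (sum(singlets) + mixed)`. Used to recompute the published rate
#' directly from printed cell counts.
#'
#' @param species_counts Named (or unnamed) integer vector of singlet cell
#'   counts per species.
#' @param mixed_count Number of mixed barcodes.
#' @return The doublet rate (fraction).
#' @examples
#' doublet_rate_from_counts(c(202, 45), 4)  # 4/251
#' @export
doublet_rate_from_counts <- function(species_counts, mixed_count) {
  stopifnot(all(species_counts >= 0), mixed_count >= 0)
  mixed_count / (sum(species_counts) + mixed_count)
}

#' @export
print.barnyard_report <- function(x, ...) {
  cat("Barnyard:",
      paste(names(x$species_counts), x$species_counts, collapse = ", "),
      "; mixed", x$mixed_count,
      sprintf("(doublet rate %.1f%%)\n", 100 * x$doublet_rate))
  invisible(x)
}

#' Sequencing saturation curve
#'
#' For each target depth `d` (reads per cell), subsamples the tagged read
#' table without replacement to `d * n_cells` total reads (uniformly over
#' reads, as raw-read subsampling would), re-runs UMI deduplication, and
#' records the median number of detected genes per called cell. Depths
#' exceeding the library size are marked unattainable (`NA`), not errors.
#'
#' @param tagged A table with `barcode`, `umi`, `gene_id` (one row per raw
#'   read) restricted to called cells, or with a `barcode` column filtered
#'   via `cells`.
#' @param genes A `gene_models` table.
#' @param cells Character vector of called-cell barcodes.
#' @param depths Reads-per-cell targets (default the published ladder
#'   1k/2k/4k/9k/13k/18k/22k).
#' @param seed Integer seed for the subsampling.
#' @return A `data.table` of class `saturation_curve` with `depth`,
#'   `n_reads_used`, `median_genes`, `median_umis`.
#' @export
saturation <- function(tagged, genes, cells,
                       depths = c(1000L, 2000L, 4000L, 9000L, 13000L,
                                  18000L, 22000L),
                       seed = 1L) {
  stopifnot(all(diff(depths) > 0))
  tg <- data.table::as.data.table(tagged)[barcode %in% cells]
  n_cells <- length(cells)
  out <- data.table::data.table(depth = as.numeric(depths),
                                n_reads_used = NA_real_,
                                median_genes = NA_real_,
                                median_umis = NA_real_)
  withr::with_seed(as.integer(seed), {
    for (k in seq_along(depths)) {
      target <- round(depths[k] * n_cells)
      if (target > nrow(tg)) next  # unattainable at this library size
      sub <- if (target == nrow(tg)) tg else
        tg[sample.int(nrow(tg), target)]
      per_cell <- sub[!is.na(gene_id),
                      .(genes = data.table::uniqueN(gene_id),
                        umis = data.table::uniqueN(paste(gene_id, umi))),
                      by = barcode]
      # cells that received no reads at this depth detect 0 genes
      g <- c(per_cell$genes, rep(0L, n_cells - nrow(per_cell)))
      u <- c(per_cell$umis, rep(0L, n_cells - nrow(per_cell)))
      data.table::set(out, i = k, j = "n_reads_used", as.numeric(target))
      data.table::set(out, i = k, j = "median_genes", median(g))
      data.table::set(out, i = k, j = "median_umis", median(u))
    }
  })
  class(out) <- c("saturation_curve", class(out))
  out[]
}

#' Gene-body coverage profile
#'
#' Per-base coverage of each qualifying gene is binned into 100 equal
#' percentile bins oriented 5' to 3' by gene strand, each gene's profile is
#' normalized by its mean coverage (so genes contribute equally), profiles
#' are averaged across genes, and the result is scaled so the maximum bin
#' equals 1.
#'
#' @param alignments Alignment table (`contig`, `start`, `end`).
#' @param genes A `gene_models` table.
#' @param min_length Minimum gene length to include (default 100 nt).
#' @return A numeric vector of 100 bin values (class `coverage_profile`),
#'   bin 1 at the 5' end.
#' @export
gene_body_coverage <- function(alignments, genes, min_length = 100L) {
  stopifnot(inherits(genes, "gene_models"))
  keep <- genes$length >= min_length
  if (!any(keep)) stop("no transcripts of length >= ", min_length)
  genes <- genes[keep, , drop = FALSE]
  al <- data.table::as.data.table(alignments)

  profiles <- matrix(NA_real_, nrow = sum(keep), ncol = 100L)
  row <- 0L
  for (ctg in unique(genes$contig)) {
    g_sel <- which(genes$contig == ctg)
    a_sel <- al[contig == ctg]
    ctg_len <- max(genes$end[g_sel], if (nrow(a_sel)) max(a_sel$end) else 0L)
    cov <- if (nrow(a_sel)) {
      as.integer(IRanges::coverage(
        IRanges::IRanges(start = a_sel$start, end = a_sel$end),
        width = ctg_len))
    } else rep(0L, ctg_len)
    for (g in g_sel) {
      row <- row + 1L
      v <- cov[genes$start[g]:genes$end[g]]
      if (genes$strand[g] == "-") v <- rev(v)
      # 100 percentile bins, 0-based half-open internally
      bin <- pmin(100L, floor((seq_along(v) - 1L) * 100L / length(v)) + 1L)
      prof <- vapply(split(v, bin), mean, numeric(1))
      m <- mean(prof)
      profiles[row, ] <- if (m > 0) prof / m else prof
    }
  }
  avg <- colMeans(profiles, na.rm = TRUE)
  if (max(avg) > 0) avg <- avg / max(avg)
  structure(unname(avg), class = "coverage_profile")
}

#' Slope of the antitonic (non-increasing) fit to a coverage profile
#'
#' Fits a non-increasing step function by isotonic regression on the
#' reversed profile and returns the mean per-bin slope
#' `(fit[100] - fit[1]) / 99`; negative values indicate 5' to 3' decay.
#'
#' @param profile A `coverage_profile` (or any numeric vector).
#' @return The fitted slope (per bin).
#' @export
coverage_decay_slope <- function(profile) {
  x <- as.numeric(profile)
  fit <- rev(isoreg(rev(x))$yf)  # non-increasing fit
  (fit[length(fit)] - fit[1L]) / (length(fit) - 1L)
}

#' Pseudo-bulk expression correlation
#'
#' Pearson correlation of per-gene `log10(count + 1)` pseudo-bulk totals
#' between two matrices, over the union of their gene universes (missing
#' genes count 0). Gene sums are computed over the supplied (called-cell)
#' columns only.
#'
#' @param matrixA,matrixB `umi_count_matrix` objects.
#' @return Pearson `r` in [-1, 1].
#' @export
pseudobulk_correlation <- function(matrixA, matrixB) {
  stopifnot(inherits(matrixA, "umi_count_matrix"),
            inherits(matrixB, "umi_count_matrix"))
  universe <- union(matrixA$genes$gene_id, matrixB$genes$gene_id)
  if (length(universe) < 3L) stop("fewer than 3 shared genes")
  a <- setNames(rep(0, length(universe)), universe)
  b <- a
  a[matrixA$genes$gene_id] <- Matrix::rowSums(matrixA$counts)
  b[matrixB$genes$gene_id] <- Matrix::rowSums(matrixB$counts)
  cor(log10(a + 1), log10(b + 1), method = "pearson")
}
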