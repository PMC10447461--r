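# Separating putative cells from background barcodes: barcode rank plot,
# simple-knee primary call, and an EmptyDrops-like Monte-Carlo rescue that
# compares low-count barcodes' expression profiles against an ambient
# profile pooled from deep-rank barcodes.

#' Knee-filter parameters
#'
#' The ten numeric parameters of the knee-plus-rescue cell caller, with the
#' published defaults. `indMin`/`indMax` delimit (by rank) the ambient
#' window; `umiMin`/`umiMinFracMedian`/`candMaxN` select rescue candidates;
#' `FDR` and `simN` control the Monte-Carlo test.
#'
#' @param nExpectedCells Expected number of cells (default 1500).
#' @param maxPercentile Quantile of the top `nExpectedCells` barcodes used
#'   as the robust maximum (default 0.99).
#' @param maxMinRatio Ratio dividing the robust maximum into the knee
#'   threshold (default 10).
#' @param indMin,indMax Rank window (exclusive, inclusive] pooled into the
#'   ambient profile (defaults 45000, 90000).
#' @param umiMin Absolute minimum UMIs for a rescue candidate (default 300).
#' @param umiMinFracMedian Candidate floor as a fraction of the median UMIs
#'   of knee cells (default 0.01).
#' @param candMaxN Maximum number of rescue candidates, taken by rank
#'   (default 20000).
#' @param FDR BH false-discovery threshold for rescue (default 0.01).
#' @param simN Monte-Carlo draws per candidate total (default 10000).
#' @return A list of class `knee_params`.
#' @export
knee_params <- function(nExpectedCells = 1500L, maxPercentile = 0.99,
                        maxMinRatio = 10, indMin = 45000L, indMax = 90000L,
                        umiMin = 300L, umiMinFracMedian = 0.01,
                        candMaxN = 20000L, FDR = 0.01, simN = 10000L) {
  stopifnot(indMin < indMax, maxPercentile > 0, maxPercentile <= 1,
            nExpectedCells > 0, maxMinRatio > 0, umiMin >= 0, candMaxN > 0,
            FDR > 0, FDR < 1, simN > 0)
  structure(list(nExpectedCells = as.integer(nExpectedCells),
                 maxPercentile = maxPercentile, maxMinRatio = maxMinRatio,
                 indMin = as.integer(indMin), indMax = as.integer(indMax),
                 umiMin = as.integer(umiMin),
                 umiMinFracMedian = umiMinFracMedian,
                 candMaxN = as.integer(candMaxN), FDR = FDR,
                 simN = as.integer(simN)),
            class = "knee_params")
}

#' Barcode rank series
#'
#' Orders barcodes from the largest to the smallest metric -- the total
#' number of detected genes by default, total UMIs by flag. Ties are broken
#' by the other metric (descending) and then lexicographically by barcode,
#' so the ranking is deterministic.
#'
#' @param matrix A `umi_count_matrix`.
#' @param metric `"genes"` (default) or `"umi"`.
#' @return A `data.table` with `rank_idx`, `barcode`, `n_genes`, `n_umis`,
#'   `metric` (the ranking metric value), ordered by rank.
#' @export
rank_plot <- function(matrix, metric = c("genes", "umi")) {
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "umi_count_matrix"))
  if (ncol(matrix$counts) == 0L) stop("empty matrix: no barcodes to rank")
  pb <- data.table::copy(matrix$per_barcode)
  pb[, metric := if (metric == "genes") n_genes else n_umis]
  tie1 <- if (metric == "genes") pb$n_umis else pb$n_genes
  ord <- order(-pb$metric, -tie1, pb$barcode)
  pb <- pb[ord]
  pb[, rank_idx := seq_len(.N)]
  data.table::setcolorder(pb, c("rank_idx", "barcode", "n_genes", "n_umis",
                                "metric"))
  pb[]
}

#' Simple knee threshold
#'
#' The knee threshold is the `maxPercentile` quantile of the metric over the
#' top `nExpectedCells` barcodes, divided by `maxMinRatio`; barcodes at or
#' above it are primary cells.
#'
#' @param series A [rank_plot()] result.
#' @param params A `knee_params`.
#' @return A list with `knee_threshold`, `knee_index` (number of barcodes at
#'   or above the threshold) and `cells_above` (their barcodes).
#' @export
simple_knee <- function(series, params = knee_params()) {
  if (nrow(series) < 10L) {
    stop("insufficient_barcodes: need at least 10 barcodes, got ",
         nrow(series))
  }
  top <- series$metric[seq_len(min(params$nExpectedCells, nrow(series)))]
  robust_max <- unname(quantile(top, params$maxPercentile, names = FALSE))
  threshold <- robust_max / params$maxMinRatio
  above <- series$metric >= threshold
  list(knee_threshold = threshold, knee_index = sum(above),
       cells_above = series$barcode[above])
}

# multinomial log-likelihood of count vector columns under log-probs lp
.multinom_loglik <- function(counts, lp) {
  # counts: genes x draws (dense); lp: log probabilities
  tot <- colSums(counts)
  lgamma(tot + 1) - colSums(lgamma(counts + 1)) + colSums(counts * lp)
}

#' EmptyDrops-like rescue of sub-knee barcodes
#'
#' The ambient profile is the pooled gene count vector of barcodes ranked in
#' `(indMin, indMax]` (smoothed with a 1e-8 pseudocount). Candidates are
#' barcodes below the knee with at least
#' `max(umiMin, umiMinFracMedian * median UMIs of knee cells)` UMIs, capped
#' at `candMaxN` by rank. Each candidate's observed multinomial
#' log-likelihood under the ambient profile is compared with `simN`
#' simulated draws of the same total;
#' `p = (1 + #\{simulated <= observed\}) / (simN + 1)` (never exactly zero),
#' followed by Benjamini-Hochberg across candidates; `q <= FDR` rescues the
#' barcode. With fewer than 100 barcodes in the ambient window the caller
#' warns and falls back to knee-only calling.
#'
#' @param matrix A `umi_count_matrix`.
#' @param series A [rank_plot()] result for `matrix`.
#' @param knee A [simple_knee()] result.
#' @param params A `knee_params`.
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return A list of class `cell_call_result`: `calls` (a `data.table` with
#'   `barcode`, `rank_idx`, `n_genes`, `n_umis`, `p_value`, `q_value`,
#'   `label` in `{cell, rescued_cell, background}`), `knee_threshold`,
#'   `knee_index`, `ambient_profile`, `params`.
#' @export
empty_drops_rescue <- function(matrix, series, knee, params = knee_params(),
                               seed = 1L) {
  stopifnot(inherits(matrix, "umi_count_matrix"))
  calls <- series[, .(barcode, rank_idx, n_genes, n_umis)]
  calls[, `:=`(p_value = NA_real_, q_value = NA_real_,
               label = "background")]
  calls[barcode %in% knee$cells_above, label := "cell"]

  amb_rows <- which(series$rank_idx > params$indMin &
                      series$rank_idx <= params$indMax)
  if (length(amb_rows) < 100L) {
    warning("fewer than 100 barcodes in the ambient window (",
            length(amb_rows), "); falling back to knee-only calling")
    return(.finish_cell_call(calls, knee, NULL, params))
  }
  amb_counts <- Matrix::rowSums(
    matrix$counts[, series$barcode[amb_rows], drop = FALSE])
  ambient <- amb_counts + 1e-8
  ambient <- ambient / sum(ambient)
  lp <- log(ambient)

  knee_umis <- calls$n_umis[calls$label == "cell"]
  umi_floor <- max(params$umiMin,
                   params$umiMinFracMedian *
                     (if (length(knee_umis)) median(knee_umis) else 0))
  cand <- which(calls$label == "background" & calls$n_umis >= umi_floor)
  cand <- head(cand, params$candMaxN)  # calls is rank-ordered
  if (length(cand)) {
    obs <- as.matrix(matrix$counts[, calls$barcode[cand], drop = FALSE])
    obs_ll <- .multinom_loglik(obs, lp)
    totals <- as.integer(round(colSums(obs)))
    p <- numeric(length(cand))
    withr::with_seed(as.integer(seed), {
      # one simN-draw null per distinct total, shared by its candidates
      for (tot in unique(totals)) {
        sims <- rmultinom(params$simN, tot, ambient)
        sim_ll <- .multinom_loglik(sims, lp)
        sel <- which(totals == tot)
        for (i in sel) {
          p[i] <- (1 + sum(sim_ll <= obs_ll[i])) / (params$simN + 1)
        }
      }
    })
    q <- p.adjust(p, method = "BH")
    data.table::set(calls, i = cand, j = "p_value", p)
    data.table::set(calls, i = cand, j = "q_value", q)
    data.table::set(calls, i = cand[q <= params$FDR], j = "label",
                    "rescued_cell")
  }
  .finish_cell_call(calls, knee, ambient, params)
}

.finish_cell_call <- function(calls, knee, ambient, params) {
  structure(list(calls = calls[], knee_threshold = knee$knee_threshold,
                 knee_index = knee$knee_index, ambient_profile = ambient,
                 params = params),
            class = "cell_call_result")
}

#' @export
print.cell_call_result <- function(x, ...) {
  tab <- table(x$calls$label)
  cat("Cell calling: knee threshold", signif(x$knee_threshold, 4),
      "->", sum(x$calls$label == "cell"), "cells,",
      sum(x$calls$label == "rescued_cell"), "rescued,",
      sum(x$calls$label == "background"), "background\n")
  invisible(x)
}

#' Call cells from a UMI count matrix
#'
#' Convenience wrapper: [rank_plot()] + [simple_knee()] +
#' [empty_drops_rescue()].
#'
#' @param matrix A `umi_count_matrix`.
#' @param params A `knee_params`.
#' @param metric Ranking metric, `"genes"` (default) or `"umi"`.
#' @param seed Monte-Carlo seed.
#' @return A `cell_call_result`.
#' @export
call_cells <- function(matrix, params = knee_params(),
                       metric = c("genes", "umi"), seed = 1L) {
  series <- rank_plot(matrix, metric = metric)
  knee <- simple_knee(series, params)
  empty_drops_rescue(matrix, series, knee, params, seed = seed)
}

#' Barcodes labelled as cells (knee or rescued)
#'
#' @param result A `cell_call_result`.
#' @return Character vector of barcodes.
#' @export
called_barcodes <- function(result) {
  result$calls$barcode[result$calls$label != "background"]
}
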