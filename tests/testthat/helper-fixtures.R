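# Shared fixtures and independent oracles, all built in code.

# small split-pool design: 8 x 8 x 4 = 256 barcodes, segments 10+10+10
toy_design <- function(seed = 1L, cardinalities = c(8L, 8L, 4L)) {
  bead_primer_design(generate_segment_sets(seed, cardinalities))
}

toy_whitelist <- function(seed = 1L, cardinalities = c(8L, 8L, 4L)) {
  build_whitelist(toy_design(seed, cardinalities))
}

random_dna <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# --- brute-force oracles ----------------------------------------------------

# nearest-neighbour scan over the whole whitelist: returns the unique member
# within Hamming <= 2, or NA (zero or several candidates)
brute_correct <- function(queries, whitelist_barcodes) {
  L <- nchar(whitelist_barcodes[1L])
  wl_mat <- matrix(unlist(strsplit(whitelist_barcodes, "", fixed = TRUE)),
                   nrow = L)
  vapply(queries, function(q) {
    qc <- strsplit(q, "", fixed = TRUE)[[1L]]
    if (length(qc) != L) return(NA_character_)
    d <- colSums(wl_mat != qc)
    hits <- which(d <= 2L)
    if (length(hits) == 1L) whitelist_barcodes[hits] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# regex scan of both strands for N20-NGG protospacers (independent of the
# implementation's enumeration)
brute_guide_scan <- function(seq) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }
  scan_one <- function(s, strand, L) {
    out <- list()
    if (nchar(s) >= 23L) {
      for (i in seq_len(nchar(s) - 22L)) {
        win <- substr(s, i, i + 22L)
        if (substr(win, 22L, 23L) == "GG") {
          cut <- if (strand == "+") i + 16L else L - i - 15L
          out[[length(out) + 1L]] <- data.frame(
            spacer = substr(win, 1L, 20L), pam = substr(win, 21L, 23L),
            strand = strand, cut_pos = cut, stringsAsFactors = FALSE)
        }
      }
    }
    out
  }
  L <- nchar(seq)
  do.call(rbind, c(scan_one(seq, "+", L), scan_one(revcomp(seq), "-", L)))
}

# minimal covering by dynamic programming (independent of the greedy
# implementation): smallest subset of cut sites with consecutive gaps (and
# the gaps to position 0 and to gene_len) all <= max_gap; Inf if infeasible
brute_min_cover_size <- function(cuts, max_gap, gene_len) {
  cuts <- sort(cuts)
  n <- length(cuts)
  f <- rep(Inf, n)  # f[i]: min picks covering [0, cuts[i]] and ending at i
  for (i in seq_len(n)) {
    if (cuts[i] <= max_gap) f[i] <- 1
    prev <- which(cuts[i] - cuts < max_gap + 1e-9 & cuts < cuts[i])
    if (length(prev) && any(is.finite(f[prev]))) {
      f[i] <- min(f[i], 1 + min(f[prev]))
    }
  }
  ok_end <- which(gene_len - cuts <= max_gap)
  if (!length(ok_end) || all(!is.finite(f[ok_end]))) return(Inf)
  min(f[ok_end])
}

# default 2-species simulation scaled for unit tests
small_sim <- function(seed = 11L, n_cells = c(30L, 30L),
                      umi_meanlog = log(20), error_rate = 0,
                      lambda = 0.1, wl = NULL) {
  sp1 <- synthesize_species_profile("ecoli", seed = 101L, n_genes = 20L)
  sp2 <- synthesize_species_profile("bsub", seed = 102L, n_genes = 20L)
  if (is.null(wl)) wl <- toy_whitelist(3L)
  cfg <- sim_config(list(sp1, sp2), n_cells = n_cells,
                    loading_lambda = lambda,
                    umi_per_cell_meanlog = umi_meanlog,
                    barcode_error_rate = error_rate, seed = seed)
  list(sim = simulate_library(cfg, wl), profiles = list(sp1, sp2),
       genes = combine_gene_models(list(sp1, sp2)), config = cfg)
}

# run demux -> assign -> count on a simulation, exact UMI collapse
run_pipeline <- function(sim, genes, handle) {
  dm <- demux_reads(sim$r1, sim$r2, sim$whitelist, handle = handle)
  asg <- assign_reads(sim$alignments, genes)
  tagged <- merge(dm$tagged, asg[, c("read_id", "gene_id")], by = "read_id")
  list(demux = dm, assigned = asg,
       matrix = count_umis(tagged, genes), tagged = tagged)
}

# truth UMI matrix as sorted (barcode, gene, count) triplets
truth_triplets <- function(truth) {
  tt <- unique(truth[, c("barcode_true", "gene_id", "umi")])
  agg <- stats::aggregate(umi ~ barcode_true + gene_id, tt, length)
  names(agg) <- c("barcode", "gene_id", "count")
  agg[order(agg$barcode, agg$gene_id), ]
}

matrix_triplets <- function(m) {
  s <- Matrix::summary(m$counts)
  df <- data.frame(barcode = m$barcodes[s$j],
                   gene_id = m$genes$gene_id[s$i],
                   count = s$x, stringsAsFactors = FALSE)
  df[order(df$barcode, df$gene_id), ]
}
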