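make_two_species_matrix <- function(umisA, umisB, barcodes = NULL) {
  # 2 genes, one per species; umisA/umisB give per-barcode UMIs
  gm <- gene_models(c("ec_g1", "bs_g1"), "mRNA", c("ecoli", "bsub"),
                    c(1L, 1L), c(1000L, 1000L))
  n <- length(umisA)
  if (is.null(barcodes)) barcodes <- sprintf("bc%04d", seq_len(n))
  counts <- rbind(umisA, umisB)
  dimnames(counts) <- list(NULL, barcodes)
  m <- microdrops:::new_umi_count_matrix(
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    gm, barcodes)
  list(matrix = m, species = c(ec_g1 = "ecoli", bs_g1 = "bsub"))
}

test_that("barnyard labels majority, mixed and computes the doublet rate", {
  # 3 pure A, 2 pure B, 1 genuine doublet, 1 A with trace B (not mixed)
  fx <- make_two_species_matrix(c(100, 80, 60, 0, 0, 50, 90),
                                c(0, 0, 0, 70, 110, 60, 3))
  rep_ <- barnyard(fx$matrix, fx$species)
  expect_equal(unname(rep_$species_counts["ecoli"]), 4L)
  expect_equal(unname(rep_$species_counts["bsub"]), 2L)
  expect_equal(rep_$mixed_count, 1L)
  expect_equal(rep_$doublet_rate, 1 / 7)
  # specificity: pure-A singlets all 1 except the trace one (90/93)
  expect_equal(unname(rep_$specificity["bsub"]), 1)
  expect_lt(unname(rep_$specificity["ecoli"]), 1 + 1e-12)

  # all barcodes pure species A
  fxA <- make_two_species_matrix(c(10, 20, 30), c(0, 0, 0))
  repA <- barnyard(fxA$matrix, fxA$species)
  expect_equal(repA$doublet_rate, 0)
  expect_equal(unname(repA$specificity["ecoli"]), 1)

  # doublet rate is invariant to species label order
  fx_sw <- make_two_species_matrix(c(0, 0, 0, 70, 110, 60, 3),
                                   c(100, 80, 60, 0, 0, 50, 90))
  expect_equal(barnyard(fx_sw$matrix, fx_sw$species)$doublet_rate,
               rep_$doublet_rate)
})

test_that("the printed two-species counts reproduce the 1.6% doublet rate", {
  rate <- doublet_rate_from_counts(c(202L, 45L), 4L)
  expect_equal(rate, 4 / 251)
  expect_equal(round(100 * rate, 1), 1.6)
})

test_that("simulated doublets are labelled mixed when ambient is zero", {
  s <- small_sim(seed = 121L, n_cells = c(150L, 150L), lambda = 0.8,
                 umi_meanlog = log(60),
                 wl = toy_whitelist(3L, c(24L, 24L, 8L)))
  res <- run_pipeline(s$sim, s$genes, s$config$r2_handle)
  sp_map <- species_gene_map(s$profiles)
  # balanced doublets are threshold-insensitive; loosen the thresholds so
  # the comparison with droplet truth is exact, not borderline
  rep_ <- barnyard(res$matrix, sp_map, min_umis = 5L, mixed_threshold = 0.1)
  dro <- s$sim$droplets
  true_mixed <- dro$barcode[vapply(dro$species_set, length, 1L) == 2L]
  got_mixed <- rep_$per_barcode$barcode[rep_$per_barcode$label == "mixed"]
  # every true cross-species doublet is called mixed; no pure barcode is
  expect_true(all(true_mixed %in% got_mixed))
  expect_true(all(got_mixed %in% true_mixed))
})

test_that("saturation is identity at full depth, zero at depth zero, monotone", {
  s <- small_sim(seed = 131L, n_cells = c(60L, 60L), umi_meanlog = log(40),
                 wl = toy_whitelist(3L, c(24L, 24L, 8L)))
  res <- run_pipeline(s$sim, s$genes, s$config$r2_handle)
  tagged <- res$tagged
  cells <- unique(tagged$barcode)
  full_depth <- nrow(tagged) / length(cells)
  depths <- c(1L, 5L, 10L, floor(full_depth))
  sc <- saturation(tagged, s$genes, cells, depths = depths, seed = 2L)
  expect_true(all(diff(stats::na.omit(sc$median_genes)) >= 0))
  # unattainable depth is NA, not an error
  sc2 <- saturation(tagged, s$genes, cells,
                    depths = c(10L, 10L * full_depth), seed = 2L)
  expect_true(is.na(sc2$median_genes[2L]))
  # full-library subsample equals the unsubsampled median
  per_cell <- tapply(tagged$gene_id, tagged$barcode,
                     function(g) length(unique(g)))
  md <- median(per_cell[cells])
  sc3 <- saturation(tagged, s$genes, cells, depths = floor(full_depth),
                    seed = 3L)
  expect_equal(sc3$median_genes[1L], unname(md))
  # monotone across seeds
  for (sd in 4:6) {
    sck <- saturation(tagged, s$genes, cells, depths = depths, seed = sd)
    expect_true(all(diff(stats::na.omit(sck$median_genes)) >= 0))
  }
})

test_that("coverage is flat under complete uniform tiling", {
  gm <- gene_models(c("g1", "g2"), "mRNA", "c1", c(1L, 3001L),
                    c(2000L, 4500L), c("+", "-"))
  # deterministic complete tiling: one single-base read per position
  al <- data.frame(contig = "c1",
                   start = c(1:2000, 3001:4500),
                   end = c(1:2000, 3001:4500))
  prof <- gene_body_coverage(al, gm)
  expect_length(prof, 100L)
  expect_equal(max(prof), 1)
  expect_true(all(abs(prof - 1) < 1e-12))
})

test_that("reads confined to the first 10% cover only the first 10 bins", {
  gm <- gene_models("g1", "mRNA", "c1", 1L, 1000L)
  al <- data.frame(contig = "c1", start = rep(1:100, 5L),
                   end = rep(1:100, 5L))
  prof <- gene_body_coverage(al, gm)
  expect_true(all(prof[1:10] > 0))
  expect_true(all(prof[11:100] == 0))
})

test_that("coverage of a reverse-strand gene is the mirror of the forward one", {
  gm <- gene_models(c("gf", "gr"), "mRNA", c("cf", "cr"), c(1L, 1L),
                    c(1000L, 1000L), c("+", "-"))
  # same physical pile-up on both contigs, biased to low coordinates
  al <- data.frame(contig = rep(c("cf", "cr"), each = 300L),
                   start = rep(sort(rep(1:300, 1L)), 2L),
                   end = rep(sort(rep(1:300, 1L)) + 9L, 2L))
  pf <- gene_body_coverage(al, gm[gm$gene_id == "gf", , drop = FALSE])
  pr <- gene_body_coverage(al, gm[gm$gene_id == "gr", , drop = FALSE])
  expect_equal(as.numeric(pf), rev(as.numeric(pr)))
})

test_that("5'-biased simulation yields a decreasing profile; uniform does not", {
  gm <- gene_models(sprintf("g%02d", 1:8), "mRNA", "c1",
                    seq(1L, by = 2000L, length.out = 8L),
                    seq(1L, by = 2000L, length.out = 8L) + 1499L,
                    rep(c("+", "-"), 4L))
  biased <- simulate_capture_positions(gm, 2e5, coverage_decay = 0.003,
                                       seed = 12L)
  pb <- gene_body_coverage(biased, gm)
  expect_lt(coverage_decay_slope(pb), -0.005)
  expect_gt(pb[1L], pb[100L])

  unif <- simulate_capture_positions(gm, 2e5, coverage_decay = 0, seed = 13L)
  pu <- gene_body_coverage(unif, gm)
  expect_gt(coverage_decay_slope(pu), -0.001)
})

test_that("pseudobulk correlation is 1 against itself and high for replicates", {
  s <- small_sim(seed = 141L, n_cells = c(60L, 60L), umi_meanlog = log(40),
                 wl = toy_whitelist(3L, c(24L, 24L, 8L)))
  res <- run_pipeline(s$sim, s$genes, s$config$r2_handle)
  expect_equal(pseudobulk_correlation(res$matrix, res$matrix), 1)

  # replicate with a different sampling seed, same generative profiles
  s2 <- small_sim(seed = 142L, n_cells = c(60L, 60L), umi_meanlog = log(40),
                  wl = toy_whitelist(3L, c(24L, 24L, 8L)))
  res2 <- run_pipeline(s2$sim, s2$genes, s2$config$r2_handle)
  expect_gte(pseudobulk_correlation(res$matrix, res2$matrix), 0.95)

  tiny <- make_two_species_matrix(c(1, 2), c(3, 4))
  expect_error(pseudobulk_correlation(tiny$matrix, tiny$matrix), "3")
})
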