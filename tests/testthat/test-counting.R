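test_that("interval assignment handles lone, ambiguous and unknown cases", {
  gm <- gene_models(c("gA", "gB", "gC"), "mRNA", c("c1", "c1", "c2"),
                    c(100L, 450L, 100L), c(500L, 900L, 400L))
  al <- data.frame(
    read_id = paste0("r", 1:5),
    contig = c("c1", "c1", "c1", "c3", "c1"),
    start = c(200L, 460L, 950L, 10L, 300L),
    end = c(260L, 480L, 990L, 60L, 360L),
    strand = "+",
    unique = c(1L, 1L, 1L, 1L, 0L), stringsAsFactors = FALSE)
  out <- assign_reads(al, gm)
  expect_equal(out$gene_id, c("gA", NA, NA, NA, NA))
  expect_equal(out$status,
               c("assigned", "ambiguous", "no_feature", "unknown_contig",
                 "not_unique"))
  # conservation: statuses partition all reads
  expect_equal(sum(unlist(attr(out, "assignment_counts"))), nrow(al))
})

test_that("perfect-aligner records reproduce the simulator's own assignment", {
  s <- small_sim(seed = 101L)
  out <- assign_reads(s$sim$alignments, s$genes)
  expect_true(all(out$status == "assigned"))
  expect_identical(out$gene_id,
                   s$sim$truth$gene_id[match(out$read_id,
                                             s$sim$truth$read_id)])
})

test_that("identical UMIs collapse once; directional merges 1-mismatch children", {
  gm <- gene_models("g1", "mRNA", "c", 1L, 1000L)
  tg <- data.frame(barcode = "b1", gene_id = "g1",
                   umi = c(rep("AAAAAAAA", 3L)), stringsAsFactors = FALSE)
  m <- count_umis(tg, gm)
  expect_equal(sum(m$counts), 1)

  # the hand-enumerated directional-network case: {AAAAAAAA x5, AAAAAAAT x1}
  # parent 5 >= 2*1 - 1, so directional merges to 1; exact keeps 2
  tg2 <- data.frame(barcode = "b1", gene_id = "g1",
                    umi = c(rep("AAAAAAAA", 5L), "AAAAAAAT"),
                    stringsAsFactors = FALSE)
  expect_equal(sum(count_umis(tg2, gm, collapse = "exact")$counts), 2)
  expect_equal(sum(count_umis(tg2, gm, collapse = "directional")$counts), 1)

  # counts 5 and 4: 5 < 2*4 - 1, so directional keeps both
  tg3 <- data.frame(barcode = "b1", gene_id = "g1",
                    umi = c(rep("AAAAAAAA", 5L), rep("AAAAAAAT", 4L)),
                    stringsAsFactors = FALSE)
  expect_equal(sum(count_umis(tg3, gm, collapse = "directional")$counts), 2)

  # a chain A(8) -> B(4) -> C(2) merges into one cluster
  tg4 <- data.frame(barcode = "b1", gene_id = "g1",
                    umi = c(rep("AAAAAAAA", 8L), rep("AAAAAAAT", 4L),
                            rep("AAAAAATT", 2L)), stringsAsFactors = FALSE)
  expect_equal(sum(count_umis(tg4, gm, collapse = "directional")$counts), 1)
})

test_that("UMI records of the wrong length are rejected and counted", {
  gm <- gene_models("g1", "mRNA", "c", 1L, 1000L)
  tg <- data.frame(barcode = "b1", gene_id = "g1",
                   umi = c("AAAAAAAA", "AAAA"), stringsAsFactors = FALSE)
  m <- count_umis(tg, gm)
  expect_equal(attr(m, "n_rejected_umi_length"), 1L)
  expect_equal(sum(m$counts), 1)
})

test_that("exact counting is invariant to read order and duplication", {
  gm <- gene_models(c("g1", "g2"), "mRNA", "c", c(1L, 2000L), c(1000L, 3000L))
  withr::with_seed(3L, {
    tg <- data.frame(
      barcode = sample(c("b1", "b2"), 200L, TRUE),
      gene_id = sample(c("g1", "g2"), 200L, TRUE),
      umi = sample(random_dna(40L, 8L), 200L, TRUE),
      stringsAsFactors = FALSE)
  })
  m1 <- count_umis(tg, gm)
  m2 <- count_umis(tg[rev(seq_len(nrow(tg))), ], gm)
  m3 <- count_umis(tg[rep(seq_len(nrow(tg)), 3L), ], gm)  # 3x duplication
  expect_equal(as.matrix(m1$counts), as.matrix(m2$counts))
  expect_equal(as.matrix(m1$counts), as.matrix(m3$counts))
  # per-barcode totals are consistent with the matrix
  expect_equal(m1$per_barcode$n_genes,
               unname(Matrix::colSums(m1$counts > 0)))
})

test_that("full chain on error-free simulation reproduces the truth matrix", {
  s <- small_sim(seed = 111L)
  res <- run_pipeline(s$sim, s$genes, s$config$r2_handle)
  got <- matrix_triplets(res$matrix)
  want <- truth_triplets(s$sim$truth)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got$barcode, want$barcode)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$count, want$count)
})

test_that("biotype proportions cover the five categories and sum to one", {
  gm <- gene_models(c("g1", "g2"), c("rRNA", "mRNA"), "c",
                    c(1L, 2000L), c(1000L, 3000L))
  asg <- data.frame(read_id = paste0("r", 1:4),
                    gene_id = c("g1", "g1", "g2", NA),
                    stringsAsFactors = FALSE)
  rep_ <- biotype_report(asg, gm)
  expect_equal(sum(unlist(rep_$proportions)), 1)
  expect_equal(rep_$proportions$rRNA, 0.5)
  expect_equal(rep_$proportions$unassigned, 0.25)

  # all-rRNA input
  all_r <- biotype_report(data.frame(read_id = "r", gene_id = "g1"), gm)
  expect_equal(all_r$proportions$rRNA, 1)

  # empty input: explicit zero totals
  empty <- biotype_report(data.frame(read_id = character(),
                                     gene_id = character()), gm)
  expect_equal(empty$total, 0)
  expect_true(all(unlist(empty$counts) == 0))
})

test_that("SAM adapter maps mapped records with MAPQ above threshold", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:10000",
    paste("r1", "0", "c1", "100", "60", "10M", "*", "0", "0",
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r2", "16", "c1", "200", "0", "10M", "*", "0", "0",
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r3", "4", "*", "0", "0", "*", "*", "0", "0",
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t")), sam)
  al <- read_sam_alignments(sam)
  expect_equal(nrow(al), 2L)
  expect_equal(al$unique, c(1L, 0L))
  expect_equal(al$strand, c("+", "-"))
  expect_equal(al$end[1L], 109L)
})
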