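test_that("guide enumeration matches constructed single-site cases", {
  # 23-nt target with a PAM GG on the forward strand only
  t1 <- c(t1 = "ACACACACACACACACACACTGG")
  g <- enumerate_guides(t1)
  expect_equal(nrow(g), 1L)
  expect_equal(g$strand, "+")
  expect_equal(g$spacer, unname(substr(t1, 1L, 20L)))
  expect_equal(g$pam, "TGG")
  expect_equal(g$cut_pos, 17L)

  # no GG or CC dinucleotide anywhere: no candidates
  t2 <- c(t2 = paste(rep("AT", 20L), collapse = ""))
  expect_equal(nrow(enumerate_guides(t2)), 0L)

  # shorter than 23 nt: empty list
  expect_equal(nrow(enumerate_guides(c(s = "ACGTGG"))), 0L)
})

test_that("guide enumeration equals the brute-force both-strand scan", {
  withr::with_seed(17L, seqs <- random_dna(10L, 2000L))
  for (k in seq_along(seqs)) {
    got <- enumerate_guides(setNames(seqs[k], "t"))
    want <- brute_guide_scan(seqs[k])
    got_key <- sort(paste(got$spacer, got$pam, got$strand, got$cut_pos))
    want_key <- sort(paste(want$spacer, want$pam, want$strand, want$cut_pos))
    expect_identical(got_key, want_key)
  }
})

test_that("guide filters drop GC extremes, homopolymers and seed off-targets", {
  cand <- data.frame(
    target_gene = "t",
    spacer = c("ATATATATATATATATATAT",      # GC 0
               "GCGCGCGCGCATATATATAT",      # GC 0.5, clean
               "GCGCGCGCGCATATTTTTAT",      # contains TTTT
               "GCGCGCGCGCAAAAATATAT",      # A x5 homopolymer
               "GCGCACGTACGTACGTACGT"),     # clean, used for off-target
    pam = "AGG", strand = "+", cut_pos = c(100L, 200L, 300L, 400L, 500L),
    gc_fraction = c(0, 0.5, 0.35, 0.5, 0.5), stringsAsFactors = FALSE)
  kept <- filter_guides(cand)
  expect_equal(kept$cut_pos, c(200L, 500L))

  # off-target: plant seed (spacer 9..20) + NGG of the last guide in a
  # non-rRNA sequence, verified against a brute-force substring search
  seed12 <- substr(cand$spacer[5L], 9L, 20L)
  offt <- paste0("CCCCC", seed12, "TGG", "CCCCC")
  kept2 <- filter_guides(cand, offtarget_seqs = offt)
  expect_equal(kept2$cut_pos, 200L)
  expect_true(grepl(paste0(seed12, "[ACGT]GG"), offt))
})

test_that("greedy tiling is minimal and respects max_gap on toy instances", {
  # candidates every 10 nt on a 500-nt gene
  cand <- data.frame(target_gene = "t",
                     spacer = strrep("A", 20L), pam = "AGG", strand = "+",
                     cut_pos = seq(10L, 490L, by = 10L),
                     gc_fraction = 0.5, stringsAsFactors = FALSE)
  gs <- tile_guides(cand, max_gap = 50L, target_lengths = c(t = 500L))
  cuts <- sort(gs$guides$cut_pos)
  gaps <- diff(c(0L, cuts, 500L))
  expect_true(all(gaps <= 50L))
  expect_equal(nrow(gs$guides),
               brute_min_cover_size(cand$cut_pos, 50L, 500L))

  # irregular candidate spacing, still minimal
  withr::with_seed(23L, irr <- sort(sample(5:295, 12L)))
  cand2 <- cand[seq_along(irr), ]
  cand2$cut_pos <- irr
  gs2 <- tile_guides(cand2, max_gap = 60L, target_lengths = c(t = 300L))
  if (nrow(gs2$uncovered) == 0L) {
    expect_equal(nrow(gs2$guides),
                 brute_min_cover_size(irr, 60L, 300L))
  }

  # single candidate is selected; empty candidate set stays empty
  single <- cand[1L, ]
  gs3 <- suppressWarnings(tile_guides(single, max_gap = 50L,
                                      target_lengths = c(t = 500L)))
  expect_equal(nrow(gs3$guides), 1L)
  gs4 <- tile_guides(cand[0L, ], max_gap = 50L)
  expect_equal(nrow(gs4$guides), 0L)

  # a candidate desert is recorded as an uncovered interval, not an error
  gapped <- cand[cand$cut_pos <= 100L | cand$cut_pos >= 300L, ]
  expect_warning(gs5 <- tile_guides(gapped, max_gap = 50L,
                                    target_lengths = c(t = 500L)),
                 "uncovered")
  expect_gt(nrow(gs5$uncovered), 0L)
})

test_that("digestion composition algebra holds and conserves non-rRNA", {
  # d = 0 leaves the composition unchanged
  mols <- data.frame(insert = random_dna(50L, 60L),
                     is_rrna = rep(c(TRUE, FALSE), 25L))
  empty_guides <- data.frame(target_gene = character(), spacer = character(),
                             pam = character(), strand = character(),
                             cut_pos = integer(), stringsAsFactors = FALSE)
  rep0 <- digest_in_silico(mols, empty_guides, initial_rrna_fraction = 0.83)
  expect_equal(rep0$depleted_fraction, 0)
  expect_equal(rep0$predicted_post_rrna_fraction, 0.83)
  expect_equal(rep0$n_non_rrna_out, rep0$n_non_rrna_in)

  # fully tiled molecules: every rRNA molecule spans a cut site -> d == 1
  withr::with_seed(29L, target <- random_dna(1L, 400L))
  site <- "GCGCACGTACGTACGTACGTAGG"  # protospacer + PAM planted verbatim
  target <- paste0(substr(target, 1L, 100L), site,
                   substr(target, 124L, 400L))
  guides <- data.frame(target_gene = "t",
                       spacer = substr(site, 1L, 20L),
                       pam = substr(site, 21L, 23L),
                       strand = "+", cut_pos = 117L, stringsAsFactors = FALSE)
  rr <- data.frame(insert = substring(target, 95L + 0:5, 95L + 0:5 + 40L),
                   is_rrna = TRUE)
  rr$insert <- substring(target, 95L, 130L)  # all span the full site
  nr <- data.frame(insert = random_dna(20L, 36L), is_rrna = FALSE)
  repF <- digest_in_silico(rbind(rr, nr), guides)
  expect_equal(repF$depleted_fraction, 1)
  expect_equal(repF$n_non_rrna_out, 20L)
  # reverse-orientation inserts are cut too
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rr$insert[1L])))
  repR <- digest_in_silico(data.frame(insert = rc, is_rrna = TRUE), guides)
  expect_equal(repR$depleted_fraction, 1)

  # algebra: r = 0.83, d = 0.904 -> post close to 0.32
  post <- 0.83 * (1 - 0.904) / (0.83 * (1 - 0.904) + 0.17)
  expect_equal(post, 0.319, tolerance = 1e-3)
})

test_that("depletion is monotone non-increasing in max_gap", {
  withr::with_seed(31L, target <- random_dna(1L, 3000L))
  cand <- enumerate_guides(c(rr = target))
  filt <- filter_guides(cand)
  starts <- withr::with_seed(32L, sample(1:(3000L - 149L), 1500L,
                                         replace = TRUE))
  mols <- data.frame(insert = substring(target, starts, starts + 149L),
                     is_rrna = TRUE)
  d_prev <- 1
  for (gap in c(40L, 80L, 160L, 320L)) {
    gs <- suppressWarnings(tile_guides(filt, max_gap = gap,
                                       target_lengths = c(rr = 3000L)))
    d <- digest_in_silico(mols, gs)$depleted_fraction
    expect_lte(d, d_prev + 1e-12)
    d_prev <- d
  }
})

test_that("transcription templates follow the T7 rules and round-trip", {
  guides <- data.frame(
    target_gene = c("t", "t"),
    spacer = c("GACGTACGTACGTACGTACG",    # starts with G
               "ACGTACGTACGTACGTACGA"),   # does not
    pam = "AGG", strand = c("+", "-"), cut_pos = c(50L, 150L),
    stringsAsFactors = FALSE)
  tmpl <- emit_templates(guides)
  t7 <- microdrops:::.T7_PROMOTER; sc <- microdrops:::.SGRNA_SCAFFOLD
  expect_equal(nchar(tmpl$template[1L]), nchar(t7) + 20L + nchar(sc))
  expect_equal(nchar(tmpl$template[2L]), nchar(t7) + 21L + nchar(sc))

  fa <- withr::local_tempfile(fileext = ".fasta")
  emit_templates(guides, path = fa)
  back <- parse_templates(fa)
  expect_equal(back$spacer, guides$spacer)
  expect_equal(back$cut_pos, guides$cut_pos)
  expect_equal(back$strand, guides$strand)
})
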