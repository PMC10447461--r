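# Read-level simulator emulating the droplet single-microbe library chemistry:
# random-primer capture with 5'->3' positional decay, dA tailing (a trailing
# A-run on Read2), droplet co-encapsulation of cells with barcoded beads
# (Poisson loading), rRNA-dominated biotype composition, per-cell UMI budgets
# and uniform barcode sequencing errors. Every emitted read carries ground
# truth, and a "perfect aligner" TSV gives each read's true locus so the
# downstream counting chain can be verified exactly.

#' Poisson droplet loading statistics
#'
#' For a mean of `lambda` cells per droplet, the droplet occupancy K is
#' Poisson(lambda): the empty fraction is `exp(-lambda)`, the singlet
#' fraction (among all droplets) is `lambda * exp(-lambda)`, and the
#' multiplet fraction among occupied droplets is
#' `(1 - exp(-lambda) - lambda*exp(-lambda)) / (1 - exp(-lambda))`.
#'
#' @param lambda Mean cells per droplet; must be positive.
#' @return A list with `empty_fraction`, `singlet_fraction`,
#'   `multiplet_fraction_among_occupied`.
#' @export
loading_stats <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("lambda must be a single positive number")
  }
  p0 <- exp(-lambda)
  p1 <- lambda * exp(-lambda)
  list(
    empty_fraction = p0,
    singlet_fraction = p1,
    multiplet_fraction_among_occupied = (1 - p0 - p1) / (1 - p0)
  )
}

#' Synthesize a species transcriptome profile
#'
#' Builds a synthetic bacterial species: `n_genes` single-interval genes laid
#' end to end (with gaps) on one contig, each with a random sequence, a
#' biotype, and a within-biotype relative abundance. Molecule sampling first
#' picks the biotype -- rRNA with probability `rrna_read_fraction` (default
#' 0.83, the pre-depletion rRNA dominance typical of bacterial libraries),
#' the remainder split by `nonrrna_read_props` -- then a gene within that
#' biotype by abundance.
#'
#' @param name Species name (also the contig name).
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param gene_length_range Min/max gene length (nt).
#' @param biotype_gene_props Fraction of genes per biotype (gene counts, not
#'   reads); at least one gene per biotype is forced.
#' @param rrna_read_fraction Fraction of captured molecules that are
#'   rRNA-derived (default 0.83).
#' @param nonrrna_read_props Split of the non-rRNA molecule mass over
#'   mRNA/tRNA/ncRNA.
#' @return An object of class `species_profile` with fields `name`, `genes`
#'   (a `gene_models` table), `sequences` (named character), `abundance`
#'   (per gene, sums to 1 within each biotype), `rrna_read_fraction`,
#'   `nonrrna_read_props`.
#' @export
synthesize_species_profile <- function(
    name, seed = 1L, n_genes = 60L,
    gene_length_range = c(500L, 1500L),
    biotype_gene_props = c(mRNA = 0.80, rRNA = 0.06, tRNA = 0.07,
                           ncRNA = 0.07),
    rrna_read_fraction = 0.83,
    nonrrna_read_props = c(mRNA = 16 / 17, tRNA = 0.5 / 17, ncRNA = 0.5 / 17)) {
  stopifnot(rrna_read_fraction >= 0, rrna_read_fraction <= 1, n_genes >= 4L)
  withr::with_seed(as.integer(seed), {
    bt_n <- round(n_genes * biotype_gene_props / sum(biotype_gene_props))
    bt_n <- pmax(bt_n, 1L)
    while (sum(bt_n) > n_genes) bt_n["mRNA"] <- bt_n["mRNA"] - 1L
    while (sum(bt_n) < n_genes) bt_n["mRNA"] <- bt_n["mRNA"] + 1L
    biotype <- sample(rep(names(bt_n), bt_n))
    lens <- sample(seq(gene_length_range[1L], gene_length_range[2L]),
                   n_genes, replace = TRUE)
    gap <- 200L
    starts <- cumsum(c(1L, head(lens, -1L) + gap))
    genes <- gene_models(
      gene_id = sprintf("%s_g%03d", name, seq_len(n_genes)),
      biotype = biotype, contig = name, start = starts,
      end = starts + lens - 1L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
    seqs <- setNames(.random_dna_lengths(lens), genes$gene_id)
    # gamma-distributed expression, normalized within each biotype
    ab <- stats::rgamma(n_genes, shape = 0.8, rate = 1) + 1e-6
    for (bt in unique(genes$biotype)) {
      sel <- genes$biotype == bt
      ab[sel] <- ab[sel] / sum(ab[sel])
    }
  })
  nonrrna_read_props <- nonrrna_read_props / sum(nonrrna_read_props)
  structure(list(name = name, genes = genes, sequences = seqs,
                 abundance = ab, rrna_read_fraction = rrna_read_fraction,
                 nonrrna_read_props = nonrrna_read_props),
            class = "species_profile")
}

# random DNA strings of varying lengths
.random_dna_lengths <- function(lens) {
  all <- sample(.DNA, sum(lens), replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_along(lens),
         function(i) paste(all[starts[i]:ends[i]], collapse = ""),
         character(1))
}

# molecule-level gene sampling probability for one species profile
.gene_probs <- function(profile) {
  genes <- profile$genes
  r <- profile$rrna_read_fraction
  share <- profile$nonrrna_read_props
  p <- numeric(nrow(genes))
  has_rrna <- any(genes$biotype == "rRNA")
  for (bt in unique(genes$biotype)) {
    sel <- genes$biotype == bt
    mass <- if (bt == "rRNA") r else {
      (if (has_rrna) 1 - r else 1) * share[[bt]]
    }
    p[sel] <- mass * profile$abundance[sel]
  }
  p / sum(p)
}

# truncated geometric capture start: P(pos = k) ~ (1-p)^(k-1) * p, k in 1..L
# (L may be a vector, one truncation bound per draw); p = 0 degenerates to
# the uniform distribution (no positional bias).
.rtrunc_geom <- function(n, p, L) {
  if (p <= 0) return(pmax(1L, as.integer(ceiling(runif(n) * L))))
  u <- runif(n)
  pos <- floor(log1p(-u * (1 - (1 - p)^L)) / log1p(-p)) + 1
  as.integer(pmin(pmax(pos, 1), L))
}

#' Simulation configuration
#'
#' @param species_profiles List of `species_profile` objects.
#' @param n_cells Integer vector: cells per species (recycled to match).
#' @param loading_lambda Mean cells per droplet (Poisson loading).
#' @param umi_per_cell_meanlog,umi_per_cell_sdlog Log-normal parameters of
#'   the per-cell molecule (UMI) budget.
#' @param reads_per_umi_mean Mean reads per molecule (PCR duplication);
#'   each molecule gets `1 + Poisson(mean - 1)` reads.
#' @param insert_length_range cDNA insert length range in nt (default
#'   100--400, matching the library's insert sizes after adapter removal).
#' @param coverage_decay Per-nt geometric decay of the capture start
#'   position from the 5' end; 0 gives uniform capture.
#' @param barcode_error_rate Per-base substitution rate applied to the
#'   30-nt barcode in Read1.
#' @param r1_length Read1 length (UMI + barcode + poly(T) fill).
#' @param r2_handle Constant 5' handle on Read2 (the random-primer PCR
#'   handle); trimmed by the demultiplexer.
#' @param da_tail_range Range of the Read2 trailing A-run (dA tailing).
#' @param seed Master seed; the same configuration is byte-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(species_profiles, n_cells,
                       loading_lambda = 0.1,
                       umi_per_cell_meanlog = log(40), umi_per_cell_sdlog = 0.4,
                       reads_per_umi_mean = 5,
                       insert_length_range = c(100L, 400L),
                       coverage_decay = 0.003,
                       barcode_error_rate = 0,
                       r1_length = 50L,
                       r2_handle = "GATTGGAGTG",
                       da_tail_range = c(6L, 12L),
                       seed = 1L) {
  stopifnot(loading_lambda > 0, length(species_profiles) >= 1L,
            insert_length_range[1L] >= 1L,
            insert_length_range[2L] >= insert_length_range[1L],
            barcode_error_rate >= 0, barcode_error_rate < 1)
  n_cells <- rep_len(as.integer(n_cells), length(species_profiles))
  structure(list(species_profiles = species_profiles, n_cells = n_cells,
                 loading_lambda = loading_lambda,
                 umi_per_cell_meanlog = umi_per_cell_meanlog,
                 umi_per_cell_sdlog = umi_per_cell_sdlog,
                 reads_per_umi_mean = reads_per_umi_mean,
                 insert_length_range = as.integer(insert_length_range),
                 coverage_decay = coverage_decay,
                 barcode_error_rate = barcode_error_rate,
                 r1_length = as.integer(r1_length),
                 r2_handle = toupper(r2_handle),
                 da_tail_range = as.integer(da_tail_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a paired-read library with ground truth
#'
#' Cells are thrown into droplets (multinomial occupancy approximating
#' Poisson loading at `loading_lambda`); droplets holding three or more cells
#' are collapsed to two. Each occupied droplet receives a distinct whitelist
#' barcode. Every cell draws a log-normal molecule budget; each molecule gets
#' a random 8-nt UMI, a gene (biotype first: rRNA with the profile's
#' `rrna_read_fraction`), a capture start with 5'-weighted geometric decay
#' and an insert length from `insert_length_range` (truncated at the gene
#' end), and `1 + Poisson` PCR duplicate reads. Read1 is
#' UMI + 30-nt barcode (+ poly(T) fill), with substitution errors injected in
#' the barcode at `barcode_error_rate`; Read2 is the constant handle + the
#' cDNA fragment + a dA tail.
#'
#' @param config A `sim_config`.
#' @param whitelist A `barcode_whitelist` (or a `bead_primer_design`, from
#'   which the whitelist is built). Must hold at least as many barcodes as
#'   occupied droplets.
#' @return An object of class `microdrops_sim`: `r1`, `r2` (FASTQ-style read
#'   tables), `truth` (per-read: `read_id`, `barcode_true`, `cell_id`,
#'   `species`, `gene_id`, `biotype`, `umi`, `capture_pos`, `insert_len`,
#'   `ambient`), `alignments` (perfect-aligner table: `read_id`, `contig`,
#'   `start`, `end`, `strand`, `unique`), `droplets` (barcode-level truth:
#'   species set, singlet/doublet), `whitelist`, `config`.
#' @export
simulate_library <- function(config, whitelist) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(whitelist, "bead_primer_design")) {
    whitelist <- build_whitelist(whitelist)
  }
  stopifnot(inherits(whitelist, "barcode_whitelist"))

  profiles <- config$species_profiles
  species_names <- vapply(profiles, `[[`, character(1), "name")
  total_cells <- sum(config$n_cells)

  withr::with_seed(config$seed, {
    ## --- droplets -----------------------------------------------------
    cell_species <- rep(species_names, config$n_cells)
    n_droplets <- max(2L, round(total_cells / config$loading_lambda))
    droplet_of_cell <- sample.int(n_droplets, total_cells, replace = TRUE)
    # collapse k >= 3 co-encapsulations to 2 cells (negligible at low lambda)
    ord <- order(droplet_of_cell)
    within_idx <- stats::ave(seq_along(ord), droplet_of_cell[ord],
                             FUN = seq_along)
    keep_cell <- logical(total_cells)
    keep_cell[ord] <- within_idx <= 2L
    cells <- data.table::data.table(
      cell_id = sprintf("cell%05d", seq_len(total_cells)),
      species = cell_species, droplet = droplet_of_cell)[keep_cell]
    occupied <- sort(unique(cells$droplet))
    if (length(occupied) > whitelist$n) {
      stop("capacity error: ", length(occupied),
           " occupied droplets exceed whitelist size ", whitelist$n)
    }
    bc_idx <- sample.int(whitelist$n, length(occupied))
    droplet_barcode <- setNames(whitelist$barcodes[bc_idx],
                                as.character(occupied))
    cells[, barcode := droplet_barcode[as.character(droplet)]]

    ## --- molecules ----------------------------------------------------
    n_umis <- pmax(1L, as.integer(round(rlnorm(nrow(cells),
                                               config$umi_per_cell_meanlog,
                                               config$umi_per_cell_sdlog))))
    mol <- cells[rep(seq_len(nrow(cells)), n_umis),
                 .(cell_id, species, barcode)]
    mol[, umi := .random_dna(.N, 8L)]
    # per-species gene draw
    mol[, gene_idx := 0L]
    for (si in seq_along(profiles)) {
      pr <- profiles[[si]]
      sel <- which(mol$species == pr$name)
      if (length(sel)) {
        mol$gene_idx[sel] <- sample.int(nrow(pr$genes), length(sel),
                                        replace = TRUE,
                                        prob = .gene_probs(pr))
      }
    }
    gene_tab <- data.table::rbindlist(lapply(profiles, function(pr) {
      data.table::data.table(species = pr$name,
                             gene_id = pr$genes$gene_id,
                             biotype = pr$genes$biotype,
                             contig = pr$genes$contig,
                             g_start = pr$genes$start,
                             g_len = pr$genes$length,
                             seq = unname(pr$sequences[pr$genes$gene_id]))
    }))
    gene_tab[, row_in_species := seq_len(.N), by = species]
    data.table::setkey(gene_tab, species, row_in_species)
    mol <- gene_tab[mol, on = c(species = "species",
                                row_in_species = "gene_idx")]
    # leave at least the minimum insert length downstream of the capture
    # start (fragments below the size selection would be lost anyway, and a
    # fragment shorter than the dA tail would be indistinguishable from it)
    mol[, capture_pos := .rtrunc_geom(
      .N, config$coverage_decay,
      pmax(1L, g_len - config$insert_length_range[1L] + 1L))]
    mol[, insert_len := pmin(
      sample(seq(config$insert_length_range[1L],
                 config$insert_length_range[2L]), .N, replace = TRUE),
      g_len - capture_pos + 1L)]

    ## --- reads (PCR duplicates share the molecule's fragment) ---------
    n_reads <- 1L + rpois(nrow(mol), max(0, config$reads_per_umi_mean - 1))
    reads <- mol[rep(seq_len(nrow(mol)), n_reads)]
    reads[, read_id := sprintf("read%07d", seq_len(.N))]

    ## --- R1: UMI + barcode (+ errors) + poly(T) fill -------------------
    bc <- reads$barcode
    if (config$barcode_error_rate > 0) {
      bl <- whitelist$barcode_length
      bm <- matrix(unlist(strsplit(bc, "", fixed = TRUE)),
                   ncol = bl, byrow = TRUE)
      hit <- matrix(runif(length(bm)) < config$barcode_error_rate,
                    ncol = bl)
      n_hit <- sum(hit)
      if (n_hit) {
        # substitute with one of the three other bases, uniformly
        shift <- sample.int(3L, n_hit, replace = TRUE)
        bm[hit] <- .DNA[((match(bm[hit], .DNA) - 1L + shift) %% 4L) + 1L]
      }
      bc <- do.call(paste0, as.data.frame(bm, stringsAsFactors = FALSE))
    }
    fill <- config$r1_length - 8L - whitelist$barcode_length
    r1_seq <- paste0(reads$umi, bc,
                     if (fill > 0L) strrep("T", fill) else "")
    ## --- R2: handle + fragment + dA tail -------------------------------
    frag <- substr(reads$seq, reads$capture_pos,
                   reads$capture_pos + reads$insert_len - 1L)
    tails <- sample(seq(config$da_tail_range[1L], config$da_tail_range[2L]),
                    nrow(reads), replace = TRUE)
    r2_seq <- paste0(config$r2_handle, frag, strrep("A", tails))
  })

  r1 <- data.frame(id = reads$read_id, seq = r1_seq,
                   qual = strrep("I", nchar(r1_seq)), stringsAsFactors = FALSE)
  r2 <- data.frame(id = reads$read_id, seq = r2_seq,
                   qual = strrep("I", nchar(r2_seq)), stringsAsFactors = FALSE)
  truth <- reads[, .(read_id, barcode_true = barcode, cell_id, species,
                     gene_id, biotype, umi, capture_pos, insert_len)]
  truth[, ambient := FALSE]
  alignments <- reads[, .(read_id, contig,
                          start = g_start + capture_pos - 1L,
                          end = g_start + capture_pos + insert_len - 2L,
                          strand = "+", unique = 1L)]
  droplets <- cells[, .(cell_ids = list(cell_id),
                        species_set = list(sort(unique(species))),
                        n_cells = .N), by = barcode]
  droplets[, is_doublet := n_cells >= 2L]

  structure(list(r1 = r1, r2 = r2, truth = truth, alignments = alignments,
                 droplets = droplets, whitelist = whitelist, config = config),
            class = "microdrops_sim")
}

#' @export
print.microdrops_sim <- function(x, ...) {
  cat("Simulated library:", nrow(x$r1), "read pairs,",
      nrow(x$droplets), "barcoded droplets (",
      sum(x$droplets$is_doublet), "doublets),",
      length(unique(x$truth$cell_id)), "cells\n")
  invisible(x)
}

#' Inject ambient (cross-cell) molecules
#'
#' Re-draws a fraction of each barcode's reads from the pooled molecule pool
#' of all cells, emulating free-floating RNA shared across droplets. Truth,
#' Read2 and the perfect-aligner table are updated; the read keeps its
#' droplet barcode and UMI.
#'
#' @param sim A `microdrops_sim`.
#' @param ambient_rate Fraction of reads to re-draw, in [0, 1).
#' @param seed Seed for the re-draw (default derived from the simulation
#'   seed).
#' @return The modified `microdrops_sim`.
#' @export
inject_ambient <- function(sim, ambient_rate,
                           seed = sim$config$seed + 7919L) {
  stopifnot(inherits(sim, "microdrops_sim"),
            ambient_rate >= 0, ambient_rate < 1)
  if (ambient_rate == 0) return(sim)
  n <- nrow(sim$truth)
  withr::with_seed(as.integer(seed), {
    flip <- which(runif(n) < ambient_rate)
    donor <- sample.int(n, length(flip), replace = TRUE)
  })
  if (!length(flip)) return(sim)
  cols <- c("species", "gene_id", "biotype", "capture_pos", "insert_len")
  for (cl in cols) {
    data.table::set(sim$truth, i = flip, j = cl, sim$truth[[cl]][donor])
  }
  data.table::set(sim$truth, i = flip, j = "ambient", TRUE)
  for (cl in c("contig", "start", "end")) {
    data.table::set(sim$alignments, i = flip, j = cl,
                    sim$alignments[[cl]][donor])
  }
  sim$r2$seq[flip] <- sim$r2$seq[donor]
  sim$r2$qual[flip] <- sim$r2$qual[donor]
  sim
}

#' Combined gene models of several species profiles
#'
#' @param profiles List of `species_profile` objects.
#' @return A single `gene_models` table over all species (contigs stay
#'   species-specific).
#' @export
combine_gene_models <- function(profiles) {
  g <- data.table::rbindlist(lapply(profiles, function(p)
    as.data.frame(p$genes)))
  gene_models(g$gene_id, g$biotype, g$contig, g$start, g$end, g$strand)
}

#' Gene-to-species map of several species profiles
#'
#' @param profiles List of `species_profile` objects.
#' @return Named character vector: `gene_id` -> species name.
#' @export
species_gene_map <- function(profiles) {
  unlist(lapply(profiles, function(p)
    setNames(rep(p$name, nrow(p$genes)), p$genes$gene_id)))
}

#' Simulate capture positions only (no sequence synthesis)
#'
#' A molecule-level positional generator for coverage and saturation studies
#' that only need alignment intervals: each read picks a gene (uniformly by
#' default), a capture start with the same truncated-geometric 5' bias as
#' [simulate_library()], and an insert length. Orders of magnitude faster
#' than synthesizing read sequences.
#'
#' @param genes A `gene_models` table.
#' @param n_reads Number of reads to place.
#' @param coverage_decay Per-nt geometric decay of the capture start; 0 is
#'   uniform.
#' @param insert_length_range Insert length range (nt), truncated at gene end.
#' @param seed Integer seed.
#' @param gene_weights Optional sampling weight per gene (default uniform).
#' @return A `data.table` with `read_id`, `contig`, `start`, `end`, `strand`,
#'   `unique`, plus truth columns `gene_id`, `capture_pos`, `insert_len`.
#' @export
simulate_capture_positions <- function(genes, n_reads, coverage_decay = 0,
                                       insert_length_range = c(1L, 1L),
                                       seed = 1L, gene_weights = NULL) {
  stopifnot(inherits(genes, "gene_models"), n_reads >= 1L)
  withr::with_seed(as.integer(seed), {
    gi <- sample.int(nrow(genes), n_reads, replace = TRUE,
                     prob = gene_weights)
    g_len <- genes$length[gi]
    pos <- .rtrunc_geom(n_reads, coverage_decay, g_len)
    ins <- pmin(sample(seq(insert_length_range[1L], insert_length_range[2L]),
                       n_reads, replace = TRUE),
                g_len - pos + 1L)
  })
  # orient by gene strand: capture_pos counts from the transcript 5' end
  gstart <- genes$start[gi]; gend <- genes$end[gi]
  fwd <- genes$strand[gi] == "+"
  start <- ifelse(fwd, gstart + pos - 1L, gend - pos - ins + 2L)
  data.table::data.table(
    read_id = sprintf("pread%08d", seq_len(n_reads)),
    contig = genes$contig[gi],
    start = as.integer(start),
    end = as.integer(start + ins - 1L),
    strand = genes$strand[gi],
    unique = 1L,
    gene_id = genes$gene_id[gi],
    capture_pos = as.integer(pos),
    insert_len = as.integer(ins))
}
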