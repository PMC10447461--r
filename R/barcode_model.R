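# Split-pool bead primer model and combinatorial barcode whitelist.
#
# Beads carry a single primer species built in three ligation rounds on top of
# a PCR handle: handle -- [round-1 segment] -- linker -- [round-2 segment] --
# linker -- [round-3 segment] -- UMI -- poly(T). The three segments
# concatenated (without linkers) form the 30-nt cell barcode observed in
# Read1. Default round cardinalities 96 x 96 x 48 give a whitelist of
# 442,368 barcodes.

.DNA <- c("A", "C", "G", "T")

.random_dna <- function(n, len) {
  m <- matrix(sample(.DNA, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# character strings -> integer matrix (one row per string), for Hamming math
.seq_int_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1L)
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), .DNA),
              nrow = length(x), byrow = TRUE)
  m
}

#' Generate split-pool segment sets with a guaranteed intra-round distance
#'
#' Draws random DNA segments for each ligation round, accepting a candidate
#' only if its Hamming distance to every segment already accepted in that
#' round is at least `min_intra_round_distance`. With the default minimum
#' distance of 3, up to two sequencing errors confined to one round can never
#' convert one segment into another ambiguously.
#'
#' @param seed Integer seed; the same seed reproduces the same sets.
#' @param cardinalities Number of segments per round (default `c(96, 96, 48)`).
#' @param lengths Segment length (nt) per round (default `c(10, 10, 10)`;
#'   must sum to 30 to form the 30-nt cell barcode).
#' @param min_intra_round_distance Minimum pairwise Hamming distance within a
#'   round (default 3).
#' @return A list of class `segment_sets`: one element per round with fields
#'   `round_index` and `segments`; attributes record the observed minimum
#'   intra-round distance.
#' @export
generate_segment_sets <- function(seed, cardinalities = c(96L, 96L, 48L),
                                  lengths = c(10L, 10L, 10L),
                                  min_intra_round_distance = 3L) {
  stopifnot(length(cardinalities) == length(lengths))
  d <- as.integer(min_intra_round_distance)
  # Singleton bound: a code of length L and min distance d holds at most
  # 4^(L - d + 1) words; reject demands that exceed it.
  for (r in seq_along(cardinalities)) {
    cap <- 4^(lengths[r] - d + 1)
    if (cardinalities[r] > cap) {
      stop("capacity error: round ", r, " requests ", cardinalities[r],
           " segments of length ", lengths[r], " at min distance ", d,
           " (Singleton bound ", cap, ")")
    }
  }
  sets <- vector("list", length(cardinalities))
  observed_min <- rep(Inf, length(cardinalities))
  withr::with_seed(as.integer(seed), {
    for (r in seq_along(cardinalities)) {
      k <- cardinalities[r]; L <- lengths[r]
      accepted <- matrix(NA_integer_, nrow = k, ncol = L)
      n_acc <- 0L
      tries <- 0L
      max_tries <- 5000L + 500L * k
      while (n_acc < k) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("capacity error: could not place ", k, " segments of length ",
               L, " at min distance ", d, " in round ", r,
               " after ", max_tries, " draws")
        }
        cand <- sample.int(4L, L, replace = TRUE)
        ok <- if (n_acc == 0L) TRUE else {
          dists <- rowSums(accepted[seq_len(n_acc), , drop = FALSE] !=
                             matrix(cand, nrow = n_acc, ncol = L, byrow = TRUE))
          all(dists >= d)
        }
        if (ok) {
          n_acc <- n_acc + 1L
          accepted[n_acc, ] <- cand
        }
      }
      segs <- apply(accepted, 1L, function(row) paste(.DNA[row], collapse = ""))
      sets[[r]] <- list(round_index = r, segments = segs)
      observed_min[r] <- if (k > 1L) {
        min_pairwise_hamming_cpp(segs)
      } else Inf
    }
  })
  structure(sets, class = "segment_sets",
            min_intra_round_distance = min(observed_min))
}

#' Serialize segment sets as a TSV table
#'
#' Columns `round`, `index`, `sequence`; the format real bead manifests can be
#' dropped into.
#'
#' @param sets A `segment_sets` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    data.frame(round = s$round_index, index = seq_along(s$segments),
               sequence = s$segments, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segment sets from a TSV table
#'
#' User-supplied tables are validated (unique, equal length within a round)
#' and the observed minimum intra-round Hamming distance is recorded;
#' ambiguity is reported, never repaired.
#'
#' @param path TSV with columns `round`, `index`, `sequence`.
#' @return A `segment_sets` object.
#' @export
read_segment_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("round", "index", "sequence") %in% names(df)))
  rounds <- sort(unique(df$round))
  sets <- lapply(rounds, function(r) {
    segs <- df$sequence[df$round == r][order(df$index[df$round == r])]
    if (anyDuplicated(segs)) {
      stop("duplicate segments in round ", r, " of ", path)
    }
    if (length(unique(nchar(segs))) != 1L) {
      stop("unequal segment lengths in round ", r, " of ", path)
    }
    list(round_index = r, segments = toupper(segs))
  })
  observed <- vapply(sets, function(s) {
    if (length(s$segments) > 1L) min_pairwise_hamming_cpp(s$segments) else Inf
  }, numeric(1))
  structure(sets, class = "segment_sets",
            min_intra_round_distance = min(observed))
}

# Fixed plumbing sequences. The published bead manifest keeps its handle and
# linker sequences in supplementary material, so these defaults are
# synthetic placeholders sized to reproduce the printed stage lengths
# (27/44/58/96 nt); all are overridable.
.DEFAULT_HANDLE27 <- "CTACACGACGCTCTTCCGAUCTGGGAC"  # 27 nt, U = cleavage site
.DEFAULT_LINKERS <- c("GTGGCCG", "ATCG")            # 7 nt, 4 nt

#' Model the bead barcoding primer
#'
#' Bundles the PCR handle (with its enzymatic cleavage-site position), the
#' three split-pool segment sets, the inter-round linkers, the UMI length and
#' the poly(T) tail length, and derives the primer length after initial
#' synthesis and after each ligation round. With all defaults those stage
#' lengths are 27, 44, 58 and 96 nt and the three segments concatenate to the
#' 30-nt cell barcode.
#'
#' @param segment_sets A `segment_sets` object; generated with defaults from
#'   `seed` when omitted.
#' @param pcr_handle Handle sequence present before round 1 (27 nt default;
#'   the embedded `U` marks the uracil cleavage site used to release primers).
#' @param linkers Two linker sequences ligated between rounds 1-2 and 2-3.
#' @param umi_length UMI length in nt; fixed at 8.
#' @param polyT_length Length of the poly(T) capture tail (default 20).
#' @param seed Seed used only when `segment_sets` is omitted.
#' @return An object of class `bead_primer_design` with fields
#'   `segment_sets`, `pcr_handle`, `cleavage_site_marker`, `linkers`,
#'   `umi_length`, `polyT_length`, `stage_lengths`, `cardinalities`,
#'   `barcode_length`.
#' @export
bead_primer_design <- function(segment_sets = NULL,
                               pcr_handle = .DEFAULT_HANDLE27,
                               linkers = .DEFAULT_LINKERS,
                               umi_length = 8L, polyT_length = 20L,
                               seed = 1L) {
  if (is.null(segment_sets)) {
    segment_sets <- generate_segment_sets(seed)
  }
  if (umi_length != 8L) stop("umi_length is fixed at 8 nt in this design")
  seg_lens <- vapply(segment_sets, function(s) nchar(s$segments[1L]),
                     integer(1))
  barcode_length <- sum(seg_lens)
  if (barcode_length != 30L) {
    stop("segment lengths (", paste(seg_lens, collapse = "+"),
         ") must sum to the 30-nt cell barcode")
  }
  if (length(linkers) != length(segment_sets) - 1L) {
    stop("need exactly ", length(segment_sets) - 1L, " linkers")
  }
  stage <- integer(length(segment_sets) + 1L)
  stage[1L] <- nchar(pcr_handle)
  for (r in seq_along(segment_sets)) {
    add <- seg_lens[r] +
      if (r < length(segment_sets)) nchar(linkers[r]) else
        umi_length + polyT_length
    stage[r + 1L] <- stage[r] + add
  }
  structure(list(
    segment_sets = segment_sets,
    pcr_handle = gsub("U", "T", pcr_handle),
    cleavage_site_marker = as.integer(regexpr("U", pcr_handle, fixed = TRUE)),
    linkers = linkers,
    umi_length = as.integer(umi_length),
    polyT_length = as.integer(polyT_length),
    stage_lengths = stage,
    cardinalities = vapply(segment_sets, function(s) length(s$segments),
                           integer(1)),
    barcode_length = barcode_length
  ), class = "bead_primer_design")
}

#' @export
print.bead_primer_design <- function(x, ...) {
  cat("Bead primer design:",
      paste(x$cardinalities, collapse = " x "), "segments;",
      "stage lengths", paste(x$stage_lengths, collapse = "/"), "nt;",
      "UMI", x$umi_length, "nt; poly(T)", x$polyT_length, "nt\n")
  invisible(x)
}

#' Construct the combinatorial barcode whitelist
#'
#' Concatenates one segment per round, in round order, into every possible
#' 30-nt cell barcode. The whitelist size is exactly the product of the round
#' cardinalities (442,368 with the default 96 x 96 x 48 design); a collision
#' between concatenations is a construction error, never a silent
#' deduplication.
#'
#' @param design A `bead_primer_design`.
#' @return An object of class `barcode_whitelist`: fields `barcodes`
#'   (character vector), `n`, `barcode_length`, `cardinalities`,
#'   `min_distance` (guaranteed minimum pairwise Hamming distance over the
#'   whole whitelist), and per-round segment tables.
#' @export
build_whitelist <- function(design) {
  stopifnot(inherits(design, "bead_primer_design"))
  sets <- lapply(design$segment_sets, `[[`, "segments")
  bc <- sets[[1L]]
  for (r in seq_along(sets)[-1L]) {
    bc <- as.vector(outer(bc, sets[[r]], paste0))
  }
  dup <- anyDuplicated(bc)
  if (dup) {
    stop("whitelist construction error: concatenated barcode collision at '",
         bc[dup], "'")
  }
  # Two distinct barcodes differ in at least one round's segment; each
  # differing round contributes at least that round's min intra-round
  # distance, so the whole-whitelist min distance is the min over rounds.
  per_round_min <- vapply(sets, function(s) {
    if (length(s) > 1L) min_pairwise_hamming_cpp(s) else Inf
  }, numeric(1))
  structure(list(
    barcodes = bc,
    n = length(bc),
    barcode_length = design$barcode_length,
    cardinalities = design$cardinalities,
    min_distance = min(per_round_min),
    segment_sets = design$segment_sets
  ), class = "barcode_whitelist")
}

#' Wrap an arbitrary barcode list as a whitelist
#'
#' For user-supplied or deliberately ambiguous toy whitelists. The minimum
#' pairwise Hamming distance is computed exactly for lists of up to
#' `max_exact` members; beyond that it is recorded as unknown (1), which
#' disables the exact-match shortcut in [correct_barcode()] and forces the
#' full neighbourhood scan.
#'
#' @param barcodes Character vector of equal-length barcodes.
#' @param max_exact Size up to which the min pairwise distance is computed.
#' @return A `barcode_whitelist`.
#' @export
as_whitelist <- function(barcodes, max_exact = 4000L) {
  barcodes <- toupper(barcodes)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in whitelist")
  if (length(unique(nchar(barcodes))) != 1L) {
    stop("whitelist barcodes must all have the same length")
  }
  md <- if (length(barcodes) <= max_exact && length(barcodes) > 1L) {
    min_pairwise_hamming_cpp(barcodes)
  } else 1
  structure(list(barcodes = barcodes, n = length(barcodes),
                 barcode_length = nchar(barcodes[1L]),
                 cardinalities = length(barcodes),
                 min_distance = md, segment_sets = NULL),
            class = "barcode_whitelist")
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat("Barcode whitelist:", x$n, "barcodes of", x$barcode_length,
      "nt (min pairwise Hamming distance", x$min_distance, ")\n")
  invisible(x)
}

#' Export a whitelist as one barcode per line
#'
#' @param whitelist A `barcode_whitelist`.
#' @param path Output path.
#' @param gz Gzip-compress the output.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(whitelist, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(whitelist$barcodes, con)
  invisible(path)
}

#' Assemble the full-length bead primer sequence
#'
#' Concatenates, 5' to 3': PCR handle (carrying the cleavage-site marker),
#' round-1 segment, linker, round-2 segment, linker, round-3 segment, UMI and
#' poly(T). With the default design the result is 96 nt and the intermediate
#' stage lengths are 27, 44 and 58 nt.
#'
#' @param design A `bead_primer_design`.
#' @param segment_choices Integer vector of 3 segment indices (one per round).
#' @param umi UMI sequence of length `design$umi_length`.
#' @return The full primer as a single DNA string.
#' @export
assemble_full_primer <- function(design, segment_choices, umi) {
  stopifnot(inherits(design, "bead_primer_design"))
  if (nchar(umi) != design$umi_length) {
    stop("umi must be ", design$umi_length, " nt, got ", nchar(umi))
  }
  if (length(segment_choices) != length(design$segment_sets)) {
    stop("need one segment choice per round")
  }
  parts <- design$pcr_handle
  for (r in seq_along(design$segment_sets)) {
    seg <- design$segment_sets[[r]]$segments[segment_choices[r]]
    if (is.na(seg)) stop("segment index out of range in round ", r)
    parts <- c(parts, seg,
               if (r < length(design$segment_sets)) design$linkers[r])
  }
  primer <- paste0(paste(parts, collapse = ""), umi,
                   strrep("T", design$polyT_length))
  if (nchar(primer) != design$stage_lengths[length(design$stage_lengths)]) {
    stop("design error: assembled primer length ", nchar(primer),
         " != declared stage length ",
         design$stage_lengths[length(design$stage_lengths)])
  }
  primer
}

#' Primer length after initial synthesis and after each ligation round
#'
#' @param design A `bead_primer_design`.
#' @return Integer vector of 4 stage lengths (27, 44, 58, 96 with defaults).
#' @export
primer_stage_lengths <- function(design) design$stage_lengths
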