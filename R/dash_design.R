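# Cas9 sgRNA pool design against rRNA-derived cDNA and in-silico digestion.
# Guides are N20-NGG protospacers enumerated on both strands of the cDNA
# duplex; the cut site is the canonical blunt position 3 bp 5' of the PAM
# (between protospacer positions 17 and 18). Any cut between a molecule's
# terminal adapters separates its two primer sites, so re-amplification is
# abolished -- the depletion model is binary.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Enumerate Cas9 guide candidates on both strands
#'
#' Every 23-nt window matching N20-NGG on either strand of each target
#' yields one candidate. `cut_pos` is the target-forward coordinate such
#' that Cas9 cuts between `cut_pos` and `cut_pos + 1` (3 nt 5' of the PAM).
#' Targets shorter than 23 nt yield no candidates.
#'
#' @param target_sequences Named character vector of target (cDNA) sequences.
#' @return A `data.table` with `target_gene`, `spacer` (20 nt), `pam`
#'   (NGG), `strand` (`+` = guide matches the given sequence, `-` = its
#'   reverse complement), `cut_pos`, `gc_fraction`.
#' @export
enumerate_guides <- function(target_sequences) {
  stopifnot(!is.null(names(target_sequences)))
  res <- lapply(names(target_sequences), function(gene) {
    s <- toupper(target_sequences[[gene]])
    L <- nchar(s)
    if (L < 23L) return(NULL)
    one_strand <- function(seq, strand) {
      # PAM GG dinucleotide at positions s+21..s+22 of a window starting at s
      gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1L]]
      if (gg[1L] == -1L) return(NULL)
      sp_start <- gg - 21L
      sp_start <- sp_start[sp_start >= 1L & sp_start + 22L <= L]
      if (!length(sp_start)) return(NULL)
      spacer <- substring(seq, sp_start, sp_start + 19L)
      pam <- substring(seq, sp_start + 20L, sp_start + 22L)
      cut <- if (strand == "+") sp_start + 16L else L - sp_start - 15L
      data.table::data.table(target_gene = gene, spacer = spacer, pam = pam,
                             strand = strand, cut_pos = as.integer(cut))
    }
    data.table::rbindlist(list(one_strand(s, "+"),
                               one_strand(.revcomp(s), "-")))
  })
  out <- data.table::rbindlist(res)
  if (!nrow(out)) {
    return(data.table::data.table(target_gene = character(),
                                  spacer = character(), pam = character(),
                                  strand = character(), cut_pos = integer(),
                                  gc_fraction = numeric()))
  }
  out[, gc_fraction := (nchar(spacer) -
                          nchar(gsub("[GC]", "", spacer))) / nchar(spacer)]
  out[]
}

#' Filter guide candidates
#'
#' Keeps a candidate iff its GC fraction lies in `gc_range`, it has no
#' homopolymer run longer than `max_homopolymer` and no `TTTT` run (which
#' terminates T7 transcription), and its 12-nt PAM-proximal seed followed by
#' NGG does not occur in the off-target sequences (either strand). The seed
#' + NGG exact-match off-target rule is deliberately conservative.
#'
#' @param candidates An [enumerate_guides()] table.
#' @param gc_range Allowed GC fraction (default 0.30--0.70, inclusive).
#' @param max_homopolymer Longest allowed homopolymer run (default 4; T runs
#'   of 4 are excluded regardless).
#' @param offtarget_seqs Character vector of non-target (non-rRNA) gene
#'   sequences, or `NULL` to skip the off-target screen.
#' @return The filtered table, with logical columns `homopolymer` and
#'   `off_target` retained for the dropped criteria on the kept rows (all
#'   `FALSE` by construction).
#' @export
filter_guides <- function(candidates, gc_range = c(0.30, 0.70),
                          max_homopolymer = 4L, offtarget_seqs = NULL) {
  cand <- data.table::as.data.table(candidates)
  if (!nrow(cand)) return(cand)
  homo_re <- sprintf("A{%d,}|C{%d,}|G{%d,}", max_homopolymer + 1L,
                     max_homopolymer + 1L, max_homopolymer + 1L)
  homopolymer <- grepl(homo_re, cand$spacer) |
    grepl(sprintf("T{%d,}", min(4L, max_homopolymer + 1L)), cand$spacer)
  gc_ok <- cand$gc_fraction >= gc_range[1L] & cand$gc_fraction <= gc_range[2L]
  off_target <- rep(FALSE, nrow(cand))
  if (!is.null(offtarget_seqs) && length(offtarget_seqs)) {
    haystack <- c(toupper(offtarget_seqs), .revcomp(toupper(offtarget_seqs)))
    seeds <- substring(cand$spacer, 9L, 20L)
    pats <- paste0(seeds, "[ACGT]GG")
    for (u in unique(pats)) {
      hit <- any(grepl(u, haystack))
      if (hit) off_target[pats == u] <- TRUE
    }
  }
  cand[, `:=`(homopolymer = homopolymer, off_target = off_target)]
  cand[gc_ok & !homopolymer & !off_target][]
}

#' Tile guides along each target by greedy interval covering
#'
#' Left-to-right greedy selection: starting from the target 5' end, always
#' pick the rightmost candidate whose cut site is at most `max_gap`
#' downstream of the last covered position (the standard interval-covering
#' argument makes this selection minimal among feasible tilings). Regions
#' with no candidate within reach are recorded as uncovered intervals
#' (warnings, not errors); no two selected guides share a cut site.
#'
#' @param filtered A [filter_guides()] table.
#' @param max_gap Maximum allowed distance between consecutive cut sites
#'   (and from the target ends), in nt (default 50).
#' @param target_lengths Named integer vector of target sequence lengths
#'   (for trailing-gap accounting); optional.
#' @return A list of class `guide_set`: `guides` (selected rows, ordered by
#'   target and cut position), `max_gap`, `uncovered` (`target_gene`,
#'   `from`, `to`), `per_gene` (guide counts and largest inter-cut gap).
#' @export
tile_guides <- function(filtered, max_gap = 50L, target_lengths = NULL) {
  cand <- data.table::as.data.table(filtered)
  empty_guides <- data.table::data.table(
    target_gene = character(), spacer = character(), pam = character(),
    strand = character(), cut_pos = integer(), gc_fraction = numeric())
  sel_list <- list(empty_guides)
  unc_list <- list()
  # targets with no candidates at all are fully uncovered
  if (!is.null(target_lengths)) {
    for (gene in setdiff(names(target_lengths), cand$target_gene)) {
      unc_list[[length(unc_list) + 1L]] <- data.table::data.table(
        target_gene = gene, from = 1L, to = target_lengths[[gene]])
    }
  }
  for (gene in unique(cand$target_gene)) {
    g <- cand[target_gene == gene][order(cut_pos, strand)]
    g <- g[!duplicated(cut_pos)]
    cuts <- g$cut_pos
    glen <- if (!is.null(target_lengths) && gene %in% names(target_lengths)) {
      target_lengths[[gene]]
    } else max(cuts) + 6L  # protospacer+PAM extends ~6 nt past the cut
    pos <- 0L
    chosen <- integer()
    repeat {
      if (glen - pos <= max_gap) break  # gene end already within reach
      feas <- which(cuts > pos & cuts <= pos + max_gap)
      if (length(feas)) {
        pick <- feas[length(feas)]  # rightmost reachable
        chosen <- c(chosen, pick)
        pos <- cuts[pick]
      } else {
        beyond <- which(cuts > pos)
        if (!length(beyond)) {
          if (glen - pos > max_gap) {
            unc_list[[length(unc_list) + 1L]] <- data.table::data.table(
              target_gene = gene, from = pos + 1L, to = glen)
          }
          break
        }
        nxt <- beyond[1L]
        unc_list[[length(unc_list) + 1L]] <- data.table::data.table(
          target_gene = gene, from = pos + 1L, to = cuts[nxt] - 1L)
        chosen <- c(chosen, nxt)
        pos <- cuts[nxt]
      }
    }
    sel_list[[gene]] <- g[chosen]
  }
  guides <- data.table::rbindlist(sel_list, fill = TRUE)
  uncovered <- if (length(unc_list)) data.table::rbindlist(unc_list) else
    data.table::data.table(target_gene = character(), from = integer(),
                           to = integer())
  if (nrow(uncovered)) {
    warning(nrow(uncovered), " uncovered interval(s) with no candidate in ",
            "reach; largest ", max(uncovered$to - uncovered$from + 1L), " nt")
  }
  per_gene <- guides[, .(n_guides = .N,
                         max_cut_gap = if (.N > 1L) max(diff(sort(cut_pos)))
                         else NA_integer_),
                     by = target_gene]
  structure(list(guides = guides[order(target_gene, cut_pos)],
                 max_gap = as.integer(max_gap),
                 uncovered = uncovered, per_gene = per_gene),
            class = "guide_set")
}

#' @export
print.guide_set <- function(x, ...) {
  cat("Guide set:", nrow(x$guides), "guides over",
      length(unique(x$guides$target_gene)), "target(s), max_gap",
      x$max_gap, "nt;", nrow(x$uncovered), "uncovered interval(s)\n")
  invisible(x)
}

#' In-silico Cas9 digestion of an amplicon pool
#'
#' A molecule is depleted iff at least one selected guide's full
#' protospacer+PAM occurs (in either orientation) in its insert -- the
#' sequence between its terminal adapters -- since any cut separates the two
#' primer sites and abolishes re-amplification. The predicted post-depletion
#' rRNA fraction follows `r(1-d) / (r(1-d) + (1-r))` for initial rRNA
#' fraction `r` and rRNA depleted fraction `d`; non-rRNA molecules are
#' conserved exactly when no guide matches them.
#'
#' @param molecules A data.frame with columns `insert` (sequence between
#'   adapters) and `is_rrna` (logical).
#' @param guide_set A `guide_set` (or a guides table with `spacer`, `pam`,
#'   `strand`).
#' @param initial_rrna_fraction `r` used in the composition prediction;
#'   default the observed rRNA fraction of the input pool.
#' @param cutting_efficiency Global per-site cut probability (default 1,
#'   the binary model; values < 1 thin cuts Bernoulli-wise).
#' @param seed Seed, used only when `cutting_efficiency < 1`.
#' @return A list of class `digest_report`: `cut_count_distribution`,
#'   `depleted_fraction` (d, among rRNA molecules), `depleted_fraction_all`,
#'   `initial_rrna_fraction`, `predicted_post_rrna_fraction`,
#'   `observed_post_rrna_fraction`, `survivors` (row indices),
#'   `n_non_rrna_in`, `n_non_rrna_out`.
#' @export
digest_in_silico <- function(molecules, guide_set,
                             initial_rrna_fraction = NULL,
                             cutting_efficiency = 1, seed = 1L) {
  guides <- if (inherits(guide_set, "guide_set")) guide_set$guides else
    data.table::as.data.table(guide_set)
  mol <- data.table::as.data.table(molecules)
  stopifnot(all(c("insert", "is_rrna") %in% names(mol)))
  inserts <- toupper(mol$insert)

  cut_counts <- integer(nrow(mol))
  if (nrow(guides)) {
    # site as it reads on the target-forward strand
    site <- ifelse(guides$strand == "+",
                   paste0(guides$spacer, guides$pam),
                   .revcomp(paste0(guides$spacer, guides$pam)))
    site_rc <- .revcomp(site)
    for (k in seq_along(site)) {
      hit <- grepl(site[k], inserts, fixed = TRUE) |
        grepl(site_rc[k], inserts, fixed = TRUE)
      if (cutting_efficiency < 1) {
        withr::with_seed(as.integer(seed) + k, {
          hit <- hit & (runif(length(hit)) < cutting_efficiency)
        })
      }
      cut_counts <- cut_counts + hit
    }
  }
  cut <- cut_counts > 0L
  r <- if (is.null(initial_rrna_fraction)) mean(mol$is_rrna) else
    initial_rrna_fraction
  d <- if (any(mol$is_rrna)) mean(cut[mol$is_rrna]) else 0
  predicted <- r * (1 - d) / (r * (1 - d) + (1 - r))
  survivors <- which(!cut)
  obs_post <- if (length(survivors)) mean(mol$is_rrna[survivors]) else NaN
  structure(list(
    cut_count_distribution = table(cut_counts),
    depleted_fraction = d,
    depleted_fraction_all = mean(cut),
    initial_rrna_fraction = r,
    predicted_post_rrna_fraction = predicted,
    observed_post_rrna_fraction = obs_post,
    survivors = survivors,
    n_non_rrna_in = sum(!mol$is_rrna),
    n_non_rrna_out = sum(!mol$is_rrna & !cut)),
    class = "digest_report")
}

#' @export
print.digest_report <- function(x, ...) {
  cat(sprintf(
    "Digest: d = %.3f (rRNA molecules cut); rRNA %.1f%% -> predicted %.1f%%\n",
    x$depleted_fraction, 100 * x$initial_rrna_fraction,
    100 * x$predicted_post_rrna_fraction))
  invisible(x)
}

# canonical constants for in-vitro transcription templates
.T7_PROMOTER <- "TAATACGACTCACTATAG"
.SGRNA_SCAFFOLD <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCA",
                          "ACTTGAAAAAGTGGCACCGAGTCGGTGC")

#' Emit in-vitro transcription templates for a guide set
#'
#' Each template is T7 promoter + spacer + scaffold; a `G` is prepended to
#' spacers not starting with `G` (T7 initiates on G). Optionally written as
#' FASTA; [parse_templates()] inverts the emission.
#'
#' @param guide_set A `guide_set` or guides table.
#' @param t7_promoter Promoter sequence (default the canonical T7 promoter).
#' @param scaffold sgRNA scaffold sequence (configurable constant).
#' @param path Optional FASTA output path.
#' @return A `data.table` with `guide_id`, `spacer`, `template`.
#' @export
emit_templates <- function(guide_set, t7_promoter = .T7_PROMOTER,
                           scaffold = .SGRNA_SCAFFOLD, path = NULL) {
  guides <- if (inherits(guide_set, "guide_set")) guide_set$guides else
    data.table::as.data.table(guide_set)
  gid <- sprintf("%s|%d|%s", guides$target_gene, guides$cut_pos,
                 guides$strand)
  sp <- guides$spacer
  sp_t7 <- ifelse(startsWith(sp, "G"), sp, paste0("G", sp))
  templates <- paste0(t7_promoter, sp_t7, scaffold)
  out <- data.table::data.table(guide_id = gid, spacer = sp,
                                template = templates)
  if (!is.null(path)) {
    writeLines(paste0(">", gid, "\n", templates), path)
  }
  out[]
}

#' Parse emitted sgRNA templates back into guides
#'
#' @param path FASTA of templates written by [emit_templates()].
#' @param t7_promoter,scaffold The constants used at emission.
#' @return A `data.table` with `guide_id`, `spacer`, `target_gene`,
#'   `cut_pos`, `strand` (decoded from the identifiers).
#' @export
parse_templates <- function(path, t7_promoter = .T7_PROMOTER,
                            scaffold = .SGRNA_SCAFFOLD) {
  fa <- Biostrings::readDNAStringSet(path)
  tmpl <- as.character(fa)
  core <- substr(tmpl, nchar(t7_promoter) + 1L, nchar(tmpl) - nchar(scaffold))
  # a 21-nt core starting with G carries the prepended T7 initiation G
  spacer <- ifelse(nchar(core) == 21L & startsWith(core, "G"),
                   substr(core, 2L, 21L), core)
  parts <- data.table::tstrsplit(names(fa), "|", fixed = TRUE)
  data.table::data.table(guide_id = names(fa), spacer = spacer,
                         target_gene = parts[[1L]],
                         cut_pos = as.integer(parts[[2L]]),
                         strand = parts[[3L]])
}
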