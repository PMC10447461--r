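---
title: "Models and methods behind microdrops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microdrops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdrops)
```

`microdrops` is a toolkit for droplet-based single-microbe RNA-seq: it models
the bead barcode chemistry, demultiplexes and counts reads, separates cells
from background barcodes, computes the standard quality metrics, and designs
Cas9 guide pools for depleting rRNA-derived cDNA. A read-level simulator with
per-read ground truth makes every stage verifiable without external data.
This vignette explains the models, the defaults, and the choices made where
the design was genuinely open.

## The library model

A bacterial cell is fixed, permeabilized, and its total RNA is captured in
situ by random primers; cDNA receives a poly(dA) tail and is barcoded inside
a droplet by primers released from a hydrogel bead. Each bead carries one
barcode out of a combinatorial whitelist built by three split-pool ligation
rounds. Sequencing yields read pairs in which Read1 carries an 8-nt unique
molecular identifier (UMI) followed by the 30-nt cell barcode (and residual
poly(T)), and Read2 carries the cDNA fragment flanked by a constant handle
and the dA tail.

The bead primer model (`bead_primer_design()`) tracks the full molecule:
PCR handle with a uracil cleavage site, three barcode segments with
inter-round linkers, UMI, poly(T). The printed stage lengths of the primer
-- 27 nt after initial synthesis and 44, 58, 96 nt after the three ligation
rounds -- constrain the sum of segment and linker lengths but not their
split. We default to three 10-nt segments (so the concatenated cell barcode
is 30 nt) and linkers of 7 and 4 nt with a 20-nt poly(T) tail, which
reproduces every stage length; all of these are configurable, since the
published bead manifest keeps its exact sequences in supplementary tables.

## Barcode whitelist

`generate_segment_sets()` draws random segments subject to a minimum
pairwise Hamming distance of 3 within each round, rejecting demands that
violate the Singleton bound. With the default 96 x 96 x 48 cardinalities the
whitelist holds exactly 442,368 barcodes. Because any two distinct barcodes
differ in at least one round, and each differing round contributes at least
its intra-round minimum distance, the whole whitelist inherits a minimum
pairwise distance of 3 -- the property that makes unambiguous correction of
up to two sequencing errors possible.

## Demultiplexing and barcode correction

A raw 30-mer is merged into the whitelist iff **exactly one** member lies
within Hamming distance 2. We read "uniquely assigned" literally: zero
candidates and two-or-more candidates are both discards, counted by reason
and never repaired by frequency priors. The implementation enumerates the
4,006-sequence Hamming-<=2 neighbourhood of the observed barcode against a
whitelist hash (exactly equivalent to a nearest-neighbour scan over the
whole whitelist, and cross-checked against one in the tests). When the
whitelist's recorded minimum pairwise distance is at least 3 an exact match
provably excludes any rival within distance 2, so it short-circuits the
enumeration; user-supplied whitelists without that guarantee always get the
full scan.

Read2 trimming removes a leading exact handle match and a trailing
A-homopolymer of at least 6 nt (the dA tail). A genuine A-run at the 3' end
of an insert is indistinguishable from the tail and is trimmed with it; this
is inherent to dA-tailing chemistry, and the tests therefore check trimmed
lengths against truth with that ambiguity in mind.

## Read assignment and UMI counting

Bacterial genes are modelled as single intervals. A uniquely mapped read is
assigned to a gene iff its interval overlaps exactly one gene by at least
1 nt (multi-overlap reads are dropped, mirroring the common featureCounts
default); assignment is unstranded by default because random-primed
bacterial cDNA yields reads of both orientations, with a stranded mode
available. Within each (barcode, gene) pair identical UMIs count once.
Directional collapse -- merging a UMI at Hamming distance 1 into a more
abundant neighbour when the parent count is at least `2*child - 1` -- is
available but off by default: the upstream pipeline names a deduplication
tool without stating its method, and exact deduplication is the conservative
reading. The alignment interchange is a documented TSV (`read_id`, `contig`,
`start`, `end`, `strand`, `unique`), with SAM accepted through a thin
adapter that maps MAPQ to uniqueness; the aligner itself is out of scope.

## Cell calling

Barcodes are ranked by the number of detected genes (ties broken by UMIs,
then lexicographically). The knee threshold is the `maxPercentile` (0.99)
quantile of the top `nExpectedCells` (1500) barcodes divided by
`maxMinRatio` (10). Below the knee, an EmptyDrops-like rescue compares each
candidate barcode's expression profile with an **ambient profile** pooled
from barcodes ranked in `(indMin, indMax]` (45,000--90,000 by default,
scaled down in the packaged experiments to match their barcode counts):
candidates need at least `max(umiMin, umiMinFracMedian * median knee-cell
UMIs)` UMIs and are capped at `candMaxN` by rank. For each candidate the
observed multinomial log-likelihood under the (1e-8-smoothed) ambient
profile is compared with `simN` Monte-Carlo draws of the same total; the
p-value `(1 + #{sim <= obs}) / (simN + 1)` can never be zero, and
Benjamini-Hochberg across candidates with `q <= FDR` (0.01) rescues the
barcode. Draws are cached per distinct candidate total, and everything is
seeded, so calling is deterministic given (matrix, params, seed).

The upstream tool names this filter and its ten parameters but not its
algorithm; the contract above is this package's own definition of
"EmptyDrops-like", chosen to reproduce the published parameterization's
semantics without binding to external code. Note one ambiguity we surface
rather than hide: the rank plot is described in terms of detected genes,
while the thresholds (`umiMin`) are UMI-denominated; genes is our default
ranking metric and `metric = "umi"` is a flag. A practical corollary of the
Monte-Carlo design: the smallest attainable BH q-value is roughly
`n_candidates / (rank * (simN + 1))`, so `simN` must be large relative to
the candidate count for rescue at small FDR.

## Quality metrics

**Barnyard.** Each called barcode is labelled by majority species, or
*mixed* when the minor-species UMI fraction is at least `mixed_threshold`
(0.2) and the top two species both contribute at least `min_umis` (10).
The doublet rate is mixed over total labelled barcodes; species specificity
is the median own-species UMI fraction over that species' singlets. The
published two-species counts (202 + 45 singlets, 4 mixed) give
4/251 = 1.6%, which `doublet_rate_from_counts()` recomputes directly --
the mixed-call thresholds are this package's convention, exposed as flags.

**Saturation.** Reads (not UMIs) are subsampled without replacement to
`depth * n_cells`, the counting chain is re-run, and the median detected
genes per called cell is recorded; the default ladder is 1k/2k/4k/9k/13k/
18k/22k reads per cell. Subsampling raw reads preserves the duplicate
structure, so the curve saturates realistically.

**Gene-body coverage.** Per-base coverage of each gene of length >= 100 nt
is binned into 100 percentile bins oriented 5'->3' by strand, each gene is
normalized by its mean (so genes contribute equally), profiles are averaged
and scaled to a maximum of 1. Coverage binning is done in 0-based half-open
arithmetic internally; all user-visible coordinates are 1-based inclusive.
Random-primed, 5'->3' synthesized libraries decay towards the 3' end;
`coverage_decay_slope()` summarizes the profile by the slope of its
antitonic (non-increasing) isotonic fit.

## CRISPR depletion design (DASH)

rRNA-derived cDNA is removed by Cas9 loaded with a tiled sgRNA pool: any cut
between a molecule's terminal adapters separates its primer sites and
abolishes re-amplification. Guides are all N20-NGG protospacers on either
strand; the cut site is the canonical blunt position 3 bp 5' of the PAM.
Filters keep GC in [0.30, 0.70], reject homopolymer runs longer than 4 (and
any `TTTT`, which terminates T7 transcription), and drop guides whose 12-nt
PAM-proximal seed followed by NGG occurs in the non-rRNA sequence set -- a
deliberately conservative exact-match off-target rule. Tiling is greedy
left-to-right (always the rightmost candidate within `max_gap` of the last
covered position), which the standard interval-covering argument makes
minimal; gaps with no candidate are recorded as uncovered intervals.
Coverage-weighted tiling is exposed as an option through `gene_weights` in
the simulator-driven workflow but is not the default, as the published
design procedure does not state its weighting.

The depletion model is binary -- one in-insert cut kills the molecule --
with a global `cutting_efficiency` multiplier (default 1); the published
protocol gives molar ratios (cDNA:Cas9:sgRNA = 1:100:1000) but no kinetic
model, so the ratios are metadata only. For an initial rRNA fraction $r$
and a depleted fraction $d$ among rRNA molecules, the predicted
post-depletion rRNA fraction is

$$r' = \frac{r(1-d)}{r(1-d) + (1-r)},$$

which conserves non-rRNA molecules exactly. With $r = 0.83$, reducing rRNA
to about 32% requires $d \approx 0.904$. The packaged digestion experiment
realizes that $d$ geometrically: guides are designed on the 5' 4,410 nt of
six 5-kb rRNA cDNA targets (leaving a 3' region undesigned, as happens when
a design reference omits a variable region), so that uniformly placed
150-bp amplicons escape with probability close to 0.096. Several targets are
used precisely to average out the jitter of the last covered position.

## The simulator

`simulate_library()` emulates: Poisson droplet loading (cells thrown into
`total_cells / lambda` droplets; occupancy is multinomial, which converges
to Poisson, and >=3-cell droplets are collapsed to 2 since they are
negligible at the relevant loading); log-normal per-cell molecule budgets
(default meanlog `log(40)`, sdlog 0.4 at test scale -- the published
per-cell medians are in the hundreds-to-thousands, scaled down so suites run
in seconds); biotype-first molecule sampling with an rRNA fraction of 0.83
(the pre-depletion dominance of rRNA in bacterial libraries) and the
non-rRNA remainder split ~94/3/3% over mRNA/tRNA/ncRNA so that mRNA is
~16% of molecules; truncated-geometric capture starts from the 5' end
(`coverage_decay` per nt; 0 = uniform); insert lengths uniform on 100--400
bp truncated at the gene end, with capture starts capped so at least the
minimum insert remains (shorter fragments would be lost to size selection,
and a fragment shorter than the dA tail is indistinguishable from it);
`1 + Poisson` PCR duplicates per molecule; and uniform substitution errors
in the barcode at `barcode_error_rate`. Quality strings are constant:
errors are injected in sequence space, which is sufficient for testing
correction logic. A "perfect aligner" TSV gives each read's true locus, so
counting can be validated without an actual aligner.

`simulate_capture_positions()` is a molecule-level positional generator
(no sequence synthesis) for coverage and saturation studies that only need
alignment intervals; it is orders of magnitude faster and shares the same
positional model. `inject_ambient()` re-draws a fraction of reads from the
pooled molecule pool to emulate free-floating RNA; with a 50/50 two-species
mixture and ambient rate $a$, singlet own-species purity centres on
$1 - a/2$.

What the simulator does **not** model -- and hence what passing tests do
not show about real data: sequencing-error models beyond uniform
substitution, chimeras and realistic PCR family-size distributions, droplet
size or bead occupancy beyond Poisson, strand-specific capture biases, and
genome-wide mapping ambiguity (the perfect aligner has none). Conclusions
about aligner behaviour or base-quality-aware correction are out of reach
by construction.

## Numerical choices and problem sizes

Ambient profiles are smoothed with a 1e-8 pseudocount before likelihood
evaluation to avoid minus infinity on genes unseen in the ambient window.
Ranking ties break deterministically (secondary metric, then barcode).
Monte-Carlo p-values use the +1 correction. The packaged experiments run at
deliberately small scale -- toy whitelists of a few thousand barcodes,
hundreds of cells, ~1e5 reads for the end-to-end identity check, 2e6
positional reads for the coverage flatness check, `simN` 1000--2000 for the
rescue tests -- sizes chosen so the full suite completes in well under an
hour on one core while keeping every statistical check adequately powered;
the defaults users see (`knee_params()`, the saturation ladder, the 0.83
rRNA fraction) are the published operating points.

## Known limitations

Correction treats insertions/deletions as mismatches (substitution-only
model, as in the published pipeline); the knee is the simple
quantile-over-expected-cells rule, not a curvature estimator; the off-target
rule is presence/absence, not an alignment score; and the depletion model
ignores partial cutting kinetics. Each of these is an explicit, documented
convention of this toolkit rather than a claim about the original
instrument software.
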