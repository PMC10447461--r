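# microdrops

Simulation, demultiplexing, counting, cell calling and QC for droplet-based
high-throughput single-microbe RNA-seq.

Bacterial single-cell RNA-seq cannot use poly(T) capture (bacterial mRNA is
not polyadenylated) and is dominated by rRNA (>80% of molecules). One
droplet-based answer is: capture total RNA in situ with random primers,
dA-tail the cDNA, barcode it in droplets with split-pool bead barcodes, and
remove rRNA-derived cDNA from the library with Cas9 loaded with a tiled
sgRNA pool (DASH), so that any cut between a molecule's primer sites kills
its re-amplification. `microdrops` implements the computational side of
that design as a tested R toolkit, for people building, validating or
teaching such pipelines:

- **Barcode model** — the 3-round split-pool bead primer (stage lengths
  27/44/58/96 nt) and its combinatorial whitelist
  (96 × 96 × 48 = 442,368 barcodes of 30 nt, min pairwise Hamming
  distance ≥ 3).
- **Demultiplexing** — Read1 = 8-nt UMI + 30-nt barcode; a raw barcode is
  merged iff **exactly one** whitelist member lies within Hamming
  distance 2 (ambiguity is discarded, not repaired); Read2 handle and
  dA-tail trimming.
- **Counting** — unique-read interval assignment to single-interval
  bacterial genes, exact or directional UMI deduplication into a sparse
  genes × barcodes matrix with biotype accounting
  (mRNA/rRNA/tRNA/ncRNA).
- **Cell calling** — barcode rank plot, simple-knee threshold
  (`quantile(top nExpectedCells, 0.99) / 10`), and an EmptyDrops-like
  Monte-Carlo rescue of sub-knee barcodes against an ambient profile
  (multinomial test, BH, `q ≤ FDR`), with the published ten-parameter
  defaults (`nExpectedCells = 1500`, …, `simN = 10000`).
- **QC** — barnyard species-mixing metrics (doublet rate, per-species
  specificity), read-subsampling saturation curves, 100-bin 5′→3′
  gene-body coverage, pseudo-bulk correlation.
- **DASH design** — N20-NGG guide enumeration on both strands, GC /
  homopolymer / seed-level off-target filters, minimal greedy tiling,
  in-silico digestion. For initial rRNA fraction *r* and depleted fraction
  *d*, the predicted post-depletion rRNA fraction is
  *r(1−d) / (r(1−d) + (1−r))*; with *r* = 0.83, *d* ≈ 0.904 yields ≈ 0.32.
- **Simulator** — paired FASTQ with per-read ground truth: Poisson droplet
  loading, log-normal UMI budgets, 0.83 rRNA molecule fraction, 100–400 bp
  inserts, truncated-geometric 5′ capture bias, barcode sequencing errors,
  plus a "perfect aligner" TSV so the whole chain is verifiable offline.

## Worked example

```r
library(microdrops)

design <- bead_primer_design(seed = 1)   # default 96 x 96 x 48 bead design
design
#> Bead primer design: 96 x 96 x 48 segments; stage lengths 27/44/58/96 nt;
#> UMI 8 nt; poly(T) 20 nt

# a small two-species experiment against a toy whitelist
wl  <- build_whitelist(bead_primer_design(generate_segment_sets(1, c(24, 24, 12))))
ec  <- synthesize_species_profile("ecoli", seed = 1, n_genes = 60)
bs  <- synthesize_species_profile("bsub",  seed = 2, n_genes = 60)
cfg <- sim_config(list(ec, bs), n_cells = c(120, 120), seed = 9)
sim <- simulate_library(cfg, wl)
sim
#> Simulated library: 52937 read pairs, 230 barcoded droplets ( 10 doublets), 240 cells

dm <- demux_reads(sim$r1, sim$r2, sim$whitelist, handle = cfg$r2_handle)
dm
#> Demux: 52937 of 52937 reads tagged (too_short: 0 , barcode_unassigned: 0 ,
#> empty_after_trim: 0 )

genes  <- combine_gene_models(list(ec, bs))
asg    <- assign_reads(sim$alignments, genes)
tagged <- merge(dm$tagged, asg[, c("read_id", "gene_id")], by = "read_id")
mat    <- count_umis(tagged, genes)
mat
#> UMI count matrix: 120 genes x 230 barcodes; 10566 UMIs

round(unlist(biotype_report(mat)$proportions), 3)
#>       mRNA       rRNA       tRNA      ncRNA unassigned
#>      0.156      0.833      0.006      0.005      0.000

barnyard(mat, species_gene_map(list(ec, bs)))
#> Barnyard: bsub 112, ecoli 113 ; mixed 5 (doublet rate 2.2%)
```

Reading the output: every error-free read demultiplexes to its true
barcode; the UMI matrix reproduces the simulator's ground truth exactly
(this identity is asserted in the test suite); the biotype report recovers
the configured 83% rRNA dominance; and the barnyard table labels the
cross-species droplets — here 5 mixed barcodes out of 230, consistent with
the simulation's 10 two-cell droplets, of which the cross-species ones are
detectable.

A thin command-line front end is installed as `exec/microdrops`
(`whitelist`, `demux`, `callcells`, `barnyard`, `dash-design`
subcommands); the R functions above are the primary interface.

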