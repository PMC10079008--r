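# gcrescue

Recovery and characterization of GC-rich genes that are missing from
genome assemblies.

## The problem

Genes with extreme GC content and long G/C homopolymer stretches resist
PCR amplification and short-read assembly, so they can be absent from a
species' reference genome and annotation even though they are present in
the organism — and in its raw sequencing data. Annotation-based
orthology searches then wrongly conclude the gene is missing from the
lineage (the avian T-cell adaptor gene *LAT* is the motivating example:
GC-extreme coding sequence, well-conserved protein). `gcrescue` is for
comparative genomicists and immunogeneticists who want to pull such
"hidden" genes directly out of raw read sets and then demonstrate, with
explicit statistics, that the recovered sequence is the real orthologue.

## What it computes

* **Read recruitment** — k-mer seeded, banded Smith–Waterman alignment of
  reads against a bait sequence, thresholded on the bit score
  `S' = (λS − ln K)/ln 2` (defaults: +1/−2 match/mismatch, λ = 1.28,
  K = 0.46, word size 11, threshold 100 bits — an effective ~54 nt floor
  on exact matches).
* **Targeted assembly** — deterministic greedy overlap-layout-consensus
  (overlap ≥ 30 nt, mismatch rate ≤ 0.02, quality-weighted majority
  consensus), iterated with the growing contig as the new bait
  (`iterative_rescue()`), plus six-frame ORF extraction.
* **G/C-stretch statistics** — GC fraction and maximal runs of ≥ 3
  consecutive G/C per CDS; background gene-set profiles (CDS ≥ 300 nt)
  with histogram and query percentile.
* **Ortholog verification** — progressive protein MSA (NJ guide order,
  BLOSUM62, affine gaps), reference-numbered position mapping (e.g.
  "Y132"), a signaling-motif scanner (palmitoylation dicysteine,
  PLC-gamma YLVV with G131-vs-D/E context classing, Grb2 Y-x-N, LCK
  PIPRSP, proline-region fraction), and Saitou–Nei neighbor joining with
  column-bootstrap supports written as Newick node labels.
* **Expression profiling** — per-tissue recruited-read counts normalized
  as `RPKM = count / ((L/1000)(N/10^6))` and an explicit, artifact-defined
  immune-enrichment score.
* **Synthetic data with known truth** — LAT-like protein scaffolds with
  planted motifs, GC-biased reverse translation (exact protein
  preservation), ortholog families evolved along a tree with invariant
  motif sites, single-end read simulation with truth-tracking ids, and
  tissue panels realizing true RPKMs by Poisson sampling.

## Worked example: rescue a planted 72%-GC gene from raw reads

```r
library(gcrescue)

# a 199-aa LAT-like scaffold, reverse-translated at 72% GC (600-nt CDS),
# embedded in a transcript and sequenced at 40x with error-free reads
params <- lat_scaffold_params(protein_length = 199L,
                              docking_tyrosine_positions = c(132L, 155L, 170L, 190L),
                              background_bias = "gc_rich")
prot <- make_lat_like_protein(params, seed = 1)
cds  <- reverse_translate_gc_biased(prot, target_gc = 0.72, seed = 2)
stretch_summary(cds$residues, id = "planted_cds")
#> <stretch_profile> planted_cds: 600 nt, GC 0.702, 62 stretches (>= 3), mean length 5.63

tx    <- make_transcript(cds, seed = 3)
reads <- simulate_reads(tx, n_reads = 320, read_length = 100, error_rate = 0, seed = 4)

# rescue starting from a 200-nt internal fragment of the gene
res <- iterative_rescue(reads, substr(cds$residues, 201, 400),
                        scoring_scheme(), max_rounds = 12)
res$rounds
#>   round n_recruited
#> 1     1          90
#> 2     2         131
#> 3     3         165
#> 4     4         202
#> 5     5         246
#> 6     6         287
#> 7     7         320
#> 8     8         320
res$contig
#> <contig> 796 nt from 320 reads, mean depth 40.2

# the planted ORF is recovered byte-identically
orfs <- find_orfs(res$contig)
hit  <- orfs[orfs$translation == prot$residues, ]
identical(substr(res$contig$consensus, hit$start + 1, hit$end), cds$residues)
#> [1] TRUE

motif_scan(prot)
#> <motif_report>
#>   dicysteine: found at 26
#>   PLC-gamma motif: Y at 132 (context glycine)
#>   Grb2-type Y-x-N: 3 site(s) at 155, 170, 190
#>   LCK-binding PIPRSP: absent
#>   proline fraction in region: 0.549
```

Recruitment grows monotonically as the bait extends (about 45 nt per
side per round: reads need ≥ 54 exact-match-equivalent nucleotides
inside the current bait to clear 100 bits), converging when the
recruited set stops changing. The stretch profile shows why the gene
hides: 62 G/C runs averaging 5.6 nt in a 600-nt CDS, far beyond typical
coding background (its percentile against random-composition background
genes is 100).

A thin command-line layer over the same functions ships in
`inst/cli/gcrescue.R` with subcommands `simulate`, `gcstats`, `recruit`,
`assemble`, `rescue`, `verify` and `express`; see the script header for
usage.

## The acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on
synthetic inputs generated under the given seed: it plants a 600-nt
72%-GC coding sequence and rescues it from 40x reads starting from a
200-nt bait fragment; profiles the rescued CDS against a 60-gene
background; evolves a six-species ortholog family, aligns it, scans the
motif panel, and builds the bootstrapped NJ tree; and quantifies a
six-tissue expression panel against its planted truth. Run it from the
repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It prints a per-stage summary, writes the supporting TSV/FASTA/Newick
outputs next to the JSON report, and exits non-zero on failure.

## Vignette

`vignettes/gc-rescue-methods.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical tie-breaking
and degenerate-input choices, and known limitations.
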