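---
title: "Recovering GC-rich hidden genes: models, parameters and synthetic worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering GC-rich hidden genes: models, parameters and synthetic worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcrescue)
options(gcrescue.verbose = FALSE)
```

## The problem

Some protein-coding genes are absent from genome assemblies and
annotations even though they are present in the underlying genome and
transcriptome. A recurring cause is extreme GC content: long runs of
consecutive G or C bases defeat both PCR amplification and short-read
assembly, so the gene never makes it into the reference, and
annotation-based orthology searches conclude it is missing. The avian
T-cell adaptor gene *LAT* is a canonical example: its coding sequence is
GC-extreme in birds while the protein itself is well conserved.

`gcrescue` implements the desk-scale computational workflow for this
situation: recruit raw reads by homology to a bait from a related
species, assemble them into a candidate coding sequence, iterate with the
growing contig as the new bait, and then verify the candidate — by its
G/C-stretch statistics against a background gene set, by conserved
signaling motifs under reference-based numbering, by a distance-based
phylogeny with bootstrap supports, and by a tissue expression profile.
Because the real inputs (SRA-scale read archives) are not reproducible at
desk scale, the package ships a synthetic-data module that generates all
of these inputs with known truth; every pipeline stage is tested against
that truth.

## Read recruitment

Recruitment is seed-and-extend local alignment against the bait with a
bit-score cutoff, mirroring a BLASTN search with a fixed bit-score
threshold:

* every exact k-mer shared between read and bait (or its reverse
  complement) seeds a banded Smith–Waterman extension with affine gaps
  (band half-width 15 around the seed diagonal);
* the best raw score $S$ over all seeds and strands is converted to a bit
  score $S' = (\lambda S - \ln K)/\ln 2$;
* reads with $S' \ge$ `bit_threshold` are recruited, one best hit per
  read (ties prefer the lower bait coordinate).

The defaults are match $+1$, mismatch $-2$, gap open $-5$, gap extension
$-2$ (a gap of length $L$ costs $5 + 2L$), $\lambda = 1.28$, $K = 0.46$,
word size 11 and threshold 100 bits. The threshold is the procedure's
scientifically meaningful knob; the scoring constants are this package's
self-contained stand-ins for "default BLASTN parameters", chosen so the
bit conversion is documented and configurable rather than
implementation-defined. No claim is made that scores equal BLAST's;
tests instead pin the internal consistency of the identity (an exact
100-nt match scores $(1.28 \cdot 100 - \ln 0.46)/\ln 2 \approx 185.8$
bits) and its consequences (exact matches shorter than 54 nt fall below
100 bits, so the threshold imposes an effective read-length floor).

The band half-width matters only at high divergence: at the $\le 5\%$
divergence where recruitment operates, the optimum alignment stays within
the band, and the test suite checks equality against an unbanded
Smith–Waterman oracle at $\le 2\%$ divergence.

## Targeted assembly and iterative rescue

Recruited reads are assembled by a fully specified greedy
overlap-layout-consensus procedure: repeatedly merge the pair of
reads/contigs with the longest suffix–prefix overlap of at least
`min_overlap` (30) bases and mismatch rate at most `max_mismatch_rate`
(0.02), both orientations considered; ties prefer the longer resulting
contig, then lexicographically smaller read ids. The consensus is a
per-column weighted majority (weights are base qualities when present,
else 1) with ties resolved in the fixed order A < C < G < T. This is
deliberately a defined, deterministic procedure rather than a call into a
commercial assembler: single-gene targeted assembly at desk scale does
not need a de Bruijn graph, and determinism makes every downstream
assertion exact.

`iterative_rescue()` alternates recruitment and assembly, promoting the
longest contig (oriented to the strand that aligns best to the current
bait) to be the next bait, and stops when the recruited read set stops
changing or after `max_rounds`. Starting from a 200-nt internal bait
fragment, each round can extend the recruitable window by roughly
`read_length` minus the ~54-nt threshold floor on each side, which is why
full-length recovery of a 600-nt gene needs on the order of 5–10 rounds.
One caveat: at very low coverage the longest contig can be *shorter* than
a full-length starting bait, in which case the recruited count can drop
between rounds; the monotone-growth property holds in the adequate
coverage regime (tests use 30–40x) where the procedure is meant to
operate.

In GC-extreme contigs one artifact deserves note: stop codons are AT-rich
(TAA/TAG/TGA), so a 70%+ GC contig can contain long stop-free runs in
frames other than the true one. `find_orfs()` therefore reports *all*
ATG-to-stop ORFs of at least `min_aa` codons in all six frames; the
longest is flagged as the candidate, but verification (motifs, homology)
— not length alone — identifies the true CDS when a spurious
reverse-frame ORF happens to be longer.

## G/C-stretch statistics

A G/C stretch is a maximal run of consecutive G or C bases of length at
least `min_len` (default 3). Maximality is taken literally: a run is
flanked by a non-G/C base or the sequence end, so adjacent G/C bases are
always part of the same stretch. The per-gene summary is the GC fraction
and the mean length of qualifying stretches; runs shorter than `min_len`
contribute neither to the count nor to the mean. `N` bases terminate a
run and are excluded from the GC fraction entirely — a conservative
choice (the statistic can only be deflated, never inflated, by ambiguous
bases) that matters only for robustness, since assembled CDSs should be
N-free.

Gene-set profiling keeps coding sequences of at least 300 nt (i.e.
longer than 299 nt), histograms the mean stretch length with bin width
0.1 (the reported tables are binning-independent; the width only shapes
the histogram TSV), and reports the percentile rank of a designated
query gene — the natural summary for "the rescued CDS is more
stretch-laden than essentially the entire background gene set".

## Ortholog verification

**Pairwise and progressive alignment.** `nw_align()` is global
Needleman–Wunsch with BLOSUM62 and affine gaps (open $-10$, extension
$-1$ per residue; a gap of length $L$ costs $10 + L$, matching the
Biostrings convention so the two implementations are directly
cross-checkable). Traceback ties prefer diagonal, then up, then left, so
alignments are deterministic. `progressive_msa()` builds a guide order by
neighbor joining on $1 - \text{identity}$ distances and merges profiles
by profile–profile Needleman–Wunsch with column-average scoring; a gap in
a profile column contributes 0 to the column score, with gap creation
priced only by the DP's affine penalties. For zero-indel families at
modest divergence this produces gapless alignments; at higher divergence
occasional staggered gaps are genuinely score-optimal and are accepted as
such.

**Reference numbering and motifs.** Positions in all human-facing output
are 1-based in a designated reference sequence (the convention used for
LAT throughout the literature, e.g. Y132); internally all intervals are
0-based half-open, converted only at I/O boundaries.
`map_ref_position()` transfers a reference position through the
alignment to every row. `motif_scan()` reports: the palmitoylation
dicysteine `C-x(1,4)-C` searched within residues 1–45 (an approximation
of "extracellular + transmembrane" that avoids a transmembrane predictor);
the PLC-gamma binding motif (default exact `YLVV`, configurable for
divergent orthologs) with its context class — `glycine` when the residue
before the tyrosine is G (the tetrapod arrangement that makes the site a
suboptimal kinase substrate), `acidic` for D/E (the fish arrangement);
Grb2-type `Y-x-N` sites; the exact LCK-binding hexapeptide `PIPRSP`; and
the proline fraction over the reference-numbered region 30–100, defined
as the number of prolines divided by the region length in reference
numbering.

**Phylogeny.** Tree inference is Saitou–Nei neighbor joining on p- or
Poisson-corrected ($d = -\ln(1-p)$) distances computed over columns where
neither row is gapped, with bootstrap supports from column resampling
(500 replicates by default). Q-criterion ties are broken by
lexicographic taxon-pair order and negative branch lengths are clamped to
zero with a log entry — standard practice that keeps Newick output valid.
Maximum-likelihood inference (LG model, gamma rates, SPR search) is
deliberately out of scope: the tree's role in this workflow is orthology
and clade-membership verification, which topology-level NJ supports at a
fraction of the implementation budget; this is the package's largest
methodological substitution. Similarly, a single progressive alignment
over all inputs replaces group-wise alignment followed by a merge step,
which exists in practice only when clades are aligned separately.

## Expression profiling

Per tissue, the recruited-read count against the gene CDS is normalized
as RPKM: $\text{count} / ((L/1000)(N/10^6))$ with $L$ the gene length
and $N$ the *total* number of reads in the dataset. Using total rather
than "mapped" reads is the only computable reading of the procedure when
recruitment runs against whole datasets and genome-wide mapping never
happens; the choice is logged in the output. Immune-organ enrichment is
formalized (and labeled artifact-defined, since the underlying
observation is qualitative): records sorted by RPKM, immune and
non-immune median RPKMs with their ratio (undefined when the non-immune
median is zero), and an `enriched` flag that is true iff every immune
tissue exceeds the non-immune median.

## The synthetic worlds

`make_lat_like_protein()` generates a LAT-like scaffold: initiator
methionine, dicysteine at 26/29, docking tyrosines at 132/171/191/226
with `YLVV` context at the first and `Y-x-N` at the others, a
configurable residue (G/D/E) at 131, a proline-enriched region at 30–100
(proline probability 0.4, matching the proline-dense intracellular
N-terminus of real LAT), and optionally `PIPRSP` at 104. Background
residues avoid C and Y so the planted motifs are unique with high
probability. Two compositions are available: `uniform` over the 18
remaining amino acids, and `gc_rich`, which up-weights G/A/P/R
(each offering a fully-GC codon) 4-fold. The biased composition exists
because a uniform amino-acid composition caps the synonymous-codon GC
ceiling at roughly 0.63–0.71 depending on the draw, whereas the
GC-extreme genes this package targets owe their composition partly to
exactly this kind of amino-acid bias; the avian-like test worlds use
`gc_rich` so that a 72% GC coding sequence is reachable for every seed.

`reverse_translate_gc_biased()` samples synonymous codons with weights
$e^{\beta \cdot \text{GC}(codon)}$, tuning $\beta$ by bisection so the
expected GC matches the target, followed by a deterministic
synonymous-swap pass until the realized GC is within 0.02 of the target
(or of the closest achievable bound; targets more than 0.05 beyond the
achievable range are an error that reports the range). The protein, and
hence the motif panel, is preserved exactly — mirroring the real
situation where the protein is conserved while the CDS is GC-extreme.

`evolve_orthologs()` substitutes each non-invariant site with probability
$1 - e^{-b}$ along a branch of length $b$ (expected substitutions per
site), replacements uniform over the 19 other residues. A uniform
replacement model rather than an empirical matrix is a deliberate
pairing: the inference stage is distance-based and only topology recovery
is asserted, so simulating under LG would add a dependency without
changing what is testable — and it keeps generator and inference
independent. Planted motif sites are passed as invariant so the panel
survives divergence.

`simulate_reads()` draws single-end reads with template choice
proportional to weight x length, uniform start and strand, uniform
substitution errors at `error_rate`, constant Q30 qualities, and the true
origin recorded in the read id. Substitution-only errors are the default
(short-read data of the relevant platforms are substitution-dominated); a
simple indel mode exists, off by default, to stress the assembler.
`make_transcript()` embeds a CDS in random UTR flanks with an in-frame
stop immediately upstream of the ATG, making the planted open reading
frame exactly the recoverable unit — without it, a chance upstream
in-frame ATG can fuse flank sequence onto the recovered protein. Rescue
tests simulate reads from such transcripts rather than bare CDSs because
uniform read starts cover the extreme first and last template bases only
~38% of the time each at 40x, so exact end-to-end recovery of a bare
template would be a coin flip rather than a property.

`make_tissue_panel()` realizes per-tissue target read counts as Poisson
draws with mean $\text{RPKM} \cdot (L/1000)(N/10^6)$ and fills the
remainder of each library from background genes. The default truth table
has six chicken-like tissues — spleen, thymus and bursa (immune) at RPKM
400/300/250, liver, brain and muscle (non-immune) at 40/15/0 — with
$10^5$-read libraries: strong lymphoid enrichment of a moderately
expressed adaptor gene, with per-tissue target counts in the tens so that
Poisson noise is visible but not dominant. The tissue-to-immune
designation is user-supplied configuration throughout; there is no
hard-coded taxonomy of "immune organs".

What the generator does *not* emulate — and what a green test therefore
does not establish: empirical codon-usage tables, platform-specific error
or coverage profiles, paired-end structure, intron-containing (genomic)
reads and spliced alignment, and sequence-composition biases of real
transcriptomes beyond GC content. The pipeline targets contiguous
transcript-like templates; genomic mode is future work.

## Numerical and degenerate-input choices

* All stochastic operations take an explicit seed (default 42) and are
  byte-reproducible; seeds derived inside compound generators stay below
  $2^{31}$.
* Seed diagonals within band/2 of an already-scanned diagonal are
  collapsed, and at most 64 diagonals per strand are extended, so
  pathological reads cannot blow up the banded extension.
* An alignment with zero comparable columns for some pair, a p-distance
  of 1 under the Poisson correction, an all-N sequence, an empty
  post-filter gene set, and a tissue with no flags are all hard errors;
  an empty read set in expression counting is a warning with count 0.
* A zero-variation alignment bootstraps to 100% support on every edge
  because NJ's lexicographic tie-breaking resolves star topologies
  deterministically.
* `write_newick()` emits branch lengths at 6 significant digits and
  supports as internal node labels; re-parsing reproduces topology and
  lengths to that precision.

## Limitations

Beyond the generator's stated non-goals: the greedy assembler is
quadratic in read count and sized for single-gene read sets (hundreds to
thousands of reads), not genome-scale assembly; recruitment assumes the
bait and target differ by at most a few percent at the nucleotide level,
as is the case within the bird clade for the motivating gene family; and
the CLI writes TSV/FASTA/Newick only — plotting is left to the caller.
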