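---
title: "Comparing related prokaryote genomes: ANI, AAI, shared genes, and read-recruitment discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing related prokaryote genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

When a new genome is recovered from a metagenome — say, a sulfate-reducing
Firmicutes bin assembled from deep-subsurface borehole fluids — the first
questions are comparative: how similar is it to its closest sequenced
relative, which genes do the two share, and can short metagenome reads from
an environmental sample be attributed to one lineage or the other?
`genopair` implements the standard battery of pairwise statistics used to
answer them:

* **ANI** (average nucleotide identity): the unweighted mean percent
  identity over bidirectional best-hit gene pairs passing an identity floor
  of 70% and ≥70% coverage of the shorter gene. ~95% is the conventional
  species boundary; values in the high 70s indicate clearly distinct
  species.
* **Two-way AAI** (average amino acid identity): the protein-level
  analogue, computed over reciprocal best-hit protein pairs restricted to
  proteins of ≥100 aa; 65–75% spans the genus boundary.
* **Percent shared genes**:
  `100 · 2·n_pairs / (n_A + n_B)`, where `n_pairs` is the number of
  reciprocal protein pairs entering the two-way AAI and `n_A`, `n_B` count
  proteins passing the length floor in each genome.
* **Shared/unique inventories**: a gene of genome A is *shared* iff it has
  at least one directional hit in B passing E ≤ 1e−5 and identity ≥ 30%;
  inventories can be summarized over COG categories.
* **Fragment-recruitment discrimination**: both genomes are cut into
  non-overlapping 150 bp fragments, each genome's fragments are mapped
  against the *other* genome across a 70–100% identity sweep, and the
  discrimination threshold is the smallest identity at which cross-mapping
  (spurious matches) falls to ~1% in both directions. Reads are then
  recruited against the joint reference at that threshold with a single
  best hit per read, and the per-genome read counts give the
  lineage-abundance ratio.

Every stage runs on a synthetic genome pair with known ground truth, so the
whole pipeline is testable end to end without downloading anything.

## The alignment engine

All statistics rest on one local aligner (in compiled code): exact-match
k-mer seeds (k = 11 nucleotide, 4 protein) are collected per
query–subject pair, seed diagonals are clustered, and each cluster is
extended by a banded affine Smith–Waterman restricted to the cluster's
diagonals plus a pad of 16. Percent identity is defined once, everywhere,
as `100 · matches / alignment_columns` with gap columns counted. Scoring
defaults are the community-standard +1/−2 with gaps −5/−2 (nucleotide) and
BLOSUM62 with gaps −11/−1 (protein). `N`/`X` never count as matches and
break seeds.

Two deliberate approximations:

* **E-values** use ungapped Karlin–Altschul constants applied to gapped
  scores (`E = K·m·n·e^{−λ·score}`; λ solved exactly for the nucleotide
  scheme at uniform composition, published BLOSUM62 constants for
  protein). Downstream, E is only a coarse 1e−5 filter, for which
  monotonicity in score is what matters.
* **Banded extension** is exact whenever the optimal alignment stays
  within the seeded band. The test suite verifies, on hundreds of toy gene
  pairs, that the seeded path reproduces the exhaustive full-matrix
  dynamic program score-for-score, and that the exhaustive path in turn
  agrees with `Biostrings::pairwiseAlignment`.

Ties between equal-scoring hits are broken by higher identity, then longer
alignment, then lexicographically smallest subject id, so every run is
deterministic.

## The simulator and what it does (not) emulate

`generate_ancestor()` emits a single-contig, gene-dense chromosome
(defaults: 100 kb, 90% coding, mean gene 900 bp, GC 0.602 — the
characteristics of a small subsurface Firmicutes genome), with ATG starts,
stop-free interiors, terminal stop codons, and ~50% of genes on the minus
strand to exercise strand handling.

`diverge_pair()` applies, independently on two lineages:

* **Substitutions**, i.i.d. per site with a transition/transversion bias
  (default κ = 2). The per-lineage substitution probability `p` is solved
  exactly from `2p(1−p) + p²(1−c) = d`, where `c` is the probability two
  independent mutant draws coincide under the ts/tv kernel, so the
  *pairwise* expected mismatch fraction equals the programmed
  `site_divergence` with no small-`d` approximation; the realized value is
  calibrated to within ±0.005 up to `d = 0.231` in the test suite. Inside
  genes, draws that would create an in-frame stop codon are redrawn among
  the remaining alternatives, and the terminal stop codon is left alone.
* **Indels** (default 5·10⁻⁴ per site, ≤6 bp): codon-aligned inside genes
  (whole interior codons inserted or deleted, so frames and stops survive)
  and free-length between genes, never crossing a gene boundary.
* **Gene loss**: each gene deleted from each lineage independently with
  probability `gene_loss_fraction`, removed from both the sequence and the
  gene table.

The truth record carries the surviving ortholog pairs, their
substitution-level nucleotide and protein identities, and the realized
aligned-site divergence of the emitted pair (computed over the ancestral
coordinate map, which the element-wise representation keeps exact through
indels and loss).

`simulate_reads()` draws fixed-length reads (default 150 bp — the typical
metagenome read length) from uniformly random positions and strands of
genomes chosen by weight, adds i.i.d. substitution errors (default 0.5%, a
free choice since real error models vary by platform), and can mix in an
i.i.d.-random background component that should recruit nothing at high
identity. Per-read provenance is retained.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: rate heterogeneity across loci (no highly
conserved rRNA operons or slow core genes), codon-usage structure,
rearrangements, horizontal transfer, repeats, and compositional skews.
Two consequences worth knowing:

1. On real genome pairs at ~77% ANI the cross-mapping sweep keeps a ~1%
   tail of spurious matches up to a 96% identity threshold, driven by
   conserved regions; uniform-rate synthetic pairs at the same divergence
   concentrate fragment identities near the mean, so the ~1% operating
   point is reached already at ~86–87%. The sweep/selection machinery is
   identical; only the curve's tail differs.
2. Under neutral uniform-rate substitution most changes are
   nonsynonymous, so AAI sits well below what purifying selection produces
   at the same ANI. `nonsyn_fraction` tunes AAI relative to ANI, but only
   within the genetic code's structural limits (fourfold-degenerate sites
   cannot be forced nonsynonymous). AAI recovery is therefore validated
   against the generator's realized protein identity, not against a value
   typical of real pairs.

## A worked example

```{r, eval = FALSE}
library(genopair)

anc  <- generate_ancestor(ancestor_spec(genome_length = 100000, seed = 11))
pair <- diverge_pair(anc, divergence_spec(0.231, gene_loss_fraction = 0.15,
                                          seed = 12))
pair$truth$realized_site_divergence
#> [1] 0.2304448

m <- pair_metrics(pair$genome_a, pair$genome_b)
m
#> <genopair_metrics> ancestor_A vs ancestor_B
#>   ANI (A->B): 77.0%  (B->A 77.0%, 83 gene pairs)
#>   AAI two-way: 57.3%  (83 protein pairs)
#>   Percent shared genes: 90.2%
#>   Shared in ancestor_A: 83 / 91 (91.2%)

sw  <- threshold_sweep(pair$genome_a, pair$genome_b, L = 150)
sel <- select_threshold(sw, max_spurious = 0.01)
sel
#> [1] 87
autoplot(sw)

reads <- simulate_reads(
  list(A = pair$genome_a, B = pair$genome_b),
  read_mix_spec(10000, weights = c(A = 4, B = 1), seed = 5))
discrimination_ratio(reads, pair$genome_a, pair$genome_b, threshold = sel)
```

A genome at 23.1% site divergence yields ANI ≈ 77% — the divergence regime
of two distinct species in one genus — and the 4:1 read mixture is
recovered as a ratio near 4 because cross-mapping at the calibrated
threshold is below 1%.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally, 1-based inclusive only
  in GFF3 output and the 12-column hit tables.
* **Identity denominator** includes gap columns (BLAST-style); stated once
  and used everywhere, including the filters.
* **"Bidirectional best hits" for ANI** are read as reciprocal best hits;
  one-way best hits are available via `reciprocal = FALSE` for sensitivity
  analysis, as is alignment-length weighting (`weighted = TRUE`). The
  defaults are unweighted reciprocal means.
* **AAI uses reciprocal pairs for both directions**, so the pair count
  feeding `percent_shared_genes()` is the same "number of proteins used
  for two-way AAI" that appears in the formula, keeping the two statistics
  self-consistent. The length floor counts *proteins* of ≥100 aa, the only
  reading under which the formula stays ≤100%.
* **ANI with no qualifying pairs** is `NA` (undefined), never 0.
* **Sweep cross-mapping** aligns a genome's fragments against the other
  genome *alone*: with a joint reference every fragment would trivially
  self-hit at 100% and spurious mapping would be identically zero. The
  discrimination step, by contrast, uses the joint reference with a single
  best hit per read — matching how recruitment is actually run.
* **Read similarity** is local-alignment identity with ≥80% of the read
  aligned; the coverage floor prevents short high-identity slivers from
  counting as recruitment.
* **Degenerate inputs**: `select_threshold()` on identical genomes errors
  (cross-mapping ≡ 1) with the curve attached; zero reads yield an empty,
  well-formed recruitment result; `percent_shared_genes()` with empty
  proteomes errors rather than dividing by zero.
* **Problem sizes in the tests**: calibration properties use 30 kb
  genomes with 10 replicates per divergence; parameter-recovery and
  discrimination checks use 100 kb pairs and 10,000 reads. These sizes
  give binomial confidence intervals comfortably inside the stated
  tolerances while keeping the default suite quick.

## Limitations

Translated (nucleotide↔protein) search, full BLAST statistics with
edge-effect corrections, rearrangement-aware alignment, and exact
reproduction of any particular tool's seeding heuristics are out of scope.
Gene calling is consumed, never performed: gene models come from the
simulator or from GFF3. The package compares *two* genomes; all-vs-all
matrices are a loop away but not provided.
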