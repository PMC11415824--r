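---
title: "Calling mobile element variants from long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mobile element variants from long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mobile genetic elements — Alu (~300 bp), LINE-1 (L1, up to ~6 kb and very
often 5'-truncated) and SVA (composite, ~1–5 kb) — account for a large
fraction of structural variation in human genomes. A mobile element variant
(MEV) is an insertion (MEI) or deletion (MED) whose sequence content is such
an element. Long reads span these events whole, but the signal is noisy: the
same element class appears at wildly different lengths (truncation, polyA
tail variation), copies diverge from any consensus, and sequencing errors
fragment the alignment evidence.

`mevcall` detects and genotypes MEVs from coordinate-sorted long-read
alignments in four stages, and ships a simulator and an evaluation module so
that the whole pipeline is testable end to end without any external data.

## Pipeline model

### 1. Signature extraction

Every passing primary alignment (MAPQ ≥ `min_mapq`, not secondary, not
supplementary) is scanned for insertion/deletion *signatures*:

* **CIGAR channel** — each `I` operation of length ≥ `min_signature_size`
  yields an INS signature at the reference coordinate preceding the
  insertion point, carrying the inserted bases; each qualifying `D`
  operation yields a DEL signature at the deleted interval's start.
* **Split-read channel** — supplementary placements (SA tag) of the same
  read on the same chromosome and strand are ordered by query offset (hard
  clips counted). For each adjacent pair with query gap $q$ and reference
  gap $g$: $q - g \ge$ `min_signature_size` is an INS, $g - q \ge$
  `min_signature_size` a DEL, both placed at the upstream segment's
  reference end. Cross-chromosome and cross-strand pairs (translocation /
  inversion signals) are out of scope and skipped.

`min_signature_size` defaults to 30 bp — far below the Alu scale, so that
fragmented evidence still contributes. Coordinates are 0-based half-open
internally and converted to 1-based only in VCF output.

### 2. Clustering and consensus

Signatures of one SV type are sorted by position and chained by single
linkage: a signature joins the open cluster iff its gap to the previous
member is ≤ `cluster_max_distance` (default 1000 bp) and its length agrees
with the cluster's running median within `cluster_size_ratio` (default 0.7,
min/max). Both defaults follow long-read SV-caller convention; the source
method leaves them open. Clusters with fewer than `min_support` distinct
read names (the `-s` parameter) are discarded.

Each INS cluster is collapsed to one consensus sequence by a
partial-order-alignment stand-in: the member whose length is closest to the
cluster median becomes the backbone, all other members (capped at
`max_consensus_reads = 10`) are globally aligned to it, and every backbone
column is decided by majority vote. Ties follow the fixed order
A < C < G < T < N < gap, so runs are bit-reproducible; columns whose
majority is a gap are dropped; insertions relative to the backbone are
ignored. Unanimous clusters and single-member clusters return the member
sequence verbatim — these two contracts are what any substitute consensus
backend (e.g. a real POA library) must also satisfy. DEL clusters take the
reference substring `[anchor_pos, anchor_pos + median_length)`: the content
of the deleted allele, which is what gets classified next.

### 3. Two-round classification

**First round — template alignment.** The consensus is aligned against
every library template on both strands with an affine-gap Smith-Waterman
(match 2, mismatch −4, gap open −4, gap extend −2; a gap of length $L$
costs $open + L \cdot extend$; `N` scores 0 and never counts as a match).
For speed, sequences longer than 256 bp are aligned inside a diagonal band
of half-width $\max(64,\ 0.2\,\max(n,m))$ centred on the diagonal sharing
the most k-mers with the template; with no shared k-mer the full dynamic
program runs. At test sizes the band provably changes nothing, which the
test suite asserts against an independent unbanded oracle.

The best template's class is assigned iff identity ≥
`first_round_identity_threshold` (0.7) **and** the aligned query span
covers ≥ `first_round_span_fraction` (0.5) of the *template* length. The
span rule is deliberately template-relative: a heavily truncated fragment
aligns perfectly over its own full length, so any consensus-relative rule
would classify arbitrarily small fragments in round one and leave nothing
for the second round — the stage that exists precisely to handle fragmented
elements. Score ties are broken by higher identity, then shorter template,
then template name, so library order never matters.

**Second round — prescreen plus pluggable classifier.** Sequences the first
round leaves unclassified are first prescreened: the fraction of the
consensus's distinct 11-mers shared with some template (either strand) must
reach `prescreen_min_fraction` (0.2). Uniform random DNA shares essentially
no 11-mers with a template (~$m/4^{11}$ per k-mer), while a 2%-diverged
element copy retains $0.98^{11} \approx 0.80$ of them, so the prescreen
cleanly excludes unrelated sequence — the role a fast mapper plays in
heavier implementations. Survivors go to the second-round classifier behind
a plugin contract: any function `(sequence) -> list(me_class, confidence)`.
A plugin error is caught and logged; the pipeline never crashes on a
plugin, it just leaves the call unclassified.

The bundled baseline classifies by **6-mer containment**: the fraction of
the query's distinct 6-mers present in a template (max over templates and
strands), assigning the best class when that fraction reaches 0.5. We chose
containment over a symmetric measure (e.g. cosine over profiles) after
noting that a 35–50% fragment's cosine against its own full template is
$\approx \sqrt{0.35..0.5} \approx 0.6..0.7$ *before* divergence and polyA
dilution, i.e. hovering at any usable threshold exactly on the inputs this
round exists for, whereas containment stays near $0.98^6 \approx 0.89$
regardless of truncation. The slot is designed for a heavier model — a
fine-tuned DNA language model drops in behind the same contract without
code changes. `second_round_enabled = FALSE` (CLI `--no-second-round`) is
the ablation mode: first round only.

### 4. Genotyping and output

Each classified call is genotyped from `dv` (cluster support) and `dr`
(passing primaries spanning `pos ± spanning_flank` that contributed no
signature to this cluster; reads soft-clipped at the event do not span and
are counted on neither side). With $af = dv/(dv+dr)$: below
`het_af_low` (0.2) the locus is dropped — `0/0` is never emitted; within
`[0.2, 0.8]` it is `0/1`; above, `1/1`. These allele-frequency bands follow
the convention of the cuteSV family; a binomial-likelihood model would slot
into the same contract. Output is VCF 4.2 with `SVTYPE`, `SVLEN`, `END`,
`MECLASS`, `CROUND` and `GT:DR:DV`; deletions are symbolic `<DEL>` by
default with explicit alleles behind a flag, and `--fixed-header-date`
makes output byte-identical across runs.

## The simulator: what it emulates, and what it does not

`simulate_genome()` builds an i.i.d. uniform random reference in which one
element copy per MED is embedded, then edits per-haplotype: MEIs insert an
element copy, MEDs delete theirs, ordinary SVs insert random sequence or
delete random intervals (50–2000 bp). Element copies are template copies
with 2% substitution divergence and a geometric polyA tail (mean 30 bp); L1
copies are 5'-truncated to a uniform fraction ≥ 0.3 when `l1_truncation` is
on (default). Events are heterozygous with probability `het_fraction`
(default 0.5 — the natural diploid default in the absence of a stated
allele-frequency spectrum) and are laid out with ≥ 3 kb separation so
neighbouring events never interact. Ordinary SVs exist specifically so the
false-discovery rate is a meaningful metric: random insertions must *not*
be classified as MEVs.

`simulate_reads()` samples reads uniformly per haplotype at `depth/2` fold
coverage each, Normal lengths truncated at 500 bp, and injects per-base
errors (HiFi-like: substitutions 0.002, indels 0.0005; ONT-like: 0.02 /
0.02). Alignments are *projected analytically* from the known
haplotype-to-reference coordinate map — no aligner runs — so implanted
insertions become `I` operations, deletions `D` operations, and deletions
≥ `split_del_threshold` split the read into primary + supplementary
placements with reciprocal SA tags. This keeps the artifact deterministic
and download-free; a FASTQ can be written for users who prefer to run a
real aligner.

The built-in template library is three fixed pseudo-random sequences (Alu
300 bp, SVA 600 bp, L1 900 bp — L1 longest, mirroring the real classes at
toy scale). They are synthetic stand-ins, not biological consensus
sequences: a green test establishes the pipeline's mechanics (signature
arithmetic, clustering, consensus, classification logic, genotyping), not
performance on the real human repeat landscape. Real-data features the
simulator deliberately omits: a repetitive genome backbone (thus mapping
ambiguity), target site duplications, nested or adjacent MEVs, GC/coverage
bias, chimeric reads, and subfamily structure within a class.

A trio mode composes a child genome from one haplotype of each of two
simulated parents sharing a reference, so Mendelian consistency holds by
construction and measured discordance is caller error.

## Evaluation

A call matches a truth record iff same SV type, position within `window`
(1000 bp) and min/max size ratio ≥ 0.7; matching is greedy by position
distance with each truth record used at most once (the test suite checks
greedy attains the optimal bipartite matching size on small instances).
Calls at a matched locus with the wrong ME class are a separate
false-positive category (`fp_class`), mirroring the two FP categories the
field distinguishes (wrong class vs wrong locus). Presence F1 ignores
class; class-aware F1 requires it; genotype-aware F1 additionally requires
genotype agreement. FDR is $fp/(tp+fp) = 1 -$ precision. Trio analysis
takes the union of matched loci (absent call = `0/0`) and counts a site
discordant iff the child's genotype cannot be assembled from one
transmitted allele per parent.

## Numerical and degenerate-input choices

* Consensus column ties: fixed base order; a base always beats a gap.
* Classification score ties: identity, then shorter template, then name.
* Cluster anchor and length: integer medians of member positions/lengths.
* Empty inputs: empty SAM → empty callset; `dv + dr = 0` → error; empty
  library → error; consensus shorter than k → prescreen false.
* All RNG flows from a single integer seed; derived seeds (reads: seed+1;
  trio members: seed+11/22/33) stay below $2^{31}$. Identical seed and
  configuration reproduce truth VCF, SAM and call VCF byte for byte.

## Known limitations

* At 5× total depth a heterozygous event is covered by ≥ 2 carrier reads
  only ~71% of the time (Poisson with mean 2.5), which bounds het recall no
  matter the caller; the 5× benchmark reflects this arithmetic.
* One linear chromosome per invocation; no multi-sample joint calling, no
  phasing, no inversion/duplication/translocation signatures.
* The consensus backend ignores insertions relative to the backbone; with
  more divergent members than the toy setting a true POA would be
  preferable (the strategy is interchangeable behind the two contracts
  above).
* Subfamily-level annotation (e.g. AluYa5 vs AluYb8) is out of scope.
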