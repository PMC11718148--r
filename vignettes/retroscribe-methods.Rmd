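---
title: "Quantifying repeat transcription from genome skims: methods and design"
author: "retroscribe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat transcription from genome skims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant genomes are dominated by repetitive DNA — LTR retroelements of the
Ty1/copia and Ty3/gypsy superfamilies, DNA transposons, satellites, rDNA —
and a central question of repeat biology is which of these repeats are
*transcribed*, in which tissues, and through which pathway: selfish Pol II
transcription of young, active elements (visible in poly-A RNA libraries)
versus silencing-associated Pol IV/V transcription through the RdDM
pathway (visible only in ribo-depleted libraries). `retroscribe`
implements, at desk scale, a reference-free route to that question:

1. **Repeat discovery from a genome skim.** Low-coverage shotgun reads are
   clustered into repeat families: two reads join when their best local
   alignment is at least 90 % identical over at least 55 % of the (shorter)
   read. Connected components of that graph are the repeat clusters;
   clusters with more than 150 reads ("top clusters") are quantified. The
   genome proportion (GP) of a cluster is its read count divided by all
   analyzed reads, excluding reads in clusters of organellar origin.
2. **Per-cluster genomic characteristics.** The modal pairwise similarity
   score (mode of per-pair percent identities at or above an 80 % floor,
   a proxy for repeat age) and the pooled GC content of the member reads.
3. **Structural annotation of LTR retroelements** in an assembled genome:
   detection of the LTR pair, the primer binding site (PBS) and the target
   site duplication (TSD). An element is *complete* exactly when all three
   are present, *incomplete* when at least one is missing. Elements are
   placed in genomic context (intronic / gene-adjacent / intergenic).
4. **Transcript proportion (TP).** RNA-seq reads map to the cluster
   consensus contigs (or to annotated elements) under the same
   90 % / 55 % criterion; each read counts once, for its best target.
   TP of a unit is its mapped reads divided by the library's reads after
   removing reads mapping to rRNA/organellar/tRNA clusters, as a
   percentage.
5. **Models.** Ordinary least-squares fits of TP against GP, GC and modal
   similarity (log10 transforms where stated; zero-TP clusters are dropped
   only when the response is logged), and Tukey HSD comparisons of
   similarity/GC across lineages with a compact letter display.

Because the real study-scale inputs (hundreds of millions of reads,
external annotation pipelines) are out of reach for a package test suite,
every step is validated against a **synthetic genome generator with a
ground-truth manifest**: the generator is first-class, tested code, and
the recovery of GP, TP, similarity, completeness and context against the
manifest is the package's primary evidence of correctness.

## The synthetic generator

`repeatFamilySpec()` describes one family: class and lineage label, copy
number, unit length, GC target, per-copy divergence, indel rate,
structure (LTR length, PBS tRNA, TSD length; TIRs; satellite monomer and
array size), the fraction of copies emitted structurally incomplete, and
per-library transcription weights. `buildFamilyMaster()` emits the family
master with exact-count base composition (random segments compensate for
the fixed motif segments); LTR masters carry two initially identical LTRs
with the canonical `TG…CA` boundary motif, a PBS complementary to a tRNA
3' 18-mer immediately internal to the 5' LTR, and protein-domain motifs
in the superfamily's canonical order (`GAG-PROT-INT-RT-RH` for Ty1/copia,
`GAG-PROT-RT-RH-INT` for Ty3/gypsy). The domain and tRNA libraries are
small synthetic fixtures bundled in code — distinct, stable peptides and
18-mers — not database sequences.

`plantGenome()` inserts independently mutated copies (star phylogeny) at
uniform non-overlapping positions, flanked by a 4–6 bp TSD unless the
copy is flagged incomplete-without-TSD; a configurable fraction of
LTR-family copies is placed inside introns of generated gene models.
Copies planted without a TSD receive fixed guard pads so that an exact
4–6 bp flank match cannot arise by chance — the completeness ground
truth is then unambiguous. The manifest records, per family, the planted
GP (family bases over nuclear genome bases — organellar contigs are
excluded from the denominator, mirroring the GP estimator), the
*empirical* expected pairwise identity (mean banded global-alignment
identity over sampled copy pairs, rather than the approximation
`1 − 2d(1−d)`), and the realized GC.

Read simulators emit paired-end skim reads (uniform fragments, strand
sampled at ½, substitution errors; contigs weighted by length × copy
factor so the plastid-like contig is over-represented as in real skims;
the coverage→pair-count helper uses ceiling so a requested sampling
fraction is never under-shot) and RNA libraries. Poly-A libraries draw
from spliced gene transcripts plus each family's poly-A weight; intronic
repeat copies contribute only through an intron-retention rate (default
0.1) on pre-mRNA, emulating co-transcription with host genes.
Ribo-depleted libraries additionally draw from every nuclear repeat
family in proportion to planted GP scaled by an `rddmGpCoupling` knob
(default 0.05), plus a residual rRNA fraction (default 0.02). The
coupling knob is a modelling choice of this package — the mechanistic mix
of polymerases behind ribo-depleted repeat reads is not something the
generator can claim — and it is the knob that makes hypothesis-style
TP~GP relationships testable. The expected-TP table records the
*realized* per-family read fractions by read origin, so sampling noise is
not charged to the estimator.

What the generator deliberately does **not** emulate: base-quality error
models, PCR duplicates, splice isoform diversity, nested or chimeric
insertions, small-RNA libraries. Passing tests therefore demonstrate that
the analysis recovers planted truth under clean conditions; they do not
certify behaviour on the full messiness of real libraries.

## Numerical and algorithmic choices

**Alignment.** All comparisons use one affine-gap Gotoh core (match +1,
mismatch −1, a gap of length L costs 2 + (L−1)); identity is
matches/columns of the optimal path and coverage is the aligned span on
the shorter read. `pairwiseHits()` is exact full dynamic programming over
both orientations. The scalable clustering path proposes candidate pairs
from shared canonical 13-mers and aligns in a ±25 diagonal band around
the seed; two cheap, conservative rejections make it fast — a pair whose
seed diagonal caps the achievable overlap below the coverage rule is
dropped without DP, and a pair whose exact-match rate along the seed
diagonal is below 0.45 (random ≈ 0.25) is dropped before DP. Pairs
already in one connected component are skipped, which provably leaves
the components unchanged. At the 90 % identity boundary a shared 13-mer
is not strictly guaranteed by a pigeonhole argument, but at the
divergences the generator plants (≤ ~0.05 per copy, so ≥ ~90 % pairwise
identity with many clean 13-mer runs) the filter is lossless in
practice; the exact path remains available and is the oracle route in
tests.

**Cluster ids and determinism.** Components are ordered by descending
size, ties by first-seen read; one global seed drives every stochastic
stage, config hash and seed are stamped into each output table, and an
identical rerun is byte-identical.

**Consensus.** Greedy layout: the longest read seeds a contig; remaining
reads that pass the clustering thresholds against the current contig are
placed (reverse-complemented as needed) by their alignment offset, and a
per-column majority vote (ties resolved alphabetically) rebuilds the
contig, which may extend beyond the seed; passes repeat until no read
merges. With substitution-only read error this reconstructs an exact
template substring.

**Cluster statistics.** Pair scores are best-orientation identities of
local alignments spanning at least 55 % of the shorter read — the same
criterion that defines the cluster — with self-hits excluded and each
unordered pair scored once. The mode uses 1-point bins with left-edge
reporting and ties resolved upward; clusters above 2,000 reads are
subsampled (seeded) before scoring, a cluster-size cap whose effect on a
1-point-binned mode is negligible. GC is pooled over reads (not averaged
per read), N excluded from both numerator and denominator.

**LTR detection.** Direct-repeat candidates come from shared 13-mers at
a near-constant separation; runs are extended outward by exact match and
snapped to the canonical `TG…CA` boundary motif (the maximal direct
repeat can exceed the true LTR by a few chance-matching flank bases —
snapping restores exact boundaries, which exact TSD detection needs).
A tandem-array guard rejects candidates whose "LTR" continues tandemly
into the interior, which removes satellite arrays; rDNA-scale tandem
units fail the LTR-length bound. The TSD is the longest exact 4–6 bp
match between the immediate flanks (an exactness choice that keeps the
ground-truth oracle trivial); the PBS is a ≥12 bp match with ≤1 mismatch
to the reverse complement of a library tRNA 3' 18-mer within 30 bp
internal to the 5' LTR, searched in both element orientations; domains
are best ungapped six-frame peptide matches at ≥60 % identity, the
lineage call is the majority lineage of the passing domains, and the
expected domain order is attached as a consistency annotation, never
used as a filter. Elements lacking both LTRs are not reported — the
detector is anchored on the LTR pair — so the genome-wide census of
fragmentary elements is out of its reach by design.

**Quantification.** "Counts once" means unique best assignment per read,
with score ties resolved to the smaller target id; reads hitting several
contigs of one cluster count once for that cluster. Reads are capped at
151 bp, never padded. Per-element counting is union-style: reads
overlapping two or more elements are discarded as ambiguous rather than
fractionally split. The TP denominator excludes rRNA/organellar-mapped
reads; both the excluded count and the denominator are reported so either
convention can be audited.

**Models.** Base-10 logs throughout (a reported field, not a hidden
default); zero-TP rows are dropped only under a logged response;
p-values across the fit battery are reported unadjusted with a
Benjamini–Hochberg column alongside for transparency, never used for
gating. The compact letter display is derived from the Tukey-adjusted
p-matrix by insert-absorb at α = 0.05; lineages with a single cluster
are excluded from the test and listed separately.

## Study conditions and problem sizes

The canonical benchmark (`studyConditions()` / `runBenchmark()`) uses a
20 Mb nuclear background with ten planted families at Table-1-like
proportions (per-family GP 0.5–1.8 %, divergences 0.004–0.035, GC
0.37–0.55), 120 gene models with 30 % of LTR copies intronic, a
30 kb plastid-like contig at 40× copy weight, 50,000 skim read pairs and
200,000-read RNA libraries. Copy numbers are chosen so that each
family's *master coverage* (genome coverage × copy number) exceeds
~20×: below that, the read-overlap graph of a family fragments — the
same copy-number detection floor that genome-skim clustering exhibits on
real data (the method only sees families above roughly 100–200 copies).
The real study genome (0.78 Gb sampled at 0.4 %) is three orders of
magnitude larger; scaling the genome down while keeping the criterion
read counts preserves the per-family read depths that the estimators
actually see. The published headline numbers themselves (GPs of a real
genome, TPs of real libraries) are not reproducible from synthetic data;
what the package reproduces exactly is the *arithmetic* of the published
tables (class sums, totals, fractions, ratios) through its summarizers,
and the recovery of planted truth under the stated tolerances
(GP within 20 % relative at ≥0.5 % GP; TP within 15 % relative at
≥0.05 % TP; modal similarity within ±1 point; completeness exact on
noise-free copies).

A smaller demonstration configuration (`demoPipelineConfig()`: 2 Mb,
scaled copy numbers, 20,000 pairs) runs the full pipeline in a few
minutes and is what the README walks through.

## Known limitations

* Connected components stand in for the graph-community clustering of
  the reference pipeline; with well-separated synthetic families the
  partitions coincide, but on real data communities are finer.
* The 55 % span rule is applied to the shorter read — the permissive,
  deterministic reading of an ambiguous convention; it is recorded in
  the output metadata.
* The banded alignment paths (clustering, mapping, scoring) are exact
  only when the optimal alignment stays within the seeded band; at the
  generator's indel rates this is effectively always, and the exhaustive
  paths exist for verification.
* Structural annotation has no HMM domain models, no nested-element or
  chimera handling, and reports incomplete elements only when an LTR
  pair is found.
* Replicate libraries are pooled as points in the fits; no mixed-effects
  modelling.
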