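---
title: "Methods: profiling telomeric repeat variation from HiFi-like reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling telomeric repeat variation from HiFi-like reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Plant telomeres are arrays of the canonical 7-bp repeat 5'-TTTAGGG-3'
synthesized by telomerase. Proximal to the pure canonical tract, chromosome
ends carry *variant* repeats (single-edit relatives such as TTCAGGG or
TATAGGG) and, closer still to the centromere-proximal side, irregular
*degenerate* repeats — all in head-to-tail arrangement. Accurate long reads
(PacBio HiFi) are long enough to anchor a telomeric tract to a specific
chromosome end via its unique repeat-adjacent flank, which makes a
population-scale, per-end atlas of repeat variation possible.

`teloatlas` implements that workflow end to end on synthetic data with
known truth: a generator for chromosome-end structures and HiFi-like reads,
read anchoring and clipping, repeat-unit tokenization, an error model for
homopolymer artifacts, per-end consensus arrays and unit catalogs,
higher-order repeat (HOR) annotation, and repeat-compression haplotype
statistics with neighbor-joining (NJ) trees of the non-coding flanks.

# Unit definition and tokenization

A repeat *unit* begins at a T and ends with the last non-T base before the
next unit, and has the canonical-like shape (T)x(A)y(G)z. The tokenizer
turns this convention into a deterministic dynamic program over an oriented
tract:

* segment lengths are constrained to 2–17 bp;
* segment boundaries sit preferentially at non-T→T transitions (a boundary
  anywhere else carries a large penalty and is only used when the length
  bounds force it);
* a segment spanning more than one maximal G-run is penalized (two G-runs
  mean two (T)x(A)y(G)z shapes), but this penalty is smaller than the
  off-transition penalty, so a unit like TTGAGGG with no internal non-T→T
  transition stays whole;
* subject to those constraints the total edit distance of segments to
  TTTAGGG is minimized, with deterministic tie-breaks: more boundaries at
  G→T or A→T transitions, then fewer segments, then leftmost-longest;
* finally, any forced off-transition boundary is shifted left over trailing
  T's so that each unit begins at a T where one is available.

The structural constraints are essential: unconstrained minimum-edit
segmentation prefers to merge adjacent short units (the edit distance of a
merged 9-bp segment to the canonical unit can undercut the sum of its
parts), which contradicts the unit convention. With the constraints,
`tokenize("TGTTTAGGGTCTGATGGG")` yields `TG TTTAGGG TCTGA TGGG`;
`TATAGGG` tandems stay whole rather than splitting at their internal A→T;
the ambiguous `TTTAGGATTAGGG` resolves deterministically to
`TTTAGGA TTAGGG` (its only non-T→T transition); and a pure canonical array
of n units tokenizes to exactly n canonical units. Tokenization is lossless
by construction: the units concatenate back to the input.

Units are classified as *canonical* (exactly TTTAGGG), *variant* (edit
distance ≤ 2 and length 5–9 bp; both thresholds configurable — no numeric
boundary between variant and degenerate exists in the literature, so these
are explicit package choices), or *degenerate* (everything else).

# Locating the array start

The boundary between flank and degenerate repeats is intrinsically
ambiguous, so the array start is defined operationally as the first
instance of (T)x(M)(G)y(M), M ∈ {A, C}. The trailing M is context only:
the array starts at the leading T and the M base is not consumed. When a
tract contains no such instance at all — a pure canonical tract, as seen at
ends that carry no variant repeats — the first exact canonical unit is used
instead.

During anchoring, a read's exact-match block against its accession's flank
can end early when a sequencing error interrupts it. The clip point is
therefore computed from anchor coordinates (the unmatched flank residue is
skipped before applying the array-start rule), which keeps clipping exact
in the presence of errors.

# Read anchoring

Reads are first oriented to the 5'-TTTAGGG-3' convention: a read with more
CCCTAAA than TTTAGGG instances is reverse-complemented; ties stay as is.
Assignment uses exact k-mer seeding (k = 31) with ungapped extension
against each end's repeat-adjacent flank; a read is assigned when its
longest exact block reaches `min_anchor` (default: half the flank core,
mirroring the common practice of demanding most of the flank before
trusting an assignment), and flagged ambiguous when two flanks reach it.
Mutual consistency within an end is then checked on a read graph (edges at
≥ 99% identity over ≥ 200 bp of overlapping pre-array sequence); reads
outside the largest connected component are flagged as putative chimeras.
This replaces by a fixed rule what is usually done by visual inspection;
reads whose pre-array portions do not overlap are reported but never
flagged.

Two ends abut a shared rDNA-like array instead of a unique flank. Reads
matching that shared flank and carrying at least three consecutive
canonical repeats are clustered by greedy single linkage on pairwise flank
identity (join at ≥ 98%); the two largest clusters are reported as the two
putative rDNA-adjacent ends.

# Homopolymer error model

HiFi reads show 1-bp indels in T/G homopolymer runs, replacing TTTAGGG
with TTAGGG or TTTAGG, at a rate that grows as read quality (rq) falls.
For each read, the terminal canonical region is compared against ideal
sequences TTTAGGG^n: the search starts at n₀ = round(len/7) and
hill-climbs in steps of one repeat until no neighbour improves, with ties
resolved to the smaller n. Because the distance profile in n is only
empirically unimodal, the local optimum is probed two steps out on each
side and any disagreement triggers exhaustive minimisation — so the result
provably equals the exhaustive argmin. The minimized distance divided by
the observed length is the *relative distance*, an indel-density measure
that is correlated (Pearson, two-sided t-based p) against rq and the
subread count np.

The terminal canonical region itself is delimited across the reads of one
end: reads' unit sequences are star-aligned at unit level to the
median-length read, a non-canonical unit is *conserved* when it occupies
the same homologous column in at least half the reads (ceiling), and the
region distal to the most distal conserved non-canonical unit is treated
as canonical-with-artifacts and excluded from repeat-content analyses. The
majority quorum is a package decision; "conserved" has no quantitative
definition in the literature.

# Consensus arrays, catalog and saturation

Per accession and end, two reads whose degenerate+variant array length
equals the median (ties resolved to nearest-median) are drawn with a fixed
seed; their unit sequences are globally aligned at unit level (+1/−1/−1)
and non-conserved columns are masked as "N". The catalog counts distinct
units over all consensus arrays (N excluded) with relative frequencies,
singleton fraction and a top-20 list; the saturation curve accumulates
distinct units over accessions in input order (optionally averaged over
seeded permutations).

# Higher-order repeats

Five organization patterns are annotated on unit sequences: singleton
arrays, monomer homogenization (runs of ≥ 3 identical non-canonical
units), simple HORs (2–4-unit blocks), multi-monomer HORs (≥ 5-unit
blocks) and HORs with mutated copies. The detector scans every block size
k = 2..8 and phase, greedily extending tandem tilings that deviate from
the rolling position-wise majority consensus by at most one unit per copy.
Candidates whose consensus has a smaller internal period are discarded, as
are mutated tilings with fewer than two exact copies (a 2-copy tiling in
which one copy is "mutated" is indistinguishable from chance). The final
annotation set is chosen greedily — longest span, then fewest mutated
units, then smallest k, then leftmost — and therefore never overlaps and
is deterministic. Nested structures resolve to the larger span.

# Haplotype structure

To compare repeat arrays across accessions despite repeat-number
variation, arrays are *repeat-compressed*: maximal runs of identical units
collapse to one copy and the surviving units' bases are concatenated.
Pairwise similarity is the relative Levenshtein distance — edit distance
divided by the longer sequence's length in bp (base-level, matching the
"length of the longer sequence" normalisation; unit-level compression
followed by base-level distance). Distances are pooled into same-end
versus cross-end and same-group versus cross-group samples and compared
with a two-tailed variance-ratio F test (p = 2·min of the two tails,
capped at 1) and a Wilcoxon rank-sum test (exhaustive enumeration of group
assignments for pooled n ≤ 12, which stays valid under ties; otherwise the
tie-corrected normal approximation with continuity correction). Reported
p-values below ~1e-300 in this kind of analysis are floating-point floors,
not meaningful magnitudes.

Non-coding regions (between the most distal gene and the array start) are
compared with the same pairwise relative distance, alignment-free — a
stated simplification of MSA-derived distances, adequate for
substitution-dominated divergence. NJ trees (Saitou–Nei Q criterion, via
the standard `ape` implementation; labels sorted first so ties resolve by
label order) supply the leaf order for the merged per-end matrix: repeat
distances in the upper triangle, non-coding distances in the lower. The
association between the two distance structures is quantified by a
Mantel-style permutation test (Pearson correlation of off-diagonal
entries, seeded permutations) — an addition that turns a visual
correspondence into a number, and labelled as such in the output.

# The synthetic-data generator

The generator emulates, per accession × end: a unique anchor core
(default 2,000 bp, standing in for a 5-kb flank at desk scale; cores are
screened so no two share an exact block ≥ 200 bp), a distal gene at the
core's end, a non-coding region (0–1,200 bp), degenerate then variant unit
arrays, planted HORs (block sizes 1–8, 2–15 copies, per-copy mutation
probability 0.2), optional non-telomeric insertions (a 110-bp
organellar-like fragment on chr1p sourced from the emitted library; a
495-bp fragment shared between chr3q and chr5q and deliberately absent
from the library), and a per-molecule canonical tail (300–800 bp).
Accessions belong to genetic groups: variant arrays, degenerate arrays and
non-coding regions descend from per-end global ancestors through group
ancestors (substitution rate 0.15) to accessions (rate 0.05), so
within-group material is three times less diverged than between-group
material, and repeat and non-coding divergence are linked through the
shared ancestry. Two rDNA-like ends share a flank (each diverged 2% from a
common base, so the two flanks are ~4% apart — comfortably across the 98%
clustering threshold) and carry a variant array only with probability
12/148.

Reads are flank suffixes (55–100% of the core, so assignments are
unambiguous when error-free) plus the full array and tail, with
per-molecule somatic jitter of unit runs (rate 0.02). Errors are 1-bp
indels in runs of ≥ 2 identical T/G bases, one candidate event per run,
insertion and deletion equiprobable, at rate `error_rate_fn(rq)` (default
0.3·(1−rq)); rq is a deterministic strictly increasing function of the
subread count np plus small noise, so both error-likelihood covariates
exist. Every injected event is logged, and reads round-trip exactly to
their molecules by undoing the log. Reads are reverse-complemented with
probability 0.5. All randomness flows from explicit seeds; the same
configuration reproduces byte-identical outputs.

Two generator choices deserve emphasis. First, truth unit lists are
normalized through the package's own unit definition (tokenizing the
concatenated degenerate+variant bases from the detected array start):
adjacent short degenerate draws such as TG+TAG have no unique
decomposition, so "the planted units" are only well defined under the unit
convention itself. The tokenizer is validated independently against its
worked examples and the lossless/DP-cost properties, so this normalization
does not make the recovery tests circular at the read level — they still
exercise orientation, anchoring, clipping, boundary detection and
consensus. Second, each degenerate segment begins with a unit that matches
the array-start rule (TAGGA, TTAGGA or TCGA): the array start is *defined*
as the first rule match, so a truth array that began upstream of any match
would simply have a different start under its own definition.

What the generator does not emulate: real empirical np/rq distributions
(unpublished for the motivating data; the defaults are configurable
placeholders), true 45S rDNA sequence biology (rDNA flanks are merely long
shared sequences), chimeric molecules (planted only explicitly in tests),
real inter-end flank homology structure, and alignment reference biases.
Passing tests therefore demonstrate algorithmic correctness and
recoverability under the stated generative model, not performance on real
HiFi data.

# Problem sizes and numerical choices

The test-suite and acceptance computations use: 1,000 random pairs
(≤ 200 bp) for the edit-distance oracle; 200 random strings for the
hill-climbing/exhaustive equivalence; 1,000 simulated arrays for lossless
tokenization; 25 accessions × 8 ends × depth 10 error-free reads (200
ends, 2,000 reads) for parameter recovery; the full k = 2..8 × copies =
2..15 grid for HOR recovery plus 100 single-mutated-copy plants; 500 reads
for the error-model sign; 20 accessions in 2 groups for haplotype
structure; 50 random additive matrices (5–8 leaves) for NJ; and a
3-accession full pipeline run twice for byte-identical determinism. These
sizes keep the whole suite within a few minutes on one CPU while leaving
each property's expected failure modes observable.

Other numerical conventions: all coordinates are 0-based half-open in every
emitted table (declared in each file's header comment); distance matrices
are symmetric with zero diagonals and entries in [0, 1]; `N` mismatches
every base including `N` in edit distances; empty-versus-empty relative
distance is 0; F-test reciprocal symmetry (swapping samples inverts the
statistic, p unchanged) is preserved exactly.

# Known limitations

* The degenerate/variant boundary (edit distance ≤ 2, length 5–9) is a
  stated stand-in; no quantitative definition exists to match.
* Non-coding distances are alignment-free; long indel-rich divergence
  would be better served by an MSA.
* The rDNA read path assigns reads to two clusters but cannot name which
  physical end each cluster belongs to — the same limitation real data
  has without complete rDNA assemblies.
* HOR detection operates on unit tokens only; HORs that straddle
  tokenization ambiguities may be missed.
* A 2-copy HOR with one mutated copy is deliberately not reported.
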