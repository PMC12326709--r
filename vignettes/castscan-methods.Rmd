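---
title: "Methods: characterizing CAST integration products from sequencing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing CAST integration products from sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castscan)
```

## The measurement problem

CRISPR-associated transposases (CASTs) insert kilobase-scale DNA cargos at
an RNA-programmed genomic location. Characterizing what such a system
actually produced requires several read-level measurements:

* **Where** did the transposon land? Type I-F CAST integration occurs a
  nearly fixed distance downstream of the 3' end of the crRNA-complementary
  target sequence (about 49 bp for the system modeled here), so the signed
  distance between the target 3' end and the first transposon-joined
  genomic base is the key positional readout.
* **In which orientation?** The element can insert with its right end (RE)
  or left end (LE) proximal to the target; we write T-RL when the right end
  is target-proximal. Efficient Type I-F systems are strongly T-RL-biased.
* **How cleanly?** Cut-and-paste transposition duplicates a short
  target-site sequence (TSD; 5 bp here) on both sides of the insertion,
  repairs the staggered-cut gaps (occasionally introducing substitutions
  into the duplicated copy), and should produce neither indels at
  unintegrated alleles nor donor-backbone-containing cointegrates.
* **How specifically?** Genome-wide integration-site discovery with a
  unidirectional, UMI-tagged library (UDiTaS-style) measures how many
  independent integration events landed on-target versus elsewhere.

`castscan` implements all four readouts against a seeded synthetic-read
generator with a machine-readable truth manifest, so every analysis stage
is testable end to end without external data.

## Coordinate and orientation conventions

All coordinates are 0-based, half-open. The target site is the interval of
the crRNA-complementary sequence; its `three_prime_end` is `end` on the plus
strand and `start` on the minus strand. An integration event is recorded by
`tsd_start`, the coordinate (reference plus strand) of the first duplicated
base; the signed insertion offset is positive downstream of the target 3'
end *in target-strand orientation*. Internally every computation runs in a
canonical frame in which the target is plus-strand (minus-strand inputs are
reverse-complemented and coordinates mapped back), so strand-mirror
invariance of distances and orientation calls holds by construction rather
than by case analysis.

The token T-RL is used for insertions whose RIGHT end is target-proximal
(closest to the target 3' end); T-LR is the reverse-complement product. The
integrated element is modeled as `RE + cargo + LE` in the target-strand
direction for T-RL, and its reverse complement for T-LR. The orientation
token is widely used for Tn7-like systems but rarely defined base-for-base;
this package fixes the definition once and uses it consistently in the
generator and the classifier, which is what matters for recovery tests.

The reported junction position is always the first base of the
**target-distal** TSD copy. A target-proximal junction read (genomic flank,
TSD copy, then transposon end) therefore has its raw flank-end coordinate
shifted by the assumed duplication length to the canonical coordinate; a
distal-side read yields it directly. With this convention both junction
sides agree on one insertion coordinate, and the modal distance equals the
generator's offset. The alternative convention (distance to the first
non-duplicated base) would differ by exactly the TSD length; the choice is
declared here rather than inferred.

## The synthetic-data generator

`simulate_events()` draws integration events with:

| parameter | default | meaning |
|---|---|---|
| `offset_mode` | 49 bp | modal insertion offset (target 3' end to first duplicated base) |
| `offset_spread` | 1 bp | SD of an integer-rounded Gaussian around the mode |
| `p_trl` | 0.95 | probability of T-RL orientation |
| `tsd_len` | 5 bp | duplication length |
| `tsd_sub_rate` | 0.004 /base | substitution rate inside the duplicated copy |
| `offtarget_rate` | 0 (0.005 in the UDiTaS scenario) | fraction of untargeted background events |

The 49-bp mode and 5-bp TSD are the structural values of the modeled
system. The spread is not printed anywhere as a number; because integration
is described as occurring predominantly with single-base precision, a
discretized Gaussian with SD 1 bp is used and exposed as a parameter rather
than asserted as a system constant. The orientation bias (0.95) and the TSD
substitution rate (0.004/base, i.e. about 2% of 5-bp duplications carrying
at least one substitution, below the reported <3% read-level bound) are
likewise defaults chosen to be realistic for a strongly biased, high-fidelity
system. Untargeted background events are placed uniformly, excluding a 1-kb
zone around the target so truth labels are unambiguous, and each carries a
single UMI in the UDiTaS emitter, reflecting that observed off-targets
represent single integration events.

Three emitters build reads from events:

* `emit_amplicon_reads()` models a fixed-primer amplicon: each integrated
  read is the read-length prefix of the integration product starting at the
  forward primer, so it runs genomic flank, then the TSD copy, then into
  the proximal transposon end; `junction_side = "distal"`/`"both"` adds the
  reverse-primer read over the distal junction. Unintegrated reads are
  plain amplicon copies, optionally with one indel injected near the
  insertion site (per-read rate, length range, Gaussian position).
* `emit_uditas_reads()` models the unidirectional UMI library: `UMI +
  transposon-end anchor + genomic flank` read outward from the insertion
  point. Independent molecules get independent random UMIs.
* `emit_long_reads()` spans whole products: `flank-RE-cargo-LE-flank` for
  simple insertions; cointegrates additionally carry the donor backbone and
  a second right-end copy between cargo and downstream flank.

Gap-repair substitutions are placed in the TSD copy that junction reads
traverse (the copy adjacent to the transposon end in the emitted read), so
the substitution signal is measurable from the reads while flank mapping —
which tolerates up to two edits — still locates the site. Sequencing errors
are substitutions only and qualities are constant, which keeps indel truth
unambiguous; this is a deliberate simplification (below).

Determinism: every generator call takes a seed and restores the caller's
RNG state afterward; identical `(parameters, seed)` reproduce reads and
manifest byte-for-byte, which the suite verifies via file checksums.

## Junction calling

Anchors are the junction-abutting termini of the element: the first
`anchor_len` bases of the right end and the last `anchor_len` of the left
end, searched in both orientations. Matching is edit-bounded (Biostrings
pattern matching with mismatches and indels), ascending from exact matches
so the reported edit distance is minimal; the defaults `anchor_len = 20`,
`max_edit = 2` tolerate simulated error rates while keeping the chance of a
spurious 20-mer match within 2 edits negligible at desk scale. A read whose
best match ties between the two end identities is excluded as ambiguous and
counted.

The genomic flank preceding the anchor (its junction-proximal 60 bp) is
placed on the reference by the same ascending edit-bounded search on both
strands — exact placement first, escalating only for imperfect reads, with
per-flank memoization since reads from one junction share flank strings.
Flanks matching more than one locus equally well are excluded as
multimapped, never randomly assigned; flanks shorter than `min_flank`
(20 bp) are excluded as too short. Every input read lands in exactly one of
six categories (junction-called, unintegrated-candidate, ambiguous,
multimap, too-short, unmatched), and the counts must sum to the input size
— an invariant under test.

From a mapped flank the caller derives which junction side the read covers,
the canonical junction coordinate, the signed `distance_bp`, and the
orientation (proximal side: right end means T-RL; distal side: left end
means T-RL). `distance_profile()` bins distances at integer resolution and
reports the mode, ties broken toward the smaller distance.

`infer_tsd()` uses the raw adjacent-base coordinates: with `p_L` the last
genomic base before the element (proximal side) and `p_R` the first genomic
base after it (distal side), the duplication length is `p_L - p_R + 1`; 0
is a blunt join, and lengths below -1 are flagged as inconsistent. The
population mode takes modal coordinates per side. The per-event mode groups
all calls into insertion loci by single-linkage coordinate clustering
(gap > 20 bp) and takes the modal per-locus length; for a dense single
locus it degenerates, correctly, to the population estimate.

## Purity metrics

**Indels at unintegrated loci.** Each unintegrated read is globally aligned
to the amplicon (read-global, amplicon-local; match +1, mismatch -1, gap
open 4, gap extend 1 — free choices, exposed as configuration, with
leftmost gap placement on ties). A read is indel-positive when any gap
overlaps the half-open window `[center - w/2, center + w/2)` around the
predicted insertion site, with `w = 40` by default; deletions overlap as
intervals of removed reference bases, and an insertion is the point between
two reference bases. The half-open rule makes the boundary deterministic:
exactly 40 integer deletion offsets score in-window. The predicted center
is the modal junction distance applied to the target 3' end, falling back
to the configured offset when no junctions exist. Note that on repetitive
sequence a gap's placement (hence its window membership at the boundary) is
only defined up to alignment equivalence; the test fixtures use
repeat-free amplicons where placement is unique.

**TSD substitutions.** For each proximal-side junction call the read's TSD
bases (immediately before the anchor) are compared with the duplicated
reference bases; the rate is the fraction of evaluable reads with at least
one mismatch. Reads whose TSD is truncated are excluded and counted.
Sequencing errors inside the 5-bp window are not deconvolved from
repair-derived substitutions — the reported rate is raw, matching how such
values are usually reported.

**Integration fraction.** Junction-called over junction-called plus
unintegrated reads: a read-count proxy for integration efficiency (the
droplet-PCR efficiency assays themselves are out of scope). Excluded
categories are reported, never silently dropped.

**Long-read product classes.** A read is scanned (both strands) for the
end anchors, a central cargo anchor, and a central backbone anchor. Simple
insertion: each end exactly once and no backbone. Cointegrate: backbone
present, or three or more end copies. Neither end found: unclassified — a
label, not an error.

## Off-target discovery

`extract_umi()` takes the first `umi_len` bases as the UMI and requires the
transposon-end anchor to follow within `max_edit` edits; `map_flank()`
places the remaining flank uniquely on either strand (the reported position
is the insertion-adjacent base); `cluster_sites()` merges same-strand
positions within 5 bp by single linkage and deduplicates each cluster's
UMIs by single-linkage Hamming clustering at distance 1. Single-linkage
dedup (rather than directional-adjacency networks) is the simplest
defensible rule at desk scale, and is exposed as configuration. With
4^12 possible 12-mers, random UMI pairs within Hamming 1 are rare but not
impossible at ~10^3 molecules; recovery tests therefore compare fractions
rather than raw tallies when a merge could shift a count by one.

`label_and_scan()` marks clusters within 100 bp of the expected insertion
position as on-target (the tolerance generously covers the insertion-offset
spread) and scores each cluster's +/-50-bp flank by local alignment against
the target sequence, both strands. Because no published score cutoff exists
for "no detected homology", the homology threshold is calibrated
empirically as the 99th percentile of scores against 1000 base-shuffled
flanks under a fixed seed. `replicate_overlap()` matches sites across
replicates within 5 bp on the same strand (greedy one-to-one) and reports
shared counts and Jaccard indices, computed over off-target sites with
on-target matches tallied separately, since off-target reproducibility is
the scientific question. `on_target_fraction()` is the deduplicated-UMI
mass in on-target clusters over the total.

## Pipeline, configuration, and problem sizes

`run_pipeline()` drives simulate, junctions, purity, and offtarget from one
nested configuration (YAML-serializable, every parameter defaulted, seeds
mandatory — never wall-clock). The report bundle carries the metrics, the
read-accounting counts, and provenance (seed, configuration MD5 hash,
package version); metrics of skipped stages are absent, never zero.
`compare_conditions()` reports per-metric fold changes between two bundles,
with a zero denominator reported as an explicit "infinite" sentinel.

The default configuration analyzes a 100-kb, 41% GC reference (GC matching
the human genome average) with a 32-bp target, a 1-kb cargo flanked by
100-bp ends, and a 2-kb plasmid backbone. Recovery analyses in the test
suite and the acceptance script use 5,000 junction reads for the distance
mode, 500 paired-junction events for the duplication length, 500 long reads
for product purity, and ~1,000 UMI-tagged molecules for the on-target
fraction; these sizes give binomial standard errors comfortably below the
effect sizes being recovered while keeping a full run in the minutes range
on one core.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analyses assume —
junction geometry, orientation mixture, duplication and its repair errors,
UMI labeling, product classes — not the physics of a sequencer or the
biology of a genome. It has no base-quality model, no PCR
duplicates or chimeras, no tagmentation bias, no repeats beyond what a
random sequence contains, and no diploid variation. Recovery of the
generator's parameters therefore validates the analysis logic
(coordinate arithmetic, classification rules, accounting, thresholds), not
performance on real libraries: real data would add multimapping repeats,
quality-dependent errors, and coverage biases that this package's
edit-bounded, desk-scale matching does not attempt to model. Known further
limitations: no full read-aligner integration, no paired-end merging, no
quality trimming, no microhomology or translocation analysis, and
substitution/sequencing-error confounding in the TSD metric as noted above.
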