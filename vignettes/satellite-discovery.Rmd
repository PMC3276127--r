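---
title: "Discovering subtelomeric satellite repeats from low-coverage shotgun reads"
author: "SatelliteSeeker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering subtelomeric satellite repeats from low-coverage shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SatelliteSeeker)
```

## The problem and the model

Satellite DNA is organized as long tandem arrays of a short monomer and
resists assembly, yet at shotgun coverage well below 1× it is readily
*discoverable*: two reads drawn from the same satellite family almost
always overlap (every monomer copy is a potential overlap partner),
whereas two single-copy reads almost never do. `SatelliteSeeker` turns
that observation into a tested pipeline with three statistical cores.

**Similarity-graph clustering.** Reads are nodes; an edge joins two
reads whose best local alignment (either orientation) reaches 90 %
identity over at least 55 % of the longer read. Identity is defined as
matches over alignment columns with gap columns counted in the
denominator — the definition must be fixed for the cutoff to be
reproducible, and this is the most conservative common convention.
Clusters are the connected components; this is the minimal reading of
"clusters of mutually overlapping reads", and a `method = "community"`
switch is reserved in `clusterReads()` should finer partitioning ever be
needed. The fraction of dataset reads in a cluster estimates the genome
fraction of that repeat family. The estimate is read-count based, not
base-pair based, because satellite reads and background reads share the
same length distribution; a bp-weighted variant can be had by passing
base totals to `genomeProportion()`.

**Alignment-free monomer reconstruction.** All k-mer occurrences of the
cluster's reads *and their reverse complements* are counted (shotgun
reads are unstranded). The most frequent unused k-mer with frequency at
least `seedMinFreq` seeds a fragment that is extended greedily in both
directions: among the four k-mers overlapping the terminus by k−1 bases
the most frequent is taken, until its frequency falls below
`extensionThreshold` times the *current terminal* k-mer's frequency or
the k-mer is already in the fragment. The relative-to-current stop rule
makes the walk locally scale-free: a monomer whose copy number is 10×
another's is walked with the same stringency. For a tandem monomer the
k-mer graph is a cycle, so the walk returns to its start; circularity is
detected as an exact (k−1)-mer wrap, and the cycle length is the monomer
length. With k between 17 and 20 a chance wrap has probability ≈ 4^−16
per fragment and is negligible. A finished fragment also consumes the
k-mers of its mirror strand, otherwise every monomer would be
reconstructed twice, once per orientation.

Monomers are reported in **canonical rotation** — the lexicographic
minimum over all rotations of the monomer and of its reverse complement
(computed with Booth's least-rotation algorithm) — so phase and
orientation, which are not identifiable from shotgun data, never affect
comparisons. Published monomer coordinate systems use an arbitrary
rotation that cannot be recovered from sequence alone; all coordinates
printed by this package are 1-based on the canonical rotation and say
so.

**Greedy multimer collapse.** When monomer copies diverge, the walk can
run the cycle twice — master route on one lap, a variant branch on the
other — and close as an exact 2× multimer. `clusterConsensus()`
therefore checks every divisor p ≥ 10 of the recovered length: if
rotating the circular monomer by p matches ≥ 95 % of positions, the
monomer is collapsed to the per-phase majority over the L/p repeats.
This check runs on the reconstructed sequence only and cannot confuse
genuinely different monomer families (unrelated sequence matches a
rotation at ~25 %).

## Junction segmentation

Clones spanning array boundaries are tiled with segments from telomere
run detection (unit TTTAGGG, ≥ 2 tandem copies, ≤ 1 mismatch per copy)
and local alignment against a 3-copy linearization of each circular
monomer reference. Pure best-local-alignment tiling has a failure mode
on mixed junctions: an alignment happily *bridges* a short foreign
fragment whenever the flanking match gain exceeds the gap/mismatch
cost, swallowing an alternating block. Candidate segments are therefore
confined to intervals anchored by exact 12-mer matches to the reference
(a foreign block of ≥ 12 bp cannot be bridged), their boundaries are
then refined by exact-match extension that absorbs an isolated
substitution only when the following 4 bases match, and any residual
internal gap is absorbed into a flanking segment only when the gap
bases continue that segment's repeat at ≥ 60 % ungapped identity at the
best split point — a 30-bp random insert sits at ~25–35 % and stays
unlabelled. Verdicts: an internal unlabelled gap ≥ 10 bp ⇒
`insert_containing`; ≥ 3 alternating repeat blocks ⇒ `mixed`; two
abutting blocks ⇒ `direct`; one block ⇒ `single_repeat`; < 50 % of the
clone labelled ⇒ `unresolved`. Segment boundaries carry an intrinsic
±5 bp wobble (boundary bases shared by both repeats can be claimed by
either side), which is why gaps below 10 bp are treated as slack rather
than inserts.

## Fiber-FISH calibration

Stretched-fiber measurements in μm convert to DNA lengths at a default
3.0 kb/μm. The factor is configurable; 3.0 sits inside the 2.9–3.3
kb/μm range in common use and is the value consistent with a 322 μm
signal reading 966 kb. One derived quantity is knowingly inconsistent
in the source material: a 1031 μm fiber converts to 3093 kb, which is
0.368 % of an 840 Mb genome and rounds half-up to 0.4 %, while the
figure printed alongside it is 0.3 %; the package reports the computed
arithmetic and leaves the discrepancy documented here rather than
resolved. Size categories come from sorting the lengths and splitting
at the n−1 largest adjacent gaps — deterministic, order-free, and exact
on well-separated data (a centroid-based alternative was considered and
rejected for its initialization dependence). The "±" on category means
is the standard error, sd/√n, which matches the magnitudes usually
printed with such categories; with n = 1 the SE is reported as 0.

## The synthetic generator and what passing tests mean

`SimConfig`/`buildArray`/`simulateReads` emulate the statistical
structure the analysis relies on, under a **star phylogeny**: every
copy is mutated independently from the master monomer, optionally
within subfamilies that each derive their own master. Defaults are the
study conditions: mean read length 361 bp, coverage 0.53×, telomere
unit TTTAGGG, monomer classes 182 bp and 339 bp. Values the source
material does not state were fixed once at realistic levels and are
configurable: read-length sd 60 bp (454-like dispersion, truncated at
50 bp), per-base substitution error 0.5 % in benchmarks, per-copy
divergence 2 % (within the homogenized-satellite range), telomere run
30 units, junction fragments 40–120 bp. Read count is Poisson at
coverage × genome / mean length; strands are uniform; every read, copy,
and junction segment carries 0-based half-open truth coordinates.

The generator deliberately does *not* model 454 homopolymer indel
errors, quality-score realism, paired ends, higher-order repeat
structure, or interspersed-repeat background. Passing the synthetic
benchmarks therefore shows the pipeline recovers planted structure
under idealized substitution-only noise at the stated scales — it does
not certify performance on real flowgram data, where homopolymer
indels would perturb k-mer walks and lower alignment identities.

## Problem sizes and numerical choices

The packaged benchmarks run at desk scale, chosen so the full suite
completes in minutes while keeping each estimate's sampling error well
inside its acceptance margin: monomer-length recovery uses 110-copy
arrays in ~80–100 kb genomes over 20 seeded replicates per monomer
class; junction classification uses 100 clones per style; oracle
equivalence instances use ≤ 60 reads (hand-written Smith–Waterman in
the test suite is quadratic in R) and ≤ 200-node graphs. All
randomness flows through explicit integer seeds; generators save and
restore the caller's RNG state. Alignment scoring is +1 match, −2
mismatch, linear gap 2 per column throughout, so the clustering
breakeven identity (~66 %) sits safely below the 90 % cutoff; ties
between orientations resolve to the forward strand, equal-size clusters
order by their lexicographically smallest read id, and k-mer frequency
ties break lexicographically, making every stage byte-reproducible.

## Known limitations

- Cluster membership requires 55 % coverage of the longer read, so
  reads straddling an array edge with roughly half their length in
  background sequence may stay unclustered; truth-based evaluation
  counts reads fully inside an array.
- The k-mer prefilter skips read pairs sharing no exact 12-mer; a pair
  at exactly 90 % identity with pathologically evenly spaced mismatches
  (one per ≤ 11 bp, everywhere) could be missed. Such pairs do not
  arise under the generator's noise models; `prefilter = FALSE` gives
  the exhaustive scan.
- Monomers shorter than ~k are not representable by the k-mer walk, and
  arrays whose within-family divergence approaches the read error rate
  of the data can fragment into multiple clusters.
- `positionalLogo()` errors if any monomer position is uncovered rather
  than guessing; at the benchmark coverages this does not occur, but
  very small clusters may need deeper read sets.
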