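---
title: "From Hi-C read pairs to 3D chromatin models: the methods behind tadmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Hi-C read pairs to 3D chromatin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadmod)
```

`tadmod` covers the full Hi-C analysis chain: restriction-fragment maps
and FASTQ quality control, artifact filtering of mapped read pairs,
contact-matrix construction and balancing, TAD segmentation, border
alignment across experiments, restraint-based 3D modelling of genomic
regions, and structural analysis of the resulting model ensembles. This
vignette explains the models and procedures each stage implements, the
parameters that matter, the numerical choices we made where a published
description left the details open, and what the synthetic-data tests do
and do not establish about real data.

## Coordinates and conventions

All genomic positions are 0-based, half-open, everywhere: cut sites are
the 0-based position of the scission, fragments are `[start, end)` tiles,
BED output needs no conversion. Bins and fragments are 1-based *indices*
(R convention). A single convention eliminates off-by-one drift between
the stages.

## Fragment maps and FASTQ statistics

In-silico digestion records one cut per motif occurrence at
`occurrence start + cut offset` (HindIII: `AAGCTT`, offset 1).
Palindromic motifs are searched on the forward strand only — the reverse
strand carries the same sites; non-palindromic motifs are additionally
searched as their reverse complement with cuts mapped back to forward
coordinates. Ambiguity codes are rejected rather than expanded: every
enzyme this toolkit targets has an exact motif. Chromosome ends act as
fragment boundaries; terminal fragments are ordinary tiles.

The Hi-C-aware FASTQ statistics rest on one observation: a *ligated*
molecule carries the re-ligation junction, not the intact motif. After
fill-in, the junction of an enzyme with motif length `L` and cut offset
`o` reads `motif[1..L-o] + motif[o+1..L]` (HindIII: `AAGCTAGCTT`, length
10). A read is counted digested when it contains no complete motif; a
strict dangling end starts with the post-cut remainder (`AGCTT`). The
default spot-check examines the first million reads; PHRED offset
defaults to 33.

## The ten pair filters

Pairs are canonicalized (both ends in genome order) so that "inward"
always means strands `(+,-)` and "outward" `(-,+)`, independent of which
mate was read 1. Same-fragment geometry is classified definitionally:
inward = dangling end (unligated molecule), outward = self-circle
(fragment circularized on itself), same strand = error. Different-fragment
pairs can be flagged as extra dangling ends (inward, closer than the
maximum sequenced-molecule length — they behave like undigested
molecules), too close to a cut site, on a too-short/too-long or
over-represented fragment, duplicated, or as random breaks (the distances
from each 5' end to its ligation-side cut sum to more than a sequenceable
molecule). One deliberate restriction: the random-break (molecule-size)
test applies only to different-fragment pairs, because the size of a
"molecule" is only defined for a ligation product, and same-fragment
geometries already have their own three classes. Without this restriction
no pair geometry could satisfy exactly one definition, and exact
reconciliation against planted truth would be impossible.

Thresholds (500 bp maximum molecule length, 5 bp minimum distance to a
cut site, 50 bp / 100 kb fragment-size window, 0.5% over-representation
quantile) are protocol parameters, not constants; all are exposed. The
over-representation rule is a *strict* quantile: fragments exactly at the
threshold survive, so a flat count distribution blacklists nothing.
Reports use union accounting — each filter counts every pair it flags, so
percentages may sum above 100, while "valid" counts pairs with no flag at
all.

## Column masking and truncated ICE

Bins that attract almost no reads (unmappable or repeat-rich regions)
corrupt balancing. Masking proceeds in two steps: zero-sum columns always
go; then a degree-6 polynomial is fitted to the log-density of the
non-zero column sums on a 100-bin histogram, and the exclusion threshold
is the first local minimum of the fitted curve left of its global
maximum — the valley after the first mode of a bimodal sum distribution.
A candidate valley must additionally lie at least `log 2` below both the
preceding local maximum and the global maximum. Without this prominence
requirement, polynomial wiggle on perfectly unimodal histograms
manufactures shallow valleys and masks good bins; a factor of 2 in
density is the weakest separation we would call a distinct mode. On
unimodal inputs the threshold is therefore 0 and only zero columns are
masked. Degree and bin count are configurable.

ICE balancing then assigns each unmasked bin a multiplicative bias,
updated once per iteration by the bin's relative row sum (biases
recentred to geometric mean 1 for identifiability), and — the deliberate
twist — *stops early*: iteration ends when the maximum relative deviation
of row sums from their mean is at most 10% (configurable `maxDev`). A
fully balanced matrix is a flat matrix in the limit; stopping at 10%
removes local biases while leaving large-scale structure measurable. The
balanced matrix is rescaled to the raw total so counts keep their scale.
With `maxDev` near zero the procedure converges to the unique symmetric
Sinkhorn scaling, which the tests verify against an independent
fixed-point oracle to 1e-6.

## Comparing matrices

Two normalized matrices are compared (i) by Spearman rank correlation of
the entries at each genomic distance, pooling chromosomes, with masks
unioned and distances with fewer than three usable pairs reported missing
rather than zero; and (ii) by the Pearson correlation of their leading
eigenvectors. Eigenvector signs are arbitrary, so each vector is oriented
to make its largest-magnitude entry positive and correlations are
reported as absolute values. We decompose the normalized matrix directly;
a correlation-transformed variant was considered and left out — worth
noting that for a strictly positive matrix the leading (Perron)
eigenvector is dominated by the near-constant coverage component, so
compartment signatures typically appear in the later eigenvectors unless
the expected background is removed first.

## TAD segmentation

A chromosome is tiled by `m` TADs. The background model is the
distance-decay expectation `e_ij`: the mean unmasked count at each
distance, refit for every input matrix. Within a candidate TAD `[i..j]`,
counts are Poisson with a segment-specific intensity `w` relative to that
expectation; the maximum-likelihood estimate over the intra-TAD triangle
is `w = S_o / S_e` (observed over expected sums), and the segment score is
the log-likelihood *ratio* against the background,
`S_o log w - (w - 1) S_e`. Scoring the improvement over background rather
than the absolute likelihood is essential: absolute intra-triangle
likelihoods grow with the number of covered cells, so coarser
segmentations would win simply by covering more of the matrix.

A dynamic program over (last border, number of TADs) yields the exact
optimum for every `m`; the reported segmentation maximizes
`L(m) - (2m - 1)/2 · log T` (BIC with one intensity per TAD plus one per
internal border; `T` = usable upper-triangle cells; multiplier
configurable). Two refinements shape the final algorithm:

* **Background refit.** The pooled decay estimate is contaminated by
  intra-TAD enrichment — at short distances nearly every cell is
  intra-TAD, flattening the contrast to near 1. After a first pass, the
  decay is re-estimated from cross-TAD cells only (distances with fewer
  than 5 cross cells keep the pooled value) and the program re-run, up to
  `refinePasses` times or until the borders stabilize. On simulated
  chromosomes this step roughly doubles border recovery.
* **Enrichment-only scoring in refined passes.** The likelihood ratio
  also rewards `w < 1`, so once the background is clean, depleted
  cross-TAD pockets could be harvested as spurious micro-domains, which
  destroys border persistence across constrained `m`. Refined passes
  therefore score only enrichment (`w >= 1`; a one-sided test). The first
  pass stays two-sided because against the contaminated background the
  depletion signal is most of what is visible.

Scale invariance: BIC compares a scale-dependent likelihood against a
fixed penalty, so the raw procedure would segment a matrix and twice that
matrix differently. Since the scale of a normalized matrix is arbitrary,
the input is canonically rescaled to a reference mean unmasked count of
10 — a typical per-cell coverage at 10 kb resolution — making the result
depend on relative enrichment only. Both the rescale and the reference
are exposed (`rescale`, `referenceMean`).

Border robustness counts, for each border of the optimum with `m*` TADs,
in how many of the constrained-optimal segmentations with
`m*, m*+1, ..., m*+9` domains (clipped to feasible `m`) the border
persists at the same bin — 10 means the border survives every refinement.
Segments may span masked bins (masked cells are excluded from all sums),
but a border may not sit inside a run of 5 or more consecutive masked
bins. Defaults bound TADs between 2 bins and 300 bins (20 kb and 3 Mb at
10 kb). A target `m` can be forced (`forceM`) to compare against an
external border count.

The DP is verified against exhaustive enumeration of all border sets for
`n <= 12`, and against planted-block simulations: on 100-bin chromosomes
with five TADs at 3x enrichment under Poisson noise, at least 90% of
borders are recovered within one bin (in practice, essentially all).

## Border alignment

Border lists are compared in bp, so mixed resolutions align. The global
(Needleman–Wunsch) alignment maximizes the summed match scores
`max(0, 1 - |a - b| / maxDist)` minus a gap penalty (default 0.2; the
score reaches zero at `maxDist`, default 100 kb); reciprocal-closest
matching accepts `(a, b)` only when each is the other's nearest neighbour
within `maxDist`, ties broken leftmost. Agreement is the percentage of
*reference* borders with a partner within a tolerance — deliberately
asymmetric, since list sizes differ. More than two experiments are
aligned progressively against a growing consensus (largest list first,
matched consensus positions updated to running means). One caveat
documented in the tests: reciprocal matches are contained in the
zero-gap NW matches only when borders are well separated (at most one
counterpart within `maxDist`); with crowded lists the global optimum can
prefer two moderate matches over one mutual-nearest pair. TAD border
lists at 10 kb resolution live in the well-separated regime.

## Restraint-based 3D modelling

The region is a homopolymer chain: one sphere per bin, constant size —
particle occupancy follows 0.01 nm/bp (the canonical 30 nm fibre), so a
10 kb particle has diameter 100 nm. Allowing per-particle sizes would
explode the parameter count, and using chromatin-state information to set
sizes would contaminate the later state-vs-structure analysis.

Contact frequencies become z-scores of `log10` counts over unmasked,
non-zero, off-diagonal entries (zeros are "no data", not evidence of
distance). Restraints:

* consecutive particles: harmonic at the sum of their radii (`2r`);
* `z >= upfreq`: harmonic at `d(z)`, the linear *decreasing* map of the
  observed z-range onto `[2r, maxdist]` (the strongest contact sits at
  particle contact; the boundary `z = upfreq` is attractive);
* `z <= lowfreq`: harmonic lower bound at the proximal distance (default
  `maxdist`, separately settable) — penalised only when closer;
* all remaining pairs: soft excluded-volume lower bound at `2r` with a
  tenth of the base force constant.

Force constants are `k = 0.05` per nm² for bonds and `k |z|` for
z-derived restraints — stiffer where the evidence is stronger. The
objective is the sum of (one-sided where applicable) harmonic penalties;
its gradient is closed-form. Optimization runs in compiled code: a seeded
random start uniform in a sphere of radius `n^{1/3} · 2r`, 500 sweeps of
single-particle Metropolis moves under a geometric temperature schedule
(10 to 0.01), then a deterministic L-BFGS-B polish. Every model is a pure
function of its seed; ensembles (`nCompute` computed, best `nKeep` kept
by objective; production default 2500/2000) are bit-reproducible.

The three free parameters — `lowfreq`, `upfreq`, `maxdist` — are chosen
by grid search: a small ensemble per grid point, scored by the Spearman
correlation between the ensemble contact map (fraction of models with
particles within `dcutoff`, default `2·maxdist/3`) and the input matrix.
Note that reflections do not change distances, so mirror-image minima are
equivalent for contact-map recovery; the optimizer does not need to break
that symmetry and the clustering stage exposes it instead.

## Structural analysis

Superposition is Kabsch via SVD with the determinant correction, so only
*proper* rotations are allowed: a chiral conformation and its mirror
image retain a positive RMSD. Model-model similarity blends, half and
half, the fraction of particle pairs whose contact state at `dcutoff`
agrees and `1 - RMSD/maxRMSD`; clustering is our own Markov Cluster
implementation (expansion, inflation 2, self-loops kept, deterministic),
with one practical preprocessing step: off-diagonal similarities are
stretched linearly onto `[0, 1]` before clustering, because any two
conformations of the same chain share most contact states and flow-based
clustering needs the contrast. On a block-diagonal similarity matrix the
algorithm provably returns the connected components, which the tests
assert; mirror-image ensembles split into (at least) two clusters.
Cluster 1 is the most populated; each cluster is represented by its
medoid, and per-particle ensemble profiles average over cluster 1 by
default (flag for the whole ensemble).

The four per-particle measures:

* **accessibility** — `nMesh` points on a deterministic Fibonacci spiral
  at radius `r + probe` around the particle; a point is accessible when no
  other particle centre is within `r + probe` of it (defaults: 75 nm
  probe, 100 points). The mesh is fixed in the global frame, so the
  estimate is rigid-invariant only up to mesh resolution.
* **density** — genomic span of the `±w` chain window (bp, ends clipped)
  over the summed consecutive 3D distances (nm); a straight 10 kb/100 nm
  chain gives exactly 100 bp/nm.
* **interactions** — particles within 250 nm (ensemble-averaged).
* **angle** — at each interior particle, the angle between the vectors to
  its chain neighbours, in [0, 180]°.

Chromatin colors (the five-state fly classification: black, blue, green,
yellow, red) are assigned per particle when at least 50% of its bin is
covered by one color — exactly 50% qualifies; a 50/50 tie between two
colors goes to the first in canonical order — otherwise the particle is
"white". Per-color differences in the four measures are tested with
Tukey's HSD on particle-level values; colors with fewer than three
particles are excluded from testing.

## Synthetic data: what it emulates, and what it does not

Every upstream input has a deterministic generator. `simulatePairs`
constructs pair geometries that each satisfy exactly one artifact
definition — the valid pairs spread over fragment pools with
Latin-square indexing so no fragment becomes accidentally
over-represented — making filter reconciliation exact, not approximate.
`simulateMatrix` draws symmetric Poisson counts around
`depth · d^(-α) · f` with `f = intraFactor` inside planted TADs (the
diagonal is treated as distance 1); the defaults `depth = 100` at 10 kb
and a decay exponent of 1 are typical of a well-sequenced fly Hi-C map,
and 3x intra-TAD enrichment is a mid-strength domain. `toyStructure`
provides closed-form chains (straight, helix, seeded random walk);
`structureToMatrix` induces Poisson counts through a logistic contact
probability of width `noise · dcutoff` (hard threshold at `noise = 0`).

These generators define the study conditions the tests and the
acceptance script run at; sizes were chosen so the whole suite runs on a
laptop: chromosomes of 100 bins and 25-100 replicate seeds for
segmentation, 20×20 matrices for balancing oracles, 50-particle chains
and 50-model ensembles on a reduced parameter grid for model recovery.
What passing them shows: the algorithms are exact where exactness is
claimed (DP optimality, Sinkhorn limit, superposition) and recover
planted truth under calibrated noise. What they do not show: robustness
to everything real Hi-C adds — GC and mappability bias, translocations,
copy-number variation, library complexity — none of which the generators
emulate. Real-data behaviour must be judged on real data.

## Degenerate inputs and tie rules, collected

Zero-variance z-scores are defined as 0 with a warning; segments without
usable signal score 0; an all-zero matrix refuses to mask; ICE refuses
unmasked zero-sum columns; `locateFragment` rejects out-of-range
positions; coincident chain neighbours yield missing angles with a
warning; intensity ratio exactly 1 flags a TAD as "higher" (the `>=`
rule); `z = upfreq` exactly is attractive; a reciprocal-closest tie goes
to the leftmost candidate; duplicate detection keeps the first pair in
canonical sort order.
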