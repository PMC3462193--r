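---
title: "Quantifying the coupling between chromosome territory organization and transcription"
author: "ctcoupler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the coupling between chromosome territory organization and transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Interphase chromosomes occupy discrete territories whose radial and
relative positions are non-random and cell-type specific.  `ctcoupler`
implements a quantitative framework for asking whether that spatial
arrangement is coupled to transcriptional output: distance-matrix
statistics with a permutation null, an energy function linking chromosome
adjacency to transcription-factor-network (TFN) activity, and an image
pipeline that measures territory interface distances in two-channel
chromosome-paint confocal stacks.  A synthetic-data module generates every
input with known ground truth, so the full pipeline is testable without
microscopes or microarrays.

## The distance matrices

Three chromosome-by-chromosome matrices are compared.

* **IPD** (inter-chromosome physical distance).  For each nucleus and pair
  of autosomes, the four distances between the two homologues of each
  chromosome are reduced to their mean (`mode = "mean"`) or minimum
  (`mode = "min"`); per-nucleus values are then averaged over all nuclei
  contributing both chromosomes.  Coordinates are in units of the nuclear
  radius.  Diagonal entries hold the mean homologue-homologue distance;
  they are stored for inspection but flagged excluded, and every
  correlation routine works on the off-diagonal upper triangle only.
* **IAD** (inter-chromosome activity distance).  Probe intensities are
  normalized to the mean of each array, averaged over replicates and then
  over a gene's probes, summed per chromosome and divided by the
  *annotated* gene number N (not the observed count and not chromosome
  length), giving the mean chromosome activity `A_chr`.  Then
  `IAD[i, j] = |ln A_i − ln A_j|` — an exact one-dimensional embedding
  metric, invariant to global intensity rescaling.
* **IBD** (basepair-length difference), `|Chrbp_i − Chrbp_j|`, the size
  control.

Two gene-selection refinements are provided: per-chromosome
high-expresser filtering (keep genes above 40% of the chromosome's mean
observed-gene activity, roughly the top quarter of a log-normal expression
distribution), and cell-type differential selection by the full width at
half maximum (FWHM) of the per-gene expression-difference histogram.  For
the FWHM we use Freedman–Diaconis bins, measure the width of the
contiguous half-height run containing the modal bin, and centre the
selection at the modal bin midpoint (`center = "zero"` is available; the
modal centre is the more robust default when array normalization shifts
the bulk of differences off zero).  The same selected gene set feeds both
matrices of a cell-type pair, so per-chromosome selected counts match by
construction.

## Permutation null and FDR

The significance of a matrix correlation `PCC_0` is assessed against the
null of scrambled chromosome identities: one matrix is conjugated by a
random label permutation (rows and columns permuted together, preserving
the off-diagonal entry multiset and, for metric inputs, the triangle
inequality), correlated with the other, and the FDR is the fraction of
permutations with `PCC > PCC_0`.  The inequality is strict: ties — which
arise exactly when the matrix has symmetric labels — count as
non-discoveries.  Null draws are uniform over the full symmetric group,
identity included.  For up to eight labels an exhaustive enumeration mode
replaces sampling.

The historical randomization device — a cumulative chain of random
row/column transpositions — is kept for trajectory analyses
(`permute_matrix()`, `randomization_decay()`).  One subtlety is worth
recording: a chain of exactly `s` transpositions realises only
permutations of parity `(−1)^s`, so a fixed-length chain reaches only half
of the symmetric group.  The package's unit tests verify chi-square
uniformity over all of `S_4` using chains of mixed parity and assert the
parity constraint itself.  For every statistic computed here the effect is
negligible — trajectories mix parities across steps, and the FDR engine
uses uniform permutations rather than chains — but the property explains
why `random_conjugation()` rather than a literal 200-swap chain backs the
null ensembles.

## The network-coupling energy H

Chromosome proximity is encoded by an exponential adjacency,
`A[i, j] = exp(−IPD[i, j] / λ)` with length scale `λ` as a fraction of the
nuclear radius (default 0.07).  Network activity is the chromosomes ×
networks matrix `Φ`, where `Φ[i, f]` is the natural log of the summed
activity of network `f`'s genes on chromosome `i`, and exactly zero where
the network has no genes there.  The energy is

```
H = Σ_f Σ_{i<j} A[i, j] (Φ[i, f] − Φ[j, f])²
```

summed over unordered pairs (ordered summation would double `H` but leave
every derived statistic unchanged).  `H` is non-negative, zero iff every
network column is constant, invariant to per-network additive shifts and
to simultaneous relabelling of adjacency and `Φ`, and strictly increasing
in any single informative adjacency weight — all asserted exactly in the
test suite against a literal triple-loop oracle.

Optimality is probed by randomizing the adjacency matrix (cumulative swap
chain, `H` recorded at each of 10⁴ steps by default; an independent mode
re-randomizes 100 swaps from the original per draw) and summarising the
recorded values as `ΔH = (H_av − H_0)/σ`.  The corresponding p-value is
the two-sided Gaussian tail `2(1 − pnorm(ΔH))`; this mapping reproduces
the conventional deviate/p pairs (1.97 → 0.049, 1.02 → 0.308,
0.71 → 0.478, 0.92 → 0.358) and is reported alongside the empirical
fraction of randomized `H` values at or below `H_0`.  With a degenerate
constant `Φ`, `σ = 0` and the deviate is reported as `NA` rather than
invented.  Because diagonal adjacency terms multiply a zero squared
difference, the "exclude homologues" variant (diagonal zeroing) is exact
bookkeeping and provably leaves every trajectory unchanged.

`scan_lambda()` sweeps λ over 2–80% of the nuclear radius (1% steps by
default) and reports the deviate per λ and its argmax; ties break to the
first maximum.  `per_network_sensitivity()` runs the randomization per
network column (200 steps, the window in which most of the H rise occurs)
and reports `ΔH_f / H_0f` together with its correlation against network
size; networks with `H_0f = 0` are flagged `NA`.

### The Φ scale convention

`Φ` is built from array-mean-normalized activities throughout the
package.  This choice matters more than it may look: the "assign zero
where a network has no genes" convention makes `H` sensitive to the
overall intensity scale, because a chromosome carrying network genes
contributes `Φ ≈ ln(scale × Σ normalized activity)` against literal
zeros.  On a raw intensity scale the constant `ln(scale)` dominates the
in/out contrast and the zero *pattern* (which chromosomes carry the
network) carries most of the energy; at normalized scale the activity
*values* dominate.  We adopt the normalized convention because it keeps
one gene-activity table for the whole pipeline and makes the λ-scan and
the matched-versus-mismatched ΔH contrast sharp; the consequence — the
per-network size law is muted relative to what an integrated-raw-intensity
convention yields — is a documented limitation (below).

## The confocal interface pipeline

Each channel of a two-channel paint stack is binarized at a single global
threshold, mean + SD of the whole z-stack (a per-slice variant exists
behind `mode = "per_slice"`); the two largest 26-connected 3D components
are taken as the homologues (smaller components are debris, dropped below
`min_size` voxels); per-slice 2D edge voxels (foreground with a 4-adjacent
in-plane background neighbour) are extracted and scaled by the anisotropic
voxel spacing; and the interface distance of a pairing is the exact
all-pairs minimum Euclidean distance between the two edge sets, evaluated
in blocks.  Four pairings arise per chromosome pair; both their mean and
their minimum are reported.  The mean is the default per-pair summary;
the minimum is the natural choice when centroid or size bias is the
concern, and since the two conventions are genuinely in tension in the
source literature we always compute both and leave the choice explicit.

Discretization accuracy, verified on phantoms: cuboid face gaps are
recovered to within one voxel diagonal; with per-slice 2D edges a sphere's
polar cap centre is not an edge voxel (it has no in-plane background
neighbour), so near-vertical gaps can overshoot the analytic value by up
to the cap disc radius `sqrt(2 r dz)`.  Distances can undershoot by at
most one voxel diagonal (edge voxel centres lie inside the true surface).
Overlapping or touching territories return the in-plane voxel pitch, never
a negative value.

## The synthetic-data generator

The generator is first-class code: it defines the conditions under which
every downstream claim is tested.

**Nuclei.**  Each of 22 autosomes receives a ground-truth log activity
`~ N(0, activity_sd²)`.  Chromosomes sorted by activity form consecutive
*co-regulation neighbourhoods* of `cluster_size = 4`; each neighbourhood
sits at a random point in the nucleus, its members laid out along a random
direction with steps proportional to their log-activity gaps and mean
step `coupling_length = 0.07` nuclear radii.  These coupled positions are
blended with uniform ball positions with weight `coupling_beta`, and each
of the 54 nuclei jitters both homologues independently (isotropic SD
`position_jitter = 0.10`).  The essential design property is a *finite
coupling range*: within a neighbourhood, distance grows with activity
difference at the 0.07 scale; between neighbourhoods, position carries no
activity information.  A single global activity gradient was considered
and rejected: it makes the coupling infinite-range, so the λ-scan deviate
grows monotonically with λ (no interior optimum exists to recover) and
the per-network sensitivity inverts.  An interior adjacency optimum of
the kind seen in real nuclei is itself evidence that positional coupling
is short-ranged, and the generator encodes exactly that.

**Expression.**  Probe intensities are multiplicative log-normal around
the chromosome activity, with independent gene-level and probe-level
layers both governed by `noise_sd = 0.3` and each mean-corrected by
`−σ²/2` so that linear-scale expectations equal the target activity and
log-activity recovery is unbiased (verified by a 50-replicate Monte-Carlo
test).  Defaults: 3 probes per gene, duplicate arrays, a native intensity
scale of 500 units (removed by array-mean normalization), and a
heterogeneous per-chromosome gene-count profile (log-normal around 120,
ln-SD 0.5) reflecting the several-fold gene-density differences between
real chromosomes.  `activity_sd = 0.4` keeps chromosome-mean expression
within the few-fold range seen in chromosome-level averages; the IPD–IAD
correlation is exactly invariant to this scale, which only sets the
relative weight of activity versus gene-count variation inside `Φ`.

**Networks.**  87 networks with log-uniform sizes in 5–300 genes.  Each
network's chromosome occupancy follows the saturating law
`1 − exp(−size/s0)` with `s0` calibrated so the mean realized occupancy
matches `occupancy_target = 0.6`; small networks therefore concentrate on
few chromosomes and occupancy rises monotonically with size.  When the
ground-truth activity is supplied, a network's chromosomes are a
contiguous window in activity rank snapped to neighbourhood boundaries —
co-regulated targets sit on activity-similar, hence spatially coherent,
chromosomes.  Without it, chromosome sets are uniform draws.

**Phantoms.**  Two-channel voxel stacks with spherical or cuboidal
territories specified in micrometres, uniform background, optional
Gaussian noise, and analytic minimum surface gaps for all four
cross-channel pairings as ground truth.

**What the generator does not emulate.**  Chromosome-size-dependent
radial preferences, nuclear envelope interactions and chromatin polymer
structure; probe-level sequence effects, background correction or
MAS5-style summarization (tables are taken as summarized intensities);
imaging noise beyond additive Gaussian, chromatic shift and
photobleaching.  Passing tests therefore demonstrate the correctness and
calibration of the *statistics* under a transparent generative model, not
biological conclusions about real nuclei.

## Numerical choices and degenerate inputs

* Matrix symmetry is required exactly (tolerance 0) at construction; file
  readers locate and report the worst asymmetric entry.
* Chromosomes with zero observed genes get `excluded = TRUE` and leave
  both the IAD and the jointly-subset IPD rows/columns by label.
* Empty FWHM selections (e.g. identical tables) abort with advice to
  coarsen bins rather than returning an empty matrix pair.
* `nclass.FD` histogram bins by default, overridable; no smoothing.
* Seeds: every stochastic stage takes an explicit seed; the pipeline
  derives per-stage seeds from one global seed by fixed offsets, so a run
  is byte-identical given its configuration.
* Test and acceptance problem sizes are the study conditions (54 nuclei,
  22 autosomes, 87 networks) with 10⁴ permutations/iterations where a
  distributional summary is needed, and reduced iteration counts
  (200–600) inside grid scans where only a per-point deviate is needed;
  phantom stacks are 64×64×32 voxels at 0.2×0.2×0.5 µm spacing.

## Known limitations

* With coupling confined to neighbourhoods of four chromosomes, only
  about 25 of the 231 chromosome pairs are informative, so the per-seed
  power of the permutation FDR at 54 nuclei is around 80%, not 100%:
  a fully-coupled synthetic dataset occasionally fails to reject the
  null at the 5% level.  This is a property of the study conditions, not
  of the estimator (the null calibration tests are exact).
* The per-network size law depends on the Φ scale convention (above):
  under the normalized convention adopted here, most networks still show
  an H increase under randomization, but the rank correlation between
  `ΔH_f/H_0f` and network size is not negative on synthetic data.
* Per-slice 2D edge detection biases near-vertical interface distances
  upward by up to the polar-cap disc radius; a 3D surface definition
  would remove this but is deliberately not the default, to preserve the
  section-wise edge semantics of the original measurement.
* The generator treats homologues as exchangeable and places them around
  a common base position; real homologues can occupy distinct radial
  zones.
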