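# ctcoupler

Quantifies the coupling between the three-dimensional organization of
chromosome territories in the interphase nucleus and the transcriptional
output of the genome.

Interphase chromosomes occupy discrete territories at reproducible,
cell-type-specific positions. `ctcoupler` asks, and answers
statistically, whether chromosomes with similar transcriptional activity
sit close together. It is aimed at nuclear-organization and regulatory
genomics groups who have (or simulate) chromosome centroid coordinates,
microarray-style expression tables, transcription-factor gene sets and/or
two-channel chromosome-paint confocal stacks.

## The statistics at its core

For chromosomes *i*, *j* with centroid coordinates **r** (in units of the
nuclear radius) measured over many nuclei, and per-chromosome mean
activities *A* (total observed gene activity over the annotated gene
number *N*):

- **IPD**, inter-chromosome physical distance — the mean (or minimum) of
  the four homologue-pairing distances |**r**ᵢ − **r**ⱼ|, averaged over
  nuclei; diagonal (homologue–homologue) entries are kept but excluded
  from all correlations.
- **IAD**, activity distance — |ln *A*ᵢ − ln *A*ⱼ|.
- **IBD**, basepair-length difference — |Chrbpᵢ − Chrbpⱼ| (size control).
- **Permutation FDR** — matrices are correlated over their off-diagonal
  upper triangles; significance comes from conjugating one matrix by
  random label permutations and counting the fraction with
  PCC > PCC₀ (strict; ties are non-discoveries).
- **Network-coupling energy** —
  H = Σ_f Σ_{i<j} A_ij (Φ_if − Φ_jf)², with adjacency
  A_ij = exp(−IPD_ij/λ) and Φ_if the log summed activity of network *f*'s
  genes on chromosome *i* (0 where absent). Randomizing chromosome
  identities and summarising the recorded H values gives the optimality
  deviate ΔH = (H_av − H₀)/σ and its Gaussian-tail p-value; a λ-scan
  locates the adjacency length scale where the coupling is sharpest.
- **Interface distances** — confocal paint stacks are thresholded at
  mean + SD of the z-stack, split into homologue territories
  (26-connected components), reduced to per-slice 2D edges, and the
  minimum 3D edge-to-edge distance is measured for all four homologue
  pairings.

A synthetic-data module generates nuclei with tunable position–activity
coupling (strength `coupling_beta`, length scale `coupling_length`),
probe-level expression, TF-network catalogs with controlled occupancy,
and phantom image stacks with analytic ground truth — so every stage is
testable end to end.

## Worked example

Fully coupled synthetic nuclei (54 nuclei, 22 autosomes), expression, and
the complete analysis:

```r
library(ctcoupler)

cfg   <- sim_config(coupling_beta = 1, seed = 3)
nuc   <- simulate_nuclei(cfg)
expr  <- simulate_expression(cfg, nuc$activity)
ipd   <- compute_ipd(nuc$coords)
genes <- aggregate_probes(normalize_to_array_mean(expr$table))
iad   <- compute_iad(chromosome_activity(genes, expr$annotation))

glance(correlate_matrices(ipd, iad))
#> # A tibble: 1 × 4
#>     pcc slope intercept n_pairs
#>   <dbl> <dbl>     <dbl>   <int>
#> 1 0.566 0.390   0.00194     231

glance(permutation_fdr(ipd, iad, n_perm = 1e4, seed = 42))
#> # A tibble: 1 × 6
#>    pcc0   fdr n_perm null_mean null_sd exhaustive
#>   <dbl> <dbl>  <int>     <dbl>   <dbl> <lgl>
#> 1 0.566     0  10000  0.000122  0.0803 FALSE

nets <- simulate_networks(cfg,
  dplyr::distinct(expr$table, gene_id, chromosome),
  activity = nuc$activity)
phi  <- build_network_matrix(genes, nets, chromosomes = dm_labels(ipd))
rz   <- randomize_H(build_adjacency(ipd, 0.07), phi,
                    energy_config(n_iterations = 1e4, seed = 7))
glance(rz)
#> # A tibble: 1 × 8
#>      h0  h_av sigma delta_h p_gaussian p_empirical mode       n_iterations
#>   <dbl> <dbl> <dbl>   <dbl>      <dbl>       <dbl> <chr>             <int>
#> 1  3.54  27.8  2.58    9.40          0           0 cumulative        10000
```

Reading: the 231 chromosome pairs of physical and activity distance
correlate at PCC 0.566, and none of 10⁴ random chromosome relabelings
does better (FDR 0). Randomizing chromosome positions raises the
network-coupling energy from H₀ = 3.54 to a mean of 27.8 — a deviate of
9.4 standard deviations — so the simulated arrangement is strongly
optimized for its own transcriptional program, as it was built to be.
`autoplot()` on any of these objects (matrices, correlations, FDR nulls,
H trajectories, λ-scans) draws the corresponding figure.

A thin command-line front end over the same functions ships at
`inst/cli/territory-coupling.R`
(`simulate | ipd | ibd | iad | correlate | fdr | decay | energy |
scan-lambda | occupancy | interface-distance | validate | run`).

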