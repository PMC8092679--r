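# parbsbm

Quantitative modeling of ParB·*parS* partition complexes on supercoiled
bacterial DNA.

ParABS systems segregate bacterial chromosomes and low-copy plasmids.
Hundreds of ParB dimers condense into a cluster anchored at the
centromeric *parS* site, and ChIP-seq sees ParB bound non-specifically
over ~10 kb around *parS*.  The **Stochastic Binding Model (SBM)**
explains that profile without spreading: DNA looping stochastically
carries distal loci into the ParB-rich region, so the binding
probability at genomic offset *s* is

    B(s) = ∫ 4π r² P_s(r) C(r) dr

with `P_s(r)` the equilibrium distribution of the spatial distance
between the locus at genomic distance *s* and *parS*, and `C(r)` the
ParB occupation probability at spatial distance *r* from *parS*.

The package is aimed at people modeling bacterial chromosome
organization or protein condensates on DNA.  It provides, end to end:

* **Polymer engine** — circular DNA as a self-avoiding rod-like chain
  (10.2 nm cylinders, hard-core diameter 4 nm, persistence length
  50 nm, torsional stiffness 86 nm), sampled by crankshaft
  Metropolis Monte Carlo with exact segment-pair writhe bookkeeping
  (`Lk = Tw + Wr`) and a simulated-annealing ladder of supercoiling
  densities σ from 0 to −0.08.
* **Observables** — radius of gyration, distance distributions
  `P_s(r)`, local-writhe profiles and plectoneme branch counting via
  deep local-writhe minima.
* **Cluster models** — quenched (sharp droplet), gaussian, exponential,
  and the *leaky* cluster: a saturated core of radius ω/4 plus a 1/r
  halo, the stationary solution of protein production at the core edge,
  diffusion, and dilution (screening length ξ = √(D/Γ)); plus the
  cluster-center offset kernel Π_r(x), the predicted ParB count
  N_P = (ω/4a)³ [1 + (3/2)((4R/ω)² − 1)], and `B(s)` itself.
* **Fitting** — ingestion of TSV/bedGraph coverage profiles,
  max-normalization after background subtraction, and RMSD grid fits
  over (σ, ω) in a fit window (default 1.5–9 kb).
* **Synthetic data** — ground-truth generator (analytic `P_s(r)`
  stand-in, Poisson reads, fragment smoothing, promoter-like dips) for
  end-to-end recovery testing.

## Worked example

Predicted ParB protein numbers from the leaky cluster (nucleoid radius
400 nm, cluster FWHM 36 nm):

```r
library(parbsbm)
cm <- cluster_model("leaky", omega = 36)
sapply(c(5, 10, 15, 20), function(a) protein_count(cm, a = a, R = 400))
#> [1] 17277.0840  2159.6355   639.8920   269.9544
```

Only an effective protein radius of 15–20 nm is consistent with the few
hundred ParB per complex seen experimentally — the crosslinked
footprint, not the bare ~5 nm protein.

A small supercoiling study and its binding profile:

```r
em  <- energy_model()                     # l_p = 50 nm, C = 86 nm
ens <- run_annealing_protocol(
  n_bp = 3000,
  schedule = annealing_schedule(sweeps_per_level = 800),
  plan = sampling_plan(n_runs = 3, frames_per_run = 20),
  em = em, mp = move_params(M = 10), seed = 1)

gyration_curve(ens)[c(1, 9, 17), ]
#>          sigma        Rg      sem
#> 1   0.00000000 136.37481 1.203586
#> 9  -0.03859649  63.80666 8.356338
#> 17 -0.08070175  56.18186 7.875312

ds <- distance_samples(ens, level = 9, s_grid_bp = seq(0, 1500, 300))
bp <- binding_profile(ds, cluster_model("leaky", omega = 44))
head(bp, 3)
#>   s_bp         B
#> 1    0 1.0000000
#> 2  300 0.2374620
#> 3  600 0.1770657
```

Supercoiling compacts the molecule (radius of gyration 136 → 56 nm with
the plateau past |σ| ≈ 0.04), and the leaky cluster turns the sampled
distances into a binding profile that decays from 1 at *parS* over a
few kilobases, as in the ChIP-seq data this model was built to explain.
Fit a (σ, ω) grid against a normalized coverage profile with
`grid_fit()`; recover planted parameters from synthetic data with
`recovery_experiment()`.

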