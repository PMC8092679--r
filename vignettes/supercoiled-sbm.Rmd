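---
title: "Modeling ParB partition complexes on supercoiled DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ParB partition complexes on supercoiled DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parbsbm)
```

## The scientific problem

Bacterial ParABS partition systems build clusters of hundreds of ParB
dimers anchored at a centromeric *parS* site.  ChIP-seq experiments see
ParB bound non-specifically over roughly ten kilobases around *parS*,
decaying smoothly with genomic distance and showing a sharp drop within
the first couple hundred base pairs.  The Stochastic Binding Model (SBM)
explains this profile without any spreading mechanism: DNA loops
stochastically carry distal loci into the ParB-rich region, where
crosslinking during the ChIP protocol captures them.  The binding
probability at genomic offset $s$ is

$$B(s) = \int 4\pi r^2 \, P_s(r)\, C(r)\, dr,$$

where $P_s(r)$ is the equilibrium probability for the locus at genomic
distance $s$ from *parS* to sit at spatial distance $r$ from it, and
$C(r)$ is the probability that a point at distance $r$ from *parS*
overlaps a ParB protein during crosslinking.  `parbsbm` implements all
three ingredients: a polymer Monte-Carlo engine for $P_s(r)$ on
*supercoiled* circular DNA, a family of cluster concentration models for
$C(r)$, and the machinery to confront the resulting $B(s)$ with
coverage data over a grid of supercoiling densities $\sigma$ and cluster
widths $\omega$.

## The polymer model

DNA is a self-avoiding rod-like chain (sRLC): a closed polygon of rigid
cylinders of length $l = 10.2$ nm (30 bp of B-DNA) and hard-core radius
$r_e = 2$ nm (non-adjacent axes may not approach closer than 4 nm, the
effective electrostatic diameter at in-vivo salt).  Each joint carries a
bending energy $\kappa(1-\cos\theta)$ and the molecule as a whole a
torsional energy.  Elastic constants are standard B-DNA values:
persistence length $l_p = 50$ nm, torsional stiffness $C = 86$ nm.

Two numerical choices deserve comment.

**Bending constant.**  The discrete chain reproduces $l_p$ exactly when
$\kappa$ solves $\coth\kappa - 1/\kappa = e^{-l/l_p}$ (the equilibrium
tangent correlation of the discrete worm-like chain), giving
$\kappa = 5.418$ at our discretization; the cruder continuum ratio
$\kappa = l_p/l = 4.902$ is available as a configuration option
(`energy_model(kappa_method = "ratio")`).

**Twist representation.**  A closed chain satisfies
$Lk = Tw + Wr$: the linking number is a topological invariant
partitioned between twist and writhe.  Since the chain has no intrinsic
curvature and torsional energy is quadratic and homogeneous, the twist
at equilibrium is uniform at fixed writhe, so we book-keep torsion with
the uniform-twist energy
$E_{tw} = (2\pi^2 C/L)\,\Delta Tw^2$, $\Delta Tw = (Lk - Lk_0) - Wr$,
instead of per-joint Euler frames.  The equilibrium ensemble is
identical; the bookkeeping is far cheaper.  Per-joint frames could be
added as an alternative backend without changing any interface.

Writhe is computed with the closed-form Gauss-integral contribution of
straight segment pairs; adjacent pairs contribute exactly zero.  During
a crankshaft move only moved-against-unmoved pairs can change, so the
writhe is updated incrementally and recomputed in full every 1000
accepted moves (tolerance $10^{-6}$ turns) to guard against drift.

**Topology protection.**  The linking number is only conserved if
strands never pass through each other.  Rejected hard-core overlaps
catch most passage attempts; as a second guard, any move whose
incremental writhe change exceeds one turn (the signature of a passage)
is rejected.  This follows the standard practice for rod-like-chain
simulations of supercoiled DNA.

## The Monte-Carlo engine

Closed chains evolve by crankshaft rotations: two articulating sites at
most $M$ cylinders apart are chosen uniformly and the block between them
is rigidly rotated about their axis by an angle uniform in
$[-\pi/4, +\pi/4]$.  The proposal is symmetric, so plain Metropolis
acceptance applies.  The rotation amplitude is a free choice (the
amplitude is not dictated by the model); $\pi/4$ keeps acceptance
between roughly 0.25 and 0.85 across the whole $\sigma$ ladder studied
here while keeping writhe jumps rare, and it is held fixed during
production to preserve detailed balance.  A *sweep* is $N/M$ elementary
attempts (10 for the reference geometry $N = 1000$, $M = 100$).

Open chains (used only for calibration checks, never for production)
instead use suffix-pivot moves — the tail beyond a random vertex is
rotated about a uniformly random axis.  Plain crankshaft moves on an
open chain would leave both end vertices, and hence the end-to-end
distance, frozen; pivot moves are ergodic and exactly preserve the
product-of-spheres measure on bond directions, so the joint-angle
marginal of a torsion-free phantom chain is exactly
$\sin\theta\, e^{-\kappa(1-\cos\theta)}$.  This is the reference
distribution against which the sampler is validated
(Kolmogorov–Smirnov), and the same ensemble recovers
$l_p = -l/\ln\langle\cos\theta\rangle$ within sampling error.  A closed
ring would *not* serve here: closure correlates the joints and shifts
the angle marginal (we measure
$\langle\cos\theta\rangle \approx 0.72$ for a 12-gon against $0.816$
unconstrained), which is a property of the physics, not of the sampler.

**Supercoiling protocol.**  A run starts from a planar circle at
$\sigma = 0$ ($Lk = Lk_0$, e.g. 2850 turns for 30 kb at the default
helical repeat of 30000/2850 bp per turn) and anneals down to
$\sigma = -0.08$ in 17 levels of $0.005$: sample a fixed number of
sweeps at constant $\sigma$, then remove helices (decrement $Lk$; about
14 turns per step at 30 kb, realized as integer $Lk$ targets
$\mathrm{round}(Lk_0(1+\sigma_t))$ so that nominal levels are hit as
closely as integer linking numbers allow).  Frames are collected only
from the second half of each level's sweeps — the first half is the
implicit equilibration — at evenly spaced sweep indices.  The
supercoiling rate is expressed as $v = 1$ for $5\times 10^5$ sweeps per
level; production results should use rates slow enough that observables
are insensitive to halving them, which is tested explicitly.

Reproducibility is a hard contract: per-run RNG streams derive from the
master seed and identical seeds give bit-identical trajectories.

## Observables

* **Radius of gyration** per $\sigma$ level, averaged over frames and
  runs; the standard error of the mean uses the across-run variance
  divided by $n_{runs}-1$ (for 20 runs, $\mathrm{var}/19$).
* **Distance samples / $P_s(r)$**: distances between loci at genomic
  offset $s$, averaged over all reference vertices and both directions
  (the chain is sequence-homogeneous, so this is pure variance
  reduction).
* **Local writhe** $wr(i)$: the writhe restricted to a window of
  $m = 10$ cylinders (two persistence lengths) around site $i$ — small
  enough to resolve the tightest plectonemic curls.  Deep negative
  minima of the profile mark plectoneme ends.
* **Branch counting**: per $\sigma$, local-writhe minima are pooled
  over the ensemble; when their distribution is multimodal a threshold
  $wr^*$ is placed at the kernel-density antimode between the
  non-plectonemic mode near zero and the plectonemic mode, and the
  branch count of a conformation is the number of minima at or below
  $wr^*$.  Unimodal distributions (weak supercoiling) give zero.

The antimode rule needed two robustness guards that the bare idea does
not supply.  Shallow thermal minima always outnumber branch apexes, so
the plectonemic component appears as a low bump on the flank of a
dominant near-zero peak: (i) candidate plectonemic modes are searched at
or below $-0.1$ turns, past the thermal ripple scale of the $m = 10$
window ($\pm 0.05$ turns) but well above typical apex depths
($\lesssim -0.2$); (ii) a candidate counts as a genuine mode only if its
density exceeds the intervening valley by a factor 1.2, which
discriminates real bumps from kernel wiggles.  Bandwidth is Silverman's
rule.  All three knobs are exposed, and a manual per-$\sigma$ threshold
override is available — the same operating mode as picking thresholds
from the minima histograms by eye.

## The cluster models

All concentration profiles are normalized to $C^{(0)}(0) = 1$ and
parametrized by their full width at half maximum $\omega$
($C^{(0)}(\omega/2) = 1/2$ for every kind; super-resolution microscopy
puts $\omega$ near $37\pm5$ nm):

| kind | $C^{(0)}(r)$ | core radius $\rho$ |
|---|---|---|
| quenched | $\theta(\omega/2 - r)$ | $\omega/2$ |
| leaky | $1$ for $r \le \omega/4$, else $(\omega/4)/r$ | $\omega/4$ |
| gaussian | $e^{-4\ln 2\, r^2/\omega^2}$ | — |
| exponential | $e^{-2\ln 2\, r/\omega}$ | — |

The gaussian and exponential forms are the unique profiles with unit
center value and the stated FWHM.  The *leaky* profile is the stationary
solution of protein production at the core edge, diffusion, and dilution
by growth: writing $X = rC^{(0)}$ turns the stationary
diffusion–dilution equation into $D X'' = \Gamma X$, giving the Yukawa
form $C^{(0)} = A e^{-r/\xi}/r$ with screening length
$\xi = \sqrt{D/\Gamma}$.  With $D \ge 1\,\mu m^2/s$ and of order a
thousand proteins diluted per cell cycle ($\Gamma \sim 1\,s^{-1}$ per
protein), $\xi \gtrsim 1000$ nm exceeds the cell, so the pure $1/r$ form
is the default and the finite-$\xi$ Yukawa is a configuration option.
Saturation at the core edge ($C^{(0)}(\rho) = 1$) fixes $A = \rho$, and
$\rho = \omega/4$ makes the FWHM come out at $\omega$.

**Cluster-center offset.**  The measured cluster is centered on itself,
not on *parS*; the *parS*-centered effective profile is
$C(r) = \int \Pi_r(x)\, C^{(0)}(x)\, dx$ where $\Pi_r(x)$ is the density
of center–probe distances when the center is uniform in the ball of
radius $\rho$ around *parS*.  $\Pi_r$ has a closed form in two regimes
(full sphere inside the ball, partial overlap) and integrates to one for
every $(r, \rho)$.  Convolution is on by default for the kinds with a
sharp core (quenched, leaky) and off for the smooth kinds, where no
natural $\rho$ exists and the direct $C^{(0)}$ approximation only
matters at small binding probabilities; when requested there,
$\rho$ defaults to $\omega/2$.

**Protein count.**  Integrating the leaky profile over a nucleoid of
radius $R$ and dividing by an effective protein volume $4\pi a^3/3$
gives the closed form
$$N_P = \left(\frac{\omega}{4a}\right)^3
  \left[1 + \frac{3}{2}\left(\left(\frac{4R}{\omega}\right)^2 - 1\right)\right],$$
which the package cross-checks against direct quadrature.  With
$R = 400$ nm and $\omega = 36$ nm this reproduces the series 17280,
2160, 640, 270 for $a = 5, 10, 15, 20$ nm.  Note that $\omega = 36$ nm
is a reconstruction: it is the width for which the quadrature reproduces
that printed series (its source does not state the width used), and it
should not be quoted as a measured value.

## Estimating B(s) and fitting data

`binding_profile()` evaluates the SBM integral as the sample mean of
$C(r)$ over the distance samples at each offset — the Monte-Carlo
estimator of the radial integral, bounded automatically by the sampled
volume.  A binned-histogram estimator of the same integral agrees within
Monte-Carlo error and serves as a consistency check.

Coverage data are ingested from two-column TSV or bedGraph (via
rtracklayer), background-subtracted, clipped at zero and max-normalized
to 1, mirroring how ChIP-seq read-count profiles are prepared
(fragment-center assignment, strand-aware, is provided for raw read
starts; the background default is a user-supplied scalar or distal
window because no universal definition exists).  Model and data are
compared by RMSD after linear interpolation of the model onto the data
positions inside a fit window, by default $[1.5, 9]$ kb — inside that
window the profile is informative, while the excluded flanks are
dominated by the *parS* region itself and by reproducible
promoter/roadblock distortions.  No amplitude is fitted: both curves
live on the $[0,1]$ scale.  `grid_fit()` scans $(\sigma, \omega)$ and
reports the argmin cell, breaking exact ties toward smaller $\omega$,
then larger $|\sigma|$.

## The synthetic-data generator

Testing the SBM and fitting layers should not require hours of polymer
simulation, so the package ships an analytic stand-in for $P_s(r)$: a
Gaussian chain whose locus–*parS* vector at offset $s$ is isotropic
Gaussian with rms $b\,s^{\nu}$ ($\nu = 0.5$, $b = 2$ nm/bp$^{1/2}$ by
default, i.e. about 200 nm at 10 kb — a realistic in-vivo scale).
Coverage profiles are generated as Poisson counts with expectation
`depth * B_true(s)`, optionally box-smoothed over the fragment size and
multiplied by localized Gaussian-shaped dips that mimic promoter
distortions.  Two realism details matter for the normalization step.
First, the generator includes a saturated plateau of about 0.7 kb
upstream of the `s = 0` origin, standing in for the array of strong
specific *parS* sites whose edge defines the origin: real profiles take
their maximum there, so fragment smoothing does not depress it.  Without
the plateau, max-normalizing a smoothed profile inflates the data by
>10% relative to a model anchored at $C(0)=1$ and biases $\omega$
estimates upward.  Second, the default depth is $10^4$ expected reads at
the maximum (a well-covered library); dividing by the *observed* maximum
is biased low by the extreme-value fluctuation of Poisson counts, an
effect that shrinks as depth$^{-1/2}$.  Poisson noise is the minimal ChIP-seq-like model; since
real library noise is not specified anywhere we rely on, recovery
criteria (does the fit find the planted $(\mathrm{kind}, \omega)$?)
rather than likelihood criteria.  The stand-in deliberately omits
supercoiling, excluded volume and the short-range plectonemic drop;
passing recovery tests therefore validates the *fitting machinery*, not
the polymer physics, which is exercised by the simulation tests.

## Scaled-down study sizes

The reference protocol (30 kb, 17 levels, up to $1.6\times 10^7$ sweeps
per level, 20 runs) is cluster-scale.  The package's own test suite runs
a reduced study chosen to fit in minutes on one core while preserving
the phenomenology: a 6 kb chain ($N = 200$, $Lk_0 = 570$, $M = 20$),
5 runs, 2000 sweeps per level, 30 frames per run and level.  At this
scale the compaction of the coil with increasing $|\sigma|$ and its
plateau beyond $|\sigma| \approx 0.04$ are reproduced clearly.  Branch
statistics converge much more slowly: pilot studies at 3–4 times slower
rates still show branch counts relaxing downward at the deepest
$\sigma$ levels as young branches merge, so the reduced study
over-counts branches at strong supercoiling relative to equilibrium
and the location of the branch-count maximum there should be read with
that bias in mind.  Rate insensitivity itself is tested on a 3 kb chain
by comparing two rates differing by a factor two.

## Known limitations

* Sequence homogeneity: no sequence-dependent elasticity, intrinsic
  curvature, or explicit electrostatics beyond the hard core.
* No stretching force, no cellular confinement, no DNA–cluster
  interaction: $P_s(r)$ comes from an isolated chain.
* The hyperbranched regime below $\sigma = -0.08$ is out of scope; the
  constructor warns if you ask for it.
* MC time is not physical time; no dynamic quantities are produced.
* Branch counting reports external branches only, not the full
  plectonemic tree topology.
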