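---
title: "A mesoscale patchy-particle model of outer membrane protein clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mesoscale patchy-particle model of outer membrane protein clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesomp)
```

## The model

Outer membrane proteins (OMPs) of Gram-negative bacteria such as *E. coli*
cluster into micrometre-scale "islands" that restrict their lateral
diffusion. Simulating that process at molecular resolution is prohibitively
expensive at the length and time scales where islands become visible, so
`mesomp` implements a two-dimensional mesoscale model in which each protein
is a single rigid disc moving in the membrane plane:

* **State.** Each protein *i* carries a position $(x_i, y_i)$ in nm and an
  in-plane orientation $\theta_i \in [0, 360)$ degrees, plus a cluster
  membership. Nothing else — lipids, protein internal structure and membrane
  curvature are deliberately outside the model.
* **Interfaces.** Each species carries "sticky patches": angular intervals
  on the disc perimeter in the body frame. Two proteins at centre distance
  $d$ interact when $d$ lies in the interaction band
  $(0.98 \cdot c,\; c]$ (with cutoff $c = 5$ nm for BtuB, i.e. 4.9–5.0 nm)
  *and* the bearing of each partner falls inside a patch of the other:
  $\mathrm{atan2}(y_2-y_1, x_2-x_1) - \theta_1$ in a patch of protein 1 and
  the same bearing $+180^\circ - \theta_2$ in a patch of protein 2, all
  modulo 360. The BtuB geometry used throughout is two patches, 15–80° and
  180–230°. With `specific_interfaces = FALSE` the angular condition is
  dropped — the isotropic control.
* **Irreversible association.** Interacting proteins join a cluster and
  never leave it. This encodes the observation that OMP–OMP contacts are
  effectively permanent on the millisecond scale of these simulations: a
  free-energy of association around −50 kJ/mol corresponds to
  $K_d \sim 1$ nM and, for diffusion-limited association rates, to
  dissociation times of seconds or more (`kinetics_estimates()` reproduces
  this arithmetic). Because association only ever merges components, the
  cluster partition is stored as a union–find structure; it is an exact
  record of every bond ever formed.
* **Motion.** At each step every cluster receives an independent random
  rigid move: translations per axis and a rotation about the cluster centre
  of mass, each drawn from zero-mean Gaussians whose standard deviation
  follows the mobility power law $\mathrm{std}(n) = A\,n^{-b}$ in the
  cluster size $n$. One step represents 10 ns. Member orientations are
  incremented by the cluster rotation so that patch geometry stays
  consistent (a requirement of the rigid-body picture, even though only the
  positions are strictly needed for distances).
* **Excluded volume.** No two centres may approach below
  $0.98 \cdot c = 4.9$ nm. The threshold is strict: exactly 4.9 nm is
  clash-free, which keeps the clash region and the interaction band
  disjoint and unambiguous to test.

### The update step

1. Enumerate clusters in ascending minimum-member-id order and draw, in that
   order, $dx, dy, d\theta$ for each — a fixed draw order makes runs exactly
   reproducible from the seed.
2. Apply all moves rigidly.
3. Hard-wall boxes: any cluster with a member outside the box has its whole
   move rejected (clusters move as one entity, so the wall test is also
   per-cluster). Periodic boxes: distances are minimum-image; coordinates
   are kept unwrapped internally and wrapped (with integer winding numbers)
   only when frames are recorded.
4. Clash cascade: find all pairs closer than 4.9 nm and revert *both*
   involved clusters to their start-of-step poses; iterate until no clash
   remains. Reverting both sides is symmetric and guarantees termination,
   because the start-of-step state is clash-free — every iteration returns
   at least one moved cluster to a legal pose, so the cascade can run at
   most once per cluster.
5. Re-derive interactions from the new geometry and merge clusters
   (permanently). When a merge spans a periodic boundary the absorbed
   cluster is shifted by whole box lengths so member coordinates stay
   mutually consistent; centres of mass are always computed on unwrapped
   coordinates.

Any patch of one protein may bind any patch of another; no pairing rule
between specific interfaces is imposed (none is implied by the interface
statistics the patches derive from).

The stepper is implemented in C++ (via Rcpp) with a cell-list neighbour
search, capped at $O(n)$ cells so sparse configurations in large boxes do
not pay for empty space; a 400-protein, $10^5$-step run takes seconds.
All randomness flows through R's RNG, so `set.seed()` (or the `seed` field
of `sim_config()`) fully determines a trajectory.

### Initialization and insertion

Runs start from a square grid at 10 nm spacing centred in the box, with
uniform random orientations — spacing above the cutoff guarantees a legal,
interaction-free start. `insert_proteins()` mimics insertion of newly
synthesized proteins by the β-barrel assembly machinery: new singletons are
placed by rejection sampling at uniform positions at least 4.9 nm from
everyone, leaving existing poses untouched.

## Parameterization from trajectories

In production use the motion laws and patches are fitted from
finer-grained particle trajectories (per-protein $x$, $y$, $\theta$ at
10 ns resolution). `motion_stats_by_cluster_size()` collects displacement
and rotation samples over 10 ns windows at every recorded frame, grouped by
the cluster size at the window start; windows in which the size changes are
discarded, as are windows that span a gap between pooled replicate runs.
Spreads are reported as root-mean-square values — the displacement
distributions are zero-mean by construction, so the mean is checked, not
subtracted. `fit_power_law()` then fits $\mathrm{std}(n) = A n^{-b}$ by
least squares on $\log$–$\log$ axes, which is exact on noiseless power-law
data and scale-equivariant.

Two measurement conventions are provided. `per = "protein"` (default)
measures each molecule's own displacement — the natural convention for
finer-grained input. `per = "cluster"` measures the centre-of-mass
displacement of each cluster and one rotation sample per cluster. For
trajectories generated by this engine the cluster mode is the exact inverse
of the forward model; per-molecule displacements of clustered proteins
additionally contain tangential motion induced by the cluster rotation
($\sim r\,d\theta$ for a member at radius $r$), which inflates the apparent
translational spread of large clusters and biases $b$ low by 0.2–0.3 under
typical settings. Recovery tests therefore use cluster mode; fits are
restricted to cluster sizes with at least ~100 windows, since the spread of
a handful of windows is too noisy to constrain the exponent.

Patches are called from the angular density of interacting neighbours
around a central protein (`neighbor_angular_density()`): bearings in the
central body frame, binned (default 5°, configurable), normalized to a
per-degree probability density. Contiguous above-threshold runs of bins
become patches, merged across the 0/360 seam. The default threshold is the
mean bin density plus one standard deviation; for engine-generated
fixtures, where out-of-patch density is strictly zero but individual bonds
contribute spiky, unequal weights (a bond is frozen at its formation angle
for the rest of the run), the plain mean is a cleaner separator and the
recovery tests use it. On engine data `bonded_only = TRUE` restricts the
count to same-cluster pairs, because mere adjacency can persist without
interaction at high crowding.

## Trajectory analyses

* `assign_clusters()` is the frame-wise *analysis* clustering — connected
  components under species-pair centroid cutoffs (BtuB–BtuB 6.0 nm,
  OmpF–OmpF 8.8 nm, BtuB–OmpF 7.3 nm by default), with no patch condition
  and no memory. It is deliberately distinct from the engine's permanent
  clustering.
* `compute_msd()` computes the time-averaged mean squared displacement on
  unwrapped coordinates and fits $\mathrm{MSD}(t) = 4Dt$ over lag points
  1–4 with an intercept (the localization-noise convention of
  single-particle tracking); $D$ is a quarter of the slope, reported in
  nm²/ns and µm²/s (1 nm²/ns = 1000 µm²/s).
* `classify_motion()` is a deterministic surrogate for neural-network
  SPT classifiers. Per window it computes the MSD scaling exponent
  $\alpha$ (log–log slope over lags 1–4) and a confinement ratio
  $R = \max\|\mathbf{r}(t)-\mathbf{r}(0)\|^2 / (4 D_\mathrm{local}
  t_\mathrm{win})$; a window is confined if $\alpha < 0.5$ or $R < 0.2$,
  Brownian if $\alpha \ge 0.8$ and $R \ge 0.2$, otherwise unclassified. A
  protein is *mixed* iff both Brownian and confined windows occur;
  trajectory edges not covered by a complete window stay unclassified.
  The defaults — 128-frame non-overlapping windows and the thresholds above
  — are calibration constants chosen by a replicate study on synthetic
  free/corral/switching walks: because a single mislabelled window flips a
  protein to "mixed", per-window false-positive rates must be well below
  1%, which shorter (32-frame) windows and a looser $R$ threshold do not
  achieve (pure Brownian walks were then mislabelled "mixed" in roughly
  half the replicates). With the defaults all three classes are recovered
  in ≥95% of replicates on well-separated fixtures. These constants are not
  comparable number-for-number with published neural-network classifiers.
* `motion_fractions()` reports class fractions over classified proteins,
  optionally with the subsampling convention used for large systems
  (random samples of 100 proteins, five resamples, mean ± sd).

## Synthetic generators

`gen_brownian()` (exact law $\mathrm{MSD} = 4Dt$), `gen_corral()` (Brownian
proposals rejected outside a hard disc — the simplest confinement model
with a provable MSD bound), `gen_switching()` (continuous concatenation,
ground truth for "mixed"), `gen_pseudo_cg()` (the engine run with known
parameters, tagged with its ground truth) and `gen_random_config()`
(uniform non-clashing placement at a given density). The pseudo-CG fixture
reuses the engine rather than an independent kinetic model on purpose: it
tests the parameterization as the inverse of the exact forward model.
Corral test fixtures are generated in the moderately-to-strongly confined
regime (radius ~1.5× the per-step rms) with
$4 D t_\mathrm{win} \gg r^2$; weakly confined walks with rare boundary
contacts are genuinely ambiguous at these window lengths.

What the fixtures do *not* emulate: finite-lifetime contacts, interface
flexibility within a bond (bonds here are frozen at their formation
geometry), lipid-mediated effects, and localization noise. Passing
recovery tests therefore demonstrates internal consistency of the
workflow, not performance on experimental single-particle-tracking data.

## Study conditions and problem sizes

The package's reference experiments, exercised by the test suite and the
acceptance script:

* **Validation run**: 144 BtuB-like particles, 12×12 grid at 10 nm in a
  hard-wall 120×120 nm box, 2000 steps (20 µs), monomer translation std
  0.2 nm per axis per step ($D \approx 2$ µm²/s), rotation std 2° per step,
  $b = 0.5$ for both laws, median over 3 seeds. Under these surrogate
  motion parameters the largest cluster after 20 µs has a median of about
  5–6 proteins while monomers persist; clusters of ten or more appear by
  roughly $10^4$ steps, or at several-fold higher rotational mobility.
  Growth at this density is alignment-limited, so the late-time cluster
  sizes are sensitive to the rotational law, for which no published value
  is available at this scale.
* **Isotropic control**: 400 proteins, 20×20 grid covering a hard-wall
  200×200 nm box (10,000 µm⁻²), no patch condition, $10^5$ steps (1 ms):
  the system coarsens to a single cluster holding >95% of proteins
  (occasionally one small straggler cluster survives a single run, which is
  why the check uses the median over three seeds).
* Property suites (diffusion oracle, rigidity, excluded volume, parameter
  recovery, classifier accuracy) run on deliberately small systems — tens
  to hundreds of proteins, $10^3$–$10^5$ steps — sized so estimator noise
  sits well inside the asserted tolerances.

## Numerical choices and degenerate inputs

Angles are degrees on $[0, 360)$, counter-clockwise, bearings from
`atan2`; patch intervals may wrap and membership is inclusive of the
endpoints. Distances at exactly the clash threshold are legal; at exactly
the cutoff, interacting. A zero-amplitude motion law is allowed (frozen
species draw no random numbers). `gen_brownian()` accepts $D = 0$
(constant trajectory) and rejects negative $D$. Empty patch lists with
specific interfaces enabled give a species that never associates — used to
build ideal free-diffusion ensembles. MSD fits require at least five
frames; classification requires at least one complete window and windows
of at least 16 frames. File formats: a `#`-headed CSV dialect (UTF-8,
comma, `.` decimal, shortest round-trip numeric representation) and an
Arrow/Parquet container carrying the same JSON header in its metadata;
both round-trip all fields losslessly.

## Known limitations

No dissociation kinetics (bonds are permanent by design), no forces or
energies (motion is sampled, not integrated), single-species mesoscale
runs are the validated regime (mixed-species clusters take the motion law
of their lowest-id member), and the renderer (`render_frames()`) is a
forward emulator of under-labelled TIRF imaging for tracking-style
analysis, not a calibrated microscope model.
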