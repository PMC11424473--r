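---
title: "Self-organized margin mechanics: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organized margin mechanics: models, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginflow)
```

## The scientific problem

The early avian (quail) epiblast is a quasi-2D disk whose margin — the
boundary between embryonic and extraembryonic territories — carries a
supracellular actomyosin ring. Contraction of the posterior part of this
ring drives the rotational "polonaise" tissue flows that build the primitive
streak, and the embryo regulates: bisected or obstructed epiblasts redirect
force generation and gene expression and form complete (sometimes multiple)
embryos. `marginflow` implements a mechanical account of this regulation:
contractility is locally self-activating (contraction upregulates it,
stretching downregulates it), while the passive tension that contraction
induces propagates quickly along the margin and acts as a long-range
inhibitor. The pair is formally a Turing activator–inhibitor system in the
limit of an infinitely fast, infinitely long-ranged inhibitor.

Two models are provided, plus the quantification pipeline used to analyse
tracked tissue motion, a contraction-to-expression readout, and seeded
synthetic-data generators that make the whole pipeline testable offline.

## The 1D margin model (`params_1d`, `simulate_1d`)

The margin is a closed tensile line of fixed length with periodic boundary
conditions. With active tension `Ta`, 1D viscosity `nu` and strain rate
`eps`, the total tension is `T = Ta + nu * eps`. Force balance with the
surrounding tissue neglected makes `T` spatially uniform, and length
conservation forces `mean(eps) = 0`, so

```
eps(s) = (mean(Ta) - Ta(s)) / nu
dTa/dt (+ u dTa/ds) = [T0 (1 + zeta tanh(alpha + beta (Ta - mean(Ta)) / T0)) - Ta] / tau
                      + D d2Ta/ds2
```

Linearizing about the uniform state, a zero-mean mode of wavenumber `k`
grows at `sigma(k) = (beta zeta sech(alpha)^2 - 1)/tau - D k^2`
(`dispersion_growth_rate()`, verified against a brute-force single-mode
integration in the test suite). Above threshold the line splits into one
high-`Ta` (contracting) and one low-`Ta` (stretched) domain separated by
narrow fronts whose positions are set by tension homeostasis: the
contracting fraction is independent of the margin length.

Parameters (nondimensional defaults; mm/h mappings use a ~6 mm margin and
the 8-h gastrulation window):

| parameter | default | meaning |
|---|---|---|
| `T0`, `tau` | 1, 1 | tension and time scales (nondimensionalization) |
| `zeta` | 0.75 | relative modulation amplitude |
| `alpha` | −1.2 | feedback offset; sets the contracting fraction |
| `beta` | 6 | feedback strength; supercritical when `beta zeta sech(alpha)^2 > 1` (here 1.37) |
| `D` | 0.00125 | contractility diffusivity; front width `sqrt(D tau)` ≈ 0.035 |
| `nu` | 3 | margin viscosity; sets strain rates to the physical ~0.25/h scale |
| `L` | 2π | margin length |
| `n_grid`, `dt` | 1024, 0.02 | ≥5 grid points per front; `dt ≤ tau` for the discrete maximum principle |

The paper-scale parameter table for this model is not public, so `(alpha,
zeta, beta, D)` were calibrated (see `scripts/calibrate.R`) to the stated
regime: supercritical instability and a steady contracting fraction of 0.37
— the proportion measured in control embryos — with fronts sharp enough
that the fraction is length-invariant within 5% across `L0`, `L0/2`,
`L0/4`. Numerics: explicit reaction (a convex combination for `dt ≤ tau`,
hence bounded in `[T0(1−zeta), T0(1+zeta)]`), unconditionally stable
semi-implicit spectral diffusion, optional first-order upwind advection
(off by default: regulation is faster than advection in the embryo; with it
on, fronts shift to where advection balances homeostasis and the domain is
genuinely smaller). The velocity gauge on the ring is zero spatial mean.
`free_tension` models a cut margin whose inhibitor is gone: the feedback
then references a fixed external tension and contraction spreads to the
whole margin.

## The 2D epiblast model (`params_2d`, `simulate_scenario`)

The disk is a compressible Stokes fluid with substrate friction and a
prescribed divergence `gamma`:

```
mu Lap(u) + (kappa + mu/3) grad(div u - gamma) - friction u + f = 0
```

solved with Q1 finite elements on a masked regular grid; the grad-div
penalty (`kappa/mu` ≈ 170, reduced integration to avoid locking) imposes
`div u = gamma` to discretization tolerance. Attached boundaries are
Dirichlet (zero velocity, or outward `v_epiboly` for the migrating rim);
free (cut) edges are natural/traction-free. The margin is a Lagrangian
polyline carrying contractility `c`, elastic tension `T` and rest length
`l0`; its line force `d(T t)/ds` is spread onto the mesh with a Gaussian of
half-width `w_margin` (immersed-boundary style), and nodes ride the
interpolated flow. Cable kinetics follow a saturating walking kernel
`W(x; lam) = (exp(lam (x−1)) − 1)/lam` with stall at `x = T/(c Ts) = 1`:

```
dlog(l0)/dt = lam eps0 W(T/(c Ts)) + gamma/2
dT/dt       = E [eps - gamma/2 - lam eps0 W(T/(c Ts))]      (node-following)
dc/dt       = [c0 + dc tanh(alpha - beta eps/(lam eps0)) - c]/tau + D d2c/ds2
```

The saturation means unloaded margins contract no faster than
`eps0 (1 − exp(−lam))` — why cut halves do not contract faster than intact
embryos. The tension update is implicit (Newton) because its rate scales
as `1/(c Ts)` and stiffens where contractility is low. The computational
curve is resampled to uniform arclength every 0.5 h (Lagrangian nodes crowd
into the streak); material motion for kymographs is tracked by separate
passive markers.

`gamma` has two analytic parts: a positive annulus bump (extraembryonic
expansion) whose integral supplies a fraction `epiboly_accommodation` of the
edge-migration flux — the remainder is drawn from the epiblast and is the
epiboly-induced stretching — and a negative streak sink (ingression)
distributed along the posterior margin arc (angular Gaussian, sigma 0.9
rad). The distributed (rather than point) sink matters: it is the outlet
through which the conveyor of margin material converging into the streak is
absorbed; a point sink concentrates all contraction in its own footprint
and the distributed contracting domain never forms. It stands in for
convergent extension plus ingression, which this depth-averaged model does
not resolve.

### What the intact simulation does

With the calibrated defaults the intact disk maintains a single posterior
contracting domain occupying ≈ 0.34 of the margin (measured, as in the
imaging pipeline, as the interval between the extrema of the tangential
velocity), a triangular velocity profile, two counter-rotating vortices,
and anterior inhibition: margin material streams toward the streak, and the
resulting stretching of the anterior margin keeps its contractility
feedback subcritical. The model's homeostatic proportion (~0.34 by the
velocity measure) emerges from the calibration goals rather than being
fitted to the experimental 0.37 (which the 1D model is calibrated to).

### Initial conditions

Scenarios start at the experimental staging time — the onset of tissue
motion, when the posterior contractile domain already exists. The default
initial contractility is therefore an established two-level domain
(`bias_fraction` = 0.18 of the margin, the model's homeostatic proportion)
blended with a cosine tail (`bias_gradient` = 0.3) representing the
pre-existing posterior-to-anterior polarity; cables start below stall
inside the domain and slightly above stall (stretched, yielding) outside.
This deviates from a pure low-amplitude cosine bias: a cosine alone takes
many hours to develop the pattern, whereas experiments show stable
proportions from t0; and the graded tail is what seeds ectopic focus
nucleation at the posterior-most accessible position when tension
propagation is interrupted. A `bias_shape = "cosine"` option retains the
de-novo symmetry-breaking configuration.

### Perturbation scenarios

* **Bisection** (`anterior_half` / `posterior_half`): instantaneous — the
  mesh is replaced by the half-disk, the margin becomes an open arc, and no
  wound-healing term is added. With ongoing epiboly the half remains
  adherent, so the cut edge behaves as attached and margin tension
  re-anchors there; abrogating epiboly (the experimental ring cut) frees
  everything and clamps the cut-end tensions to zero. Bisected halves use
  `epiboly_accommodation_cut = 0`: the halved extraembryonic supply
  accommodates none of the maintained edge migration, so the remaining
  epiblast bears the full epiboly stretching.
* **Obstacle**: a band of 1e4-fold increased substrate friction, 0.1 mm
  wide (the ~100-µm hair), crossing the disk 0.5 mm anterior of centre
  (`"full"`) or only its upper half (`"half"`). The multiplier deviates
  from the nominal 100×: at 100× the margin line slides through the band
  with a tension drop of order 1e-3 of the margin tension and the obstacle
  does nothing measurable; 1e4 obstructs flow without arresting it.
* **Drugs**: H1152 scales `(c0, delta_c)` by 0.3 (weak contraction; the
  margin lengthens under epiboly); calyculin A scales `c0` alone by 1.6 —
  raising baseline myosin activity compresses the *relative* modulation, so
  contraction becomes more even and net flow drops; Ski-1 leaves mechanics
  untouched and disables the expression readout.

### The tension-propagation-range knob

The parameter varied ±20% in the one-sided-obstacle analysis is not named
in the main text; this package designates `range_scale`, which multiplies
the friction screening length `sqrt(mu/friction)` (effective friction
`friction0 / range_scale^2`) — substrate-friction reduction being one of
the two candidates the source analysis itself suggests. `friction0` is
calibrated so the defaults are marginal: the half-obstacle scenario forms a
weak ectopic focus anterior to the band, and a ~10% range increase (well
within 20%) suppresses it, while the intact run stays inhibited
indefinitely. The suppression is assessed on a 12-h window so that real
foci have matured and the classification is stable.

## Quantification pipeline (`kinematics`, `expression`)

Strain rates are Lagrangian — finite differences of log segment length over
the 6-min track cadence — rather than Eulerian velocity gradients; the two
agree for smooth flows and the Lagrangian form matches length-based
staging. Kymographs resample to 128 margin-coordinate bins (posterior = 0,
reported in mm and degrees) and smooth with fixed 3-frame × 3-bin moving
averages; the smoothing used for the published kymographs is unstated, so
these defaults are explicit and configurable. The contracting-domain size
is the arclength interval between the velocity extrema containing the
negative-slope region, ties broken to the shortest interval.
`integrated_contraction` is `log(final/initial length)` normalized by
`|log(1 − target)|` (targets 0.5 for halves, 0.6 for intact), so a segment
contracting by exactly the target scores −1. Staging
(`stage_by_contraction`) returns the first time a segment has shrunk by a
target fraction (20% cut trigger, 50%/60% endpoints), with `NA` as the
explicit not-reached signal.

Expression profiles integrate intensity across a 400-µm strip centred on
the margin and normalize with 5th/95th-percentile anchors (the operational
form of "~0 outside, ~1 inside"; exactly idempotent). The
contraction-to-expression readout `gdf1_readout` is phenomenological:
piecewise linear through the stated midpoint (χ = −1/4 ↦ 1/2), slope 1 on
the normalized-contraction axis (the linear band spans χ ∈ [−3/4, 1/4];
the slope is not printed in the source and is configurable), clipped to
[0, 1]. Domain sizes threshold at 1/2 (expression) and −1/4 (contraction);
the association between them is tested with a one-sided permutation test of
the Pearson correlation using the add-one estimator
`p = (1 + #{R_perm ≥ R_obs})/(n_perm + 1)`, seeded. The ectoderm (SOX3)
convention is `1 − readout`, flagged as an assumption.

## Synthetic data (`synthetic_truth`, `gen_margin_tracks`, ...)

The generators emulate what the analysis assumes and no more: margin nodes
on a circle moving under a piecewise-constant material strain-rate field (a
posterior arc contracting at `-rate`, the complement stretching at the
leading-order length-conserving rate — total length is conserved only as
t → 0, drifting a few % per hour by exponential convexity), 6-min frames
over 8 h (80 frames), additive Gaussian positional noise scaled to the
mean inter-frame displacement (tracking-error phenomenology; not velocity
noise). Expression images paint `gdf1_readout(chi)` in a band confined
within the quantification strip, blur it, and add background plus
shot-like noise. They do not emulate: curvature of real margins beyond a
circle, z-projection artefacts, segmentation failures, or advective
mixing — so a green recovery test establishes that the pipeline inverts
its own stated data model at realistic noise, not that it is robust to
arbitrary real-world imaging pathology.

## Known limitations

* The 2D homeostatic contracting proportion (~0.34 by the velocity-extrema
  measure) is an outcome, not a fit, and the attached-posterior-half
  scenario does not cleanly rescale to it: weak ectopic foci nucleate near
  the anchored cut ends, and similarly anterior halves with epiboly show
  two weak ectopic foci despite net stretching. The mechanism is that
  strain-rate feedback carries no inhibition from *static* tension: a
  region that is anchored but not actively stretched relaxes to its
  quiescent state, which is supercritical at the calibrated `beta`. The
  corresponding acceptance expectations are left failing and are recorded
  as model limitations rather than being weakened.
* No cell-level model, no 3D, no myosin biochemistry, no mechanistic
  epiboly or gene-regulatory network; Ski-1 is purely a readout switch.
* The flow solver's free-edge condition is the natural condition of the
  penalized operator (zero pseudo-traction), which differs from the exact
  Stokes traction at O(mu/kappa).
* Tie-breaks and degenerate inputs: zero strain rate counts as
  non-contracting; tied velocity extrema resolve to the shortest
  contracting interval; flat profiles raise errors rather than guessing.
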