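# marginflow

Self-organized tissue mechanics of embryonic regulation in the early avian
(quail) epiblast.

## What this package is for

During early avian gastrulation a supracellular actomyosin ring along the
embryo **margin** (the embryonic/extraembryonic boundary) contracts in its
posterior part and drives the tissue flows that build the primitive streak.
The embryo *regulates*: cut it in half, or block tension transmission with a
hair laid across the epiblast, and force generation, tissue motion and gene
expression (GDF1) are redirected — sometimes building complete ectopic
embryos. `marginflow` implements a mechanical account of this regulation and
the analysis pipeline used to quantify it, for researchers in tissue
biophysics and morphogenesis who want to simulate, perturb and measure these
models without any external data.

The core model: margin contractility `c` (or active tension `Ta` in 1D)
**locally self-activates** — contraction upregulates it, stretching
downregulates it —

```
dTa/dt = [ T0 (1 + ζ tanh(α + β (Ta − ⟨Ta⟩)/T0)) − Ta ] / τ + D ∂²Ta/∂s²,
ε̇(s) = (⟨Ta⟩ − Ta(s)) / ν,     ⟨ε̇⟩ = 0  (closed margin, uniform tension T = ⟨Ta⟩)
```

while the passive tension it induces propagates fast and far and acts as the
**long-range inhibitor**: a mechanical Turing system in the limit of an
infinitely fast, infinitely long-ranged inhibitor. Above the threshold
`β ζ sech²(α) > 1` the margin splits into a contracting and a stretched
domain whose proportions are restored after perturbations (front
homeostasis). The 2D model embeds the same feedback in a compressible-Stokes
tissue with substrate friction, an immersed viscoelastic margin line with a
saturating "walking kernel" (stall tension `c·Ts`, contraction-rate plateau),
and prescribed areal growth (epiboly, streak ingression).

Modules:

* **1D margin model** — `params_1d()`, `simulate_1d()`,
  `dispersion_growth_rate()`, `domain_fraction()`.
* **2D epiblast model** — `params_2d()`, `scenario_spec()` (intact,
  bisections, sectors, friction obstacles, drug presets),
  `simulate_scenario()`, `contraction_foci()`.
* **Kinematics** — `strain_rate_along_margin()` (kymographs),
  `contracting_domain_size()`, `integrated_contraction()`,
  `deformation_map()`, `stage_by_contraction()`.
* **Expression** — `quantify_profile()`, `gdf1_readout()`,
  `domain_size_by_threshold()`, `permutation_test_correlation()`.
* **Synthetic data** — `synthetic_truth()`, `gen_margin_tracks()`,
  `gen_expression_image()`, `gen_flow_fixture()`.
* **CLI & calibration** — `run_cli()`, `calibrate_defaults()`,
  `read_config()`/`write_config()`.

See the methods vignette (`vignettes/margin-mechanics.Rmd`) for the models,
parameter meanings, calibration rationale and known limitations.

## Worked example

```r
library(marginflow)

# 1D: linear instability and the patterned state
p <- params_1d()
dispersion_growth_rate(p, 1)      # growth rate of the k = 1 mode (1/h)
#> 0.37134
sim <- simulate_1d(p, "posterior_bias", t_end = 40)
domain_fraction(sim$states[[length(sim$states)]])
#> 0.3505859                       # contracting fraction ~ 0.37 at steady state

# 2D: intact embryo, 8 simulated hours on the default coarse mesh (~7 s)
traj <- simulate_scenario(scenario_spec("intact", t_end = 8),
                          record_every = 2, tracer_spacing = NA)
traj$summary[, c("time", "margin_length", "domain_fraction_velocity",
                 "mean_speed")]
#>  time margin_length domain_fraction_velocity mean_speed
#>     2      8.142372                0.3750134 0.09800854
#>     4      8.151706                0.3593907 0.09569208
#>     6      8.184235                0.3437632 0.09329448
#>     8      8.229932                0.3437627 0.09265217

# quantification on synthetic tracked data (PIV-like, 10% noise)
g <- gen_margin_tracks(synthetic_truth(fraction = 0.37, noise_sigma = 0.1,
                                       seed = 4))
contracting_domain_size(velocity_profile_from_tracks(g$tracks))$fraction
#> 0.3747159                       # truth 0.37 recovered within one bin
integrated_contraction(c(1, 0.5), target = 0.5)
#> -1                              # a segment halved in length scores exactly -1
```

Reading the numbers: the margin length stays near its initial 8.14 mm while
the contracting domain holds a stable ~0.34–0.37 of the margin over 8 h
(`domain_fraction_velocity` is the fraction between the tangential-velocity
extrema, the same measure used on tracked embryos); mean tissue speed is
~0.09 mm/h. The pipeline recovers a known synthetic contracting fraction to
within one margin-node bin at 10% tracking noise.

A command-line interface wraps the same operations:

```sh
Rscript -e 'marginflow::run_cli()' simulate-2d --scenario posterior_half \
    --boundary free --epiboly false --t_end 3 --out run1
Rscript -e 'marginflow::run_cli()' analyze --tracks run1/tracks.csv --out run1_analysis
```

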