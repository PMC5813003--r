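# poreperm

Permeation analysis for single-file membrane channels such as aquaporins,
working from particle trajectories in the channel frame — per frame and
molecule, the axial coordinate *z* (Å) and the radial distance *d<sub>xy</sub>*
from the channel axis.

Narrow channels conduct water in a near single-file chain. Two distinct
permeability coefficients characterise them at equilibrium:

- the **osmotic permeability** *p<sub>f</sub>* = *v*<sub>w</sub> *D<sub>n</sub>*,
  where *D<sub>n</sub>* is the diffusion coefficient of the collective
  permeation coordinate *n*(*t*), accumulated from
  d*n* = Σ<sub>i</sub> (*z<sub>i</sub>*(*t*) − *z<sub>i</sub>*(*t* − Δ*t*))/*L*
  over in-pore waters, with *D<sub>n</sub>* taken as half the slope of
  ⟨Δ*n*²(τ)⟩ over 50 < τ ≤ 1000 ps;
- the **diffusion permeability** *p<sub>d</sub>* = *v*<sub>w</sub> *q*₀, with
  *q*₀ the one-way rate of complete pore passages.

Their ratio *p<sub>f</sub>*/*p<sub>d</sub>* measures the effective number of
single-file steps. For slowly permeating solutes, a factorized kinetic
estimator replaces direct counting:

*p<sub>d</sub>* ≈ *v*<sub>w</sub> *k*<sub>w</sub>(*z<sub>l</sub>*; *z<sub>u</sub>*)
e^(*F*<sub>w</sub>(*z<sub>l</sub>*) − *F*(*z<sub>l</sub>*))
*p*(*z*₀ → *z<sub>l</sub>*) e^(*F*(*z<sub>l</sub>*) − *F*(*z*₀))
*f*(*z*₀ → *z<sub>u</sub>*),

built from boundary-crossing rates, splitting probabilities measured at
0.01 ps resolution, detailed balance, and bulk-referenced free-energy
profiles *F*(*z*) obtained either by counting molecules in bins along *z*
or by a 1D adaptive-weight-histogram (AWH) sampler with a dynamic harmonic
bias. Per-monomer profiles combine through a self-consistent exponential
average with jackknife errors. Structural statistics — geometric
hydrogen-bond detection (3.5 Å / 150° cutoffs), SF-region bonding
probabilities, gating-dihedral classification (open −94°, closed −35°,
±10°), and a conserved-contact monomer quality filter (< 4 Å for ≥ 90% of
frames) — round out the pipeline. A seeded overdamped Langevin simulator
of single-file pores supplies synthetic trajectories with exactly known
ground truth for every estimator.

## Worked example

Simulate a single-file pore with a wildtype-like landscape (four lower
minima spaced 2.5 Å, barriers 1–2 k<sub>B</sub>T, top barrier 2 k<sub>B</sub>T)
and estimate both permeabilities:

```r
library(poreperm)

model <- build_pore_model("wildtype_like")
model
#> <pore_model 'wildtype_like'>  6 wells, max barrier 2 kBT, D = 0.25 A^2/ps

params <- langevin_params(dt = 0.01, out_interval = 50, n_steps = 2e7,
                          seed = 1, n_particles = 14, single_file = TRUE)
traj <- simulate_langevin(model, params)   # a 200 ns channel-frame table
traj
#> # A tibble: 56,000 x 6
#>    time    id species monomer     z  d_xy
#>   <dbl> <int> <chr>     <int> <dbl> <dbl>
#> 1    50     1 water         0 -13.5 0.697
#> 2    50     2 water         0 -18.7 4.55
#> ...

pf <- osmotic_permeability(traj, segment_ns = 50)
pd <- diffusion_permeability(traj)
pf
#> <p_f_result>  p_f = 1.883 +/- 0  [1e-14 cm^3/s]  (n = 1 monomers)
pd
#> <p_d_result>  p_d = 0.3676 +/- 0  [1e-14 cm^3/s]  (n = 1 monomers)
permeability_ratio(pf, pd)
#> # A tibble: 1 x 2
#>   ratio    se
#> 1  5.12    NA
```

The ratio ≈ 5 is the effective single-file step count, consistent with the
~6 in-pore positions of the model. The free-energy profile recovered from
the same run tops out near the model's 2 k<sub>B</sub>T barrier:

```r
prof <- density_free_energy_1d(traj, "water")
glance(prof)
#> # A tibble: 1 x 6
#>   barrier bin_width source  n_bins n_masked traversals
#> 1    1.86      0.25 density    144        0         NA
autoplot(prof)
```

Result objects follow broom conventions (`tidy()` per monomer,
`glance()` for the headline number) and each result type has an
`autoplot()` method.

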