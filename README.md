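# pddrecon

Estimation of megavoltage photon energy spectra as functions of radial
distance from the beam central axis, by constrained unfolding of percentage
depth dose (PDD) curves against a monoenergetic depth dose (MDD) basis.

## Why

Flattened linac beams soften off-axis: the flattening filter preferentially
hardens the central axis, so the mean photon energy drops by ~20–25% between
the axis and an off-axis distance of 18 cm. Convolution dose algorithms that
carry a single central-axis spectrum across a 40 cm field miscalculate depth
dose and lateral profiles at the field edge. `pddrecon` recovers a separate
spectrum for every measured fan line from standard beam-scanning data, giving
beam modelers a laterally resolved spectral description without Monte Carlo
modeling of the treatment head.

## The method

Energies 0.05–7 MeV are discretized into 13 variable-width bins with
mid-energies E_i. A spectrum is the relative fluence vector p_i ≥ 0,
Σ p_i = 1. The forward model superposes monoenergetic depth doses D(E_i, d)
along the divergent fan line through surface radius r0 (interpolated on a
cylindrical dose grid at r(d) = (r0/SSD)(SSD + d)):

    PDD(d) = 100 · Σᵢ pᵢ D(Eᵢ, d) / Σᵢ pᵢ D(Eᵢ, d₁₀)

The unfolding minimizes the variance σ² of the per-depth relative difference
δ_j (%) between reconstructed and measured PDDs over a 2–25 cm window,
subject to unimodality of p about a scanned peak bin and, solving outward
radius by radius, an off-axis softening ordering (low-energy fluence may
only grow with radius, high-energy fluence only shrink). A normalization
substitution turns each candidate-peak subproblem into an exact convex
quadratic program, so results are deterministic and globally optimal per
candidate. Lateral fluence ratios w(r0) — the degree of freedom PDD shapes
cannot see — are fitted to measured off-axis ratio (OAR) profiles in closed
form. A synthetic beam generator (analytic MDD basis, ground-truth spectrum
families, seeded noisy scans) makes the whole pipeline testable closed loop.

See the methods vignette (`vignettes/pdd-spectrum-unfolding.Rmd`) for the
model, constraints, solver and design rationale.

## Worked example

Load the packaged reference spectra (unfolded 6 MV Elekta Versa HD beam,
40 × 40 cm², SSD 100 cm) and run a full closed-loop synthetic experiment:

```r
library(pddrecon)

fam <- reference_spectra_6mv()
fam
#> Spectrum family: 10 radii ( 0,  2,  4,  6,  8, 10, 12, 14, 16, 18 cm), 13 bins
round(sapply(fam$members, mean_energy), 3)
#>  [1] 2.309 2.333 2.255 2.187 2.075 1.972 1.866 1.794 1.618 1.572
```

The mean energy falls from 2.31 MeV on the axis to 1.57 MeV at 18 cm —
about a 32% drop, the off-axis softening the method exists to quantify.

```r
cl <- closed_loop(synthetic_beam_spec(seed = 1))
cl$result
#> Unfolded spectrum family
#>  r0     sigma2 peak_index iterations converged max_abs_delta
#>   0 0.05423168          6          1      TRUE     0.6140524
#>   2 0.04862628          6          1      TRUE     0.5505609
#>   4 0.04533065          5          1      TRUE     0.5224594
#>   6 0.07694556         11          1      TRUE     0.7239108
#>   8 0.05239393         10          1      TRUE     0.6334360
#>  10 0.07664068          9          1      TRUE     0.6804183
#>  12 0.10180473         10          1      TRUE     0.7566297
#>  14 0.04824983         10          1      TRUE     0.6641671
#>  16 0.03760716          8          1      TRUE     0.5051658
#>  18 0.07696529          9          1      TRUE     0.8258381
cl$max_abs_delta_pdd   # vs noise-free target PDDs, all radii and depths
#> [1] 0.2748412
cl$max_abs_delta_oar   # vs noise-free target OARs at 5/10/20 cm depth
#> [1] 0.2272132
```

`sigma2` and `max_abs_delta` in the table are measured against the *noisy*
scans (0.2% point noise); the headline numbers compare against the hidden
noise-free truth — both reconstructions agree within ±0.3%, comfortably
inside the ±0.5% the method is expected to deliver.

A thin command-line front end with verbs `synth`, `unfold`, `reconstruct`,
`oar` and `compare` ships at `inst/cli/pddrecon`
(`Rscript $(Rscript -e 'cat(system.file("cli","pddrecon",package="pddrecon"))') unfold --help-style flags ...`).

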