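---
title: "Unfolding off-axis photon spectra from percentage depth dose curves"
author: "pddrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unfolding off-axis photon spectra from percentage depth dose curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The photon spectrum of a flattened linac beam is not laterally uniform: the
conical flattening filter is thickest on the central axis, so rays leaving
the field edge traverse less filter material and keep more of their
low-energy component. The mean photon energy of a 6 MV beam falls by
roughly a fifth to a quarter between the central axis and an off-axis
distance of 18 cm. Convolution dose engines that assume a single
central-axis spectrum across a 40 cm field therefore miscalculate both
depth dose and lateral profiles at the field periphery — errors that matter
clinically for large-field treatments.

Direct spectrometry on a linac is impractical, and full Monte Carlo
modeling of the treatment head is slow and machine-specific. `pddrecon`
implements the pragmatic alternative: *unfold* the spectrum at each
off-axis position from quantities every clinic already measures — percentage
depth dose (PDD) curves scanned along divergent fan lines — using a
precalculated basis of monoenergetic depth dose (MDD) curves.

## Forward model

Energies between 0.05 and 7 MeV are discretized into $n$ bins with
mid-energies $E_i$ and widths $\Delta E_i$; the default 13-bin scheme
(`default_binning()`) narrows the bins at low energy where the water
attenuation coefficient — and hence the depth-dose shape — changes fastest.
A spectrum is the vector of relative fluences $p_i \ge 0$,
$\sum_i p_i = 1$. The PDD along the fan line through radius $r_0$ on the
surface is the fluence-weighted superposition of the monoenergetic curves,

$$
\mathrm{PDD}(d) \;=\; 100 \,
\frac{\sum_i p_i \, D(E_i, d)}{\sum_i p_i \, D(E_i, d_{10})},
$$

normalized at $d_{10} = 10$ cm (this avoids both electron contamination
near the surface and the positional uncertainty of the dose maximum; the
classical $d_{\max}$ convention is available through `norm_depth`). Bin
widths cancel because $p_i$ is already the per-bin fluence fraction. The
energy-fluence form used by TERMA-based dose engines is
$\Psi_i = p_i E_i$ (`psi_from_p()` / `p_from_psi()`), and the mean energy
is $\bar E = \sum_i \Psi_i$.

Fan-line geometry is handled explicitly: depths are measured parallel to
the central axis, and the divergent ray through $r_0$ crosses radius
$r(d) = (r_0/\mathrm{SSD})(\mathrm{SSD}+d)$ at depth $d$, where the
cylindrical MDD table is interpolated linearly in radius
(`resample_to_fanline()`).

## The inverse problem

The unfolding minimizes the variance of the per-depth relative difference
between reconstructed and measured PDDs,

$$
\sigma^2 = \frac{1}{m} \sum_{j=1}^{m} \delta_j^2,
\qquad
\delta_j = \frac{\mathrm{PDD}_\mathrm{recon}(d_j) -
                 \mathrm{PDD}_\mathrm{meas}(d_j)}
                {\mathrm{PDD}_\mathrm{meas}(d_j)} \times 100,
$$

over a fit window that excludes the buildup region (default 2–25 cm).
Because depth dose varies only weakly within a small energy interval, the
problem is severely ill-posed: the 13 basis curves are nearly collinear
and the unconstrained minimizer oscillates unphysically. Two families of
shape constraints restore a physical solution:

* **Unimodality.** $p$ must rise to a single peak bin $E_p$ and fall
  after it.
* **Off-axis softening.** Solving outward from the central axis, the
  fluence below the peak may only grow with radius and the fluence above
  the peak may only shrink, pairwise between adjacent radii and hence
  along the whole chain.

### An exact convex formulation

The objective is a ratio of linear forms in $p$ (the reconstruction is
renormalized at $d_{10}$). Substituting
$q = p / \sum_i p_i D(E_i, d_{10})$ makes the reconstructed curve
$100\,(Dq)_j$ *linear* in $q$, so $\sigma^2$ becomes an ordinary linear
least squares; every shape constraint, being scale-free in $p$, maps to a
homogeneous linear inequality in $q$. For each candidate peak bin the
subproblem is therefore a convex quadratic program with a unique global
minimum, solved exactly with `quadprog::solve.QP`. No random starts are
needed and results are bit-reproducible; a generic nonlinear solver with
multistart would add stochasticity without improving the optimum, which is
why the package does not use one.

The peak bin itself is found by exhaustive scan: each candidate from the
bin containing 0.5 MeV upward yields one QP, and the feasible candidate
with the smallest *evaluated* $\sigma^2$ wins, ties going to the lower
peak (`peak_scan` in `unfold_config()`).

### Scale handling: `profiled` (default) versus `pinned`

A measured PDD is normalized by its own reading at $d_{10}$ — a single
sample that carries the same noise as every other point. Forcing the
reconstruction through that exact value (the `pinned` objective, i.e. the
equality $\sum_i q_i D(E_i,d_{10}) = 1$ inside the QP) converts
normalization noise into a correlated offset that the fit absorbs by
tilting the spectrum, biasing the recovered curve at the window edges. The
default `profiled` mode instead treats the overall curve scale as a
nuisance parameter — the homogeneous $q$ is left free, the QP profiles the
scale out, and the reconstruction is renormalized afterwards. On synthetic
beams with 0.2% point noise this roughly halves the worst-case deviation
from the noise-free truth. The `pinned` mode remains available and is the
exact minimizer of $\sigma^2$ as written above; it is the mode the test
suite compares against a brute-force simplex grid search.

### Sequential and joint modes

The default `sequential` mode mirrors the practical workflow: solve the
central axis first, then each radius outward with its inner neighbour's
spectrum as the softening bound — the pairwise bounds enforce the full
ordering chain transitively. The `joint` mode refines the sequential
solution by block-coordinate descent, re-solving each radius under bounds
from *both* neighbours (peak bins held fixed) until the summed objective
stops decreasing; each block is again an exact QP. The two modes generally
return different fluence vectors — the problem is underdetermined — but
agree in PDD space, which is the quantity the method is accountable for.

## Numerical choices

* **Conditioning.** Columns of the least-squares design are equilibrated
  to unit norm (an exact reparametrization), and a Tikhonov ridge of
  $10^{-9}$ on the unit-scaled Gram matrix makes the factorization
  well-posed; the ridge lives in the numerically null directions of the
  objective and shifts the achieved $\sigma^2$ by far less than solver
  tolerance. If the active-set solver still reports a spurious
  inconsistency on degenerate constraint sets (tied fluences produce
  duplicate rows), the ridge is escalated ($10^{-7}$, then $10^{-5}$)
  before a candidate peak is declared infeasible. Constraint rows are also
  normalized to unit length.
* **Feasibility.** Every returned spectrum is re-checked against its
  constraint set within `tol_feasibility` ($10^{-8}$); an infeasibility
  across all scanned peaks raises an error naming the radius rather than
  returning a silently unconstrained fit.
* **Ties and degenerate inputs.** Peak-scan ties resolve to the lower
  bin; a single-energy basis short-circuits to $p = (1)$; an all-zero
  spectrum, a zero superposed dose at the normalization depth, or a
  measured zero inside the fit window raise typed errors.
* **Resampling.** Measured curves are linearly resampled onto the basis
  depth grid before comparison, making the contracts grid-agnostic.
* **Extrapolation.** Fan lines through large $r_0$ leave the scored
  cylinder at depth (at $r_0 = 18$ cm beyond ${\sim}19.4$ cm depth for a
  21.5 cm outermost annulus); the basis is clamped to its outermost
  column with a warning by default, or extrapolated linearly when the
  geometry is built with `extrapolation = "linear"`. Clamping avoids
  inventing dose outside the scored region.
* **Depth convention.** Scoring bins 2 mm wide are represented by their
  outer edge (0.2, 0.4, … cm); annular scoring regions by the single
  representative radii 1.5–21.5 cm, the central axis by radius 0.

## The synthetic beam generator

Real commissioning inputs — Monte Carlo MDD tables and water-phantom
scans — cannot ship with a package, so `pddrecon` generates both from a
transparent analytic model, and the whole pipeline is validated closed
loop against a known ground truth.

* `analytic_mdd()` builds each monoenergetic curve as
  buildup $\times$ exponential attenuation $\times$ inverse-square
  divergence: $\kappa(E)\, e^{-\mu(E)d} (1-e^{-\beta(E)d})
  \left(\tfrac{SSD+10}{SSD+d}\right)^2$ with
  $\beta(E) = \ln(20)/\max(0.05,\,0.25E)$ cm$^{-1}$. The buildup term is a
  deliberate cartoon of secondary-electron range growth; what matters for
  the unfolding is only that $\mu(E)$ is smooth and strictly decreasing,
  so normalized curves penetrate more at higher energy. The built-in
  attenuation table holds approximate water coefficients; a parametric
  fallback $\mu(E) = 0.0707 E^{-0.35}$ cm$^{-1}$ is equivalent for every
  closed-loop purpose.
* `generate_true_family()` draws a discretized log-normal fluence bump
  (default mode 1.8 MeV, log-width 0.55 — a plausible flattened 6 MV
  shape) and softens it outward by a mass-conserving downward-transport
  kernel (rate `softening_rate` per cm, default 0.05, lowering the mean
  energy by roughly a quarter from the axis to 18 cm). The kernel
  preserves unimodality and satisfies the softening ordering *by
  construction*, so the ground truth is exactly feasible — and
  `project_softening()` is the identity on it.
* `synth_measured()` produces the "measured" scans: forward-model PDDs
  per radius and lateral profiles at 5, 10 and 20 cm with a gentle horn
  fluence profile $w(r_0) = 1 + 0.03 (r_0/20)^2 - 0.02 (r_0/20)^6$,
  perturbed by seeded multiplicative Gaussian noise (default 0.2%,
  typical scanning-chamber repeatability) and renormalized; noise-free
  twins are returned for evaluation.

What the generator does **not** emulate: charged-particle contamination
in the buildup region (which is why the fit window starts beyond the dose
maximum), phantom-scatter tails outside the scored cylinder, spectral
contamination from collimator scatter, and any claim of dosimetric realism
in $\kappa$ and $\mu$. Closed-loop success therefore demonstrates that the
estimator inverts its own forward model under realistic noise and
ill-conditioning — the inverse-problem claim — not that any specific linac
spectrum is reproduced.

## Off-axis ratios

PDD shapes constrain spectral *shape* per fan line but not the relative
fluence *magnitude* between fan lines. That lateral degree of freedom is
the per-radius fluence ratio $w(r_0)$, fitted to measured lateral profiles
at several depths. Because $w$ enters the computed profile linearly, the
least-squares solution per radius is closed form: with
$t_d = \mathrm{OAR}_{\mathrm{calc},w=1}(r_0,d)/\mathrm{OAR}_\mathrm{meas}(r_0,d)$,
$w = \sum_d t_d / \sum_d t_d^2$. One ratio is shared across depths by
default — a fluence ratio is depth-independent physics, and sharing makes
three-depth agreement a real test; a `per_depth` variant exists for
diagnostics. The fitted $w$ absorbs whatever lateral scale the
underdetermined spectra leave over, so $w$ itself is not compared with the
generator's horn profile — the lateral dose agreement is.

## Problem sizes and validation

The test suite and acceptance script run entirely on generated data:

* the full closed loop uses the standard grid (13 energies × 22 radii ×
  125 depths), 10 fan lines at 0–18 cm, 0.2% noise, and checks the
  reconstructed PDDs against the noise-free targets within ±0.5% over the
  2–25 cm window, and lateral profiles at 5/10/20 cm within ±0.5% after
  the fluence-ratio fit;
* optimizer correctness is cross-checked against an independent
  brute-force enumeration of the 0.01-step probability simplex on 3-bin,
  6-depth toys (pinned mode, which shares the oracle's objective);
* generator properties (unimodality, exact softening ordering,
  monotonically non-increasing mean energy) are asserted over 100 seeded
  parameter draws;
* the packaged reference table of unfolded 6 MV Versa HD spectra is
  ingested, renormalized and summarized (central-axis mean energy
  2.31 MeV) as an end-to-end format check.

## Known limitations

* Spectra are *relative* per radius; no absolute fluence calibration is
  carried anywhere, and cross-radius magnitude lives entirely in the
  fitted fluence ratios.
* The recovered fluence vector is one member of a near-flat set: two
  spectra differing along poorly identified directions can reproduce the
  same PDD to within measurement noise. Conclusions should be drawn from
  reconstructed dose quantities, mean energies, or explicitly
  regularized summaries — not from individual bin values.
* Buildup-region data (depths below the fit window) never constrain the
  fit; spectra say nothing about electron contamination.
* The softening ordering is enforced pairwise outward; a beam that
  genuinely hardens off-axis (e.g. flattening-filter-free with unusual
  filtration) would need the constraint chain disabled, which the current
  interface does not expose.
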