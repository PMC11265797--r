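---
title: "Methods: free-energy landscapes, titration and thermodynamic cycles for alternating-access transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy landscapes, titration and thermodynamic cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feltools)
```

This vignette is the package's own account of the science behind its
functions: the models and estimators, their assumptions, the tunable
parameters with their defaults and units, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The scientific setting

Secondary-active peptide transporters of the SLC15 (POT) family move
substrate against its gradient by symporting protons. Structurally they are
two six-helix bundles whose relative motion opens either an extracellular or
an intracellular gate, cycling outward-facing (OF) → occluded (OCC) →
inward-facing (IF). Two questions dominate the computational analysis of
such a cycle: *which protonation states tilt the conformational free-energy
landscape in which direction*, and *how is proton movement coupled to
substrate binding*. The corresponding analysis artifacts are 2D potentials
of mean force (PMFs) over gating collective variables in different
protonation states, pKa values of gating residues with and without
substrate, and absolute binding free energies (ABFE) that close
thermodynamic cycles linking the two.

All internal units are nm, ps and kcal/mol; force constants given in
kJ mol⁻¹ unit⁻² (the MD-engine convention) are converted with 1 kcal =
4.184 kJ exactly; kB = 1.987204259×10⁻³ kcal mol⁻¹ K⁻¹ and the default
temperature is 310 K, giving kT = 0.616 kcal/mol and RT ln 10 = 1.4186
kcal/mol per pKa unit.

## Gate collective variables

The extracellular and intracellular gates are quantified as inter-bundle
centre-of-mass distances: the *tip* CV between the extracellular ends of the
N- and C-terminal bundles and the *base* CV between their intracellular
ends. `builtin_gate_cvs()` carries the canonical residue intervals — six
12-residue helical segments per bundle selection, 72 Cα atoms per group.
The COM is mass-weighted; over Cα-only selections all masses are equal, so
this coincides with the geometric mean, but the choice matters for custom
selections that mix elements. Within a bundle the tip and base selections of
the two different CVs share a few residues (120–121 and 227–228) — that is a
property of the printed intervals and is permitted, since the overlapping
groups never feed the same CV.

`contact_fraction()` reports the fraction of frames in which the minimum
distance between two selections is at most a cutoff. The default cutoff is
0.4 nm, a common salt-bridge criterion between polar heavy atoms; the
underlying study reports occupancy percentages without stating a cutoff, so
this is a package choice and it is configurable.

## The synthetic-data generator

Every downstream analysis is validated against data with known ground
truth, generated by `langevin_sample()`: overdamped (Brownian) dynamics

$$x \leftarrow x - D\beta\,\nabla(U + b)\,\Delta t + \sqrt{2D\Delta t}\,\xi,
\qquad D = kT/\gamma,$$

on analytic surfaces (harmonic; quartic double-well with barrier $h$ and
minima $\pm a$; Gaussian-basin mixtures with harmonic confinement). Inertia
is deliberately absent: WHAM and the titration/ABFE estimators consume
equilibrium *distributions*, not kinetics, and overdamped dynamics reach the
Boltzmann distribution with the fewest parameters. The generator emulates:

* harmonically restrained umbrella windows on 1D/2D landscapes with basins
  and barriers of a few kcal/mol, including the pooled two-tier,
  24-centre × 2-tier × 3-replicate (144-window) design in which a softer
  force-constant tier covers basins and a stiffer one bridges transition
  regions;
* two-state protonation traces per pH replica from a Markov chain with the
  Henderson–Hasselbalch stationary law and a prescribed autocorrelation
  time;
* replicate transition-path ensembles displaced along a planted orthogonal
  unit direction, the statistical structure that the CV optimizer is built
  to detect;
* forward/reverse alchemical work samples from the unique Gaussian pair
  satisfying the Crooks relation for a planted ΔG
  ($W_F \sim N(\Delta G + \beta\sigma^2/2, \sigma^2)$,
  $W_R \sim N(-\Delta G + \beta\sigma^2/2, \sigma^2)$).

What it does **not** emulate: atomistic degrees of freedom, membrane and
lipid environment, replica-exchange kinetics, force-field error, or slow
orthogonal relaxation (hysteresis). Passing tests therefore demonstrate that
the *estimators* are correct and internally consistent on data satisfying
their assumptions — not that any particular MD campaign is converged.

Numerical cautions: the Euler–Maruyama update inflates the sampled variance
of a harmonic mode with stiffness $k$ by a factor $2/(2 - k\Delta t/\gamma)$,
so timesteps are chosen per force-constant tier to keep $k\Delta t/\gamma
\lesssim 0.05$ (hence `make_umbrella_campaign()` accepts per-tier
`langevin_params`); a single step larger than `max_step` (default 1 CV unit)
aborts with advice to reduce the timestep. The first 10% of each run is
discarded as burn-in (configurable). All stochastic functions take explicit
seeds and R's RNG drives the compiled samplers, so every run is reproducible.

The stock 2D fixture `stock_transporter_surface()` has three Gaussian basins
along the first CV with planted offsets (0, +3, +2) kcal/mol at the basin
centres and barriers of a few kcal/mol — the scale of transporter
conformational landscapes. These numbers are fixtures with known truth, not
claims about any protein; the exact 1D reference against which recovery is
judged is the numerically marginalized Boltzmann profile from `exact_pmf()`,
whose basin offsets (≈2.0 and ≈1.9 kcal/mol after marginalization) differ
from the 2D centre values because the confinement contributes entropy.

## Optimizing the second collective variable

When replicate transition paths disagree, the disagreement identifies a slow
orthogonal degree of freedom that a 1D CV misses. PCA of the pooled path
frames (optionally after Kabsch superposition, the conventional trajectory
PCA pre-processing — two fit passes to a converged mean shape) gives the
main transition motion as PC 1. The orthogonal direction is found by
maximizing the entropy-like separation metric over unit combinations
$v = \sum_k w_k \mathrm{PC}_k$ of PCs 2–16:

$$M(w) = \frac{2}{N_{\mathrm{rep}}(N_{\mathrm{rep}}-1)}
\sum_{i<j}\sum_{n=1}^{N_{\mathrm{win}}} \log d^2(n, i, j).$$

Two readings of $d^2$ are implemented, because the defining prose and the
defining formula of this metric genuinely differ: the default scalar
projection $d^2 = (v\cdot\Delta x)^2$ onto the single combined direction,
and a per-PC weighted sum $d^2 = \sum_k (w_k\,\mathrm{PC}_k\cdot\Delta x)^2$
behind `mode = "per_pc"`. Both are tested; neither is asserted as uniquely
correct.

Numerical choices worth recording:

* **log floor.** $d^2$ is floored at $\varepsilon = 10^{-12}$ (CV units²)
  before the log; coincident frames otherwise produce $-\infty$.
* **Scale covariance.** Scaling $w$ shifts $M$ by a constant, so the
  optimization is over directions. Candidates are normalized *inside* the
  objective: on a bounded search box the covariant term otherwise rewards
  the largest attainable norm and drags the search into box corners.
* **Optimizer.** A compact rand/1/bin differential evolution (population
  15 × dimension, weights in [−1, 1], F = 0.8, CR = 0.9, default seed 2024)
  followed by an L-BFGS-B polish of the winner — the standard finishing step
  of reference DE implementations, needed here because the log-metric is
  extremely flat near its maximum. Non-finite candidates are rejected.
* **Sign.** $M(w) = M(-w)$; the returned weights are canonicalized so the
  largest-magnitude weight is positive.
* PC 1 is excluded from the candidate set by construction, so the optimized
  direction never contaminates the main transition coordinate.

## WHAM, projection, alignment, convergence

`wham()` solves the standard self-consistent equations on a fixed grid
(defaults 72 bins in 1D, 48×48 in 2D):

$$P(\xi) \propto \frac{\sum_i n_i(\xi)}{\sum_j N_j e^{\beta(f_j - b_j(\xi))}},
\qquad f_j = -kT \ln \sum_\xi P(\xi)\, e^{-\beta b_j(\xi)},$$

iterated until $\max_j |\Delta\beta f_j| < 10^{-7}$ (cap $10^5$ iterations) —
tighter than the statistical noise at any problem size used here. Binned
WHAM (rather than a binless estimator) is the deliberate choice because it
is the method named for this class of data. Replica-exchange structure is
ignored: samples are treated as window-labelled equilibrium draws, the
standard WHAM treatment of replica-exchange umbrella output. Heterogeneous
force constants and pooled tiers/replicates need no special handling — each
window enters only through its own bias. Zero-count bins are masked
undefined and carry +∞ semantics (zero probability) through every downstream
operation. Disconnected window-histogram components trigger a warning
listing the components, since only relative offsets within a component are
determined. PMFs are defined up to additive constants; only *responses* of a
landscape to changed conditions are meaningful, never absolute basin
placement.

`project_pmf()` computes the Boltzmann-reweighted marginal
$F_1(x) = -kT\ln\sum_y e^{-\beta F_2(x,y)}\Delta y$ over defined bins.
`align_pmf()` fixes the additive constant either by least-squares against a
reference curve over co-defined bins (used for convergence analysis) or by
zeroing the mean over an explicit CV region (used to pin a reference state;
the region bounds are always explicit configuration, since "the reference
state" has no universal definition on a synthetic axis).

`convergence_band()` recomputes the full pipeline with the first 40%, last
40% and 100% of each window's samples — truncation acts per window on the
time axis, the only reading consistent with replica-exchange data — aligns
the partial curves to the 100% result, and reports the per-bin min/max
envelope. The 100% curve lies inside the band by construction; a narrow band
(the tests require ≤ 0.15 kcal/mol median on stationary data) indicates
stationary sampling.

`basin_barrier_report()` reads minima and saddle heights off a (optionally
moving-average smoothed) 1D profile. Only interior local minima count — the
lowest bin of a monotone profile is not a basin — and a `min_prominence`
filter iteratively removes minima whose smallest flanking barrier (relative
to the shallower of the adjacent pair) is below threshold, which suppresses
sampling-noise wiggles at sparsely visited grid edges.

## Titration analysis

Constant-pH simulation output is reduced to per-pH deprotonated fractions
and fitted to $f(\mathrm{pH}) = 1/(1+10^{\,n(\mathrm{p}K_a - \mathrm{pH})})$
by bounded least squares (pKa constrained to [min pH − 2, max pH + 2]). The
deprotonated-fraction convention — the curve *rises* with pH — is fixed
throughout the package. The Hill coefficient defaults to 1 (single-site
residues) and is fitted only on request, for coupled-site synthetic tests.
All-0 or all-1 fraction tables are rejected as unidentifiable; in chunked
analysis (`chunked_pka()`, default mirror of 10 ns convergence chunks) such
chunks are skipped and counted rather than clamped, because clamping would
fabricate histogram mass at the pH-range edges. Replicate summaries use the
sample (n−1) standard deviation.

The bimodality screen on chunk histograms is a 2-means split with an
Ashman-style separation $D = |m_1-m_2| / \sqrt{(s_1^2+s_2^2)/2}$, flagged at
$D > 4$ with both clusters ≥ 15% populated. The threshold sits well above
the $D \approx 2.7$ that a 2-means split of a *unimodal* Gaussian produces;
this is a deliberate lightweight screen, chosen over a formal dip test to
keep the dependency surface minimal, and it is documented as such.

pKa shifts convert to protonation free energies as
$\Delta\Delta G = -RT\ln 10\cdot\Delta\mathrm{p}K_a$ (−0.851 kcal/mol for a
+0.6-unit shift at 310 K); the sign convention — positive shift means more
favourable protonation — is stated once here and used consistently by the
cycle builder, to prevent double negation.

## Free-energy estimators and cycle assembly

`bar_estimate()` solves the Bennett self-consistency by root finding; the
root always exists, so lack of overlap is detected from the Fermi weights at
the solution collapsing to 0/1, and one-sided input falls back to
exponential averaging with a warning. The SD is the asymptotic Bennett
variance. `ti_estimate()` is trapezoidal quadrature over the λ schedule with
SEMs propagated through the trapezoid weights.

The ligand-side restraint term uses the closed-form standard-state free
energy of six harmonic Boresch restraints in the stiff-spring (Gaussian)
limit:

$$\Delta G = -kT\ln\!\left[\frac{8\pi^2 V^\circ}
{r_0^2 \sin\theta_A \sin\theta_B}\,
\frac{\sqrt{k_r k_{\theta_A} k_{\theta_B} k_{\phi_A} k_{\phi_B} k_{\phi_C}}}
{(2\pi kT)^3}\right],$$

with $V^\circ = 1.660539$ nm³ (1 M standard state). The value is negative
for stiff restraints — it is the *release* direction, restrained dummy →
free ligand at standard volume — and the tests validate it against direct
numerical quadrature of the restrained configurational integral rather than
trusting the transcription.

`assemble_abfe()` uses one documented sign table: (+) complex legs
(restrain, then annihilate coulomb and vdw in the complex), (−) ligand legs
(annihilate the free ligand), (+) the analytic release term; the sum is
ΔG_unbind at standard state, reported as a positive "affinity" with
ΔG_bind = −affinity. The canonical λ schedules ship as a preset
(`abfe_lambda_presets()`): 13 restraint points concentrated near 0, coulomb
at even 0.1 spacings, vdw at even 0.05 spacings. Cycle edges are signed and
oriented; `cycle_closure()` validates that the edges form a single closed
loop and returns the oriented sum with root-sum-square error — the stated
error rule for cycle residuals.

## Problem sizes and what the tests show

The test and acceptance suites run at desk scale by design: 24 windows ×
2×10⁴ samples for the 1D double-well oracle, 144 windows × ~3,200–4,000
samples for the 2D three-basin pipeline, 10⁵ frames × 8 pH replicas for
titration recovery, 400 work samples per alchemical interval. At these sizes
the pipelines recover analytic truth with ~0.05–0.1 kcal/mol RMSD, planted
directions with cosine > 0.99, pKa values to ±0.02 and planted affinities
within one propagated SD. Known limitations: no MBAR/decorrelation-based
uncertainties on PMFs (convergence bands are the provided diagnostic), no
periodic CVs (gate distances and PC projections are aperiodic), no kinetics,
and the synthetic generator's idealizations listed above.
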