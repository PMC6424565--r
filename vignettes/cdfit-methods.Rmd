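---
title: "Correlation-driven density fitting: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-driven density fitting: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdfit)
```

## The refinement problem

Cryo-EM reconstructions deliver a three-dimensional density map; turning a
map into an atomic model requires moving an initial structure — often a
crystal structure in a different conformational state, or a homology model —
until it explains the density while remaining stereochemically sound.
`cdfit` implements the correlation-driven approach to this problem at desk
scale: the model is evolved by molecular dynamics under its force field
plus a single global biasing potential that rewards agreement between the
experimental map and a density simulated from the current coordinates.

## The biasing potential

A simulated density is produced by convolving the atomic positions with an
isotropic Gaussian of width $\sigma$:

$$\rho_\mathrm{sim}(\mathbf{r}) \;=\; \sum_{i \in \text{fit mask}} w_i
  \exp\!\left(-\frac{|\mathbf{r}-\mathbf{x}_i|^2}{2\sigma^2}\right),$$

with amplitudes $w_i$ proportional to the atomic number by default (heavier
atoms scatter more; a uniform mode exists for toy systems). The kernel is
deliberately *unnormalized* — the correlation coefficient below is invariant
under uniform rescaling of either map, so a $(2\pi\sigma^2)^{-3/2}$
prefactor would be unobservable; omitting it keeps the blur-semigroup
property cleanly testable. The kernel is truncated on a sphere of radius
$4\sigma$ (relative amplitude $e^{-8} \approx 3.4\times10^{-4}$), which
makes spreading linear in the atom count with an error far below map noise.

Agreement is measured by the real-space correlation coefficient over *all*
voxels of the (trimmed) experimental box,

$$\mathrm{c.c.} \;=\;
  \frac{\sum_v \rho_\mathrm{exp}(v)\,\rho_\mathrm{sim}(v)}
       {\sqrt{\sum_v \rho_\mathrm{exp}^2(v)\,\sum_v \rho_\mathrm{sim}^2(v)}},$$

*without* mean subtraction: the cosine form uses the full density
information, including negative densities, which contribute with their
sign. A Pearson (mean-subtracted) variant is available behind a flag but is
not the default. The biasing potential and its forces are

$$V_\mathrm{fit} = k\,(1 - \mathrm{c.c.}), \qquad
  \mathbf{F}_i = -\nabla_{\mathbf{x}_i} V_\mathrm{fit},$$

with the gradient taken analytically through the correlation quotient: both
the cross term (pulling atoms toward experimental density) and the
simulated-map normalization self-term contribute, so even an atom far from
any experimental density feels a force through the normalization. The force
constant $k$ (kJ mol$^{-1}$) sets the weight of $V_\mathrm{fit}$ relative
to the force field. The analytic gradient is validated against central
finite differences (max relative error $<10^{-4}$, typically $\sim10^{-9}$)
and against an untruncated brute-force double loop on small instances.

Degenerate inputs raise rather than return silently: zero-norm maps (the
correlation is undefined), empty fit masks, non-positive $\sigma$, and
denominators below $10^{-30}$.

## Adaptive resolution and the staged protocol

Fitting directly at the map's full resolution traps the model in local
minima of a rugged correlation landscape. The protocol therefore ramps
*only the simulated density* from very smooth to the target width while the
full experimental density is used throughout:

* $\sigma$ starts at 0.6 nm and $k$ at $0.5\times10^5$ kJ mol$^{-1}$; both
  are held for the first 3/50 of the training stage and then ramped
  linearly to $\sigma_\mathrm{stop}$, $k_\mathrm{stop}$.
* $\sigma_\mathrm{stop}$ is determined by scanning $\sigma$ from 0.6 to
  0.1 nm in 0.01 nm steps against the target map and taking the argmax of
  the correlation (ties break toward the larger, smoother width).
* Stage 1 refines against a *training* half-map in one of three
  temperature incarnations — 100 K for 50 time units, 150 K for 30, or
  200 K for 20 — cross-validating every 5 units (below). Lower-temperature
  incarnations are slower but less prone to overfitting on noisy maps.
* Stage 2 swaps in the full reconstruction for 15 units of simulated
  annealing (rapid heating to a 300 K peak within 1 unit — a 500 K / 3 unit
  variant exists — then cooling) plus 5 units at the stage temperature.
  $\sigma$ and $k$ are held constant and $k$ is never increased here,
  because no validation map remains to control overfitting. The cooling
  functional form is not prescribed by the protocol's sources; linear
  cooling was chosen as the simplest monotone interpolant.
* The final model is the unweighted coordinate average over the trailing
  5 units. No superposition is applied before averaging: the map frame
  anchors the model. Averaging over the window reduces the positional
  scatter below any single snapshot's.

Times are "toy picoseconds": the published nanosecond-scale protocol maps
onto the desk-scale engine 1 ns $\to$ 1 ps with every ratio (hold:ramp,
annealing:final) preserved. The schedule shapes, not the absolute times,
carry the method.

## Half-map cross-validation and the overfitting detector

Refining atomic coordinates against a noisy map can push atoms into noise.
Following standard practice, stage 1 trains against one half-map and
validates against the other: every 5 units the current snapshot is stripped
of waters, ions and hydrogens, spread at $\sigma_\mathrm{stop}$ (even while
the live $\sigma(t)$ is larger), and its Fourier shell correlation against
both half-maps is computed. The divergence score is the *one-sided* mean
gap $\overline{\max(0, \mathrm{FSC}_\mathrm{train} -
\mathrm{FSC}_\mathrm{val})}$ — one-sided because overfitting inflates the
training-map agreement specifically — flagged above a threshold of 0.05.
The score can be capped at the map's nominal resolution
(`crossval_smax`); by default all shells up to Nyquist contribute, which on
the synthetic fixtures gives the flag its best contrast between
noise-chasing and honest refinement. If the final training-stage record is
flagged, the report recommends the latest unflagged snapshot — a structure
at a lower force constant from the same trajectory — and stage 2 proceeds
from it; remediation is advisory rather than an automatic re-run, keeping
every run deterministic and auditable.

FSC is computed as the real part of the normalized cross-spectrum in
shells of $|\mathbf{q}|$ (physical units, so anisotropic voxels are
handled), shell width one frequency voxel of the largest axis, DC excluded,
shells ending at the smallest-axis Nyquist. The nominal resolution is the
linearly interpolated first downward crossing of 0.143, and
$\mathrm{FSC}_\mathrm{avg}$ is the trapezoidal mean of the curve between
$1/100\,\text{Å}^{-1}$ and the nominal resolution.

When no half-maps exist, a sweep of independent full-map refinements over a
range of force constants stands in: per $k$ the final correlation,
$\mathrm{FSC}_\mathrm{avg}$ and geometry diagnostics (RMS bond/angle
deviations) are tabulated and the smallest $k$ within 1% of the best
correlation with acceptable geometry is selected. Published guidance on
choosing $k$ is qualitative (roughly 10% of the total system energy, with
instability at 15–20%); the energy ratio
$V_\mathrm{fit}/(V_\mathrm{fit}+|V_\mathrm{ff}|)$ is reported as a
diagnostic, but selection uses the operationally testable
correlation/geometry rule.

## The desk-scale engine

The full method couples the biasing potential to an all-atom force field in
a production MD engine. For a desk-scale, fully testable artifact, `cdfit`
substitutes a minimal bonded force field — harmonic bonds and angles plus a
soft-core repulsion $\varepsilon(1 - r/r_\mathrm{min})^2$ between
non-bonded pairs — and a Langevin integrator with BAOAB splitting. BAOAB
was chosen over extended-system thermostats because it is simple, ergodic
for small systems, and exact at $T = 0$, which makes the determinism and
zero-temperature contracts directly testable. Defaults: 12 amu masses,
friction 5 ps$^{-1}$, time step 0.002 ps against default bond stiffness
(a warning fires when the step exceeds a tenth of the stiffest bond
period). There is no pressure coupling — without solvent, a barostat is
meaningless — and no constraints or virtual sites. The *only* coupling
surface between engine and potentials is the force-provider contract:
`function(coords, time) -> list(energy, forces, ...)` in kJ mol$^{-1}$ and
kJ mol$^{-1}$ nm$^{-1}$; the fitting potential and the toy force field are
interchangeable plug-ins, and an external engine could implement the same
contract. Model coordinates are stored in nm, map grids in Å (the file
convention); the factor of 10 is applied in exactly one place.

Instability — non-finite coordinates or energy — aborts with a condition
carrying the step and time context; the command-line layer maps it to exit
code 2.

## Synthetic fixtures: what they emulate and what they do not

All tests run on generated data. The standard fixture is a 20-atom helical
polymer (bond length 0.38 nm, the C$\alpha$ virtual bond; stiffnesses
$5\times10^4$ kJ mol$^{-1}$ nm$^{-2}$ and 400 kJ mol$^{-1}$ rad$^{-2}$,
chosen in the range of coarse-grained protein models) built exactly at
mechanical equilibrium, spread at $\sigma_\mathrm{true} = 0.2$ nm onto a
$24^3$ grid of 2 Å voxels. Half-maps add independent Gaussian noise scaled
to the ground-truth RMS; the full map is the half-map average (a deliberate
simplification — real full maps are independent reconstructions). White
noise is the default; a band-limited option (grid-smoothed to a chosen
correlation length) exists because voxel-correlated noise is what a model
can physically chase, which the overfitting controls exploit. The noise
model is not frequency-colored like real half-map noise, there is no CTF
or image-formation model, and the toy force field has no torsional or
electrostatic structure: passing tests demonstrate the correctness of the
fitting machinery, schedules and detectors, not force-field-quality
refinement of real proteins.

Perturbations for recovery experiments are either chain-correlated random
displacement fields rescaled to an exact target RMSD (emulating thermal
drift away from the target state) or rigid hinge rotations of half the
chain (emulating domain motions), with the rotation angle solved so the
RMSD matches the request.

## Study conditions exercised by the test suite

The suite runs the full protocol at deliberately modest problem sizes so
that everything completes on one CPU in minutes; sizes are stated here as
the package's chosen study conditions:

* *Recovery*: the standard fixture perturbed to RMSD 0.6 nm
  ($= 3\sigma_\mathrm{stop}$), refined with the 100 K / 50-unit incarnation
  at $k_\mathrm{stop} = 3\times10^5$ (the published optimum range), recovers
  to RMSD $< 0.05$ nm with final c.c. $> 0.99$ at a fixed seed.
* *Overfitting controls*: a 40-atom chain — the longer chain supplies the
  excess degrees of freedom that make overfitting expressible, mirroring
  how side-chain-level capacity drives overfitting in real refinements —
  against half-maps with band-limited noise at 1.5$\times$ the signal RMS
  on a $32^3$ grid. An oversized $k_\mathrm{stop} = 1\times10^7$ must flag
  the final-stage divergence while $k_\mathrm{stop} = 1\times10^5$ must
  not, with the dynamics seed shared so only the force constant differs.
  The 100 K incarnation is used — the low-temperature protocol is the one
  recommended for very noisy half-maps.
* *Force-constant sweep*: the standard chain with a lower-resolution map
  ($\sigma_\mathrm{true} = 0.3$ nm) refined against its own noiseless map
  at $k \in \{1, 2, 4\}\times10^5$ (150 K incarnation); all runs must fit
  (c.c. $> 0.99$) and the smallest adequate $k$ wins. The low-resolution
  regime is where full-map-only sweeps are the published fallback, and its
  smoother correlation landscape avoids the register-trapping that the
  desk-scale time compression (a $\sim10^3\times$ faster
  $\sigma$-quench than the published schedule) can induce at
  $\sigma_\mathrm{stop} = 0.2$ nm for intermediate force constants.
* *Null control*: with $k \equiv 0$ the correlation shows no systematic
  increase (one-sided 95% confidence bound over 5 seeds).
* Determinism, equipartition of a thermostatted bond (within 15%),
  FSC/propensity identities and the finite-difference force oracle run at
  their natural small sizes.

## Numerical choices

* Trimming uses zero-based half-open voxel boxes and shifts the origin so
  physical coordinates never move; resampling spans the identical physical
  box with trilinear interpolation (a constant map resamples to itself).
* Maps are canonicalized on read (fastest axis = x) rather than lazily
  permuted, because spreading and FFTs assume a fixed memory layout.
  Non-orthogonal cells are rejected; anisotropic voxels are supported.
* The origin convention (center of voxel zero) makes trim
  coordinate-invariance exactly testable; whether trimmed maps should
  instead be zero-padded is left open upstream, and preserving physical
  coordinates is the least surprising choice.
* Sigma-scan ties break toward larger sigma; sweep selection prefers the
  smallest adequate k — both prefer the gentler model.
* Empty FSC shells are skipped with a warning; FSC values are clamped to
  $[-1, 1]$ against rounding.
* Schedules clamp outside their node range, so querying before the first
  or after the last node is safe.

## Known limitations

The toy force field cannot reproduce side-chain rotamers, secondary
structure or DNA geometry, so stereochemical conclusions about real systems
are out of reach by construction; outlier statistics are computed from
externally produced outlier flags (the propensity module), not detected
internally. The half-map "full map" is an average, not an independent
reconstruction. Exact numeric parity with external FSC servers is not
claimed (shell binning differs between implementations). Rigid-body
pre-placement and ensemble refinement are out of scope.
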