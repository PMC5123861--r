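---
title: "Methods: quantitative analysis of C2-domain membrane binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of C2-domain membrane binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2membrane)
```

# The scientific problem

Synaptotagmin-1 triggers fast neurotransmitter release when Ca2+ drives its
tandem C2 domains (the C2AB fragment) onto the presynaptic plasma membrane.
Two membrane signals matter: the bulk anionic lipid phosphatidylserine
(PtdSer), which the Ca2+-binding loops engage, and the scarce but highly
charged phosphoinositide PtdIns(4,5)P2, which a conserved polybasic lysine
patch on the C2B beta-sandwich binds even without Ca2+. Characterising this
system quantitatively requires five independent biophysical measurements,
and this package implements the analysis chain for all of them, together
with ground-truth simulators so every fitter can be validated end to end:

1. **Stopped-flow kinetics** — how fast the protein associates with and
   dissociates from vesicles.
2. **Isothermal titration calorimetry (ITC)** — the affinity and
   stoichiometry of the soluble PtdIns(4,5)P2 head group (InsP3) for the
   polybasic patch, with full thermodynamic decomposition.
3. **Vesicle sedimentation partitioning** — equilibrium membrane affinity
   as a reciprocal molar partition coefficient.
4. **EPR power saturation** — how deeply spin-labelled sites insert
   relative to the lipid phosphate plane.
5. **Depth-restrained rigid-body docking** plus **NMR chemical-shift
   perturbation (CSP)** mapping — the orientation of the docked domain and
   the residues that touch the ligand.

# Stopped-flow kinetics

Under pseudo-first-order conditions (vesicles in large excess over
protein), the fluorescence trace after mixing relaxes as a single
exponential,

$$F(t) = F_0 + A_\mathrm{obs}\, e^{-k_\mathrm{obs} t},$$

and the observed rate is linear in vesicle concentration,
$k_\mathrm{obs} = k_\mathrm{on}[v] + k_\mathrm{off}$, so a titration
yields the bimolecular association rate constant (slope), the dissociation
rate constant (intercept) and the apparent dissociation constant
$K_d = k_\mathrm{off}/k_\mathrm{on}$.

Vesicle concentration is total lipid divided by the lipids per vesicle
(default 90,000, appropriate for ~100 nm large unilamellar vesicles).
`fit_monoexponential()` uses a Levenberg–Marquardt fit started from a
log-linear regression of $|F - F_\infty|$; on non-convergence it restarts
from rate scalings of $10^{\pm 1/2}$, $10^{\pm 1}$ and $10^{2}$.
`fit_rate_law()` is an ordinary (optionally SE-weighted) linear regression;
a negative fitted intercept is reported *unclamped* with a classed warning
so that delta-method error propagation to $K_d$ stays honest.

```{r kinetics}
comp <- lipid_composition(c(PtdChol = 0.75, PtdSer = 0.25))
v <- vesicle_concentration(c(30e-6, 90e-6, 180e-6, 270e-6), comp)
traces <- simulate_stopped_flow(1e11, 20, v, noise = noise_model(0.004, 1))
fits <- lapply(traces, fit_monoexponential)
fit_rate_law(kinetic_series(v, sapply(fits, `[[`, "k_obs")))
```

Replicated rate constants across lipid compositions are compared with
`compare_conditions()`: a one-way ANOVA followed by *protected* Fisher
least-significant-difference pairwise tests (pairwise t statistics on the
pooled mean square, flagged significant only when the omnibus F test has
p < alpha).

# Isothermal titration calorimetry

Injection heats follow the single-site model. After each injection the
perfusion (overflow) cell dilutes both species:
$P \leftarrow P(1 - v/V_0)$ and $L \leftarrow L(1 - v/V_0) + S\,v/V_0$.
The bound concentration solves the mass-action quadratic

$$B = \tfrac{1}{2}\left[(nP + L + K_d) - \sqrt{(nP + L + K_d)^2 - 4nPL}\right],$$

and the heat of injection $i$ is
$q_i = \Delta H\, V_0 (B_i - B_{i-1}(1 - v_i/V_0))$. `fit_isotherm()` fits
$(n, K_d, \Delta H)$ — plus a small constant per-injection offset by
default, standing in for the heat of dilution — over log-parameterised
$n$ and $K_d$ with several $K_d$ starts, and warns (classed condition)
when the Wiseman c-value $n P_\mathrm{cell}/K_d$ leaves the informative
1–1000 window. `derive_thermo()` converts $K_d$ to
$\Delta G = RT \ln K_d$ and $-T\Delta S = \Delta G - \Delta H$.

```{r itc}
prot <- titration_protocol(1.4e-3, 50e-6, 1e-3, rep(10e-6, 25))
sim <- simulate_itc(1, 14e-6, -30, prot,
                    noise_model(0.02 * max(abs(predict_heats(1, 14e-6, -30,
                                                             prot)$q)), 2))
fit <- fit_isotherm(sim, prot)
c(n = fit$n, K_d_uM = fit$K_d * 1e6, dH = fit$dH, dG = fit$dG)
```

The default protocol (25 °C, 50 µM protein in a 1.4 mL cell, 25 × 10 µL
injections from a 1 mM syringe, ΔH = −30 kJ/mol) gives a c-value near 4 —
deliberately a *hard but realistic* regime for a 14 µM site, which is why
recovery is asserted on medians over replicates rather than single fits.

# Equilibrium partitioning

Sedimentation assays measure the bound protein fraction versus
*accessible* lipid (outer leaflet only, default 50% of total):

$$f_b = \frac{K[L]}{1 + K[L]},$$

where $K$ is the reciprocal molar partition coefficient; $1/K$ is the
accessible lipid concentration at half binding. `fit_partition()` fits
$\log K$ by Levenberg–Marquardt and refuses datasets that cannot constrain
it (fewer than 4 points, under a decade of lipid span, or fractions pinned
near 0/1). Two derived quantities carry the biology:

* `delta_delta_G(K_a, K_b)` $= RT\ln(K_a/K_b)$, the free-energy cost of a
  mutation or composition change;
* `effective_local_concentration()` — the lipid concentration seen by a
  membrane-tethered domain confined within a tether range (default 4 nm)
  above a bilayer of given area per lipid (0.65 nm²): ≈ 0.64 M at
  defaults, four orders of magnitude above the ~20 µM half-binding
  concentration of a PtdSer/PtdIns(4,5)P2 bilayer. This is the quantitative
  argument for why a pre-tethered C2 domain stays membrane-bound.

The measured coefficients used in the worked examples ship as a plain-text
table, `partition_coefficients()`.

# EPR power saturation and depth calibration

The amplitude of a nitroxide EPR line versus microwave power follows

$$A(P) = I\sqrt{P}\,\bigl[1 + (2^{1/\varepsilon} - 1) P / P_{1/2}\bigr]^{-\varepsilon},$$

with $P_{1/2}$ the half-saturation power and
$\varepsilon \in [0.5, 1.5]$ the homogeneity exponent. Collisions with O2
(enriched in the hydrocarbon core) raise $P_{1/2}$ for buried labels;
collisions with NiEDDA (aqueous) raise it for exposed labels. The depth
parameter is

$$\Phi = \ln\frac{\Delta P_{1/2}^{\mathrm{O_2}}}{\Delta P_{1/2}^{\mathrm{NiEDDA}}},$$

with both shifts measured against the N2 baseline. $\Phi$ maps
monotonically onto the signed distance from the phosphate plane
(+ = hydrocarbon interior). `fit_calibration()` fits the empirical
sigmoid $\Phi(x) = A\tanh(B(x - C)) + D$ to measured $(\Phi, x)$ pairs —
15 ship with the package as `spin_label_depths()` — and inverts it
analytically; when the tanh misfits (RMS above `fallback_rms`) it falls
back to a monotone (Hyman-filtered) interpolating spline. Non-monotone
pair sets are rejected with a classed error rather than silently
smoothed. Depth uncertainty is propagated through the local slope,
$\sigma_x = \sigma_\Phi / |d\Phi/dx|$.

```{r epr}
tab <- spin_label_depths()
cal <- fit_calibration(tab)
depth_from_phi(1.20, cal)$x   # deep Ca-loop site, ~8.8 Angstrom
```

The 12 default powers are log-spaced over 0.6–36 mW, matching typical
loop-gap resonator practice.

# Depth-restrained rigid-body docking

Given per-site insertion depths, the domain is docked as a rigid body
against the membrane plane $z = 0$. Each spin-labelled site is represented
by a surrogate label point: the Cβ atom extended 7 Å along the Cα→Cβ
direction, a standard stand-in for the R1 side chain's nitroxide. Only
three pose degrees of freedom are observable from plane distances — tilt,
body azimuth and the offset along z — and `dock_to_plane()` minimises a
flat-bottom harmonic objective (zero within each restraint's range,
quadratic outside) over a 5° × 5° × 0.5 Å coarse grid followed by
Nelder–Mead refinement of the best nodes. All poses within 1e-3 of the
minimum objective are returned as degenerate alternatives; with fewer
than three non-degenerate restraints the problem is under-determined and
the function says so (single restraint: translation-only solution with a
classed warning). Because no experimental structure ships with the
package, the examples and tests use `make_toy_domain()`, a deterministic
bent-helix fold whose geometry is entirely reproducible from its seed.

# NMR chemical-shift perturbation

Ligand-induced amide shifts are combined with the standard weighting

$$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (0.2\,\Delta\delta_N)^2},$$

matching peaks strictly by residue assignment; residues present in only
one condition (candidates for exchange broadening) are flagged, never
dropped silently. `rank_perturbed()` orders residues by CSP and applies
the mean + 1 SD threshold (or a fixed top-k), with stable ordering for
ties.

# Generator realism and its limits

Every simulator draws additive Gaussian noise through a `noise_model`
whose seed is isolated with an internal RNG-state guard, so seeded
simulations never perturb an enclosing random stream, and the same seed
is bitwise reproducible. The generators are deliberately simple:

* noise is homoscedastic and Gaussian — no photobleaching drifts, no
  baseline walks, no injection-volume errors;
* stopped-flow traces are strictly single-exponential (no mixing dead
  time);
* the ITC offset term models a constant dilution heat only;
* the toy docking domain is a caricature fold, not a C2 sandwich; it
  exists to make the geometry chain testable, not to predict real
  structures.

These choices keep every fitter's ground truth exactly known, which is
what the test suite exploits: zero-noise round trips are asserted to
machine precision, noisy recoveries against independent oracles (grid
searches, bisection, closed forms) and printed-value checks.

# Numerical choices

* All nonlinear fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  log-parameterised positive quantities and multiple starts, so failure
  modes surface as classed conditions rather than silent divergence.
* The mass-action quadratic uses the numerically stable root with a guard
  against cancellation at extreme c-values.
* The tanh calibration is inverted in closed form; the spline fallback is
  inverted by bisection on its monotone domain.
* Errors and warnings throughout are classed conditions
  (`c2membrane_error` / `c2membrane_warning` subclasses), so callers can
  distinguish, e.g., `degenerate_data` from `fit_failure`
  programmatically.

# Limitations

* Single-site models only: no sequential or cooperative binding isotherms.
* Partitioning assumes protein dilute relative to accessible lipid
  (no lipid depletion correction).
* Docking treats the membrane as a rigid plane; no membrane deformation,
  no restraint weighting by depth uncertainty beyond the flat-bottom
  ranges.
* CSP analysis does not fit titration curves (no per-residue Kd from
  shift trajectories).
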