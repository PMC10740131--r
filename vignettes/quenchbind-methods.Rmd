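---
title: "Methods: quenching thermodynamics, spectral analysis and trajectory metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quenching thermodynamics, spectral analysis and trajectory metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The binding model

A fluorophore-bearing protein titrated with a quenching ligand loses
fluorescence according to the Stern–Volmer relation

$$\frac{F_0}{F} = 1 + K_{sv}[Q],$$

where $F_0$ and $F$ are the intensities without and with quencher, $[Q]$
the quencher molar concentration, and $K_{sv}$ (M$^{-1}$) the Stern–Volmer
constant. The bimolecular quenching rate constant $K_q = K_{sv}/\tau_0$
($\tau_0$ the unquenched fluorophore lifetime) discriminates mechanism:
diffusion-limited collisions cannot exceed about $2\times10^{10}$
M$^{-1}$s$^{-1}$, so larger $K_q$ implies ground-state complex formation
(static quenching). The temperature trend of $K_{sv}$ gives the
complementary signal — collisional (dynamic) quenching strengthens with
temperature, complexation usually weakens. `classify_quenching()` combines
both: rising $K_{sv}$ *and* $K_q$ above the limit is *combined* quenching;
rising alone is *dynamic*; falling with $K_q$ above the limit is *static*;
anything else is reported *indeterminate* rather than forced into a class.

Binding affinity and stoichiometry come from the double-logarithmic form

$$\log_{10}\frac{F_0-F}{F} = \log_{10}K_a + n\,\log_{10}[Q],$$

and the temperature dependence of $K_a$ yields the thermodynamics via
Van't Hoff,

$$\ln K_a = -\frac{\Delta H}{RT} + \frac{\Delta S}{R}, \qquad
\Delta G = \Delta H - T\Delta S,$$

with $R = 8.314$ J/(mol·K). The signs of $\Delta H$ and $\Delta S$ name
the dominant noncovalent force (Ross–Subramanian convention): both
negative — hydrogen bonding / van der Waals; both positive — hydrophobic;
$\Delta H \approx 0$ with $\Delta S > 0$ — electrostatic.

### Assumptions and caveats

All fits are ordinary least squares, unweighted, with
$r^2 = 1 - SS_{res}/SS_{tot}$: quenching data of this kind are short
(typically five usable concentrations) and carry no replicate-level
variance estimates that would justify weighting. Van't Hoff assumes
$\Delta H$ and $\Delta S$ constant over the (narrow, ~17 K) temperature
window. The double-log form assumes a single class of equivalent,
independent sites; `n` far from 1 or a poor $r^2$ signals that assumption
failing, not a refined stoichiometry.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau0` | 1e-8 | s | Typical intrinsic protein fluorophore lifetime is ~ns–10 ns; 1e-8 s also makes $K_q$ in $10^{11}$ units numerically equal $K_{sv}$ in $10^3$ units, matching how such constants are conventionally tabulated. Always caller-settable. |
| `diffusion_limit` | 2e10 | M⁻¹s⁻¹ | The standard maximum diffusive collision rate constant. |
| `anchored` | `FALSE` | — | The Stern–Volmer line passes through 1 in theory, but experimental intercepts rarely do; a free intercept keeps $r^2$ meaningful and the intercept itself is reported as a diagnostic. |
| `tol` (forces) | 1 | kJ/mol | Threshold for "ΔH ≈ 0"; no convention exists, 1 kJ/mol is well inside typical Van't Hoff uncertainty. |
| trend ties | 1e-6 | relative | $K_{sv}$ values equal within 1e-6 count as ties (flat trend). |
| `tol` (shift) | 0.5 | nm | Half a typical 1-nm scan step: moves below it are grid noise, the 2–4 nm shifts of interest are far above it. |
| `probe_radius` | 0.14 | nm | Water probe. |
| `n_points` | 960 | — | Shrake–Rupley quadrature; converges to <1 % against 3840 points on small clusters. |
| H-bond cutoffs | 0.35 nm, 30° | — | The common geometric criterion in MD analysis tools. |

Temperatures are always caller-supplied, never hard-coded. The bundled
worked-example configuration uses 293/303/310 K because that is the set
under which the example's Gibbs energies are internally consistent with
its enthalpy and entropy.

## Spectral peak analysis

`find_lambda_max()` takes the discrete argmax (ties broken toward the
shorter wavelength) and refines it by fitting a parabola through the
argmax and its two neighbours, returning the vertex. On a 1-nm grid this
resolves sub-nanometre peak positions and stabilizes noisy maxima; the raw
argmax is returned alongside. Degenerate cases are explicit: a maximum on
the window boundary disables refinement and warns, and a non-concave
3-point neighbourhood falls back to the raw argmax. No smoothing is
applied by default (`smooth_width` enables a moving average). The default
analysis window is the caller's choice; emission scans that include the
excitation line should be windowed past it (e.g. 300–450 nm for 280 nm
excitation).

## CD deconvolution

`deconvolve_cd()` solves a non-negative least-squares problem on the
common wavelength range of spectrum and basis (requiring ≥ 30 nm overlap),
then renormalizes the weights onto the unit simplex. Two consequences are
deliberate:

- **Scale invariance.** Mean-residue-ellipticity normalization (path
  length, concentration, residue count) cancels in the renormalization, so
  uncalibrated spectra deconvolve to the same fractions.
- **Synthetic basis.** The packaged `cd_basis()` is built from Gaussian
  band parameterizations of the canonical far-UV shapes (helix: positive
  ~193 nm, double minima at 208/222 nm; sheet: minimum ~218 nm; coil:
  strong minimum ~198 nm). It is clearly labelled synthetic: commercial
  deconvolution packages use proprietary protein reference sets, so
  absolute fractions from real spectra will differ between bases.
  Within-study *changes* in fractions are far more transferable than the
  absolute values.

The NNLS core is an active-set solver (tolerance ~1e-8); noiseless
mixtures of the basis are recovered to machine precision, and at 2 %
additive noise the mean absolute fraction error stays below 0.03 in the
test suite's 100-replicate simulation.

## Trajectory metrics

All coordinates are nm internally (PDB/XYZ files, being Ångström, are
converted on ingest).

- **RMSD** uses Kabsch superposition: centroid removal, optimal rotation
  from the SVD of the coordinate cross-covariance, with the reflection
  case removed by sign-flipping the smallest singular direction so the
  determinant is +1.
- **RMSF** superposes every frame onto a reference, then reports each
  atom's RMS deviation from its time-mean position. The default reference
  is the time-mean structure from two alignment passes (align to the first
  frame, average, re-align to the average). `align = FALSE` supports
  pre-aligned input; note that superposition itself absorbs part of any
  single-atom displacement, so closed-form expectations (an atom
  oscillating ±d has RMSF exactly d) hold exactly only without alignment.
- **SASA** (Shrake–Rupley) places a golden-spiral point set on each atom's
  probe-inflated sphere and counts points outside all other inflated
  spheres; per-atom areas are summed into hydrophobic and hydrophilic
  totals using the frame's per-atom flags (default: C/S/H hydrophobic,
  N/O hydrophilic — the partition rule is caller-overridable since
  residue-based conventions also exist). Points exactly on a shared
  boundary are assigned to the lower-indexed atom so coincident surface is
  not double-counted.
- **Hydrogen bonds** use the geometric criterion: donor–acceptor distance
  ≤ 0.35 nm and H–donor–acceptor angle ≤ 30°, for a hydrogen within
  0.12 nm of the donor heavy atom; each donor–acceptor pair counts at most
  once.

The package does not run molecular dynamics; it post-processes coordinate
sets. Published per-trajectory values (mean RMSD/RMSF of a specific 30-ns
simulation, MM/PBSA energies, docking scores) are functions of
trajectories that are not distributed and are therefore out of scope; the
metrics are instead validated against analytic cases and a brute-force
rotation-grid RMSD oracle.

## The synthetic-data generators

Every analysis stage has a generator that inverts it, so at zero noise
`analysis(generator(theta)) = theta` to numerical precision — this
round-trip identity is the backbone of the test suite. The defaults
reproduce the study conditions of the motivating experiment: six quencher
concentrations 0–3.802×10⁻⁴ M and temperatures 293/303/310 K.

Noise models: fluorescence intensities get *multiplicative lognormal*
noise (detector noise scales with signal), CD/absorbance readings get
*additive Gaussian* noise. A single integer seed drives a named sub-stream
per generator (offset hashing into 32-bit range, via seed-scoped RNG so
the ambient RNG state is untouched), making outputs byte-identical for a
fixed config while decoupling the modules.

What the generators do **not** emulate: inner-filter effects, wavelength-
dependent detector response, correlated baseline drift, aggregation
artifacts at high ligand load, or real protein photophysics. Passing
recovery tests therefore demonstrates the estimators are correct and
noise-stable, not that any instrument's systematic errors are handled.

Problem sizes in the tests were chosen to exercise the statistics while
staying lightweight: 200 replicates for noisy Stern–Volmer recovery, 100
for CD, 500 for calibration inversion, toy trajectories of 10–50 atoms and
up to 200 frames.

## Numerical choices and degenerate inputs

- Logarithm bases follow the equations as written: base 10 for the
  double-log fit, natural log for Van't Hoff. R is held in J/(mol·K)
  internally; ΔH/ΔS/ΔG are reported in kJ.
- Double-log points with $F \ge F_0$ (no quenching) are dropped with a
  warning; fewer than 3 surviving points is an error.
- A perfectly flat, perfectly fitted response reports $r^2 = 1$; anchored
  fits clamp $r^2$ into [0, 1].
- Negative BPB-bound values and out-of-range calibration inversions are
  returned with warnings, never clamped — downstream QC decides.
- A calibration slope below 1e-12 (relative to the intercept scale) is
  treated as non-invertible.
- The driving-force rule table leaves ΔH > 0 with ΔS ≤ 0 unnamed; it maps
  to the electrostatic (residual) class.

## Known limitations

Absolute CD fractions depend on the basis (see above). The mechanism and
force classifications are rule-based sign tests with fixed thresholds —
they inherit the noise of the underlying fits and report no uncertainty.
The urea/thiourea partition treats the two releases as independent
measurements and says nothing about forces neither agent disrupts.
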