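# quenchbind

Tools for characterizing how a small flavor molecule binds a protein from
spectroscopic readouts. The motivating system is hydroxy-α-sanshool (α-SOH),
the numbing amide of Sichuan pepper, binding myofibrillar proteins (MPs) of
pork muscle — but every calculator is generic: any fluorescence-quenching
titration, far-UV CD spectrum, colorimetric assay reading, or multi-frame
coordinate set flows through the same functions. A fully seeded
synthetic-data module generates every input with known ground truth, so the
whole pipeline is testable without an instrument.

## What it computes

**Quenching thermodynamics.** For titrations of fluorescence intensity `F`
against quencher concentration `[Q]` at several temperatures:

- Stern–Volmer: `F0/F = 1 + Ksv[Q]` fitted by OLS (free intercept by
  default, optionally anchored at 1); `Kq = Ksv/τ0` with the fluorophore
  lifetime `τ0` (default 1e-8 s).
- Double-log: `log10((F0−F)/F) = log10(Ka) + n·log10[Q]` giving the
  apparent binding constant `Ka` and binding-site number `n`.
- Van't Hoff: `ln Ka = −ΔH/(RT) + ΔS/R`, then `ΔG = ΔH − TΔS` per
  temperature (R = 8.314 J/(mol·K); results in kJ).
- Mechanism call: Ksv rising with temperature plus every Kq above the
  diffusion-controlled limit (2×10¹⁰ M⁻¹s⁻¹) ⇒ *combined* quenching;
  the other sign patterns map to *dynamic*, *static*, or *indeterminate*.
- Driving-force call (Ross–Subramanian signs): ΔH<0 & ΔS<0 ⇒ hydrogen
  bond / van der Waals; both >0 ⇒ hydrophobic; ΔH≈0 ⇒ electrostatic.

**Spectra.** Sub-grid emission-peak localization (parabolic refinement of
the discrete argmax) and red/blue-shift classification with a 0.5 nm dead
band, for intrinsic and synchronous (Δλ = 15/60 nm) fluorescence.

**Assays.** Bromophenol-blue surface hydrophobicity
(`200 µg × (A_blank − A_sample)/A_blank`), Ellman sulfhydryl content
(Beer–Lambert with explicit dilution bookkeeping), linear standard curves
with inverse prediction and range warnings, and the urea/thiourea release
partition that names the dominant noncovalent force.

**CD deconvolution.** Secondary-structure fractions by non-negative least
squares against a packaged *synthetic* four-class basis (α-helix, β-sheet,
β-turn, random coil), renormalized onto the unit simplex so the result is
scale-invariant.

**Trajectory metrics.** Kabsch minimal RMSD, per-atom RMSF with iterative
mean-structure alignment, Shrake–Rupley SASA with a
hydrophobic/hydrophilic split, and geometric hydrogen-bond counting
(donor–acceptor ≤ 0.35 nm, H–donor–acceptor angle ≤ 30°), with PDB/XYZ
readers (coordinates in nm internally).

## Worked example

Generate quenching titrations at the study conditions (six concentrations,
0–3.802×10⁻⁴ M; 293/303/310 K) with 1 % intensity noise and run the full
analysis:

```r
library(quenchbind)
cfg <- gen_config(seed = 7, noise_sigma = 0.01)
series <- lapply(seq_along(cfg$temperatures), function(i) {
  cfg_i <- gen_config(seed = 7 + i, noise_sigma = 0.01)
  gen_quenching_series(c(750, 1120, 1460)[i], cfg_i,
                       temperature = cfg$temperatures[i])
})
quench_analysis(series, tau0 = 1e-8)
```

```
 temperature_K    ksv_M1      kq_M1s1     r2_sv     ka_M1   n_sites     r2_dl
           293  745.9661  74596609649 0.9619370  726.6347 1.0028828 0.9659678
           303 1114.8611 111486114386 0.9966167  917.0274 0.9791108 0.9922752
           310 1448.9948 144899482188 0.9985526 2219.8216 1.0542950 0.9972936
 delta_g_kJ_mol
      -15.76917
      -17.91126
      -19.41072
<thermo_result> dH = 46.994 kJ/mol, dS = 0.2142 kJ/(mol K), force = hydrophobic
<mechanism_call> combined (Ksv increasing with T, Kq above diffusion limit 2e+10)
```

The fitted Ksv recover the generating truths (750/1120/1460 M⁻¹) to within
a percent or so; Kq = Ksv/τ0 lands near 10¹¹ M⁻¹s⁻¹, far above the
diffusion limit, and together with the rising Ksv trend yields the
*combined* quenching call. Because this synthetic dataset was generated
with Ka rising with temperature, the Van't Hoff fit is endothermic and the
driving-force call is *hydrophobic* — the classifications follow the data
they are given. Feeding the analysis an exothermic Ka(T) set (e.g.
`gen_vant_hoff_dataset(-164.076, -0.501)`) returns negative ΔG at every
temperature and the *hydrogen-bond/van der Waals* label instead.

## Scope

The package covers post-hoc analysis only: it does not run molecular
dynamics or docking, does not model photophysics, and its CD basis is a
synthetic stand-in for proprietary reference sets (fractions from real
spectra are indicative, not calibrated). See the methods vignette
(`vignettes/quenchbind-methods.Rmd`) for the model assumptions, parameter
defaults, and limitations.
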