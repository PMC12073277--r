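# asdkit

Stability and molecular-mobility analysis of amorphous solid dispersions
(ASDs) — drug-in-polymer formulations such as resveratrol in
polyvinylpyrrolidone — from time-domain NMR relaxometry, powder-diffraction
peak widths, and molecular-dynamics trajectories. The package is written
for formulation scientists and NMR/MD practitioners who need the full
chain from raw observable to physical conclusion as reproducible,
tested code, together with a synthetic-data generator that stands in for
the spectrometer, the diffractometer and the MD engine.

## What it computes

**Saturation recovery.** Magnetization recovery is fitted as
M(τ) = M₀ Σᵢ fᵢ (1 − e^(−τ/T₁ᵢ)) with one or two components
(`fit_recovery()`); `select_recovery_model()` decides the exponentiality by
corrected-AIC improvement (> 10) plus a 5% fraction floor. One-phase
systems recover mono-exponentially; two-phase systems with domains larger
than the spin-diffusion length recover bi-exponentially, and
`proton_fraction()` / `assign_phases()` map the magnetization fractions to
phases by proton counting. `stability_report()` tracks fitted parameters
over storage time.

**FID decomposition.** `decompose_fid()` splits the free-induction decay
into a rigid Gaussian and a mobile exponential part,
S(t) = M₀ [f_G e^(−t²/2T₂G²) + (1−f_G) e^(−t/T₂E)], the standard probe of
plasticization by absorbed water.

**Multi-process BPP relaxation.** `fit_t1_series()` fits
1/T₁ = Σₖ Cₖ [τ/(1+ω₀²τ²) + 4τ/(1+4ω₀²τ²)], τ = τ₀e^(E_A/RT), on log T₁,
extracting activation energies; `t1_minimum()` returns the T₁ minimum in
closed form via the universal condition ω₀τ ≈ 0.6158.

**Crystallite sizing.** `scherrer_size()` / `average_scherrer()` apply
L = Kλ/(β cos θ) to peak lists; `spin_diffusion_length()` computes the
domain size above which recovery turns bi-exponential (both published
readings of the formula, behind an explicit `convention` switch).

**Trajectory analysis.** Minimum-image pair distribution functions
(`pair_distribution()`), geometric hydrogen-bond detection at the
3.5 Å/30° criteria (`detect_hbonds()`), per-molecule bond censuses and
cluster statistics (`hb_count_distribution()`, `hb_clusters()`,
`unbonded_molecules()`), signed dihedrals, orientational distributions and
bond-vector correlation functions with fitted decay times
(`torsion_series()`, `orientation_distribution()`, `angular_correlation()`).

**Synthetic data.** `gen_recovery()`, `gen_fid()`, `gen_t1_curve()`,
`gen_peaks()`, `gen_box()` (periodic boxes with hydrogen-bond networks
planted so the measured census reproduces a requested plan exactly) and
`gen_torsion_trajectory()` (two-state jumps with an analytic ACF) produce
every input with known ground truth. `run_pipeline()` wires the stages
together; the `"paper-replay"` preset regenerates the reference scenario
end to end under one seed.

## A worked example

Fit a noisy bi-exponential recovery curve of a 50/50 drug/polymer sample
and assign the components to phases:

```r
library(asdkit)

curve <- gen_recovery(recovery_spec(
  data.frame(t1 = c(0.36, 1.1), fraction = c(0.65, 0.35)),  # seconds
  noise_sd = 0.01, seed = 1
))
fit <- select_recovery_model(curve)
fit
#> <recovery_fit> 2 component(s)
#>   T1 = 0.3536 s  fraction = 0.631
#>   T1 = 1.089 s  fraction = 0.369
#>   M0 = 1.003  residual RMS = 0.00867  AICc = -596.7
```

The model selector chose two components; the recovered times (354 ms,
1.09 s) and fractions (63/37) sit within the 1% noise of the generating
truth (360 ms/1.1 s at 65/35). Proton counting says which phase is which:
resveratrol (C14H12O3) contributes 39.4% of the protons at 50/50 w/w
against the PVP monomer (C6H9NO), so the long-T₁ component is the drug:

```r
asg <- assign_phases(fit, data.frame(
  phase = c("RSV", "PVP-rich"), proton_fraction = c(0.394, 0.606)
))
asg
#> # A tibble: 2 × 6
#>   component  t1_s observed_fraction phase    predicted_fraction mismatch
#> 1 short     0.354             0.631 PVP-rich              0.606   0.0251
#> 2 long      1.09              0.369 RSV                   0.394   0.0251
```

The total mismatch (0.050) is the quantitative version of "the long
component matches the drug's proton share". On the temperature side, the
intermediate motional process of the 70/30 dispersion
(C = 5.7×10⁷ s⁻², τ₀ = 2.4×10⁻¹¹ s, E_A = 6.8 kJ/mol) has its T₁ minimum at

```r
t1_minimum(relaxation_process(5.7e7, 2.4e-11, 6.8, "intermediate"), 25e6)
#> # A tibble: 1 × 4
#>   t_min_K t1_min_s omega_tau in_range
#> 1    161.     1.93     0.616 TRUE
```

i.e. ~160 K at 25 MHz, with the universal ω₀τ ≈ 0.616 at the minimum. And
four reflections generated for a single 40 nm crystallite analyse back to
exactly that average:

```r
peaks <- gen_peaks(peak_set_spec(
  data.frame(two_theta = c(6.6, 16.4, 19.2, 22.4), crystallite_size = 40)
))
average_scherrer(peaks)
#> [1] 40
```

The methods vignette (`vignettes/asd-stability-analysis.Rmd`) documents the
models, conventions, tunable parameters, generator scope and known
limitations.

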