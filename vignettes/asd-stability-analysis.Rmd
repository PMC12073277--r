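---
title: "Models and methods: relaxometry, crystallite sizing and trajectory analysis for amorphous solid dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdkit)
```

# The scientific problem

An amorphous solid dispersion (ASD) stabilises a poorly soluble drug by
dispersing it molecularly in a polymer matrix. Whether the dispersion stays
amorphous — or the drug nucleates nanocrystals — is governed by composition,
humidity, and the hydrogen-bond network connecting drug, polymer and any
absorbed water. Time-domain NMR observes this without long-range order:
spin-lattice relaxation (T1) distinguishes one-phase from two-phase systems
through the exponentiality of saturation recovery; the FID line shape splits
protons into rigid and mobile populations; T1 measured across temperature
exposes the motional processes and their activation barriers. Powder
diffraction peak widths size any crystallites, and molecular-dynamics
trajectories expose the hydrogen-bond census behind the stability. This
package implements that entire analysis chain, plus a synthetic-data
generator that produces every input with known ground truth, so each stage
is testable by parameter recovery rather than against undeposited raw data.

# Saturation recovery and phase composition

The recovery of longitudinal magnetization after saturation is modelled as

$$M(\tau) = M_0 \sum_{i=1}^{n} f_i\,(1 - e^{-\tau/T_{1,i}}),
\qquad n \in \{1, 2\},\ \textstyle\sum_i f_i = 1.$$

`fit_recovery()` estimates the component amplitudes $a_i = M_0 f_i$ and
$\log T_{1,i}$ by Levenberg–Marquardt least squares with non-negative
amplitudes, started from a deterministic grid of log-spaced $T_1$ seeds that
spans the delay range (all pairs of six seeds for the two-component model).
The fit is unweighted: recovery amplitudes are baseline-subtracted
instrument readings with approximately constant noise. Components are
reported in ascending $T_1$.

A heterogeneous two-phase solid gives bi-exponential recovery only when both
phase domains exceed the spin-diffusion length (below); the *decision*
between one and two components therefore carries physical meaning and should
not rest on visual inspection. `select_recovery_model()` fits both models
and accepts the richer one only if the corrected AIC improves by more than
10 *and* both fractions exceed 5%. The AICc threshold of 10 is the
conventional "decisive" evidence level and, on 64-point curves, rejects the
second component whenever it merely absorbs noise; the fraction floor
guards against the degenerate solutions that nested models admit. Both
knobs are arguments.

Magnetization amplitudes are proportional to proton counts, so
`proton_fraction()` converts weight fractions $w_i$ of components with
hydrogen counts $H_i$ and molar masses $M_i$ (monomer values for polymers)
into expected magnetization shares $w_i H_i/M_i$ (normalised), and
`assign_phases()` matches them to the observed fractions by minimising the
total absolute mismatch. For a 50/50 w/w resveratrol/PVP mixture the
arithmetic gives a 39.4% resveratrol proton share; experimental reports for
such systems quote ~37%, a discrepancy consistent with residual water in
the polymer being counted. The package performs the exact arithmetic and
lets the caller add water as an explicit component; it never forces the
rounder figure.

Atomic weights are a fixed table inside the package so that these fractions
are bit-stable across environments.

# FID decomposition

The free-induction decay of a mixed rigid/mobile proton system is modelled
as a Gaussian plus an exponential,

$$S(t) = M_0\!\left[f_G\, e^{-t^2/(2 T_{2G}^2)} + (1-f_G)\, e^{-t/T_{2E}}\right],$$

with the Gaussian (shorter $T_2$) carrying the rigid fraction and the
exponential tail the mobile one. Two conventions for the Gaussian circulate;
this package uses $e^{-t^2/2T_2^2}$ everywhere — the alternative
$e^{-(t/T_2)^2}$ rescales $T_{2G}$ by $\sqrt2$, so the convention is stated
here once and shared by generator and fitter. The constraint
$T_{2G} < T_{2E}$ is built into the parameterisation
($T_{2E} = T_{2G} + \Delta$, $\Delta > 0$), so fits cannot wander into the
unphysical ordering. The rigid fraction is reported as the Gaussian
amplitude share at $t = 0$. A warning is raised when the sampled window is
shorter than about three fitted $T_{2E}$, where the tail is poorly
constrained.

`stability_report()` tracks any fitted parameter across storage time and
flags the first departure beyond a relative threshold (default 15%, roughly
three times the ~5% repeatability of relaxation measurements).

# Multi-process BPP relaxation

Each thermally activated motion contributes a relaxation rate of the
Bloembergen–Purcell–Pound form

$$\frac{1}{T_1} = C\left[\frac{\tau_c}{1+\omega_0^2\tau_c^2}
 + \frac{4\tau_c}{1+4\omega_0^2\tau_c^2}\right],
 \qquad \tau_c = \tau_0\, e^{E_A/RT},$$

with $R = 8.314$ J/(mol K) frozen and $E_A$ in kJ/mol throughout. Rates add
over processes. The rate is maximal at the universal reduced frequency
$\omega_0\tau_c \approx 0.6158$ — independent of $C$, $\tau_0$, $E_A$ —
which `t1_minimum()` exploits to return the minimum temperature in closed
form by inverting the Arrhenius law at $\tau_c^* = 0.6158/\omega_0$; a test
checks this against a dense scan to 0.1 K.

`fit_t1_series()` minimises residuals on $\log T_1$: the quantity spans
decades over a temperature sweep and its measurement error is relative, so
a log loss weights the whole curve evenly. $C$ and $\tau_0$ are optimised on
a log10 scale with bounds $\tau_0 \in [10^{-14}, 10^{-9}]$ s and
$E_A \in [0.5, 100]$ kJ/mol. A process whose minimum lies outside the
measured window has no separately identifiable $C$ and $\tau_0$; such
processes are fitted in `"slope"` mode — a pure Arrhenius rate
$e^{a + b/T}$ reporting only $E_A = |b|R$ and a composite amplitude — which
mirrors how low- and high-temperature branches are treated in practice.
Starting values may be supplied (the acceptance analyses refit from
deliberately perturbed truths); otherwise a fixed grid of slope- and
magnitude-derived seeds is tried in a deterministic order. Under-determined
configurations (fewer than three points per parameter in-window) are
rejected with a diagnostic rather than fitted.

For synthetic multi-process curves, the reference intermediate process
(C = 5.7×10⁷ s⁻², τ₀ = 2.4×10⁻¹¹ s, E_A = 6.8 kJ/mol at 25 MHz) is paired
with a high-temperature companion whose amplitude parameters are not
published; this package uses τ₀ = 5×10⁻¹¹ s and C = 8×10⁷ s⁻², chosen so
that the companion's minimum sits near 356 K — above the 120–300 K window —
leaving in-window only the slow-motion slope that the measured
high-temperature branch shows. Tests state these values where they use them.

# Crystallite size and the spin-diffusion criterion

`scherrer_size()` implements $L = K\lambda/(\beta\cos\theta)$ with $\beta$
the FWHM in radians; the shape constant defaults to the conventional
$K = 0.9$ and is an argument, since the underlying reports rarely state it.
Instrumental broadening is *not* subtracted — inputs are assumed
pre-corrected, and this is deliberately loud in the documentation because
silently double-correcting is the common failure mode.
`average_scherrer()` reports the arithmetic mean over a peak list and keeps
the per-peak table.

The spin-diffusion detectability length couples the NMR and diffraction
views: magnetization diffusing with coefficient $D_s$ averages over domains
smaller than $A$, so bi-exponential recovery requires both domains to exceed
it. The published formula's typography admits two readings,

$$A = \sqrt{\frac{\pi D_s T_1^1 T_1^2}{8\,(T_1^2 - T_1^1)}}
\quad\text{or}\quad
A = \sqrt{\frac{\pi D_s T_1^1 T_1^2}{T_1^2 - T_1^1}},$$

which give 13.0 and 36.7 nm for $D_s = 0.8$ nm²/ms, $T_1$ = 0.36/1.1 s —
neither reproducing the ~43 nm usually quoted for those inputs (43 nm is
numerically consistent with $\sqrt{\pi D_s \bar T_1}$ on the mean
relaxation time). Because the intended formula cannot be recovered from the
source text, both literal readings sit behind an explicit `convention`
switch (default `"as-printed"`), the result always echoes the convention
used, and no attempt is made to tune toward 43. `exponentiality_prediction()`
then applies the stated rule — bi-exponential iff domain size exceeds $A$ —
with the boundary assigned to mono.

# Trajectory observables

**Pair distribution functions.** `pair_distribution()` histograms
minimum-image distances between two atom groups and normalises by the
ideal-gas shell count $N_a\,4\pi r^2\Delta r\,\rho_b$ per frame, with
$\rho_b$ the box density of the second group. Self pairs are always
excluded and intramolecular pairs by default, because the hydrogen-bond
diagnostics live in the *intermolecular* part of the PDF. The default bin
width of 0.05 Å resolves the ~2.7 Å O–O contact of hydrogen-bonded
hydroxyls. `r_max` beyond half the smallest box edge is refused by name —
the minimum-image convention is meaningless there. Boxes are orthorhombic
only; coordinates are wrapped on construction.

**Hydrogen bonds.** A bond is a (donor-heavy, H, acceptor) triple with
donor–acceptor distance < 3.5 Å and an angle < 30° measured *at the donor
heavy atom* between the donor→H and donor→acceptor vectors — small angles
mean a near-linear D–H···A arrangement. Default typing follows the chemistry
of PVP-like chains (carbonyl O: acceptor only), hydroxyl-bearing small
molecules (O: donor and acceptor) and water (two donor H, acceptor O).
`hb_count_distribution()` reproduces the published table layout — percent of
focal molecules with 0/1/2/3 bonds of a class and direction — always adding
an explicit "4+" bin so columns sum to 100 (published columns that sum short
presumably fold that bin away). Frames are weighted equally (arithmetic mean
of per-frame percentages). `hb_clusters()` takes connected components of the
molecule-level bond graph (monomer/dimer/trimer/4+), and
`unbonded_molecules()` reports the fully unbonded percentage across all bond
classes, the figure whose vanishing marks a saturated network.

**Torsions.** `torsion_series()` returns signed dihedrals in (−180°, 180°]
(IUPAC convention) from minimum-image bond vectors; collinear frames yield
`NA` with a warning rather than an arbitrary angle.
`orientation_distribution()` bins over molecules and frames with bins
*centred* on round angles (so states at 0°, 60°, 180° fall on bin centres;
+180° wraps onto the −180° bin), normalised to sum 1.

**Angular correlations.** `angular_correlation()` computes
$\langle \hat u(t_0)\cdot\hat u(t_0+t)\rangle$ over all molecules and all
overlapping time origins. Overlapping origins maximise statistics but
correlate successive lags; no independence correction is applied, and the
fitted decay time should be read accordingly. The exponential time constant
is obtained by log-linear regression over lags where the ACF exceeds 0.05,
below which log-noise dominates. ACF(0) = 1 exactly by unit-vector
normalisation, and the function is invariant under global rotations (both
are tested).

# The synthetic-data generator

The generator replaces instruments and the MD engine, producing every input
with known ground truth at the study conditions: 64 log-spaced recovery
delays from 5 ms to 50 s; recovery components (350 ms mono; 360/1100 ms at
65/35; 170/600 ms at 74/26 for the humid scenario); FIDs with
$f_G = 0.9$, $T_{2G} = 10$ µs, $T_{2E} = 80$ µs; three-parameter BPP
processes per the reference activation table at 25 MHz; diffraction peaks
at 6.6°, 16.4°, 19.2°, 22.4° 2θ broadened by the inverse Scherrer relation;
and amorphous boxes at the simulated composition (6 chains × 100 monomers,
120 small molecules, 52.04 Å box; 420 waters in the hydrated variant).

Noise models: additive Gaussian on recovery and FID amplitudes (they are
baseline-subtracted); multiplicative log-normal on $T_1(T)$ (its error is
relative). Identical spec and seed give bit-identical output; the global
seed fans out to stages through a name-keyed hash (`derive_seed()`), so new
stages never disturb existing streams.

**Planted hydrogen-bond networks.** `gen_box()` must produce a box whose
*measured* census (via `detect_hbonds()` at 3.5 Å/30°) equals a requested
per-molecule bond-count plan exactly. Requested percentages are first
rounded to achievable integer counts (largest-remainder, with the total
number of within-class bond ends made even). Within-class bonds are
realised as a *forest*: tree edges can always be embedded one molecule at a
time, whereas cycles would impose simultaneous geometric constraints; the
published cluster statistics (dimers, trimers) do not require cycles.
Embedding is breadth-first: each bonded neighbour is placed with its
acceptor oxygen inside the donor's 24°/2.65–3.35 Å tolerance region (safely
inside the detection criteria), growing outward along an axis tilted 55°
off the bond so the new molecule extends away from the cluster while its
own hydrogens stay clear of the 32° reverse-bond cone. Two placement rules
make accidental bonds *impossible* rather than merely unlikely: every
non-planted oxygen–oxygen pair across molecules is kept beyond 3.55 Å
(> the 3.5 Å cutoff), and any planted acceptor's own hydrogen is kept at
least 32° from the donor direction. Failed placements are retried, then the
component is re-laid-out, then the whole box is regenerated from a derived
seed; the finished box is re-measured and the generator refuses to return
anything that does not reproduce its plan. Chains are deliberately
schematic — acceptor sites with correct counts and roles, no conformational
realism — and the limitations section below says what that implies.

Two-state torsional jump trajectories (`gen_torsion_trajectory()`) flip a
tagged bond between two angles as a Poisson process; for 180° states the
bond-vector ACF is analytically $e^{-2kt}$, the benchmark used to validate
the correlation machinery end to end.

**Composition bookkeeping.** The published composition table for the
simulated boxes is internally inconsistent (its atom totals do not match
its own composition lines: 6×100×17 + 120×29 = 13,680 ≠ 13,728); the
generator and `box_density()` therefore target the composition lines, which
reproduce the stated 1.11 g/cm³ at the stated box edge.

# What passing tests do and do not show

Synthetic curves share the exact functional form of the fitters, so
parameter-recovery tests validate the estimation machinery, units and
conventions — not the adequacy of mono/bi-exponentiality or the BPP
spectral density for any real formulation. The planted boxes have correct
site counts, roles and bond geometry but schematic chemistry: no packing
realism, no polymer conformations, no energetics; censuses and cluster
statistics are exercised exactly, but real trajectories will show thermal
geometry distributions these boxes do not. The ACF benchmark validates lag
averaging and fitting against an analytic model, not the mapping from any
specific molecular torsion to a measured NMR process.

# Problem sizes and determinism

The shipped tests and the acceptance script run, by choice, at the study's
own scales where that is cheap (64-point recovery curves, 91-point
temperature sweeps, four-peak Scherrer sets, one 120-molecule box at the
simulated composition) and at reduced scales for pure property checks
(20–60-molecule boxes for oracle equivalence, 5,000-frame jump trajectories
for the ACF benchmark). Everything is seeded; rerunning any example or the
full pipeline (`run_pipeline(pipeline_config(preset = "paper-replay"))`)
with the same seed reproduces identical numbers and manifest hashes.

# Known limitations

- Saturation-recovery and FID models only; no inversion recovery, CPMG, or
  instrument-level corrections (phasing, dead time).
- The BPP spectral density with a single Arrhenius correlation time per
  process; no Cole–Davidson or correlation-time distributions.
- Scherrer sizing without instrumental-broadening subtraction or
  Williamson–Hall separation of strain.
- Orthorhombic boxes and minimum-image convention only; no binary
  trajectory formats (DCD/XTC) in this version.
- `gen_box()` plans are per-molecule count distributions for four bond
  classes with waters as donors; it does not plant small-molecule→water
  bonds or bond-length/angle *distributions*.
- Hydrogen-bond kinetics (lifetimes, rates) are out of scope; the census is
  static per frame.
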