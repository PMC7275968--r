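---
title: "Methods: derivative-ratio and MCR-ALS quantification of overlapped UV-Vis spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: derivative-ratio and MCR-ALS quantification of overlapped UV-Vis spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadspec)
```

`quadspec` quantifies atenolol (AT), paracetamol (PR), hydrochlorothiazide
(HZ) and levofloxacin (LV) in mixtures whose UV absorption bands overlap
across the whole 200–330 nm range, optionally in the presence of an
uncalibrated urine background. This vignette explains the two methods, the
assumptions they rest on, the tunable parameters and their defaults, what
the synthetic-spectra generator does and does not emulate, and the numerical
design choices made where the design was genuinely open.

## Model assumptions

Both methods assume additive Beer–Lambert absorbance at a 1 cm path:
the mixture spectrum is the concentration-weighted sum of the pure-component
spectra, `A(λ) = Σ_k c_k u_k(λ)`, with photometric noise added per
wavelength. No baseline, scatter or smoothing preprocessing is applied
anywhere in the package — the raw (or simulated) absorbances enter the
calculations directly.

## Extended derivative ratio (EDR)

For target analyte `t`, a *divisor* spectrum is stored: a ternary mixture of
the three other analytes at fixed concentrations. Dividing a mixture
spectrum by the divisor gives

`A_mix(λ)/A_div(λ) = c_t · u_t(λ)/A_div(λ) + g(λ)`,

where `g` collects the interferent contributions. When the interferent
profile in the sample is proportional to the divisor recipe, `g` is constant
in λ and any derivative removes it exactly — this is the method's core
invariance, and it holds to machine precision in the package (see the
interferent-invariance tests). For general interferent proportions `g` is
only approximately constant; the residual derivative at the analytical
wavelength ("leakage") is what limits accuracy on arbitrary mixtures, which
is why the analytical wavelengths are chosen where that leakage is
negligible for all three interferents simultaneously.

Fixed method parameters (per target): divisor recipes
AT ← PR 7 / HZ 2 / LV 4 µg/mL, PR ← AT 15 / HZ 3 / LV 5,
HZ ← AT 15 / PR 10 / LV 5, LV ← AT 15 / PR 7 / HZ 2; derivative order 2 for
AT and LV, 1 for PR and HZ; Δλ = 4 nm (2 nm for HZ); scaling factor 10;
analytical wavelengths 281.6 / 237.6 / 279.2 / 282.8 nm.

**Δλ semantics.** Instrument software leaves the derivative kernel
unspecified, so the package fixes one reproducible choice: a Savitzky–Golay
derivative whose window spans Δλ nm (`round(Δλ/step) + 1` points, forced
odd — 21 points for Δλ = 4 nm on the 0.2 nm grid), fitting a polynomial of
degree `order + 1`, reported in per-nm units, with the scaling factor
applied as a pure display multiplier *after* differentiation. Amplitudes
therefore match other implementations only up to an instrument-kernel
constant; calibration and prediction share the kernel, so predictions are
unaffected.

**Division guard.** Grid points where the divisor magnitude falls below
1 × 10⁻³ AU are flagged unusable (`NA`) and propagate through the derivative
window; an analytical wavelength that touches a guarded region raises an
error rather than returning a silently unstable amplitude. With the default
divisors, every analytical wavelength sits in a region where the divisor is
well above the guard.

**Calibration.** Pure-target standards are divided by the divisor,
differentiated and read at the analytical wavelength; amplitude is
regressed on concentration by ordinary least squares. On noiseless data the
fit is exact (r² = 1, intercept 0). LOD and LOQ use the ICH
intercept-deviation form, 3.3 and 10 times `S_a/|b|`. Negative predicted
concentrations are returned as-is with a warning; truncation is left to the
caller.

## MCR-ALS with non-negativity and correlation constraints

The spectra matrix `D` (samples × wavelengths, 220–290 nm at 0.4 nm) is
decomposed as `D = C Sᵀ + E` with five components: the four analytes plus
one free component for the uncalibrated background. Model quality is
reported as lack of fit, `lof% = 100·√(ΣE²/ΣD²)`, and explained variance,
`100·(ΣD² − ΣE²)/ΣD²`; the two satisfy
`explained = 100 − lof²/100` identically, which the tests assert for every
fitted model.

**Initialisation (SIMPLISMA).** Purest wavelengths are selected by the
purity criterion `p_j = s_j/(μ_j + offset)` with `offset = 5 %` of the
largest column mean, deflated after each pick by the determinant weight on
the correlation-around-origin matrix of the length-scaled data. The initial
spectral estimates are the non-negative least-squares solution of the data
on the pure-variable columns. The tests check the ranking against an
independent QR/residual-volume oracle.

**Alternating updates.** Each iteration solves the rows of `C` by
non-negative least squares given `S` (Lawson–Hanson active-set, compiled),
applies the correlation constraint to the analyte columns, and solves the
columns of `S` likewise given `C`. Iteration stops when the relative change
in lack of fit drops below 0.01 % or after 100 iterations, keeping the
best-so-far model (the best-model sequence is non-increasing by
construction; on this problem the raw lof sequence is also monotone after
the burn-in, which the tests assert).

**Component assignment and burn-in.** Components are matched to analytes by
greedy maximal absolute correlation between resolved concentration columns
and the references — but only after 5 unconstrained burn-in iterations.
Assigning on the very first iteration occasionally locks a wrong
component-to-analyte mapping (the SIMPLISMA ordering of strongly collinear
components is not reliable at iteration 1), from which the constrained
iteration cannot escape; the short burn-in makes the assignment stable
across noise realisations.

**Correlation-constraint variant.** Two standard variants are implemented.
The default, `"equality"`, replaces the calibration entries of each analyte
column with the known reference concentrations, so resolved concentrations
are in µg/mL directly and the stored per-analyte regression is the identity.
The alternative, `"regression"`, regresses resolved on reference values each
iteration, replaces calibration entries by the fitted values and converts
unknowns through the inverse regression. The equality variant is the default
because on exactly bilinear (noise-free) data the regression variant admits
degenerate self-consistent fixed points — the free intercept lets a
mis-scaled solution reproduce itself, stalling at a lack of fit far above
the attainable one — whereas the equality variant converges monotonically to
the generating profiles in every tested configuration.

**Rotational ambiguity.** With the analyte columns anchored, the only
remaining indeterminacy is mixing between each analyte spectrum and the free
component: `(s_a, c_u) → (s_a − µ·u_u, c_u + µ·ref_a)` leaves `C Sᵀ`
unchanged for any µ. Non-negativity bounds µ on both sides: subtraction is
limited by the smallest ratio `s_a/u_u` across the window, addition by the
calibration rows with near-zero background level. The generator's urine
levels are drawn from a wide range starting near zero (0.05–1.5) precisely
so that those boundary constraints pin the solution close to the true
profiles; the resolved spectra then correlate with the generating ones
above 0.999.

**Prediction.** Unknown spectra are projected onto the fixed resolved
spectra by non-negative least squares and the analyte columns are converted
through the stored regressions. Samples containing the background component
at levels never seen in calibration remain quantifiable because the free
component absorbs them.

## The calibration design

The five-level four-factor design has 25 runs: run 1 holds every factor at
the centre level, factor 1 follows a fixed cyclic sequence of the 24
remaining coded levels, and each subsequent factor repeats the previous one
with runs 2–25 rotated up by one position. Every factor takes each level
exactly five times and distinct coded columns are exactly orthogonal, so the
four analytes' concentrations are mutually uninformative across the design.
Concentration levels are AT {5, 10, 15, 20, 25}, PR and HZ
{1, 3.5, 5.5, 8, 10}, LV {1, 2.5, 4, 5.5, 7} µg/mL. Seven fixed runs
(3, 4, 9, 15, 18, 20, 23) form the external validation set; the other 18
build the model. The bundled `reference_design25.csv` fixture carries the
same matrix with its validation flags, and the generator reproduces it
exactly.

## The synthetic-spectra generator

No instrument data ship with the package; a seeded generator stands in for
them. Each component is a sum of Gaussian bands (absorbance per µg/mL), and
mixtures are exactly bilinear with i.i.d. Gaussian photometric noise added
per grid point.

What the generator emulates:

* the qualitative band layout of the four drugs — AT weak with maxima near
  225 and in the high 270s, PR strong in the low 240s, HZ with maxima near
  226/273/317, LV strong in the high 280s — over a shared rising
  end-absorption edge below 220 nm and a broad common backbone, giving the
  strong pairwise overlap (all pairwise correlations positive over
  220–290 nm) that motivates the methods;
* a broad, featureless urine background whose in-window shape is close to
  the drugs' common mode but retains an out-of-span part (≈ 35 % of its
  norm), so it is identifiable as a fifth component;
* per-sample background variability: urine levels uniform on 0.05–1.5
  units;
* photometric noise: σ = 0.002 AU additive Gaussian per 0.2 nm grid point
  (a deliberate design constant; instrument noise is not reported for the
  reference data).

The sharp sub-bands near the four analytical wavelengths were calibrated
once, as versioned constants, so that each wavelength is informative for its
target (adequate derivative sensitivity relative to the noise floor) and the
derivative-ratio leakage of the other three components is nulled there —
the property the original wavelengths were selected for empirically. A
consequence of fixing the noise at 0.002 AU while requiring percent-level
recoveries down to 1 µg/mL is that the synthetic absorptivities are larger
than the real drugs'; mixture absorbances can exceed the linear range of a
real instrument. Because the generator is exactly bilinear by construction,
this affects realism, not correctness.

What it does not emulate: baseline drift, stray light, wavelength-axis
error, Beer-law deviations at high absorbance, heteroscedastic or correlated
noise, and any quantitative match to real spectra or published regression
coefficients. Passing tests therefore demonstrate the *methods* — exact
interferent invariance, resolution of five overlapped components,
correct statistics — not instrument-level performance on real samples.

Reproducibility: one seed per dataset; the spectrum of row *i* uses seed
`seed + i`, so any single spectrum can be regenerated in isolation.

## Validation statistics

Figures of merit for predicted-vs-known concentrations are RMSEP, bias,
SEP (bias-corrected, n − 1 denominator) and RE%, which satisfy
`RMSEP² = bias² + SEP²·(n−1)/n` identically. Recoveries, their SDs, and
RSDs all use the sample (n − 1) standard deviation. Method comparison
offers both the pooled-variance two-sample t from summary statistics and a
paired t from raw values — published tables often print only summaries, so
both are labelled explicitly. The F statistic is always the larger variance
over the smaller (≥ 1, symmetric in the methods). Full precision is kept
internally; rounding (2 decimals for concentrations and statistics, 1 for
percentages) is applied only in reports.

Urinary excretion converts a measured (back-calculated) urine concentration
and collected volume to the excreted amount and percent of dose.

## Greenness

The Analytical Eco-Scale deducts penalty points from 100: each reagent
contributes amount points × hazard points (so a non-hazardous reagent such
as water contributes nothing, whatever its amount bracket), and instrument
items — energy, occupational exposure, waste — contribute additively. The
bundled rule table (`eco_scale_rules.csv`) is an editable CSV so any sheet
is auditable. The standard spectrophotometric workflow (water and ethanol
under 10 mL, < 0.1 kWh per sample, no vapour emission, 1–10 mL waste)
scores 95. The NEMI profile is four caller-supplied booleans (PBT-free,
non-hazardous, 2 ≤ pH ≤ 12, waste < 50 g) rendered as a quadrant diagram;
chemical classification look-ups are out of scope.

## Numerical choices and limitations

* Wavelength grids are closed intervals addressed by physical nm;
  decimation (0.2 → 0.4 nm) keeps every second point from the window start.
* The division guard is 1 × 10⁻³ AU; guarded points and incomplete
  derivative windows are `NA`, never silently extrapolated.
* NNLS is Lawson–Hanson with a tolerance of 1 × 10⁻¹⁰ on the normal
  equations; an all-zero resolved component aborts the fit with an error
  rather than returning a degenerate model.
* Test and acceptance problem sizes are the study conditions themselves:
  651-point acquisition spectra, the 25-run design, 18/7 split, 176-point
  working window — small enough that the full suite runs in seconds.
* The EDR leakage nulling holds for the built-in library at the built-in
  divisor recipes and wavelengths; user-supplied component models or
  recipes require re-checking interferent leakage (the invariance to
  divisor-proportional backgrounds holds for any library).
* The MCR spectral profiles are identifiable only up to the non-negativity
  bounds on mixing with the free component; concentration predictions for
  the constrained analytes are unaffected by that residual ambiguity.
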