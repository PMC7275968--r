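# quadspec

Quantification of four co-formulated drugs — atenolol (AT), paracetamol
(PR), hydrochlorothiazide (HZ) and levofloxacin (LV) — from severely
overlapped UV-Vis absorption spectra (200–330 nm), including in the
presence of an uncalibrated urine background. The four analytes absorb
across the same wavelength range, so none of them can be read off a
zero-order spectrum; `quadspec` implements two complementary resolution
strategies for exactly this situation, plus everything needed to validate
them.

## Methods

**Extended derivative ratio (EDR).** Under additive Beer–Lambert
absorbance, dividing a mixture spectrum by the stored spectrum of a ternary
mixture of the three *other* analytes turns their joint contribution into an
additive term that is constant in wavelength whenever the interferent
profile is proportional to the divisor; differentiation annihilates it,
leaving a derivative amplitude proportional to the target concentration:

    A_mix(λ) / A_div(λ) = c_target · u_target(λ)/A_div(λ) + K,
    d/dλ [A_mix/A_div](λ*) ∝ c_target.

The derivative is a Savitzky–Golay smoothed derivative whose window spans
Δλ nm (order + 1 polynomial), scaled ×10, read at per-analyte analytical
wavelengths: 281.6 nm (AT, 2nd derivative, Δλ = 4), 237.6 nm (PR, 1st, 4),
279.2 nm (HZ, 1st, 2), 282.8 nm (LV, 2nd, 4). Calibration is ordinary least
squares of amplitude on concentration, with ICH limits
LOD = 3.3·S_a/|b|, LOQ = 10·S_a/|b|.

**Correlation-constrained MCR-ALS.** The spectra matrix is decomposed as
`D = C Sᵀ + E` by alternating non-negative least squares (Lawson–Hanson,
compiled), initialised from SIMPLISMA purest wavelengths, with a
correlation constraint that anchors the four analyte columns of `C` to the
known calibration concentrations each iteration. A fifth, unconstrained
component absorbs the urine background, so analytes are quantified even
though urine was never calibrated. Model quality is tracked as
lack of fit, `lof% = 100·√(ΣE²/ΣD²)`, and explained variance
`= 100 − lof²/100`.

Supporting modules: the five-level four-factor 25-run calibration design
(balanced, mutually orthogonal coded columns; 18/7
calibration/validation split), a seeded synthetic-spectra generator (five
Gaussian-band component models emulating the four drugs plus urine),
prediction figures of merit (RMSEP, SEP, bias, RE%), recovery/RSD/t/F
statistics, urinary-excretion arithmetic, and greenness assessment (NEMI
profile and the Analytical Eco-Scale).

## Worked example

```r
library(quadspec)

# design and synthetic spectra at the study noise level (0.002 AU)
design <- scale_design(multilevel_design(5, 4), default_levels())
spec   <- simulate_dataset(cbind(design, URINE = urine_levels(25, seed = 1017)),
                           default_library(), acquisition_grid(),
                           sigma = 0.002, seed = 17)

# EDR: calibrate paracetamol, then quantify it in a four-drug mixture
def <- edr_defaults("PR")
div <- divisor_spectrum(default_library(), def$divisor_concs)
std <- simulate_dataset(matrix(c(1, 5, 10, 15, 20, 25), ncol = 1,
                               dimnames = list(NULL, "PR")),
                        default_library(), sigma = 0.002, seed = 21)
cal <- edr_calibrate(std, c(1, 5, 10, 15, 20, 25), div, "PR")
print(cal)
#> EDR calibration for PR
#>   derivative order 1, delta-lambda 4 nm, scaling 10
#>   amplitude at 237.6 nm = -0.00026774 + 0.112185 x conc  (r2 = 1.000000)
#>   S_a = 0.000332, S_b = 2.19e-05, LOD = 0.00975, LOQ = 0.0295 ug/mL
#>   calibration range 1-25 ug/mL (n = 6)

mix <- mixture_spectrum(default_library(), c(AT = 15, PR = 10, HZ = 3, LV = 6),
                        sigma = 0.002, seed = 5)
predict(cal, mix)
#> 9.998   # ug/mL, nominal 10
```

The slope (0.1122 amplitude units per µg/mL) is the method's sensitivity at
237.6 nm; the near-zero intercept and r² = 1.000000 confirm the ratio-then-
derivative step removed the interferent term, and the LOD/LOQ translate the
intercept noise into the smallest quantifiable concentration.

```r
# MCR-ALS on the 18 calibration runs, predict the 7 validation runs
sp  <- split_calibration_validation(design)
sw  <- spec_resample(spec_window(spec, 220, 290), 0.4)
fit <- mcr_als(sw[sp$calibration_rows], sp$calibration)
print(fit)
#> MCR-ALS model: 5 components, 18 samples x 176 wavelengths
#>   lack of fit 0.0174%, explained variance 99.999997%
#>   100 iterations (not converged), constraint variant 'equality'
#>   analyte components: AT -> AT, PR -> PR, HZ -> HZ, LV -> LV

round(100 * predict(fit, sw[sp$validation_rows]) / sp$validation, 2)
#>        AT     PR     HZ     LV
#> 3  100.01 100.03  99.98 100.00
#> 4  100.01 100.00  99.97 100.00
#> 9  100.03  99.99  99.96  99.99
#> 15 100.01 100.00 100.01  99.99
#> 18  99.98 100.03 100.05 100.01
#> 20 100.02 100.00  99.99  99.97
#> 23 100.00  99.89  99.97  99.99
```

The lack of fit (0.017 %) is at the level implied by 0.002 AU noise, the
fifth (urine) component is left free, and all 28 validation recoveries sit
within ±0.11 % of nominal.

```r
eco_scale(eco_items_default())$score   # 95: excellent green analysis
nemi(TRUE, TRUE, TRUE, TRUE)$all_green # TRUE
```

A command-line interface over the same functions is installed at
`system.file("cli", "quadspec.R", package = "quadspec")` with subcommands
`design`, `simulate`, `edr-calibrate`, `edr-predict`, `mcr-fit`,
`mcr-predict`, `validate`, `greenness` and `demo`.

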