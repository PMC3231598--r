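# etongue

Simulation, characterisation and neural-network calibration of a
potentiometric **electronic tongue** — an array of cross-sensitive
ion-selective electrodes (ISEs) whose combined signal is inverted by a
multivariate model — applied to the simultaneous determination of **sulfide
(S²⁻) and perchlorate (ClO₄⁻)** in water. The package is aimed at
chemometricians and sensor researchers who want a fully reproducible,
testable software counterpart of such a study: every experiment table is
generated in code from a published electrode parameterisation, and every
estimation stage is validated by recovering those generating parameters.

## The model

Each electrode follows the Nikolsky–Eisenmann response law

    E = E0 + s · log10[ a_i + a_bg + Σ_j k_pot(i,j) · a_j^(z_i/z_j) ]

with single-ion activities `a = γc` from the Davies equation (extended
Debye–Hückel optional), slope `s` in mV/decade, selectivity coefficients
`k_pot`, signed charge ratios in the exponent (½ for ClO₄⁻ vs S²⁻, 2 the
other way round), and a background activity `a_bg` that produces the
low-concentration flattening and equals the electrode's IUPAC detection
limit. The shipped five-electrode panel (`default_panel()`) encodes the
published response characteristics of electrodes P1, S1–S3 and G.

The inverse model is a 5-input, 2-output single-hidden-layer perceptron
(default 8 `tansig` units, linear output) trained by **Bayesian
regularisation**: Levenberg–Marquardt descent on `F = β·E_D + α·E_W` with
MacKay evidence updates `γ = N_w − 2α·tr(H⁻¹)`, `α ← γ/(2E_W)`,
`β ← (n−γ)/(2E_D)`. Evaluation reproduces the study's framework: RMSE,
obtained-vs-expected regressions with 95% intervals, percentage relative
errors, a single-electrode interpolation baseline, and paired t tests
against nominal concentrations.

## Worked example

```r
library(etongue)

## noise-free characterisation recovers the shipped panel parameters
ch <- characterize_array(default_panel(), noise_sd = 0, n_sessions = 0)
ch$table[, c("id", "primary_ion", "slope", "lod", "interferent", "log_k_pot")]
#>   id primary_ion slope       lod interferent log_k_pot
#> 1 P1        ClO4 -57.7 5.274e-06           S    -1.953
#> 2 S1           S -33.3 1.315e-05        ClO4    -2.674
#> 3 S2           S -30.9 9.878e-06        ClO4    -3.222
#> 4 S3           S -28.9 9.978e-06        ClO4    -3.741
#> 5  G           S -44.3 8.378e-06        ClO4     1.156

## full study pipeline under 0.5 mV reading noise
res <- run_pipeline(seed = 1)
print(res$model)
#> Electronic-tongue inverse model: 5-8-2 MLP (tansig/purelin)
#>   strategy: bayesian_regularization, 300 epochs (max_epochs), best of 5 restart(s)
#>   F = 59, E_D = 0.002819, E_W = 55.34, alpha = 0.382, beta = 1.34e+04, gamma_eff = 42.3 / 66
#>   train RMSE 1.14e-06 mol/L; test RMSE 7.7e-06 mol/L

round(rbind(ET = res$evaluation$mean_rel_err_et,
            single_ISE = res$evaluation$mean_rel_err_baseline), 2)
#>              ClO4     S
#> ET           7.18  3.52
#> single_ISE 124.17 12.31

res$evaluation$t_tests$ClO4
#> Paired t test: t = -2.366, df = 5, critical t* = 2.57 (95%), p = 0.0643
#> no significant difference from the nominal values
```

Reading: the electrode slopes, detection limits (activity scale) and log
selectivity coefficients are recovered from simulated calibrations — exactly
on noise-free data, as above. The trained array resolves spiked
application mixtures with mean relative errors of a few percent for sulfide
and 5–8% for perchlorate (the array's single ClO₄⁻ electrode loses
sensitivity under sulfide interference at the low end), while conventional
one-electrode interpolation fails outright on perchlorate (~100% error on
sulfide-rich mixtures). `summary(res$model)` and `plot(res$model)` show the
obtained-vs-expected comparisons; `run_pipeline(..., outdir = "out")` writes
all tables, the model JSON and a run log, regenerable from `(config, seed)`.

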