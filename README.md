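# robustfc

Statistically valid resting-state functional connectivity for slow
hemodynamic time series (fNIRS and similar modalities).

## The problem and who this is for

The textbook Pearson correlation and its p-value assume serially independent
samples. Hemodynamic recordings violate that assumption twice over: the
vascular impulse response is a slow (~10 s) low-pass filter, so neighboring
samples are strongly dependent, and transient motion artifacts add
heavy-tailed outliers that often hit several channels at once. Between two
*independent* channels the variance of the sample correlation is inflated by
`c^2 = 1 + 2 * sum_k rho_A(k) * rho_B(k)` (the product of the channels'
autocorrelations), so a nominal 5% test can reject 40–90% of the time, and a
single shared artifact can drive the estimate toward ±1 through leverage.
Anyone computing all-to-all connectivity from such data — or simulating it to
check a pipeline's type-I error — is the intended user.

## The estimators

- **Prewhitening** (`fit_ar`, `prewhiten_pair`): each channel is fitted with
  an AR(P) model `Y[t] = sum a_i Y[t-i] + e[t]`, P selected by BIC up to
  `min(ceiling(10 * fs), 40)`, and replaced by its innovations `e[t]` — a
  serially flat series for which the t reference distribution is honest.
- **Joint preweighting** (`joint_preweight`): samples whose bivariate radius
  `r[t] = sqrt(A[t]^2 + B[t]^2)` is an outlier of the radius distribution are
  downweighted by a translated square-root Tukey bisquare
  (`kappa = 4.685`, scale `1.4826 * MAD`), catching artifacts that co-occur
  in both channels.
- **Bidirectional robust correlation** (`robust_correlation`,
  `fc_correlate`): iteratively reweighted regression in both directions, each
  slope scaled to correlation units by the MAD scale ratio, combined as
  `|R| = sqrt(R_ab * R_ba)` with a p-value on the weighted effective degrees
  of freedom. With unit weights this is algebraically identical to Pearson.
- **Wavelet coherence** (`fc_coherence`): smoothed Morlet squared coherence
  `|S(Wab/s)|^2 / (S(|Wa|^2/s) S(|Wb|^2/s))`, plain (`wCOH`) or on the
  innovations (`AR-wCOH`), with a scalar statistic (mean squared coherence
  outside the cone of influence) and a surrogate-data p-value.

Comparison models `COR`, `LPF-COR`, `W-COR`, `AR-COR`, `AR-W-COR` are
selectable by name. `run_fdr_experiment()`, `run_roc_experiment()` and
`calibration_curve()` reproduce the Monte-Carlo characterizations
(false-discovery rate vs sampling rate, ROC/AUC, p-value calibration) on
synthetic hemodynamic signals built by `simulate_neural_pair()`,
`canonical_hrf()`, `hemodynamic_convolve()` and `inject_motion()`.

## Worked example

Two channels with true correlation 0.5, 5% co-occurring 10x-variance motion
artifacts, convolved with the canonical HRF at 4 Hz:

```r
library(robustfc)
pair <- simulate_neural_pair(3000, rho = 0.5, seed = 42, fs = 4)
pair <- inject_motion(pair, fraction = 0.05, var_scale = 10, seed = 43)
h <- canonical_hrf(4)
a <- hemodynamic_convolve(pair$a, h)
b <- hemodynamic_convolve(pair$b, h)

fc_correlate(a, b, method = "COR")
#> COR connectivity: A ~ B
#>   r = 0.5282  (effective dof = 2998.0, p = 3.16e-215)
fc_correlate(a, b, method = "AR-W-COR")
#> AR-W-COR connectivity: A ~ B
#>   r = 0.4338  (effective dof = 2800.0, p = 6.29e-129)
#>   AR orders: 13 / 11
```

Both find the connection. The difference shows on a **null** pair (true
correlation zero) with the same artifacts:

```r
null <- simulate_neural_pair(3000, rho = 0, seed = 44, fs = 4)
null <- inject_motion(null, 0.05, 10, seed = 45)
an <- hemodynamic_convolve(null$a, h); bn <- hemodynamic_convolve(null$b, h)

fc_correlate(an, bn, method = "COR")
#> COR connectivity: A ~ B
#>   r = -0.1042  (effective dof = 2998.0, p = 1.06e-08)
fc_correlate(an, bn, method = "AR-W-COR")
#> AR-W-COR connectivity: A ~ B
#>   r = -0.0033  (effective dof = 2814.7, p = 0.861)
#>   AR orders: 13 / 13
```

The naive estimator declares a wildly significant spurious connection
(p = 1e-8); the robust prewhitened estimator reports r = -0.003, p = 0.86.
The serial correlation alone — no motion needed — makes naive p-values
untrustworthy: on independent HRF-convolved channels at 1 Hz the naive test
with nominal p < 0.05 rejects about 40% of the time (see below), against 5%
for its prewhitened counterpart.

A command-line surface wraps the same functionality
(`inst/cli/robustfc connectivity <table.csv> --fs 4 --method AR-W-COR
--fdr-correct --out net`, plus `simulate-fdr`, `simulate-roc`, `calibrate`),
writing CSV tables and a JSON manifest for every run.

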