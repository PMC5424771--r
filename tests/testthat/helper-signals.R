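# shared fixture builders (all data generated in code)

# stationary AR series with a burn-in
gen_ar <- function(n, coefs, seed, sd = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = coefs), n, sd = sd))
}

# HRF-convolved null or correlated pair at a given rate
gen_hemo_pair <- function(n, fs, rho = 0, seed = 1) {
  pair <- simulate_neural_pair(n, rho = rho, seed = seed, fs = fs)
  h <- canonical_hrf(fs)
  list(a = hemodynamic_convolve(pair$a, h),
       b = hemodynamic_convolve(pair$b, h))
}

# combined robust estimate assembled from the exported building blocks;
# used to cross-check fc_correlate against its own components
combined_from_parts <- function(av, bv, pw) {
  f1 <- robust_regress(av, bv, preweights = pw)
  f2 <- robust_regress(bv, av, preweights = pw)
  sqrt(abs(f1$coefficients[["slope"]] * f2$coefficients[["slope"]]))
}
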