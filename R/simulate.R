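#' Canonical hemodynamic response function
#'
#' Double-gamma kernel: a positive gamma lobe peaking at `peak_time` seconds
#' minus an undershoot gamma lobe peaking at `undershoot_time` seconds scaled
#' by `ratio`, sampled over a 32-s support and normalized to unit peak
#' amplitude. This is the slow impulse response that links "neural" activity
#' to the measured hemodynamic signal; convolving white noise with it produces
#' the serially correlated null signals used throughout the simulation
#' harness.
#'
#' @param fs sampling rate in Hz.
#' @param peak_time time of the response peak (s).
#' @param undershoot_time time of the undershoot trough (s).
#' @param ratio undershoot amplitude ratio.
#' @param duration kernel support in seconds.
#' @return An object of class `fc_hrf` with `taps`, `fs`, `peak_time`.
#' @export
canonical_hrf <- function(fs, peak_time = 6, undershoot_time = 16,
                          ratio = 1 / 6, duration = 32) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  L <- round(duration * fs)
  if (L < 2L) stop("sampling rate too low: kernel would have fewer than 2 taps")
  t <- (0:(L - 1L)) / fs
  # gamma density with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = peak_time + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_time + 1, rate = 1)
  h <- h / max(h)
  structure(list(taps = h, fs = fs, peak_time = t[which.max(h)]),
            class = "fc_hrf")
}

#' @export
print.fc_hrf <- function(x, ...) {
  cat(sprintf("<fc_hrf> %d taps at %g Hz, peak at %g s\n",
              length(x$taps), x$fs, x$peak_time))
  invisible(x)
}

#' Simulate a pair of i.i.d. Gaussian "neural" signals
#'
#' Draws `n` samples from a bivariate standard normal with correlation `rho`
#' (off-diagonal of the covariance model). `rho = 0` gives the null pairs used
#' for false-discovery experiments.
#'
#' @param n number of samples per channel.
#' @param rho true correlation, `|rho| < 1`.
#' @param seed optional seed; identical seeds give bit-identical output.
#' @param fs sampling rate attached to the channels (Hz).
#' @return list with [fc_ts] elements `a` and `b`.
#' @export
simulate_neural_pair <- function(n, rho = 0, seed = NULL, fs = 1) {
  if (!is.numeric(n) || n < 2L) stop("n must be at least 2")
  if (!is.numeric(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  list(a = fc_ts(z1, fs = fs, label = "A"),
       b = fc_ts(rho * z1 + sqrt(1 - rho^2) * z2, fs = fs, label = "B"))
}

#' Convolve a neural signal with an HRF kernel
#'
#' Linear (causal) convolution truncated to the input length, so a unit
#' impulse at the first sample returns the kernel taps. The output is the
#' serially correlated "hemodynamic" signal.
#'
#' @param x an [fc_ts] or numeric vector.
#' @param hrf an `fc_hrf` from [canonical_hrf()] at the same sampling rate.
#' @param fs sampling rate when `x` is a bare vector.
#' @return [fc_ts] of the same length and rate as `x`.
#' @export
hemodynamic_convolve <- function(x, hrf, fs = NULL) {
  stopifnot(inherits(hrf, "fc_hrf"))
  fsr <- ts_fs(x, fs)
  if (!isTRUE(all.equal(fsr, hrf$fs)))
    stop(sprintf("sampling rates differ: signal %g Hz, kernel %g Hz", fsr, hrf$fs))
  v <- ts_values(x)
  n <- length(v)
  y <- stats::convolve(v, rev(hrf$taps), type = "open")[seq_len(n)]
  fc_ts(y, fs = fsr, label = ts_label(x))
}

#' Inject transient heteroscedastic ("motion") artifacts into a pair
#'
#' Adds zero-mean Gaussian noise with `var_scale` times each channel's base
#' variance to `round(fraction * n)` samples. With `shared_times = TRUE`
#' (co-occurring artifacts) the same sample indices are hit in both channels;
#' the added values are drawn independently per channel unless
#' `identical_values = TRUE`. This emulates heavy-tailed motion contamination
#' of the neural signals before hemodynamic convolution.
#'
#' @param pair list with elements `a`, `b` as returned by
#'   [simulate_neural_pair()].
#' @param fraction proportion of contaminated samples, in `[0, 1)`.
#' @param var_scale added-noise variance as a multiple of the channel variance.
#' @param shared_times hit the same indices in both channels.
#' @param identical_values reuse the same artifact values in both channels
#'   (the fully shared motion scenario).
#' @param seed optional seed.
#' @return list with contaminated `a`, `b`; the artifact indices are attached
#'   as attribute `"motion_indices"` (a list for unshared times).
#' @export
inject_motion <- function(pair, fraction = 0.05, var_scale = 10,
                          shared_times = TRUE, identical_values = FALSE,
                          seed = NULL) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  if (var_scale < 0) stop("var_scale must be non-negative")
  if (fraction == 0) return(pair)
  av <- ts_values(pair$a); bv <- ts_values(pair$b)
  n <- length(av)
  k <- round(fraction * n)
  if (k < 1L) stop("fraction * n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  idx_a <- sample.int(n, k)
  idx_b <- if (shared_times) idx_a else sample.int(n, k)
  sd_a <- sqrt(var_scale * stats::var(av))
  sd_b <- sqrt(var_scale * stats::var(bv))
  noise_a <- stats::rnorm(k, sd = sd_a)
  noise_b <- if (identical_values) noise_a * (sd_b / sd_a)
             else stats::rnorm(k, sd = sd_b)
  av[idx_a] <- av[idx_a] + noise_a
  bv[idx_b] <- bv[idx_b] + noise_b
  out <- list(a = fc_ts(av, ts_fs(pair$a), ts_label(pair$a, "A")),
              b = fc_ts(bv, ts_fs(pair$b), ts_label(pair$b, "B")))
  attr(out, "motion_indices") <- if (shared_times) idx_a
                                 else list(a = idx_a, b = idx_b)
  out
}
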