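# Morlet wavelet machinery following the Torrence & Compo conventions
# (omega0 = 6, frequency-domain transform with zero padding, e-folding COI).

morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Default dyadic scale grid for the Morlet transform
#'
#' Scales run from `s0 = 2/fs` upward in steps of `dj` octaves (default 12
#' voices per octave) while the equivalent Fourier period stays within the
#' record length.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param dj scale resolution in octaves (default 1/12).
#' @param s0 smallest scale in seconds (default `2/fs`).
#' @param omega0 Morlet center frequency.
#' @return increasing vector of scales in seconds.
#' @export
morlet_scales <- function(n, fs, dj = 1 / 12, s0 = 2 / fs, omega0 = 6) {
  ff <- morlet_fourier_factor(omega0)
  smax <- (n / fs) / ff              # largest scale whose period fits the record
  if (smax < s0) stop("record too short for the requested smallest scale")
  J <- floor(log2(smax / s0) / dj)
  s0 * 2^(dj * (0:J))
}

#' Continuous Morlet wavelet transform
#'
#' Analytic Morlet mother wavelet (`omega0 = 6` by default), computed by
#' frequency-domain convolution with zero padding to the next power of two
#' past twice the record length. Scales whose Fourier period exceeds the
#' record length are excluded with a warning.
#'
#' @param y an [fc_ts] or numeric vector of length >= 32.
#' @param scales vector of wavelet scales in seconds; default [morlet_scales()].
#' @param omega0 Morlet center frequency.
#' @param fs sampling rate when `y` is a bare vector.
#' @return complex matrix, one row per scale, `length(y)` columns, with the
#'   (possibly reduced) scales attached as attribute `"scales"`.
#' @export
morlet_cwt <- function(y, scales = NULL, omega0 = 6, fs = NULL) {
  fs <- ts_fs(y, fs)
  v <- ts_values(y)
  n <- length(v)
  if (n < 32L) stop("need at least 32 samples for the wavelet transform")
  if (is.null(scales)) scales <- morlet_scales(n, fs, omega0 = omega0)
  if (is.unsorted(scales, strictly = TRUE)) stop("scales must be strictly increasing")
  ff <- morlet_fourier_factor(omega0)
  ok <- ff * scales <= n / fs
  if (!all(ok)) {
    warning(sprintf("%d scale(s) exceed the record length; excluded", sum(!ok)))
    scales <- scales[ok]
  }
  if (!length(scales)) stop("no usable scales")

  v <- v - mean(v)
  npad <- 2^(floor(log2(n)) + 2L)
  fy <- stats::fft(c(v, rep(0, npad - n)))
  k <- 0:(npad - 1L)
  omega <- 2 * pi * fs * ifelse(k <= npad / 2, k, k - npad) / npad
  pos <- omega > 0
  W <- matrix(0i, nrow = length(scales), ncol = n)
  norm0 <- pi^(-0.25)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    psi[pos] <- norm0 * sqrt(2 * pi * s * fs) * exp(-0.5 * (s * omega[pos] - omega0)^2)
    w <- stats::fft(fy * psi, inverse = TRUE) / npad
    W[j, ] <- w[seq_len(n)]
  }
  attr(W, "scales") <- scales
  W
}

# Convolve the rows of one or more matrices with per-scale Gaussian kernels
# (SD = scale, in time units) sharing the kernel FFTs, then boxcar-smooth
# across scales. Kernels are normalized to sum 1, so constants are preserved
# away from the record edges.
wc_smooth <- function(mats, scales, fs, dj = 1 / 12, dj0 = 0.6) {
  n <- ncol(mats[[1L]])
  ns <- length(scales)
  npad <- 2^ceiling(log2(3 * n))
  ffts <- lapply(mats, function(m) {
    t(apply(m, 1L, function(row) stats::fft(c(row, rep(0, npad - n)))))
  })
  out <- lapply(mats, function(m) matrix(0i, ns, n))
  for (j in seq_len(ns)) {
    sd_samp <- scales[j] * fs
    hw <- min(as.integer(ceiling(4 * sd_samp)), n)
    kern <- exp(-0.5 * ((-hw:hw) / sd_samp)^2)
    kern <- kern / sum(kern)
    kpad <- numeric(npad)
    kpad[seq_len(hw + 1L)] <- kern[(hw + 1L):(2L * hw + 1L)]
    kpad[(npad - hw + 1L):npad] <- kern[seq_len(hw)]
    fk <- stats::fft(kpad)
    for (i in seq_along(mats)) {
      sm <- stats::fft(ffts[[i]][j, ] * fk, inverse = TRUE) / npad
      out[[i]][j, ] <- sm[seq_len(n)]
    }
  }
  # scale smoothing: renormalized boxcar spanning dj0 (log2 units)
  h <- max(0L, as.integer(floor(dj0 / (2 * dj))))
  if (h > 0L && ns > 1L) {
    out <- lapply(out, function(m) {
      sm <- m
      for (j in seq_len(ns)) {
        idx <- max(1L, j - h):min(ns, j + h)
        sm[j, ] <- colMeans(m[idx, , drop = FALSE])
      }
      sm
    })
  }
  out
}

#' Smooth a wavelet-domain matrix
#'
#' Time smoothing with a Gaussian kernel whose standard deviation equals the
#' scale of each row, followed by scale smoothing with a renormalized boxcar
#' spanning 0.6 octaves (the Morlet decorrelation length). These are the
#' smoothing operators that make wavelet coherence well defined (unsmoothed
#' coherence is identically 1).
#'
#' @param w real or complex matrix, one row per scale.
#' @param scales scales (seconds) matching the rows of `w`.
#' @param fs sampling rate in Hz.
#' @param dj scale resolution of the grid in octaves.
#' @param dj0 boxcar width in octaves.
#' @return matrix of the same shape (complex if the input was).
#' @export
smooth_wavelet <- function(w, scales, fs, dj = 1 / 12, dj0 = 0.6) {
  if (nrow(w) != length(scales))
    stop("nrow(w) must equal length(scales)")
  res <- wc_smooth(list(w), scales, fs, dj = dj, dj0 = dj0)[[1L]]
  if (is.complex(w)) res else Re(res)
}

#' Morlet wavelet squared coherence
#'
#' Smoothed squared cross-spectral correlation over time and scale:
#' `R2 = |S(Wab / s)|^2 / (S(|Wa|^2 / s) * S(|Wb|^2 / s))`, where `S` is the
#' time-then-scale smoothing of [smooth_wavelet()] and the `1/s` factor
#' normalizes the spectra across scales. Values lie in `[0, 1]`; the e-folding
#' cone of influence marks the edge-affected region.
#'
#' @param a,b channels of equal length and sampling rate.
#' @param scales scale grid in seconds; default [morlet_scales()].
#' @param omega0 Morlet center frequency.
#' @param dj scale resolution in octaves.
#' @param fs sampling rate when `a`, `b` are bare vectors.
#' @return An object of class `fc_cohmap`: `coherence` (scales x time, in
#'   `[0,1]`), `scales`, `freqs` (equivalent Fourier frequencies, Hz), `coi`
#'   (largest unaffected scale per time point), `cross_spectrum` (smoothed
#'   complex cross spectrum), `fs`, and the whitening state.
#' @export
wavelet_coherence <- function(a, b, scales = NULL, omega0 = 6, dj = 1 / 12,
                              fs = NULL) {
  fsr <- check_pair(a, b, fs)
  av <- ts_values(a); bv <- ts_values(b)
  if (stats::var(av) == 0 || stats::var(bv) == 0)
    stop("zero-variance channel")
  n <- length(av)
  if (is.null(scales)) scales <- morlet_scales(n, fsr, dj = dj, omega0 = omega0)
  Wa <- morlet_cwt(av, scales, omega0 = omega0, fs = fsr)
  Wb <- morlet_cwt(bv, scales, omega0 = omega0, fs = fsr)
  scales <- attr(Wa, "scales")
  inv_s <- 1 / scales

  A2 <- (Mod(Wa)^2) * inv_s          # row-wise recycling over columns
  B2 <- (Mod(Wb)^2) * inv_s
  Xab <- (Wa * Conj(Wb)) * inv_s

  sm <- wc_smooth(list(A2 + 1i * B2, Xab), scales, fsr, dj = dj)
  SA <- Re(sm[[1L]]); SB <- Im(sm[[1L]]); SX <- sm[[2L]]
  den <- SA * SB
  coh <- Mod(SX)^2 / pmax(den, .Machine$double.xmin)
  coh[den <= 0] <- 0
  coh <- pmin(pmax(coh, 0), 1)

  coi <- (1 / fsr) * pmin(0:(n - 1L), (n - 1L):0) / sqrt(2)
  structure(list(coherence = coh, scales = scales,
                 freqs = 1 / (morlet_fourier_factor(omega0) * scales),
                 coi = coi, cross_spectrum = SX, fs = fsr, omega0 = omega0,
                 dj = dj, n = n, whitened = FALSE,
                 inputs = list(a = av, b = bv),
                 labels = c(ts_label(a, "A"), ts_label(b, "B"))),
            class = "fc_cohmap")
}

#' Prewhitened wavelet coherence
#'
#' Whitens the power spectrum of both channels with BIC-selected AR filters
#' ([prewhiten_pair()]) before computing [wavelet_coherence()] on the
#' innovations. Removes the spurious low-frequency coherence that slow
#' hemodynamics induce between independent channels.
#'
#' @inheritParams wavelet_coherence
#' @param max_order AR order cap, default [max_order_bound()].
#' @export
ar_wavelet_coherence <- function(a, b, max_order = NULL, scales = NULL,
                                 omega0 = 6, dj = 1 / 12, fs = NULL) {
  fsr <- check_pair(a, b, fs)
  pp <- prewhiten_pair(a, b, max_order = max_order, fs = fsr)
  map <- wavelet_coherence(pp$a, pp$b, scales = scales, omega0 = omega0,
                           dj = dj)
  map$whitened <- TRUE
  map$ar_orders <- c(a = pp$models$a$order, b = pp$models$b$order)
  map$labels <- c(ts_label(a, "A"), ts_label(b, "B"))
  map
}

coi_mask <- function(map) {
  outer(map$scales, map$coi, `<=`)   # TRUE where the scale is unaffected
}

# simulate a zero-mean series from a fitted AR model (for spectrum-matched
# surrogates); white noise if the model has order 0
simulate_ar_series <- function(model, n) {
  sd_e <- sqrt(model$noise_variance)
  if (model$order == 0L) return(stats::rnorm(n, sd = sd_e))
  burn <- 100L + 5L * model$order
  e <- stats::rnorm(n + burn, sd = sd_e)
  x <- stats::filter(e, model$coeffs, method = "recursive")
  as.numeric(x[(burn + 1L):(burn + n)])
}

#' Scalar coherence statistic with a surrogate-data p-value
#'
#' Reduces a coherence map to the mean squared coherence over all time-scale
#' points outside the cone of influence, and (optionally) attaches a
#' Monte-Carlo p-value: the observed statistic is ranked among statistics from
#' independent surrogate channel pairs with matched spectra -- white noise for
#' maps computed on prewhitened innovations, AR-matched noise (models fitted
#' to the original inputs) otherwise -- using the `(k + 1) / (N + 1)`
#' convention, so the smallest attainable p-value is `1 / (n_surrogates + 1)`.
#'
#' @param map an `fc_cohmap` from [wavelet_coherence()] or
#'   [ar_wavelet_coherence()].
#' @param n_surrogates number of surrogate pairs (>= 19 for a p-value at the
#'   0.05 level); 0 skips the Monte-Carlo test and returns only the statistic.
#' @param seed optional seed for the surrogate draws.
#' @return An object of class `fc_coh`: `statistic`, `pvalue` (NA when
#'   `n_surrogates = 0`), `n_surrogates`, `map`.
#' @export
coherence_statistic <- function(map, n_surrogates = 99L, seed = NULL) {
  stopifnot(inherits(map, "fc_cohmap"))
  mask <- coi_mask(map)
  if (!any(mask)) stop("all time-scale points lie inside the cone of influence")
  stat <- mean(map$coherence[mask])
  pvalue <- NA_real_
  if (n_surrogates > 0L) {
    if (n_surrogates < 19L) stop("need at least 19 surrogates for a p-value")
    if (!is.null(seed)) set.seed(seed)
    n <- map$n
    if (map$whitened) {
      gen <- function() list(stats::rnorm(n, sd = stats::sd(map$inputs$a)),
                             stats::rnorm(n, sd = stats::sd(map$inputs$b)))
    } else {
      mo <- max_order_bound(map$fs)
      while (n <= 3L * mo && mo > 0L) mo <- mo %/% 2L
      ma <- fit_ar(map$inputs$a, max_order = mo, fs = map$fs)
      mb <- fit_ar(map$inputs$b, max_order = mo, fs = map$fs)
      gen <- function() list(simulate_ar_series(ma, n),
                             simulate_ar_series(mb, n))
    }
    exceed <- 0L
    for (k in seq_len(n_surrogates)) {
      s <- gen()
      m_k <- wavelet_coherence(fc_ts(s[[1L]], map$fs), fc_ts(s[[2L]], map$fs),
                               scales = map$scales, omega0 = map$omega0,
                               dj = map$dj)
      if (mean(m_k$coherence[mask]) >= stat) exceed <- exceed + 1L
    }
    pvalue <- (exceed + 1) / (n_surrogates + 1)
  }
  structure(list(statistic = stat, pvalue = pvalue,
                 n_surrogates = as.integer(n_surrogates), map = map),
            class = "fc_coh")
}

#' Wavelet coherence between two channels
#'
#' Front end mirroring [fc_correlate()] for the frequency-domain models:
#' `"wCOH"` (Morlet wavelet squared coherence) and `"AR-wCOH"` (the same after
#' AR prewhitening). Returns the map together with the scalar statistic and,
#' when `n_surrogates > 0`, a surrogate-data p-value.
#'
#' @param a,b the two channels.
#' @param method `"AR-wCOH"` (default) or `"wCOH"`.
#' @param n_surrogates surrogate pairs for the Monte-Carlo p-value (0 = none).
#' @param seed optional seed for the surrogate draws.
#' @param fs sampling rate when `a`, `b` are bare vectors.
#' @param max_order AR order cap for the prewhitened variant.
#' @param ... further arguments to [wavelet_coherence()].
#' @return An object of class `fc_coh`.
#' @export
fc_coherence <- function(a, b, method = c("AR-wCOH", "wCOH"),
                         n_surrogates = 0L, seed = NULL, fs = NULL,
                         max_order = NULL, ...) {
  method <- match.arg(method)
  map <- if (method == "AR-wCOH")
    ar_wavelet_coherence(a, b, max_order = max_order, fs = fs, ...)
  else wavelet_coherence(a, b, fs = fs, ...)
  out <- coherence_statistic(map, n_surrogates = n_surrogates, seed = seed)
  out$method <- method
  out
}

#' @export
print.fc_coh <- function(x, ...) {
  m <- if (is.null(x$method)) if (x$map$whitened) "AR-wCOH" else "wCOH" else x$method
  cat(sprintf("%s: mean squared coherence outside COI = %.4f\n", m, x$statistic))
  if (!is.na(x$pvalue))
    cat(sprintf("  surrogate p-value = %.4g (%d surrogates)\n",
                x$pvalue, x$n_surrogates))
  cat(sprintf("  map: %d scales x %d samples, periods %.2f-%.1f s\n",
              nrow(x$map$coherence), ncol(x$map$coherence),
              1 / max(x$map$freqs), 1 / min(x$map$freqs)))
  invisible(x)
}

#' @export
print.fc_cohmap <- function(x, ...) {
  cat(sprintf("<fc_cohmap> %s ~ %s: %d scales x %d samples at %g Hz%s\n",
              x$labels[1L], x$labels[2L], nrow(x$coherence), ncol(x$coherence),
              x$fs, if (x$whitened) " (prewhitened)" else ""))
  invisible(x)
}

#' @export
plot.fc_cohmap <- function(x, ...) {
  graphics::image(x = seq_len(x$n) / x$fs, y = log2(x$scales),
                  z = t(x$coherence), zlim = c(0, 1),
                  xlab = "time (s)", ylab = "log2 scale (s)",
                  main = "wavelet squared coherence", ...)
  graphics::lines(seq_len(x$n) / x$fs, log2(pmax(x$coi, min(x$scales))),
                  lty = 2)
  invisible(x)
}

#' @export
plot.fc_coh <- function(x, ...) plot(x$map, ...)

#' Export a coherence map as delimited text plus a JSON sidecar
#'
#' Writes the time-by-scale coherence grid as CSV (rows = time points) and a
#' `<path>.json` sidecar holding scales, frequencies, the cone-of-influence
#' boundary, and the sampling rate.
#'
#' @param map an `fc_cohmap`.
#' @param path output CSV path.
#' @export
write_coherence_map <- function(map, path) {
  m <- t(map$coherence)
  colnames(m) <- sprintf("scale_%g", map$scales)
  utils::write.csv(m, path, row.names = FALSE)
  side <- list(scales = map$scales, freqs = map$freqs, coi = map$coi,
               fs = map$fs, omega0 = map$omega0, whitened = map$whitened)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
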