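#' Default upper bound on the autoregressive model order
#'
#' Slow hemodynamic signals need AR orders that grow with the sampling rate:
#' roughly ten times the rate in Hz, capped (by default at 40) because higher
#' orders are rarely selected and are expensive to fit.
#'
#' @param fs sampling rate in Hz (> 0).
#' @param hard_cap maximum admissible order.
#' @return `min(ceiling(10 * fs), hard_cap)` as an integer.
#' @export
max_order_bound <- function(fs, hard_cap = 40L) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  as.integer(min(ceiling(10 * fs), hard_cap))
}

#' Bayesian information criterion for an AR fit
#'
#' `n * log(rss / n) + order * log(n)`, where `n` is the number of regression
#' rows entering the conditional least-squares fit.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of regression rows.
#' @param order candidate AR order.
#' @export
compute_bic <- function(rss, n, order) {
  if (!is.finite(rss) || rss <= 0)
    stop("degenerate fit: residual sum of squares must be positive")
  if (order < 0 || n <= order)
    stop("need n > order >= 0")
  n * log(rss / n) + order * log(n)
}

#' Fit an autoregressive model with BIC order selection
#'
#' Mean-centers the series and fits AR(P) models for P = 0..`max_order` by
#' conditional least squares on the lagged design matrix, selecting the order
#' that minimizes [compute_bic()]. For order selection all candidates are
#' conditioned on the first `max_order` samples (the same regression rows, so
#' the criteria are comparable); the winning order is then refit on its own
#' n − P rows, and those residuals are the innovations.
#'
#' The candidate RSS sequence is obtained from a single QR decomposition of the
#' max-order design (nested-model identity: the RSS of the leading-p-column
#' model is `y'y` minus the cumulative squared components of `Q'y`). If the QR
#' pivots (near-singular design), a direct per-order least-squares loop is used
#' instead.
#'
#' @param y an [fc_ts] or numeric vector.
#' @param max_order highest candidate order; defaults to
#'   [max_order_bound()] of the sampling rate.
#' @param fs sampling rate, required when `y` is a bare numeric vector.
#' @return An object of class `fc_ar`: `coeffs` (length = `order`), `order`,
#'   `innovations` (length `n - order`), `noise_variance`, `bic_trace`
#'   (orders 0..max_order), plus the sampling rate and removed mean.
#' @examples
#' set.seed(1)
#' y <- as.numeric(stats::arima.sim(list(ar = c(0.5, 0.3)), 2000))
#' fit_ar(y, max_order = 10, fs = 1)
#' @export
fit_ar <- function(y, max_order = NULL, fs = NULL) {
  fs <- ts_fs(y, fs)
  v <- ts_values(y)
  if (is.null(max_order)) max_order <- max_order_bound(fs)
  max_order <- as.integer(max_order)
  if (max_order < 0L) stop("max_order must be non-negative")
  n <- length(v)
  if (n <= 3L * max_order)
    stop(sprintf("series too short (n = %d) for max_order = %d; need n > 3 * max_order",
                 n, max_order))
  if (stats::var(v) == 0)
    stop("cannot fit an AR model to a constant (zero-variance) series")
  mu <- mean(v)
  yc <- v - mu

  if (max_order == 0L) {
    bic <- compute_bic(sum(yc^2), n, 0L)
    return(new_fc_ar(numeric(0), 0L, yc, sum(yc^2) / n, bic, fs, mu, n,
                     ts_label(y)))
  }

  E <- stats::embed(yc, max_order + 1L)
  yr <- E[, 1L]
  X <- E[, -1L, drop = FALSE]
  nr <- length(yr)
  yty <- sum(yr^2)

  qx <- qr(X)
  if (qx$rank == max_order && identical(qx$pivot, seq_len(max_order))) {
    qty <- qr.qty(qx, yr)[seq_len(max_order)]
    rss <- yty - cumsum(c(0, qty^2))
  } else {
    rss <- vapply(0:max_order, function(p) {
      if (p == 0L) yty
      else sum(stats::lm.fit(X[, seq_len(p), drop = FALSE], yr)$residuals^2)
    }, numeric(1))
  }
  rss <- pmax(rss, yty * .Machine$double.eps)
  bic <- vapply(0:max_order, function(p) compute_bic(rss[p + 1L], nr, p),
                numeric(1))
  ord <- which.min(bic) - 1L

  if (ord == 0L) {
    innov <- yc
    coeffs <- numeric(0)
  } else {
    Es <- stats::embed(yc, ord + 1L)
    fit <- stats::lm.fit(Es[, -1L, drop = FALSE], Es[, 1L])
    coeffs <- unname(fit$coefficients)
    innov <- unname(fit$residuals)
  }
  new_fc_ar(coeffs, ord, innov, sum(innov^2) / length(innov), bic, fs, mu, n,
            ts_label(y))
}

new_fc_ar <- function(coeffs, order, innovations, noise_variance, bic_trace,
                      fs, mean, n, label) {
  structure(list(coeffs = coeffs, order = order, innovations = innovations,
                 noise_variance = noise_variance, bic_trace = bic_trace,
                 fs = fs, mean = mean, n = n, label = label),
            class = "fc_ar")
}

#' @export
print.fc_ar <- function(x, ...) {
  cat(sprintf("Autoregressive model for '%s' (n = %d at %g Hz)\n",
              x$label, x$n, x$fs))
  cat(sprintf("  BIC-selected order: %d (candidates 0..%d)\n",
              x$order, length(x$bic_trace) - 1L))
  if (x$order > 0L)
    cat("  coefficients:", paste(sprintf("%.4f", x$coeffs), collapse = " "), "\n")
  cat(sprintf("  innovations: %d samples, variance %.4g\n",
              length(x$innovations), x$noise_variance))
  invisible(x)
}

#' @export
coef.fc_ar <- function(object, ...) object$coeffs

#' @export
residuals.fc_ar <- function(object, ...) object$innovations

#' Filter a series by a fitted AR model
#'
#' Produces the innovations of `y` under `model`: the series is mean-centered
#' and each sample beyond the conditioning window is replaced by its one-step
#' prediction error, `e[t] = y[t] - sum(a_i * y[t - i])`. The first `order`
#' samples are conditioned on and dropped, so the output has `n - order`
#' samples. An order-0 model returns the mean-centered input.
#'
#' @param y an [fc_ts] or numeric vector longer than the model order.
#' @param model an `fc_ar` fit, typically from [fit_ar()].
#' @param fs sampling rate when `y` is a bare vector.
#' @return An [fc_ts] of innovations at the same sampling rate.
#' @export
apply_ar_filter <- function(y, model, fs = NULL) {
  fs <- ts_fs(y, if (is.null(fs)) model$fs else fs)
  v <- ts_values(y)
  p <- model$order
  if (p >= length(v))
    stop("model order must be smaller than the series length")
  yc <- v - mean(v)
  if (p == 0L) {
    eps <- yc
  } else {
    E <- stats::embed(yc, p + 1L)
    eps <- drop(E[, 1L] - E[, -1L, drop = FALSE] %*% model$coeffs)
  }
  fc_ts(eps, fs = fs, label = paste0(ts_label(y), ".innov"))
}

#' Prewhiten a channel pair
#'
#' Fits an AR model to each channel independently (each gets its own
#' BIC-selected order), filters each channel to its innovations, and trims both
#' innovations series to a common length by aligning their final samples (the
#' channel with the lower order loses its extra leading samples).
#'
#' @param a,b [fc_ts] objects (or numeric vectors with `fs`) of equal length
#'   and sampling rate.
#' @param max_order highest candidate order for both fits; default
#'   [max_order_bound()].
#' @param fs sampling rate when `a`, `b` are bare vectors.
#' @return A list with elements `a`, `b` (aligned innovations as [fc_ts]) and
#'   `models` (the two `fc_ar` fits).
#' @export
prewhiten_pair <- function(a, b, max_order = NULL, fs = NULL) {
  fs <- check_pair(a, b, fs)
  ma <- fit_ar(a, max_order = max_order, fs = fs)
  mb <- fit_ar(b, max_order = max_order, fs = fs)
  ia <- ma$innovations
  ib <- mb$innovations
  L <- min(length(ia), length(ib))
  ia <- ia[(length(ia) - L + 1L):length(ia)]
  ib <- ib[(length(ib) - L + 1L):length(ib)]
  list(a = fc_ts(ia, fs = fs, label = paste0(ts_label(a, "A"), ".innov")),
       b = fc_ts(ib, fs = fs, label = paste0(ts_label(b, "B"), ".innov")),
       models = list(a = ma, b = mb))
}
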