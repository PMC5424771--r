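#' All-to-all connectivity matrix
#'
#' Applies one estimator to every unordered channel pair. The diagonal is 1 by
#' convention; off-diagonal cells hold the combined correlation (or coherence
#' statistic), its p-value, and the effective degrees of freedom. Optionally
#' adjusts the strictly-upper-triangle p-values for multiplicity by
#' Benjamini-Hochberg.
#'
#' @param channels list of [fc_ts] objects of equal length and sampling rate
#'   (at least 2), e.g. from [read_timeseries_table()].
#' @param method estimator name (see [fc_correlate()] / [fc_coherence()]) or a
#'   function `function(a, b)` returning `list(r = , pvalue = , dof = )`.
#' @param fdr_correct add Benjamini-Hochberg adjusted q-values.
#' @param max_order,kappa,cutoff,n_surrogates estimator options.
#' @return An object of class `fc_connectivity` with `labels`, symmetric
#'   matrices `r`, `pvalues`, `dof`, optional `qvalues`, and `method`.
#' @export
connectivity_all_pairs <- function(channels, method = "AR-W-COR",
                                   fdr_correct = FALSE, max_order = NULL,
                                   kappa = 4.685, cutoff = 0.1,
                                   n_surrogates = 99L) {
  k <- length(channels)
  if (k < 2L) stop("need at least 2 channels")
  lens <- vapply(channels, length, 0L)
  if (length(unique(lens)) != 1L) stop("channels must have equal lengths")
  labels <- vapply(seq_len(k), function(j)
    ts_label(channels[[j]], default = paste0("ch", j)), "")
  if (!is.null(names(channels)) && all(nzchar(names(channels))))
    labels <- names(channels)

  est <- if (is.function(method)) {
    function(a, b) method(a, b)
  } else if (method %in% c("wCOH", "AR-wCOH")) {
    function(a, b) {
      fit <- fc_coherence(a, b, method = method, n_surrogates = n_surrogates,
                          max_order = max_order)
      list(r = fit$statistic, pvalue = fit$pvalue, dof = NA_real_)
    }
  } else {
    function(a, b) {
      fit <- fc_correlate(a, b, method = method, max_order = max_order,
                          kappa = kappa, cutoff = cutoff)
      list(r = fit$r, pvalue = fit$pvalue, dof = fit$dof)
    }
  }

  r <- diag(1, k); p <- matrix(0, k, k); dof <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(dof) <- list(labels, labels)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      out <- est(channels[[i]], channels[[j]])
      r[i, j] <- r[j, i] <- out$r
      p[i, j] <- p[j, i] <- out$pvalue
      d <- if (is.null(out$dof)) NA_real_ else out$dof
      dof[i, j] <- dof[j, i] <- d
    }
  }
  q <- NULL
  if (fdr_correct) {
    up <- upper.tri(p)
    q <- matrix(NA_real_, k, k, dimnames = dimnames(p))
    q[up] <- stats::p.adjust(p[up], method = "BH")
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
  }
  structure(list(labels = labels, r = r, pvalues = p, qvalues = q, dof = dof,
                 method = if (is.function(method)) "custom" else method),
            class = "fc_connectivity")
}

#' @export
print.fc_connectivity <- function(x, digits = 3, ...) {
  cat(sprintf("%s connectivity over %d channels\n", x$method, length(x$labels)))
  print(round(x$r, digits))
  if (!is.null(x$qvalues))
    cat("Benjamini-Hochberg q-values available in $qvalues\n")
  invisible(x)
}
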