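#' Simulation configuration
#'
#' Bundles the study conditions of the Monte-Carlo experiments: 3000 samples
#' per channel, 2000 replicates, 5% motion contamination at 10x variance with
#' co-occurring times and independent values, and a 0.05 nominal level.
#'
#' @param n_samples samples per channel.
#' @param n_reps Monte-Carlo replicates per condition.
#' @param fs_grid sampling rates (Hz) to sweep.
#' @param rho true correlation of positive-class pairs (ROC runs).
#' @param motion_fraction proportion of contaminated samples, in `[0, 1)`.
#' @param motion_var_scale artifact variance multiplier (>= 0).
#' @param shared_times co-occurring artifact times in both channels.
#' @param identical_values identical artifact values in both channels.
#' @param alpha nominal significance level, in `(0, 1)`.
#' @param seed master seed; every replicate seed derives from it.
#' @return list of class `fc_config`.
#' @export
fc_config <- function(n_samples = 3000L, n_reps = 2000L, fs_grid = 1,
                      rho = 0.5, motion_fraction = 0.05,
                      motion_var_scale = 10, shared_times = TRUE,
                      identical_values = FALSE, alpha = 0.05, seed = 1L) {
  stopifnot(n_samples >= 2, n_reps >= 1, all(fs_grid > 0),
            abs(rho) < 1, motion_fraction >= 0, motion_fraction < 1,
            motion_var_scale >= 0, alpha > 0, alpha <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_reps = as.integer(n_reps), fs_grid = fs_grid, rho = rho,
                 motion_fraction = motion_fraction,
                 motion_var_scale = motion_var_scale,
                 shared_times = isTRUE(shared_times),
                 identical_values = isTRUE(identical_values),
                 alpha = alpha, seed = as.integer(seed)),
            class = "fc_config")
}

estimator_names <- function() {
  c("COR", "LPF-COR", "W-COR", "AR-COR", "AR-W-COR", "wCOH", "AR-wCOH")
}

# Resolve an estimator spec (name or function) to function(a, b) ->
# list(pvalue = ..., score = ...); higher score = more connected.
resolve_estimator <- function(est, max_order = NULL, cutoff = 0.1,
                              kappa = 4.685, n_surrogates = 0L) {
  if (is.function(est)) {
    return(function(a, b) {
      out <- est(a, b)
      if (is.null(out$score))
        out$score <- if (!is.null(out$pvalue)) 1 - out$pvalue else out$statistic
      out
    })
  }
  if (!est %in% estimator_names())
    stop(sprintf("unknown estimator '%s'; valid: %s", est,
                 paste(estimator_names(), collapse = ", ")))
  if (est %in% c("wCOH", "AR-wCOH")) {
    function(a, b) {
      fit <- fc_coherence(a, b, method = est, n_surrogates = n_surrogates,
                          max_order = max_order)
      list(pvalue = fit$pvalue, score = fit$statistic)
    }
  } else {
    function(a, b) {
      fit <- fc_correlate(a, b, method = est, max_order = max_order,
                          kappa = kappa, cutoff = cutoff)
      list(pvalue = fit$pvalue, score = 1 - fit$pvalue)
    }
  }
}

estimator_labels <- function(estimators) {
  if (is.null(names(estimators))) {
    if (is.character(estimators)) as.character(estimators)
    else paste0("estimator", seq_along(estimators))
  } else names(estimators)
}

# replicate seed table, reproducible from the master seed
replicate_seeds <- function(seed, n_reps, n_conditions = 1L) {
  set.seed(seed)
  matrix(sample.int(2147483646L, n_reps * n_conditions), nrow = n_reps)
}

make_null_pair <- function(n, rho, fs, seed, with_motion, config, hrf) {
  pair <- simulate_neural_pair(n, rho = rho, seed = seed, fs = fs)
  if (with_motion)
    pair <- inject_motion(pair, fraction = config$motion_fraction,
                          var_scale = config$motion_var_scale,
                          shared_times = config$shared_times,
                          identical_values = config$identical_values)
  if (!is.null(hrf))
    pair <- list(a = hemodynamic_convolve(pair$a, hrf),
                 b = hemodynamic_convolve(pair$b, hrf))
  pair
}

#' False-discovery-rate experiment
#'
#' For each sampling rate in `config$fs_grid` and each estimator, generates
#' `config$n_reps` independent null pairs (`rho = 0`), optionally injects
#' motion artifacts into the neural signals, convolves with the canonical HRF
#' (unless `signal = "neural"`), computes each estimator's p-value on the same
#' data, and reports the fraction of nominal discoveries (`p < alpha`) with
#' its binomial standard error. On null data this rejection rate is the
#' empirical false-discovery rate of the estimator.
#'
#' @param config an [fc_config()].
#' @param estimators character vector of estimator names (see
#'   [fc_correlate()] and [fc_coherence()]), or a named list of functions
#'   `function(a, b)` returning `list(pvalue = ...)`.
#' @param with_motion inject motion artifacts before convolution.
#' @param signal `"hemodynamic"` (convolve with the canonical HRF) or
#'   `"neural"` (raw i.i.d. signals, the negative control).
#' @param max_order AR order cap passed to prewhitened estimators.
#' @param n_surrogates surrogate count for coherence p-values.
#' @param keep_pvalues retain the full p-value matrices (one per sampling
#'   rate) in the report, e.g. for calibration curves.
#' @return An object of class `fc_report` with `fdr_table` (estimator x fs
#'   grid of empirical FDRs and binomial SEs) and the configuration.
#' @export
run_fdr_experiment <- function(config, estimators, with_motion = FALSE,
                               signal = c("hemodynamic", "neural"),
                               max_order = NULL, n_surrogates = 99L,
                               keep_pvalues = FALSE) {
  stopifnot(inherits(config, "fc_config"), length(estimators) >= 1)
  signal <- match.arg(signal)
  labels <- estimator_labels(estimators)
  fns <- lapply(seq_along(estimators),
                function(i) resolve_estimator(estimators[[i]],
                                              max_order = max_order,
                                              n_surrogates = n_surrogates))
  fs_grid <- config$fs_grid
  seeds <- replicate_seeds(config$seed, config$n_reps, length(fs_grid))
  rows <- list()
  pvals <- list()
  for (gi in seq_along(fs_grid)) {
    fs <- fs_grid[gi]
    hrf <- if (signal == "hemodynamic") canonical_hrf(fs) else NULL
    pm <- matrix(NA_real_, config$n_reps, length(fns),
                 dimnames = list(NULL, labels))
    for (rep in seq_len(config$n_reps)) {
      pair <- make_null_pair(config$n_samples, 0, fs, seeds[rep, gi],
                             with_motion, config, hrf)
      for (ei in seq_along(fns))
        pm[rep, ei] <- fns[[ei]](pair$a, pair$b)$pvalue
    }
    fdr <- colMeans(pm < config$alpha)
    rows[[gi]] <- data.frame(estimator = labels, fs = fs, fdr = unname(fdr),
                             se = sqrt(unname(fdr) * (1 - unname(fdr)) /
                                         config$n_reps),
                             n_reps = config$n_reps)
    if (keep_pvalues) pvals[[as.character(fs)]] <- pm
  }
  structure(list(kind = "fdr", fdr_table = do.call(rbind, rows),
                 pvalues = if (keep_pvalues) pvals else NULL,
                 signal = signal, with_motion = with_motion, config = config),
            class = "fc_report")
}

# ROC curve from scores: sweep thresholds, trapezoidal AUC
roc_curve <- function(score, label) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]; l <- label[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  keep <- c(diff(s) != 0, TRUE)            # collapse ties on the score
  tpr <- c(0, tp[keep] / sum(l))
  fpr <- c(0, fp[keep] / sum(!l))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' ROC / sensitivity-specificity experiment
#'
#' Generates `config$n_reps` hemodynamic pairs at a single sampling rate,
#' exactly half with true correlation `config$rho` and half null, applies each
#' estimator, and sweeps the decision threshold over the estimator's score
#' (p-value rank for the correlation models, the scalar coherence statistic
#' for the frequency-domain models) to produce ROC points and trapezoidal
#' AUCs. Calibration curves (actual vs nominal false-positive rate) are
#' computed from the null half for every estimator that reports p-values.
#'
#' For estimator functions supplied by the caller, the generating correlation
#' of each pair is attached to the first channel as attribute `"true_rho"`
#' (useful for oracle estimators in tests).
#'
#' @inheritParams run_fdr_experiment
#' @param fs sampling rate of the ROC simulations (Hz).
#' @return An `fc_report` with `roc` (per-estimator points and `auc`),
#'   `calibration` curves, class `labels`, and the configuration.
#' @export
run_roc_experiment <- function(config, estimators, with_motion = FALSE,
                               fs = 4, max_order = NULL,
                               keep_pvalues = FALSE) {
  stopifnot(inherits(config, "fc_config"), length(estimators) >= 1)
  if (config$n_reps %% 2L != 0L)
    stop("n_reps must be even: half positive, half null pairs")
  if (config$rho <= 0) stop("config$rho must be positive for the ROC positive class")
  labels_est <- estimator_labels(estimators)
  fns <- lapply(seq_along(estimators),
                function(i) resolve_estimator(estimators[[i]],
                                              max_order = max_order))
  n_reps <- config$n_reps
  truth <- rep(c(TRUE, FALSE), each = n_reps / 2L)
  seeds <- replicate_seeds(config$seed, n_reps)
  hrf <- canonical_hrf(fs)
  scores <- matrix(NA_real_, n_reps, length(fns),
                   dimnames = list(NULL, labels_est))
  pvals <- matrix(NA_real_, n_reps, length(fns),
                  dimnames = list(NULL, labels_est))
  for (rep in seq_len(n_reps)) {
    rho_i <- if (truth[rep]) config$rho else 0
    pair <- make_null_pair(config$n_samples, rho_i, fs, seeds[rep, 1L],
                           with_motion, config, hrf)
    attr(pair$a, "true_rho") <- rho_i
    for (ei in seq_along(fns)) {
      out <- fns[[ei]](pair$a, pair$b)
      scores[rep, ei] <- out$score
      pvals[rep, ei] <- if (is.null(out$pvalue)) NA_real_ else out$pvalue
    }
  }
  roc <- lapply(seq_along(fns), function(ei) roc_curve(scores[, ei], truth))
  names(roc) <- labels_est
  calib <- lapply(seq_along(fns), function(ei) {
    p <- pvals[!truth, ei]
    p <- p[!is.na(p)]
    if (!length(p) || any(p < 0 | p > 1)) NULL else calibration_curve(p)
  })
  names(calib) <- labels_est
  structure(list(kind = "roc",
                 roc = roc,
                 auc = vapply(roc, `[[`, numeric(1), "auc"),
                 calibration = calib,
                 truth = truth,
                 pvalues = if (keep_pvalues) pvals else NULL,
                 fs = fs, with_motion = with_motion, config = config),
            class = "fc_report")
}

#' Calibration curve of null p-values
#'
#' For each nominal level in `grid`, the empirical fraction of null p-values
#' at or below it. A well-calibrated test tracks the diagonal; serially
#' correlated noise pushes the curve far above it.
#'
#' @param pvalues_null p-values computed on null (zero-correlation) data.
#' @param grid nominal levels to evaluate.
#' @return data.frame with columns `nominal` and `actual`.
#' @export
calibration_curve <- function(pvalues_null, grid = seq(0.01, 1, by = 0.01)) {
  if (length(pvalues_null) == 0) stop("no p-values supplied")
  if (any(pvalues_null < 0 | pvalues_null > 1)) stop("p-values must lie in [0, 1]")
  data.frame(nominal = grid,
             actual = vapply(grid, function(g) mean(pvalues_null <= g),
                             numeric(1)))
}

#' @export
print.fc_report <- function(x, ...) {
  if (x$kind == "fdr") {
    cat(sprintf("FDR experiment: %s signals%s, %d reps, alpha = %g\n",
                x$signal, if (x$with_motion) " + motion" else "",
                x$config$n_reps, x$config$alpha))
    tab <- x$fdr_table
    tab$fdr <- sprintf("%.3f +/- %.3f", tab$fdr, tab$se)
    print(tab[, c("estimator", "fs", "fdr")], row.names = FALSE)
  } else {
    cat(sprintf("ROC experiment: rho = %g at %g Hz%s, %d reps\n",
                x$config$rho, x$fs,
                if (x$with_motion) " + motion" else "", x$config$n_reps))
    cat("AUC:\n")
    print(round(x$auc, 4))
  }
  invisible(x)
}

#' Write an experiment report as delimited-text tables plus a JSON manifest
#'
#' @param report an `fc_report`.
#' @param prefix output path prefix; files `<prefix>_fdr.csv` or
#'   `<prefix>_roc.csv` / `<prefix>_auc.csv` / `<prefix>_calibration.csv`,
#'   plus `<prefix>_manifest.json`.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "fc_report"))
  if (report$kind == "fdr") {
    utils::write.csv(report$fdr_table, paste0(prefix, "_fdr.csv"),
                     row.names = FALSE)
  } else {
    pts <- do.call(rbind, lapply(names(report$roc), function(nm)
      cbind(estimator = nm, report$roc[[nm]]$points)))
    utils::write.csv(pts, paste0(prefix, "_roc.csv"), row.names = FALSE)
    utils::write.csv(data.frame(estimator = names(report$auc),
                                auc = unname(report$auc)),
                     paste0(prefix, "_auc.csv"), row.names = FALSE)
    cal <- report$calibration[!vapply(report$calibration, is.null, TRUE)]
    if (length(cal)) {
      cd <- do.call(rbind, lapply(names(cal), function(nm)
        cbind(estimator = nm, cal[[nm]])))
      utils::write.csv(cd, paste0(prefix, "_calibration.csv"),
                       row.names = FALSE)
    }
  }
  manifest <- c(report$config,
                list(kind = report$kind, with_motion = report$with_motion,
                     package = "robustfc",
                     version = as.character(utils::packageVersion("robustfc"))))
  jsonlite::write_json(manifest, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
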