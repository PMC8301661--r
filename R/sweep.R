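#' Partial-conjunction replicability p-value
#'
#' Combines per-threshold p-values into a single replicability p-value
#' for rejecting the null that the effect is non-zero at no more than two
#' of the selection thresholds. With the standard design of 7 thresholds
#' this is \eqn{5\,p_{(3)}} (the third-smallest p-value times the number
#' of remaining thresholds), capped at 1. For `S != 7` thresholds the same
#' Bonferroni-on-remaining logic gives \eqn{(S - 2)\,p_{(3)}}.
#'
#' @param pvalues numeric vector of at least 3 p-values in [0, 1], one per
#'   selection threshold.
#' @return the combined p-value in (0, 1].
#' @export
partial_conjunction <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  S <- length(pvalues)
  if (S < 3L)
    stopf("partial conjunction needs at least 3 p-values (got %d)", S)
  if (any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  p3 <- sort(pvalues)[3L]
  min(1, (S - 2L) * p3)
}

#' Sweep instrument-selection thresholds
#'
#' Re-runs instrument selection, fitting and mode diagnosis at each of a
#' series of selection p-value thresholds (default
#' \eqn{10^{-8}, 10^{-7}, \ldots, 10^{-2}}), then summarizes stability:
#' the mean detected mode count across thresholds and, per exposure, the
#' partial-conjunction replicability p-value over the per-threshold fit
#' p-values. Thresholds yielding too few instruments are skipped with a
#' warning rather than failing the sweep.
#'
#' @param study an [mr_study()].
#' @param sigma an [mr_sigma()] or `NULL`.
#' @param thresholds strictly increasing selection cutoffs; at least 3.
#' @param ld_r2 optional r-squared matrix for clumping.
#' @param r2_threshold clumping cutoff; default 0.001.
#' @param assume_independent skip clumping (simulated independent panels).
#' @param loss fitting loss; default biweight c = 4.6851.
#' @param c_diag diagnostic biweight constant for mode detection.
#' @param diagnose run the mode diagnosis per threshold (K = 1 only).
#' @return an object of class `mr_sweep`: list with `thresholds`, `fits`,
#'   `mode_counts`, `n_instruments`, `mean_modes`, `combined_p` (named per
#'   exposure), and `skipped`.
#' @export
threshold_sweep <- function(study, sigma = NULL,
                            thresholds = 10^seq(-8, -2),
                            ld_r2 = NULL, r2_threshold = 0.001,
                            assume_independent = is.null(ld_r2),
                            loss = robust_loss(4.6851), c_diag = 3,
                            diagnose = study$K == 1L) {
  if (length(thresholds) < 3L)
    stopf("a sweep needs at least 3 thresholds")
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly increasing")
  n_thr <- length(thresholds)
  fits <- vector("list", n_thr)
  profiles <- vector("list", n_thr)
  mode_counts <- rep(NA_integer_, n_thr)
  n_instr <- integer(n_thr)
  skipped <- logical(n_thr)
  for (i in seq_len(n_thr)) {
    instr <- tryCatch(
      build_instruments(study, thresholds[i], ld_r2 = ld_r2,
                        r2_threshold = r2_threshold,
                        assume_independent = assume_independent),
      error = function(e) NULL)
    n_instr[i] <- if (is.null(instr)) 0L else length(instr$ids)
    if (is.null(instr) || n_instr[i] <= study$K) {
      warning(sprintf(
        "threshold %g yields %d instrument(s) (need > K = %d); skipped",
        thresholds[i], n_instr[i], study$K), call. = FALSE)
      skipped[i] <- TRUE
      next
    }
    fits[[i]] <- fit_effects(study, instr, sigma, loss = loss)
    if (diagnose) {
      profiles[[i]] <- profile_curve(study, instr, sigma, c = c_diag)
      mode_counts[i] <- nrow(profiles[[i]]$modes)
    }
  }
  if (all(skipped))
    stopf("every threshold was skipped; no fit could be computed")
  pv <- do.call(rbind, lapply(fits[!skipped], function(f) f$pvalues))
  combined <- if (sum(!skipped) >= 3L)
    apply(pv, 2L, partial_conjunction)
  else stats::setNames(rep(NA_real_, study$K), study$trait_names[-1L])
  structure(list(
    thresholds = thresholds, fits = fits, profiles = profiles,
    mode_counts = mode_counts, n_instruments = n_instr,
    mean_modes = mean(mode_counts, na.rm = TRUE),
    combined_p = combined, skipped = skipped
  ), class = "mr_sweep")
}

#' @export
print.mr_sweep <- function(x, ...) {
  cat("Selection-threshold sweep\n")
  est <- vapply(seq_along(x$thresholds), function(i) {
    if (x$skipped[i]) NA_real_ else x$fits[[i]]$beta_hat[1L]
  }, numeric(1))
  tab <- data.frame(threshold = x$thresholds, n_instruments = x$n_instruments,
                    beta1_hat = signif(est, 4), modes = x$mode_counts,
                    skipped = x$skipped)
  print(tab, row.names = FALSE)
  if (!is.na(x$mean_modes))
    cat(sprintf("Mean mode count: %.2f\n", x$mean_modes))
  cat("Replicability (partial conjunction) p-value(s):\n")
  print(signif(x$combined_p, 3))
  invisible(x)
}
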