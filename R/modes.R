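#' Robust profile-likelihood curve for mode diagnosis
#'
#' Evaluates \eqn{l(b) = -\sum_j \rho_c(t_j(b, 0))} over a grid of
#' candidate effect values for a single exposure, with the overdispersion
#' fixed at zero and a sharpened biweight constant (default c = 3) so that
#' SNP groups driven by distinct pleiotropic pathways surface as distinct
#' local maxima. The default grid spans the 2.5\%-97.5\% quantiles of the
#' per-SNP ratios \eqn{\hat\Gamma_j/\hat\gamma_j}, widened by 50\%, at
#' 2001 points.
#'
#' @param study an [mr_study()] with `K = 1`.
#' @param instruments an `mr_instruments` or character vector of SNP ids.
#' @param sigma an [mr_sigma()] or `NULL` for no overlap.
#' @param c biweight constant for the diagnostic curve; default 3.
#' @param grid optional numeric vector of strictly increasing grid points
#'   overriding the default construction.
#' @param n_grid grid resolution when `grid` is not supplied.
#' @param min_support modes supported by fewer marker SNPs than this are
#'   flagged `likely_outlier`; default 2.
#' @return an object of class `mr_profile`: list with `grid`, `values`,
#'   `modes` (data.frame: `position`, `height`, `support`,
#'   `likely_outlier`), `c`, and the SNP ids used.
#' @export
profile_curve <- function(study, instruments, sigma = NULL, c = 3,
                          grid = NULL, n_grid = 2001L, min_support = 2L) {
  if (study$K != 1L)
    stopf("the mode diagnosis is defined for a single exposure (K = 1)")
  ids <- if (inherits(instruments, "mr_instruments")) instruments$ids
         else as.character(instruments)
  if (length(ids) == 0L) stopf("no instruments supplied (p = 0)")
  sub <- subset_study(study, ids)
  pt <- profile_t_parts(sub, sigma)

  ratios <- sub$Gamma_hat / sub$gamma_hat[, 1L]
  if (is.null(grid)) {
    q <- stats::quantile(ratios, c(0.025, 0.975), names = FALSE)
    if (diff(q) < .Machine$double.eps^0.5) {
      warning("all per-SNP ratios are equal; returning a single-point profile")
      grid <- q[1L]
    } else {
      half <- diff(q) / 2
      centre <- mean(q)
      grid <- seq(centre - 1.5 * half, centre + 1.5 * half,
                  length.out = n_grid)
    }
  } else {
    if (is.unsorted(grid, strictly = TRUE))
      stopf("grid must be strictly increasing")
  }

  values <- vapply(grid,
                   function(b) -sum(tukey_rho(eval_profile_t(pt, b, 0), c)),
                   numeric(1))
  prof <- structure(list(grid = grid, values = values, c = c,
                         ids = ids, modes = NULL),
                    class = "mr_profile")
  prof$modes <- find_modes(prof, study = sub, sigma = sigma,
                           min_support = min_support)
  prof
}

#' Detect modes of a profile-likelihood curve
#'
#' Local maxima of the gridded curve (strictly greater than both
#' neighbours), merged when closer than `merge_steps` grid steps (the
#' higher mode is kept) to suppress floating-point ripple. When the study
#' is supplied, each mode's support is the number of SNPs whose residual
#' at the mode is within `t0`; modes with support below `min_support` are
#' flagged `likely_outlier` — more likely a single outlying SNP than a
#' pathway — but still reported.
#'
#' @param profile an `mr_profile`.
#' @param study optional `mr_study` restricted to the profile's SNPs, used
#'   to count supporting SNPs.
#' @param sigma optional [mr_sigma()].
#' @param min_support minimum supporting SNPs for an unflagged mode.
#' @param merge_steps merge bandwidth in grid steps; default 5.
#' @param t0 residual cutoff defining a supporting SNP; default 1.
#' @return data.frame with one row per mode, sorted by position:
#'   `position`, `height`, `support`, `likely_outlier`.
#' @export
find_modes <- function(profile, study = NULL, sigma = NULL,
                       min_support = 2L, merge_steps = 5L, t0 = 1) {
  g <- profile$grid
  v <- profile$values
  n <- length(g)
  if (n < 3L) {
    idx <- if (n >= 1L) which.max(v) else integer(0)
  } else {
    idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                 v[2:(n - 1L)] > v[3:n]) + 1L
  }
  # merge near-coincident maxima, keeping the higher of each close pair
  if (length(idx) > 1L) {
    idx <- idx[order(g[idx])]
    merged <- idx[1L]
    for (i in idx[-1L]) {
      last <- merged[length(merged)]
      if (i - last < merge_steps) {
        if (v[i] > v[last]) merged[length(merged)] <- i
      } else merged <- c(merged, i)
    }
    idx <- merged
  }
  if (length(idx) == 0L)
    return(data.frame(position = numeric(0), height = numeric(0),
                      support = integer(0), likely_outlier = logical(0)))
  pos <- g[idx]
  support <- rep(NA_integer_, length(idx))
  if (!is.null(study)) {
    pt <- profile_t_parts(study, sigma)
    support <- vapply(pos, function(b)
      sum(abs(eval_profile_t(pt, b, 0)) <= t0), integer(1))
  }
  data.frame(position = pos, height = v[idx], support = support,
             likely_outlier = !is.na(support) & support < min_support)
}

#' @export
print.mr_profile <- function(x, ...) {
  cat(sprintf("Robust profile likelihood: %d grid points, c = %g, %d SNPs\n",
              length(x$grid), x$c, length(x$ids)))
  if (!is.null(x$modes) && nrow(x$modes)) {
    cat(sprintf("%d mode(s):\n", nrow(x$modes)))
    print(x$modes)
  } else cat("no modes detected\n")
  invisible(x)
}

#' Assign marker SNPs to modes
#'
#' For detected mode positions \eqn{\beta_1, \ldots, \beta_M}, computes
#' the residual matrix \eqn{r_{jm} = t_j(\beta_m, 0)} over a candidate SNP
#' set and selects SNP `j` as a marker for mode `m` when
#' \eqn{|r_{jm}| \le t_0} and \eqn{|r_{jm'}| > t_1} for every other mode
#' `m'`. With `t0 < t1` marker sets are disjoint across modes by
#' construction. The candidate set is deliberately wider than the
#' instrument set (clumped at r-squared 0.05 rather than 0.001) so that
#' biologically informative markers in mild LD are retained.
#'
#' @param study an [mr_study()] with `K = 1`.
#' @param candidates character vector of candidate SNP ids (the set G).
#' @param modes numeric vector of mode positions, or the `modes`
#'   data.frame of an `mr_profile`.
#' @param sigma an [mr_sigma()] or `NULL`.
#' @param t0 inclusion cutoff; default 1.
#' @param t1 exclusion cutoff; default 2.
#' @return an object of class `mr_markers`: list with `residuals` (|G| x M
#'   matrix), `markers` (per-mode list of SNP ids), `ratios` (per-SNP
#'   \eqn{\hat\Gamma_j/\hat\gamma_j} for reporting), `t0`, `t1`.
#' @export
select_markers <- function(study, candidates, modes, sigma = NULL,
                           t0 = 1, t1 = 2) {
  if (study$K != 1L)
    stopf("marker selection is defined for a single exposure (K = 1)")
  if (is.data.frame(modes)) modes <- modes$position
  if (length(modes) == 0L) stopf("modes must be nonempty")
  if (length(candidates) == 0L) stopf("candidate SNP set G is empty")
  if (t0 >= t1) stopf("t0 < t1 is required for disjoint marker sets")
  sub <- subset_study(study, candidates)
  pt <- profile_t_parts(sub, sigma)
  R <- vapply(modes, function(b) eval_profile_t(pt, b, 0),
              numeric(length(candidates)))
  R <- matrix(R, nrow = length(candidates),
              dimnames = list(candidates, paste0("mode", seq_along(modes))))
  markers <- lapply(seq_along(modes), function(m) {
    inc <- abs(R[, m]) <= t0
    exc <- if (length(modes) == 1L) rep(TRUE, nrow(R))
           else apply(abs(R[, -m, drop = FALSE]) > t1, 1L, all)
    candidates[inc & exc]
  })
  names(markers) <- paste0("mode", seq_along(modes))
  overlap <- if (length(markers) > 1L)
    anyDuplicated(unlist(markers)) else 0L
  stopifnot("marker sets must be disjoint across modes" = overlap == 0L)
  structure(list(residuals = R, markers = markers,
                 ratios = stats::setNames(
                   sub$Gamma_hat / sub$gamma_hat[, 1L], candidates),
                 mode_positions = modes, t0 = t0, t1 = t1),
            class = "mr_markers")
}

#' @export
print.mr_markers <- function(x, ...) {
  cat(sprintf("Marker SNPs at %d mode(s) (t0 = %g, t1 = %g):\n",
              length(x$markers), x$t0, x$t1))
  for (m in seq_along(x$markers)) {
    cat(sprintf("  mode %d at %.3f: %d marker(s)%s\n",
                m, x$mode_positions[m], length(x$markers[[m]]),
                if (length(x$markers[[m]]))
                  paste0(" [", paste(utils::head(x$markers[[m]], 5L),
                                     collapse = ", "),
                         if (length(x$markers[[m]]) > 5L) ", ..." else "",
                         "]")
                else ""))
  }
  invisible(x)
}

#' Diagnose causal direction from forward and reverse profiles
#'
#' Fits the diagnostic profile likelihood in both directions. Under the
#' correct direction the profile is unimodal near the causal effect; with
#' the roles of exposure and outcome swapped it splits into two modes,
#' one near zero (variants acting on the true outcome directly) and one
#' near the reciprocal of the forward estimate (variants acting through
#' the true exposure).
#'
#' @param forward an [mr_study()] with the hypothesized exposure-outcome
#'   orientation.
#' @param reverse the same traits with roles swapped, selected with its
#'   own selection cohort.
#' @param forward_instruments,reverse_instruments instrument sets (ids or
#'   `mr_instruments`) for each direction.
#' @param sigma_f,sigma_r shared-correlation matrices per direction.
#' @param ... passed to [profile_curve()] (e.g. `c`, `n_grid`).
#' @param zero_tol a reverse mode within this distance of 0 is annotated
#'   as the null mode; default 0.1.
#' @return an object of class `mr_direction`: list with `forward`,
#'   `reverse` (both `mr_profile`), `call` (one of `"forward"`,
#'   `"reverse"`, `"inconclusive"`), and annotations of the reverse modes
#'   nearest 0 and nearest the reciprocal of the forward mode.
#' @export
direction_diagnostic <- function(forward, reverse,
                                 forward_instruments, reverse_instruments,
                                 sigma_f = NULL, sigma_r = NULL,
                                 zero_tol = 0.1, ...) {
  pf <- profile_curve(forward, forward_instruments, sigma_f, ...)
  pr <- profile_curve(reverse, reverse_instruments, sigma_r, ...)
  nf <- nrow(pf$modes)
  nr <- nrow(pr$modes)
  call <- if (nf == 1L && nr > 1L) "forward"
          else if (nr == 1L && nf > 1L) "reverse"
          else "inconclusive"
  fwd_pos <- if (nf >= 1L) pf$modes$position[which.max(pf$modes$height)]
             else NA_real_
  rev_pos <- pr$modes$position
  near_zero <- if (nr) rev_pos[which.min(abs(rev_pos))] else NA_real_
  recip <- if (is.finite(fwd_pos) && abs(fwd_pos) > 1e-8) 1 / fwd_pos
           else NA_real_
  near_recip <- if (nr && is.finite(recip))
    rev_pos[which.min(abs(rev_pos - recip))] else NA_real_
  structure(list(
    forward = pf, reverse = pr, call = call,
    forward_mode = fwd_pos,
    reverse_mode_near_zero = if (is.finite(near_zero) &&
                                 abs(near_zero) <= zero_tol) near_zero
                             else NA_real_,
    reverse_mode_near_reciprocal = near_recip,
    reciprocal_of_forward = recip
  ), class = "mr_direction")
}

#' @export
print.mr_direction <- function(x, ...) {
  cat(sprintf("Causal-direction diagnosis: %s\n", x$call))
  cat(sprintf("  forward: %d mode(s), main at %.3f\n",
              nrow(x$forward$modes), x$forward_mode))
  cat(sprintf("  reverse: %d mode(s)", nrow(x$reverse$modes)))
  if (is.finite(x$reverse_mode_near_zero))
    cat(sprintf("; null mode at %.3f", x$reverse_mode_near_zero))
  if (is.finite(x$reverse_mode_near_reciprocal))
    cat(sprintf("; mode near 1/forward (%.3f) at %.3f",
                x$reciprocal_of_forward, x$reverse_mode_near_reciprocal))
  cat("\n")
  invisible(x)
}
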