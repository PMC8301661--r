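#' Standardized profile residual for one SNP
#'
#' The statistic \eqn{t_j(\beta, \tau^2) = (\hat\Gamma_j -
#' \hat\gamma_j^T\beta) / \sqrt{\sigma_{Yj}^2 + \beta^T\Sigma_{Xj}\beta -
#' 2\beta^T\Sigma_{XjY_j} + \tau^2}}, where \eqn{\Sigma_j = D\Sigma D}
#' with \eqn{D = diag(\sigma_{Yj}, \sigma_{Xj1}, \ldots, \sigma_{XjK})} is
#' the per-SNP error covariance induced by the shared correlation
#' \eqn{\Sigma}, \eqn{\Sigma_{Xj}} its exposure block and
#' \eqn{\Sigma_{XjY_j}} its exposure-outcome column. At the true
#' \eqn{(\beta, \tau^2)} these residuals are approximately standard
#' normal, which is what both the fit and the mode diagnosis exploit.
#'
#' @param study an [mr_study()].
#' @param beta length-K effect vector.
#' @param tau2 nonnegative overdispersion variance.
#' @param sigma an [mr_sigma()]; `NULL` means no cohort overlap
#'   (identity).
#' @param ids optional subset of SNP ids (default: all SNPs).
#' @return numeric vector of residuals, named by SNP id.
#' @export
profile_t <- function(study, beta, tau2 = 0, sigma = NULL, ids = NULL) {
  if (!is.null(ids)) study <- subset_study(study, ids)
  pt <- profile_t_parts(study, sigma)
  tv <- eval_profile_t(pt, beta, tau2)
  names(tv) <- study$snp
  tv
}

# Precompute the pieces of t_j that do not depend on (beta, tau2), so the
# optimizer can re-evaluate residuals cheaply.
profile_t_parts <- function(study, sigma = NULL) {
  K <- study$K
  if (is.null(sigma)) sigma <- independent_sigma(K)
  S <- sigma$matrix
  if (nrow(S) != K + 1L)
    stopf("Sigma is %d x %d but the study has K = %d exposures",
          nrow(S), ncol(S), K)
  list(
    snp = study$snp,
    Gamma_hat = study$Gamma_hat,
    gamma_hat = study$gamma_hat,
    se_Gamma = study$se_Gamma,
    se_gamma = study$se_gamma,
    Sx = S[-1L, -1L, drop = FALSE],     # exposure block of Sigma
    sxy = S[1L, -1L],                    # outcome-exposure correlations
    K = K
  )
}

# Variance term s_j^2 and residual t_j for all SNPs at once.
eval_profile_parts <- function(pt, beta, tau2) {
  beta <- as.numeric(beta)
  stopifnot(length(beta) == pt$K, tau2 >= -1e-12)
  W <- sweep(pt$se_gamma, 2L, beta, "*")              # p x K
  quad <- rowSums((W %*% pt$Sx) * W)                  # beta' Sigma_Xj beta
  cross <- pt$se_Gamma * as.numeric(W %*% pt$sxy)     # beta' Sigma_XjYj
  s2 <- pt$se_Gamma^2 + quad - 2 * cross + tau2
  bad <- which(s2 <= 0)
  if (length(bad))
    stopf(paste("nonpositive residual variance for SNP %s at the supplied",
                "(beta, tau2); the shared correlation matrix is invalid",
                "for these data"), pt$snp[bad[1L]])
  num <- pt$Gamma_hat - as.numeric(pt$gamma_hat %*% beta)
  list(num = num, s2 = s2, t = num / sqrt(s2), W = W)
}

eval_profile_t <- function(pt, beta, tau2) {
  eval_profile_parts(pt, beta, tau2)$t
}

# Adjusted robust profile log-likelihood l(beta, tau2) = -sum_j rho(t_j).
profile_loglik <- function(pt, beta, tau2, c) {
  -sum(tukey_rho(eval_profile_t(pt, beta, tau2), c))
}

# Per-SNP score contributions psi(t_j) * dt_j/dbeta (p x K matrix) and
# rho(t_j) - eta (length p), the stacked estimating equations behind both
# the optimizer's gradient and the sandwich variance.
score_parts <- function(pt, beta, tau2, loss) {
  ev <- eval_profile_parts(pt, beta, tau2)
  s <- sqrt(ev$s2)
  # d s2 / d beta = 2 (Sigma_Xj beta - Sigma_XjYj); U - V is that halved
  U <- pt$se_gamma * (ev$W %*% pt$Sx)
  V <- pt$se_Gamma * sweep(pt$se_gamma, 2L, pt$sxy, "*")
  dt_dbeta <- -pt$gamma_hat / s - (ev$t / ev$s2) * (U - V)
  psi <- tukey_psi(ev$t, loss$c)
  list(t = ev$t, s2 = ev$s2,
       score_beta = psi * dt_dbeta,                 # p x K
       score_tau2 = tukey_rho(ev$t, loss$c) - loss$eta)
}

# Root of sum_j rho(t_j(beta, tau2)) = p * eta in tau2 at fixed beta.
# The left side is decreasing in tau2; no positive root means tau2 = 0.
solve_tau2 <- function(pt, beta, loss, upper0 = NULL) {
  p <- length(pt$Gamma_hat)
  g <- function(tau2) sum(tukey_rho(eval_profile_t(pt, beta, tau2), loss$c)) -
    p * loss$eta
  if (g(0) <= 0) return(0)
  upper <- upper0 %||% max(pt$Gamma_hat^2, 1e-6)
  for (i in 1:60) {
    if (g(upper) < 0) break
    upper <- upper * 4
  }
  if (g(upper) >= 0) return(upper)  # pathological; flagged by convergence check
  stats::uniroot(g, c(0, upper), tol = 1e-12)$root
}

# Maximize l(beta, tau2) over beta at fixed tau2, from several starting
# values (the robust objective is non-convex), then polish to an exact
# root of the profile score. The polish matters: the joint estimator is
# the root of the stacked score, and the objective alone is too flat
# along the tau2 estimating-equation path to pin beta down numerically.
maximize_beta <- function(pt, tau2, loss, starts) {
  obj <- function(b) -profile_loglik(pt, b, tau2, loss$c)
  grad <- function(b) {
    sp <- score_parts(pt, b, tau2, loss)
    -colSums(sp$score_beta)  # d(-l)/dbeta
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, grad, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("all optimizer starts failed")
  best$par <- newton_polish_beta(pt, best$par, tau2, loss)
  best$value <- obj(best$par)
  best
}

# Damped Newton iterations driving the beta profile score to zero at
# fixed tau2 (numeric Jacobian; K is small).
newton_polish_beta <- function(pt, beta, tau2, loss, max_iter = 50L,
                               tol = 1e-11) {
  K <- length(beta)
  score <- function(b) colSums(score_parts(pt, b, tau2, loss)$score_beta)
  sc <- score(beta)
  for (it in seq_len(max_iter)) {
    if (max(abs(sc)) < tol) break
    h <- pmax(abs(beta), 1) * 1e-7
    J <- matrix(0, K, K)
    for (k in seq_len(K)) {
      up <- beta; up[k] <- up[k] + h[k]
      dn <- beta; dn[k] <- dn[k] - h[k]
      J[, k] <- (score(up) - score(dn)) / (2 * h[k])
    }
    step <- tryCatch(solve(J, -sc), error = function(e) NULL)
    if (is.null(step)) break
    # damp until the score norm decreases
    lam <- 1
    repeat {
      cand <- beta + lam * step
      sc_cand <- score(cand)
      if (sum(sc_cand^2) < sum(sc^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (sum(sc_cand^2) >= sum(sc^2)) break
    beta <- cand
    sc <- sc_cand
  }
  beta
}

# Starting values for beta: per-SNP ratio quantiles (K = 1) around a
# weighted least-squares solution (K > 1).
beta_starts <- function(pt) {
  K <- pt$K
  if (K == 1L) {
    ok <- abs(pt$gamma_hat[, 1L]) > 1e-12
    ratios <- pt$Gamma_hat[ok] / pt$gamma_hat[ok, 1L]
    qs <- stats::quantile(ratios, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    matrix(unique(qs), ncol = 1L)
  } else {
    w <- 1 / pt$se_Gamma^2
    XtX <- crossprod(pt$gamma_hat * sqrt(w))
    Xty <- crossprod(pt$gamma_hat, w * pt$Gamma_hat)
    b0 <- tryCatch(as.numeric(solve(XtX, Xty)), error = function(e) rep(0, K))
    rbind(b0, b0 * 0.5, b0 * 1.5, rep(0, K))
  }
}

#' Fit causal effects by adjusted robust profile likelihood
#'
#' Jointly estimates the causal-effect vector `beta` and the pleiotropy
#' overdispersion `tau2` from a harmonized study: `beta` maximizes the
#' adjusted robust profile likelihood \eqn{l(\beta, \tau^2) = -\sum_j
#' \rho(t_j(\beta, \tau^2))} with Tukey's biweight loss, while `tau2`
#' solves the moment condition \eqn{\sum_j \rho(t_j) = p\,\eta} (floored
#' at zero when no positive root exists). The two steps are alternated to
#' joint convergence. Standard errors come from the M-estimation sandwich
#' over the stacked estimating equations; confidence intervals and
#' p-values are Wald-type.
#'
#' For a binary outcome the estimates are log odds ratios on the
#' conservatively attenuated scale of the marginal logistic model; no
#' de-attenuation is attempted.
#'
#' @param study an [mr_study()].
#' @param instruments an `mr_instruments` from [build_instruments()], or a
#'   character vector of SNP ids.
#' @param sigma an [mr_sigma()] shared-correlation matrix; `NULL` means no
#'   cohort overlap.
#' @param loss an [robust_loss()]; default Tukey biweight with c = 4.6851.
#' @param max_iter maximum alternation iterations.
#' @param tol joint convergence tolerance on (beta, tau2).
#' @return an object of class `mr_fit` with elements `beta_hat`,
#'   `tau2_hat`, `vcov`, `se`, `ci` (95\% Wald), `pvalues`,
#'   `n_instruments`, `converged`, `objective_value`, `residuals` (the
#'   per-SNP `t_j` at the fit) and `exposures`.
#' @export
fit_effects <- function(study, instruments, sigma = NULL,
                        loss = robust_loss(4.6851),
                        max_iter = 100L, tol = 1e-8) {
  ids <- if (inherits(instruments, "mr_instruments")) instruments$ids
         else as.character(instruments)
  K <- study$K
  if (length(ids) <= K)
    stopf("need more instruments than exposures: p = %d, K = %d",
          length(ids), K)
  sub <- subset_study(study, ids)
  pt <- profile_t_parts(sub, sigma)
  p <- length(ids)

  beta <- maximize_beta(pt, 0, loss, beta_starts(pt))$par
  tau2 <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    tau2_new <- solve_tau2(pt, beta, loss)
    step <- maximize_beta(pt, tau2_new, loss, matrix(beta, nrow = 1L))
    beta_new <- step$par
    if (max(abs(beta_new - beta)) + abs(tau2_new - tau2) < tol) {
      beta <- beta_new; tau2 <- tau2_new
      converged <- TRUE
      break
    }
    beta <- beta_new; tau2 <- tau2_new
  }
  obj <- profile_loglik(pt, beta, tau2, loss$c)

  vc <- sandwich_vcov(pt, beta, tau2, loss)
  se <- sqrt(pmax(diag(vc$beta), 0))
  z <- stats::qnorm(0.975)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  pvals <- 2 * stats::pnorm(-abs(beta / se))
  pvals[!is.finite(pvals)] <- 1
  expo <- study$trait_names[-1L]
  names(beta) <- names(se) <- names(pvals) <- expo
  rownames(ci) <- expo
  dimnames(vc$beta) <- list(expo, expo)

  structure(list(
    beta_hat = beta, tau2_hat = tau2, vcov = vc$beta, se = se,
    ci = ci, pvalues = pvals, n_instruments = p,
    converged = converged, objective_value = obj,
    residuals = stats::setNames(eval_profile_t(pt, beta, tau2), ids),
    tau2_se = vc$tau2_se, exposures = expo,
    loss = loss, outcome_is_binary = study$outcome_is_binary
  ), class = "mr_fit")
}

# M-estimation sandwich over the stacked score (beta equations, then the
# tau2 moment condition). When tau2 sits on the boundary at 0 the tau2
# equation is dropped and beta's variance is computed with tau2 fixed.
sandwich_vcov <- function(pt, beta, tau2, loss) {
  K <- pt$K
  at_boundary <- tau2 <= 0
  total_score <- function(theta) {
    sp <- score_parts(pt, theta[seq_len(K)],
                      if (at_boundary) 0 else theta[K + 1L], loss)
    if (at_boundary) colSums(sp$score_beta)
    else c(colSums(sp$score_beta), sum(sp$score_tau2))
  }
  theta <- if (at_boundary) beta else c(beta, tau2)
  d <- length(theta)
  A <- matrix(0, d, d)
  h <- pmax(abs(theta), 1) * 1e-6
  for (i in seq_len(d)) {
    up <- theta; up[i] <- up[i] + h[i]
    dn <- theta; dn[i] <- dn[i] - h[i]
    if (!at_boundary && i == K + 1L && dn[i] < 0) dn[i] <- 0
    A[, i] <- -(total_score(up) - total_score(dn)) / (up[i] - dn[i])
  }
  sp <- score_parts(pt, beta, tau2, loss)
  U <- if (at_boundary) sp$score_beta
       else cbind(sp$score_beta, sp$score_tau2)
  B <- crossprod(U)
  V <- tryCatch(solve(A, t(solve(A, B))), error = function(e) {
    matrix(NA_real_, d, d)
  })
  list(beta = V[seq_len(K), seq_len(K), drop = FALSE],
       tau2_se = if (at_boundary) NA_real_ else sqrt(max(V[d, d], 0)))
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Robust profile-likelihood MR fit (%d instruments%s)\n",
              x$n_instruments,
              if (x$converged) "" else ", NOT converged"))
  tab <- data.frame(
    beta = x$beta_hat, se = x$se,
    ci_lower = x$ci[, "lower"], ci_upper = x$ci[, "upper"],
    pvalue = signif(x$pvalues, 3))
  print(tab)
  cat(sprintf("Overdispersion tau2 = %.4g%s\n", x$tau2_hat,
              if (is.na(x$tau2_se)) " (at boundary 0)"
              else sprintf(" (se %.3g)", x$tau2_se)))
  invisible(x)
}
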