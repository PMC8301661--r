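#' Configuration for the synthetic summary-statistics generator
#'
#' Describes the generative truth of a three-cohort MR design: true causal
#' effects, pervasive (possibly correlated) pleiotropy, optional
#' confounding genetic pathways, and cohort sizes with optional sample
#' overlap. The generator draws true per-SNP exposure associations from a
#' spike-and-slab law, builds the implied outcome associations, then adds
#' cohort-level estimation noise whose per-SNP standard errors follow the
#' usual \eqn{1/\sqrt{2Nf(1-f)}} law with allele frequencies drawn
#' uniformly on (0.05, 0.5).
#'
#' @param p_total number of SNPs.
#' @param K number of exposures.
#' @param beta length-K true causal effects.
#' @param tau2 variance of the random pervasive pleiotropic effects
#'   \eqn{\tilde\alpha_j \sim N(0, \tau^2)}.
#' @param correlated_a slope of correlated pleiotropy
#'   \eqn{\alpha_j = a\gamma_{j1} + \tilde\alpha_j}; 0 restores the InSIDE
#'   assumption.
#' @param pathways optional list of confounding pathways, each a list with
#'   `kappa` (pathway effect on the outcome), `delta` (pathway association
#'   with the first exposure) and `fraction` (share of SNPs acting only
#'   through the pathway). Pathway SNPs satisfy
#'   \eqn{\gamma_j = \delta\tilde\gamma_j} and
#'   \eqn{\Gamma_j = (\beta_1 + \kappa/\delta)\gamma_j + \tilde\alpha_j},
#'   so they concentrate at ratio \eqn{\beta_1 + \kappa/\delta}.
#' @param N_exposure,N_outcome,N_selection cohort sample sizes (exposure
#'   sizes recycled over K).
#' @param N_overlap number of samples shared between the outcome cohort
#'   and each exposure cohort.
#' @param overlap_corr per-sample trait correlation `Corr[Y_s, X_ks]`
#'   within the shared samples (recycled over K).
#' @param gamma_scale slab standard deviation of the true exposure
#'   associations.
#' @param gamma_prop_nonzero spike-and-slab proportion of SNPs with a
#'   nonzero exposure association.
#' @param outcome_binary simulate a binary outcome: observed outcome
#'   associations are log odds ratios conservatively attenuated by
#'   `1/attenuation`.
#' @param attenuation attenuation ratio c > 1 for the binary outcome.
#' @param seed RNG seed; fixed seeds reproduce byte-identical studies.
#' @return an object of class `mr_sim_config`.
#' @export
simulation_config <- function(p_total = 300L, K = 1L, beta = 0.5,
                              tau2 = 0, correlated_a = 0, pathways = NULL,
                              N_exposure = 1e5, N_outcome = 1e5,
                              N_selection = 1e5, N_overlap = 0,
                              overlap_corr = 0,
                              gamma_scale = 0.05, gamma_prop_nonzero = 1,
                              outcome_binary = FALSE, attenuation = 1.2,
                              seed = 1L) {
  beta <- rep_len(as.numeric(beta), K)
  N_exposure <- rep_len(N_exposure, K)
  overlap_corr <- rep_len(overlap_corr, K)
  if (any(N_overlap > pmin(N_exposure, N_outcome)))
    stopf("N_overlap cannot exceed min(N_exposure, N_outcome)")
  if (tau2 < 0) stopf("tau2 must be nonnegative")
  if (gamma_prop_nonzero < 0 || gamma_prop_nonzero > 1)
    stopf("gamma_prop_nonzero must lie in [0, 1]")
  if (!is.null(pathways)) {
    if (!is.null(pathways$kappa)) pathways <- list(pathways)
    frac <- sum(vapply(pathways, function(pw) pw$fraction, numeric(1)))
    if (frac > 1) stopf("pathway fractions sum to %g > 1", frac)
    for (pw in pathways) {
      if (pw$delta == 0)
        stopf("pathway with delta = 0: mode location beta + kappa/delta is undefined")
    }
  }
  structure(list(
    p_total = as.integer(p_total), K = as.integer(K), beta = beta,
    tau2 = tau2, correlated_a = correlated_a, pathways = pathways,
    N_exposure = N_exposure, N_outcome = N_outcome,
    N_selection = N_selection, N_overlap = N_overlap,
    overlap_corr = overlap_corr,
    gamma_scale = gamma_scale, gamma_prop_nonzero = gamma_prop_nonzero,
    outcome_binary = outcome_binary, attenuation = attenuation,
    seed = seed
  ), class = "mr_sim_config")
}

#' Simulate a three-cohort summary-statistics study
#'
#' Generates GWAS summary statistics for one outcome, K exposures and K
#' independent selection cohorts from the structural truth described by a
#' [simulation_config()]. In the truth layer
#' \eqn{\Gamma_j = \gamma_j^T\beta + \alpha_j} holds exactly; estimation
#' noise for \eqn{(\hat\Gamma_j, \hat\gamma_j)} is multivariate normal
#' with the shared correlation implied by cohort overlap,
#' \eqn{N_s/\sqrt{N_{ek} N_o}\,Corr[Y_s, X_{ks}]}. Exposure cohorts are
#' pairwise disjoint, so exposure-exposure error correlations are zero.
#' The selection cohort is drawn independently, which is what makes
#' selection leave the estimation-cohort errors unbiased (the
#' three-sample design).
#'
#' @param config an [simulation_config()].
#' @return an object of class `mr_sim`: list with `config`, `truth`
#'   (realized `gamma`, `Gamma`, `alpha`, `pathway` membership, `sigma`
#'   — the true shared correlation) and `study` (an [mr_study()]).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cf) {
  p <- cf$p_total; K <- cf$K
  snp <- sprintf("rs%06d", seq_len(p))
  alleles <- c("A", "C", "G", "T")
  # draw non-palindromic pairs so harmonization keeps every SNP
  ea <- sample(alleles, p, replace = TRUE)
  oa <- vapply(ea, function(a) {
    sample(setdiff(alleles, c(a, complement_allele(a))), 1L)
  }, character(1))

  # truth layer
  gamma <- matrix(stats::rnorm(p * K, 0, cf$gamma_scale) *
                    stats::rbinom(p * K, 1L, cf$gamma_prop_nonzero), p, K)
  alpha_tilde <- stats::rnorm(p, 0, sqrt(cf$tau2))
  pathway_id <- integer(p)
  if (!is.null(cf$pathways)) {
    free <- seq_len(p)
    for (m in seq_along(cf$pathways)) {
      pw <- cf$pathways[[m]]
      n_m <- round(pw$fraction * p)
      take <- free[seq_len(min(n_m, length(free)))]
      free <- setdiff(free, take)
      pathway_id[take] <- m
    }
  }
  alpha <- cf$correlated_a * gamma[, 1L] + alpha_tilde
  Gamma <- as.numeric(gamma %*% cf$beta) + alpha
  for (m in seq_along(cf$pathways)) {
    pw <- cf$pathways[[m]]
    on_m <- pathway_id == m
    # SNPs acting only through the pathway: ratio beta_1 + kappa/delta
    Gamma[on_m] <- (cf$beta[1L] + pw$kappa / pw$delta) * gamma[on_m, 1L] +
      alpha_tilde[on_m]
  }

  # per-SNP standard errors from allele frequency and cohort size
  maf <- stats::runif(p, 0.05, 0.5)
  denom <- sqrt(2 * maf * (1 - maf))
  se_Gamma <- 1 / (denom * sqrt(cf$N_outcome))
  se_gamma <- vapply(seq_len(K),
                     function(k) 1 / (denom * sqrt(cf$N_exposure[k])),
                     numeric(p))
  se_gamma <- matrix(se_gamma, p, K)
  se_sel <- vapply(seq_len(K),
                   function(k) 1 / (denom * sqrt(cf$N_selection)),
                   numeric(p))
  se_sel <- matrix(se_sel, p, K)

  # shared error correlation from cohort overlap (outcome x exposures)
  S <- diag(K + 1L)
  for (k in seq_len(K)) {
    S[1L, k + 1L] <- S[k + 1L, 1L] <-
      cf$N_overlap / sqrt(cf$N_exposure[k] * cf$N_outcome) *
      cf$overlap_corr[k]
  }
  L <- chol(S)
  noise <- matrix(stats::rnorm(p * (K + 1L)), p) %*% L
  Gamma_hat <- Gamma + noise[, 1L] * se_Gamma
  gamma_hat <- gamma + noise[, -1L, drop = FALSE] * se_gamma

  if (cf$outcome_binary) Gamma_hat <- Gamma_hat / cf$attenuation

  # independent selection cohort
  gamma_sel <- gamma + matrix(stats::rnorm(p * K), p) * se_sel
  sel_p <- 2 * stats::pnorm(-abs(gamma_sel / se_sel))

  study <- mr_study(
    snp = snp, effect_allele = ea, other_allele = oa,
    gamma_hat = gamma_hat, se_gamma = se_gamma,
    Gamma_hat = Gamma_hat, se_Gamma = se_Gamma,
    sel_pvalues = sel_p,
    trait_names = c("outcome", paste0("exposure", seq_len(K))),
    outcome_is_binary = cf$outcome_binary
  )
  structure(list(
    config = cf,
    truth = list(gamma = gamma, Gamma = Gamma, alpha = alpha,
                 alpha_tilde = alpha_tilde, pathway = pathway_id,
                 maf = maf, sigma = S, gamma_sel = gamma_sel),
    study = study
  ), class = "mr_sim")
}

#' @export
print.mr_sim <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "Simulated three-cohort study: p = %d, K = %d, beta = (%s), tau2 = %g\n",
    cf$p_total, cf$K, paste(signif(cf$beta, 3), collapse = ", "), cf$tau2))
  if (!is.null(cf$pathways))
    for (pw in cf$pathways)
      cat(sprintf("  pathway: kappa = %g, delta = %g (ratio %g), fraction %g\n",
                  pw$kappa, pw$delta, cf$beta[1L] + pw$kappa / pw$delta,
                  pw$fraction))
  invisible(x)
}

#' Seeded scenario catalogue for tests and worked examples
#'
#' Fixed, documented simulation scenarios exercising each analysis
#' component. Available names:
#' \describe{
#'   \item{no-pleiotropy}{K = 1, beta = 0.5, `tau2 = 0`, alpha identically
#'     zero; the clean unimodal baseline.}
#'   \item{inside-pleiotropy}{random pleiotropy `tau2 = 1e-4` independent
#'     of instrument strength (InSIDE holds).}
#'   \item{one-pathway}{beta = 0.2 plus a confounding pathway with
#'     kappa = 0.3, delta = 0.6 on 30\% of SNPs; second mode at 0.7.}
#'   \item{two-pathway}{beta = 0.2 plus pathways at ratios 0.7 and -0.4;
#'     three truth-layer ratio clusters.}
#'   \item{reverse-direction}{the reverse-orientation study of a true
#'     X -> Y effect of 0.5: half the SNPs act on the reverse-exposure
#'     directly (ratio 0), half act through the true exposure
#'     (ratio 1/0.5 = 2).}
#'   \item{overlapping-cohorts}{fully overlapping outcome/exposure cohorts
#'     with per-sample trait correlation 0.5 and a mostly-null SNP panel
#'     for estimating the shared correlation.}
#' }
#'
#' @param name scenario name.
#' @param seed optional seed override (the catalogue fixes one per
#'   scenario).
#' @return an `mr_sim` (see [simulate_study()]).
#' @export
make_fixture <- function(name, seed = NULL) {
  cfg <- switch(name,
    "no-pleiotropy" = simulation_config(
      p_total = 300L, beta = 0.5, tau2 = 0, seed = seed %||% 101L),
    "inside-pleiotropy" = simulation_config(
      p_total = 300L, beta = 0.5, tau2 = 1e-4, seed = seed %||% 102L),
    "one-pathway" = simulation_config(
      p_total = 400L, beta = 0.2,
      pathways = list(list(kappa = 0.3, delta = 0.6, fraction = 0.3)),
      seed = seed %||% 103L),
    "two-pathway" = simulation_config(
      p_total = 600L, beta = 0.2,
      pathways = list(list(kappa = 0.3, delta = 0.6, fraction = 0.25),
                      list(kappa = -0.36, delta = 0.6, fraction = 0.25)),
      seed = seed %||% 104L),
    "reverse-direction" = simulation_config(
      p_total = 400L, beta = 0,
      pathways = list(list(kappa = 1, delta = 0.5, fraction = 0.5)),
      seed = seed %||% 105L),
    "overlapping-cohorts" = simulation_config(
      p_total = 1000L, beta = 0.5, gamma_prop_nonzero = 0.3,
      N_overlap = 1e5, overlap_corr = 0.5, seed = seed %||% 106L),
    stopf("unknown fixture name: %s", name)
  )
  simulate_study(cfg)
}

#' Export a simulated study as per-trait, per-cohort TSV files
#'
#' Writes the file layout that [harmonize()] reads — `outcome.tsv`,
#' `exposure<k>.tsv` and `selection<k>.tsv` — so the full pipeline can be
#' exercised end-to-end on generated files.
#'
#' @param sim an `mr_sim`.
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulated_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- study_to_tables(sim$study)
  paths <- c(outcome = file.path(dir, "outcome.tsv"))
  utils::write.table(tabs$outcome, paths[["outcome"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (k in seq_along(tabs$exposures)) {
    pe <- file.path(dir, sprintf("exposure%d.tsv", k))
    ps <- file.path(dir, sprintf("selection%d.tsv", k))
    utils::write.table(tabs$exposures[[k]], pe, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tabs$selections[[k]], ps, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[[sprintf("exposure%d", k)]] <- pe
    paths[[sprintf("selection%d", k)]] <- ps
  }
  invisible(paths)
}
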