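#' Harmonized three-sample summary-statistics study
#'
#' Container for per-SNP GWAS summary statistics aligned to a common effect
#' allele across one outcome cohort, `K` exposure cohorts and `K`
#' independent selection cohorts. Row `j` holds the estimated outcome
#' association `Gamma_hat[j]` (a log odds ratio when the outcome is
#' binary), the length-`K` exposure associations `gamma_hat[j, ]`, their
#' standard errors, and the selection-cohort p-values used for instrument
#' selection.
#'
#' @param snp character vector of unique SNP identifiers.
#' @param effect_allele,other_allele single-character allele codes; effects
#'   are expressed per copy of `effect_allele`.
#' @param gamma_hat,se_gamma numeric p x K matrices of exposure association
#'   estimates and standard errors (one column per exposure).
#' @param Gamma_hat,se_Gamma numeric vectors of outcome association
#'   estimates and standard errors.
#' @param sel_pvalues numeric p x K matrix of selection-cohort p-values.
#' @param trait_names character vector of K + 1 trait labels, outcome
#'   first.
#' @param outcome_is_binary logical flag; when `TRUE`, estimates are
#'   interpreted on the (conservatively attenuated) log-odds scale.
#' @return an object of class `mr_study`.
#' @export
mr_study <- function(snp, effect_allele, other_allele,
                     gamma_hat, se_gamma, Gamma_hat, se_Gamma,
                     sel_pvalues, trait_names = NULL,
                     outcome_is_binary = FALSE) {
  gamma_hat <- as.matrix(gamma_hat)
  se_gamma <- as.matrix(se_gamma)
  sel_pvalues <- as.matrix(sel_pvalues)
  p <- length(snp)
  K <- ncol(gamma_hat)
  if (is.null(trait_names))
    trait_names <- c("outcome", paste0("exposure", seq_len(K)))
  x <- structure(list(
    snp = as.character(snp),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    gamma_hat = gamma_hat, se_gamma = se_gamma,
    Gamma_hat = as.numeric(Gamma_hat), se_Gamma = as.numeric(se_Gamma),
    sel_pvalues = sel_pvalues,
    K = K, trait_names = trait_names,
    outcome_is_binary = isTRUE(outcome_is_binary)
  ), class = "mr_study")
  validate_mr_study(x)
  x
}

validate_mr_study <- function(x) {
  p <- length(x$snp)
  if (anyDuplicated(x$snp))
    stopf("duplicated SNP identifier in study: %s",
          x$snp[duplicated(x$snp)][1L])
  dims_ok <- nrow(x$gamma_hat) == p && nrow(x$se_gamma) == p &&
    nrow(x$sel_pvalues) == p && length(x$Gamma_hat) == p &&
    length(x$se_Gamma) == p && length(x$effect_allele) == p &&
    length(x$other_allele) == p
  if (!dims_ok) stopf("inconsistent dimensions in mr_study")
  if (ncol(x$gamma_hat) != x$K || ncol(x$se_gamma) != x$K ||
      ncol(x$sel_pvalues) != x$K)
    stopf("exposure matrices must have K = %d columns", x$K)
  if (length(x$trait_names) != x$K + 1L)
    stopf("trait_names must have K + 1 = %d entries (outcome first)", x$K + 1L)
  if (any(x$se_Gamma <= 0) || any(x$se_gamma <= 0))
    stopf("all standard errors must be strictly positive")
  if (any(x$sel_pvalues < 0 | x$sel_pvalues > 1))
    stopf("selection p-values must lie in [0, 1]")
  if (any(x$effect_allele == x$other_allele))
    stopf("effect and other allele must differ for every SNP")
  invisible(x)
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf(
    "Harmonized MR study: %d SNPs, %d exposure(s)\n  outcome: %s (%s)\n  exposures: %s\n",
    length(x$snp), x$K, x$trait_names[1L],
    if (x$outcome_is_binary) "binary" else "continuous",
    paste(x$trait_names[-1L], collapse = ", ")))
  invisible(x)
}

#' Number of SNPs in a study
#' @param x an `mr_study`.
#' @return integer SNP count.
#' @export
n_snps <- function(x) length(x$snp)

#' Restrict a study to a subset of SNPs
#'
#' @param study an `mr_study`.
#' @param ids SNP identifiers to keep; order of `ids` is preserved.
#' @return an `mr_study` containing only the requested SNPs.
#' @export
subset_study <- function(study, ids) {
  idx <- match(ids, study$snp)
  if (anyNA(idx))
    stopf("unknown SNP id(s): %s",
          paste(utils::head(ids[is.na(idx)], 3L), collapse = ", "))
  mr_study(
    snp = study$snp[idx],
    effect_allele = study$effect_allele[idx],
    other_allele = study$other_allele[idx],
    gamma_hat = study$gamma_hat[idx, , drop = FALSE],
    se_gamma = study$se_gamma[idx, , drop = FALSE],
    Gamma_hat = study$Gamma_hat[idx],
    se_Gamma = study$se_Gamma[idx],
    sel_pvalues = study$sel_pvalues[idx, , drop = FALSE],
    trait_names = study$trait_names,
    outcome_is_binary = study$outcome_is_binary
  )
}

#' Flatten a harmonized study to a single table
#'
#' One row per SNP with outcome columns `beta`, `se` and per-exposure
#' columns suffixed by the trait name. This is the schema written by
#' [write_harmonized()].
#'
#' @param study an `mr_study`.
#' @return a `data.frame`.
#' @export
as.data.frame.mr_study <- function(x, ...) {
  study <- x
  out <- data.frame(
    SNP = study$snp,
    effect_allele = study$effect_allele,
    other_allele = study$other_allele,
    beta = study$Gamma_hat,
    se = study$se_Gamma,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(study$K)) {
    nm <- study$trait_names[k + 1L]
    out[[paste0("beta_", nm)]] <- study$gamma_hat[, k]
    out[[paste0("se_", nm)]] <- study$se_gamma[, k]
    out[[paste0("sel_pval_", nm)]] <- study$sel_pvalues[, k]
  }
  out
}

#' Write a harmonized study to a TSV file
#'
#' @param study an `mr_study`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(study, path) {
  utils::write.table(as.data.frame(study), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Decompose a harmonized study back into the per-trait, per-cohort input
# tables that harmonize() accepts (used for round-trip checks and by the
# synthetic generator's file export).
study_to_tables <- function(study) {
  base <- data.frame(SNP = study$snp,
                     effect_allele = study$effect_allele,
                     other_allele = study$other_allele,
                     stringsAsFactors = FALSE)
  outcome <- cbind(base, beta = study$Gamma_hat, se = study$se_Gamma,
                   pval = 2 * stats::pnorm(-abs(study$Gamma_hat / study$se_Gamma)))
  exposures <- lapply(seq_len(study$K), function(k) {
    cbind(base, beta = study$gamma_hat[, k], se = study$se_gamma[, k],
          pval = 2 * stats::pnorm(-abs(study$gamma_hat[, k] / study$se_gamma[, k])))
  })
  # selection tables carry only p-values; beta/se columns are filled with
  # z-equivalents so the file schema is uniform
  selections <- lapply(seq_len(study$K), function(k) {
    z <- stats::qnorm(study$sel_pvalues[, k] / 2, lower.tail = FALSE)
    z[!is.finite(z)] <- 0
    cbind(base, beta = z, se = rep(1, nrow(base)),
          pval = study$sel_pvalues[, k])
  })
  list(outcome = outcome, exposures = exposures, selections = selections)
}
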