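# Shared helpers: small hand-built tables and independent oracles.

options(mrprofile.verbose = FALSE)

# A minimal GWAS table with the required schema.
gwas_table <- function(snp, ea, oa, beta, se = 0.01, pval = 1e-4) {
  data.frame(SNP = snp, effect_allele = ea, other_allele = oa,
             beta = beta, se = se, pval = pval,
             stringsAsFactors = FALSE)
}

# Hand-built three-table fixture: 12 SNPs; rs11/rs12 palindromic (A/T and
# G/C); rs10 missing from the outcome table. Expected survivors: 9.
twelve_snp_tables <- function() {
  snp <- sprintf("rs%02d", 1:12)
  ea <- c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C", "A", "G")
  oa <- c("G", "T", "A", "C", "G", "T", "A", "C", "G", "T", "T", "C")
  full <- gwas_table(snp, ea, oa, beta = seq(0.01, 0.12, by = 0.01))
  outcome <- full[full$SNP != "rs10", ]
  list(outcome = outcome, exposure = full, selection = full)
}

# Independent greedy-clumping oracle: an explicit, slow re-derivation that
# walks candidates in p-value order and checks each against all kept SNPs.
brute_clump <- function(candidates, pvals, r2, cutoff) {
  ord <- candidates[order(pvals)]
  kept <- character(0)
  for (s in ord) {
    if (all(vapply(kept, function(k) r2[s, k] <= cutoff, logical(1))))
      kept <- c(kept, s)
  }
  kept
}

# A study whose per-SNP residuals at given mode positions are chosen by
# hand: se_Gamma = 1 and negligible exposure noise make
# t_j(b, 0) = Gamma_hat_j - b * gamma_hat_j exactly (up to 1e-12).
residual_design_study <- function(Gamma_hat, gamma_hat) {
  p <- length(Gamma_hat)
  mr_study(
    snp = sprintf("s%02d", seq_len(p)),
    effect_allele = rep("A", p), other_allele = rep("G", p),
    gamma_hat = matrix(gamma_hat, ncol = 1), se_gamma = matrix(1e-9, p, 1),
    Gamma_hat = Gamma_hat, se_Gamma = rep(1, p),
    sel_pvalues = matrix(1e-6, p, 1)
  )
}
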