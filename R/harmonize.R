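#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated text file with header columns
#' `SNP, effect_allele, other_allele, beta, se, pval`.
#'
#' @param path file path.
#' @return a `data.frame` with the required columns.
#' @export
read_gwas_table <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  check_gwas_columns(tab, path)
  tab
}

required_cols <- c("SNP", "effect_allele", "other_allele", "beta", "se", "pval")

check_gwas_columns <- function(tab, label = "table") {
  missing <- setdiff(required_cols, names(tab))
  if (length(missing))
    stopf("%s lacks required column(s): %s", label,
          paste(missing, collapse = ", "))
  invisible(tab)
}

is_palindromic <- function(a1, a2) {
  pair <- paste0(toupper(a1), toupper(a2))
  pair %in% c("AT", "TA", "GC", "CG")
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

# Align a table's effect direction to reference alleles. Returns the
# aligned beta (flipped where effect/other are swapped, complemented or
# both) and a keep mask; SNPs whose allele pair cannot be reconciled with
# the reference are dropped.
align_to_reference <- function(tab, ref_ea, ref_oa) {
  ea <- toupper(tab$effect_allele)
  oa <- toupper(tab$other_allele)
  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea
  comp <- complement_allele(ea) == ref_ea & complement_allele(oa) == ref_oa
  comp_swap <- complement_allele(ea) == ref_oa & complement_allele(oa) == ref_ea
  beta <- tab$beta
  beta[swap | comp_swap] <- -beta[swap | comp_swap]
  list(beta = beta, keep = same | swap | comp | comp_swap)
}

#' Harmonize three-sample GWAS summary statistics
#'
#' Merges one outcome table, `K` exposure tables and `K` selection-cohort
#' tables into a single [mr_study()], keeping SNPs present in every table,
#' re-expressing all association estimates per copy of a common effect
#' allele (the outcome table's), removing strand-ambiguous palindromic
#' (A/T, G/C) SNPs, and dropping records with missing fields. Counts of
#' dropped SNPs are reported via `message()`.
#'
#' @param outcome_table a `data.frame` with columns
#'   `SNP, effect_allele, other_allele, beta, se, pval`, or a file path.
#' @param exposure_tables list of `K` such tables (or paths), one per
#'   exposure, in a fixed trait order.
#' @param selection_tables list of `K` such tables (or paths) from
#'   independent selection cohorts, in the same trait order.
#' @param trait_names optional `K + 1` labels, outcome first.
#' @param outcome_is_binary logical; declare the outcome binary (log odds
#'   ratio scale).
#' @return an [mr_study()].
#' @export
harmonize <- function(outcome_table, exposure_tables, selection_tables,
                      trait_names = NULL, outcome_is_binary = FALSE) {
  load_tab <- function(x, label) {
    if (is.character(x) && length(x) == 1L) x <- read_gwas_table(x)
    check_gwas_columns(x, label)
    if (anyDuplicated(x$SNP))
      stopf("duplicated SNP id in %s: %s", label,
            x$SNP[duplicated(x$SNP)][1L])
    x
  }
  if (!is.list(exposure_tables) || is.data.frame(exposure_tables))
    exposure_tables <- list(exposure_tables)
  if (!is.list(selection_tables) || is.data.frame(selection_tables))
    selection_tables <- list(selection_tables)
  K <- length(exposure_tables)
  if (length(selection_tables) != K)
    stopf("need one selection table per exposure (got %d vs %d)",
          length(selection_tables), K)

  outcome <- load_tab(outcome_table, "outcome table")
  exposures <- lapply(seq_len(K), function(k)
    load_tab(exposure_tables[[k]], sprintf("exposure table %d", k)))
  selections <- lapply(seq_len(K), function(k)
    load_tab(selection_tables[[k]], sprintf("selection table %d", k)))

  all_tabs <- c(list(outcome), exposures, selections)
  common <- Reduce(intersect, lapply(all_tabs, function(t) t$SNP))
  n_union <- length(unique(unlist(lapply(all_tabs, function(t) t$SNP))))
  if (length(common) == 0L)
    stopf("no SNP is present in every table; nothing to harmonize")
  mrp_log(sprintf("%d of %d SNPs present in all %d tables",
                  length(common), n_union, length(all_tabs)))

  outcome <- outcome[match(common, outcome$SNP), , drop = FALSE]
  ref_ea <- toupper(outcome$effect_allele)
  ref_oa <- toupper(outcome$other_allele)

  # strand-ambiguous SNPs cannot be aligned without allele frequencies
  pal <- is_palindromic(ref_ea, ref_oa)
  for (t in c(exposures, selections)) {
    ti <- t[match(common, t$SNP), , drop = FALSE]
    pal <- pal | is_palindromic(ti$effect_allele, ti$other_allele)
  }
  if (any(pal))
    mrp_log(sprintf("dropped %d strand-ambiguous (palindromic) SNP(s)",
                    sum(pal)))

  keep <- !pal
  Gamma_hat <- outcome$beta
  se_Gamma <- outcome$se
  gamma_hat <- se_gamma <- sel_p <- matrix(NA_real_, length(common), K)
  for (k in seq_len(K)) {
    tk <- exposures[[k]][match(common, exposures[[k]]$SNP), , drop = FALSE]
    al <- align_to_reference(tk, ref_ea, ref_oa)
    keep <- keep & al$keep
    gamma_hat[, k] <- al$beta
    se_gamma[, k] <- tk$se
    sk <- selections[[k]][match(common, selections[[k]]$SNP), , drop = FALSE]
    als <- align_to_reference(sk, ref_ea, ref_oa)
    keep <- keep & als$keep
    sel_p[, k] <- sk$pval
  }
  n_mismatch <- sum(!keep & !pal)
  if (n_mismatch > 0)
    mrp_log(sprintf("dropped %d SNP(s) with irreconcilable allele pairs",
                    n_mismatch))

  complete <- stats::complete.cases(Gamma_hat, se_Gamma, gamma_hat,
                                    se_gamma, sel_p)
  if (any(keep & !complete))
    mrp_log(sprintf("dropped %d SNP(s) with missing fields",
                    sum(keep & !complete)))
  keep <- keep & complete

  if (!any(keep))
    stopf("no SNP survived harmonization")

  mr_study(
    snp = common[keep],
    effect_allele = ref_ea[keep],
    other_allele = ref_oa[keep],
    gamma_hat = gamma_hat[keep, , drop = FALSE],
    se_gamma = se_gamma[keep, , drop = FALSE],
    Gamma_hat = Gamma_hat[keep],
    se_Gamma = se_Gamma[keep],
    sel_pvalues = sel_p[keep, , drop = FALSE],
    trait_names = trait_names,
    outcome_is_binary = outcome_is_binary
  )
}
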