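#' Select candidate instruments by selection-cohort p-value
#'
#' Applies the Bonferroni-combined selection rule: SNP `j` is a candidate
#' when `min(1, K * min_k p_jk) <= threshold`, where the `p_jk` come from
#' the independent selection cohorts only, never the estimation cohorts.
#'
#' @param study an [mr_study()].
#' @param threshold selection p-value cutoff in (0, 1).
#' @return character vector of candidate SNP ids, in study order.
#' @export
select_instruments <- function(study, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  minp <- apply(study$sel_pvalues, 1L, min)
  combined <- pmin(1, study$K * minp)
  study$snp[combined <= threshold]
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the most significant remaining candidate and discards
#' every remaining candidate in linkage disequilibrium (r-squared above
#' `r2_threshold`) with a kept SNP. Output order is keep order, so kept
#' SNPs are sorted by increasing p-value.
#'
#' @param candidates character vector of candidate SNP ids.
#' @param sort_pvalues numeric vector of ranking p-values, parallel to
#'   `candidates` (or named by SNP id).
#' @param ld_r2 square symmetric matrix of pairwise r-squared values with
#'   SNP ids as dimnames; must cover every candidate pair.
#' @param r2_threshold r-squared cutoff above which two SNPs are treated
#'   as dependent (0.001 for instrument selection, 0.05 for the marker
#'   candidate set).
#' @return character vector of retained, pairwise-independent SNP ids.
#' @export
ld_clump <- function(candidates, sort_pvalues, ld_r2, r2_threshold = 0.001) {
  if (length(candidates) == 0L) return(character(0))
  if (!is.null(names(sort_pvalues)))
    sort_pvalues <- sort_pvalues[candidates]
  stopifnot(length(sort_pvalues) == length(candidates))
  if (is.null(rownames(ld_r2)) || is.null(colnames(ld_r2)))
    stopf("ld_r2 must carry SNP ids as dimnames")
  missing <- setdiff(candidates, rownames(ld_r2))
  if (length(missing))
    stopf("ld_r2 lacks entries for candidate(s): %s",
          paste(utils::head(missing, 3L), collapse = ", "))
  sub <- ld_r2[candidates, candidates, drop = FALSE]
  if (anyNA(sub))
    stopf("ld_r2 contains missing r-squared values among the candidates")

  ord <- order(sort_pvalues)  # ties broken by candidate order (stable)
  remaining <- ord
  kept <- integer(0)
  while (length(remaining)) {
    i <- remaining[1L]
    kept <- c(kept, i)
    r2_to_i <- sub[i, remaining]
    remaining <- remaining[r2_to_i <= r2_threshold]
  }
  candidates[kept]
}

#' Instrument set
#'
#' Selects candidate instruments at a p-value threshold and prunes them to
#' pairwise independence by greedy LD clumping, ranking by the
#' Bonferroni-combined selection p-value. When the SNPs are known to be
#' independent by construction (e.g. simulated panels), pass
#' `assume_independent = TRUE`; with real data an r-squared matrix is
#' required, since correlated instruments invalidate the profile
#' likelihood.
#'
#' @param study an [mr_study()].
#' @param threshold selection p-value cutoff.
#' @param ld_r2 optional square r-squared matrix (see [ld_clump()]).
#' @param r2_threshold clumping cutoff; default 0.001.
#' @param assume_independent skip clumping, asserting pairwise
#'   independence of the candidates.
#' @return an object of class `mr_instruments`: list with `ids`,
#'   `threshold`, `r2_threshold`.
#' @export
build_instruments <- function(study, threshold, ld_r2 = NULL,
                              r2_threshold = 0.001,
                              assume_independent = FALSE) {
  ids <- select_instruments(study, threshold)
  if (is.null(ld_r2)) {
    if (!isTRUE(assume_independent))
      stopf(paste("no LD matrix supplied; pass ld_r2 or set",
                  "assume_independent = TRUE if the SNPs are independent",
                  "by construction"))
  } else {
    minp <- apply(study$sel_pvalues, 1L, min)
    combined <- pmin(1, study$K * minp)
    names(combined) <- study$snp
    n_before <- length(ids)
    ids <- ld_clump(ids, combined, ld_r2, r2_threshold)
    mrp_log(sprintf("clumping kept %d of %d candidates at r2 <= %g",
                    length(ids), n_before, r2_threshold))
  }
  structure(list(ids = ids, threshold = threshold,
                 r2_threshold = if (is.null(ld_r2)) NA_real_ else r2_threshold),
            class = "mr_instruments")
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat(sprintf("Instrument set: %d SNPs at selection threshold %g (r2 cutoff %s)\n",
              length(x$ids), x$threshold,
              if (is.na(x$r2_threshold)) "none, assumed independent"
              else format(x$r2_threshold)))
  invisible(x)
}

#' Read a square r-squared matrix from TSV
#'
#' Expects SNP ids as both the header row and the first column.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stopf("LD matrix is not square")
  if (any(abs(m - t(m)) > 1e-8)) stopf("LD matrix is not symmetric")
  if (any(m < 0 | m > 1)) stopf("r-squared values must lie in [0, 1]")
  m
}
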