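#' Shared correlation matrix from overlapping cohorts
#'
#' When the outcome and exposure GWAS cohorts share samples, the
#' measurement errors of all SNPs' association estimates share a common
#' (K+1) x (K+1) correlation matrix (outcome first). It is estimated from
#' SNPs that are null for every exposure — those whose selection p-values
#' are at least `null_p_cutoff` for all exposures — as the sample
#' correlation of their Z-value columns.
#'
#' @param study an [mr_study()].
#' @param null_p_cutoff SNPs with every selection p-value at or above this
#'   cutoff form the null panel; default 0.5.
#' @param min_snps minimum size of the null panel; default 100.
#' @return an object of class `mr_sigma`: list with `matrix` (unit
#'   diagonal, outcome row/column first), `n_null_snps`, and `repaired`
#'   (whether a positive-semidefinite projection was applied).
#' @export
estimate_shared_correlation <- function(study, null_p_cutoff = 0.5,
                                        min_snps = 100L) {
  null_rows <- apply(study$sel_pvalues >= null_p_cutoff, 1L, all)
  T_null <- sum(null_rows)
  if (T_null < min_snps)
    stopf(paste("only %d SNP(s) have all selection p-values >= %g;",
                "at least %d are needed — supply a larger SNP panel"),
          T_null, null_p_cutoff, min_snps)
  Z <- cbind(study$Gamma_hat[null_rows] / study$se_Gamma[null_rows],
             study$gamma_hat[null_rows, , drop = FALSE] /
               study$se_gamma[null_rows, , drop = FALSE])
  colnames(Z) <- study$trait_names
  S <- stats::cor(Z)
  repaired <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    S <- psd_correlation(S)
    repaired <- TRUE
    mrp_log("shared correlation estimate was indefinite; projected to the nearest PSD correlation matrix")
  }
  mr_sigma(S, n_null_snps = T_null, repaired = repaired)
}

# Eigenvalue clipping at a small floor, then rescale to unit diagonal.
psd_correlation <- function(S, floor = 1e-8) {
  ev <- eigen(S, symmetric = TRUE)
  vals <- pmax(ev$values, floor)
  M <- ev$vectors %*% diag(vals, nrow = length(vals)) %*% t(ev$vectors)
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(S)
  (M + t(M)) / 2
}

#' Construct a shared-correlation object
#'
#' @param matrix symmetric (K+1) x (K+1) correlation matrix, outcome
#'   row/column first, unit diagonal.
#' @param n_null_snps number of null SNPs behind the estimate (NA for a
#'   user-fixed matrix).
#' @param repaired whether PSD repair was applied.
#' @return an `mr_sigma` object.
#' @export
mr_sigma <- function(matrix, n_null_snps = NA_integer_, repaired = FALSE) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stopf("Sigma must be square")
  if (any(abs(diag(matrix) - 1) > 1e-8)) stopf("Sigma must have unit diagonal")
  if (any(abs(matrix) > 1 + 1e-8)) stopf("Sigma entries must lie in [-1, 1]")
  if (any(abs(matrix - t(matrix)) > 1e-8)) stopf("Sigma must be symmetric")
  structure(list(matrix = matrix, n_null_snps = n_null_snps,
                 repaired = repaired),
            class = "mr_sigma")
}

#' Identity shared correlation (no cohort overlap)
#' @param K number of exposures.
#' @param trait_names optional K + 1 labels.
#' @return an `mr_sigma` object with the identity matrix.
#' @export
independent_sigma <- function(K, trait_names = NULL) {
  M <- diag(K + 1L)
  if (!is.null(trait_names)) dimnames(M) <- list(trait_names, trait_names)
  mr_sigma(M)
}

#' @export
print.mr_sigma <- function(x, ...) {
  cat(sprintf("Shared correlation matrix (%d traits%s%s):\n",
              nrow(x$matrix),
              if (is.na(x$n_null_snps)) ""
              else sprintf(", %d null SNPs", x$n_null_snps),
              if (x$repaired) ", PSD-repaired" else ""))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Write / read a shared correlation matrix as TSV
#'
#' Allows fixing Sigma across analyses.
#'
#' @param sigma an `mr_sigma`.
#' @param path file path.
#' @return `write_sigma` returns `path` invisibly; `read_sigma` an
#'   `mr_sigma`.
#' @export
write_sigma <- function(sigma, path) {
  m <- sigma$matrix
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("t", seq_len(nrow(m)) - 1L),
                        paste0("t", seq_len(nrow(m)) - 1L))
  utils::write.table(m, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_sigma
#' @export
read_sigma <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1L, check.names = FALSE))
  mr_sigma(m)
}
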