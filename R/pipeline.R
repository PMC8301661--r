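#' Run the full analysis pipeline
#'
#' Executes the complete workflow on summary-statistics files:
#' harmonization, shared-correlation estimation, instrument selection and
#' clumping, robust profile-likelihood fitting, mode diagnosis (single
#' exposure only) and an optional selection-threshold sweep. Results are
#' written as JSON and TSV under `out_prefix`, together with a plain-text
#' log of every dropped SNP count and decision taken.
#'
#' @param config a named list (or path to a YAML file; requires the
#'   `yaml` package) with entries:
#'   \describe{
#'     \item{outcome, exposures, selections}{file paths; `exposures` and
#'       `selections` are vectors of equal length K.}
#'     \item{threshold}{selection p-value cutoff (default 1e-2).}
#'     \item{ld_matrix}{optional path to a square r-squared TSV; when
#'       absent, `assume_independent: true` must be set explicitly.}
#'     \item{assume_independent}{skip clumping (default `FALSE`).}
#'     \item{sigma}{`"estimate"` (default) or a path to a fixed Sigma
#'       TSV.}
#'     \item{c_fit, c_diag}{biweight constants (defaults 4.6851 and 3).}
#'     \item{t0, t1}{marker-selection cutoffs (defaults 1 and 2).}
#'     \item{r2_instruments, r2_markers}{clumping cutoffs (defaults 0.001
#'       and 0.05).}
#'     \item{sweep}{logical; run the threshold sweep (default `FALSE`).}
#'     \item{sweep_thresholds}{cutoffs for the sweep (default 1e-8 ...
#'       1e-2).}
#'     \item{outcome_binary}{logical (default `FALSE`).}
#'     \item{min_null_snps}{minimum null-SNP panel for Sigma (default
#'       100).}
#'     \item{out_prefix}{output path prefix (default `"mrprofile"`).}
#'   }
#' @return an object of class `mr_report`: list with `study`, `sigma`,
#'   `instruments`, `fit`, `profile`, `markers`, `sweep`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  prefix <- cfg$out_prefix %||% "mrprofile"
  log_path <- paste0(prefix, ".log")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    mrp_log(line)
  }
  for (key in c("outcome", "exposures", "selections")) {
    if (is.null(cfg[[key]])) stopf("config entry '%s' is required", key)
    missing <- cfg[[key]][!file.exists(cfg[[key]])]
    if (length(missing))
      stopf("input file not found: %s", missing[1L])
  }

  note("harmonizing %d exposure(s) with outcome %s",
       length(cfg$exposures), cfg$outcome)
  drops <- utils::capture.output(
    study <- harmonize(cfg$outcome, as.list(cfg$exposures),
                       as.list(cfg$selections),
                       outcome_is_binary = isTRUE(cfg$outcome_binary)),
    type = "message")
  log_lines <- c(log_lines, sub("^\\[mrprofile\\] ", "", drops))
  note("harmonized study: %d SNPs, K = %d", n_snps(study), study$K)

  sigma_spec <- cfg$sigma %||% "estimate"
  sigma <- if (identical(sigma_spec, "estimate")) {
    s <- estimate_shared_correlation(
      study, min_snps = cfg$min_null_snps %||% 100L)
    note("estimated shared correlation from %d null SNPs%s",
         s$n_null_snps, if (s$repaired) " (PSD-repaired)" else "")
    s
  } else {
    note("using fixed shared correlation from %s", sigma_spec)
    read_sigma(sigma_spec)
  }

  ld <- if (!is.null(cfg$ld_matrix)) read_ld_matrix(cfg$ld_matrix) else NULL
  threshold <- cfg$threshold %||% 1e-2
  instruments <- build_instruments(
    study, threshold, ld_r2 = ld,
    r2_threshold = cfg$r2_instruments %||% 0.001,
    assume_independent = isTRUE(cfg$assume_independent))
  note("selected %d instrument(s) at threshold %g",
       length(instruments$ids), threshold)
  if (length(instruments$ids) <= study$K)
    stopf(paste("fit: only %d instrument(s) selected (need > K = %d);",
                "relax the threshold or supply more SNPs"),
          length(instruments$ids), study$K)

  fit <- fit_effects(study, instruments, sigma,
                     loss = robust_loss(cfg$c_fit %||% 4.6851))
  note("fit: beta_hat = (%s), tau2_hat = %g, converged = %s",
       paste(signif(fit$beta_hat, 4), collapse = ", "),
       fit$tau2_hat, fit$converged)

  profile <- NULL; markers <- NULL
  if (study$K == 1L) {
    profile <- profile_curve(study, instruments, sigma,
                             c = cfg$c_diag %||% 3)
    note("mode diagnosis: %d mode(s) at (%s)", nrow(profile$modes),
         paste(signif(profile$modes$position, 4), collapse = ", "))
    marker_ids <- if (!is.null(ld)) {
      minp <- apply(study$sel_pvalues, 1L, min)
      names(minp) <- study$snp
      ld_clump(select_instruments(study, threshold), minp, ld,
               cfg$r2_markers %||% 0.05)
    } else instruments$ids
    if (nrow(profile$modes) > 0L)
      markers <- select_markers(study, marker_ids, profile$modes, sigma,
                                t0 = cfg$t0 %||% 1, t1 = cfg$t1 %||% 2)
  }

  sweep <- NULL
  if (isTRUE(cfg$sweep)) {
    sweep <- threshold_sweep(
      study, sigma,
      thresholds = cfg$sweep_thresholds %||% 10^seq(-8, -2),
      ld_r2 = ld, assume_independent = isTRUE(cfg$assume_independent),
      loss = robust_loss(cfg$c_fit %||% 4.6851),
      c_diag = cfg$c_diag %||% 3)
    note("sweep: mean mode count %.2f, combined p = %s",
         sweep$mean_modes,
         paste(signif(sweep$combined_p, 3), collapse = ", "))
  }

  files <- write_report(prefix, study, sigma, fit, profile, markers, sweep)
  writeLines(log_lines, log_path)
  files <- c(files, log = log_path)
  note("report written under prefix %s", prefix)

  structure(list(study = study, sigma = sigma, instruments = instruments,
                 fit = fit, profile = profile, markers = markers,
                 sweep = sweep, files = files),
            class = "mr_report")
}

write_report <- function(prefix, study, sigma, fit, profile, markers,
                         sweep) {
  files <- character(0)
  fit_json <- list(
    exposures = as.list(stats::setNames(as.list(fit$beta_hat), fit$exposures)),
    se = as.list(stats::setNames(as.list(fit$se), fit$exposures)),
    ci_lower = as.list(stats::setNames(as.list(fit$ci[, "lower"]), fit$exposures)),
    ci_upper = as.list(stats::setNames(as.list(fit$ci[, "upper"]), fit$exposures)),
    pvalues = as.list(stats::setNames(as.list(fit$pvalues), fit$exposures)),
    tau2 = fit$tau2_hat, n_instruments = fit$n_instruments,
    converged = fit$converged, objective = fit$objective_value)
  if (!is.null(profile))
    fit_json$modes <- profile$modes
  if (!is.null(markers))
    fit_json$markers <- lapply(markers$markers, as.list)
  if (!is.null(sweep))
    fit_json$sweep <- list(thresholds = sweep$thresholds,
                           n_instruments = sweep$n_instruments,
                           mode_counts = sweep$mode_counts,
                           mean_modes = sweep$mean_modes,
                           combined_p = as.list(sweep$combined_p))
  fpath <- paste0(prefix, "_fit.json")
  jsonlite::write_json(fit_json, fpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files["fit_json"] <- fpath

  rpath <- paste0(prefix, "_residuals.tsv")
  utils::write.table(
    data.frame(SNP = names(fit$residuals), t = fit$residuals),
    rpath, sep = "\t", quote = FALSE, row.names = FALSE)
  files["residuals"] <- rpath

  spath <- paste0(prefix, "_sigma.tsv")
  write_sigma(sigma, spath)
  files["sigma"] <- spath

  hpath <- paste0(prefix, "_harmonized.tsv")
  write_harmonized(study, hpath)
  files["harmonized"] <- hpath

  if (!is.null(profile)) {
    ppath <- paste0(prefix, "_profile.tsv")
    utils::write.table(data.frame(b = profile$grid, l = profile$values),
                       ppath, sep = "\t", quote = FALSE, row.names = FALSE)
    files["profile"] <- ppath
  }
  files
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Pipeline report\n===============\n")
  print(x$fit)
  if (!is.null(x$profile)) print(x$profile)
  if (!is.null(x$sweep)) print(x$sweep)
  invisible(x)
}
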