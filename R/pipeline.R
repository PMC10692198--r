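#' End-to-end LD-based inference of recent effective population size
#'
#' Runs the full LD branch of the pipeline on a genotype panel: MAF
#' filtering, binned LD computation, the cross-chromosome LD structure
#' test (a warning and a diagnostic flag, never an abort: results on
#' flagged panels may be biased by admixture LD), region filtering, the
#' MAP fit and the chromosome-arm bootstrap.  Every filter decision and
#' hyperparameter is recorded in the returned `log` and diagnostics.
#'
#' @param panel a [genotype_panel()] (or a precomputed [binned_ld()], in
#'   which case the LD computation and the structure test are skipped).
#' @param ages optional [sample_age_table()].
#' @param config a [fit_config()].
#' @param window_cm,maf_min,bin_width_cm passed to [bin_ld_curve()].
#' @param bootstrap logical: compute bootstrap bands (default TRUE).
#' @return an `ne_posterior` whose diagnostics include `ccld` (the
#'   [ccld_test()] report), `regions_kept`, `regions_dropped` and `log`
#'   (character vector of decisions).
#' @export
infer_ne_ld <- function(panel, ages = NULL, config = fit_config(),
                        window_cm = c(0.5, 30), maf_min = 0.25,
                        bin_width_cm = 0.5, bootstrap = TRUE) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (inherits(panel, "binned_ld")) {
    ld <- panel
    ccld <- NULL
    say("input: precomputed binned LD (%d regions)", length(unique(ld$region)))
  } else {
    say("computing binned LD: window [%g, %g) cM, MAF > %g",
        window_cm[1], window_cm[2], maf_min)
    ld <- bin_ld_curve(panel, window_cm, maf_min, bin_width_cm,
                       seed = config$seed)
    ccld <- ccld_test(panel, maf_min, seed = config$seed)
    if (isTRUE(ccld$significant))
      say("WARNING: admixture LD detected (cross-chromosome LD p = %.3g); size estimates may be biased",
          ccld$p_value)
    else if (!is.null(ccld$pair_means))
      say("cross-chromosome LD test: p = %.3g (no structure flagged)",
          ccld$p_value)
  }
  filt <- filter_ld_regions(ld)
  say("region filter: kept %d of %d regions%s", length(filt$kept),
      length(filt$kept) + length(filt$dropped),
      if (length(filt$dropped))
        paste0(" (dropped: ", paste(filt$dropped, collapse = ", "), ")")
      else "")
  ld_kept <- subset_regions(ld, filt$kept)
  fit <- fit_map(ld_kept, config, ages)
  say("MAP fit: c = %.4g, lambda = %.4g, objective = %.6g",
      fit$diagnostics$power, fit$diagnostics$lambda,
      fit$diagnostics$objective)
  if (bootstrap) {
    fit <- bootstrap_ci(ld_kept, config, ages, fit)
    say("bootstrap: %d replicates, %d failures", config$n_bootstrap,
        fit$diagnostics$bootstrap_failures)
  }
  fit$diagnostics$ccld <- if (exists("ccld")) ccld else NULL
  fit$diagnostics$regions_kept <- filt$kept
  fit$diagnostics$regions_dropped <- filt$dropped
  fit$diagnostics$filter_report <- filt$report
  fit$diagnostics$log <- log_lines
  fit
}

#' End-to-end IBD-based inference of recent effective population size
#'
#' IBD branch of the pipeline: segment histogram (2 cM threshold), region
#' filtering, dispersion estimation, MAP fit and bootstrap.
#'
#' @param segments an `ibd_segments` data.frame (from [read_ibd()] or the
#'   simulator), or a precomputed IBD histogram.
#' @param map a [genetic_map()] (required when `segments` is a segment
#'   list).
#' @param config a [fit_config()].
#' @param u_min_cm minimum segment length in cM (default 2).
#' @param n_pairs number of analysed haplotype pairs (see
#'   [build_ibd_histogram()]).
#' @param bootstrap logical: compute bootstrap bands.
#' @return an `ne_posterior`, as for [infer_ne_ld()].
#' @export
infer_ne_ibd <- function(segments, map = NULL, config = fit_config(),
                         u_min_cm = 2, n_pairs = NULL, bootstrap = TRUE) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (inherits(segments, "ibd_histogram")) {
    hist <- segments
    say("input: precomputed IBD histogram (%d regions)",
        length(attr(hist, "region_lengths")))
  } else {
    if (is.null(map)) stop_input("a genetic map is required for IBD input")
    say("building IBD histogram: %d segments, threshold %g cM",
        nrow(segments), u_min_cm)
    hist <- build_ibd_histogram(segments, map, u_min = u_min_cm,
                                n_pairs = n_pairs %||%
                                  attr(segments, "n_pairs"))
  }
  filt <- filter_ibd_regions(hist)
  say("region filter: kept %d of %d regions%s", length(filt$kept),
      length(filt$kept) + length(filt$dropped),
      if (length(filt$dropped))
        paste0(" (dropped: ", paste(filt$dropped, collapse = ", "), ")")
      else "")
  hist_kept <- subset_regions(hist, filt$kept)
  fit <- fit_map(hist_kept, config)
  say("MAP fit: c = %.4g, lambda = %.4g, objective = %.6g",
      fit$diagnostics$power, fit$diagnostics$lambda,
      fit$diagnostics$objective)
  if (bootstrap) {
    fit <- bootstrap_ci(hist_kept, config, NULL, fit)
    say("bootstrap: %d replicates, %d failures", config$n_bootstrap,
        fit$diagnostics$bootstrap_failures)
  }
  fit$diagnostics$regions_kept <- filt$kept
  fit$diagnostics$regions_dropped <- filt$dropped
  fit$diagnostics$filter_report <- filt$report
  fit$diagnostics$log <- log_lines
  fit
}

#' Write the diagnostics of a fit as JSON
#'
#' Records the hyperparameters, filter decisions, structure-test result
#' and convergence flags of a pipeline run.
#'
#' @param posterior an `ne_posterior`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_diagnostics <- function(posterior, path) {
  d <- posterior$diagnostics
  out <- list(type = d$type, power = d$power, lambda = d$lambda,
              objective = d$objective, converged = d$converged,
              n_regions = d$n_regions,
              regions_kept = d$regions_kept %||% character(0),
              regions_dropped = d$regions_dropped %||% character(0),
              ccld_p_value = if (!is.null(d$ccld)) d$ccld$p_value else NULL,
              ccld_significant = if (!is.null(d$ccld)) d$ccld$significant
              else NULL,
              bootstrap_failures = d$bootstrap_failures %||% 0,
              log = d$log %||% character(0))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
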