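#' Numeric thresholds governing the whole pipeline
#'
#' Every hard cut-off used by the germline screen, the second-hit search and
#' the TMB computation lives in one versioned object, so that a run is fully
#' described by its input files plus one config. Defaults are the screening
#' protocol's values; the operational cut-offs that the protocol leaves to
#' the analyst (chromothripsis oscillation count, large-deletion size,
#' hypermethylation level, promoter window) are explicit and configurable.
#'
#' @param af_max Maximum gnomAD-style population allele frequency for a
#'   germline variant to survive the frequency gate. The comparison is
#'   strict (`af < af_max`); missing frequencies are treated as 0 (novel).
#' @param snv_vaf_min Minimum tumor variant allele frequency for a somatic
#'   SNV/indel to count as a second hit; strict (`vaf > snv_vaf_min`).
#' @param sv_vaf_min Minimum VAF for a structural variant; strict.
#' @param clinvar_benign_submitters_max Rule A: exclude when benign/likely
#'   benign ClinVar submitter count exceeds this (strict `>`).
#' @param local_count_synonymous_max Rule B: exclude synonymous variants seen
#'   more than this many times in the local variant database (strict `>`).
#' @param local_count_single_submitter_max Rule C: exclude variants with
#'   exactly one benign/likely-benign ClinVar submitter seen more than this
#'   many times locally (strict `>`).
#' @param expr_tail_percent Size of each expression tail, in percent of the
#'   cohort, considered aberrant (top and bottom tail).
#' @param min_expression_cohort Minimum cohort size for the percentile rule
#'   to be meaningful; below it the expression layer reports "no data".
#' @param tmb_min_depth,tmb_min_af,tmb_max_gnomad Quality gates for variants
#'   entering the TMB count: depth >= `tmb_min_depth`, VAF >=
#'   `tmb_min_af`, population frequency <= `tmb_max_gnomad`.
#' @param tmb_genome_mb Denominator, in megabases, for mutations-per-Mb.
#' @param tmb_high TMB above this (strict `>`) is flagged TMB-high.
#' @param hypermethylation_beta_min Mean promoter beta value at or above
#'   which the promoter is called hypermethylated.
#' @param promoter_window_bp Half-width of the promoter window around the
#'   TSS within which methylation probes are aggregated.
#' @param min_promoter_probes Minimum probe count in the window; fewer
#'   yields a "no data" call.
#' @param large_deletion_mb Copy-number segments longer than this (in Mb)
#'   overlapping a gene are uninformative for second-hit attribution
#'   (non-focal event).
#' @param chromothripsis_min_switches Number of copy-number state switches
#'   on one chromosome at or above which its profile is chromothripsis-like
#'   and uninformative.
#' @param cn_neutral_tol Absolute tolerance around the case ploidy within
#'   which a segment's total copy number counts as copy-neutral.
#'
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' cfg <- threshold_config()
#' cfg$af_max
#' threshold_config(snv_vaf_min = 0.1)
#' @export
threshold_config <- function(af_max = 0.01,
                             snv_vaf_min = 0.05,
                             sv_vaf_min = 0.10,
                             clinvar_benign_submitters_max = 2L,
                             local_count_synonymous_max = 100L,
                             local_count_single_submitter_max = 80L,
                             expr_tail_percent = 5,
                             min_expression_cohort = 20L,
                             tmb_min_depth = 10L,
                             tmb_min_af = 0.05,
                             tmb_max_gnomad = 0.001,
                             tmb_genome_mb = 3000,
                             tmb_high = 10,
                             hypermethylation_beta_min = 0.6,
                             promoter_window_bp = 1500L,
                             min_promoter_probes = 3L,
                             large_deletion_mb = 25,
                             chromothripsis_min_switches = 10L,
                             cn_neutral_tol = 0.3) {
  cfg <- list(
    af_max = af_max,
    snv_vaf_min = snv_vaf_min,
    sv_vaf_min = sv_vaf_min,
    clinvar_benign_submitters_max = as.integer(clinvar_benign_submitters_max),
    local_count_synonymous_max = as.integer(local_count_synonymous_max),
    local_count_single_submitter_max = as.integer(local_count_single_submitter_max),
    expr_tail_percent = expr_tail_percent,
    min_expression_cohort = as.integer(min_expression_cohort),
    tmb_min_depth = as.integer(tmb_min_depth),
    tmb_min_af = tmb_min_af,
    tmb_max_gnomad = tmb_max_gnomad,
    tmb_genome_mb = tmb_genome_mb,
    tmb_high = tmb_high,
    hypermethylation_beta_min = hypermethylation_beta_min,
    promoter_window_bp = as.integer(promoter_window_bp),
    min_promoter_probes = as.integer(min_promoter_probes),
    large_deletion_mb = large_deletion_mb,
    chromothripsis_min_switches = as.integer(chromothripsis_min_switches),
    cn_neutral_tol = cn_neutral_tol
  )
  numeric_ok <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))
  if (!all(numeric_ok)) {
    stop("all thresholds must be single positive finite numbers; offending: ",
         paste(names(cfg)[!numeric_ok], collapse = ", "), call. = FALSE)
  }
  if (cfg$expr_tail_percent <= 0 || cfg$expr_tail_percent >= 50) {
    stop("expr_tail_percent must lie in (0, 50)", call. = FALSE)
  }
  if (cfg$af_max > 1 || cfg$snv_vaf_min >= 1 || cfg$sv_vaf_min >= 1) {
    stop("frequency thresholds must be fractions in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(x)) cat(sprintf("  %-34s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_threshold_config <- function(config) {
  if (is.null(config)) return(threshold_config())
  if (inherits(config, "threshold_config")) return(config)
  if (is.list(config)) return(do.call(threshold_config, config))
  stop("`config` must be a threshold_config or a named list", call. = FALSE)
}

#' Read or write a threshold configuration as JSON
#'
#' @param path File path of the JSON config.
#' @return `read_config()` returns a [threshold_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  as_threshold_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config A [threshold_config()].
#' @export
write_config <- function(config, path) {
  config <- as_threshold_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
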