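#' Run screen, second-hit search and cohort report as one reproducible run
#'
#' Orchestrates the three analysis stages over a cohort (an in-memory
#' cohort list or a cohort directory in the [write_cohort()] layout),
#' fails fast on validation errors, and assembles a run manifest with the
#' package version, a config digest, input digests and per-stage record
#' counts. All randomness lives in the simulator; the analysis stages are
#' deterministic, so re-running on identical inputs reproduces identical
#' result digests (manifest timestamps aside). A cohort without an optional
#' data layer (e.g. no methylation table) degrades with a warning: that
#' evidence layer reports no data and the run completes.
#'
#' @param cohort A cohort list or a cohort directory path.
#' @param config A [threshold_config()] or `NULL` for defaults.
#' @param out_dir Optional output directory; when given, verdicts, the
#'   screen table, the summary and the manifest are written as TSV/JSON.
#' @param interactions Optional interaction table for pathway expansion.
#' @return A list: `screen` (`germline_screen`), `secondhit`
#'   (`secondhit_result`), `summary` (`cohort_summary`), `manifest`.
#' @export
run_pipeline <- function(cohort, config = NULL, out_dir = NULL, interactions = NULL) {
  config <- as_threshold_config(config)
  input_digests <- NULL
  if (is.character(cohort)) {
    dir <- cohort
    files <- list.files(dir, recursive = TRUE, full.names = TRUE)
    if (!length(files)) stop("validation error: empty cohort directory: ", dir, call. = FALSE)
    input_digests <- tibble::tibble(
      file = list.files(dir, recursive = TRUE),
      md5 = unname(tools::md5sum(files))
    )
    cohort <- read_cohort(dir)
  }
  req <- c("cases", "germline", "gene_map", "panel", "knowledge")
  missing <- req[!req %in% names(cohort) | vapply(cohort[req], is.null, logical(1))]
  if (length(missing)) {
    stop("validation error: cohort is missing required inputs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  degraded <- character(0)
  for (layer in c("segments", "expression", "methylation")) {
    if (is.null(cohort[[layer]])) {
      degraded <- c(degraded, layer)
      warning("cohort has no ", layer, " data; that evidence layer reports no data",
              call. = FALSE)
    }
  }

  scr <- screen_germline(cohort$germline, cohort$panel, cohort$knowledge, config = config)
  hits <- detect_second_hits(
    scr, somatic = cohort$somatic, sv = cohort$sv, segments = cohort$segments,
    expression = cohort$expression, methylation = cohort$methylation,
    gene_map = cohort$gene_map, cases = cohort$cases,
    interactions = interactions, config = config
  )
  carrier_ids <- unique(scr$reportable$case_id)
  cases <- dplyr::mutate(cohort$cases, carrier = .data$case_id %in% carrier_ids)
  summary <- summarize_cohort(cases, verdicts = hits$verdicts, screen = scr)

  cfg_file <- tempfile(fileext = ".json")
  write_config(config, cfg_file)
  result_digest <- {
    res_file <- tempfile(fileext = ".tsv")
    readr::write_tsv(hits$verdicts, res_file, progress = FALSE)
    unname(tools::md5sum(res_file))
  }
  manifest <- list(
    tool_version = as.character(utils::packageVersion("secondhit")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    degraded_layers = degraded,
    counts = list(
      cases = nrow(cohort$cases),
      germline_variants = nrow(cohort$germline),
      reportable_findings = nrow(scr$reportable),
      carrier_cases = length(carrier_ids),
      somatic_variants = nrow(cohort$somatic),
      verdicts = nrow(hits$verdicts),
      second_hits = sum(hits$verdicts$hit_found)
    ),
    result_digest = result_digest,
    inputs = input_digests
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(scr$variants, file.path(out_dir, "screen.tsv"), progress = FALSE)
    readr::write_tsv(hits$verdicts, file.path(out_dir, "verdicts.tsv"), progress = FALSE)
    readr::write_tsv(hits$evidence, file.path(out_dir, "evidence.tsv"), progress = FALSE)
    readr::write_tsv(hits$tmb, file.path(out_dir, "tmb.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(detection = summary$detection, second_hits = summary$second_hits,
           categories = summary$categories, odds_ratios = summary$odds_ratios,
           age = summary$age, actionability = summary$actionability,
           criteria = summary$criteria),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  list(screen = scr, secondhit = hits, summary = summary, manifest = manifest)
}
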