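#' Plot the germline filter funnel
#'
#' Bar chart of per-status variant counts after screening, showing how the
#' exclusion gates and rules partition the input variant set.
#'
#' @param object A `germline_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot germline_screen
#' @export
autoplot.germline_screen <- function(object, ...) {
  ggplot2::ggplot(object$funnel, ggplot2::aes(x = stats::reorder(.data$status, -.data$n),
                                              y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "variants", title = "Germline screen filter funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot verdict composition for a second-hit run
#'
#' @param object A `secondhit_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot secondhit_result
#' @export
autoplot.secondhit_result <- function(object, ...) {
  df <- object$verdicts %>%
    dplyr::mutate(outcome = dplyr::case_when(
      .data$hit_found ~ paste0("hit: ", .data$evidence_kinds),
      !.data$informative ~ "uninformative",
      TRUE ~ "no second hit"
    )) %>%
    dplyr::count(.data$outcome)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$outcome, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "darkred") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "case-gene verdicts",
                  title = "Second-hit verdicts by evidence class") +
    ggplot2::theme_minimal()
}

#' Cohort expression context for one gene and sample
#'
#' Shows the cohort FPKM distribution for the gene with the sample of
#' interest highlighted and the aberrancy tails shaded, mirroring how
#' expression outliers are assessed against the whole screening cohort.
#'
#' @param expression An `expression_matrix`.
#' @param gene Gene symbol.
#' @param sample Highlighted sample.
#' @param config A [threshold_config()].
#' @return A ggplot object.
#' @export
plot_expression_context <- function(expression, gene, sample, config = NULL) {
  config <- as_threshold_config(config)
  samples <- setdiff(names(expression), "gene")
  vals <- as.numeric(unlist(expression[expression$gene == gene, samples]))
  n <- length(vals)
  sorted <- sort(vals)
  lo <- sorted[nearest_rank_index(config$expr_tail_percent, n)]
  hi <- sorted[n - nearest_rank_index(config$expr_tail_percent, n) + 1L]
  df <- tibble::tibble(sample = samples, fpkm = vals,
                       highlight = samples == sample)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$fpkm)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$highlight, size = .data$highlight),
                         width = 0.2, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(lo, hi), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1, `TRUE` = 3)) +
    ggplot2::labs(x = gene, y = "FPKM",
                  title = sprintf("%s expression across the cohort (n = %d)", gene, n),
                  subtitle = sprintf("dashed: %g%% aberrancy tails; red: %s",
                                     config$expr_tail_percent, sample)) +
    ggplot2::theme_minimal()
}

#' Promoter methylation profile for one gene
#'
#' Beta values against distance to the TSS, cohort in grey and the case of
#' interest in red, with the promoter window and hypermethylation level
#' marked.
#'
#' @param methylation Methylation tibble.
#' @param gene Gene symbol.
#' @param sample Highlighted sample.
#' @param config A [threshold_config()].
#' @return A ggplot object.
#' @export
plot_methylation_promoter <- function(methylation, gene, sample, config = NULL) {
  config <- as_threshold_config(config)
  df <- dplyr::filter(methylation, .data$gene == !!gene) %>%
    dplyr::mutate(highlight = .data$sample == !!sample)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dist_tss, y = .data$beta,
                                   colour = .data$highlight)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * config$promoter_window_bp,
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = config$hypermethylation_beta_min,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "red")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "distance to TSS (bp)", y = "beta value",
                  title = sprintf("%s promoter methylation", gene),
                  subtitle = sprintf("red: %s; dashed: hypermethylation level %.2f",
                                     sample, config$hypermethylation_beta_min)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
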