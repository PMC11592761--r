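diagnosis_categories <- c("soft_tissue_sarcoma_high", "soft_tissue_sarcoma_low",
                          "soft_tissue_benign", "bone_sarcoma_high",
                          "bone_sarcoma_low", "bone_benign", "gist",
                          "gynaecological_tract")

# printed style: whole percent, half away from zero
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

percent_label <- function(num, den) {
  round_half_away(100 * num / den)
}

#' Germline detection rates
#'
#' The fraction of cases carrying a reportable germline finding, for the
#' whole cohort and after excluding cases with benign tumors (both
#' numerator and denominator restricted to non-benign cases).
#'
#' @param cases Case tibble with logical columns `carrier` and `malignant`.
#' @return A tibble with one row per denominator (`whole_cohort`,
#'   `excluding_benign`): numerator, denominator, `rate` and the printed
#'   whole-percent value. An all-benign cohort yields an `NA` flagged
#'   excluding-benign row.
#' @examples
#' cases <- tibble::tibble(carrier = c(TRUE, rep(FALSE, 9)), malignant = TRUE)
#' detection_rates(cases)
#' @export
detection_rates <- function(cases) {
  if (!nrow(cases)) stop("empty cohort", call. = FALSE)
  mal <- dplyr::filter(cases, .data$malignant)
  excl <- if (nrow(mal) == 0) {
    tibble::tibble(denominator_set = "excluding_benign", carriers = NA_integer_,
                   n = 0L, rate = NA_real_, percent = NA_real_,
                   flag = "undefined: all cases benign")
  } else {
    tibble::tibble(denominator_set = "excluding_benign",
                   carriers = sum(mal$carrier), n = nrow(mal),
                   rate = sum(mal$carrier) / nrow(mal),
                   percent = percent_label(sum(mal$carrier), nrow(mal)),
                   flag = NA_character_)
  }
  dplyr::bind_rows(
    tibble::tibble(denominator_set = "whole_cohort",
                   carriers = sum(cases$carrier), n = nrow(cases),
                   rate = sum(cases$carrier) / nrow(cases),
                   percent = percent_label(sum(cases$carrier), nrow(cases)),
                   flag = NA_character_),
    excl
  )
}

#' Diagnosis-category breakdown by germline-finding status
#'
#' Produces the 8-by-2 count table of histopathological categories for the
#' two subcohorts (germline finding yes/no), with per-column fractions
#' printed as whole percent (half away from zero). A case with an unmapped
#' category is an error listing the offending text.
#'
#' @param cases Case tibble with `category` and logical `carrier`.
#' @return A tibble with one row per category: counts and percent per
#'   subcohort.
#' @export
category_table <- function(cases) {
  bad <- setdiff(unique(cases$category), diagnosis_categories)
  if (length(bad)) {
    stop("unmapped diagnosis categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- cases %>%
    dplyr::count(.data$category, .data$carrier) %>%
    tidyr::complete(category = diagnosis_categories, carrier = c(TRUE, FALSE),
                    fill = list(n = 0L)) %>%
    tidyr::pivot_wider(names_from = "carrier", values_from = "n",
                       names_prefix = "carrier_") %>%
    dplyr::rename(n_no_finding = "carrier_FALSE", n_germline_finding = "carrier_TRUE") %>%
    dplyr::mutate(category = factor(.data$category, levels = diagnosis_categories)) %>%
    dplyr::arrange(.data$category) %>%
    dplyr::mutate(category = as.character(.data$category))
  tot_no <- sum(counts$n_no_finding)
  tot_yes <- sum(counts$n_germline_finding)
  dplyr::mutate(
    counts,
    pct_no_finding = if (tot_no > 0) percent_label(.data$n_no_finding, tot_no) else NA_real_,
    pct_germline_finding = if (tot_yes > 0) percent_label(.data$n_germline_finding, tot_yes) else NA_real_
  )
}

#' Second-hit rate among germline carriers
#'
#' Counts carrier cases whose tumor yielded any confirmed second hit, over
#' all carrier cases. Cases without tumor tissue stay in the denominator
#' (and the numerator cannot include them) but are flagged in the output.
#'
#' @param verdicts Verdict tibble ([detect_second_hits()] `$verdicts`), one
#'   row per carrier case-gene; multiple genes per case count once.
#' @return One-row tibble: `hits`, `carriers`, `rate`, `percent`,
#'   `n_no_tumor_tissue`, `flag`.
#' @export
second_hit_rate <- function(verdicts) {
  if (!nrow(verdicts)) {
    return(tibble::tibble(hits = NA_integer_, carriers = 0L, rate = NA_real_,
                          percent = NA_real_, n_no_tumor_tissue = 0L,
                          flag = "undefined: zero carriers"))
  }
  per_case <- verdicts %>%
    dplyr::group_by(.data$case_id) %>%
    dplyr::summarise(hit = any(.data$hit_found),
                     ntt = any(grepl("no tumor tissue", .data$narrative, fixed = TRUE)),
                     .groups = "drop")
  tibble::tibble(
    hits = sum(per_case$hit),
    carriers = nrow(per_case),
    rate = sum(per_case$hit) / nrow(per_case),
    percent = percent_label(sum(per_case$hit), nrow(per_case)),
    n_no_tumor_tissue = sum(per_case$ntt),
    flag = NA_character_
  )
}

#' Odds ratio for a 2x2 table with a normal-approximation interval
#'
#' `OR = (a * d) / (b * c)`; the 95% confidence interval uses the log-OR
#' normal approximation. When any cell is zero, the Haldane-Anscombe
#' correction (0.5 added to every cell) is applied and the result flagged.
#'
#' @param a,b,c,d Non-negative cell counts (exposed-case, exposed-control,
#'   unexposed-case, unexposed-control).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `or`, `ci_lower`, `ci_upper`, `corrected`.
#' @examples
#' odds_ratio(1, 2, 3, 4)$or  # 0.667
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    or = or,
    ci_lower = exp(log(or) - z * se),
    ci_upper = exp(log(or) + z * se),
    corrected = corrected
  )
}

#' Two-sample comparison of age distributions
#'
#' Student's two-sample t-test (equal-variance pooled form by default,
#' matching the named test; set `var_equal = FALSE` for Welch).
#'
#' @param group1,group2 Numeric age vectors, each of length at least 2.
#' @param var_equal Pooled-variance Student test when `TRUE` (default).
#' @param alpha Significance level for the `significant` flag.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean1`, `mean2`,
#'   `significant`.
#' @export
age_comparison <- function(group1, group2, var_equal = TRUE, alpha = 0.05) {
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0 && mean(group1) == mean(group2)) {
    # degenerate but well-defined: identical constant groups differ by nothing
    return(tibble::tibble(t = 0, df = length(group1) + length(group2) - 2,
                          p_value = 1, mean1 = mean(group1), mean2 = mean(group2),
                          significant = FALSE))
  }
  tt <- stats::t.test(group1, group2, var.equal = var_equal)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean1 = mean(group1), mean2 = mean(group2),
    significant = tt$p.value < alpha
  )
}

#' Full cohort summary
#'
#' Assembles the cohort-level report: detection rates, the
#' diagnosis-category table, the second-hit rate, actionability and
#' syndrome-criteria counts, odds ratios for malignancy and sex by
#' germline-finding status, and the age comparison between carriers and
#' non-carriers.
#'
#' @param cases Case tibble with `carrier`, `malignant`, `category`, `sex`,
#'   `age` and optionally `fulfils_criteria`.
#' @param verdicts Verdict tibble for the carrier cases (may be `NULL`).
#' @param screen Optional `germline_screen` object, used for actionability
#'   counts.
#' @return A `cohort_summary` object (list of tibbles).
#' @export
summarize_cohort <- function(cases, verdicts = NULL, screen = NULL) {
  detection <- detection_rates(cases)
  categories <- category_table(cases)
  shr <- if (!is.null(verdicts)) second_hit_rate(verdicts) else NULL

  carriers <- dplyr::filter(cases, .data$carrier)
  noncar <- dplyr::filter(cases, !.data$carrier)
  ors <- dplyr::bind_rows(
    dplyr::mutate(odds_ratio(sum(carriers$malignant), sum(!carriers$malignant),
                             sum(noncar$malignant), sum(!noncar$malignant)),
                  contrast = "malignant_vs_benign", .before = 1),
    dplyr::mutate(odds_ratio(sum(carriers$sex == "female"), sum(carriers$sex == "male"),
                             sum(noncar$sex == "female"), sum(noncar$sex == "male")),
                  contrast = "female_vs_male", .before = 1)
  )
  age <- if (nrow(carriers) >= 2 && nrow(noncar) >= 2) {
    age_comparison(carriers$age, noncar$age)
  } else NULL

  actionability <- if (!is.null(screen)) {
    screen$reportable %>%
      dplyr::distinct(.data$case_id, .keep_all = TRUE) %>%
      dplyr::count(.data$actionability, name = "n_cases")
  } else NULL
  criteria <- if ("fulfils_criteria" %in% names(cases) && nrow(carriers)) {
    n_fulfil <- sum(carriers$fulfils_criteria, na.rm = TRUE)
    n_carr <- nrow(carriers)
    tibble::tibble(
      fulfilling = n_fulfil,
      carriers = n_carr,
      percent = percent_label(n_fulfil, n_carr)
    )
  } else NULL

  structure(list(
    detection = detection,
    categories = categories,
    second_hits = shr,
    odds_ratios = ors,
    age = age,
    actionability = actionability,
    criteria = criteria,
    n_cases = nrow(cases)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases\n", x$n_cases))
  cat("Detection:\n"); print(x$detection)
  if (!is.null(x$second_hits)) { cat("Second hits:\n"); print(x$second_hits) }
  invisible(x)
}
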