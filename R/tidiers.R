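#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarize screen, second-hit and cohort results
#'
#' `tidy()` returns the per-record table of a result object (one variant,
#' one verdict, or one summary statistic per row); `glance()` returns a
#' one-row overview.
#'
#' @param x A `germline_screen`, `secondhit_result` or `cohort_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @name secondhit-tidiers
NULL

#' @rdname secondhit-tidiers
#' @method tidy germline_screen
#' @export
tidy.germline_screen <- function(x, ...) {
  x$variants
}

#' @rdname secondhit-tidiers
#' @method glance germline_screen
#' @export
glance.germline_screen <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x$variants),
    n_reportable = nrow(x$reportable),
    n_carrier_cases = dplyr::n_distinct(x$reportable$case_id),
    n_vus = sum(x$variants$status == "vus"),
    n_excluded = sum(startsWith(x$variants$status, "excluded"))
  )
}

#' @rdname secondhit-tidiers
#' @method tidy secondhit_result
#' @export
tidy.secondhit_result <- function(x, ...) {
  x$verdicts
}

#' @rdname secondhit-tidiers
#' @method glance secondhit_result
#' @export
glance.secondhit_result <- function(x, ...) {
  tibble::tibble(
    n_verdicts = nrow(x$verdicts),
    n_hits = sum(x$verdicts$hit_found),
    n_uninformative = sum(!x$verdicts$informative),
    hit_rate = mean(x$verdicts$hit_found),
    n_tmb_high = sum(x$tmb$tmb_high)
  )
}

#' @rdname secondhit-tidiers
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$categories
}

#' @rdname secondhit-tidiers
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  whole <- x$detection[x$detection$denominator_set == "whole_cohort", ]
  excl <- x$detection[x$detection$denominator_set == "excluding_benign", ]
  tibble::tibble(
    n_cases = x$n_cases,
    carriers = whole$carriers,
    detection_rate = whole$rate,
    detection_rate_excl_benign = excl$rate,
    second_hit_rate = if (!is.null(x$second_hits)) x$second_hits$rate else NA_real_,
    age_p_value = if (!is.null(x$age)) x$age$p_value else NA_real_
  )
}
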