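test_that("detection rates report numerator, denominator and printed percent", {
  cases <- tibble::tibble(carrier = c(TRUE, rep(FALSE, 9)),
                          malignant = c(rep(TRUE, 8), FALSE, FALSE))
  dr <- detection_rates(cases)
  whole <- dr[dr$denominator_set == "whole_cohort", ]
  expect_equal(whole$carriers, 1L)
  expect_equal(whole$n, 10L)
  expect_equal(whole$rate, 0.1)
  expect_equal(whole$percent, 10)

  expect_error(detection_rates(cases[0, ]), "empty cohort")

  all_benign <- tibble::tibble(carrier = FALSE, malignant = FALSE)
  ab <- detection_rates(all_benign)
  expect_true(is.na(ab$rate[ab$denominator_set == "excluding_benign"]))
  expect_match(ab$flag[ab$denominator_set == "excluding_benign"], "benign")
})

test_that("category table conserves counts and rounds half away from zero", {
  one <- tibble::tibble(category = "gist", carrier = FALSE)
  tab1 <- category_table(one)
  expect_equal(sum(tab1$n_no_finding), 1L)
  expect_equal(tab1$pct_no_finding[tab1$category == "gist"], 100)

  expect_error(category_table(tibble::tibble(category = "weird text", carrier = TRUE)),
               "weird text")

  # 11/24 = 45.83... prints as 46
  cases <- tibble::tibble(
    category = c(rep("soft_tissue_sarcoma_high", 11), rep("gist", 13)),
    carrier = TRUE
  )
  tab <- category_table(cases)
  expect_equal(tab$pct_germline_finding[tab$category == "soft_tissue_sarcoma_high"], 46)
  expect_equal(sum(tab$n_germline_finding), 24L)
})

test_that("second-hit rate counts carrier cases once and flags missing tissue", {
  v <- tibble::tibble(
    case_id = c("a", "a", "b", "c"),
    hit_found = c(TRUE, FALSE, FALSE, FALSE),
    narrative = c("snv", "none", "not assessable: no tumor tissue available", "no second hit")
  )
  r <- second_hit_rate(v)
  expect_equal(r$hits, 1L)
  expect_equal(r$carriers, 3L)
  expect_equal(r$n_no_tumor_tissue, 1L)

  none <- second_hit_rate(v[0, ])
  expect_match(none$flag, "zero carriers")

  all_hits <- second_hit_rate(tibble::tibble(case_id = c("a", "b"),
                                             hit_found = TRUE, narrative = "snv"))
  expect_equal(all_hits$percent, 100)
})

test_that("odds ratios satisfy the closed-form identities", {
  expect_equal(odds_ratio(1, 2, 3, 4)$or, (1 * 4) / (2 * 3))
  expect_equal(odds_ratio(5, 5, 5, 5)$or, 1)

  # Haldane-Anscombe correction with a zero cell
  z <- odds_ratio(3, 0, 2, 4)
  expect_equal(z$or, (3.5 * 4.5) / (0.5 * 2.5))
  expect_true(z$corrected)

  # reciprocal inversion for positive cells
  set.seed(1)
  for (i in 1:20) {
    cells <- sample(1:50, 4)
    expect_equal(odds_ratio(cells[1], cells[2], cells[3], cells[4])$or *
                   odds_ratio(cells[2], cells[1], cells[4], cells[3])$or, 1)
  }
  expect_error(odds_ratio(-1, 1, 1, 1), "non-negative")
})

test_that("age comparison is the pooled-variance Student t-test", {
  same <- age_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  ident <- age_comparison(c(5, 5), c(5, 5))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)

  g1 <- c(10, 12, 14); g2 <- c(20, 22, 24)
  out <- age_comparison(g1, g2)
  # hand-computed pooled-variance formula
  sp2 <- (2 * stats::var(g1) + 2 * stats::var(g2)) / 4
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(out$t, t_hand)
  expect_equal(out$df, 4)
  expect_true(out$significant)

  expect_error(age_comparison(1, c(1, 2)), "at least 2")
})

test_that("cohort summary assembles rates, odds ratios and the age test", {
  set.seed(9)
  cases <- tibble::tibble(
    case_id = sprintf("c%02d", 1:40),
    carrier = rep(c(TRUE, FALSE), c(6, 34)),
    malignant = rep(c(TRUE, FALSE), 20),
    category = rep(diagnosis_categories <- c("gist", "soft_tissue_sarcoma_high"), 20),
    sex = rep(c("female", "male"), 20),
    age = round(runif(40, 20, 80)),
    fulfils_criteria = rep(c(TRUE, FALSE), c(2, 38))
  )
  s <- summarize_cohort(cases)
  expect_s3_class(s, "cohort_summary")
  expect_equal(s$detection$carriers[1], 6L)
  expect_equal(nrow(s$odds_ratios), 2)
  expect_equal(s$criteria$fulfilling, 2L)
  g <- glance(s)
  expect_equal(g$n_cases, 40L)
  expect_equal(g$detection_rate, 6 / 40)
})
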