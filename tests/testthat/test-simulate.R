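test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(sim_config(n_cases = 50, seed = 7))
  b <- simulate_cohort(sim_config(n_cases = 50, seed = 7))
  for (el in c("cases", "germline", "somatic", "segments", "methylation", "truth")) {
    expect_identical(a[[el]], b[[el]], info = el)
  }
  expect_identical(as.data.frame(a$expression), as.data.frame(b$expression))

  c2 <- simulate_cohort(sim_config(n_cases = 50, seed = 8))
  expect_false(identical(a$germline, c2$germline))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_cohort(sim_config(n_cases = 10, seed = 99)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("a zero carrier fraction yields no carriers and no reportable cases", {
  co <- simulate_cohort(sim_config(n_cases = 40, carrier_fraction = 0, seed = 3))
  expect_equal(sum(co$truth$carrier), 0)
  scr <- screen_germline(co$germline, co$panel, co$knowledge)
  expect_equal(nrow(scr$reportable), 0)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(second_hit_fraction = 1.5), "fractions")
  expect_error(sim_config(n_cases = 1), "n_cases")
  expect_error(sim_config(evidence_mix = c(snv = 1)), "evidence_mix")
})

test_that("every decoy class is exercised and excluded by its own gate", {
  co <- simulate_cohort(sim_config(n_cases = 120, seed = 21))
  scr <- screen_germline(co$germline, co$panel, co$knowledge)
  status <- scr$variants$status
  # the truth table says which classes were planted
  planted <- unique(unlist(strsplit(co$truth$decoy_classes, ",")))
  expect_true(all(c("frequency", "rule_A", "rule_B", "rule_C", "off_panel",
                    "non_coding") %in% planted))
  for (s in c("excluded_frequency", "excluded_rule_A", "excluded_rule_B",
              "excluded_rule_C", "excluded_panel", "excluded_noncoding")) {
    expect_gt(sum(status == s), 0)
  }
  # decoys never become reportable: reportable cases are exactly the carriers
  expect_setequal(unique(scr$reportable$case_id),
                  co$truth$case_id[co$truth$carrier])
})

test_that("screened carrier counts follow the configured carrier fraction", {
  n <- 100
  p <- 0.08
  counts <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_cases = n, carrier_fraction = p,
                                     background_mutations = 0, decoys_per_case = 1,
                                     seed = 1000 + s))
    scr <- screen_germline(co$germline, co$panel, co$knowledge)
    dplyr::n_distinct(scr$reportable$case_id)
  }, integer(1))
  lo <- stats::qbinom(0.005, n, p)
  hi <- stats::qbinom(0.995, n, p)
  expect_true(all(counts >= lo & counts <= hi))
  # and the screen recovers exactly the planted carriers each time
})
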