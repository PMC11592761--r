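panel <- gene_panel(c("CHEK2", "ATM", "MUTYH", "NF1", "MLH1", "KCNQ1"))

test_that("prefilter applies panel, coding and frequency gates in order", {
  cfg <- threshold_config()
  recs <- dplyr::bind_rows(
    make_record(gene = "NOTONPANEL"),
    make_record(gene = "CHEK2", consequence = "non_coding"),
    make_record(gene = "CHEK2", population_af = 0.01),      # boundary: strict <
    make_record(gene = "CHEK2", population_af = 0.009999),
    make_record(gene = "ATM", consequence = "splice_site", population_af = 1e-4),
    make_record(gene = "ATM", population_af = NA_real_)     # missing AF compares as 0
  )
  out <- prefilter(recs, panel, cfg)
  expect_equal(out$status, c("excluded_panel", "excluded_noncoding",
                             "excluded_frequency", "pass", "pass", "pass"))
})

test_that("exclusion rules fire in order A, B, C with first-hit attribution", {
  cases <- dplyr::bind_rows(
    make_record(clinvar_classification = "benign", clinvar_blb_submitters = 3L),
    make_record(consequence = "synonymous", local_count = 101L),
    make_record(clinvar_classification = "likely_benign",
                clinvar_blb_submitters = 1L, local_count = 81L),
    make_record(clinvar_classification = "benign", clinvar_blb_submitters = 2L,
                local_count = 50L)
  )
  out <- apply_exclusion_rules(cases)
  expect_equal(out$status, c("excluded_rule_A", "excluded_rule_B",
                             "excluded_rule_C", "keep"))
  # a variant that is both A and C is attributed to A
  both <- make_record(clinvar_classification = "benign",
                      clinvar_blb_submitters = 5L, local_count = 500L,
                      consequence = "synonymous")
  expect_equal(apply_exclusion_rules(both)$status, "excluded_rule_A")
})

test_that("rule engine matches the brute-force predicate oracle on the grid", {
  cfg <- threshold_config()
  grid <- expand.grid(blb = c(0L, 1L, 3L), local = c(0L, 81L, 101L),
                      csq = c("missense", "synonymous", "nonsense"),
                      stringsAsFactors = FALSE)
  recs <- purrr::pmap(grid, function(blb, local, csq) {
    make_record(clinvar_blb_submitters = blb, local_count = local,
                consequence = csq)
  }) |> dplyr::bind_rows()
  engine <- apply_exclusion_rules(recs, cfg)$status
  oracle <- purrr::pmap_chr(grid, function(blb, local, csq) {
    oracle_exclusion(blb, local, csq, cfg)
  })
  expect_equal(engine, oracle)
})

test_that("triage distinguishes VUS from asserted pathogenic variants", {
  kn <- dplyr::bind_rows(
    make_knowledge("CHEK2"),
    make_knowledge("MITF", syndrome = "MITF-related melanoma risk",
                   truncation_is_mechanism = FALSE),
    make_knowledge("ATM", syndrome = "ATM-related cancer risk")
  )
  recs <- dplyr::bind_rows(
    # missense without reported cancer-syndrome association
    make_record(gene = "ATM", consequence = "missense",
                clinvar_classification = "pathogenic", clinvar_cancer_assoc = FALSE),
    # truncating, mechanism and phenotype association hold, asserted pathogenic
    make_record(gene = "CHEK2", consequence = "frameshift",
                clinvar_classification = "pathogenic", clinvar_cancer_assoc = TRUE),
    # truncating but truncation is not the disease mechanism
    make_record(gene = "MITF", consequence = "nonsense",
                clinvar_classification = "pathogenic", clinvar_cancer_assoc = TRUE),
    # survives rules but carries no pathogenic assertion
    make_record(gene = "CHEK2", consequence = "missense", clinvar_cancer_assoc = TRUE,
                clinvar_classification = "vus")
  )
  out <- triage_variants(dplyr::mutate(recs, status = "keep"), kn)
  expect_equal(out$status, c("vus", "pathogenic", "vus", "vus"))
})

test_that("synonymous variants surviving rule B are always VUS", {
  kn <- make_knowledge("CHEK2")
  rec <- make_record(gene = "CHEK2", consequence = "synonymous",
                     clinvar_classification = "pathogenic",
                     clinvar_cancer_assoc = TRUE, local_count = 50L)
  out <- triage_variants(dplyr::mutate(rec, status = "keep"), kn)
  expect_equal(out$status, "vus")
})

test_that("reportability follows inheritance mode", {
  kn <- dplyr::bind_rows(
    make_knowledge("CHEK2", inheritance = "dominant"),
    make_knowledge("MUTYH", syndrome = "MUTYH-associated polyposis",
                   inheritance = "recessive")
  )
  base <- function(...) {
    r <- make_record(...)
    dplyr::mutate(r, status = "pathogenic")
  }
  dom_het <- reportability(base(gene = "CHEK2"), kn)
  expect_true(dom_het$reportable)

  rec_het <- reportability(base(gene = "MUTYH"), kn)
  expect_false(rec_het$reportable)

  rec_hom <- reportability(base(gene = "MUTYH", genotype = "hom"), kn)
  expect_true(rec_hom$reportable)

  two_het <- reportability(dplyr::bind_rows(
    base(gene = "MUTYH", pos = 100L), base(gene = "MUTYH", pos = 200L)), kn)
  expect_true(all(two_het$reportable))
  expect_true(all(two_het$compound_het_unphased))
})

test_that("expectation labels follow the mesenchymal association", {
  kn <- fixture_knowledge()
  expect_equal(label_expectation("NF1", kn), "second_hit_expected")
  expect_equal(label_expectation("MLH1", kn), "semi_expected")
  expect_equal(label_expectation("KCNQ1", kn), "second_hit_not_expected")
})

test_that("lowering the frequency cut-off never grows the surviving set", {
  set.seed(42)
  recs <- dplyr::bind_rows(purrr::map(1:300, function(i) {
    make_record(gene = sample(c("CHEK2", "ATM", "ZZZ"), 1),
                pos = i * 10L,
                consequence = sample(c("missense", "synonymous", "non_coding"), 1),
                population_af = sample(c(0, 1e-4, 0.005, 0.02, NA), 1),
                clinvar_blb_submitters = sample(0:4, 1),
                local_count = sample(c(0L, 50L, 90L, 200L), 1))
  }))
  surviving <- function(af_max) {
    out <- prefilter(recs, panel, threshold_config(af_max = af_max))
    which(out$status == "pass")
  }
  for (pair in list(c(0.01, 0.005), c(0.005, 0.001))) {
    expect_true(all(surviving(pair[2]) %in% surviving(pair[1])))
  }
  # raising rule thresholds never shrinks the set kept by the rules
  kept <- function(cfg) {
    which(apply_exclusion_rules(recs, cfg)$status %in% c("keep", "pass"))
  }
  lo <- kept(threshold_config())
  hi <- kept(threshold_config(clinvar_benign_submitters_max = 5,
                              local_count_synonymous_max = 400,
                              local_count_single_submitter_max = 300))
  expect_true(all(lo %in% hi))
})

test_that("screening identical inputs is deterministic", {
  kn <- fixture_knowledge()
  recs <- fixture_cohort()$germline
  a <- screen_germline(recs, fixture_panel(), kn)
  b <- screen_germline(recs, fixture_panel(), kn)
  expect_identical(a$variants, b$variants)
  expect_identical(a$funnel, b$funnel)
})

test_that("genes missing from the knowledge table use the default row with a warning", {
  kn <- make_knowledge("CHEK2")
  rec <- make_record(gene = "ATM", consequence = "nonsense",
                     clinvar_classification = "pathogenic",
                     clinvar_cancer_assoc = TRUE)
  expect_warning(out <- triage_variants(dplyr::mutate(rec, status = "keep"), kn),
                 "ATM")
  # default row: no syndrome, no truncation mechanism, so truncating -> vus
  expect_equal(out$status, "vus")
})
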