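test_that("the carrier table fixture has the printed shape and content", {
  t1 <- table1_cases()
  expect_equal(nrow(t1), 24)
  expect_equal(sum(t1$clinical_impact == "Clinical action"), 16)
  expect_equal(sum(t1$clinical_impact == "Risk factor"), 8)
  expect_equal(sum(t1$fulfils_criteria == "Yes"), 10)
  expect_equal(sum(t1$gene == "CHEK2" & t1$hgvs_c == "c.1229del"), 3)
  expect_equal(sum(grepl("^SNV:", t1$second_hit)), 6)
  expect_equal(sum(grepl("^Deletion", t1$second_hit)), 5)
  expect_equal(sum(t1$second_hit == "NA"), 1)
})

test_that("the category count fixture matches the printed column sums", {
  t2 <- table2_counts()
  expect_equal(nrow(t2), 8)
  expect_equal(sum(t2$n_no_finding), 288)
  expect_equal(sum(t2$n_germline_finding), 24)
  expect_equal(t2$n_germline_finding[t2$category == "gist"], 4)
  expect_equal(t2$pct_no_finding[t2$category == "gist"], 13)
})

test_that("the fixture cohort expands to 312 machine-runnable cases", {
  fx <- fixture_cohort()
  expect_equal(nrow(fx$cases), 312)
  expect_equal(sum(fx$cases$carrier), 24)
  expect_equal(sum(!fx$cases$malignant), 63)
  # category assignment of carriers reproduces the printed germline column
  tab <- category_table(fx$cases)
  t2 <- table2_counts()
  expect_equal(tab$n_germline_finding, t2$n_germline_finding)
  expect_equal(tab$n_no_finding, t2$n_no_finding)
})

test_that("fixture evidence bundles reproduce the printed per-case hits", {
  fx <- fixture_cohort()
  # the printed somatic SNV for the adenosarcoma case yields SNV evidence
  som_115 <- dplyr::filter(fx$somatic, .data$case_id == "115")
  ev <- find_snv_hit(som_115, "CDC73")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$vaf, 0.35)

  # the case without tumor tissue carries the flag
  expect_true(fx$cases$no_tumor_tissue[fx$cases$case_id == "339"])
  expect_equal(sum(fx$cases$no_tumor_tissue), 1)

  # deletion bundles show copy loss with imbalance at the gene locus
  gi <- dplyr::filter(fx$gene_map, .data$gene == "MLH1")
  seg_76 <- dplyr::filter(fx$segments, .data$sample == "76")
  cn <- assess_cn_loh(seg_76, gi[, c("gene", "chrom", "start", "end")],
                      tumor_af = 0.8)
  expect_equal(cn$kind, "focal_deletion")
  expect_match(cn$detail, "alternative allele retained")
})

test_that("pathway expansion over the no-hit fixture cases finds nothing", {
  fx <- fixture_cohort()
  t1 <- table1_cases()
  no_hit <- t1$case_no[!grepl("^(SNV|Deletion)", t1$second_hit)]
  interactions <- tibble::tibble(gene = character(), partner = character())
  for (cid in no_hit) {
    som <- dplyr::filter(fx$somatic, .data$case_id == cid)
    gene <- t1$gene[t1$case_no == cid]
    ev <- suppressWarnings(pathway_expansion(gene, interactions, som, case_id = cid))
    expect_equal(nrow(ev), 0)
  }
})
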