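test_that("somatic SNV hits respect the strict VAF threshold", {
  som <- dplyr::bind_rows(
    make_somatic(gene = "SDHA", vaf = 0.4, pos = 100L),
    make_somatic(gene = "SDHA", vaf = 0.05, pos = 200L),   # boundary: strict >
    make_somatic(gene = "SDHA", vaf = 0.2, pos = 300L, consequence = "synonymous"),
    make_somatic(gene = "OTHER", vaf = 0.5, pos = 400L)
  )
  ev <- find_snv_hit(som, "SDHA")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$vaf, 0.4)
  expect_equal(ev$kind, "snv_or_indel")
  expect_equal(nrow(find_snv_hit(som, "RB1")), 0)
})

test_that("perturbing a VAF across the threshold flips evidence exactly at the boundary", {
  for (eps in c(1e-6, 1e-3, 0.01)) {
    above <- find_snv_hit(make_somatic(vaf = 0.05 + eps), "SDHA")
    below <- find_snv_hit(make_somatic(vaf = 0.05 - eps), "SDHA")
    at <- find_snv_hit(make_somatic(vaf = 0.05), "SDHA")
    expect_equal(nrow(above), 1)
    expect_equal(nrow(below), 0)
    expect_equal(nrow(at), 0)
  }
})

test_that("structural variants use their own stricter VAF threshold", {
  sv <- tibble::tibble(case_id = "case1", chrom = "chr3", start = 10L,
                       end = 5000L, svtype = "DEL", gene = "RB1",
                       vaf = c(0.10, 0.101))
  ev <- find_sv_hit(sv, "RB1")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$vaf, 0.101)
})

gene_rb1 <- tibble::tibble(gene = "RB1", chrom = "chr13", start = 1000000L,
                           end = 1100000L)

test_that("copy-number assessment distinguishes deletion, LOH and uninformative calls", {
  del <- tibble::tibble(sample = "S", chrom = "chr13",
                        start = c(0L, 900000L, 1200000L),
                        end = c(900000L, 1200000L, 30000000L),
                        total_cn = c(2, 1, 2),
                        allelic_imbalance = c(FALSE, TRUE, FALSE))
  ev <- assess_cn_loh(del, gene_rb1, tumor_af = 0.85, ploidy = 2)
  expect_equal(ev$kind, "focal_deletion")
  expect_match(ev$detail, "alternative allele retained")

  loh <- dplyr::mutate(del, total_cn = c(2, 2, 2))
  expect_equal(assess_cn_loh(loh, gene_rb1)$kind, "loh")

  neutral <- dplyr::mutate(del, total_cn = 2, allelic_imbalance = FALSE)
  expect_equal(assess_cn_loh(neutral, gene_rb1)$kind, "none")

  # a 40 Mb deleted segment is non-focal, hence uninformative
  big <- tibble::tibble(sample = "S", chrom = "chr13", start = 0L,
                        end = 40000000L, total_cn = 1, allelic_imbalance = TRUE)
  expect_equal(assess_cn_loh(big, gene_rb1)$kind, "uninformative_large_deletion")

  # no overlapping segment is explicit missing data, not a negative
  off <- tibble::tibble(sample = "S", chrom = "chr1", start = 0L,
                        end = 1000000L, total_cn = 1, allelic_imbalance = TRUE)
  expect_equal(assess_cn_loh(off, gene_rb1)$kind, "no_data")
})

test_that("deletion calls compare against the case ploidy, not against 2", {
  seg <- tibble::tibble(sample = "S", chrom = "chr13",
                        start = c(0L, 900000L, 1200000L),
                        end = c(900000L, 1200000L, 30000000L),
                        total_cn = c(3.6, 2.4, 3.6),
                        allelic_imbalance = c(FALSE, TRUE, FALSE))
  expect_equal(assess_cn_loh(seg, gene_rb1, ploidy = 3.6)$kind, "focal_deletion")
  expect_equal(assess_cn_loh(seg, gene_rb1, ploidy = 2)$kind, "none")
})

test_that("chromothripsis-like profiles are detected by oscillation count", {
  one <- tibble::tibble(chrom = "chr5", start = 0L, end = 100L, total_cn = 2,
                        allelic_imbalance = FALSE)
  expect_false(chromothripsis_like(one))

  alternating <- function(k) tibble::tibble(
    chrom = "chr5", start = seq(0L, by = 100L, length.out = k),
    end = seq(100L, by = 100L, length.out = k),
    total_cn = rep(c(1, 2), length.out = k), allelic_imbalance = FALSE
  )
  expect_true(chromothripsis_like(alternating(15)))   # 14 switches
  expect_false(chromothripsis_like(alternating(10)))  # 9 switches < 10
  expect_true(chromothripsis_like(alternating(11)))   # 10 switches

  # the flag withholds evidence at the gene locus
  segs <- dplyr::mutate(alternating(15), sample = "S", chrom = "chr13",
                        start = .data$start * 1000000L, end = .data$end * 1000000L)
  expect_equal(assess_cn_loh(segs, gene_rb1)$kind, "uninformative_chromothripsis")
})

test_that("expression aberrancy agrees with the sort-based oracle", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(20:400, 1)
    vals <- round(stats::rlnorm(n, 3, 1), 4)
    samples <- sprintf("S%03d", seq_len(n))
    em <- validate_expression(dplyr::bind_cols(
      tibble::tibble(gene = "G1"),
      tibble::as_tibble(as.list(stats::setNames(vals, samples)))
    ))
    idx <- sample(n, 1)
    got <- expression_aberrant(em, "G1", samples[idx])$kind
    expect_equal(got, oracle_expression(vals, idx), info = paste("n =", n))
  }
})

test_that("nearest-rank percentile boundaries behave as documented", {
  n <- 100
  vals <- seq_len(n)  # distinct values 1..100
  samples <- sprintf("S%03d", seq_len(n))
  em <- validate_expression(dplyr::bind_cols(
    tibble::tibble(gene = "G1"),
    tibble::as_tibble(as.list(stats::setNames(vals, samples)))
  ))
  expect_equal(expression_aberrant(em, "G1", samples[5])$kind, "expression_low")
  expect_equal(expression_aberrant(em, "G1", samples[6])$kind, "none")
  expect_equal(expression_aberrant(em, "G1", samples[96])$kind, "expression_high")
  expect_equal(expression_aberrant(em, "G1", samples[95])$kind, "none")
  expect_equal(expression_aberrant(em, "G1", samples[50])$kind, "none")
  # the unique cohort minimum is always in the lower tail
  expect_equal(expression_aberrant(em, "G1", samples[1])$kind, "expression_low")
})

test_that("small expression cohorts yield no data rather than a verdict", {
  samples <- sprintf("S%02d", 1:10)
  em <- validate_expression(dplyr::bind_cols(
    tibble::tibble(gene = "G1"),
    tibble::as_tibble(as.list(stats::setNames(1:10, samples)))
  ))
  expect_equal(expression_aberrant(em, "G1", "S01")$kind, "no_data")
})

test_that("promoter hypermethylation uses the mean beta over promoter probes", {
  meth <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    gene = "SDHC", dist_tss = c(-1200L, -100L, 800L, 90000L),
    beta = c(0.8, 0.9, 0.85, 0.1), sample = "S1"
  )
  seg <- tibble::tibble(sample = "S1", chrom = "chr1", start = 0L,
                        end = 10000000L, total_cn = 2, allelic_imbalance = FALSE)
  gi <- tibble::tibble(gene = "SDHC", chrom = "chr1", start = 100000L, end = 200000L)
  hit <- methylation_hit(meth, "SDHC", "S1", segments = seg, gene_interval = gi)
  expect_equal(hit$kind, "promoter_hypermethylation")
  expect_equal(hit$mean_beta, mean(c(0.8, 0.9, 0.85)))
  expect_match(hit$detail, "biallelic")

  low <- dplyr::mutate(meth, beta = c(0.05, 0.1, 0.08, 0.1))
  expect_equal(methylation_hit(low, "SDHC", "S1")$kind, "none")

  two <- meth[1:2, ]
  expect_equal(methylation_hit(two, "SDHC", "S1")$kind, "no_data")
})

test_that("pathway expansion labels partner-gene hits and never invents them", {
  interactions <- tibble::tibble(gene = c("NF1", "NF1"), partner = c("SPRED1", "RASA1"))
  som <- make_somatic(gene = "SPRED1", vaf = 0.3)
  ev <- pathway_expansion("NF1", interactions, som)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$level, "pathway")
  expect_equal(ev$gene, "SPRED1")

  expect_equal(nrow(pathway_expansion("NF1", interactions, make_somatic(gene = "ZZZ"))), 0)
  expect_warning(out <- pathway_expansion("TP53", interactions, som), "TP53")
  expect_equal(nrow(out), 0)
})

test_that("TMB arithmetic is exact and the gates are inclusive", {
  none <- compute_tmb(tibble::tibble(depth = integer(), vaf = double(),
                                     population_af = double()))
  expect_equal(none$tmb, 0)
  expect_false(none$tmb_high)

  thirty <- compute_tmb(tibble::tibble(depth = rep(50L, 30), vaf = 0.3, population_af = 0))
  expect_equal(thirty$tmb, 0.01)

  many <- compute_tmb(tibble::tibble(depth = rep(50L, 33000), vaf = 0.3, population_af = 0))
  expect_equal(many$tmb, 11)
  expect_true(many$tmb_high)

  # boundary values: depth >= 10, VAF >= 0.05, population AF <= 0.001
  gates <- tibble::tibble(
    depth = c(10L, 9L, 50L, 50L, 50L, 50L),
    vaf = c(0.3, 0.3, 0.05, 0.049, 0.3, 0.3),
    population_af = c(0, 0, 0, 0, 0.001, 0.0011)
  )
  expect_equal(compute_tmb(gates)$n_passing, 3L)
})

test_that("TMB is linear in the passing variant count", {
  set.seed(3)
  for (k in c(10, 117, 400)) {
    recs <- tibble::tibble(depth = rep(60L, k), vaf = 0.25, population_af = 0)
    expect_equal(compute_tmb(dplyr::bind_rows(recs, recs))$tmb,
                 2 * compute_tmb(recs)$tmb)
  }
})

test_that("verdict integration combines layers with the documented priority", {
  del <- evidence_row("c1", "MLH1", "focal_deletion", copy_number = 1,
                      detail = "copy loss")
  v <- integrate_verdict("c1", "MLH1", del, "semi_expected")
  expect_true(v$hit_found)
  expect_true(v$informative)

  nothing <- integrate_verdict("c2", "BRCA1", empty_evidence(), "second_hit_not_expected")
  expect_false(nothing$hit_found)
  expect_true(nothing$informative)
  expect_equal(nothing$narrative, "no second hit")

  uninf <- integrate_verdict("c3", "TP53",
                             evidence_row("c3", "TP53", "uninformative_chromothripsis",
                                          detail = "oscillating profile"))
  expect_false(uninf$hit_found)
  expect_false(uninf$informative)

  # SNV before methylation in the narrative, regardless of input order
  multi <- dplyr::bind_rows(
    evidence_row("c4", "SDHA", "promoter_hypermethylation", mean_beta = 0.9, detail = "beta 0.9"),
    evidence_row("c4", "SDHA", "snv_or_indel", vaf = 0.4, detail = "nonsense VAF 0.4")
  )
  v4 <- integrate_verdict("c4", "SDHA", multi)
  expect_match(v4$narrative, "^snv_or_indel")
  # pathway evidence never upgrades the same-gene verdict
  pw <- evidence_row("c5", "SPRED1", "snv_or_indel", vaf = 0.3,
                     detail = "partner hit", level = "pathway")
  expect_false(integrate_verdict("c5", "NF1", pw)$hit_found)
})
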