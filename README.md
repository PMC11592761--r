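# secondhit

Paired tumor/normal interpretation of germline findings in
mesenchymal-tumor cohorts: panel-restricted germline variant screening,
multi-omics somatic **second-hit** detection under the Knudson two-hit
model, tumor mutational burden, and cohort-level statistics — with a
synthetic paired-cohort simulator and planted-truth table so every stage
is testable end to end without patient data.

## Who this is for

Clinical-genomics and cancer-predisposition researchers who have, per
case, a germline small-variant callset, somatic small-variant and
structural-variant calls, copy-number/allelic-imbalance segments, a
cohort FPKM expression matrix and/or a promoter methylation table, and
who want an auditable, rule-based answer to: *which germline findings are
causative for this tumor?*

## The rules at the core

**Germline screen.** A variant survives iff

- gene ∈ panel, consequence is exonic/splicing, and population allele
  frequency < 0.01 (missing AF counts as 0), and none of the
  benign-evidence rules fires (evaluated A→B→C, first hit recorded):
  - **A** — benign/likely-benign in the assertion table by > 2 submitters,
  - **B** — synonymous and local-database count > 100,
  - **C** — benign/likely-benign by exactly 1 submitter and local count > 80.

Survivors are triaged (missense without cancer-syndrome association →
VUS; truncating without phenotype association or without truncation as
the disease mechanism → VUS; otherwise the per-variant P/LP assertion
applies), then reported by inheritance mode: het/hom P/LP in dominant
genes is reportable; recessive genes need hom or ≥ 2 distinct het P/LP
variants (flagged as unphased potential compound het).

**Second hit.** For each reportable (case, gene), any of:
somatic protein-altering SNV/indel with VAF > 5%; SV with VAF > 10%;
focal deletion (copy number below case ploidy, with allelic imbalance);
copy-neutral LOH; cohort expression in the bottom/top 5th percentile
(nearest-rank); promoter hypermethylation (mean beta ≥ 0.6 over ≥ 3
probes within TSS ± 1.5 kb). Chromothripsis-like chromosomes (≥ 10
copy-state switches) and aberrant segments > 25 Mb are *uninformative*,
not negative.

**TMB.** count(depth ≥ 10, VAF ≥ 0.05, population AF ≤ 0.1%) / 3000 Mb;
\> 10/Mb is TMB-high.

**Cohort report.** Detection rates (whole cohort and excluding benign),
8-category diagnosis table, second-hit rate, odds ratios
OR = ad/bc with log-normal CIs (Haldane–Anscombe 0.5 correction on zero
cells), and Student's pooled-variance t-test for age.

All numeric cut-offs live in one `threshold_config()` object.

## Worked example

Simulate a 120-case paired cohort with planted first and second hits,
run the full pipeline, and inspect the verdicts:

```r
library(secondhit)

co  <- simulate_cohort(sim_config(n_cases = 120, seed = 42))
res <- run_pipeline(co)

glance(res$screen)
#> # A tibble: 1 × 5
#>   n_variants n_reportable n_carrier_cases n_vus n_excluded
#> 1        502           10              10    66        426

glance(res$secondhit)
#> # A tibble: 1 × 5
#>   n_verdicts n_hits n_uninformative hit_rate n_tmb_high
#> 1         10      5               0      0.5          0

res$summary$detection
#> # A tibble: 2 × 6
#>   denominator_set  carriers     n   rate percent flag
#> 1 whole_cohort           10   120 0.0833       8 <NA>
#> 2 excluding_benign       10   108 0.0926       9 <NA>

dplyr::filter(tidy(res$secondhit), hit_found)
#> # A tibble: 5 × 8
#>   case_id gene   hit_found informative n_evidence evidence_kinds
#> 1 S0035   MEN1   TRUE      TRUE                 1 loh
#> 2 S0037   WT1    TRUE      TRUE                 1 snv_or_indel
#> 3 S0055   RAD51D TRUE      TRUE                 1 snv_or_indel
#> 4 S0077   RB1    TRUE      TRUE                 1 promoter_hypermethylation
#> 5 S0092   ATR    TRUE      TRUE                 1 snv_or_indel
```

Reading the output: 502 germline variants reduce to 10 reportable carrier
findings (8% of the cohort — the simulator's default carrier fraction);
the tumor layers confirm a second hit in 5 of the 10 carriers, here one
copy-neutral LOH, one promoter hypermethylation and three somatic
nonsense SNVs at VAF 0.3. The planted-truth table `co$truth` lets you
verify every verdict. `autoplot(res$screen)` draws the filter funnel;
`plot_expression_context()` and `plot_methylation_promoter()` show a
case against its cohort background.

Real data enter the same way through `read_germline_vcf()`,
`read_somatic_vcf()`, `read_segments()`, `read_expression()`,
`read_methylation()` and friends, or as a cohort directory via
`run_pipeline("path/to/cohort")`. A command-line wrapper with
`simulate` / `screen` / `secondhit` / `report` / `run-all` subcommands is
installed at `inst/scripts/secondhit-pipeline.R`.

## Package layout

- `R/io.R` — VCF/TSV readers and writers, coordinate normalization
  (internal coordinates are 0-based half-open), validation.
- `R/screen.R` — germline gates, exclusion rules, triage, reportability.
- `R/secondhit.R` — evidence layers, TMB, verdict integration.
- `R/report.R` — cohort statistics.
- `R/simulate.R` — synthetic cohort generator and on-disk cohort layout.
- `R/fixtures.R` — published-table fixtures and evidence bundles.
- `R/pipeline.R` — orchestration with a run manifest.
- `vignettes/secondhit-methods.Rmd` — the methods and design-decision
  write-up.
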