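---
title: "Methods: germline screening and somatic second-hit detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline screening and somatic second-hit detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secondhit)
library(dplyr)
```

## The problem

Patients with mesenchymal tumors (sarcomas, GISTs, and benign lesions that
mimic them) are occasionally carriers of a hereditary cancer syndrome. When
a blood sample is sequenced alongside the tumor, a germline pathogenic
variant can be interpreted in the light of the tumor's own genome: under
the Knudson two-hit model, a causative germline "first hit" in a tumor
suppressor should be accompanied in the tumor by a somatic "second hit"
that inactivates the remaining allele. Finding that second hit separates
causative germline findings from incidental ones.

`secondhit` implements this interpretation pipeline as deterministic,
auditable rules: a germline screen restricted to a hereditary-cancer gene
panel, a multi-layer somatic second-hit search, tumor mutational burden,
and cohort-level summaries — plus a synthetic paired-cohort simulator so
the whole chain is testable without any patient data.

## Germline screen

Variants in blood are screened in a fixed order, and the first gate that
fires is recorded per variant so the filter funnel is reproducible:

1. **Panel gate** — the gene must be on the configured panel. The screen
   ships a documented synthetic stand-in panel of 62 hereditary-cancer
   genes (`fixture_panel()`); any one-symbol-per-line list can replace it.
2. **Coding gate** — only exonic or splicing consequences pass
   (missense, nonsense, frameshift, splice site, synonymous, other exonic).
3. **Frequency gate** — population allele frequency must be strictly below
   `af_max` (default 0.01). A missing frequency is treated as 0: absence
   from the population reference is itself evidence of rarity.
4. **Benign-evidence rules**, evaluated in the order A, B, C with
   first-hit attribution:
   - **A**: benign/likely-benign assertions by more than 2 submitters;
   - **B**: synonymous and seen more than 100 times in the local variant
     database (a cohort of 9,244 assertion cases);
   - **C**: benign/likely-benign by exactly one submitter and seen more
     than 80 times locally.

   The source protocol lists the rules as alternatives without an order;
   fixing A→B→C changes no verdict (the engine is checked against an
   independent brute-force evaluation of the three predicates) but makes
   exclusion provenance deterministic. Rule C is implemented literally
   ("only one submitter" means exactly one). All rule thresholds are
   strict inequalities, as printed.

5. **Triage** — missense variants with no reported cancer-syndrome
   association are VUS; truncating variants are VUS when the gene has no
   association with the patient's phenotype or truncation is not the known
   disease mechanism; synonymous variants are always VUS (they cannot
   become pathogenic under these rules, so rule-B survivors are retained
   but harmless). Otherwise the classification is taken from the
   per-variant assertion table. This table doubles as the channel for
   expert ACMG/AMP judgements, which are clinical decisions that cannot be
   recomputed from rules; representing them as an overridable per-variant
   input keeps the pipeline faithful without pretending to automate expert
   assessment.
6. **Reportability** — pathogenic/likely-pathogenic findings are
   reportable when heterozygous or homozygous in dominant-disorder genes;
   for recessive-disorder genes only when homozygous or when two distinct
   het P/LP variants hit the same gene (declared a *potential* compound
   heterozygote: short-read phasing is out of scope, so the call is
   flagged unphased). A single het P/LP variant in a recessive gene is a
   carrier finding. Genes with unknown inheritance are treated as
   dominant — the conservative choice for reporting.
7. **Actionability** — defaults per gene from the knowledge table
   (`clinical_action` when a surveillance program exists, else
   `risk_factor`), overridable per case through `assessment_override`,
   because the decision weighs pedigree and phenotype (the same CHEK2
   founder variant can be clinically actionable in one carrier and a mere
   risk factor in another).
8. **Expectation labels** — genes with known or suggested mesenchymal
   tumor association are labelled `second_hit_expected`; Lynch-syndrome
   genes `semi_expected`; others `second_hit_not_expected`.

Phenotype association (step 5) defaults to "the gene has any
cancer-syndrome association in the knowledge table" and can be overridden
per record with a `phenotype_match` column; a finer rule would need the
clinical phenotype ontology, which is out of scope.

## Second-hit search

For every reportable (case, gene) pair, five evidence layers are queried;
any single layer suffices for `hit_found`:

| layer | rule | default |
|---|---|---|
| somatic SNV/indel | protein-altering or splice variant in the gene, VAF strictly above `snv_vaf_min` | 5% |
| structural variant | SV on the gene, VAF strictly above `sv_vaf_min` | 10% |
| focal deletion | overlapping segment with total copy number below the case ploidy (beyond `cn_neutral_tol`) and allelic imbalance | tol 0.3 |
| copy-neutral LOH | copy number within `cn_neutral_tol` of ploidy with allelic imbalance | tol 0.3 |
| expression outlier | cohort FPKM percentile in the bottom/top `expr_tail_percent` | 5% |
| promoter hypermethylation | mean beta over promoter probes at or above `hypermethylation_beta_min` | 0.6 |

Details and deliberate choices:

- **Ploidy-relative deletion calling.** Copy loss is judged against the
  case's average copy number (from case metadata, default 2), not against
  2: in a tumor with ploidy ~3.6 a segment at copy number 2.4 with
  imbalance is a deletion. When the germline variant's allele fraction in
  tumor reads is available, a fraction above 0.5 is reported as retention
  of the alternative allele — the pattern expected when the wild-type
  allele is lost.
- **Uninformative copy-number profiles.** Two operational rules withhold
  (never create) evidence: a chromosome whose segments switch rounded
  copy-number state at least `chromothripsis_min_switches` (default 10)
  times is chromothripsis-like, and an *aberrant* overlapping segment
  longer than `large_deletion_mb` (default 25 Mb) is a non-focal event.
  The length rule applies only to aberrant segments — a diploid
  whole-chromosome segment is normal data coverage, not a large deletion.
  When the sole copy-number finding is uninformative and no other layer
  found a hit, the verdict is marked `informative = FALSE` rather than
  negative. Neither cut-off is printed in any protocol we know of; both
  are explicit and configurable.
- **Expression percentile.** "Bottom/top 5th percentile" uses the
  nearest-rank definition on the per-gene cohort vector: the lower cut is
  the `ceiling(p/100 * n)`-th smallest value, the upper cut symmetric from
  the top, ties included in the tail. At cohort size ~312 the choice of
  interpolation is immaterial, but it must be fixed for determinism; the
  implementation is property-tested against an independent sort-and-index
  oracle. Cohorts under 20 samples yield "no data". The rule is
  cohort-wide; per-histology stratification would need larger strata than
  a single sarcoma-center cohort provides.
- **Promoter methylation.** At least 3 probes within TSS ± 1,500 bp are
  required; the call is the mean beta. When the locus is copy-neutral the
  call is labelled "consistent with biallelic hypermethylation", mirroring
  how a hypermethylated promoter with no gene-dose change implies both
  alleles are affected.
- **Pathway expansion.** For carriers without a same-gene hit, partner
  genes from a user-supplied interaction table are searched with the SNV
  rule; results are labelled `level = "pathway"` and never upgrade the
  same-gene verdict.
- **TMB.** Somatic variants with depth ≥ 10, VAF ≥ 0.05 and population
  frequency ≤ 0.1% are counted and divided by 3,000 Mb; burden strictly
  above 10/Mb is TMB-high. Depth/VAF gates are inclusive ("minimal depth
  10" reads as ≥ 10); the VAF filter for second-hit *evidence* is strict
  (">5%") — the two thresholds serve different sentences in the protocol
  and are configured independently.

A case without tumor tissue yields a verdict that is not assessable
(`informative = FALSE`), stays in the carrier denominator of the
second-hit rate, and is flagged.

## Cohort report

Detection rates are reported with numerator and denominator, whole-cohort
and excluding benign tumors (both numerator and denominator restricted).
The diagnosis-category table uses eight histopathological categories; an
unmapped diagnosis is an error, never a silent "other", because the
category definitions are conventions that must be owned by the analyst.
Percentages print as whole percent, rounded half away from zero, matching
the conventional table style. Odds ratios are `(ad)/(bc)` with the log-OR
normal-approximation CI; zero cells get the Haldane–Anscombe 0.5
correction and a flag. The age comparison is Student's pooled-variance
two-sample t-test (a Welch option exists but is off by default, since the
pooled test is what "Student's t-test" names).

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 312 cases, 8% carrying
one dominant het pathogenic first hit in a panel gene, and 11/24 of
carriers carrying one planted second hit whose class is drawn from a
configurable mix (SNV at VAF 0.3, focal deletion, copy-neutral LOH,
expression at the exact cohort minimum — planted as 0 FPKM, which is the
guaranteed minimum under any percentile definition — or promoter beta
~0.9). Non-carriers receive only decoys, at least one per case: common
variants (AF ≥ 0.01), multi-submitter ClinVar-benign variants, high
local-count synonymous variants, single-submitter benign variants with
high local counts, off-panel variants, non-coding variants, and rare
benign missense variants that legitimately survive to VUS. A truth table
records every plant, and the same seed reproduces the cohort exactly
(the generator saves and restores the caller's RNG state).

Deliberate modelling choices:

- Coordinates live on a miniature synthetic genome (eight 30 Mb
  chromosomes, `synthetic_gene_map()`); no reference genome is shipped or
  needed at desk scale.
- Expression is per-gene log-normal (gene means from N(3, 1) on the log
  scale, spread 0.5); promoter betas are Beta(1, 12) at baseline
  (unmethylated). Carriers without a planted expression hit have their
  first-hit gene held at the gene's distribution median, because their
  truth is "expression normal" and the percentile rule would otherwise
  flag ~10% of them by construction of a cohort percentile.
- Somatic passengers (Poisson, mean 20/case) are placed in dedicated
  background genes, never in first-hit genes, so the truth table's "no
  second hit" is exact.

What the simulator does **not** model — and therefore what passing tests
do not show about real data: sequencing noise and coverage bias, subclonal
VAF distributions, mutational signatures, realistic linkage between
variants, germline CNVs, tumor purity below 100%, and annotation errors.
The simulator validates the *logic* of the rules, not their clinical
sensitivity.

## Fixtures from the published tables

The package ships the published 24-carrier findings table and the
8-category cohort breakdown as plain-TSV fixtures. `fixture_cohort()`
expands them into machine-runnable inputs: germline records on the
synthetic gene map, evidence bundles constructed so the engine reproduces
the printed second-hit column (somatic SNVs at VAF 0.35–0.4 for printed
SNV hits, copy-1 segments with allelic imbalance for printed deletions,
nothing for printed negatives, a no-tumor-tissue flag for the one case
without tumor material), and 288 non-carrier filler cases matching the
printed category counts. These bundles are reconstructions sufficient to
reproduce the printed verdicts — not patient data. Per-case diagnosis
categories for the 24 carriers are assigned consistently with the printed
column sums (the publication does not print them per case), and filler
sex/age values are synthetic: group-level statistics over them are
exercised for correctness of the code path, not for reproduction of
unpublished values.

## Problem sizes and determinism

The test suite validates the rule engine on an exhaustive 3×3×3 annotation
grid plus 10,000 random tuples against brute-force predicates; the
percentile rule on 1,000 random cohorts of 20–400 samples against a
sort-based oracle; and planted-hit recovery on 20 simulated cohorts of
n = 312 (100% recovery, zero false hits in null genes). Analysis stages
contain no randomness; byte-identical inputs give byte-identical outputs,
which the run manifest records as an md5 digest of the verdict table.

## Known limitations

- ACMG/AMP classification and per-case actionability are inputs, not
  computations; the pipeline audits and applies them.
- Compound heterozygosity is declared without phasing.
- The structural-variant layer matches on gene annotation/overlap only; no
  breakpoint reasoning.
- MSI / mutational-signature evidence is out of scope; indirect
  second-hit signs (e.g. immunohistochemistry) can only enter as external
  annotations.
- The genome build is carried as an opaque label and never verified
  against sequence.
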