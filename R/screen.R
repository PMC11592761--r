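#' Attach side-table annotations to germline records
#'
#' ClinVar-style assertions and local-database counts may arrive embedded in
#' the record tibble (columns `clinvar_classification`,
#' `clinvar_blb_submitters`, `clinvar_cancer_assoc`, `local_count`) or as
#' side tables joined on the variant key; side tables win on conflict.
#' Variants absent from the tables get the neutral annotation (no ClinVar
#' report, zero submitters, zero local occurrences).
#'
#' @param records Germline record tibble ([read_germline_vcf()]).
#' @param clinvar Optional assertion tibble ([read_clinvar()]).
#' @param local_db Optional count tibble ([read_local_db()]).
#' @return The record tibble with the four annotation columns guaranteed.
#' @export
annotate_records <- function(records, clinvar = NULL, local_db = NULL) {
  out <- records
  if (!"clinvar_classification" %in% names(out)) out$clinvar_classification <- "none"
  if (!"clinvar_blb_submitters" %in% names(out)) out$clinvar_blb_submitters <- 0L
  if (!"clinvar_cancer_assoc" %in% names(out)) out$clinvar_cancer_assoc <- FALSE
  if (!"local_count" %in% names(out)) out$local_count <- 0L
  if (!is.null(clinvar) && nrow(out)) {
    cv <- dplyr::select(clinvar, "key",
                        cv_class = "classification",
                        cv_blb = "blb_submitters",
                        cv_assoc = "cancer_syndrome_assoc")
    out <- out %>%
      dplyr::left_join(cv, by = "key") %>%
      dplyr::mutate(
        clinvar_classification = dplyr::coalesce(.data$cv_class, .data$clinvar_classification),
        clinvar_blb_submitters = dplyr::coalesce(.data$cv_blb, .data$clinvar_blb_submitters),
        clinvar_cancer_assoc = dplyr::coalesce(.data$cv_assoc, .data$clinvar_cancer_assoc)
      ) %>%
      dplyr::select(-"cv_class", -"cv_blb", -"cv_assoc")
  }
  if (!is.null(local_db) && nrow(out)) {
    db <- dplyr::select(local_db, "key", db_count = "occurrence_count")
    out <- out %>%
      dplyr::left_join(db, by = "key") %>%
      dplyr::mutate(local_count = dplyr::coalesce(.data$db_count, .data$local_count)) %>%
      dplyr::select(-"db_count")
  }
  out
}

exonic_or_splicing <- c("missense", "nonsense", "frameshift", "splice_site",
                        "synonymous", "other_exonic")
truncating_classes <- c("nonsense", "frameshift", "splice_site")

#' Panel, coding and population-frequency gates
#'
#' A germline variant survives iff its gene is on the panel, its consequence
#' is exonic or splicing, and its population allele frequency is strictly
#' below `config$af_max` (default 0.01). A missing frequency is compared as
#' 0 and survives the gate (a variant absent from the population reference
#' is rare by construction). Gates are applied in the documented order
#' panel, coding, frequency and the first failing gate is recorded.
#'
#' @param records Annotated germline record tibble.
#' @param panel A [gene_panel()].
#' @param config A [threshold_config()] (or `NULL` for defaults).
#' @return `records` with a `status` column: `excluded_panel`,
#'   `excluded_noncoding`, `excluded_frequency` or `pass`.
#' @export
prefilter <- function(records, panel, config = NULL) {
  config <- as_threshold_config(config)
  in_panel <- !is.na(records$gene) & toupper(records$gene) %in% as.character(panel)
  coding <- records$consequence %in% exonic_or_splicing
  af <- dplyr::coalesce(records$population_af, 0)
  dplyr::mutate(records, status = dplyr::case_when(
    !in_panel ~ "excluded_panel",
    !coding ~ "excluded_noncoding",
    af >= config$af_max ~ "excluded_frequency",
    TRUE ~ "pass"
  ))
}

#' Benign-evidence exclusion rules A, B and C
#'
#' Variants surviving the prefilter are excluded when
#' A) reported benign or likely benign in the ClinVar-style table by more
#' than `clinvar_benign_submitters_max` submitters (default more than 2), or
#' B) synonymous and seen more than `local_count_synonymous_max` times
#' (default more than 100) in the local variant database, or
#' C) reported benign/likely benign by exactly one submitter and seen more
#' than `local_count_single_submitter_max` times (default more than 80)
#' locally. Rules are evaluated in the fixed order A, B, C and the first
#' firing rule is recorded, so exclusion provenance is deterministic.
#'
#' @param records Annotated tibble with `clinvar_blb_submitters`,
#'   `local_count`, `consequence` columns (rows with `status != "pass"` are
#'   passed through untouched if a `status` column is present).
#' @param config A [threshold_config()].
#' @return `records` with `status` set to `excluded_rule_A`,
#'   `excluded_rule_B`, `excluded_rule_C` or `keep` for evaluated rows.
#' @export
apply_exclusion_rules <- function(records, config = NULL) {
  config <- as_threshold_config(config)
  if (!"status" %in% names(records)) records$status <- "pass"
  eligible <- records$status == "pass"
  verdict <- dplyr::case_when(
    records$clinvar_blb_submitters > config$clinvar_benign_submitters_max ~ "excluded_rule_A",
    records$consequence == "synonymous" &
      records$local_count > config$local_count_synonymous_max ~ "excluded_rule_B",
    records$clinvar_blb_submitters == 1L &
      records$local_count > config$local_count_single_submitter_max ~ "excluded_rule_C",
    TRUE ~ "keep"
  )
  dplyr::mutate(records, status = ifelse(eligible, verdict, .data$status))
}

join_knowledge <- function(records, knowledge, warn_genes = NULL) {
  genes <- unique(stats::na.omit(if (is.null(warn_genes)) records$gene else warn_genes))
  missing <- setdiff(toupper(genes), toupper(knowledge$gene))
  if (length(missing)) {
    warning("genes absent from knowledge table, default row used: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  all_missing <- setdiff(toupper(unique(stats::na.omit(records$gene))), toupper(knowledge$gene))
  if (length(all_missing)) {
    knowledge <- dplyr::bind_rows(knowledge, default_knowledge_row(all_missing))
  }
  dplyr::left_join(records, knowledge, by = "gene")
}

#' Triage surviving variants into VUS / likely pathogenic / pathogenic
#'
#' Missense variants with no reported cancer-syndrome association are
#' variants of unknown significance. Potentially truncating variants
#' (nonsense, frameshift, splice site) are VUS when the gene has no
#' association to the patient's phenotype or truncation is not the known
#' disease mechanism for the gene. Synonymous variants are always VUS.
#' Otherwise the classification is taken from the per-variant assertion
#' (the ClinVar-style table doubles as the channel for expert ACMG/AMP
#' assessments, which can be supplied per variant); an assertion that is
#' not pathogenic/likely pathogenic falls back to VUS.
#'
#' Phenotype association defaults to "the gene has any cancer-syndrome
#' association in the knowledge table" and can be overridden per record
#' through a logical `phenotype_match` column.
#'
#' @param records Tibble of variants with `status == "keep"` (others pass
#'   through unchanged).
#' @param knowledge Knowledge tibble ([read_knowledge()]).
#' @return `records` with `status` replaced by `vus`, `likely_pathogenic`
#'   or `pathogenic` for triaged rows.
#' @export
triage_variants <- function(records, knowledge) {
  if (!nrow(records)) return(dplyr::mutate(records, status = character(0)))
  if (!"status" %in% names(records)) records$status <- "keep"
  kn_cols <- c("syndrome", "inheritance", "truncation_is_mechanism",
               "mesenchymal_association", "surveillance_exists")
  joined <- join_knowledge(dplyr::select(records, -dplyr::any_of(kn_cols)), knowledge,
                           warn_genes = records$gene[records$status == "keep"])
  phenotype_match <- if ("phenotype_match" %in% names(records)) {
    dplyr::coalesce(records$phenotype_match, joined$syndrome != "none")
  } else {
    joined$syndrome != "none"
  }
  truncating <- joined$consequence %in% truncating_classes
  asserted <- ifelse(joined$clinvar_classification %in% c("pathogenic", "likely_pathogenic"),
                     joined$clinvar_classification, "vus")
  verdict <- dplyr::case_when(
    joined$consequence == "synonymous" ~ "vus",
    joined$consequence == "missense" & !joined$clinvar_cancer_assoc ~ "vus",
    truncating & (!phenotype_match | !joined$truncation_is_mechanism) ~ "vus",
    TRUE ~ asserted
  )
  dplyr::mutate(joined, status = ifelse(.data$status == "keep", verdict, .data$status))
}

#' Reportability by inheritance mode
#'
#' Pathogenic or likely pathogenic variants are reportable when
#' heterozygous or homozygous in a dominant-disorder gene, or, for
#' recessive-disorder genes, when homozygous or when at least two distinct
#' het P/LP variants hit the same gene in the same case (declared a
#' potential compound heterozygote without phasing and flagged as such).
#' A single het P/LP variant in a recessive gene is a carrier finding and
#' not reportable. Genes with unknown inheritance are treated as dominant.
#'
#' @param results Triaged tibble (after [triage_variants()]), carrying an
#'   `inheritance` column from the knowledge join.
#' @param knowledge Knowledge tibble, used when `results` lacks the
#'   `inheritance` column.
#' @return `results` with logical `reportable` and `compound_het_unphased`
#'   columns.
#' @export
reportability <- function(results, knowledge = NULL) {
  if (!nrow(results)) {
    return(dplyr::mutate(results, reportable = logical(0), compound_het_unphased = logical(0)))
  }
  if (!"inheritance" %in% names(results)) {
    stopifnot(!is.null(knowledge))
    results <- join_knowledge(results, knowledge)
  }
  results %>%
    dplyr::group_by(.data$case_id, .data$gene) %>%
    dplyr::mutate(
      is_plp = .data$status %in% c("pathogenic", "likely_pathogenic"),
      n_plp_het = sum(.data$is_plp & .data$genotype == "het"),
      reportable = .data$is_plp & (
        .data$inheritance %in% c("dominant", "unknown") |
          .data$genotype == "hom" |
          .data$n_plp_het >= 2
      ),
      compound_het_unphased = .data$reportable & .data$inheritance == "recessive" &
        .data$genotype == "het" & .data$n_plp_het >= 2
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"is_plp", -"n_plp_het")
}

#' Expectation label for the somatic second-hit search
#'
#' Genes with a known or previously suggested association to mesenchymal
#' tumors are labelled "second hit expected"; Lynch-syndrome genes carry a
#' "semi expected" label; genes with no known association are "second hit
#' not expected".
#'
#' @param gene Character vector of gene symbols.
#' @param knowledge Knowledge tibble.
#' @return Character vector of labels.
#' @export
label_expectation <- function(gene, knowledge) {
  assoc <- knowledge$mesenchymal_association[match(toupper(gene), toupper(knowledge$gene))]
  assoc[is.na(assoc)] <- "none"
  dplyr::case_when(
    assoc %in% c("known", "suggested") ~ "second_hit_expected",
    assoc == "semi" ~ "semi_expected",
    TRUE ~ "second_hit_not_expected"
  )
}

#' Screen a germline variant set end to end
#'
#' Runs the full germline triage: annotation joins, panel/coding/frequency
#' gates, benign-evidence exclusion rules A/B/C, VUS triage, reportability
#' by inheritance mode, actionability and second-hit expectation labels.
#'
#' Actionability for reportable findings defaults to `clinical_action` when
#' the knowledge table records an existing surveillance program for the
#' gene's syndrome and `risk_factor` otherwise; because that decision is a
#' clinical judgement on genotype plus phenotype, a per-record
#' `assessment_override` column (values `clinical_action` / `risk_factor`)
#' takes precedence when present. Non-reportable variants get `none`.
#'
#' @param records Germline record tibble (all cases concatenated is fine).
#' @param panel A [gene_panel()].
#' @param knowledge Knowledge tibble ([read_knowledge()]).
#' @param clinvar,local_db Optional annotation side tables.
#' @param config A [threshold_config()] or `NULL`.
#' @return A `germline_screen` object: list with `variants` (one row per
#'   variant with `status`, `reportable`, `actionability`, `expectation`),
#'   `reportable` (the reportable subset), `funnel` (per-status counts) and
#'   the `config` used.
#' @examples
#' rec <- tibble::tibble(
#'   case_id = "case1", chrom = "chr22", pos = 1000L, start = 999L,
#'   end = 1000L, ref = "C", alt = "T", key = "chr22:1000:C:T",
#'   gene = "CHEK2", consequence = "frameshift", genotype = "het",
#'   population_af = 0.002, clinvar_classification = "pathogenic",
#'   clinvar_blb_submitters = 0L, clinvar_cancer_assoc = TRUE,
#'   local_count = 3L
#' )
#' kn <- tibble::tibble(gene = "CHEK2", syndrome = "CHEK2-related cancer risk",
#'   inheritance = "dominant", truncation_is_mechanism = TRUE,
#'   mesenchymal_association = "none", surveillance_exists = TRUE)
#' scr <- screen_germline(rec, gene_panel("CHEK2"), kn)
#' scr$variants$status
#' @export
screen_germline <- function(records, panel, knowledge, clinvar = NULL,
                            local_db = NULL, config = NULL) {
  config <- as_threshold_config(config)
  ann <- annotate_records(records, clinvar, local_db)
  res <- ann %>%
    prefilter(panel, config) %>%
    apply_exclusion_rules(config) %>%
    triage_variants(knowledge) %>%
    reportability()
  res <- res %>%
    dplyr::mutate(
      actionability = dplyr::case_when(
        !.data$reportable ~ "none",
        TRUE ~ dplyr::coalesce(
          if ("assessment_override" %in% names(res)) .data$assessment_override else NA_character_,
          ifelse(.data$surveillance_exists, "clinical_action", "risk_factor")
        )
      ),
      expectation = label_expectation(.data$gene, knowledge)
    ) %>%
    dplyr::arrange(.data$case_id, .data$chrom, .data$pos, .data$ref, .data$alt)
  funnel <- res %>% dplyr::count(.data$status, name = "n") %>% dplyr::arrange(.data$status)
  structure(list(
    variants = res,
    reportable = dplyr::filter(res, .data$reportable),
    funnel = funnel,
    config = config
  ), class = "germline_screen")
}

#' @export
print.germline_screen <- function(x, ...) {
  cat(sprintf("<germline_screen> %d variants, %d reportable in %d cases\n",
              nrow(x$variants), nrow(x$reportable),
              dplyr::n_distinct(x$reportable$case_id)))
  print(x$funnel)
  invisible(x)
}
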