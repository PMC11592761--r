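protein_altering <- c("missense", "nonsense", "frameshift", "splice_site", "other_exonic")

#' Construct second-hit evidence rows
#'
#' Evidence tibbles are the common currency of the second-hit layers; the
#' constructors are exported so that custom evidence (e.g. externally
#' curated findings) can be fed to [integrate_verdict()].
#'
#' @return `empty_evidence()`: a zero-row evidence tibble with the full
#'   column set.
#' @export
empty_evidence <- function() {
  tibble::tibble(
    case_id = character(), gene = character(), kind = character(),
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    vaf = double(), copy_number = double(), percentile = double(),
    mean_beta = double(), detail = character(), level = character()
  )
}

#' @rdname empty_evidence
#' @param case_id,gene,kind,chrom,pos,ref,alt,vaf,copy_number,percentile,mean_beta,detail,level
#'   Evidence fields; `kind` is one of the documented evidence kinds and
#'   `level` is `"gene"` or `"pathway"`.
#' @export
evidence_row <- function(case_id, gene, kind, chrom = NA_character_,
                         pos = NA_integer_, ref = NA_character_,
                         alt = NA_character_, vaf = NA_real_,
                         copy_number = NA_real_, percentile = NA_real_,
                         mean_beta = NA_real_, detail = NA_character_,
                         level = "gene") {
  tibble::tibble(case_id = case_id, gene = gene, kind = kind, chrom = chrom,
                 pos = pos, ref = ref, alt = alt, vaf = vaf,
                 copy_number = copy_number, percentile = percentile,
                 mean_beta = mean_beta, detail = detail, level = level)
}

#' Somatic small-variant second hits in one gene
#'
#' Returns the protein-altering or splice somatic variants in the gene with
#' a variant allele frequency strictly above `config$snv_vaf_min`
#' (default 5%), sorted by VAF descending.
#'
#' @param somatic Somatic record tibble ([read_somatic_vcf()]).
#' @param gene Gene symbol.
#' @param config A [threshold_config()].
#' @param case_id Case identifier stamped on the evidence (defaults to the
#'   record's own case id).
#' @return Evidence tibble (possibly empty) of kind `snv_or_indel`.
#' @export
find_snv_hit <- function(somatic, gene, config = NULL, case_id = NULL) {
  config <- as_threshold_config(config)
  hits <- somatic %>%
    dplyr::filter(!is.na(.data$gene), toupper(.data$gene) == toupper(!!gene),
                  .data$consequence %in% protein_altering,
                  .data$vaf > config$snv_vaf_min) %>%
    dplyr::arrange(dplyr::desc(.data$vaf))
  if (!nrow(hits)) return(empty_evidence())
  evidence_row(
    case_id = if (is.null(case_id)) hits$case_id else case_id,
    gene = gene, kind = "snv_or_indel", chrom = hits$chrom, pos = hits$pos,
    ref = hits$ref, alt = hits$alt, vaf = hits$vaf,
    detail = paste0("somatic ", hits$consequence, " VAF ", signif(hits$vaf, 3))
  )
}

#' Structural-variant second hits in one gene
#'
#' SVs whose interval overlaps the gene (or that are annotated to it) with
#' VAF strictly above `config$sv_vaf_min` (default 10%).
#'
#' @param sv SV tibble ([read_sv_vcf()]).
#' @inheritParams find_snv_hit
#' @return Evidence tibble of kind `structural_variant`.
#' @export
find_sv_hit <- function(sv, gene, config = NULL, case_id = NULL) {
  config <- as_threshold_config(config)
  hits <- sv %>%
    dplyr::filter(!is.na(.data$gene), toupper(.data$gene) == toupper(!!gene),
                  !is.na(.data$vaf), .data$vaf > config$sv_vaf_min)
  if (!nrow(hits)) return(empty_evidence())
  evidence_row(
    case_id = if (is.null(case_id)) hits$case_id else case_id,
    gene = gene, kind = "structural_variant", chrom = hits$chrom,
    pos = hits$start + 1L, vaf = hits$vaf,
    detail = paste0(hits$svtype, " VAF ", signif(hits$vaf, 3))
  )
}

#' Chromothripsis-like copy-number profile on one chromosome
#'
#' Operationalized as the number of copy-number state switches between
#' consecutive segments reaching `config$chromothripsis_min_switches`
#' (default 10). States are total copy numbers rounded to the nearest
#' integer; the heuristic only ever withholds second-hit evidence, it never
#' creates any.
#'
#' @param segments Segment tibble for one chromosome (any extra chromosomes
#'   are a usage error).
#' @param config A [threshold_config()].
#' @return `TRUE` when the profile is chromothripsis-like.
#' @export
chromothripsis_like <- function(segments, config = NULL) {
  config <- as_threshold_config(config)
  if (nrow(segments) == 0) return(FALSE)
  if (dplyr::n_distinct(segments$chrom) > 1) {
    stop("chromothripsis_like() expects segments of a single chromosome", call. = FALSE)
  }
  state <- round(segments$total_cn[order(segments$start)])
  switches <- sum(diff(state) != 0)
  switches >= config$chromothripsis_min_switches
}

#' Copy-number / LOH assessment of a gene locus
#'
#' Classifies the copy-number segments overlapping the gene: total copy
#' number strictly below the case ploidy together with allelic imbalance
#' is a focal deletion; copy-neutral allelic imbalance (within
#' `config$cn_neutral_tol` of ploidy) is LOH. Segments longer than
#' `config$large_deletion_mb` megabases and chromosomes with a
#' chromothripsis-like profile are uninformative for second-hit
#' attribution. When the germline variant's allele fraction in the tumor is
#' supplied, a fraction above 0.5 is reported as retention of the
#' alternative (variant) allele.
#'
#' @param segments Segment tibble for the case (one sample).
#' @param gene_interval One-row tibble/list with `gene`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param tumor_af Allele fraction of the germline variant in the tumor, or
#'   `NA` when not measured.
#' @param ploidy Case average copy number (default 2).
#' @param config A [threshold_config()].
#' @param case_id Case identifier for the evidence rows.
#' @return Evidence tibble with one row of kind `focal_deletion`, `loh`,
#'   `none`, `no_data`, `uninformative_large_deletion` or
#'   `uninformative_chromothripsis`.
#' @export
assess_cn_loh <- function(segments, gene_interval, tumor_af = NA_real_,
                          ploidy = 2, config = NULL, case_id = "sample") {
  config <- as_threshold_config(config)
  gi <- tibble::as_tibble(gene_interval)
  ov <- segments %>%
    dplyr::filter(.data$chrom == gi$chrom, .data$start < gi$end, .data$end > gi$start)
  if (!nrow(ov)) {
    return(evidence_row(case_id, gi$gene, "no_data", chrom = gi$chrom,
                        detail = "gene locus not covered by any segment"))
  }
  chrom_segs <- dplyr::filter(segments, .data$chrom == gi$chrom)
  if (chromothripsis_like(chrom_segs, config)) {
    return(evidence_row(case_id, gi$gene, "uninformative_chromothripsis",
                        chrom = gi$chrom,
                        detail = "chromothripsis-like profile on chromosome"))
  }
  aberrant <- ov$allelic_imbalance | abs(ov$total_cn - ploidy) > config$cn_neutral_tol
  if (any(aberrant & ov$end - ov$start > config$large_deletion_mb * 1e6)) {
    return(evidence_row(case_id, gi$gene, "uninformative_large_deletion",
                        chrom = gi$chrom,
                        detail = sprintf("non-focal aberrant segment > %g Mb", config$large_deletion_mb)))
  }
  retention <- if (!is.na(tumor_af) && tumor_af > 0.5) {
    "; alternative allele retained"
  } else if (!is.na(tumor_af)) {
    "; reference allele retained"
  } else ""
  # the most aberrant overlapping segment drives the call
  cn <- ov$total_cn[which.min(ov$total_cn)]
  imb <- any(ov$allelic_imbalance)
  if (cn < ploidy - config$cn_neutral_tol && imb) {
    return(evidence_row(case_id, gi$gene, "focal_deletion", chrom = gi$chrom,
                        copy_number = cn,
                        detail = paste0("copy number ", signif(cn, 3), " below ploidy ",
                                        signif(ploidy, 3), " with allelic imbalance", retention)))
  }
  if (abs(cn - ploidy) <= config$cn_neutral_tol && imb) {
    return(evidence_row(case_id, gi$gene, "loh", chrom = gi$chrom,
                        copy_number = cn,
                        detail = paste0("copy-neutral allelic imbalance", retention)))
  }
  evidence_row(case_id, gi$gene, "none", chrom = gi$chrom, copy_number = cn,
               detail = "no copy loss or imbalance at locus")
}

nearest_rank_index <- function(p, n) {
  as.integer(ceiling(p / 100 * n))
}

#' Expression-outlier second hit (cohort percentile rule)
#'
#' Ranks the sample's FPKM for the gene within the whole cohort. Values at
#' or below the lower `expr_tail_percent`-th percentile are aberrantly low,
#' values at or above the upper percentile aberrantly high. Percentiles use
#' the nearest-rank definition on the sorted cohort vector (lower cut is
#' the `ceiling(p/100 * n)`-th smallest value, upper cut symmetric from the
#' top); ties are included in the tail. Cohorts smaller than
#' `config$min_expression_cohort` yield a "no data" call.
#'
#' @param expression An `expression_matrix` ([read_expression()]).
#' @param gene Gene symbol.
#' @param sample Sample/case identifier (a column of the matrix).
#' @return Evidence tibble with one row of kind `expression_low`,
#'   `expression_high`, `none` or `no_data`; `percentile` records the
#'   sample's percentile rank.
#' @inheritParams find_snv_hit
#' @export
expression_aberrant <- function(expression, gene, sample, config = NULL) {
  config <- as_threshold_config(config)
  samples <- setdiff(names(expression), "gene")
  if (!sample %in% samples) stop("sample '", sample, "' absent from expression matrix", call. = FALSE)
  row <- which(expression$gene == gene)
  if (!length(row)) {
    return(evidence_row(sample, gene, "no_data", detail = "gene absent from expression matrix"))
  }
  vals <- as.numeric(unlist(expression[row[1], samples]))
  n <- length(vals)
  if (n < config$min_expression_cohort) {
    return(evidence_row(sample, gene, "no_data",
                        detail = sprintf("cohort of %d below minimum %d", n,
                                         config$min_expression_cohort)))
  }
  x <- vals[match(sample, samples)]
  sorted <- sort(vals)
  lo_cut <- sorted[nearest_rank_index(config$expr_tail_percent, n)]
  hi_cut <- sorted[n - nearest_rank_index(config$expr_tail_percent, n) + 1L]
  pct <- 100 * sum(vals <= x) / n
  if (x <= lo_cut) {
    return(evidence_row(sample, gene, "expression_low", percentile = pct,
                        detail = sprintf("FPKM %.3g at percentile %.1f (bottom %g%%)",
                                         x, pct, config$expr_tail_percent)))
  }
  if (x >= hi_cut) {
    return(evidence_row(sample, gene, "expression_high", percentile = pct,
                        detail = sprintf("FPKM %.3g at percentile %.1f (top %g%%)",
                                         x, pct, config$expr_tail_percent)))
  }
  evidence_row(sample, gene, "none", percentile = pct,
               detail = "expression within cohort range")
}

#' Promoter hypermethylation second hit
#'
#' Aggregates beta values over methylation probes within the promoter
#' window (TSS +/- `config$promoter_window_bp`, default 1500 bp) for the
#' gene and sample. A mean beta at or above
#' `config$hypermethylation_beta_min` (default 0.6) is a hypermethylation
#' call; fewer than `config$min_promoter_probes` probes yields "no data".
#' When the gene locus is copy-neutral in the supplied segments the call is
#' labelled consistent with biallelic promoter hypermethylation (no copy
#' loss to explain the signal on one allele only).
#'
#' @param methylation Methylation tibble ([read_methylation()]).
#' @param gene Gene symbol.
#' @param sample Sample identifier.
#' @param segments Optional segment tibble for the case, used with
#'   `gene_interval` for the biallelic-consistency label.
#' @param gene_interval Optional one-row gene interval.
#' @param ploidy Case ploidy for the copy-neutrality check.
#' @param config A [threshold_config()].
#' @return Evidence tibble with one row of kind
#'   `promoter_hypermethylation`, `none` or `no_data`.
#' @export
methylation_hit <- function(methylation, gene, sample, segments = NULL,
                            gene_interval = NULL, ploidy = 2, config = NULL) {
  config <- as_threshold_config(config)
  probes <- methylation %>%
    dplyr::filter(.data$gene == !!gene, .data$sample == !!sample,
                  abs(.data$dist_tss) <= config$promoter_window_bp)
  if (nrow(probes) < config$min_promoter_probes) {
    return(evidence_row(sample, gene, "no_data",
                        detail = sprintf("%d promoter probes, need >= %d",
                                         nrow(probes), config$min_promoter_probes)))
  }
  mb <- mean(probes$beta)
  if (mb < config$hypermethylation_beta_min) {
    return(evidence_row(sample, gene, "none", mean_beta = mb,
                        detail = sprintf("mean promoter beta %.2f below %.2f",
                                         mb, config$hypermethylation_beta_min)))
  }
  biallelic <- NA
  if (!is.null(segments) && !is.null(gene_interval)) {
    cn_call <- assess_cn_loh(segments, gene_interval, ploidy = ploidy,
                             config = config, case_id = sample)
    biallelic <- cn_call$kind %in% c("none", "loh")
  }
  detail <- sprintf("mean promoter beta %.2f over %d probes", mb, nrow(probes))
  if (isTRUE(biallelic)) detail <- paste0(detail, "; copy-neutral locus, consistent with biallelic hypermethylation")
  evidence_row(sample, gene, "promoter_hypermethylation", mean_beta = mb, detail = detail)
}

#' Pathway-level expansion of the second-hit search
#'
#' For a germline gene without a confirmed same-gene second hit, searches
#' the genes whose products are associated with it (interaction table) for
#' qualifying somatic small variants. Pathway evidence is labelled
#' `level = "pathway"` and never upgrades the same-gene verdict.
#'
#' @param gene Germline gene symbol.
#' @param interactions Interaction tibble ([read_interactions()]).
#' @param somatic Somatic record tibble for the case.
#' @param config A [threshold_config()].
#' @param case_id Case identifier.
#' @return Evidence tibble of pathway-level hits (possibly empty).
#' @export
pathway_expansion <- function(gene, interactions, somatic, config = NULL,
                              case_id = "sample") {
  config <- as_threshold_config(config)
  partners <- interactions$partner[toupper(interactions$gene) == toupper(gene)]
  if (!length(partners)) {
    if (!toupper(gene) %in% toupper(interactions$gene)) {
      warning("gene '", gene, "' absent from interaction table", call. = FALSE)
    }
    return(empty_evidence())
  }
  purrr::map(partners, function(p) {
    ev <- find_snv_hit(somatic, p, config, case_id = case_id)
    if (nrow(ev)) dplyr::mutate(ev, level = "pathway",
                                detail = paste0(.data$detail, " (pathway partner of ", gene, ")"))
    else ev
  }) %>% dplyr::bind_rows()
}

#' Tumor mutational burden
#'
#' Counts somatic variants passing quality control (read depth at least
#' `tmb_min_depth`, VAF at least `tmb_min_af`, population frequency at most
#' `tmb_max_gnomad`; missing population frequency counts as 0) and divides
#' by `tmb_genome_mb` megabases (default 3000). A burden strictly above
#' `tmb_high` variants/Mb (default 10) is flagged TMB-high.
#'
#' @param somatic Somatic record tibble with `depth`, `vaf`,
#'   `population_af`.
#' @param config A [threshold_config()].
#' @return A one-row tibble with `n_passing`, `tmb` (variants/Mb) and
#'   `tmb_high`.
#' @examples
#' compute_tmb(tibble::tibble(depth = rep(50L, 30), vaf = 0.3,
#'                            population_af = 0))$tmb  # 0.01
#' @export
compute_tmb <- function(somatic, config = NULL) {
  config <- as_threshold_config(config)
  passing <- sum(
    somatic$depth >= config$tmb_min_depth &
      somatic$vaf >= config$tmb_min_af &
      dplyr::coalesce(somatic$population_af, 0) <= config$tmb_max_gnomad
  )
  tmb <- passing / config$tmb_genome_mb
  tibble::tibble(n_passing = passing, tmb = tmb, tmb_high = tmb > config$tmb_high)
}

hit_kinds <- c("snv_or_indel", "focal_deletion", "loh", "structural_variant",
               "expression_low", "expression_high", "promoter_hypermethylation")
uninformative_kinds <- c("uninformative_chromothripsis", "uninformative_large_deletion")
evidence_priority <- c("snv_or_indel", "focal_deletion", "loh", "structural_variant",
                       "expression_low", "expression_high",
                       "promoter_hypermethylation", uninformative_kinds,
                       "none", "no_data")

#' Integrate all evidence layers into a per-(case, gene) verdict
#'
#' A hit is found when any gene-level evidence of kind SNV/indel, focal
#' deletion, LOH, structural variant, expression outlier or promoter
#' hypermethylation is present. When the only copy-number finding is
#' uninformative (chromothripsis-like profile or a large deletion) and no
#' other layer found a hit, the verdict is marked uninformative rather than
#' negative. The narrative lists evidence in the fixed priority order
#' SNV, deletion, LOH, SV, expression, methylation.
#'
#' @param case_id,gene Identifiers of the verdict.
#' @param evidence Evidence tibble accumulated over all layers (rows of
#'   kind `none`/`no_data` are permitted and ignored for hit finding).
#' @param expectation The second-hit expectation label from the germline
#'   screen (`second_hit_expected`, `semi_expected`,
#'   `second_hit_not_expected`), or `NA`.
#' @param no_tumor_tissue Set `TRUE` when no tumor tissue was available;
#'   the verdict is then `NA`-like: no hit, marked not assessable.
#' @return A one-row tibble: `case_id`, `gene`, `hit_found`, `informative`,
#'   `n_evidence`, `evidence_kinds`, `expectation`, `narrative`.
#' @export
integrate_verdict <- function(case_id, gene, evidence, expectation = NA_character_,
                              no_tumor_tissue = FALSE) {
  ev <- if (is.null(evidence) || !nrow(evidence)) empty_evidence() else evidence
  gene_ev <- dplyr::filter(ev, .data$level == "gene")
  hits <- dplyr::filter(gene_ev, .data$kind %in% hit_kinds)
  uninf <- dplyr::filter(gene_ev, .data$kind %in% uninformative_kinds)
  if (no_tumor_tissue) {
    return(tibble::tibble(
      case_id = case_id, gene = gene, hit_found = FALSE, informative = FALSE,
      n_evidence = 0L, evidence_kinds = "", expectation = expectation,
      narrative = "not assessable: no tumor tissue available"
    ))
  }
  hit_found <- nrow(hits) > 0
  informative <- hit_found || nrow(uninf) == 0
  ordered <- hits %>%
    dplyr::mutate(.prio = match(.data$kind, evidence_priority)) %>%
    dplyr::arrange(.data$.prio)
  narrative <- if (hit_found) {
    paste(paste0(ordered$kind, ": ", ordered$detail), collapse = " | ")
  } else if (!informative) {
    paste("uninformative:", paste(unique(uninf$detail), collapse = " | "))
  } else {
    "no second hit"
  }
  tibble::tibble(
    case_id = case_id, gene = gene, hit_found = hit_found,
    informative = informative, n_evidence = nrow(hits),
    evidence_kinds = paste(unique(ordered$kind), collapse = ","),
    expectation = expectation, narrative = narrative
  )
}

#' Run the full second-hit search for a set of screened cases
#'
#' For every reportable (case, gene) pair from the germline screen, runs
#' all available evidence layers over the case's tumor data: somatic
#' SNV/indels, structural variants, copy-number/LOH, cohort expression
#' percentile and promoter methylation, then integrates a verdict. Missing
#' data layers degrade gracefully (that layer reports no data). Pathway
#' expansion is applied to cases without a same-gene hit when an
#' interaction table is supplied.
#'
#' @param screened A `germline_screen` object or a tibble of reportable
#'   findings with `case_id`, `gene`, `expectation`.
#' @param somatic Somatic record tibble for all cases (`case_id` column).
#' @param sv Optional SV tibble.
#' @param segments Optional segment tibble (`sample` column = case id).
#' @param expression Optional `expression_matrix` (samples = case ids).
#' @param methylation Optional methylation tibble.
#' @param gene_map Gene-interval tibble ([read_gene_map()]).
#' @param cases Optional case metadata with `ploidy` and `no_tumor_tissue`.
#' @param interactions Optional interaction tibble for pathway expansion.
#' @param config A [threshold_config()].
#' @return A `secondhit_result`: list with `verdicts` (one row per
#'   case-gene), `evidence` (all evidence rows) and `tmb` (per case).
#' @export
detect_second_hits <- function(screened, somatic, sv = NULL, segments = NULL,
                               expression = NULL, methylation = NULL,
                               gene_map = NULL, cases = NULL,
                               interactions = NULL, config = NULL) {
  config <- as_threshold_config(config)
  targets <- if (inherits(screened, "germline_screen")) {
    dplyr::distinct(screened$reportable, .data$case_id, .data$gene,
                    .data$expectation, .keep_all = FALSE)
  } else {
    dplyr::distinct(screened, .data$case_id, .data$gene, .data$expectation)
  }
  germline_af <- if (inherits(screened, "germline_screen") &&
                     "tumor_af" %in% names(screened$reportable)) {
    dplyr::distinct(screened$reportable, .data$case_id, .data$gene, .data$tumor_af)
  } else if (!inherits(screened, "germline_screen") && "tumor_af" %in% names(screened)) {
    dplyr::distinct(screened, .data$case_id, .data$gene, .data$tumor_af)
  } else NULL

  all_ev <- list()
  verdicts <- purrr::pmap(targets, function(case_id, gene, expectation) {
    meta <- if (!is.null(cases)) dplyr::filter(cases, .data$case_id == !!case_id) else NULL
    ploidy <- if (!is.null(meta) && nrow(meta) && "ploidy" %in% names(meta) &&
                  !is.na(meta$ploidy[1])) meta$ploidy[1] else 2
    ntt <- !is.null(meta) && nrow(meta) && "no_tumor_tissue" %in% names(meta) &&
      isTRUE(meta$no_tumor_tissue[1])
    ev <- empty_evidence()
    som_case <- dplyr::filter(somatic, .data$case_id == !!case_id)
    ev <- dplyr::bind_rows(ev, find_snv_hit(som_case, gene, config, case_id = case_id))
    if (!is.null(sv)) {
      ev <- dplyr::bind_rows(ev, find_sv_hit(
        dplyr::filter(sv, .data$case_id == !!case_id), gene, config, case_id = case_id))
    }
    gi <- if (!is.null(gene_map)) dplyr::filter(gene_map, toupper(.data$gene) == toupper(!!gene)) else NULL
    if (!is.null(segments) && !is.null(gi) && nrow(gi)) {
      seg_case <- dplyr::filter(segments, .data$sample == !!case_id)
      taf <- if (!is.null(germline_af)) {
        hit <- dplyr::filter(germline_af, .data$case_id == !!case_id, .data$gene == !!gene)
        if (nrow(hit)) hit$tumor_af[1] else NA_real_
      } else NA_real_
      ev <- dplyr::bind_rows(ev, assess_cn_loh(seg_case, gi[1, c("gene", "chrom", "start", "end")],
                                               tumor_af = taf, ploidy = ploidy,
                                               config = config, case_id = case_id))
    }
    if (!is.null(expression)) {
      samples <- setdiff(names(expression), "gene")
      if (case_id %in% samples) {
        ev <- dplyr::bind_rows(ev, expression_aberrant(expression, gene, case_id, config))
      }
    }
    if (!is.null(methylation)) {
      seg_case <- if (!is.null(segments)) dplyr::filter(segments, .data$sample == !!case_id) else NULL
      ev <- dplyr::bind_rows(ev, methylation_hit(
        methylation, gene, case_id, segments = seg_case,
        gene_interval = if (!is.null(gi) && nrow(gi)) gi[1, c("gene", "chrom", "start", "end")] else NULL,
        ploidy = ploidy, config = config))
    }
    verdict <- integrate_verdict(case_id, gene, ev, expectation, no_tumor_tissue = ntt)
    if (!verdict$hit_found && !is.null(interactions)) {
      pw <- suppressWarnings(pathway_expansion(gene, interactions, som_case,
                                               config, case_id = case_id))
      ev <- dplyr::bind_rows(ev, pw)
    }
    all_ev[[length(all_ev) + 1]] <<- dplyr::mutate(ev, target_gene = gene)
    verdict
  }) %>% dplyr::bind_rows()
  if (!nrow(verdicts)) {
    verdicts <- tibble::tibble(
      case_id = character(), gene = character(), hit_found = logical(),
      informative = logical(), n_evidence = integer(),
      evidence_kinds = character(), expectation = character(),
      narrative = character()
    )
  }

  tmb <- somatic %>%
    dplyr::group_by(.data$case_id) %>%
    dplyr::group_modify(~ compute_tmb(.x, config)) %>%
    dplyr::ungroup()

  structure(list(
    verdicts = dplyr::arrange(verdicts, .data$case_id, .data$gene),
    evidence = dplyr::bind_rows(all_ev),
    tmb = tmb,
    config = config
  ), class = "secondhit_result")
}

#' @export
print.secondhit_result <- function(x, ...) {
  cat(sprintf("<secondhit_result> %d case-gene verdicts, %d with a second hit\n",
              nrow(x$verdicts), sum(x$verdicts$hit_found)))
  invisible(x)
}
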