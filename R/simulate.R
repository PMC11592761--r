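#' Configuration for the synthetic paired-cohort generator
#'
#' The generator emulates a prospective sarcoma-center screening cohort:
#' a cohort of 312 cases of which about 8% carry one pathogenic germline
#' first hit in a panel gene (dominant, heterozygous), and about 11/24 of
#' the carriers additionally carry one somatic second hit of a named
#' evidence class in the tumor. Non-carriers receive only decoy germline
#' variants: common variants (population frequency at or above the
#' frequency gate), multi-submitter ClinVar-benign variants, high
#' local-count synonymous variants, single-submitter benign variants with
#' high local counts, off-panel and non-coding variants, and rare benign
#' missense variants that survive filtering as VUS.
#'
#' @param n_cases Cohort size (default 312).
#' @param carrier_fraction Probability that a case carries a germline first
#'   hit (default 0.08).
#' @param second_hit_fraction Probability that a carrier's tumor carries a
#'   planted second hit (default 11/24).
#' @param evidence_mix Named numeric weights over the planted second-hit
#'   classes `snv`, `focal_deletion`, `loh`, `expression_low`,
#'   `promoter_hypermethylation`.
#' @param snv_hit_vaf VAF of planted somatic SNV second hits (default 0.3).
#' @param decoys_per_case Mean number of decoy germline variants per case.
#' @param background_mutations Mean number of somatic passenger variants
#'   per case (placed in background genes, never in first-hit genes).
#' @param expression_meanlog_sd,expression_sdlog Per-gene log-normal
#'   expression model: gene means drawn from N(3, sd) on the log scale,
#'   within-gene spread `expression_sdlog`.
#' @param methylation_shape1,methylation_shape2 Beta-distribution baseline
#'   for promoter probes (default Beta(1, 12): unmethylated promoters).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 312L,
                       carrier_fraction = 0.08,
                       second_hit_fraction = 11 / 24,
                       evidence_mix = c(snv = 0.4, focal_deletion = 0.25, loh = 0.15,
                                        expression_low = 0.1, promoter_hypermethylation = 0.1),
                       snv_hit_vaf = 0.3,
                       decoys_per_case = 4,
                       background_mutations = 20,
                       expression_meanlog_sd = 1,
                       expression_sdlog = 0.5,
                       methylation_shape1 = 1,
                       methylation_shape2 = 12,
                       seed = 1L) {
  if (n_cases < 2) stop("n_cases must be at least 2", call. = FALSE)
  for (f in c(carrier_fraction, second_hit_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  need <- c("snv", "focal_deletion", "loh", "expression_low", "promoter_hypermethylation")
  if (!all(need %in% names(evidence_mix)) || any(evidence_mix < 0) || sum(evidence_mix) <= 0) {
    stop("evidence_mix must be non-negative weights over ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_cases = as.integer(n_cases), carrier_fraction = carrier_fraction,
    second_hit_fraction = second_hit_fraction,
    evidence_mix = evidence_mix[need] / sum(evidence_mix[need]),
    snv_hit_vaf = snv_hit_vaf, decoys_per_case = decoys_per_case,
    background_mutations = background_mutations,
    expression_meanlog_sd = expression_meanlog_sd,
    expression_sdlog = expression_sdlog,
    methylation_shape1 = methylation_shape1,
    methylation_shape2 = methylation_shape2,
    seed = as.integer(seed)
  ), class = "sim_config")
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

decoy_classes <- c("frequency", "rule_A", "rule_B", "rule_C", "off_panel",
                   "non_coding", "benign_vus")

#' Generate a fully synthetic paired tumor/normal cohort
#'
#' Produces every input the pipeline consumes, entirely in memory:
#' per-case germline variant records with embedded annotations, somatic
#' small variants, copy-number segments, a cohort FPKM expression matrix,
#' a promoter methylation table, case metadata, and a truth table listing
#' every planted first hit, second hit and decoy. Coordinates live on the
#' synthetic miniature genome of [synthetic_gene_map()]. The same seed
#' reproduces the cohort exactly; [write_cohort()] serializes it to the
#' on-disk layout [read_cohort()] and [run_pipeline()] accept.
#'
#' @param config A [sim_config()].
#' @return A list of pipeline inputs plus `truth` and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cases = 40, seed = 7))
#' dplyr::count(cohort$truth, planted_second_hit)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, {
    panel <- fixture_panel()
    knowledge <- fixture_knowledge()
    # simulated first hits go to dominant genes with truncation mechanism
    hit_genes <- knowledge$gene[knowledge$inheritance == "dominant" &
                                  knowledge$truncation_is_mechanism]
    hit_genes <- intersect(hit_genes, as.character(panel))
    background_genes <- sprintf("BG%02d", 1:20)
    off_panel_genes <- sprintf("OP%02d", 1:5)
    gene_map <- synthetic_gene_map(c(as.character(panel), background_genes, off_panel_genes))

    n <- config$n_cases
    case_ids <- sprintf("S%04d", seq_len(n))
    carrier <- stats::runif(n) < config$carrier_fraction
    first_gene <- ifelse(carrier, sample(hit_genes, n, replace = TRUE), NA_character_)
    has_second <- carrier & stats::runif(n) < config$second_hit_fraction
    second_class <- ifelse(
      has_second,
      sample(names(config$evidence_mix), n, replace = TRUE, prob = config$evidence_mix),
      NA_character_
    )

    cases <- tibble::tibble(
      case_id = case_ids,
      diagnosis = sample(c("leiomyosarcoma", "liposarcoma", "osteosarcoma",
                           "gist", "leiomyoma", "angiosarcoma"), n, replace = TRUE),
      category = sample(diagnosis_categories, n, replace = TRUE,
                        prob = c(0.42, 0.11, 0.13, 0.04, 0.03, 0.02, 0.13, 0.12)),
      malignant = NA, sex = sample(c("female", "male"), n, replace = TRUE),
      age = round(stats::rnorm(n, 55, 15)), ploidy = 2, no_tumor_tissue = FALSE,
      fulfils_criteria = FALSE
    )
    cases$malignant <- !cases$category %in% c("soft_tissue_benign", "bone_benign")

    gm_lookup <- function(g) gene_map[match(g, gene_map$gene), ]

    germ_rows <- list()
    truth_decoys <- character(n)
    for (i in seq_len(n)) {
      rows <- list()
      if (carrier[i]) {
        g <- gm_lookup(first_gene[i])
        pos <- g$start + sample.int(90000L, 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          case_id = case_ids[i], chrom = g$chrom, pos = pos,
          ref = "C", alt = "T", gene = g$gene,
          consequence = sample(c("nonsense", "frameshift", "splice_site"), 1),
          genotype = "het", population_af = 0,
          clinvar_classification = "pathogenic", clinvar_blb_submitters = 0L,
          clinvar_cancer_assoc = TRUE, local_count = sample(0:5, 1),
          tumor_af = if (isTRUE(second_class[i] %in% c("focal_deletion", "loh"))) 0.8 else NA_real_
        )
      }
      n_decoys <- max(1L, stats::rpois(1, config$decoys_per_case))
      classes <- sample(decoy_classes, n_decoys, replace = TRUE)
      truth_decoys[i] <- paste(sort(unique(classes)), collapse = ",")
      for (cl in classes) {
        dg <- if (cl == "off_panel") {
          gm_lookup(sample(off_panel_genes, 1))
        } else {
          gm_lookup(sample(setdiff(as.character(panel), first_gene[i]), 1))
        }
        pos <- dg$start + sample.int(90000L, 1)
        row <- tibble::tibble(
          case_id = case_ids[i], chrom = dg$chrom, pos = pos,
          ref = "G", alt = "A", gene = dg$gene, consequence = "missense",
          genotype = "het", population_af = 0,
          clinvar_classification = "none", clinvar_blb_submitters = 0L,
          clinvar_cancer_assoc = FALSE, local_count = sample(0:10, 1),
          tumor_af = NA_real_
        )
        if (cl == "frequency") row$population_af <- stats::runif(1, 0.01, 0.3)
        if (cl == "rule_A") {
          row$clinvar_classification <- "benign"
          row$clinvar_blb_submitters <- sample(3:10, 1)
        }
        if (cl == "rule_B") {
          row$consequence <- "synonymous"
          row$local_count <- sample(101:500, 1)
        }
        if (cl == "rule_C") {
          row$clinvar_classification <- "likely_benign"
          row$clinvar_blb_submitters <- 1L
          row$local_count <- sample(81:100, 1)
        }
        if (cl == "non_coding") row$consequence <- "non_coding"
        rows[[length(rows) + 1]] <- row
      }
      germ_rows[[i]] <- dplyr::bind_rows(rows)
    }
    germline <- dplyr::bind_rows(germ_rows) %>%
      dplyr::mutate(
        pos = as.integer(.data$pos),
        start = .data$pos - 1L, end = .data$pos - 1L + nchar(.data$ref),
        key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)
      ) %>%
      dplyr::relocate("start", "end", "key", .after = "pos")

    # somatic layer: planted SNV second hits plus background passengers
    som_rows <- list()
    for (i in seq_len(n)) {
      if (isTRUE(second_class[i] == "snv")) {
        g <- gm_lookup(first_gene[i])
        som_rows[[length(som_rows) + 1]] <- tibble::tibble(
          case_id = case_ids[i], chrom = g$chrom,
          pos = g$start + sample.int(90000L, 1), ref = "G", alt = "T",
          gene = g$gene, consequence = "nonsense", vaf = config$snv_hit_vaf,
          depth = 80L, population_af = 0, filter = "PASS"
        )
      }
      n_bg <- stats::rpois(1, config$background_mutations)
      if (n_bg > 0) {
        bg <- gene_map[match(sample(background_genes, n_bg, replace = TRUE), gene_map$gene), ]
        som_rows[[length(som_rows) + 1]] <- tibble::tibble(
          case_id = case_ids[i], chrom = bg$chrom,
          pos = bg$start + sample.int(90000L, n_bg, replace = TRUE),
          ref = "A", alt = "G", gene = bg$gene, consequence = "missense",
          vaf = stats::runif(n_bg, 0.1, 0.6),
          depth = sample(30:120, n_bg, replace = TRUE),
          population_af = 0, filter = "PASS"
        )
      }
    }
    somatic <- dplyr::bind_rows(som_rows)
    if (nrow(somatic)) {
      somatic <- somatic %>%
        dplyr::mutate(pos = as.integer(.data$pos), start = .data$pos - 1L,
                      end = .data$pos - 1L + nchar(.data$ref),
                      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
        dplyr::relocate("start", "end", "key", .after = "pos")
    } else {
      somatic <- empty_somatic_records()
    }

    # copy-number layer: diploid baseline, with planted deletion/LOH over
    # the first-hit gene
    chroms <- gene_map %>%
      dplyr::group_by(.data$chrom) %>%
      dplyr::summarise(len = max(.data$end) + 2000000L, .groups = "drop")
    seg_rows <- purrr::map(seq_len(n), function(i) {
      base <- tibble::tibble(sample = case_ids[i], chrom = chroms$chrom,
                             start = 0L, end = chroms$len, total_cn = 2,
                             allelic_imbalance = FALSE)
      if (!isTRUE(second_class[i] %in% c("focal_deletion", "loh"))) return(base)
      g <- gm_lookup(first_gene[i])
      ds <- max(0L, g$start - 500000L)
      de <- g$end + 500000L
      chrom_len <- chroms$len[chroms$chrom == g$chrom]
      cn <- if (second_class[i] == "focal_deletion") 1 else 2
      dplyr::bind_rows(
        dplyr::filter(base, .data$chrom != g$chrom),
        tibble::tibble(sample = case_ids[i], chrom = g$chrom,
                       start = c(0L, ds, de), end = c(ds, de, chrom_len),
                       total_cn = c(2, cn, 2),
                       allelic_imbalance = c(FALSE, TRUE, FALSE))
      )
    })
    segments <- validate_segments(dplyr::bind_rows(seg_rows))

    # expression layer: per-gene log-normal across the cohort; planted
    # expression second hits are set to 0 FPKM (the guaranteed cohort
    # minimum under any percentile definition)
    expr_genes <- c(hit_genes, background_genes)
    meanlog <- stats::rnorm(length(expr_genes), 3, config$expression_meanlog_sd)
    expr_mat <- vapply(seq_len(n), function(i) {
      stats::rlnorm(length(expr_genes), meanlog, config$expression_sdlog)
    }, numeric(length(expr_genes)))
    colnames(expr_mat) <- case_ids
    for (i in which(!is.na(second_class) & second_class == "expression_low")) {
      expr_mat[match(first_gene[i], expr_genes), i] <- 0
    }
    # a carrier without a planted expression hit has, by the truth table,
    # normal expression of the first-hit gene: hold it at the gene's
    # distribution median so it cannot drift into a tail by chance
    for (i in which(carrier & (is.na(second_class) | second_class != "expression_low"))) {
      gi <- match(first_gene[i], expr_genes)
      expr_mat[gi, i] <- exp(meanlog[gi])
    }
    expression <- validate_expression(
      dplyr::bind_cols(tibble::tibble(gene = expr_genes),
                       tibble::as_tibble(expr_mat)))

    # methylation layer: 4 promoter probes per gene, unmethylated baseline;
    # planted promoter hypermethylation shifts the case's probes high
    meth_genes <- hit_genes
    probe_offsets <- c(-1200L, -400L, 300L, 1100L)
    meth <- tidyr::expand_grid(gene = meth_genes, offset = probe_offsets,
                               sample = case_ids) %>%
      dplyr::mutate(
        probe_id = paste0("cg_", .data$gene, "_", match(.data$offset, probe_offsets)),
        dist_tss = .data$offset,
        beta = stats::rbeta(dplyr::n(), config$methylation_shape1, config$methylation_shape2)
      ) %>%
      dplyr::select("probe_id", "gene", "dist_tss", "beta", "sample")
    hyper <- which(!is.na(second_class) & second_class == "promoter_hypermethylation")
    for (i in hyper) {
      sel <- meth$gene == first_gene[i] & meth$sample == case_ids[i]
      meth$beta[sel] <- stats::runif(sum(sel), 0.85, 0.95)
    }
    meth <- validate_methylation(meth)

    truth <- tibble::tibble(
      case_id = case_ids,
      carrier = carrier,
      first_hit_gene = first_gene,
      planted_second_hit = ifelse(is.na(second_class), "none", second_class),
      decoy_classes = truth_decoys
    )

    list(cases = cases, germline = germline, somatic = somatic, sv = NULL,
         segments = segments, expression = expression, methylation = meth,
         gene_map = gene_map, panel = panel, knowledge = knowledge,
         truth = truth, config = config)
  })
}

#' Serialize / load a cohort directory
#'
#' `write_cohort()` writes the documented on-disk layout: `cases.tsv`,
#' `germline/<case>.vcf` and `somatic/<case>.vcf` (VCF 4.2),
#' `segments.tsv`, `expression.tsv`, `methylation.tsv`, `gene_map.tsv`,
#' `panel.txt`, `knowledge.tsv` and `truth.tsv` when present.
#' `read_cohort()` loads that layout back into the in-memory cohort list;
#' missing optional layers load as `NULL`.
#'
#' @param cohort A cohort list ([simulate_cohort()], [fixture_cohort()]).
#' @param dir Cohort directory.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` the
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cases(cohort$cases, file.path(dir, "cases.tsv"))
  dir.create(file.path(dir, "germline"), showWarnings = FALSE)
  dir.create(file.path(dir, "somatic"), showWarnings = FALSE)
  for (cid in unique(cohort$germline$case_id)) {
    write_germline_vcf(dplyr::filter(cohort$germline, .data$case_id == cid),
                       file.path(dir, "germline", paste0(cid, ".vcf")))
  }
  if (!is.null(cohort$somatic)) {
    for (cid in unique(cohort$somatic$case_id)) {
      write_somatic_vcf(dplyr::filter(cohort$somatic, .data$case_id == cid),
                        file.path(dir, "somatic", paste0(cid, ".vcf")))
    }
  }
  # annotation side tables travel with the cohort so that the VCF round
  # trip does not need to re-embed them
  ann <- cohort$germline %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
  write_clinvar(dplyr::transmute(ann, chrom = .data$chrom, pos = .data$pos,
                                 ref = .data$ref, alt = .data$alt,
                                 classification = .data$clinvar_classification,
                                 blb_submitters = .data$clinvar_blb_submitters,
                                 cancer_syndrome_assoc = .data$clinvar_cancer_assoc),
                file.path(dir, "clinvar.tsv"))
  write_local_db(dplyr::transmute(ann, chrom = .data$chrom, pos = .data$pos,
                                  ref = .data$ref, alt = .data$alt,
                                  occurrence_count = .data$local_count,
                                  database_size = 9244L),
                 file.path(dir, "local_db.tsv"))
  if ("tumor_af" %in% names(cohort$germline)) {
    readr::write_tsv(dplyr::select(cohort$germline, "case_id", "key", "tumor_af"),
                     file.path(dir, "tumor_af.tsv"), progress = FALSE)
  }
  if (!is.null(cohort$segments)) write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  if (!is.null(cohort$expression)) write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  if (!is.null(cohort$methylation)) write_methylation(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_gene_map(cohort$gene_map, file.path(dir, "gene_map.tsv"))
  write_panel(cohort$panel, file.path(dir, "panel.txt"))
  write_knowledge(cohort$knowledge, file.path(dir, "knowledge.tsv"))
  if (!is.null(cohort$truth)) readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory does not exist: ", dir, call. = FALSE)
  req <- c("cases.tsv", "gene_map.tsv", "panel.txt", "knowledge.tsv")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing) || !dir.exists(file.path(dir, "germline"))) {
    stop("not a cohort directory (missing ", paste(c(missing, "germline/"), collapse = ", "),
         "): ", dir, call. = FALSE)
  }
  read_all_vcfs <- function(subdir, reader) {
    files <- list.files(file.path(dir, subdir), pattern = "\\.vcf$", full.names = TRUE)
    purrr::map(files, function(f) {
      reader(f, case_id = sub("\\.vcf$", "", basename(f)))
    }) %>% dplyr::bind_rows()
  }
  germline <- read_all_vcfs("germline", read_germline_vcf)
  clinvar <- if (file.exists(file.path(dir, "clinvar.tsv"))) read_clinvar(file.path(dir, "clinvar.tsv")) else NULL
  local_db <- if (file.exists(file.path(dir, "local_db.tsv"))) read_local_db(file.path(dir, "local_db.tsv")) else NULL
  germline <- annotate_records(germline, clinvar, local_db)
  taf_path <- file.path(dir, "tumor_af.tsv")
  if (file.exists(taf_path)) {
    taf <- readr::read_tsv(taf_path, progress = FALSE, col_types = readr::cols(
      case_id = readr::col_character(), key = readr::col_character(),
      tumor_af = readr::col_double()))
    germline <- dplyr::left_join(germline, taf, by = c("case_id", "key"))
  }
  opt <- function(file, reader) {
    p <- file.path(dir, file)
    if (file.exists(p)) reader(p) else NULL
  }
  list(
    cases = read_cases(file.path(dir, "cases.tsv")),
    germline = germline,
    somatic = if (dir.exists(file.path(dir, "somatic"))) read_all_vcfs("somatic", read_somatic_vcf) else empty_somatic_records(),
    sv = NULL,
    segments = opt("segments.tsv", read_segments),
    expression = opt("expression.tsv", read_expression),
    methylation = opt("methylation.tsv", read_methylation),
    gene_map = read_gene_map(file.path(dir, "gene_map.tsv")),
    panel = read_panel(file.path(dir, "panel.txt")),
    knowledge = read_knowledge(file.path(dir, "knowledge.tsv")),
    truth = if (file.exists(file.path(dir, "truth.tsv"))) {
      readr::read_tsv(file.path(dir, "truth.tsv"), progress = FALSE,
                      col_types = readr::cols(.default = readr::col_guess()))
    } else NULL
  )
}
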