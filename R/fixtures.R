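#' Bundled fixtures: the published 24-carrier case table
#'
#' The package ships the published per-carrier findings table (24 cases:
#' diagnosis, germline variant in HGVS notation, clinical impact, pedigree,
#' syndrome-criteria flag and the detected second hit) as a plain-TSV
#' fixture, together with the 8-category diagnosis breakdown of the full
#' 312-case cohort. [fixture_cohort()] expands these into machine-runnable
#' inputs for the whole pipeline.
#'
#' @return `table1_cases()`: tibble of the 24 printed carrier rows.
#' @export
table1_cases <- function() {
  path <- system.file("extdata", "table1_cases.tsv", package = "secondhit")
  readr::read_tsv(path, progress = FALSE, na = character(), col_types = readr::cols(
    case_no = readr::col_character(), .default = readr::col_character()
  ))
}

#' @rdname table1_cases
#' @return `table2_counts()`: the printed 8 x 2 diagnosis-category count
#'   table with per-column percentages.
#' @export
table2_counts <- function() {
  path <- system.file("extdata", "table2_counts.tsv", package = "secondhit")
  readr::read_tsv(path, progress = FALSE, col_types = readr::cols(
    category = readr::col_character(), .default = readr::col_integer()
  ))
}

#' @rdname table1_cases
#' @return `fixture_knowledge()`: the bundled gene-to-syndrome knowledge
#'   table; `fixture_panel()`: the bundled stand-in gene panel (the study's
#'   787-gene list is not published, so a documented synthetic stand-in
#'   ships instead and any list can replace it).
#' @export
fixture_knowledge <- function() {
  read_knowledge(system.file("extdata", "knowledge.tsv", package = "secondhit"))
}

#' @rdname table1_cases
#' @export
fixture_panel <- function() {
  read_panel(system.file("extdata", "panel_synthetic_standin.txt", package = "secondhit"))
}

# consequence class from the printed HGVS strings
hgvs_consequence <- function(hgvs_c, hgvs_p) {
  dplyr::case_when(
    grepl("fs", hgvs_p) ~ "frameshift",
    grepl("Ter", hgvs_p) ~ "nonsense",
    grepl("[+-][0-9]", hgvs_c) ~ "splice_site",
    hgvs_p != "NA" & hgvs_p != "" ~ "missense",
    TRUE ~ "other_exonic"
  )
}

hgvs_offset <- function(hgvs_c) {
  as.integer(sub("^c\\.(\\d+).*$", "\\1", hgvs_c))
}

hgvs_alleles <- function(hgvs_c) {
  snv <- regmatches(hgvs_c, regexpr("[ACGT]>[ACGT]", hgvs_c))
  if (length(snv) == 1) {
    return(c(substr(snv, 1, 1), substr(snv, 3, 3)))
  }
  if (grepl("del", hgvs_c)) return(c("CA", "C"))
  if (grepl("dup", hgvs_c)) return(c("C", "CA"))
  c("A", "C")
}

#' Synthetic gene map for a panel
#'
#' Places genes on a miniature genome (eight synthetic chromosomes of 30 Mb)
#' at deterministic, evenly spaced coordinates: desk-scale stand-in
#' coordinates, not real genome positions.
#'
#' @param genes Character vector of gene symbols.
#' @return Gene-map tibble (`gene`, `chrom`, `start`, `end`, `tss`).
#' @export
synthetic_gene_map <- function(genes) {
  genes <- unique(toupper(genes))
  i <- seq_along(genes)
  chrom <- paste0("chr", ((i - 1L) %% 8L) + 1L)
  slot <- (i - 1L) %/% 8L
  start <- 2000000L + slot * 3000000L
  tibble::tibble(gene = genes, chrom = chrom, start = start,
                 end = start + 100000L, tss = start)
}

# category assignment for the 24 printed cases; reconstruction consistent
# with the printed category sums (11,1,1,0,3,0,4,4) and 3 benign carriers
table1_category <- function(case_no) {
  categories <- c(
    "40" = "gynaecological_tract", "52" = "bone_sarcoma_low",
    "62" = "gist", "63" = "gist",
    "67" = "soft_tissue_sarcoma_high", "76" = "soft_tissue_sarcoma_high",
    "95" = "soft_tissue_sarcoma_high", "101" = "soft_tissue_sarcoma_high",
    "111" = "soft_tissue_sarcoma_high", "115" = "gynaecological_tract",
    "139" = "soft_tissue_sarcoma_high", "144" = "gist",
    "168" = "soft_tissue_sarcoma_high", "207" = "soft_tissue_sarcoma_low",
    "208" = "gynaecological_tract", "231" = "soft_tissue_sarcoma_high",
    "265" = "gynaecological_tract", "295" = "bone_sarcoma_low",
    "306" = "soft_tissue_sarcoma_high", "311" = "soft_tissue_benign",
    "329" = "bone_sarcoma_low", "339" = "soft_tissue_sarcoma_high",
    "353" = "soft_tissue_sarcoma_high", "364" = "gist"
  )
  unname(categories[case_no])
}

#' Machine-runnable fixture cohort derived from the published tables
#'
#' Expands the printed 24-carrier table and the 8-category cohort breakdown
#' into the full set of pipeline inputs for a 312-case cohort: germline
#' variant records for the carriers (coordinates on the synthetic gene
#' map), ClinVar-style assertions, per-case evidence bundles constructed so
#' that the second-hit engine reproduces the printed second-hit column
#' (somatic SNVs for the printed SNV hits, deleted segments with allelic
#' imbalance for the printed deletions, nothing for the printed negatives,
#' a no-tumor-tissue flag for the one case without tumor material), and
#' per-case metadata for the 288 non-carrier cases matching the printed
#' category counts. Evidence bundles are reconstructions sufficient to
#' reproduce the printed verdicts, not patient data; sex and age of the
#' filler cases are synthetic (the publication reports only group-level
#' comparisons).
#'
#' @return A list with elements `cases`, `germline`, `somatic`, `segments`,
#'   `gene_map`, `panel`, `knowledge` (plus `sv`, `expression`,
#'   `methylation`, all `NULL`: the printed second hits involve no such
#'   layer).
#' @export
fixture_cohort <- function() {
  t1 <- table1_cases()
  t2 <- table2_counts()
  knowledge <- fixture_knowledge()
  panel <- fixture_panel()
  gene_map <- synthetic_gene_map(as.character(panel))

  carriers <- t1 %>%
    dplyr::mutate(
      case_id = .data$case_no,
      category = table1_category(.data$case_no),
      malignant = !.data$case_no %in% c("40", "265", "311"),
      carrier = TRUE,
      fulfils_criteria = .data$fulfils_criteria == "Yes",
      no_tumor_tissue = .data$second_hit == "NA",
      sex = ifelse(as.integer(.data$case_no) %% 2 == 0, "female", "male"),
      age = 35 + (as.integer(.data$case_no) %% 40),
      ploidy = 2
    )

  # non-carrier filler cases matching the printed no-finding column
  filler_counts <- stats::setNames(t2$n_no_finding, t2$category)
  filler_cat <- rep(names(filler_counts), filler_counts)
  n_fill <- length(filler_cat)
  benign_cat <- filler_cat %in% c("soft_tissue_benign", "bone_benign")
  gyn_idx <- which(filler_cat == "gynaecological_tract")
  benign_cat[gyn_idx[seq_len(15)]] <- TRUE  # benign gynaecological lesions
  filler <- tibble::tibble(
    case_id = sprintf("N%03d", seq_len(n_fill)),
    diagnosis = filler_cat,
    category = filler_cat,
    malignant = !benign_cat,
    carrier = FALSE,
    fulfils_criteria = FALSE,
    no_tumor_tissue = FALSE,
    sex = ifelse(seq_len(n_fill) %% 2 == 0, "female", "male"),
    age = 25 + (seq_len(n_fill) %% 55),
    ploidy = 2
  )
  cases <- dplyr::bind_rows(
    dplyr::select(carriers, "case_id", "diagnosis", "category", "malignant",
                  "carrier", "fulfils_criteria", "no_tumor_tissue", "sex",
                  "age", "ploidy"),
    filler
  )

  gm <- gene_map
  germ <- carriers %>%
    dplyr::mutate(consequence = hgvs_consequence(.data$hgvs_c, .data$hgvs_p)) %>%
    dplyr::left_join(gm, by = "gene") %>%
    dplyr::mutate(
      pos = .data$start + hgvs_offset(.data$hgvs_c),
      alleles = purrr::map(.data$hgvs_c, hgvs_alleles),
      ref = purrr::map_chr(.data$alleles, 1),
      alt = purrr::map_chr(.data$alleles, 2),
      genotype = "het",
      population_af = ifelse(.data$gene == "CHEK2", 0.002, 0),
      clinvar_classification = "pathogenic",
      clinvar_blb_submitters = 0L,
      clinvar_cancer_assoc = TRUE,
      local_count = 2L,
      # per-case clinical assessment where it differs from the gene default
      assessment_override = ifelse(.data$case_no == "329", "risk_factor", NA_character_),
      # allele fraction of the germline variant in tumor reads, where a
      # deletion of the wild-type allele retains the alternative allele
      tumor_af = ifelse(grepl("^Deletion", .data$second_hit), 0.8, NA_real_)
    ) %>%
    dplyr::transmute(
      case_id = .data$case_id, chrom = .data$chrom, pos = as.integer(.data$pos),
      start = as.integer(.data$pos - 1L), end = as.integer(.data$pos - 1L + nchar(.data$ref)),
      ref = .data$ref, alt = .data$alt,
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      gene = .data$gene, consequence = .data$consequence,
      genotype = .data$genotype, population_af = .data$population_af,
      clinvar_classification = .data$clinvar_classification,
      clinvar_blb_submitters = .data$clinvar_blb_submitters,
      clinvar_cancer_assoc = .data$clinvar_cancer_assoc,
      local_count = .data$local_count,
      assessment_override = .data$assessment_override,
      tumor_af = .data$tumor_af
    )

  # somatic SNV second hits exactly as printed
  snv_hits <- carriers %>%
    dplyr::filter(grepl("^SNV:", .data$second_hit)) %>%
    dplyr::mutate(
      hit_gene = sub("^SNV: ([A-Z0-9]+),.*$", "\\1", .data$second_hit),
      hit_c = sub("^.*(c\\.[^,]+),.*$", "\\1", .data$second_hit),
      hit_p = sub("^.*, (p\\..*)$", "\\1", .data$second_hit)
    ) %>%
    dplyr::left_join(gm, by = c("hit_gene" = "gene")) %>%
    dplyr::mutate(
      pos = .data$start + hgvs_offset(.data$hit_c),
      alleles = purrr::map(.data$hit_c, hgvs_alleles),
      ref = purrr::map_chr(.data$alleles, 1),
      alt = purrr::map_chr(.data$alleles, 2),
      vaf = ifelse(.data$case_no == "63", 0.4, 0.35)
    ) %>%
    dplyr::transmute(
      case_id = .data$case_id, chrom = .data$chrom, pos = as.integer(.data$pos),
      start = as.integer(.data$pos - 1L), end = as.integer(.data$pos - 1L + nchar(.data$ref)),
      ref = .data$ref, alt = .data$alt,
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      gene = .data$hit_gene,
      consequence = hgvs_consequence(.data$hit_c, .data$hit_p),
      vaf = .data$vaf, depth = 100L, population_af = 0, filter = "PASS"
    )

  # copy-number evidence: baseline diploid genome per carrier with tumor
  # tissue; printed focal deletions become low-CN segments with allelic
  # imbalance over the gene locus
  chroms <- gm %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(len = max(.data$end) + 2000000L, .groups = "drop")
  del_cases <- carriers %>%
    dplyr::filter(grepl("^Deletion", .data$second_hit)) %>%
    dplyr::mutate(del_gene = sub("^Deletion ", "", .data$second_hit)) %>%
    dplyr::left_join(gm, by = c("del_gene" = "gene")) %>%
    dplyr::select("case_id", "del_gene", "chrom", "start", "end")
  segs <- purrr::map(
    dplyr::filter(carriers, !.data$no_tumor_tissue)$case_id,
    function(cid) {
      base <- tibble::tibble(sample = cid, chrom = chroms$chrom, start = 0L,
                             end = chroms$len, total_cn = 2, allelic_imbalance = FALSE)
      del <- dplyr::filter(del_cases, .data$case_id == cid)
      if (!nrow(del)) return(base)
      for (k in seq_len(nrow(del))) {
        ds <- max(0L, del$start[k] - 500000L)
        de <- del$end[k] + 500000L
        chrom_len <- chroms$len[chroms$chrom == del$chrom[k]]
        base <- dplyr::bind_rows(
          dplyr::filter(base, .data$chrom != del$chrom[k]),
          tibble::tibble(sample = cid, chrom = del$chrom[k],
                         start = c(0L, ds, de),
                         end = c(ds, de, chrom_len),
                         total_cn = c(2, 1, 2),
                         allelic_imbalance = c(FALSE, TRUE, FALSE))
        )
      }
      base
    }) %>% dplyr::bind_rows() %>% validate_segments()

  list(
    cases = cases,
    germline = germ,
    somatic = snv_hits,
    segments = segs,
    gene_map = gm,
    panel = panel,
    knowledge = knowledge,
    sv = NULL,
    expression = NULL,
    methylation = NULL
  )
}
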