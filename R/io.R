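#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Build the canonical variant key
#'
#' Variant keys join a variant to its side-table annotations (ClinVar-style
#' assertions, local database counts). They use the external VCF convention:
#' 1-based position, reference and alternate allele as printed.
#'
#' @param chrom,pos,ref,alt Vectors describing variants (`pos` 1-based).
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# internal coordinates are 0-based half-open; VCF positions are 1-based.
vcf_to_internal <- function(pos, ref) {
  tibble::tibble(start = pos - 1L, end = pos - 1L + nchar(ref))
}

consequence_levels <- c("missense", "nonsense", "frameshift", "splice_site",
                        "synonymous", "other_exonic", "non_coding")
clinvar_levels <- c("benign", "likely_benign", "vus", "likely_pathogenic",
                    "pathogenic", "conflicting", "none")

stop_row <- function(path, row, msg) {
  stop(sprintf("%s: row %d: %s", path, row, msg), call. = FALSE)
}

check_enum <- function(x, levels, what, path) {
  bad <- which(!x %in% levels)
  if (length(bad)) {
    stop_row(path, bad[1], sprintf("invalid %s '%s' (expected one of %s)",
                                   what, x[bad[1]], paste(levels, collapse = ", ")))
  }
  invisible(x)
}

read_vcf_checked <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path, call. = FALSE)
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)), call. = FALSE)
  )
  fixed <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fixed) > 0) {
    bad <- which(is.na(fixed$POS) | is.na(suppressWarnings(as.integer(fixed$POS))))
    if (length(bad)) {
      stop(sprintf("malformed VCF '%s': non-numeric POS at data line %d", path, bad[1]), call. = FALSE)
    }
  }
  vcf
}

info_declared <- function(vcf, key) {
  any(grepl(sprintf("^##INFO=<ID=%s,", key), vcf@meta))
}

extract_info_vec <- function(vcf, key) {
  if (nrow(vcf@fix) == 0) return(character(0))
  vcfR::extract.info(vcf, element = key)
}

#' Read a single-sample germline VCF into annotated variant records
#'
#' One record per ALT allele carried by the sample; positions are converted
#' to internal 0-based half-open coordinates (`start`, `end`) while `pos`
#' keeps the external 1-based convention used for variant keys. Annotations
#' (gene symbol, consequence class, population allele frequency) are read
#' from INFO keys; they may alternatively (or additionally) be supplied as
#' side tables at screening time, in which case side tables win.
#'
#' @param path Path to a VCF 4.x file with one sample genotype column.
#' @param panel Optional [gene_panel()]; carried through as an attribute,
#'   membership is applied later by [prefilter()].
#' @param case_id Case identifier stamped on every record (defaults to the
#'   sample name in the VCF header).
#' @param info_keys Named list mapping the record fields `gene`,
#'   `consequence` and `af` to INFO keys in this VCF dialect.
#' @return A tibble of germline variant records with columns `case_id`,
#'   `chrom`, `pos`, `start`, `end`, `ref`, `alt`, `key`, `gene`,
#'   `consequence`, `genotype`, `population_af`.
#' @export
read_germline_vcf <- function(path, panel = NULL, case_id = NULL,
                              info_keys = list(gene = "GENE", consequence = "CSQCLASS", af = "POPAF")) {
  vcf <- read_vcf_checked(path)
  for (k in unlist(info_keys)) {
    if (!info_declared(vcf, k)) {
      stop(sprintf("configuration error: INFO key '%s' not declared in header of %s", k, path),
           call. = FALSE)
    }
  }
  if (is.null(case_id)) {
    smp <- colnames(vcf@gt)
    case_id <- if (length(smp) >= 2) smp[2] else "sample"
  }
  n <- nrow(vcf@fix)
  if (n == 0) return(empty_germline_records())

  fx <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  gt_raw <- unname(vcfR::extract.gt(vcf, element = "GT")[, 1])
  gene <- unname(extract_info_vec(vcf, info_keys$gene))
  csq <- unname(extract_info_vec(vcf, info_keys$consequence))
  af_raw <- unname(extract_info_vec(vcf, info_keys$af))

  rows <- purrr::map(seq_len(n), function(i) {
    alts <- strsplit(fx$ALT[i], ",", fixed = TRUE)[[1]]
    gt <- gt_raw[i]
    alleles <- if (is.na(gt)) integer(0) else
      suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
    afs <- if (is.na(af_raw[i])) character(0) else
      strsplit(af_raw[i], ",", fixed = TRUE)[[1]]
    purrr::map(seq_along(alts), function(j) {
      n_j <- sum(alleles == j, na.rm = TRUE)
      if (n_j == 0) return(NULL)
      tibble::tibble(
        chrom = fx$CHROM[i],
        pos = as.integer(fx$POS[i]),
        ref = fx$REF[i],
        alt = alts[j],
        gene = if (is.na(gene[i])) NA_character_ else gene[i],
        consequence = if (is.na(csq[i])) "non_coding" else csq[i],
        genotype = if (n_j >= 2) "hom" else "het",
        population_af = if (length(afs) >= j) suppressWarnings(as.numeric(afs[j])) else NA_real_
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) return(empty_germline_records())
  out <- out %>%
    dplyr::mutate(
      case_id = case_id,
      start = .data$pos - 1L,
      end = .data$pos - 1L + nchar(.data$ref),
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)
    ) %>%
    dplyr::select("case_id", "chrom", "pos", "start", "end", "ref", "alt",
                  "key", "gene", "consequence", "genotype", "population_af")
  check_enum(out$consequence, consequence_levels, "consequence", path)
  attr(out, "panel") <- panel
  out
}

empty_germline_records <- function() {
  tibble::tibble(
    case_id = character(), chrom = character(), pos = integer(),
    start = integer(), end = integer(), ref = character(), alt = character(),
    key = character(), gene = character(), consequence = character(),
    genotype = character(), population_af = double()
  )
}

empty_somatic_records <- function() {
  tibble::tibble(
    case_id = character(), chrom = character(), pos = integer(),
    start = integer(), end = integer(), ref = character(), alt = character(),
    key = character(), gene = character(), consequence = character(),
    vaf = double(), depth = integer(), population_af = double(),
    filter = character()
  )
}

#' Read a somatic small-variant VCF
#'
#' The variant allele frequency is derived from the tumor sample's `AD`
#' field (alt reads / total reads) when present, otherwise from an `AF`
#' FORMAT or INFO field; a record from which no VAF can be derived is a
#' parse error identifying the record. Read depth comes from `DP` or the
#' `AD` sum.
#'
#' @inheritParams read_germline_vcf
#' @return A tibble of somatic records with `vaf` in \[0,1\], `depth`,
#'   `population_af` and `filter` status.
#' @export
read_somatic_vcf <- function(path, case_id = NULL,
                             info_keys = list(gene = "GENE", consequence = "CSQCLASS", af = "POPAF")) {
  vcf <- read_vcf_checked(path)
  if (is.null(case_id)) {
    smp <- colnames(vcf@gt)
    case_id <- if (length(smp) >= 2) smp[2] else "sample"
  }
  n <- nrow(vcf@fix)
  if (n == 0) return(empty_somatic_records())

  fx <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  gene <- if (info_declared(vcf, info_keys$gene)) unname(extract_info_vec(vcf, info_keys$gene)) else rep(NA_character_, n)
  csq <- if (info_declared(vcf, info_keys$consequence)) unname(extract_info_vec(vcf, info_keys$consequence)) else rep(NA_character_, n)
  popaf <- if (info_declared(vcf, info_keys$af)) suppressWarnings(as.numeric(unname(extract_info_vec(vcf, info_keys$af)))) else rep(NA_real_, n)

  has_gt <- ncol(vcf@gt) >= 2
  ad <- if (has_gt) unname(vcfR::extract.gt(vcf, element = "AD")[, 1]) else rep(NA_character_, n)
  dp <- if (has_gt) suppressWarnings(as.integer(unname(vcfR::extract.gt(vcf, element = "DP")[, 1]))) else rep(NA_integer_, n)
  af_fmt <- if (has_gt) suppressWarnings(as.numeric(unname(vcfR::extract.gt(vcf, element = "AF")[, 1]))) else rep(NA_real_, n)

  vaf <- rep(NA_real_, n)
  depth <- dp
  for (i in seq_len(n)) {
    if (!is.na(ad[i])) {
      counts <- suppressWarnings(as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
      if (length(counts) >= 2 && !anyNA(counts)) {
        tot <- sum(counts)
        vaf[i] <- if (tot > 0) counts[2] / tot else 0
        if (is.na(depth[i])) depth[i] <- as.integer(tot)
      }
    }
    if (is.na(vaf[i]) && !is.na(af_fmt[i])) vaf[i] <- af_fmt[i]
  }
  bad <- which(is.na(vaf))
  if (length(bad)) {
    stop(sprintf("cannot derive VAF for record %s:%s in %s (no usable AD or AF field)",
                 fx$CHROM[bad[1]], fx$POS[bad[1]], path), call. = FALSE)
  }

  out <- tibble::tibble(
    case_id = case_id,
    chrom = fx$CHROM,
    pos = as.integer(fx$POS),
    ref = fx$REF,
    alt = fx$ALT,
    gene = gene,
    consequence = ifelse(is.na(csq), "other_exonic", csq),
    vaf = vaf,
    depth = ifelse(is.na(depth), 0L, depth),
    population_af = popaf,
    filter = ifelse(is.na(fx$FILTER), "PASS", fx$FILTER)
  ) %>%
    dplyr::mutate(
      start = .data$pos - 1L,
      end = .data$pos - 1L + nchar(.data$ref),
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)
    ) %>%
    dplyr::select("case_id", "chrom", "pos", "start", "end", "ref", "alt",
                  "key", "gene", "consequence", "vaf", "depth",
                  "population_af", "filter")
  check_enum(out$consequence, consequence_levels, "consequence", path)
  out
}

#' Read a structural-variant VCF (SVTYPE/END dialect)
#'
#' @inheritParams read_germline_vcf
#' @return Tibble with `svtype`, interval (`start`, `end`, 0-based
#'   half-open), `gene` and `vaf` (from the INFO `VAF` key).
#' @export
read_sv_vcf <- function(path, case_id = NULL) {
  vcf <- read_vcf_checked(path)
  if (is.null(case_id)) {
    smp <- colnames(vcf@gt)
    case_id <- if (length(smp) >= 2) smp[2] else "sample"
  }
  n <- nrow(vcf@fix)
  empty <- tibble::tibble(case_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          svtype = character(), gene = character(), vaf = double())
  if (n == 0) return(empty)
  fx <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  svtype <- unname(extract_info_vec(vcf, "SVTYPE"))
  sv_end <- suppressWarnings(as.integer(unname(extract_info_vec(vcf, "END"))))
  gene <- if (info_declared(vcf, "GENE")) unname(extract_info_vec(vcf, "GENE")) else rep(NA_character_, n)
  vaf <- suppressWarnings(as.numeric(unname(extract_info_vec(vcf, "VAF"))))
  tibble::tibble(
    case_id = case_id,
    chrom = fx$CHROM,
    start = as.integer(fx$POS) - 1L,
    end = ifelse(is.na(sv_end), as.integer(fx$POS), sv_end),
    svtype = svtype,
    gene = gene,
    vaf = vaf
  )
}

# ---- VCF writers (round-trip counterparts of the readers) -------------------

vcf_header <- function(sample, extra_info = character()) {
  c("##fileformat=VCFv4.2",
    "##source=secondhit",
    extra_info,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

#' Write germline/somatic variant records back to VCF 4.2
#'
#' Counterparts of [read_germline_vcf()] and [read_somatic_vcf()]; internal
#' 0-based coordinates are converted back to 1-based VCF positions so that
#' write-then-read is the identity on the record table.
#'
#' @param records A record tibble as returned by the corresponding reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germline_vcf <- function(records, path) {
  sample <- if (nrow(records)) records$case_id[1] else "sample"
  info_meta <- c(
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  body <- character(0)
  if (nrow(records)) {
    info <- paste0(
      ifelse(is.na(records$gene), "", paste0("GENE=", records$gene, ";")),
      "CSQCLASS=", records$consequence,
      ifelse(is.na(records$population_af), "",
             paste0(";POPAF=", formatC(records$population_af, format = "g", digits = 15)))
    )
    gt <- ifelse(records$genotype == "hom", "1/1", "0/1")
    body <- paste(records$chrom, records$start + 1L, ".", records$ref, records$alt,
                  ".", "PASS", info, "GT", gt, sep = "\t")
  }
  writeLines(c(vcf_header(sample, info_meta), body), path)
  invisible(path)
}

#' @rdname write_germline_vcf
#' @export
write_somatic_vcf <- function(records, path) {
  sample <- if (nrow(records)) records$case_id[1] else "sample"
  info_meta <- c(
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  body <- character(0)
  if (nrow(records)) {
    alt_reads <- as.integer(round(records$vaf * records$depth))
    ref_reads <- records$depth - alt_reads
    info <- paste0(
      ifelse(is.na(records$gene), "", paste0("GENE=", records$gene, ";")),
      "CSQCLASS=", records$consequence,
      ifelse(is.na(records$population_af), "",
             paste0(";POPAF=", formatC(records$population_af, format = "g", digits = 15)))
    )
    body <- paste(records$chrom, records$start + 1L, ".", records$ref, records$alt,
                  ".", records$filter, info, "GT:AD:DP",
                  paste0("0/1:", ref_reads, ",", alt_reads, ":", records$depth),
                  sep = "\t")
  }
  writeLines(c(vcf_header(sample, info_meta), body), path)
  invisible(path)
}

#' @rdname write_germline_vcf
#' @export
write_sv_vcf <- function(records, path) {
  sample <- if (nrow(records)) records$case_id[1] else "sample"
  info_meta <- c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Structural variant type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end (1-based inclusive)">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  body <- character(0)
  if (nrow(records)) {
    info <- paste0("SVTYPE=", records$svtype, ";END=", records$end,
                   ifelse(is.na(records$gene), "", paste0(";GENE=", records$gene)),
                   ifelse(is.na(records$vaf), "", paste0(";VAF=", records$vaf)))
    body <- paste(records$chrom, records$start + 1L, ".", "N", paste0("<", records$svtype, ">"),
                  ".", "PASS", info, "GT", "0/1", sep = "\t")
  }
  writeLines(c(vcf_header(sample, info_meta), body), path)
  invisible(path)
}

# ---- TSV tables -------------------------------------------------------------

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA"))
}

#' Read copy-number/allelic-imbalance segments
#'
#' Input is a BED-like TSV with columns `chrom`, `start`, `end` (0-based
#' half-open), `total_cn`, `allelic_imbalance` and optionally `sample`
#' (case id). Segments are sorted per chromosome; overlapping segments on
#' one chromosome (within one sample) are a validation error.
#'
#' @param path TSV path.
#' @return Tibble of segments with a `length` column.
#' @export
read_segments <- function(path) {
  seg <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    total_cn = readr::col_double(),
    allelic_imbalance = readr::col_logical(),
    .default = readr::col_character()
  ))
  validate_segments(seg, path)
}

#' @rdname read_segments
#' @param seg In-memory segment tibble to validate.
#' @export
validate_segments <- function(seg, path = "<segments>") {
  bad <- which(!(seg$start < seg$end))
  if (length(bad)) stop_row(path, bad[1], sprintf("start (%d) must be < end (%d)", seg$start[bad[1]], seg$end[bad[1]]))
  bad <- which(seg$total_cn < 0)
  if (length(bad)) stop_row(path, bad[1], "total_cn must be non-negative")
  if (!"sample" %in% names(seg)) seg$sample <- "sample"
  seg <- dplyr::arrange(seg, .data$sample, .data$chrom, .data$start)
  overlap <- seg %>%
    dplyr::group_by(.data$sample, .data$chrom) %>%
    dplyr::mutate(overlaps = .data$start < dplyr::lag(.data$end, default = -1L)) %>%
    dplyr::ungroup()
  bad <- which(overlap$overlaps)
  if (length(bad)) stop_row(path, bad[1], "overlapping segments on one chromosome")
  dplyr::mutate(seg, length = .data$end - .data$start)
}

#' @rdname read_segments
#' @param segments Segment tibble.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(dplyr::select(segments, -dplyr::any_of("length")), path, progress = FALSE)
  invisible(path)
}

#' Read a cohort gene-expression matrix (FPKM)
#'
#' TSV with a `gene` column and one column per sample; values are FPKM and
#' must be non-negative. The returned tibble carries the cohort size (number
#' of sample columns) as an attribute.
#'
#' @param path TSV path.
#' @return An `expression_matrix` tibble.
#' @export
read_expression <- function(path) {
  expr <- read_tsv_quiet(path, readr::cols(gene = readr::col_character(),
                                           .default = readr::col_double()))
  validate_expression(expr, path)
}

#' @rdname read_expression
#' @param expr In-memory expression tibble (gene column plus sample columns).
#' @export
validate_expression <- function(expr, path = "<expression>") {
  samples <- setdiff(names(expr), "gene")
  if (anyDuplicated(samples)) stop(sprintf("%s: duplicated sample columns", path), call. = FALSE)
  vals <- as.matrix(expr[samples])
  bad <- which(rowSums(vals < 0, na.rm = TRUE) > 0)
  if (length(bad)) stop_row(path, bad[1], "negative FPKM value")
  structure(expr, cohort_size = length(samples), class = c("expression_matrix", class(expr)))
}

#' @rdname read_expression
#' @param expression An `expression_matrix` tibble.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(expression)), path, progress = FALSE)
  invisible(path)
}

#' Read a promoter methylation table
#'
#' TSV with columns `probe_id`, `gene`, `dist_tss` (signed distance to the
#' transcription start site in bp), `beta` (methylation fraction in
#' \[0,1\]) and `sample`. Beta values outside \[0,1\] are a validation
#' error naming the row.
#'
#' @param path TSV path.
#' @return Tibble of probe-level beta values.
#' @export
read_methylation <- function(path) {
  meth <- read_tsv_quiet(path, readr::cols(
    probe_id = readr::col_character(),
    gene = readr::col_character(),
    dist_tss = readr::col_integer(),
    beta = readr::col_double(),
    sample = readr::col_character()
  ))
  validate_methylation(meth, path)
}

#' @rdname read_methylation
#' @param meth In-memory methylation tibble to validate.
#' @export
validate_methylation <- function(meth, path = "<methylation>") {
  bad <- which(meth$beta < 0 | meth$beta > 1)
  if (length(bad)) stop_row(path, bad[1], sprintf("beta value %g outside [0,1]", meth$beta[bad[1]]))
  meth
}

#' @rdname read_methylation
#' @param methylation Methylation tibble.
#' @export
write_methylation <- function(methylation, path) {
  readr::write_tsv(methylation, path, progress = FALSE)
  invisible(path)
}

#' Gene panels
#'
#' A panel is the set of genes the germline screen is restricted to. Symbols
#' are upper-cased and deduplicated; membership tests are case-sensitive
#' after that normalization. The file format is one symbol per line;
#' `# version: <label>` comment lines set the version label.
#'
#' @param genes Character vector of gene symbols.
#' @param version_label Free-text version label.
#' @return A `gene_panel` (character vector with a version attribute).
#' @export
gene_panel <- function(genes, version_label = "unversioned") {
  genes <- toupper(trimws(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("a gene panel must contain at least one gene", call. = FALSE)
  if (anyDuplicated(genes)) {
    warning("duplicate panel symbols deduplicated: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
    genes <- unique(genes)
  }
  structure(genes, version_label = version_label, class = "gene_panel")
}

#' @rdname gene_panel
#' @param path Panel file path.
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  version <- sub("^#\\s*version:\\s*", "", grep("^#\\s*version:", lines, value = TRUE))
  genes <- lines[!grepl("^#", lines)]
  gene_panel(genes, version_label = if (length(version)) version[1] else "unversioned")
}

#' @rdname gene_panel
#' @param panel A `gene_panel`.
#' @export
write_panel <- function(panel, path) {
  writeLines(c(paste0("# version: ", attr(panel, "version_label")), as.character(panel)), path)
  invisible(path)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes (version: %s)\n", length(x), attr(x, "version_label")))
  utils::head(as.character(x), 10) |> paste(collapse = ", ") |> cat("\n")
  invisible(x)
}

mesenchymal_levels <- c("known", "suggested", "semi", "none")
inheritance_levels <- c("dominant", "recessive", "unknown")

#' Read the gene-to-syndrome knowledge table
#'
#' TSV columns: `gene`, `syndrome` (free text, `none` if no associated
#' syndrome), `inheritance` (dominant/recessive/unknown),
#' `truncation_is_mechanism` (logical), `mesenchymal_association`
#' (known/suggested/semi/none) and `surveillance_exists` (logical). Genes
#' absent from the table fall back to a default row
#' (unknown inheritance, no associations) with a warning at lookup time.
#'
#' @param path TSV path.
#' @return Knowledge tibble.
#' @export
read_knowledge <- function(path) {
  kn <- read_tsv_quiet(path, readr::cols(
    gene = readr::col_character(),
    syndrome = readr::col_character(),
    inheritance = readr::col_character(),
    truncation_is_mechanism = readr::col_logical(),
    mesenchymal_association = readr::col_character(),
    surveillance_exists = readr::col_logical()
  ))
  validate_knowledge(kn, path)
}

validate_knowledge <- function(kn, path = "<knowledge>") {
  check_enum(kn$inheritance, inheritance_levels, "inheritance", path)
  check_enum(kn$mesenchymal_association, mesenchymal_levels, "mesenchymal_association", path)
  kn
}

#' @rdname read_knowledge
#' @param knowledge Knowledge tibble.
#' @export
write_knowledge <- function(knowledge, path) {
  readr::write_tsv(knowledge, path, progress = FALSE)
  invisible(path)
}

default_knowledge_row <- function(gene) {
  tibble::tibble(gene = gene, syndrome = "none", inheritance = "unknown",
                 truncation_is_mechanism = FALSE,
                 mesenchymal_association = "none", surveillance_exists = FALSE)
}

#' Read a ClinVar-style assertion table
#'
#' TSV columns: `chrom`, `pos`, `ref`, `alt`, `classification` (benign,
#' likely_benign, vus, likely_pathogenic, pathogenic, conflicting, none),
#' `blb_submitters` (count of benign/likely-benign submitters) and
#' `cancer_syndrome_assoc` (logical). A classification of `none` must carry
#' a submitter count of 0.
#'
#' @param path TSV path.
#' @return Assertion tibble keyed by `key`.
#' @export
read_clinvar <- function(path) {
  cv <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    classification = readr::col_character(),
    blb_submitters = readr::col_integer(),
    cancer_syndrome_assoc = readr::col_logical()
  ))
  validate_clinvar(cv, path)
}

validate_clinvar <- function(cv, path = "<clinvar>") {
  check_enum(cv$classification, clinvar_levels, "classification", path)
  bad <- which(cv$blb_submitters < 0)
  if (length(bad)) stop_row(path, bad[1], "blb_submitters must be >= 0")
  bad <- which(cv$classification == "none" & cv$blb_submitters != 0)
  if (length(bad)) stop_row(path, bad[1], "classification 'none' requires 0 submitters")
  dplyr::mutate(cv, key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
}

#' @rdname read_clinvar
#' @param clinvar Assertion tibble.
#' @export
write_clinvar <- function(clinvar, path) {
  readr::write_tsv(dplyr::select(clinvar, -dplyr::any_of("key")), path, progress = FALSE)
  invisible(path)
}

#' Read a local variant database count table
#'
#' TSV columns: `chrom`, `pos`, `ref`, `alt`, `occurrence_count`,
#' `database_size` (number of cases in the local assertion cohort). Counts
#' must satisfy `0 <= occurrence_count <= 2 * database_size` (diploid
#' upper bound).
#'
#' @param path TSV path.
#' @return Count tibble keyed by `key`.
#' @export
read_local_db <- function(path) {
  db <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    occurrence_count = readr::col_integer(),
    database_size = readr::col_integer()
  ))
  validate_local_db(db, path)
}

validate_local_db <- function(db, path = "<local_db>") {
  bad <- which(db$occurrence_count < 0 | db$occurrence_count > 2L * db$database_size)
  if (length(bad)) stop_row(path, bad[1], "occurrence_count outside [0, 2 * database_size]")
  dplyr::mutate(db, key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
}

#' @rdname read_local_db
#' @param local_db Count tibble.
#' @export
write_local_db <- function(local_db, path) {
  readr::write_tsv(dplyr::select(local_db, -dplyr::any_of("key")), path, progress = FALSE)
  invisible(path)
}

#' Read per-case clinical metadata
#'
#' TSV columns: `case_id`, `diagnosis`, `category` (one of the eight
#' histopathological categories), `malignant`, `sex`, `age`,
#' `radiotherapy`, `chemotherapy`, `ploidy` (tumor average copy number,
#' default 2), `no_tumor_tissue`, optional `fulfils_criteria` and
#' `assessment_override`.
#'
#' @param path TSV path.
#' @return Case tibble.
#' @export
read_cases <- function(path) {
  readr::read_tsv(path, progress = FALSE, na = c("", "NA"), col_types = readr::cols(
    case_id = readr::col_character(),
    diagnosis = readr::col_character(),
    category = readr::col_character(),
    malignant = readr::col_logical(),
    sex = readr::col_character(),
    age = readr::col_double(),
    .default = readr::col_guess()
  ))
}

#' @rdname read_cases
#' @param cases Case tibble.
#' @export
write_cases <- function(cases, path) {
  readr::write_tsv(cases, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-interaction table for pathway expansion
#'
#' TSV columns `gene`, `partner`: `partner` genes are searched for somatic
#' hits when `gene` carries an unexplained germline first hit.
#'
#' @param path TSV path.
#' @return Interaction tibble.
#' @export
read_interactions <- function(path) {
  read_tsv_quiet(path, readr::cols(gene = readr::col_character(),
                                   partner = readr::col_character()))
}

#' @rdname read_interactions
#' @param interactions Interaction tibble.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_tsv(interactions, path, progress = FALSE)
  invisible(path)
}

#' Read a miniature gene map (gene intervals and TSS)
#'
#' TSV columns: `gene`, `chrom`, `start`, `end` (0-based half-open),
#' `tss` (0-based position of the transcription start site).
#'
#' @param path TSV path.
#' @return Gene-map tibble.
#' @export
read_gene_map <- function(path) {
  gm <- read_tsv_quiet(path, readr::cols(
    gene = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    tss = readr::col_integer()
  ))
  bad <- which(!(gm$start < gm$end))
  if (length(bad)) stop_row(path, bad[1], "start must be < end")
  gm
}

#' @rdname read_gene_map
#' @param gene_map Gene-map tibble.
#' @export
write_gene_map <- function(gene_map, path) {
  readr::write_tsv(gene_map, path, progress = FALSE)
  invisible(path)
}
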