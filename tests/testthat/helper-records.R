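# builders for single-variant fixtures, with neutral defaults

make_record <- function(case_id = "case1", gene = "CHEK2", chrom = "chr22",
                        pos = 1000L, ref = "C", alt = "T",
                        consequence = "missense", genotype = "het",
                        population_af = 0,
                        clinvar_classification = "none",
                        clinvar_blb_submitters = 0L,
                        clinvar_cancer_assoc = FALSE,
                        local_count = 0L, ...) {
  tibble::tibble(
    case_id = case_id, chrom = chrom, pos = pos, start = pos - 1L,
    end = pos - 1L + nchar(ref), ref = ref, alt = alt,
    key = variant_key(chrom, pos, ref, alt), gene = gene,
    consequence = consequence, genotype = genotype,
    population_af = population_af,
    clinvar_classification = clinvar_classification,
    clinvar_blb_submitters = clinvar_blb_submitters,
    clinvar_cancer_assoc = clinvar_cancer_assoc,
    local_count = local_count, ...
  )
}

make_knowledge <- function(gene = "CHEK2", syndrome = "CHEK2-related cancer risk",
                           inheritance = "dominant",
                           truncation_is_mechanism = TRUE,
                           mesenchymal_association = "none",
                           surveillance_exists = TRUE) {
  tibble::tibble(gene = gene, syndrome = syndrome, inheritance = inheritance,
                 truncation_is_mechanism = truncation_is_mechanism,
                 mesenchymal_association = mesenchymal_association,
                 surveillance_exists = surveillance_exists)
}

make_somatic <- function(case_id = "case1", gene = "SDHA", vaf = 0.4,
                         consequence = "missense", depth = 100L,
                         population_af = 0, chrom = "chr1", pos = 5000L) {
  tibble::tibble(
    case_id = case_id, chrom = chrom, pos = pos, start = pos - 1L,
    end = pos, ref = "G", alt = "A",
    key = variant_key(chrom, pos, "G", "A"), gene = gene,
    consequence = consequence, vaf = vaf, depth = depth,
    population_af = population_af, filter = "PASS"
  )
}

# independent brute-force evaluation of the three benign-evidence exclusion
# rules, written as separate predicates (the oracle for the rule engine)
oracle_rule_A <- function(blb, local, csq, cfg) blb > cfg$clinvar_benign_submitters_max
oracle_rule_B <- function(blb, local, csq, cfg) csq == "synonymous" && local > cfg$local_count_synonymous_max
oracle_rule_C <- function(blb, local, csq, cfg) blb == 1 && local > cfg$local_count_single_submitter_max

oracle_exclusion <- function(blb, local, csq, cfg = threshold_config()) {
  if (oracle_rule_A(blb, local, csq, cfg)) return("excluded_rule_A")
  if (oracle_rule_B(blb, local, csq, cfg)) return("excluded_rule_B")
  if (oracle_rule_C(blb, local, csq, cfg)) return("excluded_rule_C")
  "keep"
}

# independent sort-and-index percentile oracle for expression aberrancy
oracle_expression <- function(values, idx, tail_percent = 5) {
  n <- length(values)
  sorted <- sort(values)
  k <- as.integer(ceiling(tail_percent / 100 * n))
  x <- values[idx]
  if (x <= sorted[k]) return("expression_low")
  if (x >= sorted[n - k + 1L]) return("expression_high")
  "none"
}

write_lines_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".vcf")
  writeLines(lines, path)
  path
}

germline_vcf_header <- c(
  "##fileformat=VCFv4.2",
  '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
  '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
  '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population AF">',
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
)

somatic_vcf_header <- c(
  "##fileformat=VCFv4.2",
  '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
  '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
  '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population AF">',
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
  '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tT1"
)
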