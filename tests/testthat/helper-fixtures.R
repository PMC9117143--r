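# shared fixture builders: everything is generated in code at test time

# a variant row with sensible defaults, overridable per field
variant_row <- function(sample_id = "S1", gene = "TP53", position = 7577120L,
                        ref = "C", alt = "T", variant_class = "SNV",
                        allele_frequency = 0.05, in_population_db = FALSE,
                        is_known_driver = FALSE, germline_flag = "unknown") {
  tibble::tibble(
    sample_id = sample_id, gene = gene, position = as.integer(position),
    ref = ref, alt = alt, variant_class = variant_class,
    allele_frequency = allele_frequency, in_population_db = in_population_db,
    is_known_driver = is_known_driver, germline_flag = germline_flag
  )
}

# small panel for unit fixtures
tiny_panel <- function(total_mb = 1.1) {
  btmb_panel(
    c("TP53", "KRAS", "EGFR", "LRP1B", "CDKN2A"),
    total_mb = total_mb,
    drivers = tibble::tibble(
      gene = "KRAS", position = 25398284L, ref = "C", alt = "A"
    ),
    population_snps = tibble::tibble(position = 55249063L, ref = "G", alt = "A")
  )
}

# random variant table for property tests: mixed classes, AFs, flags
random_variants <- function(n, sample_id = "S1") {
  genes <- c("TP53", "KRAS", "EGFR", "LRP1B", "CDKN2A")
  cls <- sample(c("SNV", "insertion", "deletion"), n, replace = TRUE,
                prob = c(0.7, 0.15, 0.15))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- unname(vapply(
    ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1)
  ))
  ins <- cls == "insertion"
  del <- cls == "deletion"
  alt[ins] <- paste0(ref[ins], "T")
  ref[del] <- paste0(ref[del], "T")
  alt[del] <- substr(ref[del], 1, 1)
  variant_row(
    sample_id = sample_id,
    gene = sample(genes, n, replace = TRUE),
    position = sample.int(1e6, n, replace = FALSE),
    ref = ref, alt = alt, variant_class = cls,
    allele_frequency = runif(n)^2, # dense near 0, occasional germline-like
    in_population_db = runif(n) < 0.15,
    is_known_driver = runif(n) < 0.1
  )
}

# brute-force one-liner oracle for the bTMB count, independent of the
# grouped/deduplicating pipeline implementation
oracle_btmb_count <- function(v, af_min = 0.005, band = 0.05) {
  germ <- v$in_population_db | abs(v$allele_frequency - 0.5) <= band |
    v$allele_frequency >= 1 - band
  q <- v[v$variant_class == "SNV" & !germ & v$allele_frequency >= af_min &
           !v$is_known_driver, ]
  length(unique(paste(q$position, q$ref, q$alt)))
}

oracle_msaf <- function(v, band = 0.05) {
  germ <- v$in_population_db | abs(v$allele_frequency - 0.5) <= band |
    v$allele_frequency >= 1 - band
  af <- v$allele_frequency[v$variant_class == "SNV" & !germ &
                             v$allele_frequency < 0.20]
  if (length(af) == 0) 0 else max(af)
}

# write a variant table as a minimal VCF 4.2 fixture (single sample,
# FORMAT/AF), for the dual-dialect round-trip tests
write_vcf_fixture <- function(variants, path) {
  stopifnot(length(unique(variants$sample_id)) == 1)
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=DB,Number=0,Type=Flag,Description="dbSNP membership">',
    '##INFO=<ID=DRIVER,Number=0,Type=Flag,Description="Known driver">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Allele frequency">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", unique(variants$sample_id), sep = "\t")
  )
  info <- paste0(
    "GENE=", variants$gene,
    ifelse(variants$in_population_db, ";DB", ""),
    ifelse(variants$is_known_driver, ";DRIVER", "")
  )
  body <- paste("chr1", variants$position, ".", variants$ref, variants$alt,
                ".", "PASS", info, "AF",
                format(variants$allele_frequency, scientific = FALSE),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# clinical cohort fixture
tiny_clinical <- function() {
  tibble::tibble(
    id = c("P1", "P2", "P3"),
    age = c(64, 71, 58),
    sex = c("male", "female", "male"),
    smoking = c("former", "never", "current"),
    histology = c("squamous", "non-squamous", "non-squamous"),
    pdl1_status = c("positive", "negative", "missing"),
    sld_mm = c(42.4, 70, 55.1),
    n_target_lesions = c(2L, 3L, 1L),
    confirmed_response = c(1L, 0L, 0L),
    pfs_time = c(5.2, 3.1, 12.0),
    pfs_event = c(1L, 1L, 0L),
    os_time = c(14.8, 9.7, 12.0),
    os_event = c(1L, 1L, 0L)
  )
}
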