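#' Read a variant-call table
#'
#' Reads per-sample ctDNA variant calls from either a 9-column TSV dialect
#' (columns `sample_id`, `gene`, `position`, `ref`, `alt`, `variant_class`,
#' `allele_frequency`, `in_population_db`, `is_known_driver`) or a VCF v4.x
#' subset. Both dialects yield the same tibble, one row per called
#' alteration, with 1-based coordinates and allele frequency stored as a
#' fraction (a trailing `"%"` is divided by 100).
#'
#' In the VCF dialect the allele frequency is taken from the per-sample
#' FORMAT field named `af_field` when genotype columns are present
#' (one output row per sample with a non-missing value), otherwise from the
#' INFO field of that name (sample id then falls back to the INFO `SAMPLE`
#' key or the file name). Gene symbols come from the INFO `GENE` key, the
#' population-database flag from the standard `DB` flag, and driver status
#' from a `DRIVER` flag.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param af_field Name of the VCF AF field (FORMAT or INFO). Default `"AF"`.
#' @param panel Optional [btmb_panel()]; when supplied the calls are passed
#'   through [annotate_variants()].
#' @param unknown_genes Passed to [annotate_variants()].
#' @return A tibble of variant calls with a `germline_flag` column
#'   initialised to `"unknown"` (assigned later by [classify_germline()]).
#' @export
read_variant_table <- function(path, dialect = c("auto", "tsv", "vcf"),
                               af_field = "AF", panel = NULL,
                               unknown_genes = c("error", "drop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  variants <- switch(dialect,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path, af_field = af_field)
  )
  variants <- validate_variants(variants)
  if (!is.null(panel)) {
    variants <- annotate_variants(variants, panel, unknown_genes = unknown_genes)
  }
  variants
}

variant_columns <- c(
  "sample_id", "gene", "position", "ref", "alt", "variant_class",
  "allele_frequency", "in_population_db", "is_known_driver"
)

read_variant_tsv <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      gene = readr::col_character(),
      position = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      variant_class = readr::col_character(),
      allele_frequency = readr::col_character(),
      in_population_db = readr::col_integer(),
      is_known_driver = readr::col_integer()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(variant_columns, names(tab))
  if (length(missing_cols) > 0) {
    stop_format(sprintf(
      "variant TSV is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  tab$allele_frequency <- parse_af(tab$allele_frequency, path)
  tab$in_population_db <- as.logical(tab$in_population_db)
  tab$is_known_driver <- as.logical(tab$is_known_driver)
  tab$germline_flag <- "unknown"
  as_tibble(tab[c(variant_columns, "germline_flag")])
}

# AF values may be fractions ("0.052") or percentages ("5.2%")
parse_af <- function(x, path = "<input>") {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  out <- suppressWarnings(as.numeric(sub("%$", "", x)))
  out[pct] <- out[pct] / 100
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop_format(sprintf(
      "%s: unparseable allele frequency in record(s) %s",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  nomiss <- which(is.na(x))
  if (length(nomiss) > 0) {
    stop_format(sprintf(
      "%s: missing allele frequency in record(s) %s",
      path, paste(head(nomiss, 5), collapse = ", ")
    ))
  }
  out
}

read_variant_vcf <- function(path, af_field = "AF") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_variant_table())
  }
  info_gene <- vcfR::extract.info(vcf, "GENE")
  # Flag-type keys have no "=value" part, so match them in the raw INFO
  info_raw <- vcfR::getINFO(vcf)
  info_db <- grepl("(^|;)DB(;|$)", info_raw)
  info_driver <- grepl("(^|;)DRIVER(;|$)", info_raw)

  has_gt <- !is.null(vcf@gt) && ncol(vcf@gt) > 1
  fmt_af <- NULL
  if (has_gt) {
    fmt_af <- tryCatch(
      vcfR::extract.gt(vcf, element = af_field, as.numeric = FALSE),
      error = function(e) NULL
    )
    if (!is.null(fmt_af) && all(is.na(fmt_af))) fmt_af <- NULL
  }

  base <- tibble(
    gene = as.character(info_gene),
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    in_population_db = info_db,
    is_known_driver = info_driver
  )
  if (any(is.na(base$gene))) {
    stop_format(sprintf(
      "%s: missing GENE INFO key in record(s) %s",
      path, paste(head(which(is.na(base$gene)), 5), collapse = ", ")
    ))
  }

  if (!is.null(fmt_af)) {
    rows <- purrr::map_dfr(colnames(fmt_af), function(s) {
      af_chr <- fmt_af[, s]
      keep <- !is.na(af_chr) & af_chr != "."
      if (!any(keep)) {
        return(tibble())
      }
      out <- base[keep, , drop = FALSE]
      out$sample_id <- s
      out$allele_frequency <- parse_af(af_chr[keep], path)
      out
    })
  } else {
    af_chr <- vcfR::extract.info(vcf, af_field)
    if (all(is.na(af_chr))) {
      stop_format(sprintf(
        "%s: no `%s` field found in FORMAT or INFO", path, af_field
      ))
    }
    if (any(is.na(af_chr))) {
      stop_format(sprintf(
        "%s: missing `%s` in record(s) %s",
        path, af_field, paste(head(which(is.na(af_chr)), 5), collapse = ", ")
      ))
    }
    sample_info <- vcfR::extract.info(vcf, "SAMPLE")
    sid <- if (all(is.na(sample_info))) {
      sub("\\.vcf(\\.gz)?$", "", basename(path), ignore.case = TRUE)
    } else {
      as.character(sample_info)
    }
    rows <- base
    rows$sample_id <- sid
    rows$allele_frequency <- parse_af(af_chr, path)
  }

  rows$variant_class <- infer_variant_class(rows$ref, rows$alt, path)
  rows$germline_flag <- "unknown"
  as_tibble(rows[c(variant_columns, "germline_flag")])
}

infer_variant_class <- function(ref, alt, path = "<input>") {
  nr <- nchar(ref)
  na_ <- nchar(alt)
  cls <- dplyr::case_when(
    nr == 1 & na_ == 1 ~ "SNV",
    na_ > nr ~ "insertion",
    na_ < nr ~ "deletion",
    TRUE ~ NA_character_
  )
  if (any(is.na(cls))) {
    stop_format(sprintf(
      "%s: unsupported multi-nucleotide REF/ALT in record(s) %s",
      path, paste(head(which(is.na(cls)), 5), collapse = ", ")
    ))
  }
  cls
}

empty_variant_table <- function() {
  tibble(
    sample_id = character(), gene = character(), position = integer(),
    ref = character(), alt = character(), variant_class = character(),
    allele_frequency = double(), in_population_db = logical(),
    is_known_driver = logical(), germline_flag = character()
  )
}

#' Validate a variant tibble
#'
#' Checks column presence, allele-frequency range, coordinate positivity and
#' the consistency of `variant_class` with REF/ALT lengths (an SNV must be a
#' single-base substitution).
#'
#' @param variants Variant tibble.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_variants <- function(variants) {
  missing_cols <- setdiff(variant_columns, names(variants))
  if (length(missing_cols) > 0) {
    stop_format(sprintf(
      "variant table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"germline_flag" %in% names(variants)) variants$germline_flag <- "unknown"
  af <- variants$allele_frequency
  bad <- which(!is.finite(af) | af < 0 | af > 1)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "allele frequency outside [0, 1] in record(s) %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (any(variants$position < 1, na.rm = TRUE)) {
    stop_validation("positions must be 1-based positive coordinates")
  }
  is_snv <- variants$variant_class == "SNV"
  bad_snv <- which(is_snv & (nchar(variants$ref) != 1 | nchar(variants$alt) != 1))
  if (length(bad_snv) > 0) {
    stop_validation(sprintf(
      "SNV with multi-base REF/ALT in record(s) %s",
      paste(head(bad_snv, 5), collapse = ", ")
    ))
  }
  ok_class <- variants$variant_class %in% c("SNV", "insertion", "deletion")
  if (!all(ok_class)) {
    stop_validation(sprintf(
      "unknown variant_class in record(s) %s",
      paste(head(which(!ok_class), 5), collapse = ", ")
    ))
  }
  as_tibble(variants)
}

#' Write a variant tibble in the TSV dialect
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants[variant_columns]
  out$in_population_db <- as.integer(out$in_population_db)
  out$is_known_driver <- as.integer(out$is_known_driver)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

clinical_required <- c(
  "id", "age", "sex", "smoking", "histology", "pdl1_status", "sld_mm",
  "n_target_lesions", "confirmed_response", "pfs_time", "pfs_event",
  "os_time", "os_event"
)

#' Read a patient-level clinical table
#'
#' CSV with one row per patient carrying baseline covariates, the confirmed
#' best-response flag and right-censored PFS/OS endpoints (`*_time` in
#' months, `*_event` 1 = event, 0 = censored). A missing PD-L1 result is
#' kept as an explicit `"missing"` level, never dropped. Optional `msaf`
#' and `btmb_score` columns are preserved when present.
#'
#' @param path CSV path.
#' @return A tibble, one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(clinical_required, names(tab))
  if (length(missing_cols) > 0) {
    stop_format(sprintf(
      "clinical table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tab$pdl1_status <- as.character(tab$pdl1_status)
  tab$pdl1_status[is.na(tab$pdl1_status) | tab$pdl1_status == ""] <- "missing"
  validate_clinical(as_tibble(tab))
}

#' Validate a clinical tibble
#'
#' Rejects negative survival times and non-binary event flags, listing the
#' offending rows.
#'
#' @param patients Clinical tibble.
#' @return The tibble, validated.
#' @export
validate_clinical <- function(patients) {
  bad_time <- which(patients$pfs_time < 0 | patients$os_time < 0)
  if (length(bad_time) > 0) {
    stop_validation(sprintf(
      "negative survival time in row(s) %s",
      paste(head(bad_time, 10), collapse = ", ")
    ))
  }
  flags <- c("pfs_event", "os_event", "confirmed_response")
  for (f in flags) {
    bad <- which(!(patients[[f]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "`%s` must be 0/1; offending row(s): %s",
        f, paste(head(bad, 10), collapse = ", ")
      ))
    }
  }
  bad_pdl1 <- which(!(patients$pdl1_status %in% c("positive", "negative", "missing")))
  if (length(bad_pdl1) > 0) {
    stop_validation(sprintf(
      "`pdl1_status` must be positive/negative/missing; offending row(s): %s",
      paste(head(bad_pdl1, 10), collapse = ", ")
    ))
  }
  patients
}

#' Write a clinical tibble as CSV
#'
#' @param patients Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(patients, path) {
  readr::write_csv(patients, path, progress = FALSE)
  invisible(path)
}
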