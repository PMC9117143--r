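#' Classify variant origin (somatic vs germline)
#'
#' Assigns the `germline_flag` column used by downstream scoring. A call is
#' flagged `"germline"` when it is a known population-database variant
#' (dbSNP/ExAC-style membership, the `in_population_db` flag) or when its
#' allele frequency falls within `af_germline_band` of the heterozygous
#' (0.5) or homozygous (1.0) germline expectation. The band rule is a
#' declared surrogate for proprietary somatic-germline-zygosity classifiers:
#' in plasma, germline variants sit near 50% or 100% allele fraction while
#' tumor-derived fragments are diluted to low fractions, so an AF band
#' around those two anchors captures rare germline variants missing from
#' population databases. Everything else is flagged `"somatic"`.
#'
#' @param variants Variant tibble (see [read_variant_table()]).
#' @param panel Optional [btmb_panel()]; when supplied, variants are first
#'   passed through [annotate_variants()] so `NA` database flags are filled
#'   from the panel's population-SNP set.
#' @param af_germline_band Half-width of the AF band around 0.5 and 1.0
#'   (default 0.05, i.e. \[0.45, 0.55\] and \[0.95, 1\] are germline-like).
#' @return The variant tibble with `germline_flag` set to `"somatic"` or
#'   `"germline"` on every row.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   sample_id = "S1", gene = "TP53", position = 1:3, ref = "C", alt = "T",
#'   variant_class = "SNV", allele_frequency = c(0.004, 0.05, 0.49),
#'   in_population_db = c(TRUE, FALSE, FALSE), is_known_driver = FALSE,
#'   germline_flag = "unknown"
#' )
#' classify_germline(v)$germline_flag # germline, somatic, germline
classify_germline <- function(variants, panel = NULL, af_germline_band = 0.05) {
  check_prob(af_germline_band, "af_germline_band")
  if (!is.null(panel)) variants <- annotate_variants(variants, panel)
  af <- variants$allele_frequency
  in_db <- variants$in_population_db
  in_db[is.na(in_db)] <- FALSE
  band <- (abs(af - 0.5) <= af_germline_band) | (af >= 1 - af_germline_band)
  variants$germline_flag <- ifelse(in_db | band, "germline", "somatic")
  variants
}
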