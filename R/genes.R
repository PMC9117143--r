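#' Gene-level alteration prevalence and bTMB association
#'
#' Exploratory genomic-landscape table. A sample carries an "altered" gene
#' when it has at least one called non-synonymous SNV, insertion or
#' deletion in that gene in the raw variant table — deliberately without
#' germline or driver filtering, mirroring how exploratory landscape
#' pipelines keep everything the caller emitted. Prevalence is computed in
#' the molecularly evaluable population (every sample present in the
#' variant table, whatever its MSAF); genes below `min_prevalence` there
#' are dropped. Each retained gene is then tested for association with
#' bTMB-high status (two-sided Fisher exact test of altered-sample counts,
#' high vs low among evaluable samples) with Benjamini-Hochberg adjustment
#' across the retained genes.
#'
#' @param variants Variant tibble (see [read_variant_table()]).
#' @param groups Tibble with `sample_id` and `btmb_group` (from
#'   [classify_btmb_group()]). Samples in the variant table but absent here
#'   are treated as non-evaluable (they still count in MEP prevalence).
#' @param min_prevalence Minimum MEP prevalence to retain a gene
#'   (default 0.02).
#' @return Tibble, one row per retained gene: `gene`, `n_mep`,
#'   `prevalence_mep`, `prevalence_high`, `prevalence_low`, `p_raw`,
#'   `p_adjusted`, sorted by adjusted then raw p.
#' @export
gene_prevalence <- function(variants, groups, min_prevalence = 0.02) {
  check_prob(min_prevalence, "min_prevalence")
  if (nrow(variants) == 0) stop_validation("empty variant table")
  if (!all(c("sample_id", "btmb_group") %in% names(groups))) {
    stop_validation("`groups` needs sample_id and btmb_group columns")
  }
  mep_ids <- unique(variants$sample_id)
  n_mep <- length(mep_ids)

  altered <- dplyr::distinct(variants, .data$sample_id, .data$gene)
  lab <- tibble(sample_id = mep_ids) |>
    dplyr::left_join(
      dplyr::select(groups, "sample_id", "btmb_group"),
      by = "sample_id"
    ) |>
    dplyr::mutate(btmb_group = as.character(.data$btmb_group)) |>
    dplyr::mutate(
      btmb_group = dplyr::coalesce(.data$btmb_group, "non_evaluable")
    )
  n_high <- sum(lab$btmb_group == "high")
  n_low <- sum(lab$btmb_group == "low")
  if (n_high == 0 || n_low == 0) {
    stop_validation("need at least one high and one low sample to test")
  }

  per_gene <- altered |>
    dplyr::left_join(lab, by = "sample_id") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_altered_mep = dplyr::n_distinct(.data$sample_id),
      n_altered_high = dplyr::n_distinct(.data$sample_id[.data$btmb_group == "high"]),
      n_altered_low = dplyr::n_distinct(.data$sample_id[.data$btmb_group == "low"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prevalence_mep = .data$n_altered_mep / n_mep,
      prevalence_high = .data$n_altered_high / n_high,
      prevalence_low = .data$n_altered_low / n_low
    ) |>
    dplyr::filter(.data$prevalence_mep >= min_prevalence)

  if (nrow(per_gene) == 0) {
    return(tibble(
      gene = character(), n_mep = integer(), prevalence_mep = double(),
      prevalence_high = double(), prevalence_low = double(),
      p_raw = double(), p_adjusted = double()
    ))
  }

  per_gene$p_raw <- purrr::map2_dbl(
    per_gene$n_altered_high, per_gene$n_altered_low,
    function(ah, al) {
      fisher.test(matrix(c(ah, n_high - ah, al, n_low - al), nrow = 2))$p.value
    }
  )
  per_gene$p_adjusted <- p.adjust(per_gene$p_raw, method = "BH")
  per_gene |>
    dplyr::mutate(n_mep = n_mep) |>
    dplyr::select(
      "gene", "n_mep", "prevalence_mep", "prevalence_high", "prevalence_low",
      "p_raw", "p_adjusted"
    ) |>
    dplyr::arrange(.data$p_adjusted, .data$p_raw, .data$gene)
}
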