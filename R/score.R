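#' Maximum somatic allele frequency (MSAF) per sample
#'
#' MSAF estimates the circulating-tumor-DNA fraction of a plasma sample: the
#' highest allele fraction among somatic-flagged base substitutions below
#' 20% (calls at or above 20% AF are excluded as likely germline or clonal
#' artifacts). Driver status does not exclude a call from MSAF. A sample
#' with no qualifying somatic substitution has MSAF 0.
#'
#' @param variants Variant tibble with `germline_flag` assigned (see
#'   [classify_germline()]).
#' @param sample_ids Optional character vector of samples to report; samples
#'   with no variant rows get MSAF 0. Defaults to the samples present.
#' @return Tibble with columns `sample_id`, `msaf`.
#' @export
compute_msaf <- function(variants, sample_ids = NULL) {
  check_germline_assigned(variants)
  eligible <- variants$variant_class == "SNV" &
    variants$germline_flag == "somatic" &
    variants$allele_frequency < 0.20
  sub <- variants[eligible, c("sample_id", "allele_frequency")]
  per <- if (nrow(sub) == 0) {
    tibble(sample_id = character(), msaf = double())
  } else {
    sub |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(msaf = max(.data$allele_frequency), .groups = "drop")
  }
  ids <- sample_ids %||% sort(unique(variants$sample_id))
  out <- tibble(sample_id = ids) |>
    dplyr::left_join(per, by = "sample_id") |>
    dplyr::mutate(msaf = dplyr::coalesce(.data$msaf, 0))
  out
}

check_germline_assigned <- function(variants) {
  if (!"germline_flag" %in% names(variants) ||
      any(variants$germline_flag == "unknown")) {
    stop_validation(
      "`germline_flag` not assigned; run classify_germline() first"
    )
  }
  invisible(variants)
}

#' Score blood tumor mutational burden per sample
#'
#' Counts, for each sample, the distinct somatic base substitutions
#' (`variant_class == "SNV"`, somatic `germline_flag`, allele frequency at
#' or above `af_min`, not flagged as a known driver) over the panel's coding
#' footprint, and converts the count to mutations per megabase. Distinct
#' means distinct `(position, ref, alt)` keys within a sample: a key called
#' twice counts once. Insertions and deletions are never counted.
#'
#' Samples whose MSAF falls below `msaf_threshold` are non-evaluable — the
#' assay lacks sensitivity at low tumor fraction — and their `btmb_score`
#' and `mut_per_mb` are masked to `NA` (MSAF itself is still reported).
#'
#' @param variants Variant tibble with `germline_flag` assigned.
#' @param panel A [btmb_panel()]; its `total_mb` is the conversion
#'   denominator.
#' @param af_min Minimum allele frequency for a substitution to count
#'   (default 0.005, i.e. 0.5%, inclusive).
#' @param msaf_threshold Minimum MSAF for an evaluable sample (default 0.01,
#'   inclusive).
#' @param sample_ids Optional samples to report (see [compute_msaf()]).
#' @return A tibble of class `btmb_result`, one row per sample:
#'   `sample_id`, `msaf`, `evaluable`, `btmb_score`, `mut_per_mb`,
#'   `counted_variant_keys` (list column of `"POS:REF:ALT"` keys).
#' @export
compute_btmb <- function(variants, panel, af_min = 0.005,
                         msaf_threshold = 0.01, sample_ids = NULL) {
  if (!inherits(panel, "btmb_panel") || panel$total_mb <= 0) {
    stop_config("`panel` must be a btmb_panel with positive total_mb")
  }
  check_prob(af_min, "af_min")
  check_prob(msaf_threshold, "msaf_threshold")
  check_germline_assigned(variants)

  msaf <- compute_msaf(variants, sample_ids = sample_ids)

  qualifying <- variants$variant_class == "SNV" &
    variants$germline_flag == "somatic" &
    variants$allele_frequency >= af_min &
    !variants$is_known_driver
  counted <- variants[qualifying, c("sample_id", "position", "ref", "alt")] |>
    dplyr::mutate(key = sprintf("%d:%s:%s", .data$position, .data$ref, .data$alt)) |>
    dplyr::distinct(.data$sample_id, .data$key) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(keys = list(.data$key), .groups = "drop")

  out <- msaf |>
    dplyr::left_join(counted, by = "sample_id") |>
    dplyr::mutate(
      counted_variant_keys = purrr::map(.data$keys, ~ .x %||% character()),
      evaluable = .data$msaf >= msaf_threshold,
      btmb_score = ifelse(
        .data$evaluable,
        purrr::map_int(.data$counted_variant_keys, length),
        NA_integer_
      ),
      mut_per_mb = .data$btmb_score / panel$total_mb
    ) |>
    dplyr::select(
      "sample_id", "msaf", "evaluable", "btmb_score", "mut_per_mb",
      "counted_variant_keys"
    )
  # non-evaluable samples do not report a counted set either
  out$counted_variant_keys[!out$evaluable] <- list(character())
  class(out) <- c("btmb_result", class(out))
  out
}

#' Assign bTMB high/low status at a cutoff
#'
#' Adds a `btmb_group` column: `"high"` when the sample is evaluable and its
#' score is at or above the cutoff (the boundary is inclusive — a score of
#' 16 at cutoff 16 is high), `"low"` when evaluable below the cutoff, and
#' `"non_evaluable"` otherwise, regardless of any score.
#'
#' @param result A `btmb_result` tibble from [compute_btmb()], or any tibble
#'   with `evaluable` and `btmb_score` columns.
#' @param cutoff Non-negative integer score cutoff (default 16, i.e.
#'   ~14.5 mut/Mb on a 1.1 Mb panel).
#' @return `result` with a `btmb_group` factor column
#'   (levels high, low, non_evaluable).
#' @export
classify_btmb_group <- function(result, cutoff = 16) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    stop_validation("`cutoff` must be a single non-negative number")
  }
  grp <- dplyr::case_when(
    !result$evaluable ~ "non_evaluable",
    result$btmb_score >= cutoff ~ "high",
    TRUE ~ "low"
  )
  result$btmb_group <- factor(grp, levels = c("high", "low", "non_evaluable"))
  result
}

#' Convert a bTMB score to mutations per megabase
#'
#' @param score Substitution count(s).
#' @param total_mb Panel coding footprint in megabases.
#' @return `score / total_mb`.
#' @export
#' @examples
#' mut_per_mb(16, 1.1) # 14.545..., prints as 14.5 at 1 d.p.
mut_per_mb <- function(score, total_mb = 1.1) {
  if (total_mb <= 0) stop_config("`total_mb` must be positive")
  score / total_mb
}
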