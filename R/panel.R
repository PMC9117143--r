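#' Assay panel definition
#'
#' A `btmb_panel` describes the hybrid-capture assay: the gene symbols it
#' targets, its coding footprint in megabases (the denominator of the
#' mutations-per-megabase conversion), the set of known driver alterations to
#' exclude from the burden count, and a population-SNP key set (dbSNP/ExAC
#' style membership) used for germline filtering.
#'
#' Driver keys are `"GENE|POS:REF:ALT"`; population-SNP keys are
#' `"POS:REF:ALT"`. Coordinates are 1-based, as in VCF.
#'
#' @param genes Character vector of gene symbols.
#' @param total_mb Coding footprint in megabases; must be positive.
#' @param drivers Data frame with columns `gene`, `position`, `ref`, `alt`
#'   listing known driver alterations, or `NULL` for none.
#' @param population_snps Data frame with columns `position`, `ref`, `alt`
#'   of population-database variants, or `NULL` for none.
#' @return An object of class `btmb_panel`.
#' @export
#' @examples
#' p <- btmb_panel(c("TP53", "KRAS"), total_mb = 0.01)
#' p$total_mb
btmb_panel <- function(genes, total_mb, drivers = NULL, population_snps = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop_config("panel must target at least one gene")
  if (!is.numeric(total_mb) || length(total_mb) != 1 || !is.finite(total_mb) ||
      total_mb <= 0) {
    stop_config("`total_mb` must be a single positive number")
  }
  driver_keys <- character()
  if (!is.null(drivers) && nrow(drivers) > 0) {
    driver_keys <- unique(sprintf(
      "%s|%d:%s:%s", drivers$gene, as.integer(drivers$position),
      drivers$ref, drivers$alt
    ))
  }
  snp_keys <- character()
  if (!is.null(population_snps) && nrow(population_snps) > 0) {
    snp_keys <- unique(sprintf(
      "%d:%s:%s", as.integer(population_snps$position),
      population_snps$ref, population_snps$alt
    ))
  }
  structure(
    list(
      genes = genes,
      total_mb = total_mb,
      driver_set = driver_keys,
      population_snp_set = snp_keys
    ),
    class = "btmb_panel"
  )
}

#' @export
print.btmb_panel <- function(x, ...) {
  cat(sprintf(
    "<btmb_panel> %d genes, %.2f Mb coding footprint, %d driver keys, %d population-SNP keys\n",
    length(x$genes), x$total_mb, length(x$driver_set),
    length(x$population_snp_set)
  ))
  invisible(x)
}

#' Default synthetic 394-gene panel
#'
#' A synthetic stand-in for a 394-gene / 1.1 Mb ctDNA hybrid-capture panel.
#' The first symbols are recurrently mutated lung-cancer genes (so simulated
#' landscapes look familiar); the remainder are placeholder symbols. A small
#' driver hotspot list and population-SNP set are included so germline and
#' driver annotation can be exercised end to end. Every position is a
#' deterministic function of the gene index, not a real genomic coordinate.
#'
#' @return A [btmb_panel()] with 394 genes and `total_mb = 1.1`.
#' @export
default_panel <- function() {
  named <- c(
    "TP53", "LRP1B", "CDKN2A", "KRAS", "EGFR", "STK11", "KEAP1", "BRAF",
    "PIK3CA", "NF1", "SMARCA4", "RBM10", "ARID1A", "PTEN", "RB1", "MET",
    "ERBB2", "ALK", "ROS1", "RET"
  )
  genes <- c(named, sprintf("PANG%03d", seq_len(394 - length(named))))
  # synthetic hotspots: one canonical driver substitution per oncogene-like gene
  driver_genes <- c("TP53", "KRAS", "EGFR", "BRAF", "PIK3CA", "MET", "ERBB2")
  drivers <- tibble(
    gene = driver_genes,
    position = gene_base_position(match(driver_genes, genes)) + 500L,
    ref = "G",
    alt = "T"
  )
  snps <- tibble(
    position = gene_base_position(seq(1, 394, by = 8)) + 123L,
    ref = "A",
    alt = "G"
  )
  btmb_panel(genes, total_mb = 1.1, drivers = drivers, population_snps = snps)
}

# deterministic per-gene coordinate block (synthetic coordinates)
gene_base_position <- function(gene_index) as.integer(gene_index) * 100000L

#' Read or write a panel definition
#'
#' Panels are stored as a small YAML document with fields `genes`,
#' `total_mb`, `drivers` (list of `"GENE|POS:REF:ALT"` keys) and
#' `population_snps` (list of `"POS:REF:ALT"` keys).
#'
#' @param path File path.
#' @return `read_panel()` returns a [btmb_panel()]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("panel file not found: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$genes) || is.null(doc$total_mb)) {
    stop_format("panel file must define `genes` and `total_mb`")
  }
  panel <- btmb_panel(unlist(doc$genes), total_mb = doc$total_mb)
  panel$driver_set <- unique(as.character(unlist(doc$drivers)))
  panel$population_snp_set <- unique(as.character(unlist(doc$population_snps)))
  panel
}

#' @param panel A [btmb_panel()].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "btmb_panel"))
  yaml::write_yaml(
    list(
      genes = as.list(panel$genes),
      total_mb = panel$total_mb,
      drivers = as.list(panel$driver_set),
      population_snps = as.list(panel$population_snp_set)
    ),
    path
  )
  invisible(path)
}

#' Annotate variant calls against a panel
#'
#' Fills the `in_population_db` and `is_known_driver` flags from the panel's
#' key sets wherever the input left them `NA`; explicit flags on the input
#' are respected. Also checks gene membership: calls in genes outside the
#' panel are an error by default because the burden score is only defined
#' over the panel footprint.
#'
#' @param variants Variant tibble (see [read_variant_table()]).
#' @param panel A [btmb_panel()].
#' @param unknown_genes `"error"` (default) or `"drop"` with a warning.
#' @return The variant tibble with both flags filled.
#' @export
annotate_variants <- function(variants, panel,
                              unknown_genes = c("error", "drop")) {
  unknown_genes <- match.arg(unknown_genes)
  stopifnot(inherits(panel, "btmb_panel"))
  off <- !(variants$gene %in% panel$genes)
  if (any(off)) {
    bad <- unique(variants$gene[off])
    if (unknown_genes == "error") {
      stop_validation(sprintf(
        "%d call(s) in genes outside the panel: %s",
        sum(off), paste(head(bad, 5), collapse = ", ")
      ))
    }
    warn(sprintf("dropping %d call(s) in off-panel genes", sum(off)))
    variants <- variants[!off, , drop = FALSE]
  }
  snp_key <- sprintf("%d:%s:%s", variants$position, variants$ref, variants$alt)
  drv_key <- sprintf("%s|%s", variants$gene, snp_key)
  variants$in_population_db <- ifelse(
    is.na(variants$in_population_db),
    snp_key %in% panel$population_snp_set,
    variants$in_population_db
  )
  variants$is_known_driver <- ifelse(
    is.na(variants$is_known_driver),
    drv_key %in% panel$driver_set,
    variants$is_known_driver
  )
  variants
}
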