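test_that("germline classification: database membership or AF band", {
  v <- dplyr::bind_rows(
    variant_row(position = 1L, allele_frequency = 0.004, in_population_db = TRUE),
    variant_row(position = 2L, allele_frequency = 0.05),
    variant_row(position = 3L, allele_frequency = 0.49),
    variant_row(position = 4L, allele_frequency = 0.97),
    variant_row(position = 5L, allele_frequency = 0.56)
  )
  out <- classify_germline(v, af_germline_band = 0.05)
  expect_equal(out$germline_flag,
               c("germline", "somatic", "germline", "germline", "somatic"))
})

test_that("band rule matches brute-force application on an AF grid", {
  af <- seq(0, 1, by = 0.01)
  v <- variant_row(position = seq_along(af), allele_frequency = af)
  out <- classify_germline(v, af_germline_band = 0.05)
  manual <- ifelse(abs(af - 0.5) <= 0.05 | af >= 0.95, "germline", "somatic")
  expect_equal(out$germline_flag, manual)
})

test_that("MSAF is the max somatic substitution AF below 20%", {
  v <- classify_germline(dplyr::bind_rows(
    variant_row(position = 1L, allele_frequency = 0.004),
    variant_row(position = 2L, allele_frequency = 0.05),
    variant_row(position = 3L, allele_frequency = 0.25)
  ))
  expect_equal(compute_msaf(v)$msaf, 0.05) # the 0.25 call is excluded

  # driver status does not exclude a call from MSAF
  v2 <- classify_germline(dplyr::bind_rows(
    variant_row(position = 1L, allele_frequency = 0.12, is_known_driver = TRUE),
    variant_row(position = 2L, allele_frequency = 0.03)
  ))
  expect_equal(compute_msaf(v2)$msaf, 0.12)

  # no somatic substitutions at all -> MSAF 0
  v3 <- classify_germline(variant_row(allele_frequency = 0.5))
  expect_equal(compute_msaf(v3)$msaf, 0)
})

test_that("bTMB counting applies class, AF, origin and driver filters", {
  p <- tiny_panel()
  qualifying <- variant_row(
    position = 1:16, allele_frequency = runif(16, 0.01, 0.15)
  )
  extras <- dplyr::bind_rows(
    variant_row(position = 101L, variant_class = "insertion", ref = "A",
                alt = "AT", allele_frequency = 0.05),
    variant_row(position = 102L, allele_frequency = 0.004), # below 0.5%
    variant_row(position = 103L, allele_frequency = 0.06,
                is_known_driver = TRUE),
    variant_row(position = 104L, allele_frequency = 0.48) # germline band
  )
  v <- classify_germline(dplyr::bind_rows(qualifying, extras))
  res <- compute_btmb(v, p)
  expect_s3_class(res, "btmb_result")
  expect_true(res$evaluable)
  expect_equal(res$btmb_score, 16L)
  expect_equal(round_half_up(res$mut_per_mb, 1), 14.5) # 16 / 1.1 Mb
  expect_equal(length(res$counted_variant_keys[[1]]), 16)

  # the excluded driver still anchors MSAF when it is the max
  v2 <- classify_germline(dplyr::bind_rows(
    variant_row(position = 1L, allele_frequency = 0.06, is_known_driver = TRUE),
    variant_row(position = 2L, allele_frequency = 0.03)
  ))
  res2 <- compute_btmb(v2, p)
  expect_equal(res2$msaf, 0.06)
  expect_equal(res2$btmb_score, 1L)
})

test_that("duplicate (position, ref, alt) keys count once", {
  p <- tiny_panel()
  v <- classify_germline(dplyr::bind_rows(
    variant_row(position = 1L, allele_frequency = 0.05),
    variant_row(position = 1L, allele_frequency = 0.08),
    variant_row(position = 2L, allele_frequency = 0.05)
  ))
  expect_equal(compute_btmb(v, p)$btmb_score, 2L)
})

test_that("low-MSAF samples are non-evaluable with masked score", {
  p <- tiny_panel()
  v <- classify_germline(variant_row(allele_frequency = 0.008))
  res <- compute_btmb(v, p)
  expect_false(res$evaluable)
  expect_true(is.na(res$btmb_score))
  expect_true(is.na(res$mut_per_mb))
  expect_equal(res$msaf, 0.008) # MSAF itself still reported
  expect_equal(classify_btmb_group(res)$btmb_group,
               factor("non_evaluable", c("high", "low", "non_evaluable")))
})

test_that("group assignment boundary is inclusive", {
  mk <- function(score) tibble::tibble(evaluable = TRUE, btmb_score = score)
  expect_equal(as.character(classify_btmb_group(mk(16), 16)$btmb_group), "high")
  expect_equal(as.character(classify_btmb_group(mk(15), 16)$btmb_group), "low")
  expect_error(classify_btmb_group(mk(10), -1), class = "btmb_validation_error")
})

test_that("empty panel footprint is a configuration error", {
  expect_error(btmb_panel("TP53", total_mb = 0), class = "btmb_config_error")
  expect_error(mut_per_mb(16, 0), class = "btmb_config_error")
})

test_that("score equals brute-force filter-and-count on random fixtures", {
  set.seed(101)
  for (i in 1:60) {
    v <- classify_germline(random_variants(sample(5:60, 1)))
    res <- compute_btmb(v, tiny_panel(), msaf_threshold = 0)
    expect_equal(res$btmb_score, oracle_btmb_count(v))
    expect_equal(res$msaf, oracle_msaf(v))
  }
})

test_that("adding a qualifying substitution never decreases score or MSAF", {
  set.seed(202)
  p <- tiny_panel()
  for (i in 1:25) {
    v <- classify_germline(random_variants(sample(5:40, 1)))
    res <- compute_btmb(v, p, msaf_threshold = 0)
    extra <- classify_germline(variant_row(
      position = 2000000L + i, allele_frequency = runif(1, 0.005, 0.19)
    ))
    res2 <- compute_btmb(dplyr::bind_rows(v, extra), p, msaf_threshold = 0)
    expect_gte(res2$btmb_score, res$btmb_score)
    expect_gte(res2$msaf, res$msaf)
  }
})

test_that("removing all somatic variants forces MSAF 0 and non-evaluability", {
  set.seed(303)
  v <- classify_germline(random_variants(30))
  germ_only <- v[v$germline_flag == "germline", ]
  res <- compute_btmb(germ_only, tiny_panel(), sample_ids = "S1")
  expect_equal(res$msaf, 0)
  expect_false(res$evaluable)
})

test_that("mut_per_mb times total_mb recovers the score exactly", {
  set.seed(404)
  for (mb in c(0.8, 1.1, 2.4)) {
    v <- classify_germline(random_variants(40))
    res <- compute_btmb(v, tiny_panel(total_mb = mb), msaf_threshold = 0)
    expect_equal(res$mut_per_mb * mb, as.numeric(res$btmb_score))
  }
})
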