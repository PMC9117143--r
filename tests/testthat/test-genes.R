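# hand-rolled Benjamini-Hochberg step-up oracle: sort, m*p/i, cummin from top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}

# hypergeometric tail enumeration oracle for the two-sided Fisher test
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

grouped_fixture <- function(seed = 33) {
  sim <- simulate_cohort(sim_config(n_patients = 60, seed = seed))
  v <- classify_germline(sim$variants)
  res <- classify_btmb_group(
    compute_btmb(v, sim$panel, sample_ids = sim$clinical$id)
  )
  list(variants = sim$variants, groups = res)
}

test_that("prevalence denominators: MEP for the gate, high/low for testing", {
  fx <- grouped_fixture()
  tab <- gene_prevalence(fx$variants, fx$groups)
  n_mep <- length(unique(fx$variants$sample_id))
  expect_true(all(tab$n_mep == n_mep))
  expect_true(all(tab$prevalence_mep >= 0.02))
  expect_true(all(tab$prevalence_mep <= 1 & tab$prevalence_high <= 1 &
                    tab$prevalence_low <= 1))
  # prevalence recomputed by hand for the top gene
  g <- tab$gene[1]
  carriers <- unique(fx$variants$sample_id[fx$variants$gene == g])
  expect_equal(tab$prevalence_mep[1], length(carriers) / n_mep)
})

test_that("a gene altered in every sample of both groups has p_raw 1", {
  groups <- tibble::tibble(
    sample_id = sprintf("S%d", 1:10),
    btmb_group = rep(c("high", "low"), each = 5)
  )
  v <- variant_row(sample_id = groups$sample_id, gene = "TP53",
                   position = 1:10 * 10L)
  tab <- gene_prevalence(v, groups)
  expect_equal(tab$p_raw, 1)
  expect_equal(tab$p_adjusted, 1) # BH identity at m = 1
})

test_that("Fisher p equals hypergeometric enumeration on small tables", {
  set.seed(231)
  for (i in 1:25) {
    m <- sample(2:30, 1); n <- sample(2:30, 1)
    a <- sample(0:m, 1); c <- sample(0:n, 1)
    got <- fisher.test(matrix(c(a, m - a, c, n - c), 2))$p.value
    want <- oracle_fisher_two_sided(a, m - a, c, n - c)
    expect_equal(got, min(want, 1), tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand-rolled step-up oracle", {
  set.seed(241)
  for (i in 1:20) {
    p <- runif(sample(1:25, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))
  }
  # and the table's adjusted column is the oracle of its raw column
  fx <- grouped_fixture(seed = 35)
  tab <- gene_prevalence(fx$variants, fx$groups)
  expect_equal(tab$p_adjusted, oracle_bh(tab$p_raw))
  expect_true(all(tab$p_adjusted >= tab$p_raw))
  expect_true(all(tab$p_adjusted > 0 & tab$p_adjusted <= 1))
})

test_that("non-evaluable samples count in MEP but not in the comparison", {
  groups <- tibble::tibble(
    sample_id = sprintf("S%d", 1:9),
    btmb_group = c(rep("high", 3), rep("low", 3), rep("non_evaluable", 3))
  )
  # gene G1 altered only in the non-evaluable samples
  v <- dplyr::bind_rows(
    variant_row(sample_id = sprintf("S%d", 7:9), gene = "TP53",
                position = 1:3 * 7L),
    variant_row(sample_id = sprintf("S%d", 1:6), gene = "KRAS",
                position = 1:6 * 11L)
  )
  tab <- gene_prevalence(v, groups)
  tp53 <- tab[tab$gene == "TP53", ]
  expect_equal(tp53$prevalence_mep, 3 / 9)
  expect_equal(tp53$prevalence_high, 0)
  expect_equal(tp53$prevalence_low, 0)
})

test_that("planted enrichment is detected and germline calls still count", {
  # high-score samples carry many more mutated genes in the generator, so
  # hotspot genes should enrich in the high group and BH should keep order
  fx <- grouped_fixture(seed = 37)
  tab <- gene_prevalence(fx$variants, fx$groups)
  hot <- tab[tab$gene == "TP53", ]
  expect_gt(hot$prevalence_high, hot$prevalence_low)
  # the table uses raw calls: no germline filtering, so prevalence from the
  # unfiltered variants must match exactly even for population-SNP carriers
  raw_carriers <- length(unique(
    fx$variants$sample_id[fx$variants$gene == "TP53"]
  ))
  expect_equal(hot$prevalence_mep,
               raw_carriers / length(unique(fx$variants$sample_id)))
})

test_that("empty inputs are rejected", {
  expect_error(
    gene_prevalence(variant_row()[0, ],
                    tibble::tibble(sample_id = "S1", btmb_group = "high")),
    class = "btmb_validation_error"
  )
})
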