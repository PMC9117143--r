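#' Simulation configuration for a synthetic bTMB trial
#'
#' Bundles every knob of the synthetic trial generator with defaults
#' matching the emulated study conditions: 152 patients, 78% with adequate
#' ctDNA (MSAF >= 1%), a discretised log-normal bTMB score distribution
#' calibrated so about 24% of evaluable patients score >= 16, response
#' probabilities and exponential PFS/OS hazards that depend on the bTMB
#' group, baseline covariates shifted between the MSAF subgroups (age,
#' smoking, PD-L1 with 36% missingness, lesion count, tumor size), and a
#' per-patient ctDNA variant profile over the 394-gene / 1.1 Mb panel
#' (somatic substitutions with allele fractions tied to the sample's MSAF,
#' germline variants near 0.5/1.0 allele fraction, known drivers, indels,
#' sub-threshold calls).
#'
#' The log-normal score parameters are quantile-matched:
#' `meanlog = log(15.5) - sdlog * qnorm(1 - p_high)` puts probability
#' `p_high` above the 16 boundary after integer rounding.
#'
#' @param n_patients Cohort size (default 152).
#' @param seed Integer seed; the same config yields identical output.
#' @param prob_evaluable P(MSAF >= 1%) (default 0.78).
#' @param p_high Target P(score >= 16 | evaluable) (default 0.24).
#' @param btmb_sdlog Log-normal sdlog of the score distribution (0.8).
#' @param response_rates Named response probabilities for `high`, `low`,
#'   `non_evaluable` patients.
#' @param pfs_median,os_median Named exponential medians (months) per group.
#' @param score_loghr_per_mut Optional log-hazard slope per score unit; when
#'   non-zero, evaluable patients' hazards become
#'   `log(2)/base_median * exp(slope * (score - 10))` instead of the
#'   group-median model (used to plant a monotone cutoff-sweep effect).
#' @param censor_range Administrative censoring window in months,
#'   `runif(min, max)` per patient (default `c(0.5, 31.4)`).
#' @param af_min,msaf_threshold Scorer settings the generator calibrates to.
#' @param confound_strength Multiplier on the planted covariate effects in
#'   [simulate_confounded_msaf()] (0 = no confounding).
#' @return A list of class `btmb_sim_config`.
#' @export
sim_config <- function(n_patients = 152,
                       seed = 1,
                       prob_evaluable = 0.78,
                       p_high = 0.24,
                       btmb_sdlog = 0.8,
                       response_rates = c(high = 0.357, low = 0.055,
                                          non_evaluable = 0.379),
                       pfs_median = c(high = 5, low = 3.5,
                                      non_evaluable = 6.8),
                       os_median = c(high = 23.9, low = 13.4,
                                     non_evaluable = 20),
                       score_loghr_per_mut = 0,
                       censor_range = c(0.5, 31.4),
                       af_min = 0.005,
                       msaf_threshold = 0.01,
                       confound_strength = 1) {
  if (n_patients < 1) stop_validation("`n_patients` must be positive")
  if (prob_evaluable <= 0 || prob_evaluable > 1) {
    stop_validation(
      "`prob_evaluable` must lie in (0, 1]: the bTMB score targets are undefined with no evaluable patients"
    )
  }
  check_prob(p_high, "p_high")
  check_prob(response_rates, "response_rates")
  if (any(pfs_median <= 0) || any(os_median <= 0)) {
    stop_validation("survival medians must be positive (hazards > 0)")
  }
  grp <- c("high", "low", "non_evaluable")
  if (!all(grp %in% names(response_rates)) ||
      !all(grp %in% names(pfs_median)) || !all(grp %in% names(os_median))) {
    stop_validation("rate/median vectors need names high, low, non_evaluable")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      seed = as.integer(seed),
      prob_evaluable = prob_evaluable,
      p_high = p_high,
      btmb_sdlog = btmb_sdlog,
      # quantile matching: P(lognormal >= 15.5) = p_high before rounding
      btmb_meanlog = log(15.5) - btmb_sdlog * qnorm(1 - p_high),
      group_cutoff = 16L,
      response_rates = response_rates,
      pfs_median = pfs_median,
      os_median = os_median,
      score_loghr_per_mut = score_loghr_per_mut,
      score_hazard_base_median = 4,
      score_hazard_ref = 10,
      censor_range = censor_range,
      af_min = af_min,
      msaf_threshold = msaf_threshold,
      # MSAF (ctDNA fraction) model for evaluable / non-evaluable samples
      msaf_meanlog = log(0.05), msaf_sdlog = 0.8,
      msaf_nonev_range = c(0.0005, 0.0095),
      # per-sample variant profile
      germline_mean = 10, germline_hom_frac = 0.2, germline_db_frac = 0.85,
      chip_mean = 0.5, driver_prob = 0.6,
      indel_base = 0.3, indel_per_snv = 0.15, subthreshold_mean = 2,
      # baseline covariates, shifted between MSAF subgroups
      age_mean = c(lt1 = 64, ge1 = 69), age_sd = 9,
      smoking_never = 0.07, smoking_current = c(lt1 = 0.14, ge1 = 0.25),
      pdl1_missing = 0.36, pdl1_positive = c(lt1 = 0.52, ge1 = 0.38),
      sld_meanlog = c(lt1 = log(42.4), ge1 = log(70)), sld_sdlog = 0.5,
      lesions_mean = c(lt1 = 1.8, ge1 = 2.4),
      male_frac = 0.6,
      squamous = c(high = 0.46, low = 0.24, non_evaluable = 0.24),
      confound_strength = confound_strength
    ),
    class = "btmb_sim_config"
  )
}

#' Simulate a complete synthetic bTMB trial
#'
#' Draws a full synthetic cohort — clinical table, per-sample ctDNA variant
#' table and the panel — such that scoring the variant table with
#' [compute_btmb()] reproduces each patient's intended evaluability and
#' bTMB score exactly: the generator writes, for each evaluable patient,
#' exactly `score` somatic substitutions with allele fraction in
#' `[af_min, msaf]` (none a known driver), an anchoring call at the
#' sample's MSAF, plus germline, driver, indel and sub-threshold decoys
#' that the scoring filters must remove.
#'
#' @param config A [sim_config()].
#' @return A list of class `btmb_sim` with elements `clinical` (tibble
#'   including simulation-truth columns `msaf`, `true_btmb_score`,
#'   `true_evaluable`, `true_group`), `variants`, `panel`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "btmb_sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  panel <- default_panel()
  gene_w <- panel_gene_weights(panel)

  evaluable <- runif(n) < config$prob_evaluable
  msaf <- ifelse(
    evaluable,
    pmin(pmax(rlnorm(n, config$msaf_meanlog, config$msaf_sdlog), 0.0102), 0.198),
    runif(n, config$msaf_nonev_range[1], config$msaf_nonev_range[2])
  )
  score <- ifelse(
    evaluable,
    pmax(0L, as.integer(round(rlnorm(n, config$btmb_meanlog, config$btmb_sdlog)))),
    rpois(n, 1)
  )
  group <- ifelse(
    !evaluable, "non_evaluable",
    ifelse(score >= config$group_cutoff, "high", "low")
  )

  ids <- sprintf("P%03d", seq_len(n))
  variants <- purrr::map_dfr(seq_len(n), function(i) {
    simulate_sample_variants(
      ids[i], evaluable[i], msaf[i], score[i], config, panel, gene_w
    )
  })

  msaf_grp <- ifelse(evaluable, "ge1", "lt1")
  clinical <- tibble(
    id = ids,
    age = round(rnorm(n, config$age_mean[msaf_grp], config$age_sd)),
    sex = ifelse(runif(n) < config$male_frac, "male", "female"),
    smoking = draw_smoking(n, msaf_grp, config),
    histology = ifelse(runif(n) < config$squamous[group], "squamous", "non-squamous"),
    pdl1_status = draw_pdl1(n, msaf_grp, config),
    sld_mm = round(rlnorm(n, config$sld_meanlog[msaf_grp], config$sld_sdlog), 1),
    n_target_lesions = 1L + rpois(n, pmax(config$lesions_mean[msaf_grp] - 1, 0)),
    confirmed_response = rbinom(n, 1, config$response_rates[group]),
    msaf = msaf,
    true_btmb_score = ifelse(evaluable, score, NA_integer_),
    true_evaluable = evaluable,
    true_group = factor(group, levels = c("high", "low", "non_evaluable"))
  )

  cens <- runif(n, config$censor_range[1], config$censor_range[2])
  pfs_rate <- hazard_for(group, score, evaluable, config, config$pfs_median)
  os_rate <- hazard_for(group, score, evaluable, config, config$os_median,
                        os = TRUE)
  t_pfs <- rexp(n, pfs_rate)
  t_os <- rexp(n, os_rate)
  clinical$pfs_time <- round(pmin(t_pfs, cens), 4)
  clinical$pfs_event <- as.integer(t_pfs <= cens)
  clinical$os_time <- round(pmin(t_os, cens), 4)
  clinical$os_event <- as.integer(t_os <= cens)

  structure(
    list(clinical = clinical, variants = variants, panel = panel,
         config = config),
    class = "btmb_sim"
  )
}

# exponential rate per patient; optionally log-linear in the score
hazard_for <- function(group, score, evaluable, config, medians, os = FALSE) {
  if (config$score_loghr_per_mut != 0 && !os) {
    base <- log(2) / config$score_hazard_base_median
    ifelse(
      evaluable,
      base * exp(config$score_loghr_per_mut * (score - config$score_hazard_ref)),
      log(2) / medians["non_evaluable"]
    )
  } else if (config$score_loghr_per_mut != 0 && os) {
    base <- log(2) / medians["low"]
    ifelse(
      evaluable,
      base * exp(config$score_loghr_per_mut * (score - config$score_hazard_ref)),
      log(2) / medians["non_evaluable"]
    )
  } else {
    log(2) / medians[group]
  }
}

draw_smoking <- function(n, msaf_grp, config) {
  u <- runif(n)
  p_cur <- config$smoking_current[msaf_grp]
  ifelse(u < config$smoking_never, "never",
         ifelse(u < config$smoking_never + p_cur, "current", "former"))
}

draw_pdl1 <- function(n, msaf_grp, config) {
  miss <- runif(n) < config$pdl1_missing
  pos <- runif(n) < config$pdl1_positive[msaf_grp]
  ifelse(miss, "missing", ifelse(pos, "positive", "negative"))
}

panel_gene_weights <- function(panel) {
  w <- rep(1, length(panel$genes))
  names(w) <- panel$genes
  hot <- c(TP53 = 12, LRP1B = 8, CDKN2A = 6, KRAS = 6, STK11 = 4, KEAP1 = 4)
  w[names(hot)] <- hot
  w / sum(w)
}

# one sample's variant profile; the counted set is exact by construction
simulate_sample_variants <- function(id, evaluable, msaf, score, config,
                                     panel, gene_w) {
  af_min <- config$af_min
  # non-evaluable samples still anchor one low-AF call at their MSAF
  n_counted <- if (evaluable) score else max(1L, min(score, 3L))
  driver_forced <- evaluable && n_counted == 0L
  n_driver <- if (driver_forced) 1L else rbinom(1, 1, config$driver_prob)
  n_indel <- rpois(1, config$indel_base + config$indel_per_snv * n_counted)
  n_sub <- rpois(1, config$subthreshold_mean)
  n_germ <- rpois(1, config$germline_mean)
  n_chip <- rpois(1, config$chip_mean)
  n_tot <- n_counted + n_driver + n_indel + n_sub + n_germ + n_chip
  if (n_tot == 0) {
    return(empty_variant_table())
  }

  # counted somatic substitutions: one anchors the MSAF, the rest sit in
  # [af_min, msaf]; non-evaluable samples anchor below the 1% gate
  lo <- if (evaluable) af_min else 0.0003
  af_counted <- if (n_counted >= 1) {
    c(msaf, runif(n_counted - 1, lo, msaf))
  } else {
    numeric()
  }
  af_driver <- if (n_driver >= 1) {
    if (driver_forced) msaf else runif(n_driver, lo, msaf)
  } else {
    numeric()
  }
  af_indel <- runif(n_indel, lo, max(msaf, lo + 1e-5))
  af_sub <- runif(n_sub, 0.0001, af_min - 1e-5)
  hom <- runif(n_germ) < config$germline_hom_frac
  af_germ <- ifelse(hom, runif(n_germ, 0.96, 0.9999), runif(n_germ, 0.46, 0.54))
  af_chip <- runif(n_chip, 0.001, 0.1)

  cls <- c(
    rep("SNV", n_counted + n_driver),
    sample(c("insertion", "deletion"), n_indel, replace = TRUE),
    rep("SNV", n_sub + n_germ + n_chip)
  )
  in_db <- c(
    rep(FALSE, n_counted + n_driver + n_indel + n_sub),
    runif(n_germ) < config$germline_db_frac,
    rep(TRUE, n_chip)
  )
  is_drv <- c(
    rep(FALSE, n_counted), rep(TRUE, n_driver),
    rep(FALSE, n_indel + n_sub + n_germ + n_chip)
  )
  af <- c(af_counted, af_driver, af_indel, af_sub, af_germ, af_chip)

  genes <- sample(panel$genes, n_tot, replace = TRUE, prob = gene_w)
  gene_idx <- match(genes, panel$genes)
  # unique per-sample offsets guarantee distinct (position, ref, alt) keys
  offsets <- sample.int(90000L, n_tot, replace = FALSE)
  positions <- gene_base_position(gene_idx) + offsets

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_tot, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1),
                       character(1)))
  ins <- cls == "insertion"
  del <- cls == "deletion"
  alt[ins] <- paste0(ref[ins], "A")
  ref[del] <- paste0(ref[del], "A")
  alt[del] <- substr(ref[del], 1, 1)

  tibble(
    sample_id = id, gene = genes, position = as.integer(positions),
    ref = ref, alt = alt, variant_class = cls, allele_frequency = af,
    in_population_db = in_db, is_known_driver = is_drv,
    germline_flag = "unknown"
  )
}

#' @export
print.btmb_sim <- function(x, ...) {
  cat(sprintf(
    "<btmb_sim> %d patients (%d evaluable, %d bTMB >= %d), %d variant calls\n",
    nrow(x$clinical), sum(x$clinical$true_evaluable),
    sum(x$clinical$true_group == "high"), x$config$group_cutoff,
    nrow(x$variants)
  ))
  invisible(x)
}

#' Simulate a cohort with MSAF confounded by baseline prognostics
#'
#' Planted-structure generator for validating the IPW adjustment: a
#' favourable-prognosis index built from age, tumor size, lesion count,
#' current smoking and PD-L1 status drives both the probability of being
#' in the MSAF < 1% subgroup and the probability of response (and the PFS
#' hazard). MSAF itself has no causal effect on outcome, so the unadjusted
#' MSAF < 1% vs >= 1% odds ratio is biased above 1 by construction while a
#' correctly weighted comparison should be null. Setting
#' `confound_strength = 0` in the config removes the planted effects
#' entirely.
#'
#' @param config A [sim_config()]; uses `n_patients`, `seed`,
#'   `confound_strength` and the covariate models.
#' @return Tibble with baseline covariates, `msaf_lt1` (logical group
#'   indicator), `confirmed_response`, `pfs_time`, `pfs_event` and the
#'   latent `prognostic_index`.
#' @export
simulate_confounded_msaf <- function(config = sim_config()) {
  stopifnot(inherits(config, "btmb_sim_config"))
  withr::with_seed(config$seed + 10000L, {
    n <- config$n_patients
    s <- config$confound_strength
    age <- round(rnorm(n, 67, 9))
    sld <- round(rlnorm(n, log(55), 0.5), 1)
    lesions <- 1L + rpois(n, 1.1)
    current <- runif(n) < 0.22
    never <- !current & runif(n) < 0.09
    pdl1_miss <- runif(n) < config$pdl1_missing
    pdl1_pos <- runif(n) < 0.45

    # favourable-prognosis index: younger, smaller tumors, fewer lesions,
    # non-smoking, PD-L1-positive
    f <- -(0.5 * (age - 67) / 9 +
             0.7 * (log(sld) - log(55)) / 0.5 +
             0.4 * (lesions - 2.1) / 1.05 +
             0.6 * current -
             0.5 * (pdl1_pos & !pdl1_miss))

    p_lt1 <- plogis(-1.73 + 1.2 * s * f)
    msaf_lt1 <- runif(n) < p_lt1
    p_resp <- plogis(-1.94 + 1.2 * s * f)
    response <- rbinom(n, 1, p_resp)

    rate <- log(2) / 4 * exp(-0.5 * s * f)
    cens <- runif(n, config$censor_range[1], config$censor_range[2])
    t_pfs <- rexp(n, rate)

    tibble(
      id = sprintf("C%03d", seq_len(n)),
      age = age,
      sex = ifelse(runif(n) < config$male_frac, "male", "female"),
      smoking = ifelse(current, "current", ifelse(never, "never", "former")),
      histology = ifelse(runif(n) < 0.28, "squamous", "non-squamous"),
      pdl1_status = ifelse(pdl1_miss, "missing",
                           ifelse(pdl1_pos, "positive", "negative")),
      sld_mm = sld,
      n_target_lesions = lesions,
      msaf_lt1 = msaf_lt1,
      confirmed_response = response,
      pfs_time = round(pmin(t_pfs, cens), 4),
      pfs_event = as.integer(t_pfs <= cens),
      prognostic_index = f
    )
  })
}
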