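# Synthetic register generator: schemas, determinism, structure,
# calibration and the generator/phenotyper contract.

test_that("empty population yields empty tables with the right schemas", {
  b <- generate_population(sim_config(n_children = 0, seed = 1))
  expect_equal(nrow(b$persons), 0)
  expect_true(all(c("person_id", "mother_id", "father_id", "birth_date",
                    "sex", "parity", "maternal_smoking",
                    "maternal_education", "maternal_age_at_delivery",
                    "foreign_born_parent", "family_income")
                  %in% names(b$persons)))
  expect_equal(nrow(b$addresses), 0)
  expect_named(b$addresses, c("person_id", "calendar_year", "in_ronneby",
                              "contaminated_water"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_children = -5), "nonnegative")
  expect_error(sim_config(group_proportions = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(sim_config(true_hr = list(asthma = c(1, 1, 0, 1))),
               "positive")
  expect_error(sim_config(sibling_rate = 1.4), "\\[0, 1\\]")
  expect_error(
    generate_health_events(
      generate_population(sim_config(n_children = 50, seed = 1,
                                     baseline_cuminc = c(wheeze = 0.1,
                                                         asthma = 0))),
      sim_config(n_children = 50, seed = 1,
                 baseline_cuminc = c(wheeze = 0.1, asthma = 0))),
    "\\(0, 1\\)")
})

test_that("the same seed reproduces the bundle bit-for-bit", {
  b1 <- generate_registers(sim_config(n_children = 300, seed = 99))
  b2 <- generate_registers(sim_config(n_children = 300, seed = 99))
  for (tb in c("persons", "addresses", "diagnoses", "dispensations",
               "vitals", "latent", "biomarkers"))
    expect_identical(b1[[tb]], b2[[tb]])
  b3 <- generate_registers(sim_config(n_children = 300, seed = 100))
  expect_false(identical(b1$persons, b3$persons))
})

test_that("group counts at full cohort size sit within binomial bounds", {
  cfg <- sim_config(n_children = 11488, seed = 2024)
  b <- generate_population(cfg)
  counts <- table(factor(b$latent$exposure, levels = EXPOSURE_LEVELS))
  expected <- c(9224, 1591, 479, 194)
  for (g in 1:4) {
    p <- expected[g] / 11488
    # sibling-pair assignment roughly doubles the variance of the paired
    # fraction; use the inflated binomial sd
    sd <- sqrt(11488 * p * (1 - p) * 1.25)
    expect_lt(abs(counts[g] - expected[g]), 2.6 * sd)
  }
  # sibling clustering near the configured rate
  sib <- table(table(b$persons$mother_id))
  frac_sib <- sum(sib[names(sib) != "1"] * 2) / nrow(b$persons)
  expect_lt(abs(frac_sib - 0.24), 0.02)
})

test_that("exact group counts are honored and missingness is calibrated", {
  cfg <- sim_config(group_counts = c(2000, 100, 50, 194), seed = 5)
  b <- generate_population(cfg)
  counts <- table(factor(b$latent$exposure, levels = EXPOSURE_LEVELS))
  expect_equal(as.integer(counts), c(2000, 100, 50, 194))
  # about 91% of children should be covariate-complete under defaults
  cfg2 <- sim_config(n_children = 8000, seed = 6)
  b2 <- generate_population(cfg2)
  complete <- with(b2$persons, !is.na(maternal_smoking) &
                     !is.na(maternal_education) & !is.na(family_income))
  expect_lt(abs(mean(complete) - 0.91), 0.015)
})

test_that("address histories round-trip through the exposure classifier", {
  for (seed in c(3, 17)) {
    b <- generate_population(sim_config(n_children = 800, seed = seed))
    got <- classify_exposure(b)
    expect_true(all(got$classifiable))
    expect_identical(as.character(got$exposure), b$latent$exposure)
  }
})

test_that("phenotyping recovers latent labels exactly, with and without noise", {
  for (noise in c(0, 0.5)) {
    b <- small_bundle(n = 1200, seed = 31, noise_rate = noise)
    ph <- ascertain_outcomes(b$persons, b$diagnoses, b$dispensations)
    expect_identical(ph$asthma_case, b$latent$asthma_case)
    expect_identical(ph$wheeze_case, b$latent$wheeze_case)
    expect_identical(ph$asthma3plus_case, b$latent$asthma3plus_case)
    expect_equal(ph$asthma_age, b$latent$asthma_age)
    expect_equal(ph$wheeze_age, b$latent$wheeze_age)
  }
})

test_that("null hazard ratios give group incidence differences centred on 0", {
  diffs <- vapply(1:30, function(seed) {
    cfg <- sim_config(n_children = 500, seed = seed,
                      true_hr = list(wheeze = rep(1, 4), asthma = rep(1, 4)),
                      missing_rate = c(smoking = 0, education = 0,
                                       income = 0))
    b <- generate_population(cfg)
    b <- generate_health_events(b, cfg)
    vh <- b$latent$exposure == "very_high"
    bg <- b$latent$exposure == "background"
    mean(b$latent$asthma_case[vh]) - mean(b$latent$asthma_case[bg])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("background cumulative incidence matches its calibration target", {
  cfg <- sim_config(n_children = 16000, seed = 77,
                    death_rate = 0, emigration_rate = 0,
                    admin_end = "2040-12-31")
  b <- generate_population(cfg)
  b <- generate_health_events(b, cfg)
  bg <- b$latent$exposure == "background"
  inc <- mean(b$latent$asthma_case[bg])
  expect_lt(abs(inc - 0.17), 3 * sqrt(0.17 * 0.83 / sum(bg)))
})

test_that("an extreme very-high hazard ratio dominates background incidence", {
  cfg <- sim_config(n_children = 2000, seed = 13,
                    true_hr = list(wheeze = rep(1, 4),
                                   asthma = c(1, 1, 1, 10)))
  b <- generate_population(cfg)
  b <- generate_health_events(b, cfg)
  vh <- b$latent$exposure == "very_high"
  bg <- b$latent$exposure == "background"
  expect_gt(mean(b$latent$asthma_case[vh]), mean(b$latent$asthma_case[bg]))
})

test_that("biomarker medians calibrate to the validation-cohort values", {
  cfg <- sim_config(seed = 8)
  bm <- generate_biomarker_cohort(cfg, n_per_group = 10000)
  med <- tapply(bm$pfhxs_ngml, bm$exposure, median)
  expect_lt(abs(med[["very_high"]] - 164.8) / 164.8, 0.05)
  expect_lt(abs(med[["background"]] - 0.8) / 0.8, 0.05)
  expect_lt(abs(med[["high"]] - 100.0) / 100.0, 0.05)
  # degenerate: zero spread collapses to the median exactly
  cfg0 <- sim_config(seed = 8)
  cfg0$biomarker$sdlog <- lapply(cfg0$biomarker$sdlog, function(x) x * 0)
  bm0 <- generate_biomarker_cohort(cfg0, n_per_group = 5)
  expect_equal(bm0$pfhxs_ngml[bm0$exposure == "very_high"],
               rep(164.8, 5))
})
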