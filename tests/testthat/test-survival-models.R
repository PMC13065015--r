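# Kaplan-Meier and Cox estimation against hand and brute-force oracles.

test_that("KM matches the hand product-limit computation", {
  fu <- data.frame(exit_age_days = c(1, 1.5, 2, 3),
                   event = c(1, 0, 1, 0), grp = "a")
  km <- km_curve(fu, group = "grp")
  # 1 - (3/4)(1/2) = 0.625 at t = 2
  expect_equal(km$cuminc[km$time == 2], 0.625)
  ok <- oracle_km(fu$exit_age_days, fu$event)
  expect_equal(km$survival[km$time %in% ok$time], ok$surv)
})

test_that("KM degenerate cases behave", {
  all_cens <- data.frame(exit_age_days = c(2, 5, 9), event = 0, g = "x")
  expect_true(all(km_curve(all_cens, "g")$cuminc == 0))
  all_ev <- data.frame(exit_age_days = c(4, 4, 4), event = 1, g = "x")
  expect_equal(max(km_curve(all_ev, "g")$cuminc), 1)
  expect_error(km_curve(data.frame(exit_age_days = -1, event = 1, g = "x"),
                        "g"), "negative")
})

test_that("KM equals the brute-force product on random fixtures", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    fu <- data.frame(exit_age_days = sample(1:15, n, TRUE),
                     event = rbinom(n, 1, 0.6), g = "x")
    km <- km_curve(fu, "g")
    ok <- oracle_km(fu$exit_age_days, fu$event)
    expect_equal(km$survival[match(ok$time, km$time)], ok$surv)
  }
})

test_that("cox_fit matches direct partial-likelihood maximization", {
  fx <- fixture_surv6()
  fit <- cox_fit(fx, covariates = character(0), strata = character(0))
  x <- as.numeric(fx$exposure == "very_high")
  beta_oracle <- oracle_cox_coef(fx$exit_age_days, fx$event, cbind(x))
  expect_equal(unname(fit$coefficients), beta_oracle, tolerance = 1e-6)

  # two covariates, untied, 8 subjects
  set.seed(5)
  d <- data.frame(person_id = paste0("p", 1:8),
                  cluster_id = paste0("p", 1:8),
                  exposure = rep(c("background", "very_high"), 4),
                  exit_age_days = sample(1:100, 8),
                  event = c(1, 1, 0, 1, 1, 0, 1, 1),
                  z = rnorm(8))
  fit2 <- cox_fit(d, covariates = "z", strata = character(0))
  X <- cbind(as.numeric(d$exposure == "very_high"), d$z)
  expect_equal(unname(fit2$coefficients),
               oracle_cox_coef(d$exit_age_days, d$event, X),
               tolerance = 1e-6)
})

test_that("a constant covariate is rejected as inestimable", {
  fx <- fixture_surv6()
  fx$z <- 1
  expect_error(cox_fit(fx, covariates = "z", strata = character(0)),
               "inestimable")
  fx2 <- fixture_surv6()
  fx2$exposure <- "background"
  expect_error(cox_fit(fx2, covariates = character(0),
                       strata = character(0)), "inestimable")
})

test_that("score test agrees with an independent log-rank statistic", {
  b <- small_bundle(n = 600, seed = 19)
  cohort <- build_analysis_cohort(b, "asthma")
  two <- cohort[cohort$exposure %in% c("background", "very_high"), ]
  fit <- cox_fit(two, covariates = character(0), strata = character(0))
  lr <- survival::survdiff(
    survival::Surv(exit_age_days, event) ~ exposure, data = two)
  expect_equal(fit$fit$score, lr$chisq, tolerance = 1e-3)
})

test_that("cluster size 1 reproduces the unclustered robust variance", {
  fx <- fixture_surv6()
  fit <- cox_fit(fx, covariates = character(0), strata = character(0),
                 cluster = "cluster_id")
  ref <- survival::coxph(
    survival::Surv(exit_age_days, event) ~ I(exposure == "very_high"),
    data = fx, ties = "efron", robust = TRUE)
  expect_equal(unname(diag(fit$vcov)), unname(diag(stats::vcov(ref))),
               tolerance = 1e-8)
})

test_that("robust Wald closed forms hold", {
  w <- robust_wald(c(b = 2), matrix(1, dimnames = list("b", "b")), "b")
  expect_equal(w$statistic, 4)
  expect_equal(w$p_value, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_equal(round(w$p_value, 4), 0.0455)
  w0 <- robust_wald(c(b = 0), matrix(1, dimnames = list("b", "b")), "b")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
})

test_that("identical data for both sexes zero the interaction terms", {
  b <- small_bundle(n = 400, seed = 3,
                    missing_rate = c(smoking = 0, education = 0,
                                     income = 0))
  cohort <- build_analysis_cohort(b, "asthma")
  half <- cohort
  half$sex <- factor("female", levels = c("female", "male"))
  mirror <- half
  mirror$sex <- factor("male", levels = c("female", "male"))
  mirror$person_id <- paste0(mirror$person_id, "m")
  mirror$cluster_id <- paste0(mirror$cluster_id, "m")
  doubled <- rbind(half, mirror)
  iw <- interaction_wald(doubled, covariates = "smoking")
  inter <- iw$fit$coefficients[grep(":sex", names(iw$fit$coefficients))]
  inter <- inter[!is.na(inter)]  # one column is stratum-collinear
  expect_true(all(abs(inter) < 1e-8))
  expect_gt(iw$wald$p_value, 0.999)
})

test_that("a strong qualitative interaction flips the stratified HRs", {
  cfg_f <- sim_config(n_children = 1500, seed = 71,
                      true_hr = list(wheeze = rep(1, 4),
                                     asthma = c(1, 1, 1, 0.2)),
                      missing_rate = c(smoking = 0, education = 0,
                                       income = 0))
  cfg_m <- sim_config(n_children = 1500, seed = 72,
                      true_hr = list(wheeze = rep(1, 4),
                                     asthma = c(1, 1, 1, 5)),
                      missing_rate = c(smoking = 0, education = 0,
                                       income = 0))
  mk <- function(cfg, sexlab, tag) {
    b <- generate_population(cfg)
    b <- generate_health_events(b, cfg)
    co <- build_analysis_cohort(b, "asthma")
    co$sex <- factor(sexlab, levels = c("female", "male"))
    co$person_id <- paste0(co$person_id, tag)
    co$cluster_id <- paste0(co$cluster_id, tag)
    co
  }
  doubled <- rbind(mk(cfg_f, "female", "f"), mk(cfg_m, "male", "m"))
  iw <- interaction_wald(doubled, covariates = "smoking")
  hr_vh <- vapply(iw$by_sex, function(f)
    f$hr_table$hr[f$hr_table$term == ".exposurevery_high"], numeric(1))
  expect_lt(hr_vh[["female"]], 1)
  expect_gt(hr_vh[["male"]], 1)
  expect_lt(iw$wald$p_value, 0.05)
})
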