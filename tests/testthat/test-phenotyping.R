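# Outcome phenotyping algorithms: rule application, boundaries,
# monotonicity, nesting.

dxf <- function(days, codes = "J45.9")
  data.frame(age_days = days, icd10_code = rep_len(codes, length(days)))
rxf <- function(days, codes = "R03AC02")
  data.frame(age_days = days, atc_code = rep_len(codes, length(days)))
B <- as.Date("2010-01-01")

test_that("asthma requires a diagnosis or a repeated dispensation", {
  r <- ascertain_asthma(dxf(1500), NULL, B)
  expect_true(r$is_case)
  expect_equal(r$incident_age_days, 1500)
  expect_false(ascertain_asthma(NULL, rxf(400), B)$is_case)
  r2 <- ascertain_asthma(NULL, rxf(c(400, 620)), B)
  expect_true(r2$is_case)
  # the first dispensation dates the incidence, the repeat only confirms
  expect_equal(r2$incident_age_days, 400)
})

test_that("asthma events at or past the 12th birthday do not qualify", {
  cap12 <- as.numeric(as.Date("2022-01-01") - B)
  expect_false(ascertain_asthma(dxf(cap12), NULL, B)$is_case)
  expect_true(ascertain_asthma(dxf(cap12 - 1), NULL, B)$is_case)
})

test_that("the repeat window restricts dispensation confirmation", {
  codes <- code_set_config(repeat_window_days = 100)
  expect_false(ascertain_asthma(NULL, rxf(c(400, 620)), B, codes)$is_case)
  expect_true(ascertain_asthma(NULL, rxf(c(400, 480)), B, codes)$is_case)
})

test_that("asthma (3+) needs a qualifying event after 36 months", {
  expect_false(ascertain_asthma_3plus(NULL, rxf(c(400, 620)), B)$is_case)
  r <- ascertain_asthma_3plus(NULL, rxf(c(400, 620, 1300)), B)
  expect_true(r$is_case)
  expect_equal(r$incident_age_days, 400)
  r2 <- ascertain_asthma_3plus(dxf(2000), NULL, B)
  expect_true(r2$is_case)
  expect_equal(r2$incident_age_days, 2000)
  # an event exactly on the 3rd birthday counts as after 36 months
  cap3 <- as.numeric(as.Date("2013-01-01") - B)
  expect_true(ascertain_asthma_3plus(dxf(c(200, cap3)), rxf(c(200, 300)),
                                     B)$is_case)
})

test_that("wheeze accepts one event before the 36-month cap", {
  r <- ascertain_wheeze(dxf(300, "J21.0"), NULL, B)
  expect_true(r$is_case)
  expect_equal(r$incident_age_days, 300)
  expect_false(ascertain_wheeze(dxf(1200), NULL, B)$is_case)
  r3 <- ascertain_wheeze(NULL, rxf(100), B)
  expect_true(r3$is_case)
  expect_equal(r3$incident_age_days, 100)
})

test_that("events dated before birth raise a data error", {
  expect_error(ascertain_asthma(dxf(-3), NULL, B), "before birth")
})

test_that("parental asthma applies the asthma rule with no age cap", {
  persons <- data.frame(person_id = "C1", mother_id = "M1",
                        father_id = "F1")
  pdx <- data.frame(person_id = "F1", event_date = as.Date("2014-05-01"),
                    icd10_code = "J45.1")
  prx <- data.frame(person_id = "M1",
                    dispense_date = as.Date("2015-01-01"),
                    atc_code = "R03AC02")
  empty_dx <- pdx[0, ]
  res <- ascertain_parental_asthma(persons, pdx, prx[0, ])
  expect_equal(res$parental_asthma, 1)
  # one unrepeated dispensation does not qualify a parent
  res2 <- ascertain_parental_asthma(persons, empty_dx, prx)
  expect_equal(res2$parental_asthma, 0)
  res3 <- ascertain_parental_asthma(persons, empty_dx, prx[0, ])
  expect_equal(res3$parental_asthma, 0)
  # events outside the study window are ignored
  pdx_out <- pdx; pdx_out$event_date <- as.Date("2003-01-01")
  expect_equal(ascertain_parental_asthma(persons, pdx_out,
                                         prx[0, ])$parental_asthma, 0)
})

test_that("asthma (3+) cases nest inside asthma cases with equal ages", {
  b <- small_bundle(n = 1500, seed = 23, noise_rate = 0.6)
  ph <- ascertain_outcomes(b$persons, b$diagnoses, b$dispensations)
  expect_true(all(!ph$asthma3plus_case | ph$asthma_case))
  sel <- ph$asthma3plus_case
  expect_equal(ph$asthma3plus_age[sel], ph$asthma_age[sel])
})

test_that("adding events only creates cases or moves incidence earlier", {
  set.seed(88)
  for (rep in 1:25) {
    ndx <- rpois(1, 2); nrx <- rpois(1, 2)
    dx <- if (ndx) dxf(sample(1:4000, ndx),
                       sample(c("J45.0", "J21.0", "J10"), ndx, TRUE))
          else NULL
    rx <- if (nrx) rxf(sample(1:4000, nrx),
                       sample(c("R03AC02", "A02BC01"), nrx, TRUE))
          else NULL
    extra_dx <- rbind(dx, dxf(sample(1:4000, 1), "J45.9"))
    for (fn in list(ascertain_wheeze, ascertain_asthma,
                    ascertain_asthma_3plus)) {
      before <- fn(dx, rx, B)
      after <- fn(extra_dx, rx, B)
      expect_true(after$is_case >= before$is_case)
      if (before$is_case && after$is_case)
        expect_lte(after$incident_age_days, before$incident_age_days)
    }
  }
})
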