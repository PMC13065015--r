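# Rank-Mahalanobis matching, balance, KM difference and the Fisherian
# randomization test.

test_that("rank-Mahalanobis distance basics hold", {
  tr <- matrix(c(1, 2), 1, 2)
  co <- matrix(c(1, 2, 5, 9), 2, 2, byrow = TRUE)
  # three points with perfectly correlated rank columns: the rank
  # covariance is singular and the ridge fallback warns
  expect_warning(D <- rank_mahalanobis_distance(tr, co), "ridge")
  expect_equal(D[1, 1], 0)
  expect_gt(D[1, 2], 0)
})

test_that("one covariate, no ties: distances follow squared rank gaps", {
  x_t <- c(0.3, 2.5)
  x_c <- c(1.1, 7.0, -4.2)
  D <- rank_mahalanobis_distance(cbind(x_t), cbind(x_c))
  pooled <- c(x_t, x_c)
  r <- rank(pooled)
  N <- length(pooled)
  v <- (N^2 - 1) / 12
  hand <- outer(r[1:2], r[3:5], function(a, b) (a - b)^2 / v)
  expect_equal(unname(D), unname(hand), tolerance = 1e-10)
})

test_that("distances are invariant to strictly monotone transforms", {
  set.seed(6)
  tr <- cbind(a = rnorm(4), b = runif(4))
  co <- cbind(a = rnorm(9), b = runif(9))
  D1 <- rank_mahalanobis_distance(tr, co)
  tr2 <- tr; co2 <- co
  tr2[, "a"] <- exp(tr2[, "a"]); co2[, "a"] <- exp(co2[, "a"])
  expect_equal(D1, rank_mahalanobis_distance(tr2, co2))
})

test_that("treated units are processed in input order", {
  D <- matrix(c(1, 2, 3, 9,
                1, 9, 9, 9), 2, 4, byrow = TRUE)
  m <- greedy_nn_match(D, ratio = 1, treated_ids = c("t1", "t2"),
                       control_ids = paste0("c", 1:4))
  # t1 takes c1 first; t2 must settle for its next-nearest
  expect_equal(m$person_id[m$set == 1 & m$treated == 0], "c1")
  expect_equal(m$person_id[m$set == 2 & m$treated == 0], "c2")
})

test_that("insufficient controls raise an informative error", {
  D <- matrix(1, 2, 5)
  expect_error(greedy_nn_match(D, ratio = 3), "insufficient controls")
})

test_that("one treated with exactly three controls matches all", {
  D <- matrix(c(0.5, 0.1, 0.9), 1, 3)
  m <- greedy_nn_match(D, ratio = 3)
  expect_equal(sort(m$person_id[m$treated == 0]), c("1", "2", "3"))
  expect_identical(m, greedy_nn_match(D, ratio = 3))
})

test_that("tie-breaking uses control input order", {
  D <- matrix(c(1, 1, 1, 1), 1, 4)
  m <- greedy_nn_match(D, ratio = 3)
  expect_equal(m$person_id[m$treated == 0], c("1", "2", "3"))
})

test_that("SMD follows the direct formula and flags zero variance", {
  d <- data.frame(person_id = as.character(1:40),
                  g = rep(c(1, 0), each = 20),
                  x = c(rnorm(20, 0.6, 0.5), rnorm(20, 0.4, 0.5)))
  # fixed values for exactness
  d$x <- c(rep(0.6, 20), rep(0.4, 20)) + rep(c(-0.5, 0.5), 20)
  bal <- covariate_balance(d, d$g == 1, matched_ids = d$person_id,
                           cols = "x")
  sd_pool <- sqrt((var(d$x[1:20]) + var(d$x[21:40])) / 2)
  expect_equal(bal$smd_before, 0.2 / sd_pool, tolerance = 1e-10)
  dz <- d; dz$x <- 1
  expect_true(is.na(covariate_balance(dz, dz$g == 1, dz$person_id,
                                      "x")$smd_before))
})

test_that("identical groups give SMD zero everywhere", {
  base <- data.frame(x = rnorm(15), y = rbinom(15, 1, 0.4))
  d <- rbind(base, base)
  d$person_id <- as.character(1:30)
  bal <- covariate_balance(d, rep(c(TRUE, FALSE), each = 15),
                           d$person_id, cols = c("x", "y"))
  expect_true(all(abs(bal$smd_before) < 1e-12))
})

test_that("matching improves balance on confounded synthetic data", {
  b <- small_bundle(n = 4000, seed = 21,
                    missing_rate = c(smoking = 0, education = 0,
                                     income = 0))
  cc <- build_analysis_cohort(b, "asthma")
  ma <- matched_analysis(cc, n_perm = 200, seed = 1)
  expect_lt(max(abs(ma$balance$smd_after)),
            max(abs(ma$balance$smd_before)))
})

test_that("KM difference statistic matches hand product-limit values", {
  fu <- data.frame(
    person_id = as.character(1:8),
    exit_age_days = c(1, 2, 3, 4, 1, 2, 3, 4),
    event = c(1, 1, 0, 0, 0, 0, 0, 1),
    treated = c(1, 1, 1, 1, 0, 0, 0, 0))
  # treated: events at 1,2 of 4 -> S = (3/4)(2/3) = 1/2
  # control: event at 4 (last at risk) -> S = 0
  t <- km_difference_statistic(fu, horizon = 10)
  expect_equal(t, 100 * ((1 - 0.5) - (1 - 0)))
  expect_equal(km_difference_statistic(transform(fu, event = 0),
                                       horizon = 10), 0)
  expect_error(km_difference_statistic(transform(fu, treated = 1), 10),
               "non-empty")
})

test_that("no events anywhere gives T = 0 and p = 1", {
  matched <- data.frame(set = rep(1:3, each = 4),
                        person_id = as.character(1:12),
                        treated = rep(c(1, 0, 0, 0), 3))
  fu <- data.frame(person_id = as.character(1:12),
                   exit_age_days = sample(100:200, 12), event = 0)
  r <- fisher_randomization_test(matched, fu, horizon = 300, n_perm = 50)
  expect_equal(r$t_obs, 0)
  expect_equal(r$p_value, 1)
})

test_that("sampled p converges to the exact enumeration p for 2 sets", {
  set.seed(33)
  matched <- data.frame(set = rep(1:2, each = 4),
                        person_id = as.character(1:8),
                        treated = rep(c(1, 0, 0, 0), 2))
  fu <- data.frame(person_id = as.character(1:8),
                   exit_age_days = c(50, 120, 200, 340, 60, 150, 280, 90),
                   event = c(1, 0, 1, 0, 1, 0, 0, 1))
  exact <- fisher_randomization_test(matched, fu, horizon = 400,
                                     n_perm = 10)
  expect_true(exact$exact)
  expect_equal(exact$n_perm, 16)
  mc <- fisher_randomization_test(matched, fu, horizon = 400,
                                  n_perm = 20000, seed = 4,
                                  exact_max_sets = 0)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 20000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1e-4)
})

test_that("p is invariant to set relabeling and within-set control order", {
  set.seed(44)
  matched <- data.frame(set = rep(1:4, each = 4),
                        person_id = as.character(1:16),
                        treated = rep(c(1, 0, 0, 0), 4))
  fu <- data.frame(person_id = as.character(1:16),
                   exit_age_days = sample(30:400, 16),
                   event = rbinom(16, 1, 0.5))
  base <- fisher_randomization_test(matched, fu, horizon = 500, n_perm = 5)
  relab <- matched
  relab$set <- c(4, 3, 2, 1)[relab$set]
  perm <- order(relab$set)
  r2 <- fisher_randomization_test(relab[perm, ], fu, horizon = 500,
                                  n_perm = 5)
  expect_equal(base$p_value, r2$p_value)
  expect_equal(base$t_obs, r2$t_obs)
  # shuffle controls within a set
  shuf <- matched[c(1, 3, 4, 2, 5:16), ]
  r3 <- fisher_randomization_test(shuf, fu, horizon = 500, n_perm = 5)
  expect_equal(base$p_value, r3$p_value)
})

test_that("single-covariate matching follows raw-value order", {
  tr <- cbind(x = c(5))
  co <- cbind(x = c(4.9, 100, 5.2, -3))
  D <- rank_mahalanobis_distance(tr, co)
  m <- greedy_nn_match(D, ratio = 3)
  # nearest three by rank distance exclude the farthest rank (-3 or 100)
  expect_equal(sort(m$person_id[m$treated == 0]), c("1", "2", "3"))
})
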