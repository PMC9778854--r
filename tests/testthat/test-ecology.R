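test_that("pond volume uses the pyramid approximation", {
  expect_equal(pond_volume(3, 1), 1)
  expect_equal(pond_volume(0, 2), 0)
  expect_equal(pond_volume(30, 0.5), 5)
  expect_error(pond_volume(-1, 1), "non-negative")
})

test_that("NN2 averages the two closest neighbors, tie-invariantly", {
  # place neighbors at controlled distances along a meridian:
  # 1 degree latitude ~ 111.2 km on the r = 6371 km sphere
  m_per_deg <- pi * 6371000 / 180
  ponds <- tibble::tibble(
    pond = c("focal", "n1", "n2", "n3"),
    lat = 59.8 + c(0, 100, 300, 800) / m_per_deg,
    lon = 23.25
  )
  r <- nn2_isolation(ponds, focal = "focal")
  expect_equal(r$nn2, 200, tolerance = 1e-3)
  # three equidistant neighbors: ties do not matter
  ponds_tie <- tibble::tibble(
    pond = c("focal", "a", "b", "c"),
    lat = 59.8 + c(0, 150, -150, 150) / m_per_deg,
    lon = 23.25
  )
  r2 <- nn2_isolation(ponds_tie, focal = "focal")
  expect_equal(r2$nn2, 150, tolerance = 1e-3)
  # a duplicated coordinate is still not its own neighbor
  dup <- tibble::tibble(pond = c("x", "y"), lat = 59.8, lon = 23.25)
  expect_error(nn2_isolation(dup, focal = "x"), "fewer than 2")
})

test_that("survey series define founding events and ages", {
  # biannual visits: [0,0,0,1] ending at the reference date
  rec <- tibble::tibble(pond = "p1",
                        date = c(0, 0.5, 1, 1.5),
                        detected = c(FALSE, FALSE, FALSE, TRUE))
  r <- age_from_survey(rec, reference_date = 1.5)
  expect_equal(r$age, 0)
  expect_true(r$newly_founded)
  # continuous detection over 31.5 years: right-censored maximum age
  rec2 <- tibble::tibble(pond = "p2", date = seq(0, 31.5, by = 0.5),
                         detected = TRUE)
  r2 <- age_from_survey(rec2, reference_date = 31.5)
  expect_equal(r2$age, 31.5)
  expect_false(r2$newly_founded)
  # a short gap (< 3 misses) is not an extinction
  rec3 <- tibble::tibble(pond = "p3", date = seq(0, 3, by = 0.5),
                         detected = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                                      TRUE))
  r3 <- age_from_survey(rec3, reference_date = 3)
  expect_equal(r3$age, 3)
  # a >= 3-miss gap refounds the subpopulation
  rec4 <- tibble::tibble(pond = "p4", date = seq(0, 3, by = 0.5),
                         detected = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                                      TRUE))
  r4 <- age_from_survey(rec4, reference_date = 3)
  expect_equal(r4$age, 1)
  expect_true(r4$newly_founded)
  # never detected: flagged undefined
  rec5 <- tibble::tibble(pond = "p5", date = 0:3, detected = FALSE)
  r5 <- age_from_survey(rec5, reference_date = 3)
  expect_false(r5$age_defined)
})

test_that("prepending non-detections before the founding run changes nothing", {
  rec <- tibble::tibble(pond = "p", date = c(2, 2.5, 3, 3.5),
                        detected = c(FALSE, FALSE, FALSE, TRUE))
  base <- age_from_survey(rec, reference_date = 4)
  more <- dplyr::bind_rows(
    tibble::tibble(pond = "p", date = c(0, 0.5, 1, 1.5),
                   detected = FALSE), rec)
  expect_equal(age_from_survey(more, reference_date = 4)$age, base$age)
})

test_that("the three-miss detection bound is below two percent", {
  expect_equal(detection_miss_probability(0.74, 3), 0.017576)
  expect_lt(detection_miss_probability(0.74, 3), 0.02)
})

test_that("covariate PCA standardizes, orients, and partitions variance", {
  set.seed(71)
  n <- 40
  x <- rnorm(n)
  cov <- tibble::tibble(pond = paste0("p", 1:n),
                        a = x, b = 2 * x + 3, c = rnorm(n))
  p <- covariate_pca(cov)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  # two perfectly correlated columns out of three: PC1 close to 2/3
  p2 <- covariate_pca(cov[, c("pond", "a", "b")])
  expect_equal(p2$variance_fraction[1], 1, tolerance = 1e-12)
  # orientation: largest-magnitude loading is positive
  for (k in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
  cov$d <- 5
  expect_warning(covariate_pca(cov), "constant")
})

test_that("single-predictor type-II tests equal the simple regression t-test", {
  set.seed(72)
  d <- tibble::tibble(pi = rnorm(30), log_age = rnorm(30))
  fit <- diversity_regression(d, response = "pi", predictors = "log_age")
  td <- tidy(fit)
  lmfit <- summary(lm(pi ~ log_age, data = d))
  expect_equal(td$statistic_t, lmfit$coefficients["log_age", "t value"],
               tolerance = 1e-10)
  expect_equal(td$p_value, lmfit$coefficients["log_age", "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_equal(glance(fit)$r_squared, lmfit$r.squared)
})

test_that("with orthogonal predictors type-II equals sequential ANOVA", {
  n <- 24
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  set.seed(73)
  d <- tibble::tibble(pi = 0.3 * x1 - 0.2 * x2 + rnorm(n), x1 = x1, x2 = x2)
  fit <- diversity_regression(d, response = "pi", predictors = c("x1", "x2"))
  seq_ss <- anova(lm(pi ~ x1 + x2, data = d))
  td <- tidy(fit)
  expect_equal(td$statistic_F, seq_ss[c("x1", "x2"), "F value"],
               tolerance = 1e-10)
})

test_that("aliased predictors raise a rank-deficiency error", {
  d <- tibble::tibble(pi = rnorm(20), a = rnorm(20))
  d$b <- 2 * d$a
  expect_error(diversity_regression(d, response = "pi",
                                    predictors = c("a", "b")),
               "aliased|deficient")
})

test_that("regression rejects noise covariates at roughly the nominal rate", {
  set.seed(74)
  n_draws <- 200
  pvals <- replicate(n_draws, {
    d <- tibble::tibble(pi = rnorm(40), noise = rnorm(40), x = rnorm(40))
    td <- tidy(diversity_regression(d, response = "pi",
                                    predictors = c("noise", "x")))
    td$p_value[td$term == "noise"]
  })
  rate <- mean(pvals <= 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})
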