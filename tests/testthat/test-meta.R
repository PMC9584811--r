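test_that("DerSimonian-Laird pooling matches the hand-computed oracle", {
  m <- random_effects_meta(c(0, 2), c(1, 1))
  expect_equal(m$q, 2)
  expect_equal(m$df, 1)
  expect_equal(m$i2, 0.5)
  expect_equal(m$tau2, 1)
  expect_equal(m$pooled, 1)
  expect_equal(m$se, 1) # 1 / sqrt(sum(1 / (1 + 1)))
  expect_true(is.na(m$pi_lower)) # k = 2: prediction interval undefined

  # homogeneous studies collapse to the common value with no heterogeneity
  h <- random_effects_meta(c(3, 3, 3), c(0.5, 1, 2))
  expect_equal(h$pooled, 3)
  expect_equal(h$tau2, 0)
  expect_equal(h$i2, 0)

  expect_error(random_effects_meta(1, 1), "at least 2")
  expect_error(random_effects_meta(c(1, 2), c(1, 0)), "positive")
})

test_that("zero heterogeneity reduces to fixed-effect inverse-variance pooling", {
  y <- c(1.0, 1.1, 0.9, 1.05)
  v <- c(0.5, 0.2, 0.4, 0.3)
  m <- random_effects_meta(y, v)
  if (m$tau2 == 0) {
    expect_equal(m$pooled, sum(y / v) / sum(1 / v))
    expect_equal(m$se, sqrt(1 / sum(1 / v)))
  }
  # force tau2 = 0 by construction (all equal)
  m0 <- random_effects_meta(rep(2, 4), v)
  expect_equal(m0$pooled, 2)
  expect_equal(m0$se, sqrt(1 / sum(1 / v)))
})

test_that("a near-zero-weight study leaves the pooled estimate unchanged", {
  y <- c(0.4, 0.9, 0.6)
  v <- c(0.1, 0.1, 0.1)
  m1 <- random_effects_meta(y, v)
  m2 <- random_effects_meta(c(y, m1$pooled), c(v, 1e8))
  expect_equal(m2$pooled, m1$pooled, tolerance = 1e-6)
})

test_that("heterogeneity statistics are shift-invariant", {
  set.seed(11)
  y <- rnorm(8)
  v <- runif(8, 0.2, 1)
  m <- random_effects_meta(y, v)
  ms <- random_effects_meta(y + 5, v)
  expect_equal(ms$pooled, m$pooled + 5)
  expect_equal(ms$tau2, m$tau2)
  expect_equal(ms$i2, m$i2)
  expect_equal(ms$q, m$q)
  # prediction interval at least as wide as the confidence interval
  expect_gte((m$pi_upper - m$pi_lower), (m$ci_upper - m$ci_lower))
})

test_that("DL pooling agrees with an independent implementation", {
  set.seed(23)
  y <- rnorm(12, mean = 10, sd = 2)
  v <- runif(12, 0.3, 1.5)
  m <- random_effects_meta(y, v)
  rma <- metafor::rma(yi = y, vi = v, method = "DL")
  expect_equal(m$pooled, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se, rma$se, tolerance = 1e-10)
  expect_equal(m$tau2, rma$tau2, tolerance = 1e-10)
  expect_equal(m$q, rma$QE, tolerance = 1e-10)
  expect_equal(100 * m$i2, rma$I2, tolerance = 1e-6)
})

test_that("meta-regression matches the independent MoM implementation", {
  set.seed(37)
  k <- 15
  x <- rnorm(k)
  y <- 1 + 0.8 * x + rnorm(k, sd = 0.5)
  v <- runif(k, 0.1, 0.6)
  fit <- meta_regression(y, v, data.frame(x = x))
  rma <- metafor::rma(yi = y, vi = v, mods = ~x, method = "DL")
  co <- tidy(fit)
  expect_equal(co$estimate, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(co$std_error, rma$se, tolerance = 1e-8)
  expect_equal(fit$tau2, rma$tau2, tolerance = 1e-8)

  # duplicating every study keeps the slope (up to the re-estimated tau2)
  # and shrinks the standard error
  fit2 <- meta_regression(c(y, y), c(v, v), data.frame(x = c(x, x)))
  co2 <- tidy(fit2)
  expect_equal(co2$estimate[co2$term == "x"],
               co$estimate[co$term == "x"], tolerance = 0.02)
  expect_lt(co2$std_error[co2$term == "x"], co$std_error[co$term == "x"])
  # with the heterogeneity held fixed the identity is exact
  fit_fixed <- meta_regression(y, v + fit$tau2, data.frame(x = x))
  fit2_fixed <- meta_regression(c(y, y), c(v, v) + fit$tau2,
                                data.frame(x = c(x, x)))
  if (fit_fixed$tau2 == 0 && fit2_fixed$tau2 == 0) {
    expect_equal(tidy(fit2_fixed)$estimate, tidy(fit_fixed)$estimate,
                 tolerance = 1e-10)
  }

  expect_error(meta_regression(y, v, rep(1, k)), "vary")
  expect_error(meta_regression(y[1:2], v[1:2], x[1:2]), "Too few")
})

test_that("variance partition recovers the hand-computed components", {
  # two balanced groups: SSB = 100, MSW = 0.5, n0 = 2
  vp <- variance_partition(c(1, 2, 11, 12), c("a", "a", "b", "b"))
  expect_equal(vp$between, (100 - 0.5) / 2)
  expect_equal(vp$within, 0.5)
  expect_equal(vp$icc, 49.75 / 50.25)

  # equal group means: share collapses to zero
  vp0 <- variance_partition(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(vp0$between, 0)
  expect_equal(vp0$icc, 0)

  # no within-group variance: everything is between
  vp1 <- variance_partition(c(1, 1, 5, 5), c("a", "a", "b", "b"))
  expect_equal(vp1$icc, 1)

  expect_error(variance_partition(1:3, c("a", "a", "a")), "at least 2")
})

test_that("proportion pooling is convex, boundary-safe and back-transformed", {
  eq <- proportion_meta(rep(25, 4), rep(50, 4))
  expect_equal(eq$pooled, 0.5)
  expect_equal(eq$scale, "logit")

  two <- proportion_meta(c(10, 30), c(100, 100))
  expect_gt(two$pooled, 0.10)
  expect_lt(two$pooled, 0.30)

  # zero and full counts survive via continuity correction
  bc <- proportion_meta(c(0, 5, 50), c(50, 50, 50))
  expect_true(is.finite(bc$pooled))
  expect_true(is.finite(bc$ci_lower) && bc$ci_lower > 0)

  expect_warning(z <- proportion_meta(c(1, 2, 0), c(10, 10, 0)), "n = 0")
  expect_equal(z$k, 2)
  expect_error(proportion_meta(c(5, 20), c(10, 10)), "0 <= count <= n")
})

test_that("country summaries recover planted group statistics", {
  scored <- dplyr::bind_rows(
    tibble::tibble(participant_id = paste0("a", 1:4), country_id = "AA",
                   discounting_score = c(0, 19, 10, 9),
                   anomaly_gain_loss = c(TRUE, TRUE, FALSE, FALSE)),
    tibble::tibble(participant_id = paste0("b", 1:2), country_id = "BB",
                   discounting_score = c(5, 7),
                   anomaly_gain_loss = c(FALSE, TRUE))
  )
  cs <- summarize_countries(scored, two_country_anchors())
  expect_equal(cs$n, c(4L, 2L))
  expect_equal(cs$mean_score, c(9.5, 6))
  expect_equal(cs$prop_gain_loss, c(0.5, 0.5))
  expect_equal(cs$var_mean, cs$sd_score^2 / cs$n)
  expect_equal(cs$gini, c(0.30, 0.50))
})

test_that("a moderator with a zero generator coefficient is covered by its interval", {
  # inflation has coefficient 0 in the generator; its meta-regression
  # interval should cover zero in at least 90% of seeded replicates
  anchors <- synthetic_country_table(61, seed = 3)
  covered <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    cfg <- population_config(n_per_country = 100, beta_inflation = 0,
                             seed = 700 + r)
    pop <- sample_population(cfg, anchors)
    sim <- simulate_study(pop, anchors, cfg)
    sc <- score_responses(sim$responses, anchors)
    cs <- summarize_countries(sc, anchors)
    co <- tidy(meta_regression(
      cs$mean_score, cs$var_mean,
      data.frame(gini = as.numeric(scale(cs$gini)),
                 gdp = as.numeric(scale(cs$log_gdp_pc)),
                 inflation = as.numeric(scale(cs$inflation_rate)))))
    covered <- covered +
      (co$conf_low[co$term == "inflation"] <= 0 &&
         co$conf_high[co$term == "inflation"] >= 0)
  }
  expect_gte(covered / reps, 0.9)
})
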