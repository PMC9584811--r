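test_that("discount factors match their closed forms", {
  # delta = 1 (rate 0): no discounting anywhere
  p0 <- respondent_params("exponential", rate = 0)
  expect_equal(discount_factor(p0, 500, "gain", 0, 24), 1.0)

  # hyperbolic 1 / (1 + k t)
  ph <- respondent_params("hyperbolic", rate = 0.5)
  expect_equal(discount_factor(ph, 500, "gain", 0, 12), 1 / 1.5)

  # quasi-hyperbolic beta * delta^t from the present
  pq <- respondent_params("quasi_hyperbolic", rate = -log(0.9), beta = 0.7)
  expect_equal(discount_factor(pq, 500, "gain", 0, 24), 0.7 * 0.81)
  # ... but no beta for intervals that start in the future
  expect_equal(discount_factor(pq, 500, "gain", 12, 24), 0.9)

  # sign ratio scales the loss rate down
  ps <- respondent_params("exponential", rate = 0.4, sign_ratio = 0.5)
  expect_equal(discount_factor(ps, 500, "loss", 0, 12), exp(-0.2))

  # magnitude scaling lowers the rate for larger prospect pairs
  pm <- respondent_params("exponential", rate = 0.4,
                          magnitude_exponent = 1, anchor_ref = 500)
  expect_equal(discount_factor(pm, 5000, "gain", 0, 12), exp(-0.04))

  # subadditive exponent discounts the whole interval less than its halves
  pu <- respondent_params("exponential", rate = 0.4, subadd_exponent = 0.5)
  whole <- discount_factor(pu, 500, "gain", 0, 24)
  halves <- discount_factor(pu, 500, "gain", 0, 12) *
    discount_factor(pu, 500, "gain", 12, 24)
  expect_gt(whole, halves)

  expect_error(discount_factor(p0, 500, "gain", 12, 12), "end > start")
  expect_error(discount_factor(p0, -5, "gain", 0, 12), "positive")
})

test_that("choice rule is logistic with deterministic zero-temperature limit", {
  item <- tibble::tibble(sign = "gain", framing = "neutral",
                         immediate_amount = 500, immediate_time = 0L,
                         delayed_amount = 550, delayed_time = 12L)
  # equal discounted utilities: 550 * exp(-log(1.1)) = 500
  p_eq <- respondent_params("exponential", rate = log(1.1),
                            temperature = 0.3, anchor_ref = 500)
  expect_equal(choice_probability(p_eq, item), 0.5)

  # T = 0: strict argmax, ties to immediate
  p_pat <- respondent_params("exponential", rate = 0.01, anchor_ref = 500)
  p_imp <- respondent_params("exponential", rate = 1, anchor_ref = 500)
  p_tie <- respondent_params("exponential", rate = log(1.1), anchor_ref = 500)
  expect_equal(choice_probability(p_pat, item), 1)
  expect_equal(choice_probability(p_imp, item), 0)
  expect_equal(choice_probability(p_tie, item), 0)

  # framing premium lowers P(delayed) under delay framing only
  delay_item <- item; delay_item$framing <- "delay"
  speed_item <- item; speed_item$framing <- "speedup"
  p_frame <- respondent_params("exponential", rate = 0.02,
                               framing_premium = 0.2, temperature = 0.1,
                               anchor_ref = 500)
  expect_lt(choice_probability(p_frame, delay_item),
            choice_probability(p_frame, speed_item))
  expect_equal(choice_probability(p_frame, speed_item),
               choice_probability(p_frame, item))
})

test_that("population sampling honours country coefficients and the seed", {
  anchors <- two_country_anchors()
  cfg0 <- no_injection_config(n_per_country = 300, beta_gini = 0,
                              beta_gdp = 0, beta_inflation = 0,
                              country_sd = 0, seed = 9)
  pop0 <- sample_population(cfg0, anchors)
  m <- tapply(pop0$log_rate_latent, pop0$country_id, mean)
  expect_lt(abs(m["AA"] - m["BB"]), 0.2) # no systematic country difference

  cfg_g <- no_injection_config(n_per_country = 300, beta_gini = 1,
                               beta_gdp = 0, country_sd = 0, seed = 9)
  pop_g <- sample_population(cfg_g, anchors)
  mg <- tapply(pop_g$log_rate_latent, pop_g$country_id, mean)
  expect_gt(mg["BB"], mg["AA"]) # BB has the larger Gini

  expect_identical(sample_population(cfg0, anchors),
                   sample_population(cfg0, anchors))
  expect_error(population_config(rate_attention = 1.5), "\\[0, 1\\]")
})

test_that("simulated studies are deterministic and respect injection rates", {
  anchors <- two_country_anchors()
  cfg <- no_injection_config(n_per_country = 40, seed = 3)
  pop <- sample_population(cfg, anchors)
  s1 <- simulate_study(pop, anchors, cfg)
  s2 <- simulate_study(pop, anchors, cfg)
  expect_identical(s1, s2)
  expect_false(any(unlist(s1$agents[grep("^injected_", names(s1$agents))])))
  expect_true(all(s1$responses$attention_choice == "receive"))
  expect_true(all(s1$responses$total_time_seconds >= 120))
  expect_true(all(s1$responses$completion_fraction == 1))

  cfg_inj <- population_config(n_per_country = 200, seed = 3,
                               rate_attention = 0.2)
  pop2 <- sample_population(cfg_inj, anchors)
  s3 <- simulate_study(pop2, anchors, cfg_inj)
  inj <- s3$agents$injected_attention
  expect_gt(sum(inj), 0)
  expect_true(all(s3$responses$attention_choice[inj] == "pay"))

  bad_pop <- pop
  bad_pop$country_id[1] <- "ZZ"
  expect_error(simulate_study(bad_pop, anchors, cfg), "unknown countries")
})

test_that("a strongly impatient deterministic agent takes the extreme path", {
  grid <- tibble::tibble(mechanism = "none", model_family = "exponential",
                         rate = 3, beta = 1, sign_ratio = 1,
                         magnitude_exponent = 0, framing_premium = 0,
                         subadd_exponent = 1)
  pop <- population_from_grid(grid)
  sim <- simulate_study(pop, us_anchor(), no_injection_config(), seed = 1)
  r <- sim$responses
  # all-immediate gains, all-delayed (deferred) losses
  expect_equal(unlist(r[paste0("small_gain_", 1:3)]),
               c(small_gain_1 = "immediate", small_gain_2 = "immediate",
                 small_gain_3 = "immediate"))
  expect_equal(unname(unlist(r[paste0("loss_", 1:3)])), rep("delayed", 3))
  expect_equal(unname(unlist(r[paste0("large_gain_", 1:3)])),
               rep("immediate", 3))
  sc <- score_responses(r, us_anchor())
  expect_equal(sc$discounting_score, 19)
})

test_that("each single-mechanism agent triggers its matching anomaly flag", {
  grid <- mechanism_grid()
  pop <- population_from_grid(grid)
  sim <- simulate_study(pop, us_anchor(), no_injection_config(), seed = 5)
  sc <- score_responses(sim$responses, us_anchor())

  flag_col <- paste0("anomaly_", grid$expected_flag)
  matched <- vapply(seq_len(nrow(grid)),
                    function(i) sc[[flag_col[i]]][i], logical(1))
  expect_true(all(matched)) # detection rate 1.0 across the documented grid

  # exclusivity under the default rules for all non-framing mechanisms
  flag_cols <- grep("^anomaly_", names(sc), value = TRUE)
  non_framing <- grid$mechanism != "delay_speedup"
  for (i in which(non_framing)) {
    others <- setdiff(flag_cols, flag_col[i])
    expect_false(any(unlist(sc[i, others])),
                 info = paste("row", i, grid$mechanism[i]))
  }
})

test_that("framing agents are fully exclusive under the two-leg present-bias rule", {
  # For stationary agents the speedup-item and shifted-item conditions are
  # algebraically identical, so the one-leg present-bias detector co-fires
  # with delay-speedup by construction; the two-leg rule separates them.
  grid <- mechanism_grid()
  pop <- population_from_grid(grid)
  sim <- simulate_study(pop, us_anchor(), no_injection_config(), seed = 5)
  sc_default <- score_responses(sim$responses, us_anchor())
  sc_conj <- score_responses(sim$responses, us_anchor(),
                             present_bias_rule = "conjunction")
  framing <- grid$mechanism == "delay_speedup"
  expect_true(all(sc_default$anomaly_present_bias[framing]))
  expect_false(any(sc_conj$anomaly_present_bias[framing]))
  flag_cols <- grep("^anomaly_", names(sc_conj), value = TRUE)
  for (i in which(framing)) {
    others <- setdiff(flag_cols, "anomaly_delay_speedup")
    expect_false(any(unlist(sc_conj[i, others])))
    expect_true(sc_conj$anomaly_delay_speedup[i])
  }
  # present-bias agents keep their flag under the stricter rule too
  expect_true(all(sc_conj$anomaly_present_bias[grid$mechanism == "present_bias"]))
})

test_that("the discounting score increases weakly with the discount rate", {
  ks <- c(0.005, 0.015, 0.05, 0.15, 0.25, 0.35, 0.5, 0.8)
  grid <- tibble::tibble(mechanism = "none", model_family = "exponential",
                         rate = ks, beta = 1, sign_ratio = 1,
                         magnitude_exponent = 0, framing_premium = 0,
                         subadd_exponent = 1)
  pop <- population_from_grid(grid)
  sim <- simulate_study(pop, us_anchor(), no_injection_config(), seed = 2)
  sc <- score_responses(sim$responses, us_anchor())
  expect_true(all(diff(sc$discounting_score) >= 0))
})

test_that("subadditive agents accept the long horizon but reject the shifted interval", {
  grid <- mechanism_grid()
  sub_rows <- grid[grid$mechanism == "subadditivity", ]
  pop <- population_from_grid(sub_rows)
  sim <- simulate_study(pop, us_anchor(), no_injection_config(), seed = 8)
  expect_true(all(sim$responses$subadditivity == "delayed"))
  expect_true(all(sim$responses$present_bias == "immediate"))
})
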