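#' @name simulator
#' @title Parametric discounting agents
#'
#' @description
#' Synthetic respondents are parametric discounted-utility agents. An agent
#' discounts a prospect pair whose sooner option sits at time `a` months and
#' later option at `b > a` months by composing per-interval factors
#' `F(0, a) * F(a, b)`, where for an elapsed interval of length `D` years
#' (from start `a`):
#'
#' * exponential: `F = exp(-k_eff * D^s)`
#' * hyperbolic: `F = 1 / (1 + k_eff * D^s)`
#' * quasi-hyperbolic: `F = beta^(a == 0) * exp(-k_eff * D^s)` -- the
#'   present-bias penalty `beta` applies once, to leaving the present.
#'
#' The effective annual rate is `k_eff = k * (m / anchor)^(-gamma) * rho^(is
#' loss)`, where `m` is the magnitude of the prospect pair (its sooner
#' amount): `gamma > 0` makes large-magnitude sets discounted at lower rates
#' (absolute magnitude effect) and `rho < 1` makes losses discounted less
#' than gains (sign effect). `s < 1` makes discounting subadditive: a whole
#' 24-month interval is discounted less than its two 12-month halves
#' composed. A framing premium `phi` (in units of the anchor) is added to
#' the immediate option's utility under delay framing only, producing the
#' delay-speedup asymmetry. Choices follow a logistic rule with temperature
#' `T` (in anchor units); `T = 0` is deterministic with ties resolved to
#' the immediate option.
NULL

#' Respondent parameter table
#'
#' Builds (and validates) a tibble of generative discounting parameters,
#' one row per agent. Scalar arguments are recycled.
#'
#' @param model_family `"exponential"`, `"hyperbolic"` or
#'   `"quasi_hyperbolic"`.
#' @param rate Positive annual discount rate `k`. For quasi-hyperbolic
#'   agents this is `-log(delta)` of the beta-delta form.
#' @param beta Present-bias factor in `(0, 1]`; forced to 1 outside the
#'   quasi-hyperbolic family.
#' @param sign_ratio Loss/gain rate ratio `rho >= 0`; `rho < 1` means losses
#'   are discounted less than gains.
#' @param magnitude_exponent `gamma >= 0`; the effective rate scales as
#'   `(magnitude / anchor)^(-gamma)`.
#' @param framing_premium `phi`, utility bonus (fraction of the anchor) for
#'   the immediate option under delay framing only.
#' @param subadd_exponent Interval-length exponent `s` in `(0, 1]`; `s < 1`
#'   yields subadditive discounting.
#' @param temperature Logistic choice temperature `T >= 0` in anchor units;
#'   0 gives deterministic choice.
#' @param anchor_ref Reference magnitude (the country anchor) used by the
#'   magnitude, framing and temperature scalings.
#' @return A tibble with one row per agent.
#' @export
respondent_params <- function(model_family = "exponential",
                              rate = 0.12,
                              beta = 1,
                              sign_ratio = 1,
                              magnitude_exponent = 0,
                              framing_premium = 0,
                              subadd_exponent = 1,
                              temperature = 0,
                              anchor_ref = 1) {
  p <- tibble(
    model_family = model_family, rate = rate, beta = beta,
    sign_ratio = sign_ratio, magnitude_exponent = magnitude_exponent,
    framing_premium = framing_premium, subadd_exponent = subadd_exponent,
    temperature = temperature, anchor_ref = anchor_ref
  )
  ok_family <- p$model_family %in%
    c("exponential", "hyperbolic", "quasi_hyperbolic")
  if (!all(ok_family)) abort("Unknown `model_family`.")
  p$beta <- ifelse(p$model_family == "quasi_hyperbolic", p$beta, 1)
  with(p, {
    if (any(rate < 0)) abort("`rate` must be >= 0.")
    if (any(beta <= 0 | beta > 1)) abort("`beta` must be in (0, 1].")
    if (any(sign_ratio < 0)) abort("`sign_ratio` must be >= 0.")
    if (any(magnitude_exponent < 0)) abort("`magnitude_exponent` must be >= 0.")
    if (any(subadd_exponent <= 0 | subadd_exponent > 1)) {
      abort("`subadd_exponent` must be in (0, 1].")
    }
    if (any(temperature < 0)) abort("`temperature` must be >= 0.")
    if (any(anchor_ref <= 0)) abort("`anchor_ref` must be > 0.")
  })
  p
}

#' Present-value multiplier over a time interval
#'
#' Vectorised discount factor for an elapsed interval, applying the model
#' family, magnitude scaling, sign ratio and subadditivity exponent (see
#' the package's generative-model description).
#'
#' @param params A parameter tibble ([respondent_params()]); rows recycled
#'   against the other arguments.
#' @param amount Magnitude of the prospect pair (its sooner amount), used
#'   only by the magnitude scaling.
#' @param sign `"gain"` or `"loss"`.
#' @param start,end Interval endpoints in months, `end > start >= 0`.
#' @return Discount factors in `(0, 1]`.
#' @examples
#' p <- respondent_params("hyperbolic", rate = 0.5)
#' discount_factor(p, 500, "gain", 0, 12) # 1 / 1.5
#' @export
discount_factor <- function(params, amount, sign = "gain", start = 0, end = 12) {
  n <- max(nrow(params), length(amount), length(sign),
           length(start), length(end))
  idx <- rep_len(seq_len(nrow(params)), n)
  p <- params[idx, ]
  amount <- rep_len(amount, n)
  sign <- rep_len(sign, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (any(end <= start) || any(start < 0)) {
    abort("Interval must satisfy end > start >= 0 (months).")
  }
  if (any(amount <= 0)) abort("`amount` must be positive.")
  k_eff <- p$rate * (amount / p$anchor_ref)^(-p$magnitude_exponent)
  k_eff <- ifelse(sign == "loss", p$sign_ratio * k_eff, k_eff)
  x <- months_to_years(end - start)^p$subadd_exponent
  f <- ifelse(p$model_family == "hyperbolic",
              1 / (1 + k_eff * x),
              exp(-k_eff * x))
  ifelse(p$model_family == "quasi_hyperbolic" & start == 0, p$beta * f, f)
}

#' Probability that an agent chooses the delayed option
#'
#' Discounted utilities of both options are computed from the evaluation
#' time (now), composing per-interval factors for shifted prospects; losses
#' enter with negated utility. The choice is logistic in the utility
#' difference scaled by `temperature * anchor_ref`; at temperature 0 it is
#' the deterministic argmax, with ties going to the immediate option.
#'
#' @param params Parameter tibble, rows recycled against items.
#' @param item Item tibble with columns `sign`, `framing`,
#'   `immediate_amount`, `immediate_time`, `delayed_amount`, `delayed_time`
#'   (as produced by [next_item()] / [build_anomaly_items()]).
#' @return Vector of probabilities of choosing the delayed option.
#' @export
choice_probability <- function(params, item) {
  n <- max(nrow(params), nrow(item))
  p <- params[rep_len(seq_len(nrow(params)), n), ]
  it <- item[rep_len(seq_len(nrow(item)), n), ]
  f_start <- ifelse(it$immediate_time > 0,
                    discount_factor(p, it$immediate_amount, it$sign,
                                    0, it$immediate_time),
                    1)
  f_interval <- discount_factor(p, it$immediate_amount, it$sign,
                                it$immediate_time, it$delayed_time)
  u_sign <- ifelse(it$sign == "loss", -1, 1)
  u_soon <- u_sign * it$immediate_amount * f_start +
    ifelse(it$framing == "delay" & it$sign == "gain",
           p$framing_premium * p$anchor_ref, 0)
  u_late <- u_sign * it$delayed_amount * f_start * f_interval
  diff <- u_late - u_soon
  ifelse(p$temperature > 0,
         stats::plogis(diff / (p$temperature * p$anchor_ref)),
         as.numeric(diff > 0))
}

#' Population configuration for the respondent simulator
#'
#' Describes how agents are drawn around a country anchor table: the
#' distribution of the latent log discount rate (a linear predictor in
#' standardised country covariates plus a country random intercept and
#' individual noise), the mixture of anomaly-generating mechanisms, the
#' choice temperature, and the rates at which quality-control violations
#' are injected with ground-truth labels.
#'
#' Defaults emulate the conditions of a large cross-country study: 200
#' respondents per country, a median annual discount rate near 0.12 with
#' wide individual dispersion, modest country effects (Gini raising and
#' log GDP lowering the discount rate), and minority subpopulations
#' carrying each anomaly mechanism.
#'
#' @param n_per_country Respondents per country (scalar or one per country).
#' @param log_rate_mean,log_rate_sd Mean and individual SD of `log(k)`.
#' @param country_sd SD of the country random intercept on `log(k)`.
#' @param beta_gini,beta_gdp,beta_inflation Coefficients on the
#'   standardised country covariates in the `log(k)` linear predictor.
#' @param p_present_bias,p_sign,p_magnitude,p_framing,p_subadd Probabilities
#'   that an agent carries each mechanism (independently).
#' @param temperature Logistic choice temperature (anchor units).
#' @param p_hyperbolic Probability that an agent without present bias uses
#'   the hyperbolic rather than exponential family.
#' @param rate_attention,rate_fast,rate_incomplete,rate_age,
#'   rate_extreme_income,rate_nonsense Injection rates of labelled
#'   quality-control violations.
#' @param seed Integer seed; fixed seed implies identical output.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_per_country = 200,
                              log_rate_mean = log(0.12),
                              log_rate_sd = 0.8,
                              country_sd = 0.15,
                              beta_gini = 0.2,
                              beta_gdp = -0.2,
                              beta_inflation = 0,
                              p_present_bias = 0.3,
                              p_sign = 0.35,
                              p_magnitude = 0.25,
                              p_framing = 0.2,
                              p_subadd = 0.25,
                              p_hyperbolic = 0.15,
                              temperature = 0.05,
                              rate_attention = 0.05,
                              rate_fast = 0.05,
                              rate_incomplete = 0.05,
                              rate_age = 0.01,
                              rate_extreme_income = 0.01,
                              rate_nonsense = 0.01,
                              seed = 1L) {
  cfg <- as.list(environment())
  rates <- cfg[grep("^(p_|rate_)", names(cfg))]
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    abort("Mechanism and injection rates must lie in [0, 1].")
  }
  if (any(cfg$n_per_country < 1)) abort("`n_per_country` must be >= 1.")
  structure(cfg, class = "population_config")
}

standardise_or_zero <- function(x) {
  if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0) return(rep(0, length(x)))
  as.numeric(scale(x))
}

#' Draw a population of agents for a set of countries
#'
#' Samples one parameter row per agent: the latent log discount rate from
#' the configured country-level linear predictor (standardised Gini,
#' log GDP and inflation), a country random intercept, individual noise,
#' and independent Bernoulli draws of the five anomaly mechanisms. Output
#' is a pure function of `config$seed`.
#'
#' @param config A [population_config()].
#' @param anchors A country anchor tibble ([country_anchors()]).
#' @return A tibble with one row per agent: `participant_id`, `country_id`,
#'   covariates, all [respondent_params()] columns, and `log_rate_latent`
#'   (the latent trait, equal to `log(rate)`).
#' @export
sample_population <- function(config, anchors) {
  stopifnot(inherits(config, "population_config"))
  anchors <- country_anchors(anchors)
  k <- nrow(anchors)
  n_c <- rep_len(config$n_per_country, k)
  set.seed(config$seed)

  z_gini <- standardise_or_zero(anchors$gini)
  z_gdp <- standardise_or_zero(anchors$log_gdp_pc)
  z_inf <- standardise_or_zero(anchors$inflation_rate)
  u_country <- stats::rnorm(k, 0, config$country_sd)
  country_mu <- config$log_rate_mean +
    config$beta_gini * z_gini + config$beta_gdp * z_gdp +
    config$beta_inflation * z_inf + u_country

  idx <- rep(seq_len(k), n_c)
  n <- length(idx)
  log_rate <- country_mu[idx] + stats::rnorm(n, 0, config$log_rate_sd)

  has_pb <- stats::runif(n) < config$p_present_bias
  has_sign <- stats::runif(n) < config$p_sign
  has_mag <- stats::runif(n) < config$p_magnitude
  has_frame <- stats::runif(n) < config$p_framing
  has_sub <- stats::runif(n) < config$p_subadd
  hyper <- !has_pb & stats::runif(n) < config$p_hyperbolic

  params <- respondent_params(
    model_family = ifelse(has_pb, "quasi_hyperbolic",
                          ifelse(hyper, "hyperbolic", "exponential")),
    rate = exp(log_rate),
    beta = ifelse(has_pb, stats::runif(n, 0.5, 0.9), 1),
    sign_ratio = ifelse(has_sign, stats::runif(n, 0.2, 0.8), 1),
    magnitude_exponent = ifelse(has_mag, stats::runif(n, 0.3, 1), 0),
    framing_premium = ifelse(has_frame, stats::runif(n, 0.05, 0.2), 0),
    subadd_exponent = ifelse(has_sub, stats::runif(n, 0.5, 0.9), 1),
    temperature = config$temperature,
    anchor_ref = anchors$anchor_value[idx]
  )
  bind_cols(
    tibble(
      participant_id = sprintf("P%06d", seq_len(n)),
      country_id = anchors$country_id[idx],
      gini = anchors$gini[idx],
      log_gdp_pc = anchors$log_gdp_pc[idx],
      inflation_rate = anchors$inflation_rate[idx],
      log_rate_latent = log_rate
    ),
    params
  )
}

# Draw one staircase choice column: returns "immediate"/"delayed".
draw_choice <- function(p_delayed, u) {
  ifelse(u < p_delayed, "delayed", "immediate")
}

simulate_set <- function(population, set_id, large_multiplier, denomination) {
  n <- nrow(population)
  base <- population$anchor_ref *
    if (set_id == "large_gain") large_multiplier else 1
  sign <- set_sign(set_id)
  item_at <- function(mult) {
    tibble(
      sign = sign, framing = "neutral",
      immediate_amount = round_currency(base, denomination),
      immediate_time = 0L,
      delayed_amount = round_currency(mult * base, denomination),
      delayed_time = 12L
    )
  }
  u <- matrix(stats::runif(3 * n), ncol = 3)
  c1 <- draw_choice(choice_probability(population, item_at(TITRATION_FIRST)),
                    u[, 1])
  ascending <- c1 == impatient_choice(set_id)
  m2 <- ifelse(ascending, TITRATION_ASC[1], TITRATION_DESC[1])
  c2 <- draw_choice(choice_probability(population, item_at(m2)), u[, 2])
  need3 <- c2 == c1
  m3 <- ifelse(ascending, TITRATION_ASC[2], TITRATION_DESC[2])
  c3 <- draw_choice(choice_probability(population, item_at(m3)), u[, 3])
  c3[!need3] <- NA_character_
  out <- tibble(c1, c2, c3)
  names(out) <- paste0(set_id, "_", 1:3)
  out
}

choices_to_pattern <- function(c1, c2, c3) {
  paste0(substr(c1, 1, 1), substr(c2, 1, 1),
         ifelse(is.na(c3), "", substr(c3, 1, 1))) |> toupper()
}

#' Simulate a full multi-country study
#'
#' Walks every agent through the complete instrument (three staircase sets,
#' indifference derivation, four anomaly items), then attaches the
#' attention check, response times, completion, demographics and finances,
#' and finally injects labelled quality-control violations at the
#' configured rates. With a fixed population and seed the output is
#' identical across runs.
#'
#' @param population Agent tibble from [sample_population()].
#' @param anchors Country anchor tibble.
#' @param config The [population_config()] holding the injection rates
#'   (defaults to a fresh `population_config()`).
#' @param seed Seed for the choice and demographic draws (defaults to
#'   `config$seed + 1`).
#' @param denomination Currency rounding unit.
#' @return A list with elements `responses` (the wide response tibble
#'   consumed by [score_responses()] / [apply_exclusions()]) and `agents`
#'   (ground-truth sidecar: parameters plus `injected_*` violation labels).
#' @export
simulate_study <- function(population, anchors, config = population_config(),
                           seed = NULL, denomination = 1) {
  stopifnot(nrow(population) >= 1)
  anchors <- country_anchors(anchors)
  set.seed(seed %||% (config$seed + 1L))
  n <- nrow(population)
  lm_by_country <- stats::setNames(anchors$large_multiplier,
                                   anchors$country_id)
  large_mult <- unname(lm_by_country[population$country_id])
  if (any(is.na(large_mult))) abort("Population references unknown countries.")

  sets <- lapply(BASELINE_SETS, function(s) {
    simulate_set(population, s, large_mult, denomination)
  })
  responses <- bind_cols(
    tibble(participant_id = population$participant_id,
           country_id = population$country_id),
    sets[[1]], sets[[2]], sets[[3]]
  )

  sg_pattern <- choices_to_pattern(responses$small_gain_1,
                                   responses$small_gain_2,
                                   responses$small_gain_3)
  ind <- derive_indifference(sg_pattern, population$anchor_ref, denomination)
  base <- round_currency(population$anchor_ref, denomination)
  premium <- ind$indifference_value - base
  anomaly_defs <- list(
    present_bias = tibble(sign = "gain", framing = "neutral",
                          immediate_amount = base, immediate_time = 12L,
                          delayed_amount = ind$indifference_value,
                          delayed_time = 24L),
    subadditivity = tibble(sign = "gain", framing = "neutral",
                           immediate_amount = base, immediate_time = 0L,
                           delayed_amount = round_currency(base + 2 * premium,
                                                           denomination),
                           delayed_time = 24L),
    delay_framing = tibble(sign = "gain", framing = "delay",
                           immediate_amount = base, immediate_time = 0L,
                           delayed_amount = ind$indifference_value,
                           delayed_time = 12L),
    speedup_framing = tibble(sign = "gain", framing = "speedup",
                             immediate_amount = base, immediate_time = 0L,
                             delayed_amount = ind$indifference_value,
                             delayed_time = 12L)
  )
  for (nm in names(anomaly_defs)) {
    p_del <- choice_probability(population, anomaly_defs[[nm]])
    responses[[nm]] <- draw_choice(p_del, stats::runif(n))
  }

  # attention check, timing, demographics, finances
  responses$attention_choice <- rep("receive", n)
  responses$total_time_seconds <-
    round(pmax(150, stats::rlnorm(n, log(420), 0.35)))
  responses$completion_fraction <- rep(1, n)
  responses$age <- sample(18:80, n, replace = TRUE)
  monthly_income <- 10 * population$anchor_ref
  responses$income <- round_currency(monthly_income *
                                       stats::rlnorm(n, 0, 0.5))
  responses$assets <- round_currency(monthly_income *
                                       stats::rlnorm(n, 1.5, 1))
  responses$debt <- round_currency(monthly_income *
                                     stats::rlnorm(n, -0.5, 1))
  responses$employment <- sample(
    c("full_time", "part_time", "unemployed", "student", "retired"),
    n, replace = TRUE, prob = c(0.45, 0.15, 0.1, 0.2, 0.1)
  )
  responses$nonsense_flag <- 0L

  inject <- function(rate) stats::runif(n) < rate
  injected <- tibble(
    injected_attention = inject(config$rate_attention),
    injected_fast = inject(config$rate_fast),
    injected_incomplete = inject(config$rate_incomplete),
    injected_age = inject(config$rate_age),
    injected_extreme_income = inject(config$rate_extreme_income),
    injected_nonsense = inject(config$rate_nonsense)
  )
  responses$attention_choice[injected$injected_attention] <- "pay"
  responses$total_time_seconds[injected$injected_fast] <-
    round(stats::runif(sum(injected$injected_fast), 20, 100))
  responses$completion_fraction[injected$injected_incomplete] <-
    round(stats::runif(sum(injected$injected_incomplete), 0.2, 0.9), 2)
  responses$age[injected$injected_age] <-
    sample(101:120, sum(injected$injected_age), replace = TRUE)
  responses$income[injected$injected_extreme_income] <- 5e8
  responses$nonsense_flag[injected$injected_nonsense] <- 1L

  list(responses = responses, agents = bind_cols(population, injected))
}

#' Documented single-mechanism agent grid
#'
#' The reference grid of deterministic (temperature 0) agents, each endowed
#' with exactly one non-neutral mechanism, together with the anomaly flag
#' each is expected to trigger. Baseline impatience for the magnitude, sign
#' and subadditivity agents is placed in the censored range of the
#' small-gain staircase (`k > log(1.5)`) so that the shifted-interval
#' present-bias detector -- which fires for any stationary agent whose
#' titration indifference is interior to the grid -- stays silent; see the
#' methods vignette for the derivation. The framing agent necessarily
#' co-fires the default present-bias detector (for stationary agents the
#' two item conditions are algebraically identical), so its exclusivity is
#' documented under the `"conjunction"` present-bias rule.
#'
#' @return A tibble of agent parameters with columns `mechanism` and
#'   `expected_flag` alongside the [respondent_params()] fields.
#' @export
mechanism_grid <- function() {
  g <- function(mechanism, family = "exponential", rate, beta = 1,
                sign_ratio = 1, gamma = 0, phi = 0, s = 1) {
    tibble(mechanism = mechanism, model_family = family, rate = rate,
           beta = beta, sign_ratio = sign_ratio, magnitude_exponent = gamma,
           framing_premium = phi, subadd_exponent = s)
  }
  grid <- bind_rows(
    g("absolute_magnitude", rate = 0.42, gamma = 1),
    g("absolute_magnitude", rate = 0.50, gamma = 1),
    g("absolute_magnitude", rate = 0.50, gamma = 2),
    g("gain_loss", rate = 0.42, sign_ratio = 0.1),
    g("gain_loss", rate = 0.42, sign_ratio = 0.2),
    g("gain_loss", rate = 0.50, sign_ratio = 0.1),
    g("subadditivity", rate = 0.45, s = 0.5),
    g("subadditivity", rate = 0.43, s = 0.6),
    g("present_bias", family = "quasi_hyperbolic",
      rate = -log(0.95), beta = 0.5),
    g("present_bias", family = "quasi_hyperbolic",
      rate = -log(0.95), beta = 0.6),
    g("delay_speedup", rate = 0.03, phi = 0.15),
    g("delay_speedup", rate = 0.05, phi = 0.20),
    g("delay_speedup", rate = 0.03, phi = 0.20)
  )
  grid$expected_flag <- grid$mechanism
  grid
}
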