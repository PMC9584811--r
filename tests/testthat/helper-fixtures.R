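# Shared fixtures: tiny anchor tables and hand-built response rows.

us_anchor <- function() {
  country_anchors(data.frame(
    country_id = "US", currency_label = "USD", anchor_value = 500,
    gini = 0.41, log_gdp_pc = 11.0, inflation_rate = 4.7
  ))
}

two_country_anchors <- function() {
  country_anchors(data.frame(
    country_id = c("AA", "BB"),
    currency_label = c("a-coin", "b-coin"),
    anchor_value = c(500, 2000),
    gini = c(0.30, 0.50),
    log_gdp_pc = c(10.5, 8.5),
    inflation_rate = c(2, 12)
  ))
}

# One wide response row from set patterns and anomaly choices.
response_row <- function(id = "p1", country = "US",
                         small_gain = "ID", loss = "DI", large_gain = "DDD",
                         present_bias = "delayed", subadditivity = "delayed",
                         delay_framing = "delayed", speedup_framing = "delayed",
                         ...) {
  split_pattern <- function(p) {
    ch <- strsplit(p, "")[[1]]
    out <- ifelse(ch == "I", "immediate", "delayed")
    length(out) <- 3
    out
  }
  sg <- split_pattern(small_gain)
  lo <- split_pattern(loss)
  lg <- split_pattern(large_gain)
  row <- tibble::tibble(
    participant_id = id, country_id = country,
    small_gain_1 = sg[1], small_gain_2 = sg[2], small_gain_3 = sg[3],
    loss_1 = lo[1], loss_2 = lo[2], loss_3 = lo[3],
    large_gain_1 = lg[1], large_gain_2 = lg[2], large_gain_3 = lg[3],
    present_bias = present_bias, subadditivity = subadditivity,
    delay_framing = delay_framing, speedup_framing = speedup_framing,
    attention_choice = "receive", total_time_seconds = 400,
    completion_fraction = 1, age = 35, income = 5000, assets = 20000,
    debt = 1000, employment = "full_time", nonsense_flag = 0L
  )
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

# Vectorised conversion of enumerate_paths() rows into the wide response
# schema consumed by score_responses().
paths_to_responses <- function(paths, country = "US") {
  unpack <- function(pattern, i) {
    ch <- substr(pattern, i, i)
    dplyr::case_match(ch, "I" ~ "immediate", "D" ~ "delayed",
                      .default = NA_character_)
  }
  out <- tibble::tibble(
    participant_id = paste0("e", seq_len(nrow(paths))),
    country_id = country
  )
  for (set in c("small_gain", "loss", "large_gain")) {
    for (i in 1:3) out[[paste0(set, "_", i)]] <- unpack(paths[[set]], i)
  }
  for (a in c("present_bias", "subadditivity", "delay_framing",
              "speedup_framing")) {
    out[[a]] <- paths[[a]]
  }
  out
}

# Deterministic agents built straight from a parameter grid row.
population_from_grid <- function(grid, anchor = 500, country = "US",
                                 temperature = 0) {
  n <- nrow(grid)
  dplyr::bind_cols(
    tibble::tibble(
      participant_id = sprintf("G%03d", seq_len(n)),
      country_id = country,
      gini = NA_real_, log_gdp_pc = NA_real_, inflation_rate = NA_real_,
      log_rate_latent = log(grid$rate)
    ),
    respondent_params(
      model_family = grid$model_family, rate = grid$rate, beta = grid$beta,
      sign_ratio = grid$sign_ratio,
      magnitude_exponent = grid$magnitude_exponent,
      framing_premium = grid$framing_premium,
      subadd_exponent = grid$subadd_exponent,
      temperature = temperature, anchor_ref = anchor
    )
  )
}

no_injection_config <- function(...) {
  population_config(rate_attention = 0, rate_fast = 0, rate_incomplete = 0,
                    rate_age = 0, rate_extreme_income = 0, rate_nonsense = 0,
                    ...)
}
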