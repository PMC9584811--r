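#' Build a validated country anchor table
#'
#' Each country entering the instrument is described by a monetary anchor --
#' approximately 10% of the national average monthly household income, in
#' local currency -- plus the macroeconomic covariates used downstream
#' (Gini coefficient, log per-capita GDP, annual inflation). All instrument
#' amounts are constant proportions of the anchor, so the same staircase
#' adapts to any currency or income standard.
#'
#' @param df A data frame with columns `country_id`, `currency_label`,
#'   `anchor_value` and optionally `large_multiplier` (default 10), `gini`
#'   (fraction in `[0, 1]`), `log_gdp_pc`, `inflation_rate` (percent/year).
#' @param gini_convention Either `"fraction"` (values in `[0, 1]`, default)
#'   or `"percent"` (values in `[0, 100]`, rescaled to fractions on input).
#'
#' @return A tibble with one row per country and the columns above, Gini
#'   stored as a fraction.
#' @examples
#' country_anchors(data.frame(
#'   country_id = "US", currency_label = "USD", anchor_value = 500,
#'   gini = 0.41, log_gdp_pc = 11.0, inflation_rate = 4.7
#' ))
#' @export
country_anchors <- function(df, gini_convention = c("fraction", "percent")) {
  gini_convention <- match.arg(gini_convention)
  df <- as_tibble(df)
  required <- c("country_id", "currency_label", "anchor_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Country table is missing required columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"large_multiplier" %in% names(df)) df$large_multiplier <- 10
  for (col in c("gini", "log_gdp_pc", "inflation_rate")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (any(!is.finite(df$anchor_value)) || any(df$anchor_value <= 0)) {
    abort("`anchor_value` must be positive and finite for every country.")
  }
  if (any(df$large_multiplier <= 0)) {
    abort("`large_multiplier` must be positive.")
  }
  if (gini_convention == "percent") df$gini <- df$gini / 100
  if (any(df$gini < 0 | df$gini > 1, na.rm = TRUE)) {
    abort("`gini` must lie in [0, 1] under the declared convention.")
  }
  if (anyDuplicated(df$country_id)) {
    abort("`country_id` must be unique.")
  }
  df[c("country_id", "currency_label", "anchor_value", "large_multiplier",
       "gini", "log_gdp_pc", "inflation_rate")]
}

#' Generate a synthetic multi-country anchor table
#'
#' Draws a plausible table of monetary anchors and macro covariates for a
#' simulated multi-country study. This is a synthetic stand-in for a real
#' country configuration: anchors are log-uniform across three orders of
#' magnitude (currencies differ wildly in unit value), Gini coefficients span
#' roughly 0.25-0.55, log per-capita GDP 7-11.5, and inflation is lognormal
#' with a heavy right tail so a few countries sit in the >10% regime.
#'
#' @param n_countries Number of countries (default 61, the scale of a large
#'   cross-country study).
#' @param seed Integer seed; the table is a pure function of it.
#' @return A validated anchor tibble (see [country_anchors()]).
#' @examples
#' synthetic_country_table(5, seed = 1)
#' @export
synthetic_country_table <- function(n_countries = 61, seed = 1L) {
  stopifnot(n_countries >= 1)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    code
  }
  withr_seed({
    id <- sprintf("C%02d", seq_len(n_countries))
    log_gdp <- stats::runif(n_countries, 7, 11.5)
    country_anchors(tibble(
      country_id = id,
      currency_label = paste0("CUR", id),
      anchor_value = round_currency(10^stats::runif(n_countries, 2, 5)),
      large_multiplier = 10,
      gini = stats::runif(n_countries, 0.25, 0.55),
      log_gdp_pc = log_gdp,
      # inflation loosely anti-correlated with GDP, heavy right tail
      inflation_rate = round(stats::rlnorm(n_countries,
                                           meanlog = 1.2 + 0.15 * (9 - log_gdp),
                                           sdlog = 0.8), 1)
    ))
  })
}

#' Bundled five-country demo anchor table
#'
#' Reads the small synthetic anchor table shipped with the package, used by
#' the demo pipeline and examples.
#'
#' @return A validated anchor tibble.
#' @export
demo_country_table <- function() {
  path <- system.file("extdata", "demo_countries.csv",
                      package = "intertemporal", mustWork = TRUE)
  read_country_table(path)
}
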