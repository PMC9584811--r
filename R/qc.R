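#' Apply the pre-registered exclusion pipeline
#'
#' Screens a raw response table with the pre-registered quality-control
#' rules, in two stages. Stage one (applied to everyone):
#'
#' 1. attention check failed -- the participant chose to *pay* 10% of
#'    monthly income in a year rather than receive it now;
#' 2. nonsense free-text response (external boolean flag column);
#' 3. age above 100 years;
#' 4. response time below `median - 3 * MAD` (raw MAD, pooled median over
#'    records surviving rules 1-3) or below 120 seconds;
#' 5. survey completion of 90% or less.
#'
#' Stage two applies only to analyses of income, assets and debt and is
#' reported separately:
#'
#' 6. income, assets or debt above 1e8;
#' 7. income more than 100 MAD above the country median;
#' 8. assets more than 1000 MAD above the country median;
#' 9. zero income while employed full time.
#'
#' Country medians and MADs for rules 7-8 are computed on records surviving
#' rules 1-5. A record failing several rules is attributed to each of them
#' (so per-rule counts can sum to more than the total removed), but is
#' removed once. Missing optional fields never trigger rules 6-9.
#'
#' @param records Raw response tibble (see [simulate_study()] for the
#'   schema). Rule columns that are absent are skipped with a warning.
#' @param stage `"all"` (default) runs both stages; `"screening"` only
#'   rules 1-5; `"financial"` only rules 6-9 (on the input as given).
#' @param mad_constant Multiplier applied to the raw MAD in rule 4
#'   (default 3).
#' @param min_seconds Absolute response-time floor (default 120).
#' @param max_age Maximum credible age (default 100; older is removed).
#' @param completion_min Minimum completion fraction, exclusive
#'   (default 0.9).
#' @param extreme_value Absolute cap for money fields (default 1e8).
#' @param income_mads,assets_mads MAD multipliers for the country-level
#'   income and assets screens (defaults 100 and 1000).
#' @return A list of class `qc_report`: `retained` (records passing stage
#'   one), `retained_financial` (also passing stage two), `rule_counts`
#'   (tibble of per-rule removal counts), `failures` (logical matrix of
#'   record-by-rule failures), `overlap` (rule-by-rule joint failure
#'   counts), and `n_input` / `n_removed` / `n_removed_financial`.
#' @examples
#' sim <- simulate_study(
#'   sample_population(population_config(n_per_country = 50, seed = 2),
#'                     synthetic_country_table(2, seed = 2)),
#'   synthetic_country_table(2, seed = 2)
#' )
#' qc <- apply_exclusions(sim$responses)
#' tidy(qc)
#' @export
apply_exclusions <- function(records,
                             stage = c("all", "screening", "financial"),
                             mad_constant = 3,
                             min_seconds = 120,
                             max_age = 100,
                             completion_min = 0.9,
                             extreme_value = 1e8,
                             income_mads = 100,
                             assets_mads = 1000) {
  stage <- match.arg(stage)
  records <- as_tibble(records)
  n <- nrow(records)
  col_or_na <- function(nm, default = NA_real_) {
    if (nm %in% names(records)) records[[nm]] else {
      if (n > 0) warn(sprintf("Column `%s` missing; its rule passes all records.", nm))
      rep(default, n)
    }
  }
  false_if_na <- function(x) !is.na(x) & x

  fails <- list()
  if (stage %in% c("all", "screening")) {
    fails$attention <- false_if_na(col_or_na("attention_choice",
                                             NA_character_) == "pay")
    fails$nonsense_text <- false_if_na(col_or_na("nonsense_flag", 0) == 1)
    fails$overage <- false_if_na(col_or_na("age") > max_age)
    # rules 1-3 define the pool for the response-time median/MAD
    pool <- !(fails$attention | fails$nonsense_text | fails$overage)
    secs <- col_or_na("total_time_seconds")
    med <- stats::median(secs[pool], na.rm = TRUE)
    mad <- raw_mad(secs[pool])
    floor_secs <- max(min_seconds,
                      if (is.na(med) || is.na(mad)) -Inf
                      else med - mad_constant * mad)
    fails$fast_response <- false_if_na(secs < floor_secs)
    fails$incomplete <-
      false_if_na(col_or_na("completion_fraction") <= completion_min)
  }

  screening_rules <- intersect(
    c("attention", "nonsense_text", "overage", "fast_response", "incomplete"),
    names(fails))
  removed_screen <- Reduce(`|`, fails[screening_rules],
                           init = rep(FALSE, n))

  if (stage %in% c("all", "financial")) {
    income <- col_or_na("income")
    assets <- col_or_na("assets")
    debt <- col_or_na("debt")
    fails$extreme_values <- false_if_na(income > extreme_value) |
      false_if_na(assets > extreme_value) |
      false_if_na(debt > extreme_value)
    # country medians computed on records surviving stage one
    pool2 <- !removed_screen
    med_by_country <- function(x) {
      tibble(country_id = records$country_id[pool2], x = x[pool2]) |>
        group_by(.data$country_id) |>
        summarise(med = stats::median(.data$x, na.rm = TRUE),
                  mad = raw_mad(.data$x), .groups = "drop")
    }
    if ("country_id" %in% names(records) && n > 0) {
      inc_stats <- med_by_country(income)
      ast_stats <- med_by_country(assets)
      i_idx <- match(records$country_id, inc_stats$country_id)
      fails$income_outlier <- false_if_na(
        income > inc_stats$med[i_idx] + income_mads * inc_stats$mad[i_idx])
      a_idx <- match(records$country_id, ast_stats$country_id)
      fails$assets_outlier <- false_if_na(
        assets > ast_stats$med[a_idx] + assets_mads * ast_stats$mad[a_idx])
    } else {
      fails$income_outlier <- rep(FALSE, n)
      fails$assets_outlier <- rep(FALSE, n)
    }
    fails$zero_income_employed <- false_if_na(income == 0) &
      false_if_na(col_or_na("employment", NA_character_) == "full_time")
  }

  fail_mat <- do.call(cbind, fails)
  if (is.null(fail_mat)) fail_mat <- matrix(FALSE, n, 0)
  financial_rules <- intersect(
    c("extreme_values", "income_outlier", "assets_outlier",
      "zero_income_employed"), colnames(fail_mat))
  removed_fin <- Reduce(`|`, fails[financial_rules], init = rep(FALSE, n))

  retained <- records[!removed_screen, , drop = FALSE]
  retained_financial <- records[!(removed_screen | removed_fin), ,
                                drop = FALSE]
  rule_counts <- tibble(
    rule = colnames(fail_mat),
    stage = ifelse(colnames(fail_mat) %in% financial_rules,
                   "financial", "screening"),
    n_failed = as.integer(colSums(fail_mat))
  )
  overlap <- if (ncol(fail_mat) > 0) crossprod(fail_mat) else
    matrix(0L, 0, 0)

  structure(
    list(retained = retained,
         retained_financial = retained_financial,
         rule_counts = rule_counts,
         failures = fail_mat,
         overlap = overlap,
         n_input = n,
         n_removed = sum(removed_screen),
         n_removed_financial = sum(!removed_screen & removed_fin)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Quality-control report: %d records in, %d removed (screening), %d flagged (financial), %d fully retained\n",
              x$n_input, x$n_removed, x$n_removed_financial,
              nrow(x$retained_financial)))
  print(x$rule_counts)
  invisible(x)
}

#' @rdname apply_exclusions
#' @param x A `qc_report`.
#' @param ... Unused.
#' @export
tidy.qc_report <- function(x, ...) x$rule_counts

#' @rdname apply_exclusions
#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_input = x$n_input,
         n_removed = x$n_removed,
         n_removed_financial = x$n_removed_financial,
         n_retained = nrow(x$retained),
         n_retained_financial = nrow(x$retained_financial))
}
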