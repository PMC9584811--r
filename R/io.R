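#' @name file_formats
#' @title File formats
#'
#' @description
#' All tables travel as UTF-8 comma-separated text with a header row:
#' money as decimals in local currency units, times in months as integers,
#' booleans as 0/1, decimal points regardless of locale. Reports are JSON.
#' Readers validate the schema and name any missing columns.
NULL

RESPONSE_REQUIRED_COLS <- c(
  "participant_id", "country_id",
  paste0(rep(c("small_gain", "loss", "large_gain"), each = 3), "_", 1:3),
  "present_bias", "subadditivity", "delay_framing", "speedup_framing"
)

check_schema <- function(df, required, what, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s `%s` is missing required columns: %s.",
                  what, path, paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' Read and write response tables
#'
#' @param path File path.
#' @param responses A wide response tibble (see [simulate_study()]).
#' @return `read_responses()` returns the validated tibble;
#'   `write_responses()` returns `path` invisibly.
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        locale = readr::locale(decimal_mark = "."))
  check_schema(df, RESPONSE_REQUIRED_COLS, "Response file", path)
  df
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  check_schema(responses, RESPONSE_REQUIRED_COLS, "Response table", path)
  readr::write_csv(responses, path, progress = FALSE)
  invisible(path)
}

#' Read and write scored tables
#'
#' @param path File path.
#' @param scored A scored tibble from [score_responses()].
#' @return `read_scored()` returns the validated tibble.
#' @export
read_scored <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_schema(df, c("participant_id", "country_id", "discounting_score"),
               "Scored file", path)
  flag_cols <- grep("^(anomaly_|inconsistent_|indifference_censored)",
                    names(df), value = TRUE)
  df[flag_cols] <- lapply(df[flag_cols], function(x) as.logical(as.integer(x)))
  df
}

#' @rdname read_scored
#' @export
write_scored <- function(scored, path) {
  out <- scored
  flag_cols <- grep("^(anomaly_|inconsistent_|indifference_censored)",
                    names(out), value = TRUE)
  out[flag_cols] <- lapply(out[flag_cols], as.integer)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a country anchor table from CSV, YAML or JSON
#'
#' @param path File path; format chosen by extension (`.csv`, `.yaml`/
#'   `.yml`, `.json`).
#' @param ... Passed to [country_anchors()] (e.g. `gini_convention`).
#' @return A validated anchor tibble.
#' @export
read_country_table <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(
    ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    yaml = ,
    yml = bind_rows(lapply(yaml::read_yaml(path), as_tibble)),
    json = as_tibble(jsonlite::fromJSON(path)),
    abort(sprintf("Unsupported country-table format: '%s'.", ext))
  )
  country_anchors(df, ...)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [apply_exclusions()].
#' @param path Output path.
#' @param seed,config_hash Optional run metadata embedded in the report.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path, seed = NULL, config_hash = NULL) {
  payload <- list(
    meta = list(seed = seed, config_hash = config_hash,
                package_version = as.character(utils::packageVersion("intertemporal"))),
    n_input = report$n_input,
    n_removed = report$n_removed,
    n_removed_financial = report$n_removed_financial,
    n_retained = nrow(report$retained),
    rule_counts = report$rule_counts,
    overlap = as.data.frame(as.table(report$overlap))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_fingerprint <- function(config) {
  # stable content hash without extra dependencies
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_along(utf8ToInt(as.character(s))) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full study pipeline
#'
#' Chains the stages end to end: (optionally) simulate a study from a
#' country anchor table, apply the quality-control exclusions, score the
#' retained responses, standardise, aggregate by country and meta-analyse.
#' Artifacts (scored CSV, QC JSON, per-country CSV, aggregate JSON, run
#' manifest) are written to `out_dir`; every artifact records the seed and
#' a config fingerprint. Stage failures abort with the stage name.
#'
#' @param anchors Country anchor tibble, or a path readable by
#'   [read_country_table()].
#' @param out_dir Output directory (created if needed).
#' @param responses Optional raw response tibble or CSV path; when `NULL`,
#'   responses are simulated from `config`.
#' @param config A [population_config()] used for simulation.
#' @param seed Overrides `config$seed` when given.
#' @param skip_qc Skip the exclusion stage (score everything).
#' @param rule_variant,present_bias_rule Passed to [score_responses()].
#' @return Invisibly, a list with `responses`, `qc`, `scored`,
#'   `country_summary`, `meta_scores` (a `meta_result`),
#'   `anomaly_meta` (list of `meta_result` per anomaly),
#'   `variance_partition`, and the artifact `paths`.
#' @export
run_pipeline <- function(anchors, out_dir,
                         responses = NULL,
                         config = population_config(),
                         seed = NULL,
                         skip_qc = FALSE,
                         rule_variant = "example",
                         present_bias_rule = "shifted") {
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)))
    })
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)

  anchors <- run_stage("config", {
    if (is.character(anchors)) read_country_table(anchors) else
      country_anchors(anchors)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim_truth <- NULL
  responses <- run_stage("simulate", {
    if (is.null(responses)) {
      pop <- sample_population(config, anchors)
      sim <- simulate_study(pop, anchors, config)
      sim_truth <- sim$agents
      sim$responses
    } else if (is.character(responses)) {
      read_responses(responses)
    } else {
      as_tibble(responses)
    }
  })

  qc <- run_stage("qc", {
    if (skip_qc) NULL else apply_exclusions(responses)
  })
  retained <- if (skip_qc) responses else qc$retained

  scored <- run_stage("score", {
    s <- score_responses(retained, anchors,
                         rule_variant = rule_variant,
                         present_bias_rule = present_bias_rule)
    s$z_score <- standardize_scores(s$discounting_score)
    s
  })

  agg <- run_stage("aggregate", {
    summary <- summarize_countries(scored, anchors)
    meta_scores <- random_effects_meta(summary$mean_score, summary$var_mean,
                                       labels = summary$country_id)
    prop_cols <- grep("^n_", names(summary), value = TRUE)
    anomaly_meta <- lapply(stats::setNames(prop_cols, sub("^n_", "", prop_cols)),
                           function(col) {
                             proportion_meta(summary[[col]], summary$n,
                                             labels = summary$country_id)
                           })
    vp <- variance_partition(scored$discounting_score, scored$country_id)
    list(summary = summary, meta_scores = meta_scores,
         anomaly_meta = anomaly_meta, vp = vp)
  })

  paths <- run_stage("write", {
    fp <- config_fingerprint(unclass(config))
    p <- list(
      scored = file.path(out_dir, "scored.csv"),
      qc = file.path(out_dir, "qc_report.json"),
      country = file.path(out_dir, "country_summary.csv"),
      aggregate = file.path(out_dir, "aggregate.json"),
      manifest = file.path(out_dir, "run_manifest.json")
    )
    write_scored(scored, p$scored)
    if (!skip_qc) write_qc_report(qc, p$qc, seed = config$seed,
                                  config_hash = fp)
    readr::write_csv(agg$summary, p$country, progress = FALSE)
    jsonlite::write_json(
      list(meta = list(seed = config$seed, config_hash = fp),
           scores = glance(agg$meta_scores),
           anomalies = lapply(agg$anomaly_meta, glance),
           variance_partition = glance(agg$vp)),
      p$aggregate, auto_unbox = TRUE, digits = NA, pretty = TRUE,
      dataframe = "rows")
    jsonlite::write_json(
      list(seed = config$seed, config_hash = fp,
           package_version = as.character(utils::packageVersion("intertemporal")),
           r_version = as.character(getRversion()),
           n_countries = nrow(anchors),
           n_responses = nrow(responses),
           n_retained = nrow(retained),
           artifacts = lapply(p, basename)),
      p$manifest, auto_unbox = TRUE, pretty = TRUE)
    p
  })

  invisible(list(responses = responses, truth = sim_truth, qc = qc,
                 scored = scored, country_summary = agg$summary,
                 meta_scores = agg$meta_scores,
                 anomaly_meta = agg$anomaly_meta,
                 variance_partition = agg$vp,
                 paths = paths))
}
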