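#' Per-country summaries of scored responses
#'
#' Collapses a scored response table to one row per country: sample size,
#' mean and SD of the discounting score, and count/proportion for each
#' anomaly flag; country covariates are joined from the anchor table when
#' given.
#'
#' @param scored Scored tibble from [score_responses()].
#' @param anchors Optional anchor tibble whose covariates (`gini`,
#'   `log_gdp_pc`, `inflation_rate`) are joined by `country_id`.
#' @return A tibble with one row per country: `n`, `mean_score`,
#'   `sd_score`, `var_mean` (`sd^2 / n`, the sampling variance of the
#'   mean), and `n_<flag>` / `prop_<flag>` per anomaly.
#' @export
summarize_countries <- function(scored, anchors = NULL) {
  scored <- as_tibble(scored)
  flag_cols <- grep("^anomaly_", names(scored), value = TRUE)
  out <- scored |>
    group_by(.data$country_id) |>
    summarise(
      n = dplyr::n(),
      mean_score = mean(.data$discounting_score),
      sd_score = stats::sd(.data$discounting_score),
      across(dplyr::all_of(flag_cols),
             list(n = ~sum(.x), prop = ~mean(.x)),
             .names = "{.fn}_{sub('anomaly_', '', .col)}"),
      .groups = "drop"
    ) |>
    mutate(var_mean = .data$sd_score^2 / .data$n,
           .after = "sd_score")
  if (!is.null(anchors)) {
    anchors <- country_anchors(anchors)
    out <- left_join(out,
                     anchors[c("country_id", "gini", "log_gdp_pc",
                               "inflation_rate")],
                     by = "country_id")
  }
  out
}

meta_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(est - z * se, est + z * se)
}

#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Pools per-country estimates with the classical method-of-moments
#' random-effects model: `tau^2 = max(0, (Q - df) / C)` from the
#' fixed-effect weights, inverse-variance pooling with weights
#' `1 / (v_i + tau^2)`, heterogeneity `I^2 = max(0, (Q - df) / Q)`, and a
#' 95% prediction interval using a t quantile with `k - 2` degrees of
#' freedom (undefined for `k = 2`).
#'
#' @param estimates Numeric vector of per-study estimates (length `k >= 2`).
#' @param variances Positive sampling variances, same length.
#' @param labels Optional study labels (used by [autoplot.meta_result()]).
#' @param level Confidence level (default 0.95).
#' @return An object of class `meta_result`; see [tidy.meta_result()] /
#'   [glance.meta_result()].
#' @examples
#' m <- random_effects_meta(c(0, 2), c(1, 1))
#' glance(m) # Q = 2, I2 = 0.5, tau2 = 1, pooled = 1
#' @export
random_effects_meta <- function(estimates, variances, labels = NULL,
                                level = 0.95) {
  k <- length(estimates)
  if (k < 2) abort("Meta-analysis needs at least 2 studies.")
  if (length(variances) != k) abort("`estimates` and `variances` differ in length.")
  if (any(variances <= 0) || any(!is.finite(variances))) {
    abort("All `variances` must be positive and finite.")
  }
  w <- 1 / variances
  fixed <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - fixed)^2)
  df <- k - 1
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / c_dl)
  w_star <- 1 / (variances + tau2)
  pooled <- sum(w_star * estimates) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  ci <- meta_ci(pooled, se, level)
  i2 <- max(0, (q - df) / q)
  if (k >= 3) {
    t_crit <- stats::qt(1 - (1 - level) / 2, df = k - 2)
    pi_half <- t_crit * sqrt(tau2 + se^2)
    pred <- c(pooled - pi_half, pooled + pi_half)
  } else {
    pred <- c(NA_real_, NA_real_)
  }
  structure(
    list(pooled = pooled, se = se, tau2 = tau2, q = q, df = df,
         q_pvalue = stats::pchisq(q, df, lower.tail = FALSE),
         i2 = i2, ci_lower = ci[1], ci_upper = ci[2],
         pi_lower = pred[1], pi_upper = pred[2],
         k = k, level = level,
         estimates = estimates, variances = variances,
         labels = labels %||% paste0("study_", seq_len(k)),
         scale = "identity"),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (DL), k = %d%s\n  pooled = %.4g [%.4g, %.4g], tau2 = %.4g, Q = %.4g (df %d, p = %.3g), I2 = %.1f%%\n",
    x$k, if (x$scale == "logit") " [logit scale]" else "",
    x$pooled, x$ci_lower, x$ci_upper, x$tau2, x$q, x$df, x$q_pvalue,
    100 * x$i2))
  if (!is.na(x$pi_lower)) {
    cat(sprintf("  %d%% prediction interval: [%.4g, %.4g]\n",
                round(100 * x$level), x$pi_lower, x$pi_upper))
  }
  invisible(x)
}

#' Broom-style accessors for meta-analysis results
#'
#' `tidy()` returns the per-study rows (estimates, variances and
#' random-effects weights); `glance()` returns the one-row model summary.
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.meta_result <- function(x, ...) {
  tibble(label = x$labels,
         estimate = x$estimates,
         variance = x$variances,
         weight = (1 / (x$variances + x$tau2)) /
           sum(1 / (x$variances + x$tau2)))
}

#' @rdname tidy.meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble(pooled = x$pooled, se = x$se, ci_lower = x$ci_lower,
         ci_upper = x$ci_upper, pi_lower = x$pi_lower,
         pi_upper = x$pi_upper, tau2 = x$tau2, q = x$q, df = x$df,
         q_pvalue = x$q_pvalue, i2 = x$i2, k = x$k)
}

#' Mixed-effects meta-regression (method of moments)
#'
#' Weighted least squares of study estimates on moderators with a
#' method-of-moments residual between-study variance: the residual
#' heterogeneity statistic `Q_E` from the fixed-effect fit gives
#' `tau2 = max(0, (Q_E - (k - p)) / c)` with
#' `c = tr(W) - tr((X'WX)^{-1} X'W^2X)`, after which the coefficients are
#' re-estimated with weights `1 / (v_i + tau2)`.
#'
#' @param estimates,variances As in [random_effects_meta()], `k >= 3`.
#' @param moderators A numeric vector, matrix or data frame of moderator
#'   values (one row per study); an intercept is added.
#' @param level Confidence level.
#' @return An object of class `meta_regression`; `tidy()` gives the
#'   coefficient table, `glance()` the fit summary.
#' @export
meta_regression <- function(estimates, variances, moderators, level = 0.95) {
  y <- as.numeric(estimates)
  k <- length(y)
  x <- as.matrix(as.data.frame(moderators))
  if (nrow(x) != k || length(variances) != k) {
    abort("`estimates`, `variances` and `moderators` must have one row per study.")
  }
  if (any(apply(x, 2, function(col) stats::sd(col) == 0))) {
    abort("Moderators must vary across studies.")
  }
  if (k < ncol(x) + 2) abort("Too few studies for the moderator set.")
  design <- cbind(`(Intercept)` = 1, x)
  p <- ncol(design)

  wls <- function(w) {
    xtwx <- crossprod(design, design * w)
    coef <- solve(xtwx, crossprod(design, y * w))
    list(coef = drop(coef), cov = solve(xtwx))
  }
  w_fe <- 1 / variances
  fit_fe <- wls(w_fe)
  resid <- y - design %*% fit_fe$coef
  q_e <- sum(w_fe * resid^2)
  # trace correction for the moments estimator under the FE weights
  xtwx_inv <- solve(crossprod(design, design * w_fe))
  trace_term <- sum(diag(xtwx_inv %*% crossprod(design, design * w_fe^2)))
  c_mom <- sum(w_fe) - trace_term
  tau2 <- max(0, (q_e - (k - p)) / c_mom)

  w_re <- 1 / (variances + tau2)
  fit <- wls(w_re)
  fit$coef <- unname(fit$coef)
  se <- unname(sqrt(diag(fit$cov)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- tibble(
    term = colnames(design),
    estimate = fit$coef,
    std_error = se,
    statistic = fit$coef / se,
    p_value = 2 * stats::pnorm(-abs(fit$coef / se)),
    conf_low = fit$coef - z * se,
    conf_high = fit$coef + z * se
  )
  structure(
    list(coefficients = coefs, tau2 = tau2, q_e = q_e, df = k - p,
         q_pvalue = stats::pchisq(q_e, k - p, lower.tail = FALSE),
         k = k, level = level),
    class = "meta_regression"
  )
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("Meta-regression (MoM), k = %d, residual tau2 = %.4g, Q_E = %.4g (df %d, p = %.3g)\n",
              x$k, x$tau2, x$q_e, x$df, x$q_pvalue))
  print(x$coefficients)
  invisible(x)
}

#' @rdname meta_regression
#' @param x A `meta_regression`.
#' @param ... Unused.
#' @export
tidy.meta_regression <- function(x, ...) x$coefficients

#' @rdname meta_regression
#' @export
glance.meta_regression <- function(x, ...) {
  tibble(tau2 = x$tau2, q_e = x$q_e, df = x$df, q_pvalue = x$q_pvalue,
         k = x$k)
}

#' Between/within-country variance partition
#'
#' One-way random-effects ANOVA components by the method of moments with
#' the unbalanced-design correction `n0 = (N - sum(n_i^2) / N) / (k - 1)`:
#' `sigma2_between = max(0, (MSB - MSW) / n0)` and the intraclass share
#' `sigma2_between / (sigma2_between + MSW)`.
#'
#' @param scores Numeric vector (individual scores, or any latent trait).
#' @param country Grouping labels, same length; at least 2 groups.
#' @return An object of class `variance_partition` with fields
#'   `between`, `within`, `icc`, `k`, `n`; `tidy()`/`glance()` available.
#' @examples
#' variance_partition(c(1, 2, 11, 12), c("a", "a", "b", "b"))
#' @export
variance_partition <- function(scores, country) {
  if (length(scores) != length(country)) {
    abort("`scores` and `country` must have the same length.")
  }
  keep <- !is.na(scores) & !is.na(country)
  scores <- scores[keep]
  country <- as.character(country[keep])
  groups <- unique(country)
  k <- length(groups)
  if (k < 2) abort("Variance partition needs at least 2 countries.")
  n_i <- tapply(scores, country, length)
  if (max(n_i) < 2) abort("At least one country needs 2 or more scores.")
  n_total <- length(scores)
  means <- tapply(scores, country, mean)
  grand <- mean(scores)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum((scores - means[country])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n_total - k)
  n0 <- (n_total - sum(n_i^2) / n_total) / (k - 1)
  between <- max(0, (msb - msw) / n0)
  structure(
    list(between = between, within = msw,
         icc = between / (between + msw),
         k = k, n = n_total),
    class = "variance_partition"
  )
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition over %d countries (N = %d):\n  between = %.4g, within = %.4g, intraclass share = %.3f\n",
              x$k, x$n, x$between, x$within, x$icc))
  invisible(x)
}

#' @rdname variance_partition
#' @param x A `variance_partition`.
#' @param ... Unused.
#' @export
tidy.variance_partition <- function(x, ...) {
  tibble(component = c("between_country", "within_country"),
         variance = c(x$between, x$within),
         share = c(x$icc, 1 - x$icc))
}

#' @rdname variance_partition
#' @export
glance.variance_partition <- function(x, ...) {
  tibble(between = x$between, within = x$within, icc = x$icc,
         k = x$k, n = x$n)
}

#' Random-effects pooling of anomaly proportions
#'
#' Pools per-country proportions on the logit scale (with a 0.5 continuity
#' correction applied at the boundaries), using the same DerSimonian-Laird
#' machinery as [random_effects_meta()], and back-transforms the pooled
#' estimate and its intervals to the proportion scale.
#'
#' @param counts Per-country event counts.
#' @param ns Per-country sample sizes; countries with `n = 0` are dropped
#'   with a warning.
#' @param labels Optional country labels.
#' @param level Confidence level.
#' @return A `meta_result` whose `pooled`, `ci_*` and `pi_*` fields are
#'   proportions (the logit-scale result is kept in `$logit`).
#' @examples
#' proportion_meta(c(10, 30), c(100, 100))
#' @export
proportion_meta <- function(counts, ns, labels = NULL, level = 0.95) {
  if (length(counts) != length(ns)) {
    abort("`counts` and `ns` must have the same length.")
  }
  if (any(counts < 0 | counts > ns)) {
    abort("Counts must satisfy 0 <= count <= n.")
  }
  labels <- labels %||% paste0("country_", seq_along(counts))
  drop <- ns == 0
  if (any(drop)) {
    warn(sprintf("Dropping %d countries with n = 0.", sum(drop)))
    counts <- counts[!drop]; ns <- ns[!drop]; labels <- labels[!drop]
  }
  boundary <- counts == 0 | counts == ns
  x_adj <- ifelse(boundary, counts + 0.5, counts)
  n_adj <- ifelse(boundary, ns + 1, ns)
  logit <- log(x_adj / (n_adj - x_adj))
  v <- 1 / x_adj + 1 / (n_adj - x_adj)
  m <- random_effects_meta(logit, v, labels = labels, level = level)
  back <- stats::plogis
  m$logit <- list(pooled = m$pooled, ci_lower = m$ci_lower,
                  ci_upper = m$ci_upper, pi_lower = m$pi_lower,
                  pi_upper = m$pi_upper)
  m$pooled <- back(m$pooled)
  m$ci_lower <- back(m$ci_lower)
  m$ci_upper <- back(m$ci_upper)
  m$pi_lower <- if (is.na(m$pi_lower)) m$pi_lower else back(m$pi_lower)
  m$pi_upper <- if (is.na(m$pi_upper)) m$pi_upper else back(m$pi_upper)
  m$scale <- "logit"
  m
}
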