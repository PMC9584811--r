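#' @name scoring
#' @title Discounting score and anomaly classification
#'
#' @description
#' A complete instrument path is scored in three parts:
#'
#' * each baseline staircase set maps to an integer category 0-5 ordered by
#'   revealed impatience (0 = accepted the 101% delayed offer,
#'   5 = rejected even the 150% offer; the loss set mirrored so that
#'   deferring payments scores high);
#' * each of the four anomaly items contributes one point when the
#'   discount-consistent (immediate-gain) option is chosen;
#' * the discounting score is the sum, ranging 0 (always delayed gains /
#'   immediate losses) to 19 (always immediate gains / delayed losses).
#'
#' Five anomaly flags are derived from the worked-example (first-item)
#' rules, together with five mirror-image inconsistency flags; a stricter
#' category-difference variant of the magnitude and gain-loss rules and a
#' two-leg variant of the present-bias rule are available behind switches.
NULL

# Category by revealed impatience for a gain-set pattern. Losses use the
# same table after swapping I/D (deferring a payment = impatient).
GAIN_CATEGORY <- c(DDD = 0L, DDI = 1L, DI = 2L, ID = 3L, IID = 4L, III = 5L)

swap_pattern <- function(pattern) {
  chartr("ID", "DI", pattern)
}

#' Titration category of one completed staircase set
#'
#' @param pattern Completed set pattern(s), `"I"`/`"D"` per item (e.g.
#'   `"ID"`).
#' @param set_id The set the pattern belongs to; the loss set is scored
#'   mirrored.
#' @return Integer categories in 0-5 (0 = most patient, 5 = most
#'   impatient).
#' @examples
#' titration_category("DDD", "small_gain") # 0
#' titration_category("III", "small_gain") # 5
#' titration_category("DDD", "loss")       # 5: always defer the payment
#' @export
titration_category <- function(pattern, set_id) {
  set_id <- rep_len(set_id, length(pattern))
  if (!all(set_id %in% BASELINE_SETS)) abort("Unknown `set_id`.")
  bad <- !pattern %in% VALID_SET_PATTERNS
  if (any(bad)) {
    abort(sprintf("Invalid staircase pattern(s): %s.",
                  paste(unique(pattern[bad]), collapse = ", ")))
  }
  effective <- ifelse(set_id == "loss", swap_pattern(pattern), pattern)
  unname(GAIN_CATEGORY[effective])
}

anomaly_point <- function(choice) {
  assert_choice_values(choice)
  as.integer(choice == "immediate")
}

first_choice <- function(pattern) substr(pattern, 1, 1)

#' Score and classify a table of instrument responses
#'
#' The main scoring entry point: takes the wide response table (one row per
#' participant, as emitted by [simulate_study()] or read with
#' [read_responses()]) and returns one scored row per participant with
#' titration categories, the derived indifference point, the 0-19
#' discounting score, five anomaly flags and five mirror inconsistency
#' flags.
#'
#' @param responses Wide response tibble with per-item choice columns
#'   (`small_gain_1` ... `speedup_framing`) and `country_id`.
#' @param anchors Country anchor tibble used to reconstruct indifference
#'   values; may be omitted if `responses` carries an `anchor_value`
#'   column.
#' @param rule_variant `"example"` (default): anomaly rules at the
#'   first-item level, following the worked examples. `"category"`: the
#'   magnitude and gain-loss flags instead compare whole-set categories
#'   (`category_small_gain > category_large_gain`, resp. `> category_loss`).
#' @param present_bias_rule `"shifted"` (default): present bias = delayed
#'   chosen at the shifted 12-to-24-month item. `"conjunction"`: requires
#'   in addition the immediate choice at the first small-gain item (the
#'   two-leg form of the worked example).
#' @param denomination Currency rounding unit.
#' @return A tibble with one row per participant: `participant_id`,
#'   `country_id`, `category_*`, `indifference_value`,
#'   `indifference_censored`, `discounting_score`, `anomaly_*` flags and
#'   `inconsistent_*` flags (logicals).
#' @export
score_responses <- function(responses, anchors = NULL,
                            rule_variant = c("example", "category"),
                            present_bias_rule = c("shifted", "conjunction"),
                            denomination = 1) {
  rule_variant <- match.arg(rule_variant)
  present_bias_rule <- match.arg(present_bias_rule)
  responses <- as_tibble(responses)
  needed <- c("participant_id", "country_id",
              paste0(rep(BASELINE_SETS, each = 2), "_", 1:2), ANOMALY_ITEMS)
  missing_cols <- setdiff(needed, names(responses))
  if (length(missing_cols) > 0) {
    abort(sprintf("Response table is missing columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  for (s in BASELINE_SETS) {
    col3 <- paste0(s, "_3")
    if (!col3 %in% names(responses)) responses[[col3]] <- NA_character_
  }

  if (is.null(anchors)) {
    if (!"anchor_value" %in% names(responses)) {
      abort("Provide `anchors` or an `anchor_value` column.")
    }
    anchor_value <- responses$anchor_value
  } else {
    anchors <- country_anchors(anchors)
    anchor_value <- anchors$anchor_value[
      match(responses$country_id, anchors$country_id)]
    if (any(is.na(anchor_value))) {
      abort("Some `country_id`s are absent from the anchor table.")
    }
  }

  pat <- lapply(BASELINE_SETS, function(s) {
    choices_to_pattern(responses[[paste0(s, "_1")]],
                       responses[[paste0(s, "_2")]],
                       responses[[paste0(s, "_3")]])
  })
  names(pat) <- BASELINE_SETS
  bad <- !pat$small_gain %in% VALID_SET_PATTERNS |
    !pat$loss %in% VALID_SET_PATTERNS |
    !pat$large_gain %in% VALID_SET_PATTERNS
  if (any(bad)) {
    abort(sprintf("Incomplete staircase patterns for participant(s): %s.",
                  paste(utils::head(responses$participant_id[bad], 5),
                        collapse = ", ")))
  }

  ind <- derive_indifference(pat$small_gain, anchor_value, denomination)
  cat_sg <- titration_category(pat$small_gain, "small_gain")
  cat_loss <- titration_category(pat$loss, "loss")
  cat_lg <- titration_category(pat$large_gain, "large_gain")
  anomaly_points <- anomaly_point(responses$present_bias) +
    anomaly_point(responses$subadditivity) +
    anomaly_point(responses$delay_framing) +
    anomaly_point(responses$speedup_framing)

  sg1 <- first_choice(pat$small_gain)
  lg1 <- first_choice(pat$large_gain)
  ls1 <- first_choice(pat$loss)
  pb_delayed <- responses$present_bias == "delayed"
  sub_delayed <- responses$subadditivity == "delayed"
  delay_imm <- responses$delay_framing == "immediate"
  speed_del <- responses$speedup_framing == "delayed"

  if (rule_variant == "example") {
    flag_mag <- sg1 == "I" & lg1 == "D"
    flag_gl <- sg1 == "I" & ls1 == "I"
    mirror_mag <- sg1 == "D" & lg1 == "I"
    mirror_gl <- sg1 == "D" & ls1 == "D"
  } else {
    flag_mag <- cat_sg > cat_lg
    flag_gl <- cat_sg > cat_loss
    mirror_mag <- cat_sg < cat_lg
    mirror_gl <- cat_sg < cat_loss
  }
  flag_pb <- if (present_bias_rule == "shifted") pb_delayed else
    pb_delayed & sg1 == "I"
  mirror_pb <- if (present_bias_rule == "shifted") !pb_delayed else
    !pb_delayed & sg1 == "D"
  flag_ds <- delay_imm & speed_del
  mirror_ds <- !delay_imm & !speed_del
  flag_sub <- sub_delayed & !pb_delayed
  mirror_sub <- !sub_delayed & pb_delayed

  tibble(
    participant_id = responses$participant_id,
    country_id = responses$country_id,
    category_small_gain = cat_sg,
    category_loss = cat_loss,
    category_large_gain = cat_lg,
    indifference_value = ind$indifference_value,
    indifference_censored = ind$indifference_censored,
    discounting_score = cat_sg + cat_loss + cat_lg + anomaly_points,
    anomaly_absolute_magnitude = flag_mag,
    anomaly_gain_loss = flag_gl,
    anomaly_delay_speedup = flag_ds,
    anomaly_present_bias = flag_pb,
    anomaly_subadditivity = flag_sub,
    inconsistent_reverse_magnitude = mirror_mag,
    inconsistent_reverse_gain_loss = mirror_gl,
    inconsistent_reverse_framing = mirror_ds,
    inconsistent_future_bias = mirror_pb,
    inconsistent_superadditivity = mirror_sub
  )
}

#' Aggregate discounting score of one complete path
#'
#' Sums the three titration categories and the four discount-consistent
#' anomaly-item points for paths given as set patterns and anomaly choices
#' (vectorised).
#'
#' @param small_gain,loss,large_gain Completed set patterns (e.g. `"III"`).
#' @param present_bias,subadditivity,delay_framing,speedup_framing Choices
#'   at the anomaly items (`"immediate"`/`"delayed"`).
#' @return The integer score in 0-19.
#' @examples
#' discounting_score("III", "DDD", "III",
#'                   "immediate", "immediate", "immediate", "immediate") # 19
#' @export
discounting_score <- function(small_gain, loss, large_gain,
                              present_bias, subadditivity,
                              delay_framing, speedup_framing) {
  titration_category(small_gain, "small_gain") +
    titration_category(loss, "loss") +
    titration_category(large_gain, "large_gain") +
    anomaly_point(present_bias) + anomaly_point(subadditivity) +
    anomaly_point(delay_framing) + anomaly_point(speedup_framing)
}

#' Standardise discounting scores
#'
#' Pooled-sample z-transform (sample SD, `n - 1` denominator), as used for
#' analysis and visualisation when raw 0-19 scores have no external
#' standard.
#'
#' @param x Numeric scores from the retained pooled sample.
#' @return z-scores with mean 0 and SD 1.
#' @export
standardize_scores <- function(x) {
  if (length(x) < 2) abort("Need at least 2 scores to standardise.")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Scores have zero variance; z-scores are undefined.")
  }
  (x - mean(x)) / s
}
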