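#' @name instrument
#' @title The adaptive titration instrument
#'
#' @description
#' The elicitation instrument is a deterministic state machine over three
#' baseline staircase sets followed by four anomaly items:
#'
#' * `small_gain`: receive the anchor amount now vs. a larger amount in 12
#'   months. The first delayed offer is 110% of the anchor. An impatient
#'   (immediate) choice moves the delayed offer up the ascending ladder
#'   (120%, then 150%); a patient choice moves it down the descending ladder
#'   (102%, then 101%). A reversal at the second item terminates the set, so
#'   each set takes 2 or 3 items and has exactly six terminal patterns.
#' * `loss`: the identical values framed as payments. Here paying *later* is
#'   the impatient choice, so the ladder ascends after "delayed" and
#'   descends after "immediate".
#' * `large_gain`: the gain set repeated at `large_multiplier` (default 10)
#'   times the anchor.
#'
#' The simplified indifference point is the smallest delayed amount the
#' participant accepted in the small-gain set (see [derive_indifference()]);
#' it parameterises the four anomaly items (see [build_anomaly_items()]).
#' Complete paths therefore span 10 to 13 binary items.
#' @keywords internal
NULL

# Staircase multipliers: first offer, then ascending / descending ladders.
TITRATION_FIRST <- 1.10
TITRATION_ASC <- c(1.20, 1.50)
TITRATION_DESC <- c(1.02, 1.01)

BASELINE_SETS <- c("small_gain", "loss", "large_gain")
ANOMALY_ITEMS <- c("present_bias", "subadditivity",
                   "delay_framing", "speedup_framing")

# The six terminal response patterns of one staircase set, written as
# "I"/"D" for immediate/delayed in presentation order.
VALID_SET_PATTERNS <- c("DDD", "DDI", "DI", "ID", "IID", "III")

set_base_amount <- function(anchor_value, set_id, large_multiplier = 10) {
  if (set_id == "large_gain") anchor_value * large_multiplier else anchor_value
}

set_sign <- function(set_id) if (set_id == "loss") "loss" else "gain"

# The choice that reveals impatience (stronger discounting) in a set:
# taking the gain now, or deferring the payment.
impatient_choice <- function(set_id) {
  if (set_id == "loss") "delayed" else "immediate"
}

#' Build the value schedule of one baseline staircase set
#'
#' Returns the immediate amount and the five possible delayed offers
#' (110%, 120%, 150%, 102% and 101% of the set base) for one baseline set,
#' rounded to the currency denomination.
#'
#' @param anchor An anchor tibble row (see [country_anchors()]) or a single
#'   positive anchor value.
#' @param set_id One of `"small_gain"`, `"loss"`, `"large_gain"`.
#' @param denomination Currency rounding unit (default 1).
#' @return A tibble with columns `set_id`, `sign`, `step` (`first`,
#'   `ascending_2`, `ascending_3`, `descending_2`, `descending_3`),
#'   `multiplier`, `immediate_amount`, `delayed_amount`.
#' @examples
#' build_titration_schedule(500, "small_gain")
#' @export
build_titration_schedule <- function(anchor, set_id = BASELINE_SETS,
                                     denomination = 1) {
  set_id <- match.arg(set_id)
  if (is.data.frame(anchor)) {
    stopifnot(nrow(anchor) == 1)
    anchor_value <- anchor$anchor_value
    large_multiplier <- anchor$large_multiplier %||% 10
  } else {
    anchor_value <- anchor
    large_multiplier <- 10
  }
  if (!is.finite(anchor_value) || anchor_value <= 0) {
    abort("`anchor_value` must be a positive number.")
  }
  base <- set_base_amount(anchor_value, set_id, large_multiplier)
  mult <- c(first = TITRATION_FIRST,
            ascending_2 = TITRATION_ASC[1], ascending_3 = TITRATION_ASC[2],
            descending_2 = TITRATION_DESC[1], descending_3 = TITRATION_DESC[2])
  tibble(
    set_id = set_id,
    sign = set_sign(set_id),
    step = names(mult),
    multiplier = unname(mult),
    immediate_amount = round_currency(base, denomination),
    delayed_amount = unname(round_currency(mult * base, denomination))
  )
}

new_titration_state <- function(set_id, anchor, denomination = 1) {
  schedule <- build_titration_schedule(anchor, set_id, denomination)
  structure(
    list(set_id = set_id, schedule = schedule, choices = character()),
    class = "titration_state"
  )
}

state_pattern <- function(state) {
  paste(substr(toupper(state$choices), 1, 1), collapse = "")
}

set_is_complete <- function(pattern) pattern %in% VALID_SET_PATTERNS

# Multiplier step presented at item `i` of a set, given earlier choices.
step_for_item <- function(set_id, choices, i) {
  if (i == 1) return("first")
  ascending <- choices[1] == impatient_choice(set_id)
  if (ascending) paste0("ascending_", i) else paste0("descending_", i)
}

#' Next item of a baseline staircase set
#'
#' Advances the deterministic staircase: records `prior_choice` (if given)
#' and returns the next choice item, or `NULL` when the set is terminal.
#' A reversal at the second item ends the set; two same-direction choices
#' lead to a third, final item.
#'
#' @param state A state created by `new_titration_state()` (or returned by a
#'   previous `next_item()` call, as `attr(item, "state")`).
#' @param prior_choice `"immediate"`, `"delayed"`, or `NULL` for the first
#'   item.
#' @return A one-row item tibble with the updated state attached as
#'   `attr(, "state")`, or `NULL` at the terminal. Requesting an item after
#'   the terminal is an error.
#' @examples
#' st <- new_titration_state("small_gain", 500)
#' item1 <- next_item(st)
#' item2 <- next_item(attr(item1, "state"), "immediate")
#' item2$delayed_amount # 600
#' @export
next_item <- function(state, prior_choice = NULL) {
  stopifnot(inherits(state, "titration_state"))
  if (!is.null(prior_choice)) {
    assert_choice_values(prior_choice, "prior_choice")
    state$choices <- c(state$choices, prior_choice)
  }
  pattern <- state_pattern(state)
  if (set_is_complete(pattern)) return(NULL)
  n_done <- length(state$choices)
  if (n_done >= 3) {
    abort(sprintf("Titration set '%s' already terminal after '%s'.",
                  state$set_id, pattern))
  }
  step <- step_for_item(state$set_id, state$choices, n_done + 1)
  row <- state$schedule[state$schedule$step == step, ]
  item <- tibble(
    set_id = state$set_id,
    sign = row$sign,
    framing = "neutral",
    immediate_amount = row$immediate_amount,
    immediate_time = 0L,
    delayed_amount = row$delayed_amount,
    delayed_time = 12L
  )
  attr(item, "state") <- state
  item
}

# Multiplier of the smallest delayed offer accepted in a small-gain pattern,
# with censoring when no delayed offer was ever accepted.
INDIFFERENCE_MULTIPLIER <- c(
  DDD = 1.01, DDI = 1.02, DI = 1.10, ID = 1.20, IID = 1.50, III = 1.50
)

#' Derive the simplified indifference point from the small-gain set
#'
#' The indifference value is the smallest delayed amount the participant
#' accepted in the small-gain staircase (e.g. a participant who rejects 550
#' but accepts 600 over an immediate 500 has indifference 600). A
#' participant who rejects every delayed offer, including the 150% one, is
#' assigned the 150% value with `censored = TRUE`; anomaly items are still
#' constructed from it.
#'
#' @param pattern Character vector of completed small-gain patterns
#'   (`"I"`/`"D"` per item, e.g. `"ID"`), or a character vector of choices
#'   for a single participant (e.g. `c("immediate", "delayed")`).
#' @param anchor Anchor value(s) (small-gain base amount), recycled.
#' @param denomination Currency rounding unit.
#' @return A tibble with columns `indifference_value` and
#'   `indifference_censored`.
#' @examples
#' derive_indifference(c("immediate", "delayed"), 500) # 600, uncensored
#' @export
derive_indifference <- function(pattern, anchor, denomination = 1) {
  if (any(pattern %in% c("immediate", "delayed"))) {
    assert_choice_values(pattern, "pattern")
    pattern <- paste(substr(toupper(pattern), 1, 1), collapse = "")
  }
  bad <- !pattern %in% VALID_SET_PATTERNS
  if (any(bad)) {
    abort(sprintf("Incomplete or invalid small-gain pattern: %s.",
                  paste(unique(pattern[bad]), collapse = ", ")))
  }
  mult <- unname(INDIFFERENCE_MULTIPLIER[pattern])
  tibble(
    indifference_value = round_currency(mult * anchor, denomination),
    indifference_censored = pattern == "III"
  )
}

#' Construct the four anomaly items from an indifference value
#'
#' Given the small-gain base and the derived indifference value, builds:
#'
#' * present bias: base at 12 months vs. indifference at 24 months (the
#'   0-12 month trade-off shifted one year into the future);
#' * subadditivity: base now vs. `base + 2 * premium` at 24 months, the
#'   additive extension of the 12-month premium over the doubled horizon;
#' * delay framing: base now vs. indifference at 12 months, the premium
#'   described as an added bonus for waiting;
#' * speedup framing: the same amounts, the premium described as a fee
#'   given up to receive the gain now.
#'
#' where `premium = indifference_value - base`.
#'
#' @param indifference_value Derived indifference value(s); must be at least
#'   the base.
#' @param anchor Small-gain base amount(s), recycled.
#' @param denomination Currency rounding unit.
#' @return A tibble with one row per item and per input, columns as in
#'   [next_item()] plus `premium`.
#' @examples
#' build_anomaly_items(600, 500)
#' @export
build_anomaly_items <- function(indifference_value, anchor, denomination = 1) {
  n <- max(length(indifference_value), length(anchor))
  indifference_value <- rep_len(indifference_value, n)
  anchor <- rep_len(anchor, n)
  if (any(indifference_value < anchor)) {
    abort("`indifference_value` must be >= the anchor base amount.")
  }
  base <- round_currency(anchor, denomination)
  premium <- indifference_value - base
  sub_amount <- round_currency(base + 2 * premium, denomination)
  one <- function(set_id, framing, imm_amt, imm_t, del_amt, del_t) {
    tibble(set_id = set_id, sign = "gain", framing = framing,
           immediate_amount = imm_amt, immediate_time = imm_t,
           delayed_amount = del_amt, delayed_time = del_t,
           premium = premium)
  }
  bind_rows(
    one("present_bias", "neutral", base, 12L, indifference_value, 24L),
    one("subadditivity", "neutral", base, 0L, sub_amount, 24L),
    one("delay_framing", "delay", base, 0L, indifference_value, 12L),
    one("speedup_framing", "speedup", base, 0L, indifference_value, 12L)
  )
}

#' Enumerate every complete path through the instrument
#'
#' Expands the six terminal patterns of each baseline set and the four
#' binary anomaly items into the full set of `6^3 * 2^4 = 3456` complete
#' response patterns, with per-path item counts.
#'
#' @param anchor Anchor value or one-row anchor tibble.
#' @param denomination Currency rounding unit.
#' @return A tibble with one row per complete path: pattern columns
#'   `small_gain`, `loss`, `large_gain` (e.g. `"ID"`), choice columns
#'   `present_bias`, `subadditivity`, `delay_framing`, `speedup_framing`
#'   (`"immediate"`/`"delayed"`), the derived `indifference_value` and
#'   `indifference_censored`, and `n_items`.
#' @examples
#' paths <- enumerate_paths(500)
#' nrow(paths)          # 3456
#' range(paths$n_items) # 10 13
#' @export
enumerate_paths <- function(anchor, denomination = 1) {
  if (is.data.frame(anchor)) {
    stopifnot(nrow(anchor) == 1)
    anchor <- anchor$anchor_value
  }
  choices <- c("immediate", "delayed")
  grid <- tidyr::expand_grid(
    small_gain = VALID_SET_PATTERNS,
    loss = VALID_SET_PATTERNS,
    large_gain = VALID_SET_PATTERNS,
    present_bias = choices,
    subadditivity = choices,
    delay_framing = choices,
    speedup_framing = choices
  )
  ind <- derive_indifference(grid$small_gain, anchor, denomination)
  grid$indifference_value <- ind$indifference_value
  grid$indifference_censored <- ind$indifference_censored
  grid$n_items <- nchar(grid$small_gain) + nchar(grid$loss) +
    nchar(grid$large_gain) + length(ANOMALY_ITEMS)
  grid
}

#' Walk one participant's choices through a full instrument path
#'
#' A reference (non-vectorised) driver that presents items one at a time via
#' [next_item()] and [build_anomaly_items()], querying `choose_fn` for each.
#' Used by the simulator's oracle tests and for interactive exploration; the
#' bulk simulator ([simulate_study()]) is vectorised.
#'
#' @param anchor One-row anchor tibble or anchor value.
#' @param choose_fn Function of a one-row item tibble returning
#'   `"immediate"` or `"delayed"`.
#' @param denomination Currency rounding unit.
#' @return A one-row wide tibble of per-item choices
#'   (`small_gain_1` ... `speedup_framing`), plus `indifference_value`,
#'   `indifference_censored`, `n_items`.
#' @export
walk_instrument <- function(anchor, choose_fn, denomination = 1) {
  out <- list()
  for (set in BASELINE_SETS) {
    state <- new_titration_state(set, anchor, denomination)
    item <- next_item(state)
    i <- 0
    while (!is.null(item)) {
      i <- i + 1
      choice <- choose_fn(item)
      assert_choice_values(choice)
      out[[paste0(set, "_", i)]] <- choice
      item <- next_item(attr(item, "state"), choice)
    }
  }
  anchor_value <- if (is.data.frame(anchor)) anchor$anchor_value else anchor
  sg <- unlist(out[grep("^small_gain_", names(out))])
  ind <- derive_indifference(sg, anchor_value, denomination)
  anomalies <- build_anomaly_items(ind$indifference_value, anchor_value,
                                   denomination)
  for (j in seq_len(nrow(anomalies))) {
    item <- anomalies[j, ]
    out[[item$set_id]] <- choose_fn(item)
  }
  res <- as_tibble(out)
  res$indifference_value <- ind$indifference_value
  res$indifference_censored <- ind$indifference_censored
  res$n_items <- sum(grepl("_[123]$", names(out))) + nrow(anomalies)
  res
}
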