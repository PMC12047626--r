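## Complementary descriptive analysis: confidence reclassification,
## participant exclusions, per-state mean confidence, and Friedman tests.

#' Reclassify a 4-level confidence rating into 2 levels
#'
#' Ratings 3 ("somewhat confident") and 4 ("very confident") become
#' `"confident"`; ratings 1 ("not at all confident") and 2 ("a little
#' confident") become `"not_confident"`. The reclassification keeps enough
#' data per joint response category for model fitting while the descriptive
#' analyses keep the raw 1-4 scale.
#'
#' @param confidence4 Integer vector with values in `{1, 2, 3, 4}` (`NA`
#'   passes through as `NA`).
#' @return Character vector of `"confident"` / `"not_confident"`.
#' @examples
#' reclassify_confidence(c(1, 2, 3, 4))
#' @export
reclassify_confidence <- function(confidence4) {
  ok <- is.na(confidence4) | (confidence4 %in% 1:4)
  if (!all(ok))
    abort(sprintf("confidence ratings must be in 1..4; offending values: %s",
                  paste(unique(confidence4[!ok]), collapse = ", ")))
  ifelse(is.na(confidence4), NA_character_,
         ifelse(confidence4 >= 3, "confident", "not_confident"))
}

#' Apply the participant exclusion rules
#'
#' A participant is excluded when they recalled strictly more than
#' `recall_max` of the famous (correct-name / incorrect-name) items, or when
#' their recognition accuracy over famous recall-failure trials is strictly
#' below `recog_min`. Recognition accuracy is computed over famous trials
#' only: catch trials have no correct answer, so accuracy is undefined there.
#'
#' @param trials Trial-level tibble (see [read_trials()] for the schema).
#' @param recall_max Recall-proportion threshold (default 0.80; strict).
#' @param recog_min Recognition-accuracy threshold (default 0.51; strict).
#' @return A tibble with one row per participant: `participant_id`,
#'   `recall_rate`, `recog_accuracy`, `excluded`, `reason` (`"recall"`,
#'   `"recognition"` or `NA`).
#' @export
apply_exclusions <- function(trials, recall_max = 0.80, recog_min = 0.51) {
  validate_trials(trials)
  famous <- dplyr::filter(trials, .data$condition != "catch")
  if (length(setdiff(unique(trials$participant_id),
                     unique(famous$participant_id))) > 0)
    abort("some participants have no famous trials; exclusion rules are undefined for them.")
  out <- famous |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      recall_rate = mean(.data$recalled),
      recog_accuracy = mean(.data$recog_accurate[!.data$recalled]),
      .groups = "drop") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$recall_rate > recall_max ~ "recall",
        .data$recog_accuracy < recog_min ~ "recognition",
        TRUE ~ NA_character_),
      excluded = !is.na(.data$reason))
  out[, c("participant_id", "recall_rate", "recog_accuracy",
          "excluded", "reason")]
}

#' Per-participant mean confidence by metacognitive state
#'
#' For each participant, the arithmetic mean of the raw 1-4 confidence
#' ratings over recall-failure trials in which the metacognitive state was
#' reported present (TOT yes / FOK high) and absent. Catch trials carry
#' metacognitive and confidence responses (they are never recalled) and are
#' included by default. Participants lacking trials in either state are
#' dropped from the paired comparison with a message.
#'
#' @param trials Trial-level tibble.
#' @param judgment `"tot"` or `"fok"`.
#' @param include_catch Include catch trials (default `TRUE`).
#' @return A tibble: `participant_id`, `mean_present`, `mean_absent`,
#'   `n_present`, `n_absent`.
#' @export
state_mean_confidence <- function(trials, judgment = c("tot", "fok"),
                                  include_catch = TRUE) {
  judgment <- match.arg(judgment)
  validate_trials(trials)
  d <- dplyr::filter(trials, !.data$recalled)
  if (!include_catch) d <- dplyr::filter(d, .data$condition != "catch")
  d$state <- if (judgment == "tot") d$tot == "yes" else d$fok == "high"
  out <- d |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      mean_present = mean(.data$confidence4[.data$state]),
      mean_absent = mean(.data$confidence4[!.data$state]),
      n_present = sum(.data$state),
      n_absent = sum(!.data$state),
      .groups = "drop")
  incomplete <- out$n_present == 0 | out$n_absent == 0
  if (any(incomplete)) {
    inform(sprintf("dropping %d participant(s) without trials in both %s states: %s",
                   sum(incomplete), toupper(judgment),
                   paste(out$participant_id[incomplete], collapse = ", ")))
    out <- out[!incomplete, ]
  }
  if (nrow(out) == 0)
    abort("no participant has trials in both metacognitive states.")
  out
}

#' Friedman rank test for repeated measures
#'
#' Within-subject rank test across `k` conditions with average ranks for ties
#' and the standard tie correction; the statistic is referred to the
#' chi-squared distribution with `k - 1` degrees of freedom. The fully
#' degenerate input (every row entirely tied) is defined to return statistic
#' 0 and p = 1.
#'
#' @param values Numeric matrix or data frame, participants (rows) x
#'   conditions (columns); no missing cells.
#' @return A tibble: `statistic`, `df`, `p.value`, `n`, `k`, `method`.
#' @examples
#' friedman_test(cbind(a = c(3, 4, 5), b = c(1, 2, 2)))
#' @export
friedman_test <- function(values) {
  m <- as.matrix(values)
  if (!is.numeric(m)) abort("`values` must be numeric.")
  if (anyNA(m)) abort("`values` must have no missing cells.")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need at least 2 participants and 2 conditions.")
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  ties <- apply(r, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  })
  denom <- n * k * (k + 1) - sum(ties) / (k - 1)
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  stat <- if (denom <= 0) 0 else num / denom
  p <- if (denom <= 0) 1 else pchisq(stat, df = k - 1, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = k - 1L, p.value = p, n = n, k = k,
                 method = "Friedman rank sum test")
}

#' Run the full descriptive comparison for one judgment
#'
#' Per-participant state means (via [state_mean_confidence()]) followed by a
#' Friedman test of present vs absent mean confidence.
#'
#' @inheritParams state_mean_confidence
#' @return A list with `means` (per-participant tibble), `summary` (group
#'   means/SDs) and `test` (the [friedman_test()] tibble).
#' @export
confidence_by_state <- function(trials, judgment = c("tot", "fok"),
                                include_catch = TRUE) {
  judgment <- match.arg(judgment)
  means <- state_mean_confidence(trials, judgment, include_catch)
  test <- friedman_test(cbind(present = means$mean_present,
                              absent = means$mean_absent))
  summary <- tibble::tibble(
    judgment = judgment,
    state = c("present", "absent"),
    mean = c(mean(means$mean_present), mean(means$mean_absent)),
    sd = c(stats::sd(means$mean_present), stats::sd(means$mean_absent)),
    n = nrow(means))
  list(means = means, summary = summary, test = test)
}
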