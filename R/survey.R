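# System Usability Scale scoring and dataset/flatten-the-curve summaries.
# SUS: ten 1-5 Likert items; odd items are positively worded, even items
# negatively worded. Items convert to 0-4 (positive: rating - 1; negative:
# 5 - rating); the overall score is 2.5 times the converted sum, on 0-100.
# Items 4 and 10 measure learnability, the remaining eight usability.

SUS_POSITIVE <- c(1, 3, 5, 7, 9)
SUS_LEARNABILITY <- c(4, 10)

#' Convert raw SUS ratings to 0-4 item scores
#'
#' @param ratings ten Likert ratings in 1..5, item order 1..10.
#' @return ten converted scores, each in \[0, 4\].
#' @export
sus_convert <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (length(ratings) != 10L)
    stop_hp("a SUS response has exactly 10 items (got %d)", length(ratings))
  if (any(is.na(ratings)) || any(ratings < 1) || any(ratings > 5) ||
      any(ratings != round(ratings)))
    stop_hp("SUS ratings must be integers in 1..5")
  converted <- 5 - ratings
  converted[SUS_POSITIVE] <- ratings[SUS_POSITIVE] - 1
  converted
}

#' SUS scores from per-item converted means
#'
#' Takes the ten per-item mean converted scores (each on 0-4) and returns the
#' overall score (`2.5 * sum`, on 0-100), the learnability mean (items 4 and
#' 10) and the usability mean (the remaining eight items).
#'
#' @param item_means ten numbers in \[0, 4\], item order 1..10.
#' @return list with `overall`, `learnability`, `usability`, `item_means`.
#' @export
sus_scores <- function(item_means) {
  item_means <- as.numeric(item_means)
  if (length(item_means) != 10L)
    stop_hp("expected 10 per-item means (got %d)", length(item_means))
  if (any(is.na(item_means)) || any(item_means < 0) || any(item_means > 4))
    stop_hp("converted item means must lie in [0, 4]")
  list(overall = 2.5 * sum(item_means),
       learnability = mean(item_means[SUS_LEARNABILITY]),
       usability = mean(item_means[-SUS_LEARNABILITY]),
       item_means = item_means)
}

#' Score a table of raw SUS responses
#'
#' @param responses matrix or data.frame, one row per respondent, ten columns
#'   of raw 1-5 ratings.
#' @return list as in [sus_scores()], computed from the per-item means of the
#'   converted scores.
#' @export
sus_survey <- function(responses) {
  responses <- as.matrix(responses)
  if (ncol(responses) != 10L) stop_hp("responses must have 10 columns")
  converted <- t(apply(responses, 1, sus_convert))
  sus_scores(colMeans(converted))
}

#' Check-in dataset summary statistics
#'
#' Mean check-ins per user and per venue, plus the busiest user and venue.
#' Either pass a record collection (counts and maxima are computed by
#' grouping) or the three totals (`n_records`, `n_users`, `n_venues`), in
#' which case only the means are available.
#'
#' @param records optional record collection.
#' @param n_users,n_venues,n_records totals used when `records` is `NULL`.
#' @return list with `n_records`, `n_users`, `n_venues`,
#'   `mean_per_user`, `mean_per_venue`, `max_per_user`, `max_per_venue`
#'   (maxima `NA` without records).
#' @export
dataset_summary <- function(records = NULL, n_users = NULL, n_venues = NULL,
                            n_records = NULL) {
  if (!is.null(records)) {
    n_records <- nrow(records)
    by_user <- table(records$visitor_id)
    by_venue <- table(records$venue_id)
    n_users <- n_users %||% length(by_user)
    n_venues <- n_venues %||% length(by_venue)
    max_user <- if (length(by_user)) max(by_user) else 0L
    max_venue <- if (length(by_venue)) max(by_venue) else 0L
  } else {
    if (is.null(n_users) || is.null(n_venues) || is.null(n_records))
      stop_hp("need either records or all of n_records, n_users, n_venues")
    max_user <- NA_integer_
    max_venue <- NA_integer_
  }
  if (n_users <= 0 || n_venues <= 0)
    stop_hp("user and venue counts must be positive")
  list(n_records = n_records, n_users = n_users, n_venues = n_venues,
       mean_per_user = n_records / n_users,
       mean_per_venue = n_records / n_venues,
       max_per_user = max_user, max_per_venue = max_venue)
}

#' Flatten-the-curve comparison of two simulations
#'
#' Peak reduction (percent) and peak delay (days) of a treated (access
#' control on) run against a baseline (no measures):
#' `reduction = 100 * (1 - treated_peak / baseline_peak)`,
#' `delay = treated_t_peak - baseline_t_peak`.
#'
#' @param baseline,treated `sim_result` objects or data.frames with `day` and
#'   `active_cases` columns.
#' @return list with `peak_reduction_pct`, `peak_delay_days`,
#'   `baseline_peak`, `treated_peak`, `baseline_t_peak`, `treated_t_peak`.
#' @export
flatten_comparison <- function(baseline, treated) {
  pb <- peak_metrics(baseline)
  pt <- peak_metrics(treated)
  if (pb$peak_active <= 0)
    stop_hp("baseline peak is zero; relative reduction is undefined")
  list(peak_reduction_pct = 100 * (1 - pt$peak_active / pb$peak_active),
       peak_delay_days = pt$t_peak - pb$t_peak,
       baseline_peak = pb$peak_active, treated_peak = pt$peak_active,
       baseline_t_peak = pb$t_peak, treated_t_peak = pt$t_peak)
}
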