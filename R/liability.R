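# Visitor liability profiling: a configurable rubric turns the six-item
# voluntary form (Home, Workplace, TravelRecord, MeansOfTransport, Symptoms,
# CloseContact) into a score vector V, and the normalized radar-map area of V
# is the liability score phi in [0,1]. Higher phi means a *safer* visitor;
# visitors with phi strictly below theta_liability are "low-liability".

RUBRIC_ITEMS <- c("home", "workplace", "travel_record", "means_of_transport",
                  "symptoms", "close_contact")

#' Construct and validate a scoring rubric
#'
#' A rubric is the configuration that maps each form item's answer tokens to
#' numeric scores, together with the per-item upper bounds used to normalize
#' the radar area and the liability threshold. The axis order is fixed as
#' home, workplace, travel_record, means_of_transport, symptoms,
#' close_contact: the radar area depends on which axes are adjacent, so a
#' canonical order is required for reproducibility.
#'
#' @param items named list of six named numeric vectors (answer token ->
#'   score), in the canonical item order.
#' @param upper_bounds six positive numbers, the per-item maxima `V_hat`.
#' @param theta_liability classification threshold in (0, 1\].
#' @return an object of class `scoring_rubric`.
#' @export
scoring_rubric <- function(items, upper_bounds,
                           theta_liability = 0.8) {
  if (!is.list(items) || length(items) != 6L ||
      !identical(names(items), RUBRIC_ITEMS))
    stop_hp("rubric must have exactly the six items %s, in order",
            paste(RUBRIC_ITEMS, collapse = ", "))
  upper_bounds <- as.numeric(upper_bounds)
  if (length(upper_bounds) != 6L || any(!is.finite(upper_bounds)) ||
      any(upper_bounds <= 0))
    stop_hp("upper_bounds must be six positive numbers")
  for (i in seq_along(items)) {
    map <- items[[i]]
    if (!is.numeric(map) || is.null(names(map)) || any(!nzchar(names(map))))
      stop_hp("item '%s' must map answer tokens to numeric scores",
              RUBRIC_ITEMS[i])
    if (any(map < 0) || any(map > upper_bounds[i]))
      stop_hp("scores for item '%s' must lie in [0, %g]",
              RUBRIC_ITEMS[i], upper_bounds[i])
  }
  assert_scalar_number(theta_liability, "theta_liability",
                       lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(items = items, upper_bounds = upper_bounds,
                 theta_liability = theta_liability),
            class = "scoring_rubric")
}

#' Default scoring rubric
#'
#' Residence items (home, workplace) are scored 1-5 by the five government
#' regional risk tiers (safest tier scores 5). Travel record and means of
#' transport follow the same 1-5 grading, with crowded public transport
#' scored low (risky) and walking scored high. Symptoms and close contact use
#' a severity map (none 5, mild/indirect 2, severe/confirmed 1). Concrete
#' values are configuration, not epidemiological claims; site administrators
#' are expected to adapt them via [read_rubric()].
#'
#' @return a `scoring_rubric`.
#' @export
default_rubric <- function() {
  tiers <- c(risk_tier_low = 5, risk_tier_guarded = 4, risk_tier_elevated = 3,
             risk_tier_high = 2, risk_tier_severe = 1)
  scoring_rubric(
    items = list(
      home = tiers,
      workplace = tiers,
      travel_record = c(none = 5, domestic_low_risk = 4,
                        domestic_medium_risk = 3, domestic_high_risk = 2,
                        international_or_outbreak_area = 1),
      means_of_transport = c(walking = 5, private_car = 4, taxi = 3,
                             bus = 2, metro = 1),
      symptoms = c(none = 5, mild = 2, severe = 1),
      close_contact = c(none = 5, indirect = 2, confirmed_case = 1)
    ),
    upper_bounds = rep(5, 6),
    theta_liability = 0.8
  )
}

#' Read a rubric from a YAML configuration file
#'
#' The file carries `items` (ordered maps answer -> score), `upper_bounds`
#' and `theta_liability`; see `system.file("extdata", "rubric.yaml",
#' package = "healthpass")` for the shipped default.
#'
#' @param path YAML file.
#' @return a `scoring_rubric`.
#' @export
read_rubric <- function(path) {
  cfg <- yaml::read_yaml(path)
  items <- lapply(cfg$items, function(m) unlist(m))
  scoring_rubric(items = items,
                 upper_bounds = unlist(cfg$upper_bounds),
                 theta_liability = cfg$theta_liability %||% 0.8)
}

#' Score a voluntary form against a rubric
#'
#' Unanswered items (missing or `NA`) score zero — the system rewards
#' complete disclosure. An answer token absent from the rubric map is a
#' scoring error naming the item.
#'
#' @param answers named character vector or list; names are a subset of the
#'   rubric items, values are answer tokens.
#' @param rubric a [scoring_rubric()].
#' @return numeric score vector `V` of length 6, named by item.
#' @export
apply_rubric <- function(answers, rubric) {
  stopifnot(inherits(rubric, "scoring_rubric"))
  answers <- as.list(answers)
  unknown <- setdiff(names(answers), RUBRIC_ITEMS)
  if (length(unknown))
    stop_hp("unknown form item '%s'", unknown[1])
  V <- setNames(numeric(6), RUBRIC_ITEMS)
  for (item in RUBRIC_ITEMS) {
    tok <- answers[[item]]
    if (is.null(tok) || length(tok) == 0 || is.na(tok) || !nzchar(tok)) next
    map <- rubric$items[[item]]
    if (!tok %in% names(map))
      stop_hp("answer '%s' is not in the rubric for item '%s'", tok, item)
    V[item] <- unname(map[[tok]])
  }
  V
}

#' Radar-map liability score
#'
#' The liability score is the area of the six-axis radar polygon spanned by
#' `V`, normalized by the area at the upper bounds:
#' \deqn{\phi(u) = \frac{\sum_{i=0}^{a-1} V_{i \bmod a}\, V_{(i+1) \bmod a}}
#'                     {\sum_{i=0}^{a-1} \hat V_{i \bmod a}\, \hat V_{(i+1) \bmod a}}}
#' with `a = 6`. The common factor `sin(2*pi/a)/2` of the triangle areas
#' cancels in the ratio. phi is 0 when no two cyclically adjacent components
#' are both positive and 1 when `V` equals the upper bounds.
#'
#' @param V numeric score vector (any length `a >= 3`; 6 in this system).
#' @param upper_bounds per-component maxima, all positive.
#' @return `phi` in \[0, 1\].
#' @export
radar_score <- function(V, upper_bounds) {
  V <- as.numeric(V)
  upper_bounds <- as.numeric(upper_bounds)
  a <- length(V)
  if (a < 3L || length(upper_bounds) != a)
    stop_hp("V and upper_bounds must have equal length >= 3")
  if (any(!is.finite(upper_bounds)) || any(upper_bounds <= 0))
    stop_hp("all upper bounds must be positive")
  if (any(!is.finite(V)) || any(V < 0) || any(V > upper_bounds + 1e-12))
    stop_hp("V must satisfy 0 <= V_i <= upper bound componentwise")
  nxt <- c(2:a, 1L)
  sum(V * V[nxt]) / sum(upper_bounds * upper_bounds[nxt])
}

#' Classify a liability score against the threshold
#'
#' A visitor is low-liability when `phi` is *strictly* below
#' `theta_liability`; a score exactly at the threshold is acceptable.
#'
#' @param phi liability score(s) in \[0, 1\].
#' @param theta_liability threshold in (0, 1\].
#' @return character vector, `"low_liability"` or `"acceptable"`.
#' @export
classify_liability <- function(phi, theta_liability = 0.8) {
  assert_scalar_number(theta_liability, "theta_liability",
                       lower = 0, upper = 1, strict_lower = TRUE)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop_hp("phi must lie in [0, 1]")
  ifelse(phi < theta_liability, "low_liability", "acceptable")
}
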