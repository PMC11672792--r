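# Venue availability monitoring. Three risk factors feed the availability:
#   R1 = number of low-liability visitors currently in the venue,
#   R2 = expected low-liability inflow from neighboring venues, estimated
#        from historical checkout->checkin transitions,
#   R3 = occupancy / capacity (crowdedness; may exceed 1 when over capacity),
# and availability omega = (1 - beta)^((R1 + R2) * R3), the probability that
# a random visitor avoids infection in random contacts within the venue.

#' Per-contact transmission rate
#'
#' `beta = R0 / tau`, where `tau` is the average number of person-to-person
#' contacts over the infectious period (`contacts_per_day * infectious_days`).
#' Defaults follow the campus deployment configuration: `R0 = 2.24`, 50
#' contacts/day over a 15-day infectious window (a 21-day disease course with
#' a 6-day non-infectious incubation), giving `tau = 750` and
#' `beta ~= 0.002987`.
#'
#' @param R0 basic reproduction number (> 0).
#' @param contacts_per_day average contacts per infected case per day.
#' @param infectious_days length of the infectious period in days.
#' @return list with `R0`, `tau` and `beta` (`beta` strictly inside (0,1)).
#' @export
transmission_rate <- function(R0 = 2.24, contacts_per_day = 50,
                              infectious_days = 15) {
  assert_scalar_number(R0, "R0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(contacts_per_day, "contacts_per_day",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(infectious_days, "infectious_days",
                       lower = 0, strict_lower = TRUE)
  tau <- contacts_per_day * infectious_days
  beta <- R0 / tau
  if (beta >= 1)
    stop_hp("beta = R0/tau = %g must be below 1; increase tau", beta)
  list(R0 = R0, tau = tau, beta = beta)
}

#' Venue member liability risk R1
#'
#' The count of occupants whose liability score falls strictly below the
#' threshold.
#'
#' @param occupant_phi liability scores of the current occupants.
#' @param theta_liability classification threshold.
#' @return integer `R1 >= 0`.
#' @export
member_risk <- function(occupant_phi, theta_liability = 0.8) {
  if (length(occupant_phi) == 0) return(0L)
  sum(classify_liability(occupant_phi, theta_liability) == "low_liability")
}

# Pairs of consecutive closed sessions of the same visitor with
# 0 <= next t_in - t_out <= max_gap. Returns per-source departure totals m
# and the source x target transfer count matrix n.
transfer_counts <- function(history, max_gap_hours = 2) {
  venues <- sort(unique(history$venue_id))
  m <- setNames(numeric(length(venues)), venues)
  n <- matrix(0, length(venues), length(venues),
              dimnames = list(venues, venues))
  h <- data.table::as.data.table(history[!is.na(history$t_out), ])
  if (nrow(h) < 2L) return(list(m = m, n = n, venues = venues))
  data.table::setorder(h, visitor_id, t_in)
  src <- h$venue_id[-nrow(h)]
  dst <- h$venue_id[-1L]
  same <- h$visitor_id[-nrow(h)] == h$visitor_id[-1L]
  gap <- h$t_in[-1L] - h$t_out[-nrow(h)]
  keep <- same & gap >= 0 & gap <= max_gap_hours * 3600
  if (any(keep)) {
    tab <- table(factor(src[keep], venues), factor(dst[keep], venues))
    n[] <- n + as.matrix(tab)
    m <- rowSums(n)
  }
  list(m = m, n = n, venues = venues)
}

#' Historical transition statistics toward a target venue
#'
#' A transfer is a visitor's checkout from venue i followed by their next
#' check-in (at any venue) within `max_gap_hours`; `m_i` counts all such
#' departures from i and `n_i` those that arrive at `target`. Open sessions
#' are ignored. Venues never observed to transfer are retained with
#' `n_i = 0`.
#'
#' @param history closed check-in records (see [checkin_records()]).
#' @param target venue whose inflow is being assessed.
#' @param max_gap_hours linkage window between checkout and the next
#'   check-in (default 2 h).
#' @return data.frame with columns `venue_id`, `n`, `m` (one row per source
#'   venue present in the history).
#' @export
transition_stats <- function(history, target, max_gap_hours = 2) {
  tc <- transfer_counts(history, max_gap_hours)
  n_target <- if (target %in% colnames(tc$n)) tc$n[, target] else
    setNames(numeric(length(tc$venues)), tc$venues)
  data.frame(venue_id = tc$venues, n = as.numeric(n_target),
             m = as.numeric(tc$m), stringsAsFactors = FALSE)
}

#' Neighboring-venue propagation risk R2
#'
#' `R2 = sum_i r_i * n_i / m_i`: the expected number of low-liability
#' visitors flowing in from each source venue, weighting the source's current
#' low-liability count `r_i` by the historical transfer fraction
#' `n_i / m_i`. Sources with no recorded departures (`m_i = 0`) contribute
#' zero — the transfer fraction is undefined there and zero is the
#' conservative limit.
#'
#' @param stats transition statistics from [transition_stats()].
#' @param current_low named numeric vector: current low-liability occupant
#'   count per source venue (missing venues count 0).
#' @return `R2 >= 0` (expected persons).
#' @export
propagation_risk <- function(stats, current_low) {
  if (nrow(stats) == 0) return(0)
  r <- rep(0, nrow(stats))
  if (length(current_low)) {
    idx <- match(stats$venue_id, names(current_low))
    r[!is.na(idx)] <- as.numeric(current_low[idx[!is.na(idx)]])
  }
  frac <- ifelse(stats$m > 0, stats$n / pmax(stats$m, 1), 0)
  sum(r * frac)
}

#' Venue crowdedness risk R3
#'
#' `R3 = N / N_c`, the occupancy-to-capacity ratio. Values above 1 indicate
#' an over-capacity venue and are passed through unbounded.
#'
#' @param N current occupancy (persons).
#' @param capacity venue capacity `N_c` (persons, >= 1).
#' @return `R3 >= 0`.
#' @export
crowdedness_risk <- function(N, capacity) {
  assert_scalar_number(capacity, "capacity", lower = 1)
  assert_scalar_number(N, "N", lower = 0)
  N / capacity
}

#' Venue availability
#'
#' `omega = (1 - beta)^((R1 + R2) * R3)`: the probability that a random
#' visitor is not infected in random contacts inside the venue. `R1 + R2` is
#' the low-liability exposure the visitor may meet and `R3` scales the
#' contact probability by crowdedness. Equal to 1 for an empty or
#' risk-free venue and strictly decreasing in each factor otherwise.
#'
#' @param R1,R2,R3 risk factors, all `>= 0`.
#' @param beta per-contact transmission probability in (0, 1) — see
#'   [transmission_rate()].
#' @return `omega` in (0, 1\].
#' @export
availability <- function(R1, R2, R3, beta) {
  assert_scalar_number(beta, "beta", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(R1, "R1", lower = 0)
  assert_scalar_number(R2, "R2", lower = 0)
  assert_scalar_number(R3, "R3", lower = 0)
  (1 - beta)^((R1 + R2) * R3)
}
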