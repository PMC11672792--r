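# Agent-based epidemic replay. Check-in streams are replayed through venues
# modelled as well-mixed compartments. Disease course: a newly infected agent
# is asymptomatic (not yet infectious) for `asymptomatic_days`, infectious
# until `course_days`, then recovered; stages only move forward. Each
# infectious agent draws up to `contacts_per_day` distinct contacts per
# venue-day, prorated by the fraction of the day the agent is checked in, and
# each susceptible contact is infected with probability beta. "Active cases"
# are agents in the asymptomatic or infectious stage.

#' Simulation parameter set
#'
#' Bundles the disease-course and control parameters. `beta` is derived via
#' [transmission_rate()] unless given explicitly. The infectious period is
#' `course_days - asymptomatic_days` (21 - 6 = 15 by default).
#'
#' @param I0 initial infection rate: the fraction of agents seeded as
#'   (low-liability) asymptomatic cases.
#' @param contacts_per_day average contacts per infectious case per full
#'   venue-day.
#' @param course_days total disease course in days.
#' @param asymptomatic_days initial non-infectious period in days.
#' @param R0 basic reproduction number used to derive `beta`.
#' @param beta per-contact transmission probability; overrides `R0` if given.
#' @param theta_liability low-liability classification threshold.
#' @param m_classes number of priority classes for access control.
#' @param max_transfer_gap_hours linkage window for historical transitions.
#' @param control_on logical: replay the stream through the access-control
#'   policy before simulating.
#' @param seed RNG seed; every random draw in a run flows from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(I0 = 0.10, contacts_per_day = 50, course_days = 21,
                       asymptomatic_days = 6, R0 = 2.24, beta = NULL,
                       theta_liability = 0.8, m_classes = 5L,
                       max_transfer_gap_hours = 2, control_on = FALSE,
                       seed = 1L) {
  assert_scalar_number(I0, "I0", lower = 0, upper = 1)
  assert_scalar_number(course_days, "course_days", lower = 1)
  assert_scalar_number(asymptomatic_days, "asymptomatic_days", lower = 0)
  if (asymptomatic_days >= course_days)
    stop_hp("asymptomatic_days must be below course_days")
  infectious_days <- course_days - asymptomatic_days
  if (is.null(beta))
    beta <- transmission_rate(R0, contacts_per_day, infectious_days)$beta
  assert_scalar_number(beta, "beta", lower = 0, upper = 1,
                       strict_upper = TRUE)
  list(I0 = I0, contacts_per_day = contacts_per_day,
       course_days = course_days, asymptomatic_days = asymptomatic_days,
       infectious_days = infectious_days, beta = beta,
       theta_liability = theta_liability, m_classes = as.integer(m_classes),
       max_transfer_gap_hours = max_transfer_gap_hours,
       control_on = isTRUE(control_on), seed = seed)
}

#' Seed initial infections
#'
#' Exactly `round(I0 * n)` agents start in the asymptomatic stage and carry a
#' liability score below the threshold; all others are susceptible with
#' scores at or above it. When the agents already carry scores (e.g. from
#' generated forms) and the low-liability count matches, those agents are the
#' seeds; otherwise seeds are drawn at random and scores are overridden to
#' keep the invariant "initial infection rate = low-liability fraction".
#'
#' @param agents data.frame with `anon_id` and optionally `phi`.
#' @param I0 initial infection rate in \[0, 1\].
#' @param theta_liability classification threshold.
#' @param seed optional RNG seed.
#' @return agents with columns `anon_id`, `phi`, `infect_day` (0 for seeds,
#'   `NA` for susceptible).
#' @export
seed_infections <- function(agents, I0, theta_liability = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(agents)
  n_seed <- round(I0 * n)
  phi <- if ("phi" %in% names(agents)) agents$phi else rep(NA_real_, n)
  low <- which(!is.na(phi) & phi < theta_liability)
  if (length(low) == n_seed) {
    seeds <- low
  } else {
    seeds <- if (n_seed > 0) sample.int(n, n_seed) else integer(0)
  }
  is_seed <- seq_len(n) %in% seeds
  # enforce phi < theta for seeds and phi >= theta for the rest
  fix_low <- is_seed & (is.na(phi) | phi >= theta_liability)
  fix_ok <- !is_seed & (is.na(phi) | phi < theta_liability)
  if (any(fix_low))
    phi[fix_low] <- runif(sum(fix_low), 0.2, theta_liability * 0.99)
  if (any(fix_ok))
    phi[fix_ok] <- runif(sum(fix_ok), theta_liability, 1)
  data.frame(anon_id = agents$anon_id, phi = phi,
             infect_day = ifelse(is_seed, 0, NA_real_),
             stringsAsFactors = FALSE)
}

# Stage of each agent at the start of day d, derived from infect_day.
# Derivation from a single infection day guarantees forward-only transitions
# and population conservation by construction.
agent_stage <- function(infect_day, day, params) {
  el <- day - infect_day
  out <- rep("susceptible", length(infect_day))
  out[!is.na(el) & el >= 0 & el < params$asymptomatic_days] <- "asymptomatic"
  out[!is.na(el) & el >= params$asymptomatic_days &
        el < params$course_days] <- "infectious"
  out[!is.na(el) & el >= params$course_days] <- "recovered"
  out
}

# Venue-day presence table: one row per (venue, day, visitor) with the
# fraction of that day the visitor is checked in. Sessions lacking a
# check-out are ignored. `origin` is the epoch second of day 0.
build_presence <- function(checkins, origin, horizon_days) {
  cc <- checkins[!is.na(checkins$t_out) & checkins$t_out > checkins$t_in, ,
                 drop = FALSE]
  if (nrow(cc) == 0)
    return(data.table::data.table(venue_id = character(), day = integer(),
                                  visitor_id = character(), frac = numeric()))
  d0 <- floor((cc$t_in - origin) / 86400)
  d1 <- ceiling((cc$t_out - origin) / 86400) - 1
  nrep <- pmax(d1 - d0 + 1, 1)
  idx <- rep.int(seq_len(nrow(cc)), nrep)
  day <- unlist(lapply(seq_len(nrow(cc)), function(i) d0[i]:d1[i]))
  dt <- data.table::data.table(
    venue_id = cc$venue_id[idx], visitor_id = cc$visitor_id[idx], day = day,
    t_in = cc$t_in[idx], t_out = cc$t_out[idx])
  day_start <- origin + dt$day * 86400
  ov <- pmin(dt$t_out, day_start + 86400) - pmax(dt$t_in, day_start)
  dt$frac <- pmax(ov, 0) / 86400
  dt <- dt[dt$frac > 0 & dt$day >= 0 & dt$day < horizon_days, ]
  dt[, list(frac = min(sum(frac), 1)),
     by = c("venue_id", "day", "visitor_id")]
}

#' Advance the epidemic by one day
#'
#' Resolves one day of venue transmission: for each venue, every infectious
#' agent present draws `min(contacts_per_day * frac, co-present - 1)`
#' distinct uniform contacts among the other occupants (fractional expected
#' draws are resolved by stochastic rounding so the expectation is exact),
#' and each susceptible contact is infected with probability `beta`.
#' Asymptomatic agents do not transmit. Stage progression is implicit in the
#' infection-day bookkeeping.
#'
#' @param presence_day data.frame with columns `venue_id`, `visitor_id`,
#'   `frac` for one day (see the venue-day presence construction in
#'   [run_simulation()]).
#' @param agents agents data.frame from [seed_infections()].
#' @param params a [sim_params()] list.
#' @param day the day index being simulated.
#' @return updated agents (new infections get `infect_day = day`).
#' @export
step_day <- function(presence_day, agents, params, day) {
  stage <- agent_stage(agents$infect_day, day, params)
  if (!any(stage == "infectious") || nrow(presence_day) == 0 ||
      params$beta <= 0)
    return(agents)
  idx_of <- match(presence_day$visitor_id, agents$anon_id)
  for (v in unique(presence_day$venue_id)) {
    rows <- which(presence_day$venue_id == v)
    occ <- idx_of[rows]
    frac <- presence_day$frac[rows]
    inf_here <- which(stage[occ] == "infectious")
    if (!length(inf_here) || length(occ) < 2L) next
    for (j in inf_here) {
      mean_draws <- min(params$contacts_per_day * frac[j], length(occ) - 1L)
      ndraw <- floor(mean_draws) + (runif(1) < (mean_draws %% 1))
      if (ndraw < 1) next
      others <- occ[-j]
      contacts <- if (length(others) == 1L) others else
        others[sample.int(length(others), ndraw)]
      hit <- contacts[runif(length(contacts)) < params$beta]
      new_inf <- hit[is.na(agents$infect_day[hit])]
      if (length(new_inf)) agents$infect_day[new_inf] <- day
    }
  }
  agents
}

#' Run the epidemic simulation over a check-in stream
#'
#' Replays the stream day by day, seeding infections with
#' [seed_infections()] and applying [step_day()] per day. With
#' `params$control_on`, the stream is first transformed by
#' [apply_access_control()]: each arrival's check-in is shifted by its
#' scheduled wait and venue occupancy respects the availability-derived
#' server count. Daily stage counts are recorded after each day's
#' transmission.
#'
#' @param checkins check-in record collection (closed sessions drive
#'   transmission).
#' @param agents data.frame with `anon_id` (and optionally `phi`) for the
#'   full population, including visitors who never check in.
#' @param venues venue registry with `venue_id`, `capacity` and (for
#'   control) `mean_dwell` in hours.
#' @param params a [sim_params()] list.
#' @param horizon_days number of days to simulate; defaults to the span of
#'   the stream.
#' @return a `sim_result`: data.frame with columns `day`, `susceptible`,
#'   `asymptomatic`, `infectious`, `recovered`, `active_cases`, with the
#'   peak metrics attached as attributes.
#' @export
run_simulation <- function(checkins, agents, venues, params,
                           horizon_days = NULL) {
  if (nrow(checkins) == 0) stop_hp("empty check-in stream")
  set.seed(params$seed)
  origin <- floor(min(checkins$t_in) / 86400) * 86400
  if (is.null(horizon_days))
    horizon_days <- ceiling((max(checkins$t_out, checkins$t_in,
                                 na.rm = TRUE) - origin) / 86400)
  agents <- seed_infections(agents, params$I0, params$theta_liability)
  if (params$control_on)
    checkins <- apply_access_control(checkins, agents, venues, params,
                                     origin = origin,
                                     horizon_days = horizon_days)
  presence <- build_presence(checkins, origin, horizon_days)
  pres_by_day <- split(as.data.frame(presence), presence$day)
  n <- nrow(agents)
  series <- data.frame(day = seq_len(horizon_days) - 1L, susceptible = NA_integer_,
                       asymptomatic = NA_integer_, infectious = NA_integer_,
                       recovered = NA_integer_)
  for (d in series$day) {
    pd <- pres_by_day[[as.character(d)]]
    if (!is.null(pd)) agents <- step_day(pd, agents, params, d)
    stage <- agent_stage(agents$infect_day, d, params)
    i <- d + 1L
    series$susceptible[i] <- sum(stage == "susceptible")
    series$asymptomatic[i] <- sum(stage == "asymptomatic")
    series$infectious[i] <- sum(stage == "infectious")
    series$recovered[i] <- sum(stage == "recovered")
  }
  series$active_cases <- series$asymptomatic + series$infectious
  stopifnot(all(series$susceptible + series$asymptomatic +
                  series$infectious + series$recovered == n))
  pk <- peak_metrics(series)
  structure(series, class = c("sim_result", "data.frame"),
            peak_active = pk$peak_active, t_peak = pk$t_peak,
            n_agents = n, control_on = params$control_on)
}

#' Peak metrics of an active-case series
#'
#' The maximum of `active_cases` and the first day attaining it (ties break
#' to the earliest day).
#'
#' @param series a `sim_result` or any data.frame with `day` and
#'   `active_cases` columns.
#' @return list with `peak_active` and `t_peak`.
#' @export
peak_metrics <- function(series) {
  if (nrow(series) == 0) stop_hp("empty series")
  i <- which.max(series$active_cases)
  list(peak_active = series$active_cases[i], t_peak = series$day[i])
}

#' Replay a check-in stream through the access-control policy
#'
#' For each venue and day the controller takes the monitoring view of the
#' *uncontrolled* stream at the day start: current occupancy and
#' low-liability counts give `R1` and `R3`, historical transitions give
#' `R2`, and availability `omega` yields the server count
#' `s = floor(omega * N_c)` (at least 1). Per-class arrival rates for the
#' day and `mu = 1/T` give the scheduled waits `W_k`; each arrival's
#' check-in is shifted by the wait of its class and then admitted only when
#' one of the `s` occupancy slots is free (priority order is approximated by
#' processing in shifted-arrival order, since higher classes receive shorter
#' shifts). The check-out time is not moved, so waiting truncates the visit;
#' a session whose wait exceeds its remaining duration — including classes
#' deferred as saturated — is dropped.
#'
#' @inheritParams run_simulation
#' @param origin epoch second of day 0 (defaults to the stream's first
#'   midnight).
#' @return the adjusted check-in record collection.
#' @export
apply_access_control <- function(checkins, agents, venues, params,
                                 origin = NULL, horizon_days = NULL) {
  if (is.null(origin)) origin <- floor(min(checkins$t_in) / 86400) * 86400
  if (is.null(horizon_days))
    horizon_days <- ceiling((max(checkins$t_out, checkins$t_in,
                                 na.rm = TRUE) - origin) / 86400)
  phi <- setNames(agents$phi, agents$anon_id)
  k_of <- priority_of(pmax(pmin(phi[checkins$visitor_id], 1), 0),
                      params$m_classes)
  low_visitor <- phi < params$theta_liability
  tc <- transfer_counts(checkins, params$max_transfer_gap_hours)
  if (is.null(venues$mean_dwell)) {
    dwell <- (checkins$t_out - checkins$t_in) / 3600
    venues$mean_dwell <- mean(dwell, na.rm = TRUE)
  }
  # occupancy and low-liability occupancy at each day start, per venue,
  # from the uncontrolled stream (sorted entry/exit time counts)
  day_starts <- origin + (0:(horizon_days - 1)) * 86400
  occ_at <- function(sub) {
    tin <- sort(sub$t_in)
    tout <- sort(sub$t_out[!is.na(sub$t_out)])
    findInterval(day_starts, tin) - findInterval(day_starts, tout)
  }
  low_by_venue <- lapply(venues$venue_id, function(u) {
    su <- checkins[checkins$venue_id == u &
                     low_visitor[checkins$visitor_id] %in% TRUE, ,
                   drop = FALSE]
    occ_at(su)
  })
  names(low_by_venue) <- venues$venue_id
  out <- vector("list", nrow(venues))
  for (vi in seq_len(nrow(venues))) {
    v <- venues$venue_id[vi]
    cap <- venues$capacity[vi]
    mu <- 1 / venues$mean_dwell[vi]
    sub_all <- checkins[checkins$venue_id == v, , drop = FALSE]
    if (nrow(sub_all) == 0) { out[[vi]] <- sub_all; next }
    # day-level controller state
    occ_v <- occ_at(sub_all)
    stats_v <- data.frame(venue_id = tc$venues,
                          n = if (v %in% colnames(tc$n)) as.numeric(tc$n[, v])
                              else rep(0, length(tc$venues)),
                          m = as.numeric(tc$m))
    day_of <- pmin(pmax(floor((sub_all$t_in - origin) / 86400), 0),
                   horizon_days - 1)
    kv <- k_of[checkins$venue_id == v]
    s_day <- integer(horizon_days); W_day <- matrix(0, horizon_days,
                                                    params$m_classes)
    for (d in seq_len(horizon_days)) {
      R1 <- low_by_venue[[v]][d]
      r_cur <- vapply(venues$venue_id, function(u) low_by_venue[[u]][d],
                      numeric(1))
      R2 <- propagation_risk(stats_v, r_cur)
      R3 <- crowdedness_risk(max(occ_v[d], 0), cap)
      om <- availability(max(R1, 0), R2, R3, params$beta)
      s_day[d] <- capacity_servers(om, cap)
      lam <- vapply(seq_len(params$m_classes), function(k)
        sum(day_of == d - 1L & kv == k), numeric(1)) / 24
      W_day[d, ] <- waiting_times_capped(lam, mu, s_day[d])
    }
    wait_h <- W_day[cbind(day_of + 1L, kv)]
    new_tin <- sub_all$t_in + wait_h * 3600
    keep <- is.finite(new_tin) & !is.na(sub_all$t_out) &
      new_tin < sub_all$t_out
    sub <- sub_all[keep, , drop = FALSE]
    sub$t_in <- new_tin[keep]
    # enforce the slot cap: admit in shifted-arrival order, delaying entry
    # to the earliest departure while all s slots are busy
    ordx <- order(sub$t_in)
    sub <- sub[ordx, , drop = FALSE]
    s_cap <- s_day[pmin(pmax(floor((sub$t_in - origin) / 86400), 0),
                        horizon_days - 1) + 1L]
    dep <- numeric(0)
    drop_row <- logical(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      e <- sub$t_in[i]
      dep <- dep[dep > e]
      while (length(dep) >= s_cap[i]) {
        e <- min(dep)
        dep <- dep[dep > e]
      }
      if (e >= sub$t_out[i]) { drop_row[i] <- TRUE; next }
      sub$t_in[i] <- e
      dep <- c(dep, sub$t_out[i])
    }
    out[[vi]] <- sub[!drop_row, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res[order(res$t_in), , drop = FALSE]
}
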