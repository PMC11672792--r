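# Synthetic campus generator. Emulates the statistical shape the queuing and
# risk models assume: homogeneous Poisson external arrivals per venue,
# exponential dwell times, Markov chaining of consecutive sessions through a
# row-stochastic transition matrix, visitors drawn with replacement (so
# per-visitor session counts are heavy-tailed), and voluntary forms sampled
# so the low-liability fraction equals the target initial infection rate I0.

CAMPUS_EPOCH <- 1588291200  # 2020-05-01T00:00:00Z, day 0 of the stream

#' Construct and validate a campus specification
#'
#' @param n_visitors population size.
#' @param venues data.frame with columns `venue_id`, `capacity`,
#'   `arrival_rate` (external arrivals, visitors/hour) and `mean_dwell`
#'   (hours).
#' @param transition_matrix row-stochastic venue-to-venue matrix governing
#'   where a chained session goes next.
#' @param p_transfer probability that a session is followed by a transfer to
#'   a next venue (within the transfer linkage window).
#' @param I0 target low-liability fraction of the population.
#' @param horizon_days stream length in days.
#' @param seed RNG seed for [generate_campus()].
#' @return a `campus_spec` list.
#' @export
campus_spec <- function(n_visitors, venues, transition_matrix,
                        p_transfer = 0.3, I0 = 0.10, horizon_days = 62,
                        seed = 1L) {
  stopifnot(is.data.frame(venues),
            all(c("venue_id", "capacity", "arrival_rate",
                  "mean_dwell") %in% names(venues)))
  b <- nrow(venues)
  if (any(venues$arrival_rate < 0)) stop_hp("arrival rates must be >= 0")
  if (any(venues$mean_dwell <= 0)) stop_hp("mean dwell times must be > 0")
  if (any(venues$capacity < 1)) stop_hp("capacities must be >= 1")
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(b, b)) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-9))
    stop_hp("transition_matrix must be %d x %d row-stochastic", b, b)
  assert_scalar_number(p_transfer, "p_transfer", lower = 0, upper = 1,
                       strict_upper = TRUE)
  assert_scalar_number(I0, "I0", lower = 0, upper = 1)
  assert_scalar_number(horizon_days, "horizon_days", lower = 0)
  rownames(tm) <- colnames(tm) <- venues$venue_id
  structure(list(n_visitors = as.integer(n_visitors), venues = venues,
                 transition_matrix = tm, p_transfer = p_transfer, I0 = I0,
                 horizon_days = horizon_days, seed = seed),
            class = "campus_spec")
}

#' Campus specification at the deployment's scale
#'
#' Five venues and 1,416 visitors over a 62-day horizon, with external
#' arrival rates solved so the expected total session count (external
#' arrivals plus chained transfers) is 128,656 — the size of the deployed
#' system's check-in/check-out dataset. Dwell times default to a 12-hour
#' mean (sessions at campus access points span most of a day on campus) and
#' capacities sit roughly 10% above the typical concurrent occupancy, so
#' pandemic capacity caps actually bind; both are configuration knobs, not
#' measurements.
#'
#' @param I0 target low-liability fraction (default 0.10).
#' @param seed RNG seed carried into [generate_campus()].
#' @return a `campus_spec`.
#' @export
default_paper_scale_spec <- function(I0 = 0.10, seed = 1L) {
  n_sessions_target <- 128656
  horizon_days <- 62
  p_transfer <- 0.3
  venue_ids <- c("gate", "shuttle", "academic-a", "academic-b", "library")
  b <- length(venue_ids)
  external_total <- n_sessions_target * (1 - p_transfer) /
    (horizon_days * 24)                       # sessions/h, all venues
  venues <- data.frame(
    venue_id = venue_ids,
    capacity = 230L,
    arrival_rate = external_total / b,
    mean_dwell = 12,
    stringsAsFactors = FALSE
  )
  tm <- matrix(c(
    0.00, 0.15, 0.30, 0.30, 0.25,   # gate ->
    0.40, 0.00, 0.25, 0.25, 0.10,   # shuttle ->
    0.20, 0.10, 0.00, 0.35, 0.35,   # academic-a ->
    0.20, 0.10, 0.35, 0.00, 0.35,   # academic-b ->
    0.25, 0.15, 0.30, 0.30, 0.00    # library ->
  ), nrow = b, byrow = TRUE)
  campus_spec(n_visitors = 1416L, venues = venues, transition_matrix = tm,
              p_transfer = p_transfer, I0 = I0,
              horizon_days = horizon_days, seed = seed)
}

# Sample n forms whose classification lands in the requested bucket.
# "acceptable" visitors answer from the safe end of each item (none/low-risk
# answers); "low_liability" visitors answer uniformly across all tokens.
# A rejection step guarantees the classification, so the generated
# population hits the target low-liability fraction exactly.
sample_forms_bucket <- function(n, rubric, bucket) {
  theta <- rubric$theta_liability
  items <- rubric$items
  # safe visitors answer from the top of each item's score range (for the
  # shipped rubric: the two safest tiers, and "none" for symptoms/contacts);
  # risky visitors answer uniformly across all tokens
  pools <- lapply(items, function(item_map) {
    if (bucket == "acceptable")
      names(item_map)[item_map >= max(item_map) - 1]
    else names(item_map)
  })
  out <- vector("list", n)
  filled <- 0L
  while (filled < n) {
    batch <- max(n - filled, 32L)
    draws <- lapply(pools, function(p) p[sample.int(length(p), batch,
                                                    replace = TRUE)])
    Vs <- mapply(function(map, tok) unname(map[tok]), items, draws)
    Vs <- matrix(Vs, nrow = batch)
    nxt <- c(2:6, 1)
    phi <- as.numeric((Vs * Vs[, nxt, drop = FALSE]) %*% rep(1, 6)) /
      sum(rubric$upper_bounds * rubric$upper_bounds[nxt])
    ok <- if (bucket == "low_liability") phi < theta else phi >= theta
    for (i in which(ok)) {
      if (filled >= n) break
      filled <- filled + 1L
      out[[filled]] <- list(
        answers = setNames(vapply(draws, `[`, "", i), RUBRIC_ITEMS),
        phi = phi[i])
    }
  }
  out
}

#' Generate a synthetic campus
#'
#' Produces visitors with anonymous identifiers and voluntary-form answers,
#' the venue registry, and a check-in/check-out stream with the generative
#' structure stated in the campus spec. External arrivals at each venue form
#' a homogeneous Poisson process; dwell times are exponential with the
#' venue's mean; after each session the visitor transfers to a next venue
#' drawn from the transition matrix with probability `p_transfer`, after a
#' short uniform gap (5-60 minutes, inside the 2-hour linkage window).
#' Exactly `round(I0 * n)` visitors are low-liability. Deterministic for a
#' given seed.
#'
#' @param spec a [campus_spec()].
#' @param rubric the scoring rubric used to sample and score form answers.
#' @return list with `visitors` (anon_id, phi, low_liability), `venues`,
#'   `checkins` (a record collection, `liability` carrying each visitor's
#'   phi) and `forms` (one row per visitor: anon_id, answers, phi).
#' @export
generate_campus <- function(spec, rubric = default_rubric()) {
  stopifnot(inherits(spec, "campus_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_visitors
  ids <- sprintf("v-%08x", sample.int(.Machine$integer.max, n))
  while (anyDuplicated(ids))
    ids[duplicated(ids)] <- sprintf("v-%08x",
                                    sample.int(.Machine$integer.max,
                                               sum(duplicated(ids))))
  n_low <- round(spec$I0 * n)
  forms_low <- sample_forms_bucket(n_low, rubric, "low_liability")
  forms_ok <- sample_forms_bucket(n - n_low, rubric, "acceptable")
  forms <- c(forms_low, forms_ok)
  ord <- sample.int(n)                     # shuffle low/acceptable together
  forms <- forms[ord]
  phi <- vapply(forms, `[[`, numeric(1), "phi")
  visitors <- data.frame(anon_id = ids, phi = phi,
                         low_liability = phi < rubric$theta_liability,
                         stringsAsFactors = FALSE)
  forms_df <- data.frame(anon_id = ids,
                         do.call(rbind, lapply(forms, function(f)
                           as.data.frame(as.list(f$answers),
                                         stringsAsFactors = FALSE))),
                         phi = phi, stringsAsFactors = FALSE)
  # external Poisson arrivals per venue
  hours <- spec$horizon_days * 24
  horizon_s <- spec$horizon_days * 86400
  b <- nrow(spec$venues)
  sessions <- list()
  cur <- list()
  for (vi in seq_len(b)) {
    n_arr <- rpois(1, spec$venues$arrival_rate[vi] * hours)
    if (n_arr == 0) next
    t_in <- CAMPUS_EPOCH + round(runif(n_arr) * horizon_s)
    dwell <- round(rexp(n_arr, 1 / spec$venues$mean_dwell[vi]) * 3600)
    cur[[length(cur) + 1L]] <- data.frame(
      visitor = sample.int(n, n_arr, replace = TRUE),
      venue = vi, t_in = t_in, t_out = t_in + dwell)
  }
  wave <- if (length(cur)) do.call(rbind, cur) else
    data.frame(visitor = integer(), venue = integer(),
               t_in = numeric(), t_out = numeric())
  while (nrow(wave) > 0) {
    sessions[[length(sessions) + 1L]] <- wave
    move <- runif(nrow(wave)) < spec$p_transfer
    wave <- wave[move, , drop = FALSE]
    if (nrow(wave) == 0) break
    # next venue from the transition matrix row of the current venue
    nv <- integer(nrow(wave))
    for (vi in seq_len(b)) {
      rows <- which(wave$venue == vi)
      if (!length(rows)) next
      nv[rows] <- sample.int(b, length(rows), replace = TRUE,
                             prob = spec$transition_matrix[vi, ])
    }
    gap <- round(runif(nrow(wave), 300, 3600))
    t_in <- wave$t_out + gap
    keep <- t_in < CAMPUS_EPOCH + horizon_s
    wave <- wave[keep, , drop = FALSE]
    if (nrow(wave) == 0) break
    nv <- nv[keep]; t_in <- t_in[keep]
    dwell <- round(rexp(nrow(wave),
                        1 / spec$venues$mean_dwell[nv]) * 3600)
    wave <- data.frame(visitor = wave$visitor, venue = nv,
                       t_in = t_in, t_out = t_in + dwell)
  }
  allses <- if (length(sessions)) do.call(rbind, sessions) else
    data.frame(visitor = integer(), venue = integer(),
               t_in = numeric(), t_out = numeric())
  checkins <- checkin_records(
    visitor_id = ids[allses$visitor],
    venue_id = spec$venues$venue_id[allses$venue],
    t_in = allses$t_in, t_out = allses$t_out,
    reason = NA, liability = phi[allses$visitor])
  list(visitors = visitors,
       venues = spec$venues,
       checkins = checkins,
       forms = forms_df)
}

#' Voluntary-form I/O (JSON-lines)
#'
#' One JSON object per visitor with the six answer tokens, the anonymous id
#' and the scored phi.
#'
#' @param forms forms data.frame as produced by [generate_campus()].
#' @param path file to write or read.
#' @return `read_forms()` returns the forms data.frame.
#' @export
write_forms <- function(forms, path) {
  lines <- vapply(seq_len(nrow(forms)), function(i)
    as.character(jsonlite::toJSON(as.list(forms[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA)), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_forms
#' @export
read_forms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l),
                                                  stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
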