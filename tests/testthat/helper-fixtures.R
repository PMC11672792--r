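# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to tempdir().

# A small record collection with integer-second timestamps.
make_records <- function(n = 10, venues = c("lib-01", "gym-02"), seed = 1,
                         open_fraction = 0) {
  set.seed(seed)
  t_in <- 1588291200 + sort(sample.int(3600 * 24, n))
  t_out <- t_in + sample.int(7200, n)
  if (open_fraction > 0)
    t_out[sample.int(n, ceiling(open_fraction * n))] <- NA
  checkin_records(
    visitor_id = sprintf("v%03d", sample.int(max(3, n %/% 2), n, replace = TRUE)),
    venue_id = sample(venues, n, replace = TRUE),
    t_in = t_in, t_out = t_out,
    reason = sample(c(NA, "study", "work"), n, replace = TRUE),
    liability = round(runif(n), 3))
}

# A compact campus for simulation tests: short dwell, tight horizon.
make_test_spec <- function(n_visitors = 200, horizon_days = 10,
                           arrival_rate = 2, mean_dwell = 4,
                           p_transfer = 0.3, I0 = 0.10, seed = 1) {
  venues <- data.frame(
    venue_id = c("a", "b", "c"),
    capacity = 60L,
    arrival_rate = arrival_rate,
    mean_dwell = mean_dwell,
    stringsAsFactors = FALSE)
  tm <- matrix(c(0, .5, .5,
                 .5, 0, .5,
                 .5, .5, 0), 3, byrow = TRUE)
  campus_spec(n_visitors, venues, tm, p_transfer = p_transfer, I0 = I0,
              horizon_days = horizon_days, seed = seed)
}
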