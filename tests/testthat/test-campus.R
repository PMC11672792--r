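test_that("a zero-length horizon yields an empty stream", {
  spec <- make_test_spec(horizon_days = 0, seed = 1)
  campus <- generate_campus(spec)
  expect_equal(nrow(campus$checkins), 0L)
  expect_equal(nrow(campus$visitors), 200L)
})

test_that("arrival counts concentrate at the Poisson mean", {
  venues <- data.frame(venue_id = "solo", capacity = 50L,
                       arrival_rate = 10, mean_dwell = 1)
  spec <- campus_spec(500, venues, matrix(1, 1, 1), p_transfer = 0,
                      I0 = 0.1, horizon_days = 100 / 24, seed = 2)
  campus <- generate_campus(spec)
  # lambda * hours = 1000; Poisson sd ~ sqrt(1000)
  expect_lt(abs(nrow(campus$checkins) - 1000), 3 * sqrt(1000))
})

test_that("dwell times are exponential with the configured mean", {
  venues <- data.frame(venue_id = "solo", capacity = 50L,
                       arrival_rate = 100, mean_dwell = 2.5)
  spec <- campus_spec(1000, venues, matrix(1, 1, 1), p_transfer = 0,
                      I0 = 0.1, horizon_days = 100 / 24, seed = 3)
  campus <- generate_campus(spec)
  dwell_h <- (campus$checkins$t_out - campus$checkins$t_in) / 3600
  n <- length(dwell_h)
  expect_gt(n, 9000)
  # exponential: sd = mean, so SE of the sample mean is T/sqrt(n)
  expect_lt(abs(mean(dwell_h) - 2.5), 3 * 2.5 / sqrt(n))
})

test_that("the same seed reproduces the identical stream", {
  c1 <- generate_campus(make_test_spec(seed = 11))
  c2 <- generate_campus(make_test_spec(seed = 11))
  expect_identical(c1$checkins, c2$checkins)
  expect_identical(c1$forms, c2$forms)
  c3 <- generate_campus(make_test_spec(seed = 12))
  expect_false(identical(c1$checkins, c3$checkins))
})

test_that("generated forms hit the target low-liability fraction exactly", {
  spec <- make_test_spec(n_visitors = 400, I0 = 0.15, seed = 13)
  campus <- generate_campus(spec)
  expect_equal(sum(campus$visitors$low_liability), 60)
  rubric <- default_rubric()
  # stored phi agrees with re-scoring the stored answers
  i <- c(1, 57, 311)
  for (j in i) {
    ans <- unlist(campus$forms[j, healthpass:::RUBRIC_ITEMS])
    V <- apply_rubric(ans, rubric)
    expect_equal(radar_score(V, rubric$upper_bounds), campus$forms$phi[j])
  }
})

test_that("chained sessions follow the transition matrix", {
  venues <- data.frame(venue_id = c("a", "b", "c"), capacity = 100L,
                       arrival_rate = 12, mean_dwell = 0.5)
  tm <- matrix(c(0, 0.8, 0.2,
                 0.3, 0, 0.7,
                 0.5, 0.5, 0), 3, byrow = TRUE)
  spec <- campus_spec(20000, venues, tm, p_transfer = 0.5, I0 = 0.1,
                      horizon_days = 25, seed = 14)
  campus <- generate_campus(spec)
  tc <- healthpass:::transfer_counts(campus$checkins, max_gap_hours = 2)
  expect_gt(sum(tc$n), 1e4)
  # chi-square goodness of fit per source row, alpha = 0.01
  for (v in c("a", "b", "c")) {
    obs <- tc$n[v, setdiff(c("a", "b", "c"), v)]
    p <- tm[match(v, c("a", "b", "c")), match(setdiff(c("a", "b", "c"), v),
                                              c("a", "b", "c"))]
    expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
  }
  # conservation: row totals of transfers never exceed departures
  expect_true(all(rowSums(tc$n) <= tc$m + 1e-9))
})

test_that("the paper-scale spec matches the deployment's shape", {
  spec <- default_paper_scale_spec()
  expect_equal(spec$n_visitors, 1416L)
  expect_equal(nrow(spec$venues), 5L)
  expect_equal(spec$horizon_days, 62)
  expect_s3_class(spec, "campus_spec")
  # Monte-Carlo mean of generated session counts within 5% of 128,656
  counts <- vapply(1:5, function(sd)
    nrow(generate_campus(default_paper_scale_spec(seed = sd))$checkins),
    numeric(1))
  expect_lt(abs(mean(counts) / 128656 - 1), 0.05)
})

test_that("forms round-trip through JSON-lines", {
  campus <- generate_campus(make_test_spec(n_visitors = 30, seed = 15))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_forms(campus$forms, path)
  back <- read_forms(path)
  rownames(back) <- rownames(campus$forms) <- NULL
  expect_equal(back, campus$forms)
})
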