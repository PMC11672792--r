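test_that("seeding matches the initial rate and the low-liability fraction", {
  agents <- data.frame(anon_id = sprintf("a%04d", 1:1000))
  s0 <- seed_infections(agents, 0, seed = 1)
  expect_true(all(is.na(s0$infect_day)))
  expect_true(all(s0$phi >= 0.8))
  s1 <- seed_infections(agents, 1, seed = 1)
  expect_true(all(s1$infect_day == 0))
  expect_true(all(s1$phi < 0.8))
  s <- seed_infections(agents, 0.10, seed = 1)
  expect_equal(sum(!is.na(s$infect_day)), 100)
  expect_equal(mean(s$phi < 0.8), 0.10)
  # already-scored populations keep their low-liability members as seeds
  agents$phi <- c(rep(0.5, 100), rep(0.9, 900))
  s2 <- seed_infections(agents, 0.10, seed = 2)
  expect_equal(which(!is.na(s2$infect_day)), 1:100)
  expect_equal(s2$phi, agents$phi)
})

test_that("no transmission occurs without infectious presence or with beta 0", {
  presence <- data.frame(venue_id = "v", visitor_id = c("a1", "a2", "a3"),
                         frac = 1)
  params <- sim_params(beta = 0.5, seed = 1)
  # all susceptible: nothing happens
  agents <- data.frame(anon_id = c("a1", "a2", "a3"), phi = 0.9,
                       infect_day = NA_real_)
  expect_equal(step_day(presence, agents, params, 0), agents)
  # asymptomatic agents do not transmit
  agents$infect_day[1] <- 0
  expect_equal(step_day(presence, agents, params, 3), agents)
  # infectious agent but beta = 0
  p0 <- sim_params(beta = 0, seed = 1)
  agents$infect_day[1] <- -10
  expect_equal(step_day(presence, agents, p0, 0), agents)
})

test_that("stage timing follows the 6/21-day disease course", {
  params <- sim_params(seed = 1)
  # the same agent seen at days 0, 5, 6, 20, 21
  st <- vapply(c(0, 5, 6, 20, 21), function(d)
    healthpass:::agent_stage(0, d, params), character(1))
  expect_equal(st, c("asymptomatic", "asymptomatic", "infectious",
                     "infectious", "recovered"))
})

test_that("peak metrics find the first-attained maximum", {
  z <- data.frame(day = 0:3, active_cases = c(0, 0, 0, 0))
  expect_equal(peak_metrics(z), list(peak_active = 0, t_peak = 0))
  s <- data.frame(day = 0:3, active_cases = c(1, 3, 3, 2))
  expect_equal(peak_metrics(s), list(peak_active = 3, t_peak = 1))
  set.seed(8)
  for (i in 1:20) {
    ac <- sample.int(50, 30, replace = TRUE)
    r <- data.frame(day = 0:29, active_cases = ac)
    expect_equal(peak_metrics(r)$peak_active, max(ac))
    expect_equal(peak_metrics(r)$t_peak, which(ac == max(ac))[1] - 1)
  }
})

test_that("a run conserves population and only moves stages forward", {
  campus <- generate_campus(make_test_spec(seed = 3))
  agents <- campus$visitors[, c("anon_id", "phi")]
  res <- run_simulation(campus$checkins, agents, campus$venues,
                        sim_params(I0 = 0.10, beta = 0.05, seed = 3))
  n <- nrow(agents)
  with(as.data.frame(res), {
    expect_true(all(susceptible + asymptomatic + infectious + recovered == n))
    expect_true(all(diff(recovered) >= 0))
    expect_true(all(diff(susceptible) <= 0))
    expect_true(all(active_cases == asymptomatic + infectious))
  })
})

test_that("with no seeds the active-case series is flat zero", {
  campus <- generate_campus(make_test_spec(I0 = 0, seed = 4))
  agents <- campus$visitors[, c("anon_id", "phi")]
  res <- run_simulation(campus$checkins, agents, campus$venues,
                        sim_params(I0 = 0, seed = 4))
  expect_true(all(res$active_cases == 0))
  expect_error(run_simulation(campus$checkins[0, ], agents, campus$venues,
                              sim_params(I0 = 0, seed = 4)), "empty")
})

test_that("beta = 0 leaves the final infected count at the initial count", {
  campus <- generate_campus(make_test_spec(seed = 5))
  agents <- campus$visitors[, c("anon_id", "phi")]
  res <- run_simulation(campus$checkins, agents, campus$venues,
                        sim_params(I0 = 0.10, beta = 0, seed = 5))
  n_seed <- round(0.10 * nrow(agents))
  final <- as.data.frame(res)[nrow(res), ]
  expect_equal(final$asymptomatic + final$infectious + final$recovered,
               n_seed)
})

test_that("the control replay only delays or drops sessions", {
  campus <- generate_campus(make_test_spec(seed = 6, arrival_rate = 4,
                                           mean_dwell = 6))
  agents <- seed_infections(campus$visitors[, c("anon_id", "phi")], 0.10)
  params <- sim_params(I0 = 0.10, control_on = TRUE, seed = 6)
  adj <- apply_access_control(campus$checkins, agents, campus$venues, params)
  expect_lte(nrow(adj), nrow(campus$checkins))
  key <- function(d) paste(d$visitor_id, d$venue_id, d$t_out)
  idx <- match(key(adj), key(campus$checkins))
  expect_false(any(is.na(idx)))
  expect_true(all(adj$t_in >= campus$checkins$t_in[idx]))
  expect_true(all(adj$t_in < adj$t_out))
})
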