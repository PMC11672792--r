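test_that("liability maps to priority classes by the clamped reciprocal", {
  expect_equal(priority_of(1.0, 5), 1L)
  expect_equal(priority_of(0, 5), 5L)
  expect_equal(priority_of(0.3, 5), 4L)   # ceil(10/3)
  expect_equal(priority_of(0.5, 5), 2L)
  expect_equal(priority_of(0.05, 5), 5L)  # clamped at m
  expect_equal(priority_of(c(1, 0.8, 0.26), 3), c(1L, 2L, 3L))
  expect_error(priority_of(1.5, 5), "\\[0, 1\\]")
})

test_that("server count is the floored availability share of capacity", {
  expect_equal(capacity_servers(1, 20), 20L)
  expect_equal(capacity_servers(0.05, 10), 1L)   # floor(0.5) clamped to 1
  expect_equal(capacity_servers(0.7415, 100), 74L)
})

test_that("priority waits reproduce the M/M/1 and Erlang-C closed forms", {
  # M/M/1: Wq = rho / (mu - lambda)
  expect_equal(waiting_times(0.5, 1, 1), 1.0, tolerance = 1e-12)
  # Erlang-C at s = 2, rho = 0.5
  expect_equal(waiting_times(1, 1, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(erlang_c_wq(0.5, 1, 1), 1.0, tolerance = 1e-12)
  expect_equal(erlang_c_wq(1, 1, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(erlang_c_wq(0, 1, 3), 0)
  # two classes at s = 1: hand-evaluated waits and the conservation check
  W <- waiting_times(c(0.25, 0.25), 1, 1)
  expect_equal(W, c(2 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(sum(c(0.5, 0.5) * W), erlang_c_wq(0.5, 1, 1),
               tolerance = 1e-12)
})

test_that("the single-class limit agrees with Erlang C across a grid", {
  for (s in 1:10) {
    for (rho in seq(0.1, 0.9, by = 0.1)) {
      mu <- 1.3
      lam <- rho * s * mu
      expect_equal(waiting_times(lam, mu, s), erlang_c_wq(lam, mu, s),
                   tolerance = 1e-10)
    }
  }
})

test_that("waits are nondecreasing in class and conserve the FCFS mean", {
  set.seed(21)
  for (i in 1:30) {
    m <- sample(2:5, 1)
    s <- sample(1:8, 1)
    mu <- runif(1, 0.5, 3)
    rho <- runif(1, 0.2, 0.92)
    shares <- as.vector(stats::rmultinom(1, 1000, runif(m))) / 1000
    lam <- shares * rho * s * mu
    W <- waiting_times(lam, mu, s)
    expect_true(all(diff(W) >= -1e-12))
    expect_true(all(W >= 0))
    fcfs <- erlang_c_wq(sum(lam), mu, s)
    expect_equal(sum(lam / sum(lam) * W), fcfs, tolerance = 1e-10)
  }
})

test_that("saturated classes raise an error naming the first one", {
  expect_error(waiting_times(c(0.3, 0.8), 1, 1), "class 2")
  expect_error(waiting_times(1.2, 1, 1), "class 1")
  # capped variant keeps the stable prefix and marks the rest Inf
  W <- healthpass:::waiting_times_capped(c(0.3, 0.8), 1, 1)
  expect_equal(W[1], waiting_times(0.3, 1, 1))
  expect_true(is.infinite(W[2]))
})

test_that("the event simulation reproduces the analytic waits", {
  des <- simulate_queue_des(0.5, 1, 1, horizon_hours = 3e4, seed = 2)
  expect_lt(abs(des$mean_wait - 1.0), 3 * des$se)
  des2 <- simulate_queue_des(c(0.25, 0.25), 1, 1, horizon_hours = 3e4,
                             seed = 3)
  expect_lt(abs(des2$mean_wait[1] - 2 / 3), 3 * des2$se[1])
  expect_lt(abs(des2$mean_wait[2] - 4 / 3), 3 * des2$se[2])
  # degenerate case: no arrivals, no waits
  des0 <- simulate_queue_des(c(0, 0), 1, 2, horizon_hours = 100, seed = 4)
  expect_equal(des0$mean_wait, c(0, 0))
})

test_that("the entry queue orders by priority and assigns the class wait", {
  q <- entry_queue(c(0.2, 0.2), mu = 1, s = 1)
  W <- waiting_times(c(0.2, 0.2), 1, 1)
  a <- assign_wait(q, "u1", 2)
  expect_equal(a$wait, W[2])
  expect_equal(a$status, "queued")
  expect_equal(a$queue$members$anon_id[1], "u1")
  # a higher-priority arrival moves ahead of the waiting head
  b <- assign_wait(a$queue, "u2", 1)
  expect_equal(b$queue$members$anon_id, c("u2", "u1"))
  expect_equal(b$wait, W[1])
  # FCFS within a class
  d <- assign_wait(b$queue, "u3", 1)
  expect_equal(d$queue$members$anon_id, c("u2", "u3", "u1"))
  # admitting the head refreshes the displayed waits for the rest
  adm <- admit_head(d$queue)
  expect_equal(adm$admitted, "u2")
  expect_equal(displayed_waits(adm$queue),
               c(u3 = W[1], u1 = W[2]))
})

test_that("saturated arrivals are deferred with a venue_saturated status", {
  q <- entry_queue(c(0.3, 0.9), mu = 1, s = 1)
  ok <- assign_wait(q, "u1", 1)
  expect_equal(ok$status, "queued")
  bad <- assign_wait(q, "u2", 2)
  expect_equal(bad$status, "venue_saturated")
  expect_true(is.infinite(bad$wait))
  expect_equal(nrow(bad$queue$members), 0L)
})
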