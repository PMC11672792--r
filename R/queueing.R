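# Dynamic access control: the entry line of a venue is modelled as an M/M/s
# queue with m non-preemptive priority classes. Class k (lower k = higher
# priority, i.e. safer visitor) has Poisson arrivals at rate lambda_k;
# service (time spent inside the venue) is exponential with rate mu = 1/T at
# each of s servers (occupancy slots). The mean queue delay of class k is
#
#   W_k = A^{-1} / ((1 - sigma_{k-1}) (1 - sigma_k)),
#   A   = s! (1 - rho) (s mu) * sum_{i=0}^{s-1} (s rho)^(i-s) / i!  +  s mu,
#
# with sigma_r = sum_{i<=r} rho_i, rho_i = lambda_i/(s mu), sigma_0 = 0.
# At m = 1 this reduces exactly to the Erlang-C delay, and the
# arrival-rate-weighted mean over classes equals the FCFS delay
# (the classical conservation law for identical service distributions).

#' Map a liability score to a priority class
#'
#' `k = ceil(1 / phi)` clamped to `1..m`; a score of zero (a blank form) maps
#' to the lowest priority `m`. Safer visitors (phi near 1) therefore enter
#' first, and the map is the inverse relation the queue discipline requires:
#' a lower k is a higher priority.
#'
#' @param phi liability score(s) in \[0, 1\].
#' @param m number of priority classes (>= 1).
#' @return integer class index vector in `1..m`.
#' @export
priority_of <- function(phi, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop_hp("m must be a positive integer")
  m <- as.integer(m)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop_hp("phi must lie in [0, 1]")
  k <- rep(m, length(phi))
  pos <- phi > 0
  k[pos] <- pmin(m, pmax(1L, as.integer(ceiling(1 / phi[pos] - 1e-12))))
  k
}

#' Available server count from venue availability
#'
#' `s = floor(omega * N_c)`, clamped below at 1: a venue with any
#' availability must admit someone eventually. This is the number of
#' occupancy slots the access controller is willing to fill.
#'
#' @param omega venue availability in (0, 1\].
#' @param capacity venue capacity `N_c` (>= 1).
#' @return integer `s >= 1`.
#' @export
capacity_servers <- function(omega, capacity) {
  assert_scalar_number(omega, "omega", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(capacity, "capacity", lower = 1)
  max(1L, as.integer(floor(omega * capacity + 1e-9)))
}

# Normalizing term of the priority-queue delay, A in the header comment.
# Computed in log space so large s stays finite. Requires rho < 1.
priority_queue_A <- function(lambda, mu, s) {
  rho <- lambda / (s * mu)
  if (lambda == 0) return(Inf)
  i <- 0:(s - 1)
  terms <- exp(lfactorial(s) - lfactorial(i) + (i - s) * log(s * rho))
  s * mu * ((1 - rho) * sum(terms) + 1)
}

#' Erlang-C delay probability and mean queue wait
#'
#' Single-class M/M/s: `erlang_c()` is the probability an arrival must wait;
#' `erlang_c_wq()` is the mean queue delay `C(s, rho) / (s mu - lambda)`.
#' These closed forms are the m = 1 limit of [waiting_times()] and serve as
#' its independent check.
#'
#' @param lambda total arrival rate (per hour).
#' @param mu per-server service rate (per hour).
#' @param s number of servers (>= 1).
#' @return probability in \[0, 1\], or mean queue wait in hours.
#' @export
erlang_c <- function(lambda, mu, s) {
  assert_scalar_number(mu, "mu", lower = 0, strict_lower = TRUE)
  assert_scalar_number(lambda, "lambda", lower = 0)
  s <- as.integer(s)
  if (s < 1) stop_hp("s must be at least 1")
  if (lambda == 0) return(0)
  a <- lambda / mu                      # offered load
  rho <- a / s
  if (rho >= 1) stop_hp("saturated system: lambda >= s * mu")
  # log-space Erlang B recursion-free form
  j <- 0:(s - 1)
  log_terms <- j * log(a) - lfactorial(j)
  log_tail <- s * log(a) - lfactorial(s) - log(1 - rho)
  mx <- max(log_terms, log_tail)
  1 / (sum(exp(log_terms - mx)) / exp(log_tail - mx) + 1)
}

#' @rdname erlang_c
#' @export
erlang_c_wq <- function(lambda, mu, s) {
  if (lambda == 0) return(0)
  erlang_c(lambda, mu, s) / (s * mu - lambda)
}

#' Mean waiting times per priority class (M/M/s, non-preemptive)
#'
#' Computes `W_k` for every class `k = 1..m` (queue delay only; the time in
#' service is excluded). Stability demands the *cumulative* utilization
#' `sigma_m = lambda / (s mu) < 1`; if any class is saturated an error names
#' the first saturated class. `W_k` is nondecreasing in `k` and satisfies
#' the conservation law `sum_k (lambda_k / lambda) W_k = Wq_FCFS`.
#'
#' @param lambdas per-class arrival rates, highest priority first (per hour).
#' @param mu per-server service rate (per hour), `1/T` for mean dwell `T`.
#' @param s number of servers (>= 1).
#' @return numeric vector of mean queue waits (hours), one per class.
#' @export
waiting_times <- function(lambdas, mu, s) {
  assert_scalar_number(mu, "mu", lower = 0, strict_lower = TRUE)
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 1L || any(!is.finite(lambdas)) || any(lambdas < 0))
    stop_hp("lambdas must be non-negative arrival rates")
  s <- as.integer(s)
  if (s < 1) stop_hp("s must be at least 1")
  sigma <- cumsum(lambdas) / (s * mu)
  sat <- which(sigma >= 1)
  if (length(sat))
    stop_hp("unstable system: cumulative utilization sigma_%d = %.4f >= 1 (class %d saturated)",
            sat[1], sigma[sat[1]], sat[1])
  A <- priority_queue_A(sum(lambdas), mu, s)
  if (!is.finite(A)) return(rep(0, length(lambdas)))
  B <- c(1, 1 - sigma)                      # B[k] = 1 - sigma_{k-1}
  (1 / A) / (B[-length(B)] * (1 - sigma))
}

# Waits with saturated classes reported as Inf instead of an error: find the
# longest stable prefix of classes and compute its waits on the truncated
# system (saturated classes are turned away, so they place no load).
waiting_times_capped <- function(lambdas, mu, s) {
  sigma <- cumsum(lambdas) / (s * mu)
  K <- if (any(sigma >= 1)) which(sigma >= 1)[1] - 1L else length(lambdas)
  W <- rep(Inf, length(lambdas))
  if (K >= 1L) W[1:K] <- waiting_times(lambdas[1:K], mu, s)
  W
}

#' Discrete-event simulation of the priority queue
#'
#' Event-driven validation oracle for [waiting_times()]: Poisson arrivals per
#' class, exponential service at `s` servers, non-preemptive
#' highest-priority-first dispatch with FCFS order within a class. Waits are
#' collected after a warm-up fraction and summarized with batch means, so the
#' standard errors are honest in the presence of queue autocorrelation.
#'
#' @param lambdas per-class arrival rates (per hour), highest priority first.
#' @param mu per-server service rate (per hour).
#' @param s number of servers.
#' @param horizon_hours simulated time span.
#' @param seed RNG seed for reproducibility.
#' @param warmup fraction of the horizon discarded before collecting waits.
#' @param n_batches batch count for the batch-means standard errors.
#' @return data.frame with columns `class`, `n`, `mean_wait`, `se`.
#' @export
simulate_queue_des <- function(lambdas, mu, s, horizon_hours = 1e4,
                               seed = NULL, warmup = 0.1, n_batches = 32L) {
  m <- length(lambdas)
  s <- as.integer(s)
  if (!is.null(seed)) set.seed(seed)
  # per-class Poisson arrival processes over the horizon
  arr_t <- vector("list", m)
  for (k in seq_len(m)) {
    if (lambdas[k] == 0) { arr_t[[k]] <- numeric(); next }
    n_exp <- ceiling(lambdas[k] * horizon_hours + 6 * sqrt(lambdas[k] * horizon_hours)) + 10
    t <- cumsum(rexp(n_exp, lambdas[k]))
    arr_t[[k]] <- t[t <= horizon_hours]
  }
  all_t <- unlist(arr_t)
  all_k <- rep.int(seq_len(m), lengths(arr_t))
  ord <- order(all_t)
  all_t <- all_t[ord]; all_k <- all_k[ord]
  n_arr <- length(all_t)
  waits <- numeric(n_arr); wclass <- integer(n_arr); wtime <- numeric(n_arr)
  n_rec <- 0L
  # per-class FIFO queues of arrival times (preallocated ring-free vectors)
  qbuf <- lapply(seq_len(m), function(k) numeric(length(arr_t[[k]])))
  qhead <- rep(1L, m); qtail <- rep(0L, m)
  dep <- numeric(0)  # departure times of jobs in service (length <= s)
  i <- 1L
  record <- function(k, t_arr, w) {
    n_rec <<- n_rec + 1L
    waits[n_rec] <<- w; wclass[n_rec] <<- k; wtime[n_rec] <<- t_arr
  }
  start_service <- function(now) dep <<- c(dep, now + rexp(1L, mu))
  while (i <= n_arr || length(dep)) {
    next_arr <- if (i <= n_arr) all_t[i] else Inf
    next_dep <- if (length(dep)) min(dep) else Inf
    if (next_arr <= next_dep) {
      k <- all_k[i]
      if (length(dep) < s) {
        record(k, next_arr, 0)
        start_service(next_arr)
      } else {
        qtail[k] <- qtail[k] + 1L
        qbuf[[k]][qtail[k]] <- next_arr
      }
      i <- i + 1L
    } else {
      dep <- dep[-which.min(dep)]
      waiting <- which(qhead <= qtail)
      if (length(waiting)) {
        k <- waiting[1L]                 # highest priority first
        t_arr <- qbuf[[k]][qhead[k]]
        qhead[k] <- qhead[k] + 1L
        record(k, t_arr, next_dep - t_arr)
        start_service(next_dep)
      }
      if (i > n_arr && all(qhead > qtail)) dep <- numeric(0)  # drain done
    }
  }
  waits <- waits[seq_len(n_rec)]; wclass <- wclass[seq_len(n_rec)]
  wtime <- wtime[seq_len(n_rec)]
  keep <- wtime > warmup * horizon_hours
  waits <- waits[keep]; wclass <- wclass[keep]
  out <- data.frame(class = seq_len(m), n = NA_integer_,
                    mean_wait = NA_real_, se = NA_real_)
  for (k in seq_len(m)) {
    w <- waits[wclass == k]
    out$n[k] <- length(w)
    if (lambdas[k] == 0) { out$mean_wait[k] <- 0; out$se[k] <- 0; next }
    if (length(w) < 2L * n_batches) next
    out$mean_wait[k] <- mean(w)
    batch <- split(w, cut(seq_along(w), n_batches, labels = FALSE))
    bm <- vapply(batch, mean, numeric(1))
    out$se[k] <- sd(bm) / sqrt(length(bm))
  }
  out
}

#' Priority entry queue with head-of-queue wait assignment
#'
#' The operational policy at a venue door: arrivals join the queue in
#' priority order (class ascending, FCFS within a class); the queue head is
#' assigned the analytic mean wait `W_k` of its class, and whenever the head
#' enters the venue the displayed waits of the remaining members are
#' recomputed for the new head. Arrivals whose class is saturated
#' (`sigma_k >= 1`) are deferred with a `"venue_saturated"` status.
#'
#' @param lambdas,mu,s queue parameters (see [waiting_times()]).
#' @return an `entry_queue` object.
#' @export
entry_queue <- function(lambdas, mu, s) {
  structure(list(
    members = data.frame(anon_id = character(), k = integer(),
                         seq = integer(), stringsAsFactors = FALSE),
    counter = 0L,
    W = waiting_times_capped(lambdas, mu, s)
  ), class = "entry_queue")
}

#' @rdname entry_queue
#' @param queue an `entry_queue`.
#' @param anon_id arriving visitor's anonymous identifier.
#' @param k arriving visitor's priority class.
#' @return `assign_wait()`: list with the updated `queue`, the scheduled
#'   `wait` (hours; `Inf` when deferred) and a `status` of `"queued"` or
#'   `"venue_saturated"`. `admit_head()`: list with the updated `queue` and
#'   the admitted `anon_id` (`NA` on an empty queue). `displayed_waits()`:
#'   named numeric vector of the wait currently shown to each member.
#' @export
assign_wait <- function(queue, anon_id, k) {
  stopifnot(inherits(queue, "entry_queue"))
  k <- as.integer(k)
  if (k < 1L || k > length(queue$W)) stop_hp("class k out of range")
  if (!is.finite(queue$W[k]))
    return(list(queue = queue, wait = Inf, status = "venue_saturated"))
  queue$counter <- queue$counter + 1L
  queue$members <- rbind(queue$members,
                         data.frame(anon_id = anon_id, k = k,
                                    seq = queue$counter,
                                    stringsAsFactors = FALSE))
  queue$members <- queue$members[order(queue$members$k, queue$members$seq), ,
                                 drop = FALSE]
  list(queue = queue, wait = queue$W[k], status = "queued")
}

#' @rdname entry_queue
#' @export
admit_head <- function(queue) {
  stopifnot(inherits(queue, "entry_queue"))
  if (nrow(queue$members) == 0)
    return(list(queue = queue, admitted = NA_character_))
  admitted <- queue$members$anon_id[1L]
  queue$members <- queue$members[-1L, , drop = FALSE]
  list(queue = queue, admitted = admitted)
}

#' @rdname entry_queue
#' @export
displayed_waits <- function(queue) {
  stopifnot(inherits(queue, "entry_queue"))
  setNames(queue$W[queue$members$k], queue$members$anon_id)
}
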