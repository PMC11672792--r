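---
title: "Methods: liability scoring, venue availability, priority queueing and epidemic replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liability scoring, venue availability, priority queueing and epidemic replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthpass)
```

# Overview

`healthpass` implements the analytical stack of a contactless check-in and
adaptive access-control system for public venues during a health crisis. The
pipeline has five stages, each usable on its own:

1. **Record store** — anonymous check-in/check-out sessions per venue, with
   occupancy and history queries (`read_checkins()`, `occupancy()`).
2. **Liability scoring** — a six-item voluntary form is scored by a
   configurable rubric and condensed into a radar-map score
   $\varphi(u) \in [0,1]$ (`apply_rubric()`, `radar_score()`).
3. **Venue availability** — three risk factors give the probability
   $\omega(v)$ that a visitor avoids infection inside the venue
   (`availability()`).
4. **Access control** — liability maps to a priority class, availability to
   a server count, and an M/M/s non-preemptive priority queue yields the
   mean waiting time per class (`priority_of()`, `capacity_servers()`,
   `waiting_times()`).
5. **Epidemic replay** — an agent-based simulation replays a check-in
   stream through venue compartments with and without the access-control
   policy and reports flatten-the-curve metrics (`run_simulation()`,
   `flatten_comparison()`).

A synthetic campus generator (`generate_campus()`) produces visitors,
forms and check-in streams with the statistical structure the models
assume, so the whole stack is testable without any deployment data.

# Liability scoring

The voluntary form has six items in a fixed cyclic order: home, workplace,
travel record, means of transport, symptoms, close contact. A rubric maps
each answer token to a score $V_i \in [0, \hat V_i]$; unanswered items score
zero, which deliberately rewards complete disclosure. The liability score is
the area of the radar polygon spanned by $V$, normalized by the polygon at
the upper bounds:

$$\varphi(u) \;=\; \frac{\sum_{i=0}^{a-1} V_{i \bmod a}\,V_{(i+1) \bmod a}}
                       {\sum_{i=0}^{a-1} \hat V_{i \bmod a}\,\hat V_{(i+1) \bmod a}},
  \qquad a = 6 .$$

The common triangle-area factor $\tfrac12\sin(2\pi/a)$ cancels, so only the
cyclic products remain. Consequences worth knowing:

* $\varphi$ is 0 whenever no two *adjacent* axes are both positive (e.g.
  $V = (5,0,5,0,5,0)$), so the axis order matters. The order above is fixed
  in the rubric and in this package; reordering axes changes scores.
* $\varphi$ is monotone nondecreasing in every component and invariant under
  joint rescaling of $V$ and $\hat V$.
* **Higher $\varphi$ means a safer visitor.** A visitor with
  $\varphi < \theta_{liability}$ (strictly below; default
  $\theta_{liability} = 0.8$) is classified *low-liability*.

The shipped rubric (`default_rubric()`, also `inst/extdata/rubric.yaml`)
scores residence items 1–5 by five regional risk tiers, transport from 1
(metro) to 5 (walking), and symptoms/close contact by a severity map
(5/2/1). These values are site configuration: the tier definitions belong
to the local authority, and administrators are expected to adapt the YAML
file rather than the code.

# Venue availability

Three factors are computed per venue:

* $R_1 = n_l$, the current number of low-liability occupants
  (`member_risk()`);
* $R_2 = \sum_i r_i\, n_i / m_i$, the expected low-liability inflow from
  neighboring venues (`propagation_risk()`), where $n_i/m_i$ is the
  historical fraction of departures from venue $i$ that arrive here within
  the linkage window (default 2 h between checkout and the next check-in)
  and $r_i$ is venue $i$'s current low-liability count. Sources with no
  recorded departures contribute zero — the fraction is undefined there and
  zero is the conservative limit;
* $R_3 = N / N_c$, occupancy over capacity (`crowdedness_risk()`), left
  unbounded above so an over-capacity venue is penalized more than a full
  one.

With the per-contact transmission probability $\beta = R_0/\tau$ (default
$R_0 = 2.24$ and $\tau = 50\ \text{contacts/day} \times 15\ \text{infectious
days} = 750$, so $\beta \approx 0.002987$), availability is

$$\omega(v) = (1-\beta)^{(R_1 + R_2)\,R_3} \in (0, 1],$$

the probability that a visitor's random contacts inside the venue all avoid
transmission: $(R_1+R_2)$ counts the risky contacts available, $R_3$ scales
how many of them are actually met.

# Access control

Liability becomes a priority class via $k = \lceil 1/\varphi \rceil$
clamped to $1..m$ (default $m = 5$), with $\varphi = 0$ mapped to class
$m$. The printed form of this map is ambiguous between a reciprocal and a
subtraction; the reciprocal is the only reading consistent with
$\varphi \in [0,1]$, integer classes, and "lower class index = higher
priority", and is used throughout. Availability sets the server count
$s = \max(1, \lfloor \omega N_c \rfloor)$ — the occupancy slots the
controller will fill.

For Poisson class arrivals $\lambda_k$, exponential service at rate
$\mu = 1/T$ ($T$ = mean dwell) and $s$ servers, the mean queue delay of
class $k$ in the non-preemptive M/M/s priority queue is

$$W_k = \frac{A^{-1}}{(1-\sigma_{k-1})(1-\sigma_k)}, \qquad
  A = s!\,(1-\rho)(s\mu) \sum_{i=0}^{s-1} \frac{(s\rho)^{i-s}}{i!} + s\mu,$$

with $\rho_i = \lambda_i/(s\mu)$, $\sigma_r = \sum_{i \le r} \rho_i$,
$\rho = \sigma_m$ and $\sigma_0 = 0$. Numerical and semantic choices:

* **$\sigma_0 = 0$.** A published piecewise form sets $\sigma_0 = 1$, which
  would zero the denominator of $W_1$; the factor $(1-\sigma_0) = 1$ is the
  standard convention and the only one under which the formula collapses to
  the M/M/1 wait $\rho/(\mu-\lambda)$ and the Erlang-C delay at $m = 1$.
  Both collapses are enforced in the test suite to $10^{-10}$ relative
  error, as is the conservation law
  $\sum_k (\lambda_k/\lambda) W_k = W^{FCFS}_q$.
* **Stability** is the aggregate condition $\sigma_m < 1$; the per-class
  condition $\rho_i < 1$ is necessary but not sufficient. `waiting_times()`
  raises an error naming the first saturated class. The internal capped
  variant used by the replay instead reports `Inf` for saturated classes
  and computes the stable prefix on the truncated system (saturated classes
  are turned away, so they place no load) — the standard overflow-control
  reading.
* The factorial terms of $A$ are evaluated in log space, so large $s$
  (hundreds of slots) is exact to double precision.
* $W_k$ is queue delay only; time in service is the visit itself.

`simulate_queue_des()` is an independent event-driven simulator of the same
system (Poisson arrivals, exponential service, priority dispatch, FCFS
within class). It exists to validate the closed form, never to replace it;
its standard errors come from batch means (32 batches after a 10% warm-up)
because successive waits are autocorrelated and naive standard errors would
be optimistically small.

The operational policy (`entry_queue()`, `assign_wait()`, `admit_head()`)
keeps the door queue in priority order (FCFS within class), displays $W_k$
to the head of the queue, and refreshes displayed waits when the head
enters. Arrivals of a saturated class are deferred with a
`venue_saturated` status rather than given an infinite wait.

# Epidemic replay

Agents carry a single state variable, the infection day; the stage at day
$d$ is derived from it: asymptomatic for `asymptomatic_days` (default 6),
infectious until `course_days` (default 21), then recovered. Deriving
stages from one timestamp makes forward-only transitions and population
conservation structural rather than tested-for. Two stage-model choices:

* The deployment describes four stages (exposed, asymptomatic, infectious,
  recovered) but specifies durations only as a 6-day non-infectious period
  inside a 21-day course, and states that pre-infectious agents do not
  transmit. The exposed and asymptomatic stages are therefore merged into
  one 6-day non-infectious stage; nothing downstream can distinguish them.
* Venues are well-mixed compartments. The original simulation ran in a 3-D
  scanned environment with free movement; the transmission logic it states
  (contact + $\beta$) is fully captured by compartments, and geometry is
  out of scope here.

Each day, every infectious agent present in a venue draws
$\min(c \cdot f, N_{present}-1)$ distinct uniform contacts among that
venue-day's occupants, where $c$ is `contacts_per_day` (default 50) and
$f$ is the fraction of the day the *infectious* agent is checked in;
fractional expected draws are resolved by stochastic rounding so the
expectation is exact. Each susceptible contact is infected with probability
$\beta$. Contacts are venue-internal: time outside venues does not
transmit, which is the conservative reading of a check-in-based system.
With one infectious agent co-present with 99 susceptibles for a full day at
$\beta = 0.003$, the expected number of new infections is
$50 \times 0.003 = 0.15$/day; the test suite verifies this against 1,000
replicates.

Seeding ties the epidemic to the scoring model: exactly
$\mathrm{round}(I_0 n)$ agents start asymptomatic *and* low-liability, so
the initial infection rate equals the low-liability fraction. Liability
and disease state are independent afterwards — a recovered low-liability
visitor keeps their score, and newly infected high-liability visitors keep
theirs (the form, not the infection, is what the system can observe).

## The access-controlled replay

With `control_on = TRUE`, the stream is transformed before simulation
(`apply_access_control()`):

1. At each day start the controller reads the *uncontrolled* stream — its
   monitoring view — for each venue's occupancy, low-liability counts and
   historical transfer fractions, giving $R_1, R_2, R_3$, then $\omega$
   and $s = \max(1,\lfloor \omega N_c \rfloor)$.
2. Per-class arrival rates for the day (from the stream itself) and
   $\mu = 1/T$ give the scheduled waits $W_k$; each arrival's check-in is
   shifted by the wait of its class.
3. Admission respects the $s$ slots: an arrival finding all slots busy
   waits for the earliest departure. Sessions are processed in
   shifted-arrival order, which approximates priority order because higher
   classes receive shorter shifts.
4. The check-out time is **not** moved: waiting truncates the visit, and a
   session whose wait (including deferral of saturated classes) exceeds its
   remaining duration is dropped. This models a visitor with a fixed
   departure constraint, and it is the mechanism by which the policy
   works — low-priority (low-liability, i.e. initially infectious) visitors
   lose in-venue exposure time while high-priority visitors are barely
   delayed.

Flatten-the-curve metrics compare paired runs on the same campus and seed:
`flatten_comparison()` reports the percent peak reduction
$100(1 - \text{peak}_{on}/\text{peak}_{off})$ and the peak delay in days,
with the peak taken at its first attainment.

# The synthetic campus

`generate_campus()` emulates the data shape the models assume. External
arrivals at each venue are homogeneous Poisson; dwell times are exponential
with the venue's mean; after a session the visitor transfers, with
probability `p_transfer`, to a venue drawn from a row-stochastic transition
matrix after a 5–60 minute gap (inside the 2-hour linkage window, so the
transfer statistics can recover the matrix). Visitors are drawn with
replacement, giving heavy-tailed per-visitor session counts. Form answers
are sampled per item — from the safe end of each answer set for acceptable
visitors, uniformly for risky ones — with a rejection step so the
low-liability fraction equals $I_0$ exactly. Everything is deterministic
given the spec's seed.

`default_paper_scale_spec()` pins the generator to the deployment's scale:
1,416 visitors, five venues, a 62-day horizon, and arrival rates solved so
the expected session count is 128,656 (the transfer chain multiplies the
external rate by $1/(1-p_{transfer})$; horizon-edge truncation loses about
1%, well inside the 5% the tests allow). Values the deployment did not
publish are set once, with the following reasoning, and are spec fields —
not claims about any real campus:

* **Mean dwell 12 h.** The replayed population is present most of the day
  (1.47 sessions/visitor/day $\times$ 12 h $\approx$ 73% of the day
  checked in), which makes the effective reproduction number
  $R_0 \times 0.73 \approx 1.6 > 1$ — an epidemic that actually grows, as
  in the original experiment. Much shorter dwell times starve the epidemic
  (50 contacts/day prorated by a small presence fraction cannot sustain
  spread); dwell near 24 h is not a venue visit.
* **Capacity 230 per venue**, about 10% above the typical concurrent
  occupancy of ~208. Pandemic-era capacity caps are set near expected
  demand precisely so that they bind; this puts the entry queues near
  $\rho \approx 0.9$, where the priority structure differentiates classes
  without saturating the safe majority.
* **`p_transfer` = 0.3**: a minority of sessions chain to a second venue,
  enough that the propagation risk $R_2$ and the transition statistics have
  signal.

What the generator deliberately does **not** reproduce: weekday/weekend
profiles, per-venue popularity skew, the real per-user session-count
distribution, or any spatial structure. Tests passing on this campus show
the *mechanisms* behave as specified (the policy lowers and never advances
the peak; more initial infection gives higher peaks); they do not certify
effect sizes on any real deployment, whose headline numbers depend on
undeposited data.

# Survey metrics

SUS responses are ten 1–5 Likert ratings; odd items are positively worded
(convert as rating − 1), even items negatively (5 − rating), each on 0–4,
and the overall score is 2.5 times the converted sum. Items 4 and 10 form
the learnability dimension, the other eight usability. One published table
labels learnability "S4 and S7"; the printed dimension value matches the
mean of items 4 and 10, and the accompanying text says 4 and 10, so the
label is treated as a typo. The same table's usability value (2.57) is not
reproducible from its own per-item means (their 8-item mean is ≈ 3.33);
`sus_scores()` reports the computed mean and this discrepancy is simply
documented. Report-style output rounds half-up at 2 decimals, matching the
published presentation.

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` size their computations for a
single CPU: queueing validation uses $(s, \rho)$ grids plus five randomized
discrete-event configurations of ~40,000 arrivals each; the radar-score
properties are exhaustive over the $6^6$ integer lattice; the epidemic
properties use ten paired campus-scale runs (~128,000 sessions each) plus
ten runs per initial rate $I_0 \in \{0.05, 0.10, 0.15\}$; the transmission
expectation uses 1,000 single-day replicates. Every stochastic component
takes an explicit seed, and a run is bit-reproducible given it.

# Known limitations

* The replay's controller reads venue state from the uncontrolled stream
  (the monitoring view) rather than co-evolving with admissions; with
  strong throttling the controlled venue is emptier than the controller
  believes, so the policy is, if anything, conservative.
* Open sessions (no checkout scan) are retained in the store but ignored by
  history-based statistics and by the simulator; no imputation is defined.
* The queue model assumes one shared service-rate $\mu$ across classes and
  exponential dwell; per-class service and general dwell distributions are
  out of scope.
* Rubric values are placeholders pending site policy; the mapping of
  governmental risk tiers to 1–5 scores is configuration.
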