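# Shared fixtures and independent oracles used across test files.

# three-subject data matching the worked person-period example:
# an event in interval 3, a censored subject in interval 4, and an event
# beyond the horizon (administratively censored at w = 5)
unit_grid5 <- function() interval_grid(0:5)

worked_example_data <- function() {
  survival_data(data.frame(id = 1:3,
                           time = c(2.5, 3.4, 6.5),
                           event = c(1, 0, 1),
                           x = c(0.2, -1.1, 0.8)),
                id = "id")
}

# brute-force per-subject expansion: loops over subjects and intervals,
# independent of the vectorized implementation
oracle_expand_rows <- function(time, event, cuts, mode) {
  J <- length(cuts) - 1L
  lo <- cuts[-(J + 1L)]; hi <- cuts[-1L]
  vapply(seq_along(time), function(i) {
    if (event[i] == 1) {
      sum(hi < time[i]) + 1L   # interval containing the event
    } else {
      switch(mode,
             observed = sum(lo < time[i]),
             half     = sum(time[i] >= (lo + hi) / 2),
             full     = sum(time[i] >= hi))
    }
  }, integer(1))
}

# risk-set product-limit oracle for the Kaplan-Meier estimate
oracle_km <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  vapply(at, function(t) {
    s <- 1
    for (u in ut[ut <= t]) {
      n_risk <- sum(time >= u)
      d <- sum(time == u & event == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }, numeric(1))
}

# life-table oracle: conditional failure proportions per interval
oracle_life_table <- function(time, event, grid) {
  J <- grid$n_intervals
  j <- interval_index(pmin(time, grid$horizon), grid)
  vapply(seq_len(J), function(k) {
    at_risk <- j >= k
    sum(at_risk & j == k & event == 1) / sum(at_risk)
  }, numeric(1))
}

# a constant-probability classifier engine
engine_constant <- function(p) {
  dtsurv_engine("constant",
                fit = function(x, y, seed, params) list(p = p),
                predict = function(state, x) rep(state$p, nrow(x)))
}

# an adversarial classifier: arbitrary probabilities, deterministic per row
engine_adversarial <- function(seed) {
  dtsurv_engine("adversarial",
                fit = function(x, y, seed_, params) list(seed = seed),
                predict = function(state, x) {
                  set.seed(state$seed + nrow(x))
                  stats::runif(nrow(x))
                })
}

surv_formula <- survival::Surv(time, event) ~ x1
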