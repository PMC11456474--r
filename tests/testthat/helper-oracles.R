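# Independent oracles used across the suite.  These are deliberately naive
# reimplementations (inverse-variance arithmetic, matrix powers, closed-form
# sums) kept free of any package internals.

# Hand-coded DerSimonian-Laird random-effects pooling on the logit scale.
dl_pool_logit <- function(events, total, cc = 0.5) {
  corner <- events == 0 | events == total
  e <- events + ifelse(corner, cc, 0)
  n <- total + ifelse(corner, 2 * cc, 0)
  yi <- log(e / (n - e))
  vi <- 1 / e + 1 / (n - e)
  w <- 1 / vi
  ybar <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - ybar)^2)
  k <- length(yi)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (vi + tau2)
  mu <- sum(ws * yi) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(estimate = plogis(mu), ci_low = plogis(mu - 1.96 * se),
       ci_high = plogis(mu + 1.96 * se), tau2 = tau2)
}

base_pset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- base_case_parameters()
    cache
  }
})

# Base set with every chance-node branch out of no_complication switched off:
# the cohort must then sit in no_complication forever.
zero_event_pset <- function(strategy = "doac") {
  ps <- base_pset()
  ps <- set_param_value(ps, "p_death_cancer", 0)
  for (s in intersect(c(strategy, "placebo"), strategies(ps))) {
    ps <- set_param_value(ps, "p_first_vte", 0, s)
    ps <- set_param_value(ps, "p_bleed", 0, s)
  }
  ps
}

# Minimal hand-assembled 3-state chain (well, well again, absorbed) used for
# oracle-equivalence checks of the cohort engine.
three_state_model <- function(p_event = 0.02, p_death_well = 0.01,
                              p_death_sick = 0.05) {
  states <- data.frame(
    name = c("no_complication", "dvt", "death"),
    base = c("no_complication", "dvt", "death"),
    tunnel = NA_real_, therapeutic = FALSE, stringsAsFactors = FALSE)
  class(states) <- c("state_space", "data.frame")
  P <- rbind(c(1 - p_event - p_death_well, p_event, p_death_well),
             c(0, 1 - p_death_sick, p_death_sick),
             c(0, 0, 1))
  dimnames(P) <- list(states$name, states$name)
  E <- matrix(0, 3, 6, dimnames = list(states$name,
                                       c("dvt", "pe", "ich", "gib", "crnmb", "mb")))
  E["no_complication", "dvt"] <- p_event
  structure(list(states = states, strategy = "toy", inputs = NULL,
                 P = P, event_probs = E, matrix_at = function(cycle) P),
            class = "transition_model")
}

three_state_payoffs <- function(u_well = 0.65, u_sick = 0.61,
                                c_well = 100, c_sick = 250, c_event = 693) {
  structure(list(
    state_utility = c(no_complication = u_well, dvt = u_sick, death = 0),
    state_cost_per_cycle = c(no_complication = c_well, dvt = c_sick, death = 0),
    event_toll_cost = c(dvt = c_event, pe = 0, ich = 0, gib = 0, crnmb = 0),
    event_toll_disutility = c(mb = 0, crnmb = 0)),
    class = "payoff_spec")
}

# Oracle for the 3-state chain: explicit matrix powers plus term-by-term
# discounted payoff sums.
three_state_oracle <- function(model, payoffs, horizon, discount) {
  occ <- c(1, 0, 0)
  cost <- qaly <- 0
  trace <- matrix(0, horizon + 1, 3)
  trace[1, ] <- occ
  for (t in 0:(horizon - 1)) {
    d <- (1 + discount)^(-t / 12)
    ev_dvt <- occ[1] * model$P[1, 2]
    cost <- cost + d * (sum(occ * payoffs$state_cost_per_cycle) +
                          ev_dvt * payoffs$event_toll_cost[["dvt"]])
    qaly <- qaly + d * sum(occ * payoffs$state_utility) / 12
    occ <- as.numeric(occ %*% model$P)
    trace[t + 2, ] <- occ
  }
  list(cost = cost, qaly = qaly, trace = trace)
}
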