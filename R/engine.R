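#' Discount factor at a monthly cycle
#'
#' Annual discounting applied continuously over monthly cycles:
#' `(1 + annual_rate)^(-cycle / 12)`, used identically for costs and QALYs.
#'
#' @param cycle non-negative cycle index (vectorised).
#' @param annual_rate annual discount rate, `>= 0`.
#' @return discount factor(s).
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(annual_rate < 0)) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

#' Per-state payoff specification
#'
#' Maps each expanded state to its utility (per year alive) and its cost per
#' monthly cycle, and each transient event to its one-time cost and QALY
#' tolls.  Drug cost accrual: the prophylactic one-cycle price applies in
#' every living state on prophylaxis (lifelong), the 3-month therapeutic
#' price is spread evenly over the three therapeutic-window cycles, and
#' off-treatment ICH accrues no drug cost.  Annual chronic-state management
#' costs (post-ICH, PTS, CTEPH) are divided by 12 per occupied cycle.  Drug
#' costs are multiplied by the self-payment ratio.
#'
#' @param inputs resolved inputs from [strategy_inputs()].
#' @param states a `"state_space"`.
#' @return an object of class `"payoff_spec"`: list with `state_utility`
#'   (annual, by state), `state_cost_per_cycle`, `event_toll_cost` (per
#'   event: dvt, pe, ich, gib, crnmb) and `event_toll_disutility` (mb,
#'   crnmb).
#' @export
payoff_spec <- function(inputs, states = expand_states()) {
  u <- inputs$u[states$base]
  names(u) <- states$name
  drug <- ifelse(states$base == "death", 0,
          ifelse(states$therapeutic, inputs$c_treat3 / 3,
          ifelse(states$base == "ich_off_treatment", 0, inputs$c_proph)))
  drug <- drug * inputs$self_pay
  manage <- ifelse(states$base %in% c("ich_on_treatment", "ich_off_treatment"),
                   inputs$c_state_year[["ich"]] / 12,
            ifelse(states$base == "pts", inputs$c_state_year[["pts"]] / 12,
            ifelse(states$base == "cteph", inputs$c_state_year[["cteph"]] / 12, 0)))
  cost <- drug + manage
  names(cost) <- states$name
  stopifnot(all(u >= 0 & u <= 1), all(cost >= 0),
            u[["death"]] == 0, cost[["death"]] == 0)
  structure(list(state_utility = u, state_cost_per_cycle = cost,
                 event_toll_cost = inputs$c_event,
                 event_toll_disutility = c(mb = inputs$du_mb,
                                           crnmb = inputs$du_crnmb)),
            class = "payoff_spec")
}

#' Per-event transition flow masses
#'
#' The probability mass flowing along selected transitions in one cycle:
#' `flow = occupancy[source] * P[source, dest]`, summed per named event.
#'
#' @param trace_row occupancy vector (one trace row).
#' @param matrix the cycle's transition matrix.
#' @param event_edges named list; each element a 2-column matrix of
#'   `(source, dest)` state indices.
#' @return named numeric vector of flow masses.
#' @export
event_flow <- function(trace_row, matrix, event_edges) {
  S <- length(trace_row)
  vapply(event_edges, function(edges) {
    edges <- rbind(edges)
    if (any(edges < 1 | edges > S)) stop("unknown edge index", call. = FALSE)
    sum(trace_row[edges[, 1]] * matrix[edges])
  }, numeric(1))
}

#' Propagate the cohort and accrue discounted costs and QALYs
#'
#' Starts with the full cohort free of complications, applies the transition
#' matrix each monthly cycle and accrues payoffs: occupancy at the start of
#' cycle `t` earns `state_utility / 12` and `state_cost_per_cycle`, the event
#' flows during cycle `t` incur one-time cost tolls (acute DVT/PE care, ICH,
#' GI bleed, CRNMB) and one-time QALY decrements (major bleeding, CRNMB), and
#' everything is discounted at `(1 + discount)^(-t/12)`.  No half-cycle
#' correction by default; `half_cycle = TRUE` averages start- and end-of-cycle
#' occupancy for the state payoffs.
#'
#' @param model a `"transition_model"`.
#' @param payoffs a `"payoff_spec"` over the same state list (defaults to the
#'   one derived from the model's inputs).
#' @param horizon_months positive integer number of monthly cycles.
#' @param discount annual discount rate (default 0.05).
#' @param half_cycle apply the standard half-cycle correction.
#' @return an object of class `"cohort_result"`: `trace`
#'   (`horizon + 1` rows of state occupancy), discounted `total_cost` and
#'   `total_qaly`, their undiscounted twins, and bookkeeping fields.
#' @export
run_cohort <- function(model, payoffs = NULL, horizon_months,
                       discount = 0.05, half_cycle = FALSE) {
  if (length(horizon_months) != 1 || is.na(horizon_months) ||
      horizon_months != round(horizon_months) || horizon_months < 1)
    stop("horizon_months must be a positive integer", call. = FALSE)
  if (is.null(payoffs)) payoffs <- payoff_spec(model$inputs, model$states)
  states <- model$states
  S <- nrow(states)
  if (length(payoffs$state_utility) != S)
    stop("model and payoffs must share the same state list", call. = FALSE)
  P <- model$P
  E <- model$event_probs
  H <- as.integer(horizon_months)
  trace <- matrix(0, H + 1, S, dimnames = list(NULL, states$name))
  occ <- c(1, rep(0, S - 1))
  trace[1, ] <- occ
  toll_cost_vec <- payoffs$event_toll_cost[c("dvt", "pe", "ich", "gib", "crnmb")]
  du <- payoffs$event_toll_disutility
  disc <- discount_factor(0:(H - 1), discount)
  cost_d <- qaly_d <- cost_u <- qaly_u <- 0
  for (t in seq_len(H)) {
    occ_next <- as.numeric(occ %*% P)
    occ_eff <- if (half_cycle) (occ + occ_next) / 2 else occ
    ev <- as.numeric(occ %*% E)
    names(ev) <- colnames(E)
    c_t <- sum(occ_eff * payoffs$state_cost_per_cycle) +
      sum(ev[c("dvt", "pe", "ich", "gib", "crnmb")] * toll_cost_vec)
    q_t <- sum(occ_eff * payoffs$state_utility) / 12 -
      ev[["mb"]] * du[["mb"]] - ev[["crnmb"]] * du[["crnmb"]]
    cost_d <- cost_d + disc[t] * c_t
    qaly_d <- qaly_d + disc[t] * q_t
    cost_u <- cost_u + c_t
    qaly_u <- qaly_u + q_t
    occ <- occ_next
    trace[t + 1, ] <- occ
  }
  structure(list(strategy = model$strategy, trace = trace,
                 total_cost = cost_d, total_qaly = qaly_d,
                 undiscounted_cost = cost_u, undiscounted_qaly = qaly_u,
                 horizon_months = H, discount = discount,
                 half_cycle = half_cycle),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s: %d cycles, cost $%.3f, %.3f QALYs (discounted)\n",
              x$strategy, x$horizon_months, x$total_cost, x$total_qaly))
  invisible(x)
}
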