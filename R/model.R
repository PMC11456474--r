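#' Fit the Markov cohort cost-effectiveness model
#'
#' The package's main entry point: builds the tunnel-state transition model
#' for each requested strategy from a parameter set, propagates the cohort
#' over the horizon with discounted cost and QALY accrual, and attaches the
#' incremental analysis (frontier with dominance flags plus pairwise ICERs
#' against no prophylaxis).
#'
#' @param parameters a `"parameter_set"` (default: the packaged base case).
#' @param strategies strategies to evaluate.
#' @param horizon_months run length in monthly cycles (default 60 = 5 years).
#' @param discount annual discount rate (default: the set's
#'   `discount_rate_annual`).
#' @param wtp willingness-to-pay per QALY (default: the set's `wtp`).
#' @param mortality_mode see [strategy_inputs()].
#' @param half_cycle apply the half-cycle correction (default `FALSE`).
#' @param states state space; defaults to the full tunnel expansion.
#' @return an object of class `"cea_markov"` with fields `results` (named
#'   list of `"cohort_result"`), `table` (strategy/cost/qaly), `frontier`,
#'   `wtp`, `parameters` and the run settings.  Methods: `print`, `summary`,
#'   `plot` (cost-effectiveness plane), `simulate` (PSA draws).
#' @examples
#' fit <- cea_markov(strategies = c("placebo", "doac"), horizon_months = 12)
#' summary(fit)
#' @export
cea_markov <- function(parameters = base_case_parameters(),
                       strategies = c("placebo", "doac", "lmwh"),
                       horizon_months = 60,
                       discount = param_value(parameters, "discount_rate_annual"),
                       wtp = param_value(parameters, "wtp"),
                       mortality_mode = "total", half_cycle = FALSE,
                       states = expand_states()) {
  stopifnot(length(strategies) >= 1)
  results <- lapply(strategies, function(s) {
    m <- transition_model(parameters, s, states, mortality_mode)
    run_cohort(m, horizon_months = horizon_months, discount = discount,
               half_cycle = half_cycle)
  })
  names(results) <- strategies
  tab <- data.frame(strategy = strategies,
                    cost = vapply(results, `[[`, numeric(1), "total_cost"),
                    qaly = vapply(results, `[[`, numeric(1), "total_qaly"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  frontier <- if (nrow(tab) >= 2) {
    ref <- if ("placebo" %in% strategies) "placebo" else NULL
    incremental_frontier(tab, reference = ref)
  } else NULL
  structure(list(results = results, table = tab, frontier = frontier,
                 wtp = wtp, parameters = parameters,
                 horizon_months = horizon_months, discount = discount,
                 mortality_mode = mortality_mode, half_cycle = half_cycle,
                 states = states, call = match.call()),
            class = "cea_markov")
}

#' @export
print.cea_markov <- function(x, digits = 3, ...) {
  cat(sprintf("Markov cohort cost-effectiveness model: %d strategies, %d monthly cycles, %.0f%% discount\n",
              nrow(x$table), x$horizon_months, 100 * x$discount))
  tab <- x$table
  tab$cost <- round(tab$cost, digits); tab$qaly <- round(tab$qaly, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cea_markov <- function(object, ...) {
  out <- list(table = object$table, frontier = object$frontier,
              wtp = object$wtp, horizon_months = object$horizon_months,
              nmb = data.frame(
                strategy = object$table$strategy,
                nmb = nmb(object$table$cost, object$table$qaly, object$wtp),
                stringsAsFactors = FALSE))
  class(out) <- "summary.cea_markov"
  out
}

#' @export
print.summary.cea_markov <- function(x, digits = 3, ...) {
  cat(sprintf("Cost-effectiveness summary (%d cycles, WTP $%.3f/QALY)\n",
              x$horizon_months, x$wtp))
  if (!is.null(x$frontier)) {
    f <- x$frontier
    for (col in c("cost", "qaly", "icer_frontier"))
      f[[col]] <- round(f[[col]], digits)
    print(f, row.names = FALSE)
  } else {
    print(x$table, row.names = FALSE)
  }
  cat("Net monetary benefit at WTP:\n")
  print(transform(x$nmb, nmb = round(nmb, digits)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.cea_markov <- function(x, ...) {
  tab <- x$table
  plot(tab$qaly, tab$cost, pch = 19, xlab = "QALYs", ylab = "Cost ($)",
       main = "Cost-effectiveness plane", ...)
  graphics::text(tab$qaly, tab$cost, tab$strategy, pos = 3)
  idx <- if (!is.null(x$frontier))
    match(x$frontier$strategy[!x$frontier$dominated & !x$frontier$ext_dominated],
          tab$strategy) else seq_len(nrow(tab))
  ord <- idx[order(tab$cost[idx])]
  graphics::lines(tab$qaly[ord], tab$cost[ord], lty = 2)
  invisible(x)
}

#' Simulate PSA draws from a fitted model
#'
#' `simulate()` on a `"cea_markov"` runs the probabilistic sensitivity
#' analysis under the fitted settings (strategies, horizon, discount).
#'
#' @param object a `"cea_markov"`.
#' @param nsim number of Monte Carlo draws.
#' @param seed integer seed (mandatory).
#' @param ... passed to [run_psa()].
#' @return a `"psa_result"`.
#' @export
simulate.cea_markov <- function(object, nsim = 1000, seed, ...) {
  run_psa(object$parameters, n = nsim, seed = seed,
          strategies = object$table$strategy,
          horizon_months = object$horizon_months,
          discount = object$discount, states = object$states, ...)
}

#' @export
plot.ceac_curve <- function(x, ...) {
  strat <- unique(x$strategy)
  cols <- seq_along(strat)
  plot(NULL, xlim = range(x$wtp), ylim = c(0, 1),
       xlab = "Willingness to pay ($/QALY)",
       ylab = "Probability cost-effective",
       main = "Cost-effectiveness acceptability curves", ...)
  for (i in seq_along(strat)) {
    sub <- x[x$strategy == strat[i], ]
    graphics::lines(sub$wtp, sub$probability, col = cols[i], lwd = 2)
  }
  graphics::legend("right", legend = strat, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
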