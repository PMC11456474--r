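#' Convert a probability over a stated period to a per-cycle probability
#'
#' Constant-rate conversion: a probability `p` over `period_months` months
#' becomes `1 - (1 - p)^(1 / period_months)` per one-month cycle.
#'
#' @param p probability in `[0, 1]` over the stated period (`p = 1` maps
#'   to 1, the documented degenerate edge).
#' @param period_months positive length of the stated period, in months.
#' @return per-cycle (monthly) probability.
#' @export
period_prob_to_cycle <- function(p, period_months) {
  if (any(period_months <= 0)) stop("period_months must be > 0", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]", call. = FALSE)
  1 - (1 - p)^(1 / period_months)
}

#' Resolve strategy-specific monthly inputs and payoffs
#'
#' Pulls every value the transition builder and the cohort engine need out of
#' a parameter set for one strategy, converting period probabilities to
#' monthly ones.  Off-treatment ICH patients (who discontinued anticoagulation
#' after an intracranial bleed) carry no-prophylaxis event composition: their
#' bleeding and VTE splits resolve against the `placebo` strategy when the set
#' defines one, else against the strategy itself.
#'
#' @param pset a `"parameter_set"`.
#' @param strategy strategy identifier.
#' @param mortality_mode `"total"` treats a state's death probability as that
#'   state's entire mortality; `"additive"` combines it with the background
#'   cancer death hazard.
#' @return a named list of monthly probabilities, splits and payoff inputs.
#' @export
strategy_inputs <- function(pset, strategy, mortality_mode = c("total", "additive")) {
  mortality_mode <- match.arg(mortality_mode)
  v <- function(name, s = strategy) param_value(pset, name, s)
  mo <- function(name, s = strategy) {
    p <- resolve_parameter(pset, name, s)
    period <- if (is.na(p$period_months)) 12 else p$period_months
    period_prob_to_cycle(p$mean, period)
  }
  off_strategy <- if ("placebo" %in% strategies(pset)) "placebo" else strategy
  m_bg <- mo("p_death_cancer")
  death_in <- function(m_state) {
    if (mortality_mode == "total") m_state else 1 - (1 - m_state) * (1 - m_bg)
  }
  list(
    strategy = strategy,
    mortality_mode = mortality_mode,
    # no-complication branch masses (monthly)
    m_vte = mo("p_first_vte"), m_bleed = mo("p_bleed"), m_death_bg = m_bg,
    pe_share = v("pe_share_first_vte"),
    mb_share = v("mb_share_bleeding"), ich_share = v("ich_share_mb"),
    pe_share_off = v("pe_share_first_vte", off_strategy),
    mb_share_off = v("mb_share_bleeding", off_strategy),
    ich_share_off = v("ich_share_mb", off_strategy),
    ich_stop = v("ich_stop_share"),
    # post-event state hazards (monthly)
    m_recur_dvt = mo("p_recur_dvt"), m_bleed_dvt = mo("p_bleed_dvt"),
    m_death_dvt = death_in(mo("p_death_dvt")),
    m_recur_pe = mo("p_recur_pe"), m_bleed_pe = mo("p_bleed_pe"),
    m_death_pe = death_in(mo("p_death_pe")),
    m_recur_ich = mo("p_recur_ich"),
    m_bleed_ich_on = mo("p_bleed_ich_on"), m_bleed_ich_off = mo("p_bleed_ich_off"),
    m_death_ich_on = death_in(mo("p_death_ich_on")),
    m_death_ich_off = death_in(mo("p_death_ich_off")),
    m_death_pts = death_in(mo("p_death_pts")),
    m_pts = c(y1 = mo("p_pts_year1"), y2 = mo("p_pts_year2"),
              y3p = mo("p_pts_year3plus")),
    m_cteph = c(y1 = mo("p_cteph_year1"), y2 = mo("p_cteph_year2"), y3p = 0),
    m_death_cteph = vapply(c("p_death_cteph_days1_90", "p_death_cteph_days91_365",
                             "p_death_cteph_year2", "p_death_cteph_year3plus"),
                           function(nm) death_in(mo(nm)), numeric(1)),
    # payoffs
    u = c(no_complication = v("u_no_complication"), dvt = v("u_dvt"),
          pe = v("u_pe"), ich_on_treatment = v("u_ich"),
          ich_off_treatment = v("u_ich"), pts = v("u_pts"),
          cteph = v("u_cteph"), death = v("u_death")),
    du_mb = v("du_mb"), du_crnmb = v("du_crnmb"),
    c_proph = v("c_prophylaxis_cycle"), c_treat3 = v("c_treatment_3mo"),
    c_event = c(dvt = v("c_event_dvt"), pe = v("c_event_pe"),
                ich = v("c_event_ich"), gib = v("c_event_gib"),
                crnmb = v("c_event_crnmb")),
    c_state_year = c(ich = v("c_post_ich_year"), pts = v("c_pts_year"),
                     cteph = v("c_cteph_year")),
    self_pay = v("self_pay_ratio"))
}

# year/period-indexed schedules by tunnel month (Inf = late tail)
.pts_rate <- function(si, t) {
  ifelse(t <= 12, si$m_pts[["y1"]], ifelse(t <= 24, si$m_pts[["y2"]], si$m_pts[["y3p"]]))
}
.cteph_rate <- function(si, t) {
  ifelse(t <= 12, si$m_cteph[["y1"]], ifelse(t <= 24, si$m_cteph[["y2"]], 0))
}
.cteph_death <- function(si, t) {
  d <- si$m_death_cteph
  ifelse(t <= 3, d[[1]], ifelse(t <= 12, d[[2]], ifelse(t <= 24, d[[3]], d[[4]])))
}

EVENTS <- c("dvt", "pe", "ich", "gib", "crnmb", "mb")

#' Build the one-cycle transition matrix over the expanded state space
#'
#' Transition probabilities out of each state are composed as mutually
#' exclusive monthly branch masses, mirroring a decision-tree chance node:
#' VTE (split PE/DVT by the PE share), bleeding (split CRNMB vs major; major
#' split ICH vs GI; CRNMB and GI bleeds are transient tolls that do not leave
#' the state), progression (PTS/CTEPH) and death, with the residual mass
#' advancing the tunnel (or staying put).  On entry to ICH the cohort splits
#' once into off-/on-treatment branches by the discontinuation share.  A
#' negative residual raises an error naming the state — inconsistent inputs
#' are never silently renormalised.
#'
#' Because tunnel states encode time since entry, the matrix is the same at
#' every cycle; `cycle` is accepted for interface compatibility and
#' validation only.
#'
#' @param inputs resolved monthly inputs from [strategy_inputs()].
#' @param states a `"state_space"` from [expand_states()].
#' @param cycle non-negative cycle index.
#' @return an `S x S` row-stochastic matrix with dimnames from the state
#'   list and an attribute `"event_probs"` (an `S x 6` matrix of per-cycle
#'   event probabilities per occupant: `dvt`, `pe`, `ich`, `gib`, `crnmb`,
#'   `mb`) used to price one-time tolls.
#' @export
build_transition_matrix <- function(inputs, states = expand_states(), cycle = 0) {
  if (cycle < 0) stop("cycle must be non-negative", call. = FALSE)
  S <- nrow(states)
  nm <- states$name
  P <- matrix(0, S, S, dimnames = list(nm, nm))
  E <- matrix(0, S, length(EVENTS), dimnames = list(nm, EVENTS))
  i_death <- match("death", nm)
  i_nc <- match("no_complication", nm)
  blk <- function(base) which(states$base == base)
  i_dvt <- blk("dvt"); i_pe <- blk("pe"); i_cteph <- blk("cteph")
  i_ich_on <- blk("ich_on_treatment"); i_ich_off <- blk("ich_off_treatment")
  i_pts <- blk("pts")
  dvt1 <- i_dvt[1]; pe1 <- i_pe[1]; cteph1 <- i_cteph[1]
  tun <- function(ii) {  # tunnel month per state; NA (debug mode) acts as month 1
    t <- states$tunnel[ii]; t[is.na(t)] <- 1; t
  }
  nxt <- function(ii) c(ii[-1], ii[length(ii)])  # advance tunnel, late absorbs

  # bleeding decomposition: returns masses c(ich, gib, crnmb)
  split_bleed <- function(bl, mb_share, ich_share) {
    mb <- bl * mb_share; ich <- mb * ich_share
    list(ich = ich, gib = mb - ich, crnmb = bl - mb)
  }
  check_residual <- function(res, ii) {
    bad <- res < -1e-12
    if (any(bad))
      stop(sprintf("negative residual transition mass at cycle %d, state(s) %s",
                   cycle, paste(nm[ii][bad], collapse = ", ")), call. = FALSE)
    pmax(res, 0)
  }
  fill_vte_rows <- function(ii, rec, bl, dth, prog, prog_dest,
                            pe_share, mb_share, ich_share) {
    b <- split_bleed(bl, mb_share, ich_share)
    if (any(rec + bl + dth + prog > 1 + 1e-12))
      stop(sprintf("competing branch masses exceed 1 at cycle %d, state(s) %s",
                   cycle, paste(nm[ii][rec + bl + dth + prog > 1 + 1e-12],
                                collapse = ", ")), call. = FALSE)
    add <- function(j, mass) P[cbind(ii, j)] <<- P[cbind(ii, j)] + mass
    add(pe1, rec * pe_share)
    add(dvt1, rec * (1 - pe_share))
    add(i_ich_off, b[["ich"]] * inputs$ich_stop)
    add(i_ich_on, b[["ich"]] * (1 - inputs$ich_stop))
    if (length(prog_dest) == 1 && any(prog > 0)) add(prog_dest, prog)
    add(i_death, dth)
    res <- check_residual(1 - rec - b[["ich"]] - dth - prog, ii)
    P[cbind(ii, nxt(ii))] <<- P[cbind(ii, nxt(ii))] + res
    E[ii, "pe"] <<- E[ii, "pe"] + rec * pe_share
    E[ii, "dvt"] <<- E[ii, "dvt"] + rec * (1 - pe_share)
    E[ii, "ich"] <<- E[ii, "ich"] + b[["ich"]]
    E[ii, "gib"] <<- E[ii, "gib"] + b[["gib"]]
    E[ii, "crnmb"] <<- E[ii, "crnmb"] + b[["crnmb"]]
  }

  # -- no complication: first VTE, bleeding, background cancer death
  with(inputs, {
    b <- split_bleed(m_bleed, mb_share, ich_share)
    if (m_vte + m_bleed + m_death_bg > 1 + 1e-12)
      stop(sprintf("competing branch masses exceed 1 at cycle %d, state no_complication",
                   cycle), call. = FALSE)
    P[i_nc, pe1] <<- m_vte * pe_share
    P[i_nc, dvt1] <<- m_vte * (1 - pe_share)
    P[i_nc, i_ich_off] <<- b[["ich"]] * ich_stop
    P[i_nc, i_ich_on] <<- b[["ich"]] * (1 - ich_stop)
    P[i_nc, i_death] <<- m_death_bg
    P[i_nc, i_nc] <<- check_residual(1 - m_vte - b[["ich"]] - m_death_bg, i_nc)
    E[i_nc, c("pe", "dvt", "ich", "gib", "crnmb")] <<-
      c(m_vte * pe_share, m_vte * (1 - pe_share), b[["ich"]], b[["gib"]], b[["crnmb"]])
  })

  # -- DVT tunnels: recurrence, bleeding, death, PTS progression
  fill_vte_rows(i_dvt, rec = rep(inputs$m_recur_dvt, length(i_dvt)),
                bl = rep(inputs$m_bleed_dvt, length(i_dvt)),
                dth = rep(inputs$m_death_dvt, length(i_dvt)),
                prog = .pts_rate(inputs, tun(i_dvt)), prog_dest = i_pts,
                pe_share = inputs$pe_share, mb_share = inputs$mb_share,
                ich_share = inputs$ich_share)
  # -- PE tunnels: recurrence, bleeding, death, CTEPH progression
  fill_vte_rows(i_pe, rec = rep(inputs$m_recur_pe, length(i_pe)),
                bl = rep(inputs$m_bleed_pe, length(i_pe)),
                dth = rep(inputs$m_death_pe, length(i_pe)),
                prog = .cteph_rate(inputs, tun(i_pe)), prog_dest = cteph1,
                pe_share = inputs$pe_share, mb_share = inputs$mb_share,
                ich_share = inputs$ich_share)

  # -- ICH states: recurrence re-enters the acute VTE tunnels (restarting
  #    therapeutic anticoagulation); a further major bleed that is again ICH
  #    keeps the patient in the ICH state (toll only)
  fill_ich <- function(i, bl, dth, pe_share, mb_share, ich_share) {
    rec <- inputs$m_recur_ich
    b <- split_bleed(bl, mb_share, ich_share)
    if (rec + bl + dth > 1 + 1e-12)
      stop(sprintf("competing branch masses exceed 1 at cycle %d, state %s",
                   cycle, nm[i]), call. = FALSE)
    P[i, pe1] <<- rec * pe_share
    P[i, dvt1] <<- rec * (1 - pe_share)
    P[i, i_death] <<- dth
    P[i, i] <<- check_residual(1 - rec - dth, i)
    E[i, c("pe", "dvt", "ich", "gib", "crnmb")] <<-
      c(rec * pe_share, rec * (1 - pe_share), b[["ich"]], b[["gib"]], b[["crnmb"]])
  }
  fill_ich(i_ich_on, inputs$m_bleed_ich_on, inputs$m_death_ich_on,
           inputs$pe_share, inputs$mb_share, inputs$ich_share)
  fill_ich(i_ich_off, inputs$m_bleed_ich_off, inputs$m_death_ich_off,
           inputs$pe_share_off, inputs$mb_share_off, inputs$ich_share_off)

  # -- PTS: state-specific death only
  P[i_pts, i_death] <- inputs$m_death_pts
  P[i_pts, i_pts] <- 1 - inputs$m_death_pts

  # -- CTEPH tunnels: period-indexed case fatality
  dth <- .cteph_death(inputs, tun(i_cteph))
  P[cbind(i_cteph, i_death)] <- dth
  P[cbind(i_cteph, nxt(i_cteph))] <- P[cbind(i_cteph, nxt(i_cteph))] + (1 - dth)

  # -- death is absorbing
  P[i_death, i_death] <- 1

  E[, "mb"] <- E[, "ich"] + E[, "gib"]
  attr(P, "event_probs") <- E
  P
}

#' Construct a strategy's transition model
#'
#' Bundles the expanded state list, the resolved inputs and the (cycle
#' invariant) transition matrix into one object.  `matrix_at(cycle)` is kept
#' as the access path for cycle-indexed use.
#'
#' @inheritParams strategy_inputs
#' @param states a `"state_space"`; defaults to the full tunnel expansion.
#' @return an object of class `"transition_model"` with fields `states`,
#'   `strategy`, `inputs`, `P`, `event_probs` and `matrix_at`.
#' @export
transition_model <- function(pset, strategy, states = expand_states(),
                             mortality_mode = "total") {
  si <- strategy_inputs(pset, strategy, mortality_mode)
  P <- build_transition_matrix(si, states)
  structure(list(states = states, strategy = strategy, inputs = si,
                 P = P, event_probs = attr(P, "event_probs"),
                 matrix_at = function(cycle) P),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> strategy '%s': %d states, cycle-invariant matrix\n",
              x$strategy, nrow(x$states)))
  invisible(x)
}
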