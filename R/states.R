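BASE_STATES <- c("no_complication", "dvt", "pe", "ich_on_treatment",
                 "ich_off_treatment", "pts", "cteph", "death")

#' Expand the health-state space, including tunnel states
#'
#' The model's seven living conditions plus death are expanded into a state
#' list in which DVT, PE and CTEPH carry monthly tunnel indices (months since
#' entry) so that time-varying hazards — the 3-month therapeutic
#' anticoagulation window after a VTE, the year-indexed PTS/CTEPH incidence
#' schedules, and the period-indexed CTEPH case fatality — are encoded in the
#' state itself.  Beyond `tunnel_months` the schedules are constant, so a
#' single "late" tail state closes each tunnel.  Ordering is deterministic:
#' `no_complication` first, `death` last, tunnels contiguous.
#'
#' @param tunnels logical; `FALSE` collapses to the 8 base states (debug mode,
#'   first-period hazards throughout).
#' @param tunnel_months months of explicit tunnel per tunnelled condition
#'   (default 24; the incidence/fatality schedules change at months 3, 12
#'   and 24).
#' @param therapeutic_months length of the therapeutic-dose window after a
#'   VTE event (default 3).
#' @return a `data.frame` of class `"state_space"` with columns `name`,
#'   `base`, `tunnel` (months since entry, `Inf` for the late tail, `NA` for
#'   untunnelled states) and `therapeutic` (on therapeutic-dose
#'   anticoagulation this month).
#' @export
expand_states <- function(tunnels = TRUE, tunnel_months = 24,
                          therapeutic_months = 3) {
  stopifnot(tunnel_months >= therapeutic_months)
  row <- function(name, base, tunnel = NA_real_, therapeutic = FALSE)
    data.frame(name = name, base = base, tunnel = tunnel,
               therapeutic = therapeutic, stringsAsFactors = FALSE)
  tun <- function(base) {
    m <- seq_len(tunnel_months)
    rbind(row(paste0(base, "_m", m), base, m, m <= therapeutic_months &
                base %in% c("dvt", "pe")),
          row(paste0(base, "_late"), base, Inf, FALSE))
  }
  out <- if (tunnels) {
    rbind(row("no_complication", "no_complication"),
          tun("dvt"), tun("pe"),
          row("ich_on", "ich_on_treatment"),
          row("ich_off", "ich_off_treatment"),
          row("pts", "pts"),
          tun("cteph"),
          row("death", "death"))
  } else {
    do.call(rbind, lapply(BASE_STATES, function(b)
      row(sub("_treatment$", "", sub("ich_on_treatment", "ich_on",
          sub("ich_off_treatment", "ich_off", b))), b)))
  }
  rownames(out) <- NULL
  class(out) <- c("state_space", "data.frame")
  out
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space>: %d states (%s ... %s)\n", nrow(x),
              x$name[1], x$name[nrow(x)]))
  invisible(as.data.frame(x))
}
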