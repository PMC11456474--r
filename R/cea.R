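#' Incremental cost-effectiveness ratio between two strategies
#'
#' @param ref reference strategy's `(cost, qaly)` (numeric length-2 vector or
#'   a `"cohort_result"`).
#' @param comp comparator strategy's `(cost, qaly)`.
#' @param ref_name,comp_name optional labels.
#' @return an object of class `"cea_comparison"`: `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` when undefined) and `status`, one of `"icer"`,
#'   `"comparator_dominant"` (comparator cheaper and more effective),
#'   `"comparator_dominated"`, or `"undefined"` (equal QALYs:
#'   cost-minimisation case).
#' @export
compute_icer <- function(ref, comp, ref_name = "reference", comp_name = "comparator") {
  pair <- function(x) {
    if (inherits(x, "cohort_result")) c(x$total_cost, x$total_qaly) else as.numeric(x)
  }
  r <- pair(ref); c2 <- pair(comp)
  if (any(!is.finite(c(r, c2)))) stop("costs and QALYs must be finite", call. = FALSE)
  dc <- c2[1] - r[1]; dq <- c2[2] - r[2]
  status <- if (dq == 0) "undefined"
            else if (dc < 0 && dq > 0) "comparator_dominant"
            else if (dc > 0 && dq < 0) "comparator_dominated"
            else "icer"
  icer <- if (dq == 0) NA_real_ else dc / dq
  structure(list(reference = ref_name, comparator = comp_name,
                 delta_cost = dc, delta_qaly = dq, icer = icer, status = status),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost $%.3f, dQALY %.3f, %s\n", x$comparator,
              x$reference, x$delta_cost, x$delta_qaly,
              switch(x$status,
                     icer = sprintf("ICER $%.3f/QALY", x$icer),
                     comparator_dominant = "dominant (saves money, gains health)",
                     comparator_dominated = "dominated",
                     undefined = "undefined ICER (equal QALYs)")))
  invisible(x)
}

#' Net monetary benefit
#'
#' @param cost total cost.
#' @param qaly total QALYs.
#' @param wtp willingness-to-pay per QALY, `>= 0`.
#' @return `qaly * wtp - cost` (vectorised).
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  qaly * wtp - cost
}

#' Efficiency-frontier analysis over a set of strategies
#'
#' Sorts strategies by cost, flags strict and extended dominance, and
#' computes sequential ICERs along the efficiency frontier.  Pairwise ICERs
#' versus a named reference strategy can be requested alongside (the
#' reporting convention of fixed-reference tables).
#'
#' @param results a `data.frame` with columns `strategy`, `cost`, `qaly`, or
#'   a list of `"cohort_result"` objects.
#' @param reference optional strategy name; adds a column of pairwise ICERs
#'   versus that strategy.
#' @return a `data.frame` sorted by cost with columns `strategy`, `cost`,
#'   `qaly`, `dominated`, `ext_dominated`, `icer_frontier` (versus the
#'   previous non-dominated strategy) and, when requested,
#'   `icer_vs_<reference>`.
#' @export
incremental_frontier <- function(results, reference = NULL) {
  tab <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r)
      data.frame(strategy = r$strategy, cost = r$total_cost, qaly = r$total_qaly,
                 stringsAsFactors = FALSE)))
  if (nrow(tab) < 2) stop("need at least two strategies", call. = FALSE)
  if (anyDuplicated(tab$strategy)) stop("duplicate strategy names", call. = FALSE)
  tab <- tab[order(tab$cost, tab$qaly), ]
  rownames(tab) <- NULL
  n <- nrow(tab)
  # strict dominance: some other strategy costs no more and yields more QALYs
  tab$dominated <- vapply(seq_len(n), function(i)
    any(tab$cost <= tab$cost[i] & tab$qaly > tab$qaly[i] &
          seq_len(n) != i), logical(1))
  # extended dominance: iterative frontier scan requiring non-decreasing ICERs
  tab$ext_dominated <- FALSE
  repeat {
    idx <- which(!tab$dominated & !tab$ext_dominated)
    if (length(idx) < 3) break
    icers <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
    drop <- which(diff(icers) < 0)
    if (length(drop) == 0) break
    tab$ext_dominated[idx[drop[1] + 1]] <- TRUE
  }
  tab$icer_frontier <- NA_real_
  idx <- which(!tab$dominated & !tab$ext_dominated)
  if (length(idx) > 1)
    tab$icer_frontier[idx[-1]] <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
  if (!is.null(reference)) {
    if (!reference %in% tab$strategy)
      stop(sprintf("reference strategy '%s' not among results", reference),
           call. = FALSE)
    rr <- tab[tab$strategy == reference, ]
    tab[[paste0("icer_vs_", reference)]] <- ifelse(
      tab$qaly == rr$qaly, NA_real_,
      (tab$cost - rr$cost) / (tab$qaly - rr$qaly))
  }
  tab
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the acceptance probability of a
#' strategy is the fraction of PSA draws in which it attains the maximum net
#' monetary benefit; ties are broken toward the cheaper strategy so the curve
#' is deterministic.
#'
#' @param draws a `data.frame` with columns `draw`, `strategy`, `cost`,
#'   `qaly` (one row per strategy per draw).
#' @param wtp_grid numeric vector of willingness-to-pay values.
#' @return an object of class `"ceac_curve"`: a `data.frame` with columns
#'   `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (is.null(draws) || nrow(draws) == 0) stop("no PSA draws supplied", call. = FALSE)
  strat <- sort(unique(draws$strategy))
  counts <- stats::xtabs(~ draw + strategy, data = draws)
  if (any(counts != 1)) stop("every draw must cover every strategy exactly once",
                             call. = FALSE)
  to_mat <- function(f) {
    m <- stats::xtabs(f, data = draws)
    matrix(m, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  wide_c <- to_mat(cost ~ draw + strategy)
  wide_q <- to_mat(qaly ~ draw + strategy)
  out <- lapply(wtp_grid, function(w) {
    benefit <- wide_q * w - wide_c
    win <- max.col(benefit, ties.method = "first")
    rmax <- benefit[cbind(seq_len(nrow(benefit)), win)]
    # exact NMB ties go to the cheaper strategy (deterministic)
    tie <- which(rowSums(benefit == rmax) > 1)
    for (i in tie) {
      top <- which(benefit[i, ] == rmax[i])
      win[i] <- top[which.min(wide_c[i, top])]
    }
    p <- tabulate(win, nbins = ncol(benefit)) / nrow(benefit)
    data.frame(wtp = w, strategy = colnames(benefit), probability = p,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("ceac_curve", "data.frame"))
}

#' Scenario grid over horizon and drug-price variants
#'
#' Runs the cohort model for each requested combination of time horizon and
#' strategy set and lays the results out like a fixed-reference
#' cost-effectiveness table: cost, QALY, ICER versus no prophylaxis and ICER
#' versus a named reference.
#'
#' @param pset a `"parameter_set"`.
#' @param horizons integer vector of horizons in months (default
#'   `c(36, 60, 120)`).
#' @param price_variant `"pooled"` compares placebo/DOACs/LMWHs plus the
#'   individual DOACs; `"original_generic"` compares placebo with
#'   original- and generic-price DOACs and LMWHs.
#' @param reference strategy for the second pairwise-ICER column (default:
#'   `"lmwh"` for the pooled set, `"doac_generic"` for the price-variant
#'   set).
#' @param discount annual discount rate.
#' @param states state space (shared across runs).
#' @return a `data.frame` with one row per (horizon, strategy).
#' @export
run_scenarios <- function(pset, horizons = c(36, 60, 120),
                          price_variant = c("pooled", "original_generic"),
                          reference = NULL, discount = 0.05,
                          states = expand_states()) {
  price_variant <- match.arg(price_variant)
  strat <- switch(price_variant,
                  pooled = c("placebo", "doac", "lmwh", "apixaban", "rivaroxaban"),
                  original_generic = c("placebo", "doac_original", "doac_generic",
                                       "lmwh_original", "lmwh_generic"))
  if (is.null(reference))
    reference <- if (price_variant == "pooled") "lmwh" else "doac_generic"
  missing <- setdiff(strat, strategies(pset))
  if (length(missing) > 0)
    stop("parameter set lacks strategies: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(horizons < 1)) stop("horizons must be positive", call. = FALSE)
  models <- lapply(strat, function(s) transition_model(pset, s, states))
  names(models) <- strat
  out <- lapply(horizons, function(h) {
    res <- lapply(models, run_cohort, horizon_months = h, discount = discount)
    tab <- data.frame(horizon_months = h, strategy = strat,
                      cost = vapply(res, `[[`, numeric(1), "total_cost"),
                      qaly = vapply(res, `[[`, numeric(1), "total_qaly"),
                      stringsAsFactors = FALSE)
    base <- tab[tab$strategy == "placebo", ]
    rr <- tab[tab$strategy == reference, ]
    tab$icer_vs_placebo <- ifelse(tab$qaly == base$qaly, NA_real_,
                                  (tab$cost - base$cost) / (tab$qaly - base$qaly))
    tab[[paste0("icer_vs_", reference)]] <-
      ifelse(tab$qaly == rr$qaly, NA_real_,
             (tab$cost - rr$cost) / (tab$qaly - rr$qaly))
    tab[order(tab$cost), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
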