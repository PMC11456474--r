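#' Beta distribution from a mean and standard deviation
#'
#' Method of moments: `k = mean (1 - mean) / sd^2 - 1`, `alpha = mean k`,
#' `beta = (1 - mean) k`.
#'
#' @param mean mean in `(0, 1)`.
#' @param sd positive standard deviation with `sd^2 < mean (1 - mean)`.
#' @return named vector `c(alpha, beta)`.
#' @export
beta_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)", call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop(sprintf("sd^2 = %.4g >= mean(1-mean) = %.4g: no beta distribution exists",
                 sd^2, mean * (1 - mean)), call. = FALSE)
  k <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Log-normal cost distribution from a median and log-scale SD
#'
#' Cost inputs are parameterised with the reported point value as the
#' distribution median and the reported "SD" as the log-scale standard
#' deviation; the implied 95% interval is `median * exp(+/- 1.96 sigma)`,
#' which reproduces the asymmetric bounds of the source table.
#'
#' @param median positive median cost.
#' @param sigma positive log-scale standard deviation.
#' @return list with `meanlog`, `sdlog`, `ci_low`, `ci_high`.
#' @export
lognormal_from_log_scale <- function(median, sigma) {
  if (median <= 0 || sigma <= 0) stop("median and sigma must be positive",
                                      call. = FALSE)
  list(meanlog = log(median), sdlog = sigma,
       ci_low = median * exp(-1.96 * sigma), ci_high = median * exp(1.96 * sigma))
}

# Draw one value from a parameter's PSA distribution using the current RNG
# stream; `scale` multiplies the dispersion (scale = 0 returns the mean).
sample_parameter <- function(p, scale = 1) {
  if (p$dist == "fixed" || is.na(p$sd) || p$sd == 0 || scale == 0) return(p$mean)
  if (p$dist == "beta") {
    if (p$mean <= 0 || p$mean >= 1) return(p$mean)  # degenerate endpoint
    sh <- beta_from_moments(p$mean, p$sd * scale)
    stats::rbeta(1, sh[["alpha"]], sh[["beta"]])
  } else {
    spec <- lognormal_from_log_scale(p$mean, p$sd * scale)
    stats::rlnorm(1, spec$meanlog, spec$sdlog * 1)
  }
}

# scale multiplies the sampling SD; used by perturb_parameters.
sample_parameter_set <- function(pset, scale = 1) {
  for (nm in names(pset$entries))
    pset$entries[[nm]]$mean <- sample_parameter(pset$entries[[nm]], scale)
  for (s in names(pset$overrides))
    for (nm in names(pset$overrides[[s]]))
      pset$overrides[[s]][[nm]]$mean <-
        sample_parameter(pset$overrides[[s]][[nm]], scale)
  pset
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Re-runs the deterministic pipeline with the parameter at the low and high
#' end of its [dsa_range()], all else at base, and records both ICERs of the
#' comparison.
#'
#' @param pset base `"parameter_set"`.
#' @param param parameter name.
#' @param strategy strategy the parameter belongs to (`NULL` for shared).
#' @param comparison character vector `c(reference, comparator)`.
#' @param horizon_months,discount,states cohort-run settings.
#' @return a one-row `data.frame`: `parameter`, `strategy`, `low`, `high`,
#'   `low_icer`, `high_icer`, `swing`.
#' @export
one_way_dsa <- function(pset, param, strategy = NULL,
                        comparison = c("placebo", "doac"),
                        horizon_months = 60, discount = 0.05,
                        states = expand_states()) {
  rng <- dsa_range(resolve_parameter(pset, param, strategy))
  icer_at <- function(value) {
    ps <- set_param_value(pset, param, value, strategy)
    res <- lapply(comparison, function(s)
      run_cohort(transition_model(ps, s, states), horizon_months = horizon_months,
                 discount = discount))
    compute_icer(res[[1]], res[[2]])$icer
  }
  lo <- icer_at(rng[["low"]]); hi <- icer_at(rng[["high"]])
  data.frame(parameter = param,
             strategy = if (is.null(strategy)) "shared" else strategy,
             low = rng[["low"]], high = rng[["high"]],
             low_icer = lo, high_icer = hi,
             swing = abs(hi - lo), stringsAsFactors = FALSE)
}

#' Tornado table for a strategy comparison
#'
#' Runs [one_way_dsa()] for every uncertain parameter touching the comparison
#' and sorts the entries by decreasing swing (the tornado ordering).
#'
#' @inheritParams one_way_dsa
#' @param params optional `data.frame` with columns `parameter`, `strategy`
#'   selecting which inputs to vary; by default every non-fixed parameter
#'   shared or belonging to a compared strategy.
#' @return a `data.frame` of tornado entries sorted by swing.
#' @export
tornado <- function(pset, comparison = c("placebo", "doac"),
                    params = NULL, horizon_months = 60, discount = 0.05,
                    states = expand_states()) {
  if (is.null(params)) {
    tab <- as.data.frame(pset)
    tab <- tab[tab$dist != "fixed" & !is.na(tab$sd) & tab$sd > 0 &
                 tab$strategy %in% c("shared", comparison), c("strategy", "name")]
    params <- data.frame(parameter = tab$name, strategy = tab$strategy,
                         stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(params)), function(i) {
    s <- params$strategy[i]
    one_way_dsa(pset, params$parameter[i],
                strategy = if (identical(s, "shared")) NULL else s,
                comparison = comparison, horizon_months = horizon_months,
                discount = discount, states = states)
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), ]
}

#' Threshold search: parameter value at which the ICER meets the WTP
#'
#' Bisection on `g(theta) = delta_cost(theta) - wtp * delta_qaly(theta)`
#' (zero exactly when the comparison's ICER equals the willingness-to-pay)
#' until `|ICER - wtp| < tol` or the bracket is narrower than `1e-6`.  The
#' bracket must produce a sign change, else an error reports the end values.
#'
#' @param pset base `"parameter_set"`.
#' @param setter either a parameter name (with `strategy`) or a function
#'   `(pset, theta) -> pset` applying the candidate value; a function allows
#'   searching on transformed scales such as a relative risk multiplying the
#'   no-prophylaxis rate.
#' @param bracket numeric `c(lower, upper)` search interval for `theta`.
#' @param wtp willingness-to-pay per QALY.
#' @param comparison `c(reference, comparator)`.
#' @param strategy strategy owning the parameter when `setter` is a name.
#' @param horizon_months,discount,states cohort-run settings.
#' @param tol tolerance on `|ICER - wtp|` (default $0.01).
#' @return list with `theta` (the threshold), `icer` at the threshold, and
#'   `iterations`.
#' @export
threshold_search <- function(pset, setter, bracket, wtp,
                             comparison = c("doac", "lmwh"), strategy = NULL,
                             horizon_months = 60, discount = 0.05,
                             states = expand_states(), tol = 0.01) {
  set_fun <- if (is.function(setter)) setter else
    function(ps, theta) set_param_value(ps, setter, theta, strategy)
  eval_at <- function(theta) {
    ps <- set_fun(pset, theta)
    res <- lapply(comparison, function(s)
      run_cohort(transition_model(ps, s, states), horizon_months = horizon_months,
                 discount = discount))
    cmp <- compute_icer(res[[1]], res[[2]])
    list(g = cmp$delta_cost - wtp * cmp$delta_qaly, icer = cmp$icer)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- eval_at(lo); f_hi <- eval_at(hi)
  if (sign(f_lo$g) == sign(f_hi$g))
    stop(sprintf(paste0("no sign change over bracket [%g, %g]: ",
                        "g(lower) = %.4f, g(upper) = %.4f"),
                 lo, hi, f_lo$g, f_hi$g), call. = FALSE)
  it <- 0
  repeat {
    it <- it + 1
    mid <- (lo + hi) / 2
    f_mid <- eval_at(mid)
    done <- (!is.na(f_mid$icer) && abs(f_mid$icer - wtp) < tol) ||
      (hi - lo) / 2 < 1e-6 || it >= 200
    if (done) return(list(theta = mid, icer = f_mid$icer, iterations = it))
    if (sign(f_mid$g) == sign(f_lo$g)) { lo <- mid; f_lo <- f_mid }
    else hi <- mid
  }
}

#' Paper-style decision thresholds for DOACs versus LMWHs
#'
#' Reports the relative-risk and drug-cost values at which the preference
#' between DOAC and LMWH prophylaxis switches at the given willingness to
#' pay.  The VTE and bleeding thresholds are on the relative-risk scale
#' (the DOAC probability is the no-prophylaxis probability times the RR);
#' the cost threshold is the one-cycle DOAC prophylaxis price in dollars.
#'
#' @param pset a `"parameter_set"` containing `doac`, `lmwh` and `placebo`.
#' @param wtp willingness-to-pay per QALY (default: the set's `wtp` entry).
#' @param horizon_months,discount,states cohort-run settings.
#' @return a `data.frame` with columns `quantity`, `scale`, `base`,
#'   `threshold`.
#' @export
doac_thresholds <- function(pset, wtp = param_value(pset, "wtp"),
                            horizon_months = 60, discount = 0.05,
                            states = expand_states()) {
  base_vte <- param_value(pset, "p_first_vte", "doac")
  base_bleed <- param_value(pset, "p_bleed", "doac")
  base_cost <- param_value(pset, "c_prophylaxis_cycle", "doac")
  p0_vte <- param_value(pset, "p_first_vte", "placebo")
  p0_bleed <- param_value(pset, "p_bleed", "placebo")
  search <- function(setter, bracket) {
    tryCatch(threshold_search(pset, setter, bracket, wtp,
                              comparison = c("doac", "lmwh"),
                              horizon_months = horizon_months,
                              discount = discount, states = states)$theta,
             error = function(e) NA_real_)
  }
  # cap the annual probability strictly below 1 so the monthly conversion
  # stays a proper branch mass
  rr_vte <- search(function(ps, th)
    set_param_value(ps, "p_first_vte", min(0.999, p0_vte * th), "doac"),
    c(0.05, 0.999 / p0_vte))
  rr_bleed <- search(function(ps, th)
    set_param_value(ps, "p_bleed", min(0.999, p0_bleed * th), "doac"),
    c(0.05, 0.999 / p0_bleed))
  cost <- search(function(ps, th)
    set_param_value(ps, "c_prophylaxis_cycle", th, "doac"),
    c(0, 4 * param_value(pset, "c_prophylaxis_cycle", "lmwh")))
  data.frame(
    quantity = c("vte_risk", "bleeding_risk", "doac_cost"),
    scale = c("relative risk vs no prophylaxis",
              "relative risk vs no prophylaxis",
              "USD per prophylaxis cycle"),
    base = c(base_vte / p0_vte, base_bleed / p0_bleed, base_cost),
    threshold = c(rr_vte, rr_bleed, cost),
    stringsAsFactors = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Samples `n` independent parameter sets (beta for probabilities,
#' proportions, utilities and disutilities; log-normal for costs; fixed
#' entries untouched), evaluates the deterministic cohort pipeline for every
#' strategy under each sampled set, and returns draw-level results plus
#' summary means.  Sampled branch probabilities feeding one chance node are
#' clamped so branch masses never exceed 1; a draw requiring clamping is
#' counted.  A seed is mandatory: PSA runs must be reproducible.
#'
#' @param pset base `"parameter_set"`.
#' @param n number of Monte Carlo draws.
#' @param seed integer RNG seed (required).
#' @param strategies character vector of strategies to evaluate per draw.
#' @param horizon_months,discount,states cohort-run settings.
#' @return an object of class `"psa_result"`: `draws` (`data.frame` with
#'   `draw`, `strategy`, `cost`, `qaly`), `summary` (mean cost/QALY per
#'   strategy), `n`, `seed`, `n_clamped`.
#' @export
run_psa <- function(pset, n, seed, strategies = c("placebo", "doac", "lmwh"),
                    horizon_months = 60, discount = 0.05,
                    states = expand_states()) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("run_psa requires an explicit integer seed", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  n_clamped <- 0L
  rows <- vector("list", n)
  for (d in seq_len(n)) {
    ps <- sample_parameter_set(pset)
    res <- lapply(strategies, function(s) {
      si <- strategy_inputs(ps, s)
      # clamp competing branch masses at the chance nodes
      tot <- si$m_vte + si$m_bleed + si$m_death_bg
      if (tot > 1) {
        si$m_vte <- si$m_vte / tot; si$m_bleed <- si$m_bleed / tot
        si$m_death_bg <- si$m_death_bg / tot
        n_clamped <<- n_clamped + 1L
      }
      P <- build_transition_matrix(si, states)
      model <- structure(list(states = states, strategy = s, inputs = si,
                              P = P, event_probs = attr(P, "event_probs"),
                              matrix_at = function(cycle) P),
                         class = "transition_model")
      run_cohort(model, horizon_months = horizon_months, discount = discount)
    })
    rows[[d]] <- data.frame(
      draw = d, strategy = strategies,
      cost = vapply(res, `[[`, numeric(1), "total_cost"),
      qaly = vapply(res, `[[`, numeric(1), "total_qaly"),
      stringsAsFactors = FALSE)
  }
  draws <- do.call(rbind, rows)
  rownames(draws) <- NULL
  summ <- do.call(rbind, lapply(split(draws, draws$strategy), function(g)
    data.frame(strategy = g$strategy[1], mean_cost = mean(g$cost),
               mean_qaly = mean(g$qaly), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ, n = n, seed = seed,
                 strategies = strategies, horizon_months = horizon_months,
                 n_clamped = n_clamped),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result>: %d draws (seed %s), %d clamped; mean outcomes:\n",
              x$n, format(x$seed), x$n_clamped))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
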