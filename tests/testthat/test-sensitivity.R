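test_that("beta method-of-moments fit and resampling round trip", {
  sh <- beta_from_moments(0.65, 0.014)
  k <- 0.65 * 0.35 / 0.014^2 - 1
  expect_equal(unname(sh), c(0.65 * k, 0.35 * k))
  expect_equal(sh[["alpha"]], 753.8, tolerance = 1e-3)
  expect_equal(sh[["beta"]], 405.9, tolerance = 1e-3)
  # symmetry at mean 1/2
  sym <- beta_from_moments(0.5, 0.1)
  expect_equal(sym[["alpha"]], sym[["beta"]])
  # moments recovered by Monte Carlo within 0.5%
  set.seed(11)
  x <- rbeta(1e6, sh[["alpha"]], sh[["beta"]])
  expect_lt(abs(mean(x) - 0.65), 0.005 * 0.65)
  expect_lt(abs(sd(x) - 0.014), 0.005 * 0.014)
  expect_error(beta_from_moments(0.5, 0.6), "no beta distribution")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("log-normal cost parameterisation reproduces the printed asymmetric bounds", {
  spec <- lognormal_from_log_scale(160.372, 0.258)
  expect_equal(spec$meanlog, log(160.372))
  expect_equal(spec$ci_low, 160.372 * exp(-1.96 * 0.258))
  expect_equal(spec$ci_high, 160.372 * exp(1.96 * 0.258))
  # consistent with the source's printed interval (100.144, 275.423) to
  # within rounding of the printed bounds
  expect_equal(spec$ci_low, 100.144, tolerance = 0.04)
  expect_equal(spec$ci_high, 275.423, tolerance = 0.04)
  expect_error(lognormal_from_log_scale(-1, 0.1), "positive")
  # sigma -> 0 degenerates at the median
  tiny <- lognormal_from_log_scale(100, 1e-12)
  expect_equal(tiny$ci_low, 100, tolerance = 1e-6)
  set.seed(3)
  expect_true(all(rlnorm(1e4, spec$meanlog, spec$sdlog) > 0))
})

test_that("PSA parameter sampling is seeded, mean-preserving and respects scale 0", {
  ps <- base_pset()
  same1 <- perturb_parameters(ps, 1, seed = 99)
  same2 <- perturb_parameters(ps, 1, seed = 99)
  expect_identical(same1, same2)
  expect_identical(perturb_parameters(ps, 0, seed = 1)$entries, ps$entries)
  # law of large numbers: sample means of key parameters near the base mean
  for (nm in c("p_death_cancer", "u_no_complication", "c_event_pe")) {
    p <- resolve_parameter(ps, nm)
    set.seed(123)
    draws <- replicate(10000, ceavte:::sample_parameter(p))
    centre <- if (p$dist == "lognormal") exp(log(p$mean) + p$sd^2 / 2) else p$mean
    expect_lt(abs(mean(draws) - centre), 3 * sd(draws) / sqrt(length(draws)) + 1e-9)
  }
})

test_that("PSA runs are reproducible and degenerate draws equal the base case", {
  ps <- base_pset()
  a <- run_psa(ps, n = 5, seed = 7, horizon_months = 24)
  b <- run_psa(ps, n = 5, seed = 7, horizon_months = 24)
  expect_identical(a$draws, b$draws)
  expect_error(run_psa(ps, n = 5, seed = NULL), "seed")
  # with all uncertainty removed the single draw is the deterministic run
  frozen <- ps
  frozen$entries <- lapply(frozen$entries, function(p) { p$sd <- 0; p })
  frozen$overrides <- lapply(frozen$overrides, function(ov)
    lapply(ov, function(p) { p$sd <- 0; p }))
  one <- run_psa(frozen, n = 1, seed = 1, horizon_months = 24)
  det <- run_cohort(transition_model(ps, "doac"), horizon_months = 24)
  expect_equal(one$draws$cost[one$draws$strategy == "doac"], det$total_cost,
               tolerance = 1e-10)
  expect_equal(one$draws$qaly[one$draws$strategy == "doac"], det$total_qaly,
               tolerance = 1e-10)
})

test_that("one-way DSA: untouched parameters swing nothing; swings match a re-run", {
  ps <- base_pset()
  st <- expand_states()
  # a parameter of a strategy outside the comparison cannot move the ICER
  ent <- one_way_dsa(ps, "c_prophylaxis_cycle", strategy = "lmwh",
                     comparison = c("placebo", "doac"), horizon_months = 24,
                     states = st)
  expect_equal(ent$swing, 0)
  # swing equals the two-point re-run by construction
  ent2 <- one_way_dsa(ps, "p_first_vte", strategy = "doac",
                      comparison = c("placebo", "doac"), horizon_months = 24,
                      states = st)
  icer_at <- function(v) {
    p2 <- set_param_value(ps, "p_first_vte", v, "doac")
    r <- lapply(c("placebo", "doac"), function(s)
      run_cohort(transition_model(p2, s, st), horizon_months = 24))
    compute_icer(r[[1]], r[[2]])$icer
  }
  expect_equal(ent2$swing, abs(icer_at(0.178) - icer_at(0.062)), tolerance = 1e-9)
  expect_gt(ent2$swing, 0)
})

test_that("tornado ordering is by swing and invariant to parameter order", {
  ps <- base_pset()
  st <- expand_states()
  sel <- data.frame(parameter = c("p_first_vte", "c_prophylaxis_cycle",
                                  "p_death_cancer"),
                    strategy = c("doac", "doac", "shared"))
  t1 <- tornado(ps, c("placebo", "doac"), params = sel, horizon_months = 24,
                states = st)
  t2 <- tornado(ps, c("placebo", "doac"), params = sel[c(3, 1, 2), ],
                horizon_months = 24, states = st)
  expect_true(all(diff(t1$swing) <= 0))
  expect_equal(t1$parameter, t2$parameter)
  expect_equal(t1$swing, t2$swing, tolerance = 1e-9)
})

test_that("threshold search solves a monotone toy crossing to tolerance", {
  ps <- base_pset()
  st <- expand_states()
  wtp <- 37125.240
  # vary the DOAC prophylaxis price: delta-cost is linear in it, so the
  # crossing is effectively analytic; the bisection must land on ICER = WTP
  sol <- threshold_search(ps, "c_prophylaxis_cycle",
                          bracket = c(0, 2000), wtp = wtp,
                          comparison = c("placebo", "doac"), strategy = "doac",
                          horizon_months = 24, states = st)
  expect_lt(abs(sol$icer - wtp), 0.01)
  # analytic cross-check: cost(theta) = a + b*theta with b the discounted
  # months of prophylaxis exposure; solve for ICER == wtp directly
  run_at <- function(v) {
    p2 <- set_param_value(ps, "c_prophylaxis_cycle", v, "doac")
    run_cohort(transition_model(p2, "doac", st), horizon_months = 24)$total_cost
  }
  pla <- run_cohort(transition_model(ps, "placebo", st), horizon_months = 24)
  doa <- run_cohort(transition_model(ps, "doac", st), horizon_months = 24)
  a <- run_at(0); b <- (run_at(100) - a) / 100
  theta_star <- (pla$total_cost + wtp * (doa$total_qaly - pla$total_qaly) - a) / b
  expect_equal(sol$theta, theta_star, tolerance = 1e-4 * theta_star)
  # a bracket with no crossing reports the end values
  expect_error(threshold_search(ps, "c_prophylaxis_cycle",
                                bracket = c(5000, 6000), wtp = wtp,
                                comparison = c("placebo", "doac"),
                                strategy = "doac", horizon_months = 24,
                                states = st),
               "no sign change")
})
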