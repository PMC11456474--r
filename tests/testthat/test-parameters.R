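test_that("packaged base set reproduces the published input table cell by cell", {
  ps <- base_pset()
  # strategy-level probabilities/proportions: mean, low, high, sd
  strat_rows <- list(
    list("p_first_vte", "doac",        c(0.105, 0.062, 0.178, 0.030)),
    list("p_first_vte", "lmwh",        c(0.113, 0.067, 0.191, 0.032)),
    list("p_first_vte", "placebo",     c(0.194, 0.115, 0.329, 0.055)),
    list("p_first_vte", "apixaban",    c(0.072, 0.043, 0.122, 0.020)),
    list("p_first_vte", "rivaroxaban", c(0.132, 0.078, 0.224, 0.037)),
    list("p_bleed", "doac",            c(0.144, 0.072, 0.285, 0.055)),
    list("p_bleed", "lmwh",            c(0.154, 0.077, 0.306, 0.058)),
    list("p_bleed", "placebo",         c(0.092, 0.046, 0.183, 0.035)),
    list("p_bleed", "apixaban",        c(0.143, 0.071, 0.284, 0.054)),
    list("p_bleed", "rivaroxaban",     c(0.145, 0.073, 0.289, 0.055)),
    list("pe_share_first_vte", "doac",        c(0.370, 0.333, 0.407, 0.019)),
    list("pe_share_first_vte", "lmwh",        c(0.441, 0.397, 0.485, 0.023)),
    list("pe_share_first_vte", "placebo",     c(0.456, 0.410, 0.501, 0.023)),
    list("pe_share_first_vte", "apixaban",    c(0.417, 0.375, 0.458, 0.021)),
    list("pe_share_first_vte", "rivaroxaban", c(0.333, 0.300, 0.367, 0.017)),
    list("mb_share_bleeding", "doac",         c(0.357, 0.321, 0.393, 0.018)),
    list("mb_share_bleeding", "lmwh",         c(0.236, 0.212, 0.259, 0.012)),
    list("mb_share_bleeding", "placebo",      c(0.285, 0.256, 0.313, 0.015)),
    list("mb_share_bleeding", "apixaban",     c(0.324, 0.292, 0.357, 0.017)),
    list("mb_share_bleeding", "rivaroxaban",  c(0.421, 0.379, 0.463, 0.022)),
    list("ich_share_mb", "doac",    c(0.125, 0.113, 0.138, 0.006)),
    list("ich_share_mb", "lmwh",    c(0.229, 0.206, 0.252, 0.012)),
    list("ich_share_mb", "placebo", c(0.231, 0.208, 0.254, 0.012)),
    list("c_prophylaxis_cycle", "doac",          c(160.372, 100.144, 275.423, 0.258)),
    list("c_prophylaxis_cycle", "lmwh",          c(348.113, 264.463, 440.683, 0.130)),
    list("c_prophylaxis_cycle", "apixaban",      c(222.621, 144.082, 364.422, 0.237)),
    list("c_prophylaxis_cycle", "rivaroxaban",   c(98.122, 56.205, 186.424, 0.306)),
    list("c_prophylaxis_cycle", "doac_original", c(263.927, 179.172, 384.985, 0.195)),
    list("c_prophylaxis_cycle", "doac_generic",  c(91.697, 46.067, 133.967, 0.272)),
    list("c_prophylaxis_cycle", "lmwh_original", c(350.800, 277.870, 440.683, 0.118)),
    list("c_prophylaxis_cycle", "lmwh_generic",  c(327.801, 219.037, 434.677, 0.175)),
    list("c_treatment_3mo", "doac",          c(1048.517, 654.152, 1802.819, 0.259)),
    list("c_treatment_3mo", "lmwh",          c(1547.152, 1130.174, 2131.714, 0.162)),
    list("c_treatment_3mo", "apixaban",      c(1439.619, 931.732, 2356.597, 0.237)),
    list("c_treatment_3mo", "rivaroxaban",   c(657.415, 376.572, 1249.041, 0.036)),
    list("c_treatment_3mo", "doac_original", c(1730.316, 1165.273, 2537.349, 0.199)),
    list("c_treatment_3mo", "doac_generic",  c(599.515, 300.389, 877.713, 0.274)),
    list("c_treatment_3mo", "lmwh_original", c(1590.548, 1114.712, 2131.714, 0.165)),
    list("c_treatment_3mo", "lmwh_generic",  c(1447.068, 900.384, 1996.903, 0.203)))
  for (row in strat_rows) {
    p <- resolve_parameter(ps, row[[1]], row[[2]])
    expect_equal(c(p$mean, p$low, p$high, p$sd), row[[3]],
                 info = paste(row[[1]], row[[2]]))
  }
  shared_rows <- list(
    ich_stop_share = c(0.657, 0.591, 0.722, 0.034),
    p_death_cancer = c(0.153, 0.132, 0.176, 0.011),
    p_recur_dvt = c(0.027, 0.024, 0.030, 0.002),
    p_bleed_dvt = c(0.054, 0.048, 0.060, 0.003),
    p_death_dvt = c(0.316, 0.278, 0.357, 0.020),
    p_recur_pe = c(0.057, 0.052, 0.063, 0.003),
    p_bleed_pe = c(0.069, 0.062, 0.076, 0.004),
    p_death_pe = c(0.402, 0.362, 0.443, 0.021),
    p_recur_ich = c(0.035, 0.032, 0.039, 0.002),
    p_bleed_ich_on = c(0.079, 0.071, 0.087, 0.004),
    p_bleed_ich_off = c(0.086, 0.077, 0.0946, 0.004),
    p_death_ich_on = c(0.097, 0.069, 0.137, 0.017),
    p_death_ich_off = c(0.191, 0.016, 0.226, 0.054),
    p_death_pts = c(0.033, 0.030, 0.037, 0.002),
    p_pts_year1 = c(0.180, 0.109, 0.251, 0.036),
    p_pts_year2 = c(0.079, 0.048, 0.110, 0.016),
    p_pts_year3plus = c(0.023, 0.014, 0.032, 0.005),
    p_cteph_year1 = c(0.031, 0.019, 0.043, 0.006),
    p_cteph_year2 = c(0.007, 0.004, 0.010, 0.002),
    p_death_cteph_days1_90 = c(0.327, 0.202, 0.499, 0.076),
    p_death_cteph_days91_365 = c(0.175, 0.114, 0.256, 0.036),
    p_death_cteph_year2 = c(0.110, 0.060, 0.184, 0.032),
    p_death_cteph_year3plus = c(0.081, 0.048, 0.129, 0.021),
    u_ich = c(0.330, 0.260, 0.400, 0.036),
    u_no_complication = c(0.650, 0.616, 0.672, 0.014),
    u_dvt = c(0.610, 0.514, 0.678, 0.042),
    u_pe = c(0.620, 0.477, 0.725, 0.063),
    u_pts = c(0.500, 0.320, 0.650, 0.084),
    u_cteph = c(0.630, 0.520, 0.730, 0.054),
    du_dvt = c(0.190, 0.060, 0.450, 0.010),
    du_pe = c(0.250, 0.090, 0.550, 0.117),
    du_mb = c(0.270, 0.246, 0.294, 0.012),
    du_crnmb = c(0.013, 0.010, 0.016, 0.002),
    du_ich = c(0.470, 0.340, 0.600, 0.066),
    du_pts = c(0.050, 0.028, 0.072, 0.011),
    du_cteph = c(0.360, 0.344, 0.376, 0.008),
    c_event_dvt = c(693.000, 329.000, 941.000, 0.268),
    c_event_pe = c(1121.000, 448.000, 1793.000, 0.354),
    c_event_ich = c(4378.347, 2677.667, 6066.547, 0.209),
    c_event_gib = c(1876.013, 978.700, 3209.564, 0.303),
    c_event_crnmb = c(8.250, 5.770, 10.720, 0.158),
    c_post_ich_year = c(2527.000, 2269.143, 2784.857, 0.052),
    c_pts_year = c(1872.904, 1498.323, 2247.490, 0.103),
    c_cteph_year = c(10747.988, 8598.390, 12897.586, 0.103))
  for (nm in names(shared_rows)) {
    p <- resolve_parameter(ps, nm)
    expect_equal(c(p$mean, p$low, p$high, p$sd), unname(shared_rows[[nm]]),
                 info = nm)
  }
  expect_equal(param_value(ps, "u_death"), 0)
  expect_equal(param_value(ps, "wtp"), 37125.240)
  expect_equal(param_value(ps, "discount_rate_annual"), 0.05)
  expect_equal(param_value(ps, "self_pay_ratio"), 1.0)
  # every entry passes the parameter invariants by construction of the loader
  expect_s3_class(ps, "parameter_set")
})

test_that("parameter validation rejects out-of-domain values and bad schemas", {
  expect_error(parameter("u_bad", "utility", 1.2, dist = "beta"),
               "outside \\[0, 1\\]")
  expect_error(parameter("p_bad", "probability", 0.5, low = 0.6, high = 0.9,
                         dist = "beta"), "low <= mean <= high")
  expect_error(parameter("c_bad", "cost", 100, dist = "beta"),
               "beta distribution on group")
  expect_error(parameter("u_odd", "utility", 0.5, dist = "lognormal"),
               "lognormal distribution on group")
  # fixed entries may omit sd (treated as no uncertainty)
  p <- parameter("wtp", "fixed", 37125.240, dist = "fixed")
  expect_true(is.na(p$sd) || p$sd == 0)
  # loader: schema errors name the entry
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("shared:", "  broken: {mean: 0.5}"), tmp)
  expect_error(load_parameters(tmp), "broken")
})

test_that("strategy resolution falls back through parent to shared entries", {
  ps <- base_pset()
  # apixaban has no ICH share of its own: falls back to the pooled DOAC value
  expect_equal(param_value(ps, "ich_share_mb", "apixaban"), 0.125)
  expect_equal(param_value(ps, "ich_share_mb", "rivaroxaban"), 0.125)
  # price variants inherit clinical rates from their strategy
  expect_equal(param_value(ps, "p_first_vte", "doac_generic"), 0.105)
  expect_equal(param_value(ps, "p_first_vte", "lmwh_original"), 0.113)
  # shared entries resolve for any strategy
  expect_equal(param_value(ps, "p_death_cancer", "lmwh"), 0.153)
  expect_error(resolve_parameter(ps, "p_first_vte"), "not found")
  expect_error(resolve_parameter(ps, "p_first_vte", "warfarin"),
               "unknown strategy")
})

test_that("load -> serialize -> load round-trips to an identical set", {
  ps <- base_pset()
  tmp <- tempfile(fileext = ".yaml")
  write_parameters(ps, tmp)
  ps2 <- load_parameters(tmp)
  expect_equal(ps2$entries, ps$entries)
  expect_equal(ps2$overrides, ps$overrides)
  expect_equal(ps2$parents, ps$parents)
})

test_that("DSA ranges use given bounds, else the cost/probability default rules", {
  ps <- base_pset()
  expect_equal(unname(dsa_range(resolve_parameter(ps, "p_first_vte", "placebo"))),
               c(0.115, 0.329))
  expect_equal(unname(dsa_range(parameter("c", "cost", 100, dist = "fixed"))),
               c(80, 120))
  # +/-10% then clamp to [0, 1]
  expect_equal(unname(dsa_range(parameter("p", "probability", 0.95, dist = "fixed"))),
               c(0.855, 1.0))
  expect_error(dsa_range(parameter("u", "utility", 0.6, dist = "fixed")),
               "no default DSA rule")
})
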