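#' The packaged base-case parameter set
#'
#' Loads and validates the parameter table shipped with the package
#' (`inst/extdata/parameters.yaml`): every transition probability,
#' proportion, utility, disutility and cost of the base analysis, with the
#' per-strategy override blocks for the pooled, individual-drug and
#' original/generic price variants.
#'
#' @return a validated `"parameter_set"`.
#' @export
base_case_parameters <- function() {
  load_parameters(system.file("extdata", "parameters.yaml", package = "ceavte",
                              mustWork = TRUE))
}

#' Generate synthetic trial arms for the pooling stage
#'
#' Emulates the evidence base behind the no-prophylaxis event rates: per
#' study, a logit-normal random effect with variance `tau2` shifts the
#' baseline rate; control events are binomial at the shifted rate and
#' treated events binomial at the shifted rate times the relative risk
#' (clamped at 1; clamped studies are counted in the `"n_clamped"`
#' attribute).
#'
#' @param true_baseline_rate control-arm event proportion in `(0, 1)`.
#' @param true_rr treated-vs-control relative risk, `> 0`.
#' @param k_studies number of studies.
#' @param arm_sizes per-arm sample size(s), each `>= 10` (recycled to
#'   `k_studies`).
#' @param tau2 between-study variance on the logit scale, `>= 0`.
#' @param seed integer RNG seed (required for reproducibility).
#' @return a `data.frame` with columns `study_id`, `arm`
#'   (`control`/`treated`), `events`, `total`.
#' @export
generate_trial_arms <- function(true_baseline_rate, true_rr, k_studies,
                                arm_sizes, tau2 = 0, seed) {
  if (missing(seed)) stop("generate_trial_arms requires a seed", call. = FALSE)
  stopifnot(true_baseline_rate > 0, true_baseline_rate < 1, true_rr > 0,
            k_studies >= 1, tau2 >= 0, all(arm_sizes >= 10))
  set.seed(as.integer(seed))
  n <- rep_len(as.integer(arm_sizes), k_studies)
  p_i <- stats::plogis(stats::qlogis(true_baseline_rate) +
                         stats::rnorm(k_studies, 0, sqrt(tau2)))
  p_t <- p_i * true_rr
  n_clamped <- sum(p_t > 1)
  p_t <- pmin(1, p_t)
  out <- data.frame(
    study_id = rep(sprintf("study_%02d", seq_len(k_studies)), each = 2),
    arm = rep(c("control", "treated"), k_studies),
    events = as.integer(rbind(stats::rbinom(k_studies, n, p_i),
                              stats::rbinom(k_studies, n, p_t))),
    total = rep(n, each = 2), stringsAsFactors = FALSE)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Perturb a parameter set by resampling from its PSA distributions
#'
#' A stress fixture for the invariant suites: each uncertain parameter is
#' redrawn from its probabilistic-sensitivity distribution with the
#' dispersion multiplied by `scale` (`scale = 0` returns the base set
#' unchanged, `scale = 1` is one legal PSA draw).
#'
#' @param base a `"parameter_set"`.
#' @param scale non-negative dispersion multiplier.
#' @param seed integer RNG seed (required).
#' @return a new validated `"parameter_set"`.
#' @export
perturb_parameters <- function(base, scale = 1, seed) {
  if (missing(seed)) stop("perturb_parameters requires a seed", call. = FALSE)
  if (scale < 0) stop("scale must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  sample_parameter_set(base, scale)
}
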