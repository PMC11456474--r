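#' Pool event proportions across trial arms by a random-effects model
#'
#' DerSimonian-Laird random-effects pooling on the logit scale, the
#' conventional choice for meta-analysis of proportions.  Arms with zero or
#' all events receive a 0.5 continuity correction (switchable).  The pooled
#' estimate and its 95% interval are back-transformed to the proportion
#' scale; the between-study variance `tau2` is reported on the logit scale.
#'
#' @param arms a `data.frame` with columns `study_id`, `events`, `total`
#'   (one row per arm), or a list of such records.
#' @param continuity continuity correction added to both cells of an arm with
#'   zero or all events (default 0.5; set 0 to disable).
#' @return an object of class `"pooled_rate"`: a list with `estimate`,
#'   `ci_low`, `ci_high`, `tau2`, `k`.
#' @export
pool_proportions <- function(arms, continuity = 0.5) {
  if (is.list(arms) && !is.data.frame(arms))
    arms <- do.call(rbind, lapply(arms, as.data.frame))
  if (is.null(arms) || nrow(arms) == 0) stop("no trial arms supplied", call. = FALSE)
  ev <- as.numeric(arms$events); n <- as.numeric(arms$total)
  if (any(is.na(ev)) || any(is.na(n))) stop("events/total must be numeric", call. = FALSE)
  if (any(n <= 0)) stop("arm total must be positive", call. = FALSE)
  if (any(ev < 0 | ev > n)) stop("events must lie in [0, total]", call. = FALSE)
  corner <- ev == 0 | ev == n
  ev[corner] <- ev[corner] + continuity
  n[corner] <- n[corner] + 2 * continuity
  yi <- log(ev / (n - ev))
  vi <- 1 / ev + 1 / (n - ev)
  if (length(yi) == 1L) {
    mu <- yi; se <- sqrt(vi); tau2 <- 0
  } else {
    fit <- metafor::rma.uni(yi = yi, vi = vi, method = "DL")
    mu <- as.numeric(fit$beta); se <- fit$se; tau2 <- fit$tau2
  }
  structure(list(estimate = stats::plogis(mu),
                 ci_low = stats::plogis(mu - 1.96 * se),
                 ci_high = stats::plogis(mu + 1.96 * se),
                 tau2 = tau2, k = length(yi)),
            class = "pooled_rate")
}

#' @export
print.pooled_rate <- function(x, ...) {
  cat(sprintf("pooled proportion %.4f (95%% CI %.4f-%.4f), tau2 = %.4g, k = %d\n",
              x$estimate, x$ci_low, x$ci_high, x$tau2, x$k))
  invisible(x)
}

#' Derive a comparative event rate from a baseline rate and a relative risk
#'
#' The comparative strategies' event rates are the no-prophylaxis rates
#' multiplied by the strategy's relative risk, truncated at 1.
#'
#' @param baseline baseline proportion in `[0, 1]`.
#' @param rr a positive relative risk, or a list with fields `rr`, `ci_low`,
#'   `ci_high`.
#' @return the derived proportion, `min(1, baseline * rr)`.
#' @export
apply_rr <- function(baseline, rr) {
  r <- if (is.list(rr)) rr$rr else rr
  if (!is.numeric(r) || is.na(r) || r < 0) stop("rr must be >= 0", call. = FALSE)
  if (baseline < 0 || baseline > 1) stop("baseline must lie in [0, 1]", call. = FALSE)
  min(1, baseline * r)
}

#' Pool a trial-arm table by strategy and outcome
#'
#' Convenience wrapper over [pool_proportions()] for a long arm-level CSV with
#' columns `study_id`, `strategy`, `outcome`, `events`, `total`.
#'
#' @param arms a `data.frame` in the long format above (e.g. from
#'   `utils::read.csv`).
#' @return a `data.frame` with one row per (strategy, outcome) and columns
#'   `estimate`, `ci_low`, `ci_high`, `tau2`, `k`.
#' @export
pool_table <- function(arms) {
  need <- c("study_id", "strategy", "outcome", "events", "total")
  if (!all(need %in% names(arms)))
    stop("arm table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  keys <- unique(arms[, c("strategy", "outcome")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- arms[arms$strategy == keys$strategy[i] & arms$outcome == keys$outcome[i], ]
    pr <- pool_proportions(sub)
    data.frame(strategy = keys$strategy[i], outcome = keys$outcome[i],
               estimate = pr$estimate, ci_low = pr$ci_low, ci_high = pr$ci_high,
               tau2 = pr$tau2, k = pr$k, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
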