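PARAM_GROUPS <- c("probability", "proportion", "utility", "disutility",
                  "cost", "rate_ratio", "fixed")
PARAM_DISTS  <- c("beta", "lognormal", "fixed")

#' Construct and validate a single model parameter
#'
#' A parameter is one row of the model's input table: a point estimate with
#' optional 95% bounds, an SD, a probabilistic-sensitivity distribution family
#' and the time window (in months) the value describes.
#'
#' @param name stable snake_case identifier.
#' @param group one of `"probability"`, `"proportion"`, `"utility"`,
#'   `"disutility"`, `"cost"`, `"rate_ratio"`, `"fixed"`.
#' @param mean point estimate.
#' @param low,high optional 95% bounds (`NA` when the source gives none).
#' @param sd standard deviation; on the natural scale for beta-distributed
#'   parameters, on the log scale for log-normal cost parameters. `NA` is
#'   treated as 0 for `dist = "fixed"`.
#' @param dist `"beta"`, `"lognormal"` or `"fixed"`.
#' @param period_months time window the value describes, in months;
#'   `NA` for one-time tolls and dimensionless splits.
#' @return an object of class `"ceavte_parameter"` (a named list).
#' @export
parameter <- function(name, group, mean, low = NA_real_, high = NA_real_,
                      sd = NA_real_, dist = "fixed", period_months = NA_real_) {
  p <- structure(
    list(name = as.character(name), group = group, mean = as.numeric(mean),
         low = as.numeric(low), high = as.numeric(high), sd = as.numeric(sd),
         dist = dist, period_months = as.numeric(period_months)),
    class = "ceavte_parameter")
  validate_parameter(p)
  p
}

#' @rdname parameter
#' @param p a `"ceavte_parameter"` object.
#' @export
validate_parameter <- function(p) {
  nm <- p$name
  if (!is.character(nm) || !nzchar(nm))
    stop("parameter must have a non-empty name", call. = FALSE)
  if (!p$group %in% PARAM_GROUPS)
    stop(sprintf("parameter '%s': unknown group '%s'", nm, p$group), call. = FALSE)
  if (!p$dist %in% PARAM_DISTS)
    stop(sprintf("parameter '%s': unknown dist '%s'", nm, p$dist), call. = FALSE)
  if (is.na(p$mean))
    stop(sprintf("parameter '%s': mean is required", nm), call. = FALSE)
  if (p$dist == "fixed" && is.na(p$sd)) p$sd <- 0
  if (!is.na(p$sd) && p$sd < 0)
    stop(sprintf("parameter '%s': sd must be >= 0", nm), call. = FALSE)
  unit <- p$group %in% c("probability", "proportion", "utility", "disutility")
  if (unit && (p$mean < 0 || p$mean > 1))
    stop(sprintf("parameter '%s': %s %.4g outside [0, 1]", nm, p$group, p$mean),
         call. = FALSE)
  if (p$group %in% c("cost", "rate_ratio") && p$mean < 0)
    stop(sprintf("parameter '%s': %s must be >= 0", nm, p$group), call. = FALSE)
  if (!is.na(p$low) && !is.na(p$high)) {
    if (!(p$low <= p$mean && p$mean <= p$high))
      stop(sprintf("parameter '%s': bounds must satisfy low <= mean <= high", nm),
           call. = FALSE)
  }
  # distribution family must suit the quantity: beta for outcomes/utilities,
  # log-normal for costs
  if (p$dist == "beta" && !unit && p$group != "rate_ratio")
    stop(sprintf("parameter '%s': beta distribution on group '%s'", nm, p$group),
         call. = FALSE)
  if (p$dist == "lognormal" && !p$group %in% c("cost", "rate_ratio"))
    stop(sprintf("parameter '%s': lognormal distribution on group '%s'",
                 nm, p$group), call. = FALSE)
  invisible(p)
}

#' Assemble a parameter set
#'
#' A parameter set is the full collection of model inputs: a shared table of
#' named parameters plus per-strategy overrides.  Resolving a name for a
#' strategy consults the strategy's own overrides first, then its parent
#' strategy (e.g. the apixaban subgroup falls back to the pooled-DOAC entry),
#' then the shared table.
#'
#' @param entries named list of [parameter()] objects (the shared table).
#' @param overrides named list (by strategy) of named lists of parameters.
#' @param parents named character vector mapping a strategy to the strategy it
#'   inherits from (absent or `NA` for none).
#' @param meta optional free-form metadata list.
#' @return an object of class `"parameter_set"`.
#' @export
parameter_set <- function(entries, overrides = list(), parents = character(),
                          meta = list()) {
  stopifnot(is.list(entries), is.list(overrides))
  for (p in entries) validate_parameter(p)
  for (ov in overrides) for (p in ov) validate_parameter(p)
  for (s in names(parents)) {
    tgt <- parents[[s]]
    if (!is.na(tgt) && !tgt %in% names(overrides))
      stop(sprintf("strategy '%s' inherits from unknown strategy '%s'", s, tgt),
           call. = FALSE)
  }
  structure(list(entries = entries, overrides = overrides,
                 parents = parents, meta = meta),
            class = "parameter_set")
}

#' Strategies defined in a parameter set
#' @param pset a `"parameter_set"`.
#' @return character vector of strategy identifiers.
#' @export
strategies <- function(pset) names(pset$overrides)

#' Resolve a parameter by name, optionally for a strategy
#'
#' @param pset a `"parameter_set"`.
#' @param name parameter identifier.
#' @param strategy optional strategy identifier; when given, strategy
#'   overrides (and the strategy's parent chain) are consulted before the
#'   shared table.
#' @return a `"ceavte_parameter"`.
#' @export
resolve_parameter <- function(pset, name, strategy = NULL) {
  s <- strategy
  while (!is.null(s) && !is.na(s)) {
    if (!s %in% names(pset$overrides))
      stop(sprintf("unknown strategy '%s'", s), call. = FALSE)
    ov <- pset$overrides[[s]]
    if (name %in% names(ov)) return(ov[[name]])
    s <- if (s %in% names(pset$parents)) pset$parents[[s]] else NULL
  }
  if (name %in% names(pset$entries)) return(pset$entries[[name]])
  stop(sprintf("parameter '%s' not found%s", name,
               if (is.null(strategy)) "" else sprintf(" for strategy '%s'", strategy)),
       call. = FALSE)
}

#' @rdname resolve_parameter
#' @export
param_value <- function(pset, name, strategy = NULL) {
  resolve_parameter(pset, name, strategy)$mean
}

#' Replace a parameter's point estimate
#'
#' Used by the deterministic sensitivity analysis to move one input to a bound
#' while everything else stays at base.  When `strategy` is given the value is
#' written into that strategy's override block (creating one if the name
#' currently resolves through the fallback chain).
#'
#' @inheritParams resolve_parameter
#' @param value new point estimate.
#' @return the modified `"parameter_set"`.
#' @export
set_param_value <- function(pset, name, value, strategy = NULL) {
  p <- resolve_parameter(pset, name, strategy)
  p$mean <- as.numeric(value)
  p$low <- NA_real_; p$high <- NA_real_   # bounds no longer describe the value
  if (is.null(strategy)) {
    pset$entries[[name]] <- p
  } else {
    pset$overrides[[strategy]][[name]] <- p
  }
  pset
}

#' Load a parameter set from a YAML or JSON config
#'
#' The config has three blocks: `strategies` (identifiers, each optionally
#' with a `parent`), `shared` (name to parameter fields) and `overrides`
#' (strategy to name to parameter fields).  Every entry must carry `mean` and
#' `dist`; invariant violations (a probability outside `[0, 1]`, bounds out of
#' order, a distribution family unsuited to the group) are errors naming the
#' offending entry.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `"parameter_set"`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  parse_parameter_block <- function(block) {
    out <- list()
    for (nm in names(block)) {
      f <- block[[nm]]
      if (is.null(f$mean) || is.null(f$dist))
        stop(sprintf("entry '%s': fields 'mean' and 'dist' are required", nm),
             call. = FALSE)
      period <- f$period
      pm <- if (is.null(period) || identical(period, "one-time")) NA_real_
            else as.numeric(period)
      out[[nm]] <- parameter(
        name = nm, group = if (is.null(f$group)) "fixed" else f$group,
        mean = f$mean,
        low = if (is.null(f$low)) NA_real_ else f$low,
        high = if (is.null(f$high)) NA_real_ else f$high,
        sd = if (is.null(f$sd)) NA_real_ else f$sd,
        dist = f$dist, period_months = pm)
    }
    out
  }
  entries <- parse_parameter_block(raw$shared)
  strat_block <- if (is.null(raw$strategies)) list() else raw$strategies
  overrides <- list()
  for (s in names(strat_block)) overrides[[s]] <- list()
  for (s in names(raw$overrides))
    overrides[[s]] <- parse_parameter_block(raw$overrides[[s]])
  parents <- vapply(strat_block, function(b) {
    if (is.null(b$parent)) NA_character_ else b$parent
  }, character(1))
  parameter_set(entries, overrides, parents,
                meta = if (is.null(raw$meta)) list() else raw$meta)
}

#' Serialize a parameter set back to YAML
#'
#' `load_parameters()` after `write_parameters()` round-trips to an identical
#' set.
#'
#' @param pset a `"parameter_set"`.
#' @param path output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(pset, path) {
  unparse <- function(p) {
    f <- list(group = p$group, mean = p$mean)
    if (!is.na(p$low)) f$low <- p$low
    if (!is.na(p$high)) f$high <- p$high
    if (!is.na(p$sd)) f$sd <- p$sd
    f$dist <- p$dist
    f$period <- if (is.na(p$period_months)) "one-time" else p$period_months
    f
  }
  doc <- list(
    meta = pset$meta,
    strategies = stats::setNames(lapply(names(pset$overrides), function(s) {
      par <- if (s %in% names(pset$parents)) pset$parents[[s]] else NA_character_
      if (is.na(par)) stats::setNames(list(), character()) else list(parent = par)
    }), names(pset$overrides)),
    shared = lapply(pset$entries, unparse),
    overrides = lapply(pset$overrides, function(ov) lapply(ov, unparse)))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Deterministic sensitivity range of a parameter
#'
#' Returns the parameter's 95% bounds when the source provides them.  When it
#' does not, costs are varied by +/-20% of the mean and transition
#' probabilities/proportions by +/-10% (clamped to `[0, 1]`).  A utility with
#' no bounds has no default rule and raises an error so the range must be set
#' explicitly in config.
#'
#' @param p a `"ceavte_parameter"`.
#' @return numeric vector `c(low, high)`.
#' @export
dsa_range <- function(p) {
  if (!is.na(p$low) && !is.na(p$high)) return(c(low = p$low, high = p$high))
  if (p$group == "cost")
    return(c(low = p$mean * 0.8, high = p$mean * 1.2))
  if (p$group %in% c("probability", "proportion"))
    return(c(low = max(0, p$mean * 0.9), high = min(1, p$mean * 1.1)))
  stop(sprintf("parameter '%s' (group %s) has no bounds and no default DSA rule",
               p$name, p$group), call. = FALSE)
}

#' Resolved per-strategy parameter table
#'
#' Flattens the set into one row per (strategy, name) pair with the fully
#' resolved values, suitable for CSV export and auditing against the source
#' table.
#'
#' @param x a `"parameter_set"`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a `data.frame`.
#' @export
as.data.frame.parameter_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  one <- function(p, strategy) {
    data.frame(strategy = strategy, name = p$name, group = p$group,
               mean = p$mean, low = p$low, high = p$high, sd = p$sd,
               dist = p$dist, period_months = p$period_months,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(x$entries), function(nm) one(x$entries[[nm]], "shared"))
  for (s in names(x$overrides))
    rows <- c(rows, lapply(names(x$overrides[[s]]),
                           function(nm) one(x$overrides[[s]][[nm]], s)))
  do.call(rbind, rows)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set>: %d shared entries, %d strategies (%s)\n",
              length(x$entries), length(x$overrides),
              paste(names(x$overrides), collapse = ", ")))
  invisible(x)
}
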