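#' Distribution specification for probabilistic sensitivity analysis
#'
#' Describes one sampling distribution for a model parameter. Four kinds are
#' supported, matching the way health-economic parameter tables are usually
#' published:
#' \describe{
#'   \item{beta}{`a` = alpha, `b` = beta; draws lie in (0, 1). Used for
#'     probabilities and utilities.}
#'   \item{gamma_mean_sd}{`a` = mean, `b` = standard deviation; converted to
#'     shape/scale by moment matching (shape = (mean/sd)^2,
#'     scale = sd^2/mean). Used for costs.}
#'   \item{triangular}{`a` = minimum, `b` = maximum, `c` = mode. Used for
#'     rare-event probabilities reported as a plausible range.}
#'   \item{fixed}{degenerate; always returns `a`.}
#' }
#'
#' @param kind One of `"beta"`, `"gamma_mean_sd"`, `"triangular"`, `"fixed"`.
#' @param a,b,c Numeric distribution parameters (see Details); `c` is only
#'   used by the triangular kind.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", 6.3, 93)
#' dist_spec("triangular", 0.001, 0.003, 0.002)
#' @export
dist_spec <- function(kind, a, b = NA_real_, c = NA_real_) {
  kind <- match.arg(kind, c("beta", "gamma_mean_sd", "triangular", "fixed"))
  stopifnot(is.numeric(a), length(a) == 1L)
  spec <- structure(list(kind = kind, a = a, b = b, c = c),
                    class = "dist_spec")
  validate_dist_spec(spec)
  spec
}

validate_dist_spec <- function(spec) {
  switch(spec$kind,
    beta = if (!(spec$a > 0 && spec$b > 0))
      stop("beta distribution requires a > 0 and b > 0", call. = FALSE),
    gamma_mean_sd = if (!(spec$a > 0 && spec$b > 0))
      stop("gamma_mean_sd requires mean > 0 and sd > 0", call. = FALSE),
    triangular = if (!(spec$a <= spec$c && spec$c <= spec$b))
      stop("triangular requires min <= mode <= max", call. = FALSE),
    fixed = invisible(NULL)
  )
  invisible(spec)
}

#' Analytic mean of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return The closed-form mean of the distribution.
#' @export
dist_mean <- function(spec) {
  switch(spec$kind,
    beta = spec$a / (spec$a + spec$b),
    gamma_mean_sd = spec$a,
    triangular = (spec$a + spec$b + spec$c) / 3,
    fixed = spec$a
  )
}

#' Draw from a distribution specification
#'
#' Draws use R's global random stream, so `set.seed()` gives bit-reproducible
#' sequences. The triangular draw inverts the closed-form CDF.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_value <- function(spec, n = 1L) {
  validate_dist_spec(spec)
  switch(spec$kind,
    beta = stats::rbeta(n, spec$a, spec$b),
    gamma_mean_sd = stats::rgamma(n, shape = (spec$a / spec$b)^2,
                                  scale = spec$b^2 / spec$a),
    triangular = rtriangular(n, spec$a, spec$b, spec$c),
    fixed = rep(spec$a, n)
  )
}

# Inverse-CDF triangular sampler; min <= mode <= max.
rtriangular <- function(n, min, max, mode) {
  if (min == max) return(rep(min, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' @export
print.dist_spec <- function(x, ...) {
  args <- switch(x$kind,
    beta = sprintf("alpha=%g, beta=%g", x$a, x$b),
    gamma_mean_sd = sprintf("mean=%g, sd=%g", x$a, x$b),
    triangular = sprintf("min=%g, max=%g, mode=%g", x$a, x$b, x$c),
    fixed = sprintf("value=%g", x$a))
  cat(sprintf("<dist_spec %s(%s), mean %.6g>\n", x$kind, args, dist_mean(x)))
  invisible(x)
}

param_fields <- function() {
  c("start_age", "discount_rate_annual", "bsa", "wtp",
    "p_variant",
    "p_tox_variant_std", "p_tox_variant_red", "p_tox_wt_std",
    "p_hosp_variant_std", "p_hosp_variant_red", "p_hosp_wt_std",
    "p_trtdeath_variant_std", "p_trtdeath_variant_red", "p_trtdeath_wt_std",
    "p_progress", "p_death_progressed",
    "cost_drug_monthly_full", "cost_unit_per_500mg", "cost_test", "cost_hosp",
    "u_pf", "u_prog", "disutil_hosp", "disutil_tox",
    "hosp_los_days", "cycle_length_days", "dose_standard", "dose_reduced",
    "dose_floor")
}

#' Base-case model parameters
#'
#' Returns the full base-case parameter record: the DPYD variant-carrier
#' prevalence, genotype- and dose-stratified monthly probabilities of grade
#' 3/4 toxicity, hospitalization given toxicity and treatment-related death,
#' progression and post-progression mortality, drug/test/hospitalization
#' costs (2024 US dollars), health-state utilities and event disutilities,
#' and structural settings (start age 62, 3% annual discounting,
#' $100,000/QALY willingness-to-pay, body surface area 1.8 m2, dose-tier
#' fractions 1.0/0.75/0.5).
#'
#' @return An object of class `dpyd_params` (a validated named list).
#' @examples
#' p <- default_parameters()
#' p$p_variant
#' @export
default_parameters <- function() {
  p <- list(
    start_age = 62,
    discount_rate_annual = 0.03,
    bsa = 1.8,
    wtp = 1e5,
    p_variant = 0.063,
    p_tox_variant_std = 0.08,
    p_tox_variant_red = 0.044,
    p_tox_wt_std = 0.026,
    p_hosp_variant_std = 0.4,
    p_hosp_variant_red = 0.54,
    p_hosp_wt_std = 0.6,
    p_trtdeath_variant_std = 0.002,
    p_trtdeath_variant_red = 0.0002,
    p_trtdeath_wt_std = 0.0001,
    p_progress = 0.11,
    p_death_progressed = 0.051,
    cost_drug_monthly_full = 115.56,
    cost_unit_per_500mg = 0.64,
    cost_test = 174.81,
    cost_hosp = 12907,
    u_pf = 0.715,
    u_prog = 0.443,
    disutil_hosp = 0.28,
    disutil_tox = 0.125,
    hosp_los_days = 5,
    cycle_length_days = 30,
    dose_standard = 1.0,
    dose_reduced = 0.75,
    dose_floor = 0.5
  )
  class(p) <- "dpyd_params"
  validate_parameters(p)
}

#' Validate a parameter record
#'
#' Checks every probability and utility lies in [0, 1], costs and
#' disutilities are non-negative, and the dose tiers are strictly
#' decreasing (standard > reduced > floor).
#'
#' @param p A `dpyd_params` object or plain named list with the same fields.
#' @return The validated object (invisibly classed `dpyd_params`).
#' @export
validate_parameters <- function(p) {
  missing <- setdiff(param_fields(), names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  prob_fields <- grep("^p_", param_fields(), value = TRUE)
  for (f in prob_fields)
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(sprintf("parameter '%s' = %g outside [0, 1]", f, p[[f]]),
           call. = FALSE)
  for (f in c("u_pf", "u_prog"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(sprintf("utility '%s' = %g outside [0, 1]", f, p[[f]]),
           call. = FALSE)
  for (f in c("disutil_hosp", "disutil_tox", "cost_drug_monthly_full",
              "cost_unit_per_500mg", "cost_test", "cost_hosp"))
    if (p[[f]] < 0)
      stop(sprintf("parameter '%s' must be >= 0", f), call. = FALSE)
  if (!(p$dose_standard > p$dose_reduced && p$dose_reduced > p$dose_floor))
    stop("dose tiers must satisfy standard > reduced > floor", call. = FALSE)
  if (p$discount_rate_annual < 0)
    stop("discount_rate_annual must be >= 0", call. = FALSE)
  class(p) <- "dpyd_params"
  p
}

#' Load parameters from a YAML configuration
#'
#' Reads a flat key-value YAML document of parameter overrides and applies
#' it on top of [default_parameters()]. Unknown keys and out-of-range values
#' are rejected with informative errors, so a configuration typo cannot
#' silently run the base case.
#'
#' @param config Path to a YAML file, or a YAML string, or a named list of
#'   overrides. `NULL` (default) returns the base case unchanged.
#' @return A validated `dpyd_params` object.
#' @examples
#' load_parameters("p_variant: 0.08")$p_variant
#' @export
load_parameters <- function(config = NULL) {
  base <- default_parameters()
  if (is.null(config)) return(base)
  overrides <-
    if (is.list(config)) config
    else if (file.exists(config)) yaml::read_yaml(config)
    else yaml::yaml.load(config)
  if (is.null(overrides) || length(overrides) == 0L) return(base)
  unknown <- setdiff(names(overrides), param_fields())
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(overrides)) base[[k]] <- as.numeric(overrides[[k]])
  validate_parameters(base)
}

#' Write a parameter record as YAML
#'
#' Round-trips through [load_parameters()]: reloading the written file
#' reproduces the record exactly.
#'
#' @param p A `dpyd_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  yaml::write_yaml(unclass(p)[param_fields()], path,
                   precision = 15L)
  invisible(path)
}

#' @export
print.dpyd_params <- function(x, ...) {
  cat("<dpyd_params> base-case model parameters\n")
  cat(sprintf("  cohort: women age %g, DPYD variant prevalence %.3f\n",
              x$start_age, x$p_variant))
  cat(sprintf("  discounting %.1f%%/yr, WTP $%s/QALY\n",
              100 * x$discount_rate_annual,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  monthly toxicity (var std/red, wt std): %.3f / %.3f / %.3f\n",
              x$p_tox_variant_std, x$p_tox_variant_red, x$p_tox_wt_std))
  cat(sprintf("  costs: drug $%.2f/mo (full dose), test $%.2f, hosp $%s\n",
              x$cost_drug_monthly_full, x$cost_test,
              format(x$cost_hosp, big.mark = ",")))
  invisible(x)
}

#' Parameter uncertainty specification
#'
#' One row of the sensitivity-analysis parameter table: the base value, the
#' deterministic low/high range, and (optionally) the sampling distribution
#' used in probabilistic sensitivity analysis. A parameter without a
#' distribution stays fixed at its base value in PSA.
#'
#' @param name A `dpyd_params` field name.
#' @param base_value Base-case value.
#' @param low,high Deterministic sensitivity range, `low <= base <= high`.
#' @param distribution A [dist_spec()] or `NULL`.
#' @param varies_in_dsa Include in one-way/tornado analyses?
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, base_value, low, high, distribution = NULL,
                       varies_in_dsa = TRUE) {
  if (!name %in% param_fields())
    stop("unknown parameter name: ", name, call. = FALSE)
  if (!(low <= base_value && base_value <= high))
    stop(sprintf("'%s': need low <= base_value <= high", name), call. = FALSE)
  if (!is.null(distribution)) validate_dist_spec(distribution)
  structure(list(name = name, base_value = base_value, low = low,
                 high = high, distribution = distribution,
                 varies_in_dsa = varies_in_dsa),
            class = "param_spec")
}

#' Default uncertainty specifications for every uncertain parameter
#'
#' Builds the canonical sensitivity table: each clinical probability, cost
#' and utility with its published PSA distribution (Beta for probabilities
#' and utilities, Gamma parameterised by mean/sd for costs, Triangular for
#' treatment-related death), and a deterministic range of base +/- 25%
#' except the variant prevalence, which uses the literature range 3--8%.
#' Structural settings (discount rate, body surface area, dose fractions)
#' are excluded.
#'
#' @param p Base parameters, defaults to [default_parameters()].
#' @return Named list of [param_spec()] objects.
#' @export
default_uncertainty_specs <- function(p = default_parameters()) {
  pm25 <- function(name, dist = NULL, cap1 = FALSE) {
    lo <- p[[name]] * 0.75
    hi <- p[[name]] * 1.25
    if (cap1) hi <- min(hi, 1)
    param_spec(name, p[[name]], lo, hi, dist)
  }
  specs <- list(
    param_spec("p_variant", p$p_variant, 0.03, 0.08,
               dist_spec("beta", 6.3, 93)),
    pm25("p_tox_variant_std", dist_spec("beta", 8.6, 94.5)),
    pm25("p_tox_variant_red", dist_spec("beta", 3, 65.5)),
    pm25("p_tox_wt_std", dist_spec("beta", 23, 879)),
    pm25("p_hosp_variant_std", dist_spec("beta", 12, 18.9)),
    pm25("p_hosp_variant_red", dist_spec("beta", 41.6, 35.4)),
    pm25("p_hosp_wt_std", dist_spec("beta", 28.4, 18.9), cap1 = TRUE),
    pm25("p_trtdeath_variant_std",
         dist_spec("triangular", 0.001, 0.003, 0.002)),
    pm25("p_trtdeath_variant_red",
         dist_spec("triangular", 0.0001, 0.0003, 0.0002)),
    pm25("p_trtdeath_wt_std",
         dist_spec("triangular", 0, 0.0002, 0.0001)),
    pm25("p_progress", dist_spec("beta", 11, 89)),
    pm25("p_death_progressed", dist_spec("beta", 5.1, 95)),
    pm25("cost_drug_monthly_full", dist_spec("gamma_mean_sd", 116, 29)),
    pm25("cost_test", dist_spec("gamma_mean_sd", 174, 44)),
    pm25("cost_hosp", dist_spec("gamma_mean_sd", 12907, 6450)),
    pm25("u_pf", dist_spec("beta", 7.2, 2.9), cap1 = TRUE),
    pm25("u_prog", dist_spec("beta", 4.4, 5.6)),
    pm25("disutil_hosp", dist_spec("beta", 28, 72)),
    pm25("disutil_tox", dist_spec("beta", 13.9, 97))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Sample one parameter set for probabilistic sensitivity analysis
#'
#' Each spec carrying a distribution is replaced by an independent draw;
#' all other fields keep their base values. Draws consume the global random
#' stream in the (fixed) order of `specs`, so a seed fully determines the
#' sample.
#'
#' @param base Base `dpyd_params`.
#' @param specs List of [param_spec()] objects (default: the full canonical
#'   set).
#' @return A validated `dpyd_params` with sampled values.
#' @export
sample_parameters <- function(base = default_parameters(),
                              specs = default_uncertainty_specs(base)) {
  p <- base
  for (s in specs) {
    if (!s$name %in% param_fields())
      stop("spec names unknown field: ", s$name, call. = FALSE)
    if (!is.null(s$distribution))
      p[[s$name]] <- sample_value(s$distribution)
  }
  validate_parameters(p)
}
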