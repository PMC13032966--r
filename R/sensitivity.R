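#' One-way deterministic sensitivity analysis
#'
#' Evaluates the full two-arm model over an equally spaced grid of one
#' parameter, all others held at base values.
#'
#' @param param_name A `dpyd_params` field name.
#' @param low,high Sweep range (`low < high`, or `low == high` for a single
#'   point).
#' @param base Base `dpyd_params`.
#' @param lt A `life_table`.
#' @param n_points Grid size.
#' @param wtp Willingness-to-pay threshold.
#' @return A data.frame: one row per grid value with incremental cost/QALY/
#'   LY, ICERs, NMB and classification.
#' @examples
#' one_way("cost_test", 0, 174.81, n_points = 3)
#' @export
one_way <- function(param_name, low, high, base = default_parameters(),
                    lt = default_lifetable(), n_points = 11L, wtp = 1e5) {
  if (!param_name %in% param_fields())
    stop("unknown parameter name: ", param_name, call. = FALSE)
  if (low > high) stop("need low <= high", call. = FALSE)
  grid <- if (low == high) low else seq(low, high, length.out = n_points)
  rows <- lapply(grid, function(v) {
    p <- base
    p[[param_name]] <- v
    p <- validate_parameters(p)
    cmp <- evaluate_strategies(p, lt, wtp = wtp)$comparison
    data.frame(parameter = param_name, value = v,
               inc_cost = cmp$inc_cost, inc_qaly = cmp$inc_qaly,
               inc_ly = cmp$inc_ly, icer_per_qaly = cmp$icer_per_qaly,
               icer_per_ly = cmp$icer_per_ly, nmb = cmp$nmb,
               classification = cmp$classification)
  })
  do.call(rbind, rows)
}

#' Variant-prevalence threshold sweep
#'
#' The canonical one-way analysis: the ICER of genotyping as a function of
#' the DPYD variant-carrier prevalence over the literature range 3--8%.
#'
#' @inheritParams one_way
#' @param low,high Prevalence range (default 0.03--0.08).
#' @return As [one_way()].
#' @export
prevalence_sweep <- function(low = 0.03, high = 0.08,
                             base = default_parameters(),
                             lt = default_lifetable(), n_points = 11L,
                             wtp = 1e5) {
  one_way("p_variant", low, high, base, lt, n_points, wtp)
}

#' Tornado analysis of one-way parameter excursions
#'
#' For each uncertainty spec flagged for deterministic analysis, evaluates
#' the ICER at its low and high endpoint and ranks parameters by the ICER
#' span |ICER(high) - ICER(low)|, the ordering used to draw a tornado
#' diagram around the base-case ICER. Ties and the ordering are
#' deterministic: entries are sorted by decreasing span with the parameter
#' name as tie-break, so the output is invariant to the input order of
#' `specs`.
#'
#' @param specs List of [param_spec()]s (default: the canonical set).
#' @param base Base `dpyd_params`.
#' @param lt A `life_table`.
#' @param wtp Willingness-to-pay threshold.
#' @param top Keep the `top` largest spans (`Inf` for all).
#' @return A data.frame: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `nmb_low`, `nmb_high`, `span`, sorted by span descending,
#'   with the base-case ICER as attribute `icer_base`.
#' @export
tornado <- function(specs = default_uncertainty_specs(base),
                    base = default_parameters(), lt = default_lifetable(),
                    wtp = 1e5, top = 6L) {
  specs <- Filter(function(s) isTRUE(s$varies_in_dsa), specs)
  if (!length(specs)) stop("no spec with varies_in_dsa", call. = FALSE)
  base_icer <- evaluate_strategies(base, lt,
                                   wtp = wtp)$comparison$icer_per_qaly
  rows <- lapply(specs, function(s) {
    lo <- one_way(s$name, s$low, s$low, base, lt, wtp = wtp)
    hi <- one_way(s$name, s$high, s$high, base, lt, wtp = wtp)
    data.frame(parameter = s$name, low = s$low, high = s$high,
               icer_low = lo$icer_per_qaly, icer_high = hi$icer_per_qaly,
               nmb_low = lo$nmb, nmb_high = hi$nmb,
               span = abs(hi$icer_per_qaly - lo$icer_per_qaly))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  if (is.finite(top)) out <- utils::head(out, top)
  attr(out, "icer_base") <- base_icer
  out
}
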