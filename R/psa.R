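#' Probabilistic sensitivity analysis
#'
#' Runs `n` Monte-Carlo iterations. Each iteration draws one parameter set
#' from the uncertainty distributions ([sample_parameters()]) and evaluates
#' both strategy arms on that common draw, so the incremental distribution
#' reflects parameter uncertainty rather than between-arm sampling noise.
#' All randomness flows from `seed`; a fixed seed makes the full result
#' bit-reproducible.
#'
#' Classification per draw: `dominant` (cost-saving) when the genotyping
#' arm is less costly with more QALYs, `dominated` for the reverse, and
#' otherwise cost-effective or not by the sign of the incremental net
#' monetary benefit at `wtp`.
#'
#' @param n Number of iterations.
#' @param seed Integer seed.
#' @param base Base `dpyd_params`.
#' @param specs Uncertainty specs (default: the canonical set).
#' @param lt A `life_table`.
#' @param wtp Willingness-to-pay threshold for classification.
#' @return A `psa_result`: list with `draws` (data.frame: iteration,
#'   per-arm cost/QALY, incremental values, ICER, NMB, classification),
#'   `fraction_cost_effective`, `fraction_cost_saving`, `n`, `wtp`,
#'   `seed`.
#' @examples
#' psa <- run_psa(50, seed = 1)
#' psa$fraction_cost_effective
#' @export
run_psa <- function(n, seed = 1L, base = default_parameters(),
                    specs = default_uncertainty_specs(base),
                    lt = default_lifetable(), wtp = 1e5) {
  stopifnot(n >= 1)
  set.seed(seed)
  cols <- c("cost_ref", "qaly_ref", "ly_ref", "cost_cmp", "qaly_cmp",
            "ly_cmp", "inc_cost", "inc_qaly", "inc_ly", "icer", "nmb")
  m <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  cls <- character(n)
  for (i in seq_len(n)) {
    p <- sample_parameters(base, specs)
    ev <- evaluate_strategies(p, lt, wtp = wtp)
    cmp <- ev$comparison
    m[i, ] <- c(ev$no_genotyping$cost, ev$no_genotyping$qaly,
                ev$no_genotyping$ly, ev$genotyping$cost,
                ev$genotyping$qaly, ev$genotyping$ly,
                cmp$inc_cost, cmp$inc_qaly, cmp$inc_ly,
                cmp$icer_per_qaly, cmp$nmb)
    cls[i] <- cmp$classification
  }
  draws <- data.frame(iteration = seq_len(n), m, classification = cls)
  out <- list(
    draws = draws,
    fraction_cost_effective = mean(draws$nmb > 0),
    fraction_cost_saving = mean(draws$inc_cost < 0 & draws$inc_qaly > 0),
    n = n, wtp = wtp, seed = seed)
  class(out) <- "psa_result"
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d Monte-Carlo iterations (seed %d)\n",
              x$n, x$seed))
  cat(sprintf("  cost-effective at $%s/QALY: %.1f%%\n",
              format(x$wtp, big.mark = ","),
              100 * x$fraction_cost_effective))
  cat(sprintf("  cost-saving (dominant): %.1f%%\n",
              100 * x$fraction_cost_saving))
  cat(sprintf("  median ICER: $%.0f/QALY\n",
              stats::median(x$draws$icer, na.rm = TRUE)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive incremental net monetary benefit at
#' each willingness-to-pay value. At WTP = 0 this is the fraction of
#' cost-saving (in the cost sense) draws; as WTP grows it approaches the
#' fraction of draws with a QALY gain. The curve is not guaranteed
#' monotone.
#'
#' @param result A `psa_result`.
#' @param wtp_grid Numeric vector of thresholds ($/QALY); order preserved.
#' @return A data.frame with columns `wtp`, `fraction_cost_effective`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 2e5, by = 1e4)) {
  stopifnot(length(wtp_grid) >= 1)
  d <- result$draws
  data.frame(
    wtp = wtp_grid,
    fraction_cost_effective =
      vapply(wtp_grid, function(w) mean(d$inc_qaly * w - d$inc_cost > 0),
             numeric(1)))
}
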