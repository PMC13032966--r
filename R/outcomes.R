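#' Per-arm totals from a cohort trace
#'
#' @param trace A `cohort_trace`.
#' @return A `strategy_result`: discounted and undiscounted total cost,
#'   QALYs and life-years, with the cost breakdown (drug, hospitalization,
#'   test).
#' @export
strategy_result <- function(trace) {
  t <- trace$totals
  structure(list(strategy = trace$strategy,
                 cost = t$cost, qaly = t$qaly, ly = t$ly,
                 cost_undisc = t$cost_undisc, qaly_undisc = t$qaly_undisc,
                 ly_undisc = t$ly_undisc,
                 cost_drug = t$cost_drug, cost_hosp = t$cost_hosp,
                 cost_test = t$cost_test),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s\n", x$strategy))
  cat(sprintf("  cost $%.2f (drug %.2f + hosp %.2f + test %.2f)\n",
              x$cost, x$cost_drug, x$cost_hosp, x$cost_test))
  cat(sprintf("  QALY %.4f, LY %.4f (discounted)\n", x$qaly, x$ly))
  invisible(x)
}

#' Incremental cost-effectiveness comparison
#'
#' Forms the incremental cost, QALYs and life-years of `comparator` minus
#' `reference`, the ICER per QALY and per life-year (only in the trade-off
#' quadrants), the incremental net monetary benefit at the willingness-to-pay
#' threshold, and the dominance classification:
#' `dominant` (less costly, more effective — cost-saving),
#' `dominated` (more costly, less effective), and otherwise
#' `cost_effective`/`not_cost_effective` by the sign of the incremental NMB.
#' When incremental QALYs are zero the ICER is undefined (`NA`) and the
#' classification falls back to the cost sign.
#'
#' @param reference,comparator `strategy_result` objects; increments are
#'   comparator minus reference.
#' @param wtp Willingness-to-pay threshold in $/QALY.
#' @return A `ce_result`.
#' @examples
#' a <- run_cohort("no_genotyping", default_parameters())
#' b <- run_cohort("genotyping", default_parameters())
#' compare_strategies(strategy_result(a), strategy_result(b))
#' @export
compare_strategies <- function(reference, comparator, wtp = 1e5) {
  ic <- comparator$cost - reference$cost
  iq <- comparator$qaly - reference$qaly
  il <- comparator$ly - reference$ly
  nmb <- iq * wtp - ic
  icer_q <- if (iq != 0) ic / iq else NA_real_
  icer_l <- if (il != 0) ic / il else NA_real_
  classification <-
    if (iq > 0 && ic < 0) "dominant"
    else if (iq < 0 && ic > 0) "dominated"
    else if (iq == 0) {
      if (ic < 0) "cost_effective"
      else if (ic > 0) "not_cost_effective"
      else "cost_effective"
    }
    else if (nmb > 0) "cost_effective" else "not_cost_effective"
  structure(list(reference = reference$strategy,
                 comparator = comparator$strategy,
                 inc_cost = ic, inc_qaly = iq, inc_ly = il,
                 icer_per_qaly = icer_q, icer_per_ly = icer_l,
                 nmb = nmb, wtp = wtp, classification = classification),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  incremental: cost $%.2f, QALY %.5f, LY %.5f\n",
              x$inc_cost, x$inc_qaly, x$inc_ly))
  icer <- if (is.na(x$icer_per_qaly)) "undefined"
          else sprintf("$%.0f/QALY", x$icer_per_qaly)
  cat(sprintf("  ICER %s; NMB $%.2f at $%s/QALY -> %s\n",
              icer, x$nmb, format(x$wtp, big.mark = ","),
              x$classification))
  invisible(x)
}

#' Run both strategy arms and compare them
#'
#' Convenience wrapper: runs the cohort model for the no-genotyping
#' (reference) and genotyping (comparator) arms on the same parameters and
#' life table and returns the per-arm totals with their incremental
#' comparison.
#'
#' @param params A `dpyd_params`.
#' @param lt A `life_table`.
#' @param wtp Willingness-to-pay ($/QALY); defaults to `params$wtp`.
#' @param horizon_age Stop age, shared by both arms.
#' @param ... Passed to [run_cohort()].
#' @return List with elements `no_genotyping`, `genotyping`
#'   (`strategy_result`) and `comparison` (`ce_result`).
#' @export
evaluate_strategies <- function(params = default_parameters(),
                                lt = default_lifetable(), wtp = NULL,
                                horizon_age = 100, ...) {
  pre <- cohort_precompute(params, lt, horizon_age)
  ref <- strategy_result(run_cohort("no_genotyping", params, lt,
                                    horizon_age = horizon_age,
                                    keep_trace = FALSE, precomp = pre, ...))
  cmp <- strategy_result(run_cohort("genotyping", params, lt,
                                    horizon_age = horizon_age,
                                    keep_trace = FALSE, precomp = pre, ...))
  list(no_genotyping = ref, genotyping = cmp,
       comparison = compare_strategies(ref, cmp,
                                       wtp = if (is.null(wtp)) params$wtp
                                             else wtp))
}

#' Results table in the standard two-arm layout
#'
#' @param ev Output of [evaluate_strategies()].
#' @return A data.frame with one row per arm plus incremental columns.
#' @export
results_table <- function(ev) {
  data.frame(
    strategy = c("no_genotyping", "genotyping"),
    total_cost = c(ev$no_genotyping$cost, ev$genotyping$cost),
    qalys = c(ev$no_genotyping$qaly, ev$genotyping$qaly),
    life_years = c(ev$no_genotyping$ly, ev$genotyping$ly),
    inc_cost = c(NA, ev$comparison$inc_cost),
    inc_qaly = c(NA, ev$comparison$inc_qaly),
    inc_ly = c(NA, ev$comparison$inc_ly),
    icer_per_qaly = c(NA, ev$comparison$icer_per_qaly),
    icer_per_ly = c(NA, ev$comparison$icer_per_ly)
  )
}
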