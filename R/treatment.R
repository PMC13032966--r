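#' Strategy and dose-tier policy
#'
#' Strategy logic for genotype-guided capecitabine dosing. Under the
#' genotyping strategy, DPYD variant carriers (intermediate and poor
#' metabolizers combined) start at the reduced 75% dose; wild-type patients
#' and everyone in the no-genotyping arm start at the standard dose. After a
#' grade 3/4 toxicity the next cycle's dose steps down one tier,
#' 1.0 -> 0.75 -> 0.5, and 0.5 is absorbing.
#'
#' @param strategy `"genotyping"` or `"no_genotyping"`.
#' @param genotype `"variant"` or `"wild_type"`.
#' @return `initial_tier`: the starting dose fraction (1.0 or 0.75).
#' @examples
#' initial_tier("genotyping", "variant")     # 0.75
#' initial_tier("no_genotyping", "variant")  # 1.0
#' @export
initial_tier <- function(strategy, genotype) {
  strategy <- match.arg(strategy, c("genotyping", "no_genotyping"))
  genotype <- match.arg(genotype, c("variant", "wild_type"))
  if (strategy == "genotyping" && genotype == "variant") 0.75 else 1.0
}

#' @rdname initial_tier
#' @param tier Current dose fraction: 1.0, 0.75 or 0.5.
#' @return `next_tier_after_toxicity`: the dose fraction for subsequent
#'   cycles.
#' @export
next_tier_after_toxicity <- function(tier) {
  check_tier(tier)
  if (tier == 1.0) 0.75 else 0.5
}

check_tier <- function(tier) {
  if (!tier %in% c(1.0, 0.75, 0.5))
    stop("dose tier must be one of 1.0, 0.75, 0.5", call. = FALSE)
  invisible(tier)
}

#' Genotype- and dose-stratified monthly event probabilities
#'
#' The measured anchors are the published genotype/dose cells: toxicity
#' 0.08 (variant, standard), 0.044 (variant, reduced), 0.026 (wild type,
#' standard); hospitalization given toxicity 0.4 / 0.54 / 0.6 for the same
#' cells; treatment-related death 0.002 / 0.0002 / 0.0001. Cells without a
#' measured anchor follow the model's proportionality assumption: toxicity
#' and treatment-death probabilities scale linearly with the dose fraction
#' from the genotype's nearest measured (lower-dose where available)
#' anchor, e.g. wild type at 0.75 has toxicity 0.026 x 0.75 and the variant
#' floor tier scales the reduced-dose anchor by 0.5/0.75. Hospitalization
#' given toxicity has no dose scaling; unlisted cells reuse the genotype's
#' nearest anchor.
#'
#' @param genotype `"variant"` or `"wild_type"`.
#' @param tier Dose fraction 1.0, 0.75 or 0.5.
#' @param params A `dpyd_params`.
#' @return A monthly probability.
#' @export
toxicity_probability <- function(genotype, tier, params) {
  genotype <- match.arg(genotype, c("variant", "wild_type"))
  check_tier(tier)
  if (genotype == "variant") {
    if (tier == 1.0) params$p_tox_variant_std
    else params$p_tox_variant_red * (tier / 0.75)
  } else {
    params$p_tox_wt_std * tier
  }
}

#' @rdname toxicity_probability
#' @export
hospitalization_probability <- function(genotype, tier, params) {
  genotype <- match.arg(genotype, c("variant", "wild_type"))
  check_tier(tier)
  if (genotype == "variant") {
    if (tier == 1.0) params$p_hosp_variant_std else params$p_hosp_variant_red
  } else {
    params$p_hosp_wt_std
  }
}

#' @rdname toxicity_probability
#' @export
treatment_death_probability <- function(genotype, tier, params) {
  genotype <- match.arg(genotype, c("variant", "wild_type"))
  check_tier(tier)
  if (genotype == "variant") {
    if (tier == 1.0) params$p_trtdeath_variant_std
    else params$p_trtdeath_variant_red * (tier / 0.75)
  } else {
    params$p_trtdeath_wt_std * tier
  }
}

#' Capecitabine cost per model cycle at a dose tier
#'
#' Drug cost scales proportionally with the dose fraction; after
#' progression treatment is discontinued and the drug cost is zero.
#'
#' @param tier Dose fraction.
#' @param params A `dpyd_params`.
#' @return Cost in dollars per monthly cycle.
#' @examples
#' drug_cost_per_cycle(0.75, default_parameters())  # 86.67
#' @export
drug_cost_per_cycle <- function(tier, params) {
  check_tier(tier)
  params$cost_drug_monthly_full * tier
}

#' Monthly capecitabine cost from the dosing regimen
#'
#' Reconstructs the monthly full-dose drug cost from first principles: the
#' FDA intermittent regimen of 1,250 mg/m2 twice daily for 14 of 21 days,
#' priced per 500 mg unit, prorated from the 21-day regimen cycle to the
#' model's cycle length (30 days by default). At $0.64/500 mg and a body
#' surface area of 1.8 m2 this gives 63,000 mg (126 units, $80.64) per
#' 21-day cycle and $115.20/month, within 0.5% of the published monthly
#' figure of $115.56 (the residual is price-file rounding).
#'
#' @param unit_price_per_500mg Dollars per 500 mg unit.
#' @param bsa Body surface area in m2.
#' @param params A `dpyd_params` (supplies `cycle_length_days`).
#' @return List with `mg_per_regimen_cycle`, `cost_per_regimen_cycle`,
#'   `monthly_cost`.
#' @export
monthly_drug_cost_from_regimen <- function(unit_price_per_500mg = 0.64,
                                           bsa = 1.8,
                                           params = default_parameters()) {
  stopifnot(unit_price_per_500mg >= 0, bsa > 0)
  mg <- 1250 * bsa * 2 * 14
  cost21 <- mg / 500 * unit_price_per_500mg
  list(mg_per_regimen_cycle = mg,
       cost_per_regimen_cycle = cost21,
       monthly_cost = cost21 * params$cycle_length_days / 21)
}
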