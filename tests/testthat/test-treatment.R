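test_that("initial dose tier follows the strategy and genotype", {
  expect_equal(initial_tier("genotyping", "variant"), 0.75)
  expect_equal(initial_tier("genotyping", "wild_type"), 1.0)
  expect_equal(initial_tier("no_genotyping", "variant"), 1.0)
  expect_equal(initial_tier("no_genotyping", "wild_type"), 1.0)
})

test_that("dose tier steps down after toxicity and the floor absorbs", {
  expect_equal(next_tier_after_toxicity(1.0), 0.75)
  expect_equal(next_tier_after_toxicity(0.75), 0.5)
  expect_equal(next_tier_after_toxicity(0.5), 0.5)
  expect_error(next_tier_after_toxicity(0.9), "dose tier")
})

test_that("event probabilities hit the measured anchors and scale by dose", {
  p <- base_params
  # measured cells
  expect_equal(toxicity_probability("variant", 1.0, p), 0.08)
  expect_equal(toxicity_probability("variant", 0.75, p), 0.044)
  expect_equal(toxicity_probability("wild_type", 1.0, p), 0.026)
  expect_equal(hospitalization_probability("variant", 1.0, p), 0.4)
  expect_equal(hospitalization_probability("variant", 0.75, p), 0.54)
  expect_equal(hospitalization_probability("wild_type", 1.0, p), 0.6)
  expect_equal(treatment_death_probability("variant", 1.0, p), 0.002)
  expect_equal(treatment_death_probability("variant", 0.75, p), 0.0002)
  expect_equal(treatment_death_probability("wild_type", 1.0, p), 0.0001)
  # proportional extension to unmeasured cells
  expect_equal(toxicity_probability("wild_type", 0.75, p), 0.026 * 0.75)
  expect_equal(toxicity_probability("wild_type", 0.5, p), 0.026 * 0.5)
  expect_equal(toxicity_probability("variant", 0.5, p), 0.044 * 0.5 / 0.75)
  expect_equal(treatment_death_probability("wild_type", 0.75, p),
               0.0001 * 0.75)
  expect_equal(treatment_death_probability("variant", 0.5, p),
               0.0002 * 0.5 / 0.75)
  # hospitalization reuses the genotype's nearest anchor, no dose scaling
  expect_equal(hospitalization_probability("wild_type", 0.75, p), 0.6)
  expect_equal(hospitalization_probability("wild_type", 0.5, p), 0.6)
  expect_equal(hospitalization_probability("variant", 0.5, p), 0.54)
})

test_that("risk and cost are monotone in dose and genotype", {
  p <- base_params
  for (g in c("variant", "wild_type")) {
    tox <- sapply(c(1.0, 0.75, 0.5), toxicity_probability,
                  genotype = g, params = p)
    td <- sapply(c(1.0, 0.75, 0.5), treatment_death_probability,
                 genotype = g, params = p)
    dc <- sapply(c(1.0, 0.75, 0.5), drug_cost_per_cycle, params = p)
    expect_true(all(diff(tox) <= 0), label = paste("toxicity", g))
    expect_true(all(diff(td) <= 0), label = paste("death", g))
    expect_true(all(diff(dc) <= 0))
  }
  for (d in c(1.0, 0.75, 0.5)) {
    expect_gte(toxicity_probability("variant", d, p),
               toxicity_probability("wild_type", d, p))
    expect_gte(treatment_death_probability("variant", d, p),
               treatment_death_probability("wild_type", d, p))
  }
})

test_that("drug cost per cycle scales with the dose fraction", {
  p <- base_params
  expect_equal(drug_cost_per_cycle(1.0, p), 115.56)
  expect_equal(drug_cost_per_cycle(0.75, p), 86.67)
  expect_equal(drug_cost_per_cycle(0.5, p), 57.78)
})

test_that("regimen arithmetic reproduces the monthly drug cost", {
  r <- monthly_drug_cost_from_regimen(0.64, 1.8)
  expect_equal(r$mg_per_regimen_cycle, 63000)
  expect_equal(r$cost_per_regimen_cycle, 80.64)
  expect_equal(r$monthly_cost, 80.64 * 30 / 21)
  # within 1% of the published monthly price
  expect_lt(abs(r$monthly_cost - 115.56) / 115.56, 0.01)
  expect_equal(monthly_drug_cost_from_regimen(0, 1.8)$monthly_cost, 0)
})
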