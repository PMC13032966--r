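test_that("cycle cascade resolves a single active event correctly", {
  p <- immortal_params()
  out <- cycle_event_probabilities("pf_wild_type_1", 62, p, null_lt)
  expect_equal(sum(out$dest), 1)
  expect_equal(unname(out$dest["pf_wild_type_1"]), 1 - 0.026,
               tolerance = 1e-9)
  expect_equal(unname(out$dest["pf_wild_type_0.75"]), 0.026,
               tolerance = 1e-9)
  expect_equal(out$tox_intensity, 0.026, tolerance = 1e-9)
  expect_equal(out$hosp_intensity, 0.026 * 0.6, tolerance = 1e-9)

  prog <- cycle_event_probabilities("progressed", 62, base_params, null_lt)
  expect_equal(unname(prog$dest["dead_progression"]), 0.051,
               tolerance = 1e-9)
  expect_equal(unname(prog$dest["progressed"]), 0.949, tolerance = 1e-9)

  # with every hazard off, any live state self-loops
  p0 <- immortal_params()
  p0$p_tox_variant_std <- 0; p0$p_tox_variant_red <- 0; p0$p_tox_wt_std <- 0
  p0$p_death_progressed <- 0
  for (s in c("pf_variant_1", "pf_wild_type_0.5", "progressed")) {
    d <- cycle_event_probabilities(s, 70, p0, null_lt)$dest
    expect_equal(unname(d[s]), 1, tolerance = 1e-9)
  }

  expect_error(cycle_event_probabilities("dead_background", 62, base_params,
                                         base_lt), "live states")
  expect_error(cycle_event_probabilities("nowhere", 62, base_params,
                                         base_lt), "unknown state")
})

test_that("transition matrices are row-stochastic with absorbing death", {
  set.seed(33)
  for (i in 1:100) {
    p <- sample_parameters()
    M <- build_transition_matrix(sample(0:455, 1), p, base_lt)
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
    for (d in c("dead_background", "dead_treatment", "dead_progression"))
      expect_equal(unname(M[d, d]), 1)
  }
  # toxicity at the floor tier self-loops
  M <- build_transition_matrix(0, base_params, base_lt)
  expect_equal(unname(M["pf_variant_0.5",
                        c("progressed", "dead_background",
                          "dead_treatment")] > 0),
               rep(TRUE, 3))
  off_diag <- M["pf_variant_0.5", setdiff(colnames(M),
                c("pf_variant_0.5", "progressed", "dead_background",
                  "dead_treatment"))]
  expect_true(all(off_diag == 0))
})

test_that("cohort trace conserves occupancy and accumulates death", {
  for (strat in c("genotyping", "no_genotyping")) {
    tr <- run_cohort(strat, base_params, base_lt)
    occ <- as.matrix(tr$cycles[, model_states()$name])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
    expect_true(all(occ >= 0))
    dead <- rowSums(occ[, c("dead_background", "dead_treatment",
                            "dead_progression")])
    expect_true(all(diff(dead) >= -1e-14))
    expect_true(all(tr$cycles$qaly <= tr$cycles$ly + 1e-14))
    expect_true(all(tr$cycles$qaly_disc <= tr$cycles$qaly + 1e-14))
    expect_true(all(tr$cycles$cost_disc <= tr$cycles$cost + 1e-14))
    expect_lte(tr$totals$qaly, tr$totals$ly)
    expect_lte(tr$totals$cost, tr$totals$cost_undisc)
    expect_equal(tr$totals$cost,
                 tr$totals$cost_drug + tr$totals$cost_hosp +
                   tr$totals$cost_test, tolerance = 1e-9)
  }
})

test_that("zero prevalence makes the arms identical up to the test cost", {
  p <- base_params
  p$p_variant <- 0
  a <- run_cohort("no_genotyping", p, base_lt)
  b <- run_cohort("genotyping", p, base_lt)
  expect_equal(b$totals$cost - a$totals$cost, 174.81)
  expect_equal(a$totals$qaly, b$totals$qaly, tolerance = 1e-12)
  expect_equal(a$totals$ly, b$totals$ly, tolerance = 1e-12)
})

test_that("immortal non-progressing cohort earns the annuity value", {
  p <- immortal_params()
  p$p_tox_variant_std <- 0; p$p_tox_variant_red <- 0; p$p_tox_wt_std <- 0
  p$u_pf <- 1
  tr <- run_cohort("no_genotyping", p, null_lt, horizon_age = 80)
  n_cyc <- (80 - 62) * 12
  expect_equal(tr$totals$ly, annuity_years(n_cyc, 0.03), tolerance = 1e-9)
  expect_equal(tr$totals$qaly, tr$totals$ly, tolerance = 1e-9)
  expect_equal(tr$totals$ly_undisc, n_cyc / 12, tolerance = 1e-9)
})

test_that("undiscounted progressed sojourn matches the geometric mean", {
  # no discounting, no background or treatment mortality: everyone
  # eventually progresses and stays 1/p_death_progressed months
  p <- immortal_params()
  p$p_progress <- 0.11
  p$p_death_progressed <- 0.051
  p$discount_rate_annual <- 0
  tr <- run_cohort("no_genotyping", p, null_lt, horizon_age = 200,
                   min_alive = 1e-12)
  months_prog <- sum(tr$cycles$progressed)
  expect_equal(months_prog, 1 / 0.051, tolerance = 1e-3)
})

test_that("trace export writes one row per cycle", {
  tr <- run_cohort("genotyping", base_params, base_lt)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), tr$n_cycles)
  expect_true(all(model_states()$name %in% names(back)))
  lean <- run_cohort("genotyping", base_params, base_lt, keep_trace = FALSE)
  expect_error(write_trace(lean, path), "keep_trace")
  expect_equal(lean$totals, tr$totals)
})
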