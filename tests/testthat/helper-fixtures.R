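# Shared fixtures: built once per test run, all in code.

base_params <- default_parameters()
base_lt <- default_lifetable()

# life table with (numerically) zero background mortality, for closed-form
# checks; q stays > 0 so table invariants hold
null_lt <- gompertz_lifetable(a = 1e-12, b = 1e-12)

# parameters with every competing risk switched off
immortal_params <- function(p = default_parameters()) {
  p$p_progress <- 0
  p$p_trtdeath_variant_std <- 0
  p$p_trtdeath_variant_red <- 0
  p$p_trtdeath_wt_std <- 0
  validate_parameters(p)
}

# discounted annuity value (in years) of n monthly cycles with payments of
# 1/12 booked at cycle start: independent closed form for trace totals
annuity_years <- function(n_cycles, annual_rate) {
  v <- (1 + annual_rate)^(-1 / 12)
  sum(v^(0:(n_cycles - 1))) / 12
}
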