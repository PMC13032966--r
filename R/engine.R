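#' Model state space
#'
#' The expanded health-state space: progression-free stratified by genotype
#' and dose tier (6 states), a single Progressed state, and three
#' cause-tagged absorbing death states (background, treatment-related,
#' post-progression disease death).
#'
#' @return A data.frame with one row per state: `name`, `type`
#'   (`pf`/`progressed`/`dead`), `genotype`, `tier`.
#' @export
model_states <- function() {
  pf <- expand.grid(tier = c(1.0, 0.75, 0.5),
                    genotype = c("variant", "wild_type"),
                    stringsAsFactors = FALSE)
  data.frame(
    name = c(sprintf("pf_%s_%g", pf$genotype, pf$tier),
             "progressed", "dead_background", "dead_treatment",
             "dead_progression"),
    type = c(rep("pf", 6), "progressed", rep("dead", 3)),
    genotype = c(pf$genotype, rep(NA, 4)),
    tier = c(pf$tier, rep(NA, 4)),
    stringsAsFactors = FALSE
  )
}

state_index <- function(name) match(name, model_states()$name)

# Per-state cascade inputs that do not depend on age: treatment-death,
# progression, toxicity, hospitalization-given-toxicity, toxicity
# destination, drug cost, utility, alive flag.
state_constants <- function(params) {
  st <- model_states()
  n <- nrow(st)
  out <- list(p_td = numeric(n), p_prog = numeric(n), p_tox = numeric(n),
              p_hosp = numeric(n), tox_dest = seq_len(n),
              cost_drug = numeric(n), util = numeric(n),
              alive = as.numeric(st$type != "dead"))
  for (i in seq_len(n)) {
    if (st$type[i] == "pf") {
      g <- st$genotype[i]; d <- st$tier[i]
      out$p_td[i] <- treatment_death_probability(g, d, params)
      out$p_prog[i] <- params$p_progress
      out$p_tox[i] <- toxicity_probability(g, d, params)
      out$p_hosp[i] <- hospitalization_probability(g, d, params)
      out$tox_dest[i] <-
        state_index(sprintf("pf_%s_%g", g, next_tier_after_toxicity(d)))
      out$cost_drug[i] <- drug_cost_per_cycle(d, params)
      out$util[i] <- params$u_pf
    } else if (st$type[i] == "progressed") {
      out$util[i] <- params$u_prog
    }
  }
  out
}

#' One-cycle event probabilities from a live state
#'
#' Applies the model's fixed competing-event cascade to a single occupant
#' of a live state at a given age. Within one monthly cycle, events are
#' mutually exclusive and resolved in a fixed conditional order:
#' (1) background death; among survivors (2) treatment-related death
#' (progression-free states only); among survivors (3) disease progression,
#' or post-progression death from the Progressed state; (4) among
#' progression-free non-progressors, grade 3/4 toxicity, which moves the
#' occupant to the next-lower dose tier (the 0.5 floor is absorbing) and
#' carries a hospitalization intensity of `p_hosp * p_tox`. Residual mass
#' self-loops. Disease death occurs only from the Progressed state.
#'
#' @param state A live state name (see [model_states()]).
#' @param age Attained age in years.
#' @param params A `dpyd_params`.
#' @param lt A `life_table`.
#' @return List with `dest` (named destination probabilities summing to 1),
#'   `tox_intensity` and `hosp_intensity` (expected events per occupant).
#' @export
cycle_event_probabilities <- function(state, age, params,
                                      lt = default_lifetable()) {
  st <- model_states()
  i <- state_index(state)
  if (is.na(i)) stop("unknown state: ", state, call. = FALSE)
  if (st$type[i] == "dead")
    stop("cycle_event_probabilities is defined for live states only",
         call. = FALSE)
  k <- state_constants(params)
  m_bg <- monthly_background_mortality(lt, age)
  dest <- stats::setNames(numeric(nrow(st)), st$name)
  tox <- 0
  if (st$type[i] == "pf") {
    s1 <- 1 - m_bg
    s2 <- s1 * (1 - k$p_td[i])
    s3 <- s2 * (1 - k$p_prog[i])
    dest["dead_background"] <- m_bg
    dest["dead_treatment"] <- s1 * k$p_td[i]
    dest["progressed"] <- s2 * k$p_prog[i]
    tox <- s3 * k$p_tox[i]
    dest[k$tox_dest[i]] <- dest[k$tox_dest[i]] + tox
    dest[i] <- dest[i] + s3 * (1 - k$p_tox[i])
  } else {
    dest["dead_background"] <- m_bg
    dest["dead_progression"] <- (1 - m_bg) * params$p_death_progressed
    dest["progressed"] <- (1 - m_bg) * (1 - params$p_death_progressed)
  }
  list(dest = dest, tox_intensity = tox,
       hosp_intensity = tox * k$p_hosp[i])
}

# Transition matrix plus event-intensity vectors for one background
# mortality level; k = state_constants(params).
cycle_matrix <- function(k, m_bg, p_death_progressed) {
  n <- length(k$p_td)
  M <- matrix(0, n, n)
  i_bg <- n - 2L; i_trt <- n - 1L; i_prog_death <- n; i_progressed <- n - 3L
  s1 <- 1 - m_bg
  tox_int <- numeric(n)
  for (i in seq_len(n - 3L)) {          # live states
    if (i == i_progressed) {
      M[i, i_bg] <- m_bg
      M[i, i_prog_death] <- s1 * p_death_progressed
      M[i, i] <- s1 * (1 - p_death_progressed)
    } else {
      s2 <- s1 * (1 - k$p_td[i])
      s3 <- s2 * (1 - k$p_prog[i])
      M[i, i_bg] <- m_bg
      M[i, i_trt] <- s1 * k$p_td[i]
      M[i, i_progressed] <- s2 * k$p_prog[i]
      tox_int[i] <- s3 * k$p_tox[i]
      j <- k$tox_dest[i]
      M[i, j] <- M[i, j] + tox_int[i]
      M[i, i] <- M[i, i] + s3 * (1 - k$p_tox[i])
    }
  }
  M[i_bg, i_bg] <- 1; M[i_trt, i_trt] <- 1
  M[i_prog_death, i_prog_death] <- 1
  list(M = M, tox_int = tox_int, hosp_int = tox_int * k$p_hosp)
}

#' Build the one-cycle transition matrix
#'
#' Assembles [cycle_event_probabilities()] over all states for the cycle's
#' attained age. Rows sum to one; dead rows are unit self-loops. The matrix
#' depends on the cycle only through the integer attained age (background
#' mortality lookup); strategies share the same matrix and differ only in
#' initial occupancy and the test cost.
#'
#' @param cycle_index Zero-based cycle number (monthly cycles from the start
#'   age).
#' @param params A `dpyd_params`.
#' @param lt A `life_table`.
#' @return A 10 x 10 row-stochastic matrix with state dimnames.
#' @export
build_transition_matrix <- function(cycle_index, params,
                                    lt = default_lifetable()) {
  stopifnot(cycle_index >= 0)
  age <- params$start_age + cycle_index / 12
  k <- state_constants(params)
  m_bg <- monthly_background_mortality(lt, age)
  M <- cycle_matrix(k, m_bg, params$p_death_progressed)$M
  dimnames(M) <- list(model_states()$name, model_states()$name)
  M
}

# Age-dependent transition matrices and event intensities, shared between
# the two strategy arms (they differ only in initial occupancy and the
# test cost); built once per parameter set.
cohort_precompute <- function(params, lt, horizon_age = 100) {
  k <- state_constants(params)
  n_cycles <- ceiling((horizon_age - params$start_age) * 12)
  ages <- pmin(pmax(floor(params$start_age + (0:(n_cycles - 1)) / 12),
                    min(lt$age)), max(lt$age))
  uages <- sort(unique(ages))
  per_age <- lapply(uages, function(a)
    cycle_matrix(k, 1 - (1 - lt$q_annual[match(a, lt$age)])^(1 / 12),
                 params$p_death_progressed))
  list(k = k, per_age = per_age, age_idx = match(ages, uages),
       n_cycles = n_cycles)
}

#' Run the cohort state-transition model for one strategy
#'
#' Propagates a unit cohort from the start age through monthly cycles until
#' the horizon age or until live occupancy is exhausted. The cohort starts
#' fully progression-free, split by genotype at the variant prevalence and
#' placed at the strategy's initial dose tier; the genotyping arm bears the
#' test cost once, at cycle 0, undiscounted. Each cycle books (at cycle
#' start, discounted by `(1 + r)^(-t/12)`): life-years and state utility
#' from current occupancy, drug cost from progression-free occupancy,
#' toxicity and hospitalization event intensities from the transition
#' cascade with hospitalization cost per event, a one-month toxicity
#' disutility per toxicity event, and a one-week hospitalization disutility
#' per hospitalization.
#'
#' @param strategy `"genotyping"` or `"no_genotyping"`.
#' @param params A `dpyd_params`.
#' @param lt A `life_table`.
#' @param horizon_age Stop age (default 100).
#' @param min_alive Stop early once live occupancy falls below this mass.
#' @param half_cycle Apply a half-cycle (trapezoid) correction to the
#'   state-occupancy reward streams. Off by default.
#' @param keep_trace Keep the full per-cycle trace (set `FALSE` inside
#'   Monte-Carlo loops for speed).
#' @param precomp Optional precomputed age-dependent transition structure,
#'   for sharing between the two arms of one parameter set (internal
#'   optimisation; built automatically when `NULL`).
#' @return A `cohort_trace`: list with `strategy`, `totals` (discounted and
#'   undiscounted cost/QALY/LY and the cost breakdown) and, if requested,
#'   `cycles`, a per-cycle data.frame of occupancy, event intensities and
#'   reward increments.
#' @examples
#' tr <- run_cohort("no_genotyping", default_parameters())
#' tr$totals$cost
#' @export
run_cohort <- function(strategy, params, lt = default_lifetable(),
                       horizon_age = 100, min_alive = 1e-8,
                       half_cycle = FALSE, keep_trace = TRUE,
                       precomp = NULL) {
  strategy <- match.arg(strategy, c("genotyping", "no_genotyping"))
  if (horizon_age <= params$start_age)
    stop("horizon_age must exceed the start age", call. = FALSE)
  st <- model_states()
  n <- nrow(st)
  if (is.null(precomp)) precomp <- cohort_precompute(params, lt, horizon_age)
  k <- precomp$k
  per_age <- precomp$per_age
  age_idx <- precomp$age_idx
  n_cycles <- precomp$n_cycles

  v0 <- numeric(n)
  v0[state_index(sprintf("pf_variant_%g", initial_tier(strategy, "variant")))] <-
    params$p_variant
  v0[state_index(sprintf("pf_wild_type_%g", initial_tier(strategy, "wild_type")))] <-
    1 - params$p_variant

  r_month <- (1 + params$discount_rate_annual)^(-1 / 12)

  occ <- matrix(0, n_cycles + 1, n); occ[1, ] <- v0
  tox_e <- hosp_e <- numeric(n_cycles)
  c_drug <- c_hosp <- c_test <- qaly <- ly <- numeric(n_cycles)
  disc <- r_month^(0:(n_cycles - 1))

  v <- v0
  t_used <- 0L
  for (t in seq_len(n_cycles)) {
    pa <- per_age[[age_idx[t]]]
    v_next <- as.numeric(v %*% pa$M)
    v_occ <- if (half_cycle) (v + v_next) / 2 else v
    tox_e[t] <- sum(v * pa$tox_int)
    hosp_e[t] <- sum(v * pa$hosp_int)
    ly[t] <- sum(v_occ * k$alive) / 12
    qaly[t] <- sum(v_occ * k$util) / 12 -
      tox_e[t] * params$disutil_tox / 12 -
      hosp_e[t] * params$disutil_hosp * 7 / 365.25
    c_drug[t] <- sum(v_occ * k$cost_drug)
    c_hosp[t] <- hosp_e[t] * params$cost_hosp
    if (t == 1L && strategy == "genotyping") c_test[t] <- params$cost_test
    occ[t + 1, ] <- v_next
    v <- v_next
    t_used <- t
    if (sum(v * k$alive) < min_alive) break
  }
  idx <- seq_len(t_used)
  d <- disc[idx]
  cost_cycle <- c_drug[idx] + c_hosp[idx] + c_test[idx]
  totals <- list(
    cost = sum(cost_cycle * d),
    cost_drug = sum(c_drug[idx] * d),
    cost_hosp = sum(c_hosp[idx] * d),
    cost_test = sum(c_test[idx] * d),
    qaly = sum(qaly[idx] * d),
    ly = sum(ly[idx] * d),
    cost_undisc = sum(cost_cycle),
    qaly_undisc = sum(qaly[idx]),
    ly_undisc = sum(ly[idx]),
    tox_events = sum(tox_e[idx]),
    hosp_events = sum(hosp_e[idx])
  )
  out <- list(strategy = strategy, totals = totals, n_cycles = t_used,
              params = params)
  if (keep_trace) {
    cyc <- data.frame(cycle = 0:(t_used - 1),
                      age = params$start_age + (0:(t_used - 1)) / 12)
    o <- occ[idx, , drop = FALSE]
    colnames(o) <- st$name
    cyc <- cbind(cyc, o)
    cyc$tox_events <- tox_e[idx]
    cyc$hosp_events <- hosp_e[idx]
    cyc$cost <- cost_cycle
    cyc$cost_disc <- cost_cycle * d
    cyc$qaly <- qaly[idx]
    cyc$qaly_disc <- qaly[idx] * d
    cyc$ly <- ly[idx]
    cyc$ly_disc <- ly[idx] * d
    out$cycles <- cyc
    out$final_occupancy <- stats::setNames(occ[t_used + 1, ], st$name)
  }
  class(out) <- "cohort_trace"
  out
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> strategy = %s, %d monthly cycles\n",
              x$strategy, x$n_cycles))
  cat(sprintf("  discounted: cost $%.2f, QALY %.4f, LY %.4f\n",
              x$totals$cost, x$totals$qaly, x$totals$ly))
  cat(sprintf("  events per cohort member: %.4f toxicities, %.4f hospitalizations\n",
              x$totals$tox_events, x$totals$hosp_events))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' @param trace A `cohort_trace` run with `keep_trace = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (is.null(trace$cycles))
    stop("trace was run with keep_trace = FALSE", call. = FALSE)
  utils::write.csv(trace$cycles, path, row.names = FALSE)
  invisible(path)
}
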