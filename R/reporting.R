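#' Standardized analysis runners with result artifacts
#'
#' Each runner loads parameters from an optional YAML config, executes one
#' analysis stage, writes its results to `outdir` as CSV/JSON, dumps the
#' full parameter set alongside for provenance, and records a run manifest
#' (`manifest.json`: command, config hash, seed, package version,
#' timestamp, output file list). Re-running with the same config and seed
#' reproduces the result files byte-for-byte (the manifest's timestamp
#' aside).
#'
#' @param config Path/string/list of parameter overrides for
#'   [load_parameters()], or `NULL` for the base case.
#' @param outdir Output directory (created if needed).
#' @param lt A `life_table`.
#' @return Invisibly, the analysis result object; files as side effect.
#' @name reporting
NULL

write_manifest <- function(command, outdir, config, seed, files) {
  manifest <- list(
    command = command,
    config_hash = config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("dpydcea")),
    schema_version = 1L,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

config_hash <- function(config) {
  p <- load_parameters(config)
  # order-stable digest of the resolved parameter values, dependency-free
  txt <- paste(param_fields(),
               vapply(param_fields(), function(f) sprintf("%.15g", p[[f]]),
                      ""),
               collapse = ";")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)))
}

prepare_outdir <- function(outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  if (file.access(outdir, 2) != 0)
    stop("output directory not writable: ", outdir, call. = FALSE)
  invisible(outdir)
}

dump_params <- function(p, outdir) {
  jsonlite::write_json(unclass(p)[param_fields()],
                       file.path(outdir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  "parameters.json"
}

#' @rdname reporting
#' @export
run_base_case <- function(config = NULL, outdir, lt = default_lifetable()) {
  prepare_outdir(outdir)
  p <- load_parameters(config)
  ev <- evaluate_strategies(p, lt)
  tab <- results_table(ev)
  utils::write.csv(tab, file.path(outdir, "base_case.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(no_genotyping = unclass(ev$no_genotyping),
         genotyping = unclass(ev$genotyping),
         comparison = unclass(ev$comparison)),
    file.path(outdir, "base_case.json"), auto_unbox = TRUE, digits = NA)
  files <- c("base_case.csv", "base_case.json", dump_params(p, outdir))
  write_manifest("basecase", outdir, config, NA, files)
  invisible(ev)
}

#' @rdname reporting
#' @param top Number of tornado entries reported.
#' @export
run_dsa <- function(config = NULL, outdir, lt = default_lifetable(),
                    top = 6L) {
  prepare_outdir(outdir)
  p <- load_parameters(config)
  tor <- tornado(default_uncertainty_specs(p), p, lt, top = top)
  utils::write.csv(tor, file.path(outdir, "tornado.csv"), row.names = FALSE)
  files <- c("tornado.csv", dump_params(p, outdir))
  write_manifest("dsa", outdir, config, NA, files)
  invisible(tor)
}

#' @rdname reporting
#' @param n_points Prevalence grid size.
#' @export
run_prevalence <- function(config = NULL, outdir,
                           lt = default_lifetable(), n_points = 11L) {
  prepare_outdir(outdir)
  p <- load_parameters(config)
  sweep <- prevalence_sweep(base = p, lt = lt, n_points = n_points)
  utils::write.csv(sweep, file.path(outdir, "prevalence_sweep.csv"),
                   row.names = FALSE)
  files <- c("prevalence_sweep.csv", dump_params(p, outdir))
  write_manifest("prevalence", outdir, config, NA, files)
  invisible(sweep)
}

#' @rdname reporting
#' @param n Monte-Carlo iterations.
#' @param seed Integer seed for the sampled parameter draws.
#' @export
run_psa_analysis <- function(config = NULL, outdir, n = 10000, seed = 1L,
                             lt = default_lifetable()) {
  prepare_outdir(outdir)
  p <- load_parameters(config)
  psa <- run_psa(n, seed = seed, base = p, lt = lt)
  scatter <- psa$draws[, c("iteration", "inc_cost", "inc_qaly", "icer",
                           "nmb", "classification")]
  utils::write.csv(scatter, file.path(outdir, "psa_scatter.csv"),
                   row.names = FALSE)
  utils::write.csv(ceac(psa), file.path(outdir, "ceac.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n = psa$n, seed = psa$seed, wtp = psa$wtp,
         fraction_cost_effective = psa$fraction_cost_effective,
         fraction_cost_saving = psa$fraction_cost_saving,
         mean_inc_cost = mean(psa$draws$inc_cost),
         mean_inc_qaly = mean(psa$draws$inc_qaly)),
    file.path(outdir, "psa_summary.json"), auto_unbox = TRUE, digits = NA)
  files <- c("psa_scatter.csv", "ceac.csv", "psa_summary.json",
             dump_params(p, outdir))
  write_manifest("psa", outdir, config, seed, files)
  invisible(psa)
}

#' @rdname reporting
#' @param n_patients Microsimulation size per arm.
#' @export
run_validation <- function(config = NULL, outdir, n_patients = 20000,
                           seed = 1L, lt = default_lifetable()) {
  prepare_outdir(outdir)
  p <- load_parameters(config)
  set.seed(seed)
  v <- validate_against_cohort(n_patients, p, lt)
  utils::write.csv(v, file.path(outdir, "validation.csv"),
                   row.names = FALSE)
  files <- c("validation.csv", dump_params(p, outdir))
  write_manifest("validate", outdir, config, seed, files)
  invisible(v)
}
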