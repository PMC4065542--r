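#' @title Reporting commands
#' @name reporting
#' @description
#' Batch entry points mirroring the analysis surface: base case, PSA, one-way
#' sensitivity analysis and microsimulation validation, each writing CSV
#' artifacts plus a JSON run manifest into an output directory. A thin
#' command-line wrapper over these functions ships at
#' `system.file("scripts", "ami_cea.R", package = "amicea")`.
NULL

.load_config <- function(config) {
  if (is.null(config)) ami_parameters() else load_parameters(config)
}

.write_manifest <- function(outdir, command, config, seed = NA_integer_) {
  manifest <- list(
    command = command,
    config = if (is.null(config)) "builtin-defaults" else normalizePath(config),
    config_md5 = if (is.null(config)) NA_character_
                 else unname(tools::md5sum(config)),
    seed = seed,
    package_version = as.character(utils::packageVersion("amicea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  outdir
}

#' Base-case report
#'
#' Writes `basecase.csv` (per-strategy discounted cost/LY/QALY and all
#' pairwise increments with ICERs per LYG and per QALY) and a run manifest.
#'
#' @param config path to a parameter YAML/JSON file, or `NULL` for defaults.
#' @param outdir output directory (created if absent).
#' @param settings a [cea_settings()] object.
#' @return The `cea_table`, invisibly.
#' @export
cmd_basecase <- function(config = NULL, outdir, settings = cea_settings()) {
  .ensure_outdir(outdir)
  m <- cea_model(.load_config(config), settings)
  write_cea_csv(m$cea, file.path(outdir, "basecase.csv"))
  .write_manifest(outdir, "basecase", config)
  invisible(m$cea)
}

#' Probabilistic sensitivity analysis report
#'
#' Writes `psa_draws.csv` (iteration, strategy, cost, ly, qaly),
#' `ceac.csv` (wtp, strategy, probability), `psa_summary.csv` and a manifest.
#'
#' @inheritParams cmd_basecase
#' @param n_iter Monte-Carlo iterations (default 1000).
#' @param seed integer seed.
#' @param wtp_max,wtp_step willingness-to-pay grid (default 0..20000 by 500).
#' @return The `psa_result`, invisibly.
#' @export
cmd_psa <- function(config = NULL, outdir, n_iter = 1000L, seed = 1L,
                    wtp_max = 20000, wtp_step = 500,
                    settings = cea_settings()) {
  .ensure_outdir(outdir)
  params <- .load_config(config)
  psa <- run_psa(params, n_iter = n_iter, seed = seed, settings = settings)
  draws <- do.call(rbind, lapply(seq_along(psa$strategies), function(j) {
    data.frame(iteration = seq_len(psa$n_iter), strategy = psa$strategies[j],
               cost = psa$cost[, j], ly = psa$ly[, j], qaly = psa$qaly[, j],
               row.names = NULL)
  }))
  utils::write.csv(draws, file.path(outdir, "psa_draws.csv"), row.names = FALSE)
  curve <- ceac(psa, seq(0, wtp_max, by = wtp_step))
  long <- do.call(rbind, lapply(psa$strategies, function(s) {
    data.frame(wtp = curve$wtp, strategy = s, probability = curve[[s]],
               row.names = NULL)
  }))
  utils::write.csv(long, file.path(outdir, "ceac.csv"), row.names = FALSE)
  utils::write.csv(psa_summary(psa)$summary,
                   file.path(outdir, "psa_summary.csv"), row.names = FALSE)
  if (psa$n_rejected > 0) {
    message("cmd_psa: ", psa$n_rejected, " parameter draws rejected and redrawn")
  }
  .write_manifest(outdir, "psa", config, seed)
  invisible(psa)
}

#' One-way sensitivity (tornado) report
#'
#' Writes `tornado.csv` (parameter, low, high, icer_low, icer_high, span;
#' ranked, top `top_n`) and a manifest. Warns when every parameter is fixed.
#'
#' @inheritParams cmd_basecase
#' @param comparison strategy pair `c(new, reference)`.
#' @param top_n rows retained after tornado ranking.
#' @return The ranked `owsa_result`, invisibly.
#' @export
cmd_owsa <- function(config = NULL, outdir, comparison = c("hsTnT", "cTnT"),
                     top_n = 10L, settings = cea_settings()) {
  .ensure_outdir(outdir)
  rows <- run_owsa(.load_config(config), comparison, settings = settings)
  if (!nrow(rows)) {
    warning("cmd_owsa: all parameters fixed; tornado is empty")
    ranked <- rows
  } else {
    ranked <- tornado_rank(rows, top_n)
  }
  utils::write.csv(ranked, file.path(outdir, "tornado.csv"), row.names = FALSE)
  .write_manifest(outdir, "owsa", config)
  invisible(ranked)
}

#' Microsimulation validation report
#'
#' Simulates a patient-level cohort per strategy, compares the cohort means
#' to the analytic tree, and writes `simulation.csv` (per strategy and
#' quantity: simulated mean, expectation, Monte-Carlo SE, z-score, verdict)
#' plus a manifest.
#'
#' @inheritParams cmd_basecase
#' @param n cohort size per strategy.
#' @param seed integer seed.
#' @return Data frame of the validation table, invisibly.
#' @export
cmd_simulate <- function(config = NULL, outdir, n = 200000L, seed = 1L,
                         settings = cea_settings()) {
  .ensure_outdir(outdir)
  params <- .load_config(config)
  strategies <- ami_strategies(params)
  out <- do.call(rbind, lapply(seq_along(strategies), function(i) {
    s <- strategies[[i]]
    tree <- evaluate_strategy(s, params, settings)
    cohort <- simulate_cohort(params, s, n = n, seed = seed + i, settings = settings)
    rep <- compare_to_tree(cohort, tree)
    cbind(strategy = s$name, rep$table,
          verdict = if (rep$pass) "pass" else "fail")
  }))
  utils::write.csv(out, file.path(outdir, "simulation.csv"), row.names = FALSE)
  .write_manifest(outdir, "simulate", config, seed)
  invisible(out)
}
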