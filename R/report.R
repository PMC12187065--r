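#' Run a full screening analysis and build a report
#'
#' Top-level convenience wrapper: assembles parameters (defaults plus
#' optional overrides), builds or loads the life table, runs the
#' deterministic base case and optionally the probabilistic sensitivity
#' analysis, and returns a report object whose print method mirrors the
#' per-arm QALY/cost, increment, ICER and NMB layout of a
#' cost-effectiveness results table. With `out_dir` set, the cohort
#' traces, PSA draws and a JSON-like summary are written as delimited
#' text.
#'
#' @param cohort_age 70 or 80.
#' @param scenario `"symptomatic_trigger"` or `"early_intervention"`.
#' @param overrides Nested override list (see [modify_parameters()]).
#' @param lifetable A `lifetable`, or `NULL` to use
#'   [synthesize_lifetable()] defaults.
#' @param psa Logical: run the PSA.
#' @param n_reps PSA replications (default from the parameter set).
#' @param seed Master RNG seed.
#' @param out_dir Optional output directory for artifact files.
#' @return An `as_report` list: `meta`, `deterministic`, optionally
#'   `psa` (`as_psa`) and `psa_summary`, and `files`.
#' @export
run_report <- function(cohort_age = 80,
                       scenario = c("symptomatic_trigger",
                                    "early_intervention"),
                       overrides = NULL, lifetable = NULL, psa = FALSE,
                       n_reps = NULL, seed = 1L, out_dir = NULL) {
  scenario <- match.arg(scenario)
  params <- modify_parameters(default_parameters(cohort_age), overrides)
  if (!is.null(n_reps)) params$econ$n_psa_reps <- n_reps
  params$econ$rng_seed <- seed
  lt <- lifetable %||% synthesize_lifetable()
  pair <- strategy_pair(cohort_age, scenario, params)

  det <- evaluate_pair(pair, params, lt, keep_traces = !is.null(out_dir))
  report <- list(
    meta = list(cohort_age = cohort_age, scenario = scenario, seed = seed,
                n_reps = if (psa) params$econ$n_psa_reps else 0L,
                discount_rate = params$econ$discount_rate_annual,
                wtp = params$econ$wtp_per_qaly,
                overridden = names(unlist(overrides))),
    deterministic = det[setdiff(names(det), "traces")],
    files = character(0)
  )

  if (psa) {
    psa_res <- run_psa(pair, params, lt, n_reps = params$econ$n_psa_reps,
                       seed = seed)
    report$psa <- psa_res
    report$psa_summary <- summary(psa_res)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- sprintf("age%d_%s", cohort_age, scenario)
    f_trace_s <- file.path(out_dir, paste0("trace_screen_", tag, ".tsv"))
    f_trace_n <- file.path(out_dir, paste0("trace_noscreen_", tag, ".tsv"))
    utils::write.table(as.data.frame(det$traces$screen), f_trace_s,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(det$traces$noscreen), f_trace_n,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$files <- c(f_trace_s, f_trace_n)
    if (psa) {
      f_draws <- file.path(out_dir, paste0("psa_draws_", tag, ".tsv"))
      utils::write.table(report$psa$draws, f_draws, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      report$files <- c(report$files, f_draws)
    }
  }
  structure(report, class = "as_report")
}

#' @export
print.as_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Aortic stenosis screening at %d years (%s)\n", m$cohort_age,
              m$scenario))
  cat(sprintf("  discount %.1f%%/yr, WTP $%.0f/QALY, seed %d\n",
              100 * m$discount_rate, m$wtp, m$seed))
  d <- x$deterministic
  cat("Deterministic base case:\n")
  cat(sprintf("  %-12s %12s %12s %12s\n", "", "Screening", "No screening",
              "Incremental"))
  cat(sprintf("  %-12s %12.2f %12.2f %12.4f\n", "QALY", d$screen$qaly,
              d$noscreen$qaly, d$delta_qaly))
  cat(sprintf("  %-12s %12s %12s %12s\n", "Cost",
              sprintf("$%.0f", d$screen$cost),
              sprintf("$%.0f", d$noscreen$cost),
              sprintf("$%.0f", d$delta_cost)))
  cat(sprintf("  ICER %s per QALY; NMB %s\n",
              if (is.na(d$icer)) "undefined" else sprintf("$%.0f", d$icer),
              sprintf("$%.0f", d$nmb)))
  if (!is.null(x$psa_summary)) print(x$psa_summary)
  if (length(x$files)) {
    cat("Artifacts:\n")
    for (f in x$files) cat(" ", f, "\n")
  }
  invisible(x)
}
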