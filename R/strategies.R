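#' Initial state occupancy for a screened or unscreened cohort
#'
#' Places the screen-positive mass (screen-positive rate split across
#' mild/moderate/severe asymptomatic disease) in the diagnosed states for
#' the screened arm or the undiagnosed states for the unscreened arm; the
#' remainder starts in the general population. Baseline severe disease
#' starts asymptomatic; symptoms arise only through the monthly
#' symptom-onset transition.
#'
#' @param screening Logical: screened arm?
#' @param sp The `screening` component of an `as_params` object.
#' @return Named occupancy vector over [state_names()], summing to 1.
#' @examples
#' p <- default_parameters(80)
#' initial_distribution(TRUE, p$screening)[["DxSevAsym"]]   # 0.228 * 0.271
#' initial_distribution(FALSE, p$screening)[["UndxSevAsym"]]
#' @export
initial_distribution <- function(screening, sp) {
  split <- sp$severity_split
  if (abs(sum(split) - 1) > 1e-9) {
    stop("severity_split must sum to 1", call. = FALSE)
  }
  v <- stats::setNames(numeric(.N_STATES), state_names())
  spr <- sp$screen_positive_rate
  v["GeneralPop"] <- 1 - spr
  target <- if (screening) c("DxMild", "DxMod", "DxSevAsym") else
    c("UndxMild", "UndxMod", "UndxSevAsym")
  v[target] <- spr * split
  v
}

#' Define a screening-versus-no-screening comparison
#'
#' Pairs the screened and unscreened initial distributions for a cohort
#' age and treatment scenario. Both arms use identical parameters; they
#' differ only in the initial placement of prevalent disease (diagnosed
#' versus undiagnosed) and the one-time screening TTE fee charged to the
#' entire screened cohort (screen-negatives included) at cycle 0.
#'
#' @param cohort_age 70 or 80 (selects [default_parameters()] when
#'   `params` is not given).
#' @param scenario `"symptomatic_trigger"` or `"early_intervention"`.
#' @param params Optional `as_params`; defaults to
#'   `default_parameters(cohort_age)`.
#' @return A `strategy_pair`: list with `cohort_age`, `scenario`,
#'   `screened_initial`, `unscreened_initial`.
#' @export
strategy_pair <- function(cohort_age,
                          scenario = c("symptomatic_trigger",
                                       "early_intervention"),
                          params = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(params)) params <- default_parameters(cohort_age)
  structure(
    list(cohort_age = params$screening$cohort_age_years,
         scenario = scenario,
         screened_initial = initial_distribution(TRUE, params$screening),
         unscreened_initial = initial_distribution(FALSE, params$screening)),
    class = "strategy_pair"
  )
}

#' Evaluate a screening comparison deterministically
#'
#' Runs the cohort model for both arms of a strategy pair under one
#' parameter set and returns per-arm discounted totals, increments, the
#' ICER and the net monetary benefit at the configured willingness-to-pay.
#'
#' @param pair A `strategy_pair`.
#' @param params An `as_params` object (shared by both arms).
#' @param lt A `lifetable`.
#' @param keep_traces Logical: retain the two `cohort_trace` objects.
#' @return A list: `screen` and `noscreen` (each `cost`, `qaly`),
#'   `delta_cost`, `delta_qaly`, `icer`, `nmb`, and optionally `traces`.
#' @export
evaluate_pair <- function(pair, params, lt, keep_traces = FALSE) {
  pc <- precompute_cycles(params, lt, pair$scenario)
  tr_s <- run_cohort(pair$screened_initial, params, lt, pair$scenario,
                     screening = TRUE, precomp = pc)
  tr_n <- run_cohort(pair$unscreened_initial, params, lt, pair$scenario,
                     screening = FALSE, precomp = pc)
  dc <- tr_s$cum_cost - tr_n$cum_cost
  dq <- tr_s$cum_qaly - tr_n$cum_qaly
  out <- list(
    screen = list(cost = tr_s$cum_cost, qaly = tr_s$cum_qaly),
    noscreen = list(cost = tr_n$cum_cost, qaly = tr_n$cum_qaly),
    delta_cost = dc,
    delta_qaly = dq,
    icer = icer(dc, dq),
    nmb = nmb(dc, dq, params$econ$wtp_per_qaly)
  )
  if (keep_traces) out$traces <- list(screen = tr_s, noscreen = tr_n)
  out
}
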