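#' Health states of the screening model
#'
#' The ordered state space of the cohort model: the screened/general
#' population, undiagnosed and diagnosed aortic stenosis by severity
#' (severe split into asymptomatic and symptomatic), a one-cycle TAVR
#' procedure state, the post-TAVR state, twelve tunnelled post-TAVR-stroke
#' months (carrying first-year stroke cost, disutility and mortality), the
#' chronic post-stroke state, and death.
#'
#' @return Character vector of the 25 state names, in matrix order.
#' @export
state_names <- function() {
  c("GeneralPop",
    "UndxMild", "UndxMod", "UndxSevAsym", "UndxSevSym",
    "DxMild", "DxMod", "DxSevAsym", "DxSevSym",
    "TAVRcycle", "PostTAVR",
    paste0("StrokeTunnel", 1:12),
    "StrokeChronic", "Death")
}

# index lookup used throughout the engine
.S <- local({
  s <- c("GeneralPop", "UndxMild", "UndxMod", "UndxSevAsym", "UndxSevSym",
         "DxMild", "DxMod", "DxSevAsym", "DxSevSym", "TAVRcycle", "PostTAVR",
         paste0("StrokeTunnel", 1:12), "StrokeChronic", "Death")
  stats::setNames(seq_along(s), s)
})

.N_STATES <- length(.S)
.STATE_NAMES <- names(.S)
.TUNNEL <- .S[paste0("StrokeTunnel", 1:12)]

#' Per-cycle cost attached to occupancy of each state
#'
#' Monthly surveillance costs for diagnosed disease and monthly post-stroke
#' costs; all other states carry no recurring cost (one-time costs are
#' charged on transitions, see [run_cohort()]).
#'
#' @param params An `as_params` object.
#' @return Named numeric vector over the state space (currency per cycle).
#' @export
state_costs <- function(params) {
  co <- params$costs
  v <- stats::setNames(numeric(.N_STATES), state_names())
  v["DxMild"] <- co$c_mild_m
  v["DxMod"] <- co$c_mod_m
  v["DxSevAsym"] <- co$c_sevdx_m
  v["DxSevSym"] <- co$c_sevdx_m
  v[paste0("StrokeTunnel", 1:12)] <- co$c_stroke_y1_m
  v["StrokeChronic"] <- co$c_stroke_y2_m
  v
}

#' Annual utility attached to each state
#'
#' Asymptomatic states (general population, mild/moderate/severe
#' asymptomatic whether diagnosed or not, post-TAVR without stroke) share
#' the base utility; severe symptomatic disease carries its own lower
#' utility; post-stroke utilities differ in the first year (tunnel) and
#' thereafter. Occupants of the one-cycle TAVR state accrue severe
#' symptomatic utility under the symptomatic-trigger model and base
#' utility under early intervention, where the procedure is elective in
#' asymptomatic patients.
#'
#' @param params An `as_params` object.
#' @param scenario `"symptomatic_trigger"` or `"early_intervention"`.
#' @return Named numeric vector of annual utilities over the state space.
#' @export
state_utilities <- function(params, scenario = "symptomatic_trigger") {
  scenario <- match.arg(scenario, c("symptomatic_trigger", "early_intervention"))
  u <- params$utilities
  v <- stats::setNames(rep(u$u_base, .N_STATES), state_names())
  v[c("UndxSevSym", "DxSevSym")] <- u$u_sevsym
  v["TAVRcycle"] <- if (scenario == "symptomatic_trigger") u$u_sevsym else u$u_base
  v[paste0("StrokeTunnel", 1:12)] <- u$u_stroke_y1
  v["StrokeChronic"] <- u$u_stroke_y2plus
  v["Death"] <- 0
  v
}
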