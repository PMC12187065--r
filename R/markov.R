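#' Monthly transition matrix at a given age
#'
#' Builds the row-stochastic transition matrix over the full state space
#' for one monthly cycle at the given age. Within a cycle, death competes
#' first; conditional on survival, severity progression is resolved before
#' detection, so progression and diagnosis cannot both occur in the same
#' month.
#'
#' State-specific mortality: general-population, diagnosed non-symptomatic
#' and post-TAVR states use life-table mortality (scaled by the
#' severity-specific relative risks, default 1); severe symptomatic
#' disease uses its fixed monthly probability; the post-stroke tunnel and
#' chronic states use life-table mortality scaled by the first-year and
#' subsequent-year stroke relative risks. The TAVR procedure cycle
#' resolves by a fixed split into procedural death, stroke (entering the
#' first tunnel month) and the post-TAVR state (which absorbs the
#' transient non-stroke complications).
#'
#' Under `early_intervention`, diagnosed severe asymptomatic patients
#' proceed to TAVR in the next cycle (conditional on survival) instead of
#' waiting for symptom onset.
#'
#' @param params An `as_params` object.
#' @param lt A `lifetable`.
#' @param age_months Cohort age in months at the start of the cycle.
#' @param scenario `"symptomatic_trigger"` (default) or
#'   `"early_intervention"`.
#' @return A 25 x 25 row-stochastic matrix with dimnames [state_names()].
#' @export
build_matrix <- function(params, lt, age_months,
                         scenario = c("symptomatic_trigger",
                                      "early_intervention")) {
  scenario <- match.arg(scenario)
  tr <- params$transitions
  S <- .S
  P <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(.STATE_NAMES, .STATE_NAMES))

  pd_gp   <- monthly_mortality(lt, age_months, 1)
  pd_mild <- monthly_mortality(lt, age_months, tr$rr_mild)
  pd_mod  <- monthly_mortality(lt, age_months, tr$rr_mod)
  pd_seva <- monthly_mortality(lt, age_months, tr$rr_sevasym)
  pd_t1   <- monthly_mortality(lt, age_months, tr$rr_stroke_y1)
  pd_chr  <- monthly_mortality(lt, age_months, tr$rr_stroke_y2plus)

  chk <- function(state, total) {
    if (total > 1 + 1e-12) {
      stop("transition probabilities out of state ", state, " sum to ",
           format(total), " (> 1) before the residual stay mass",
           call. = FALSE)
    }
  }

  # General population: death, incident mild AS, stay
  s <- 1 - pd_gp
  chk("GeneralPop", pd_gp + s * tr$incidence_gp_to_mild)
  P[S["GeneralPop"], S["Death"]] <- pd_gp
  P[S["GeneralPop"], S["UndxMild"]] <- s * tr$incidence_gp_to_mild
  P[S["GeneralPop"], S["GeneralPop"]] <- s * (1 - tr$incidence_gp_to_mild)

  # Undiagnosed mild/moderate: die, progress, else possibly detected
  undx_nonsev <- function(from, prog_p, to_prog, to_dx, pd) {
    s <- 1 - pd
    det <- tr$p_undx_to_dx_nonsev
    chk(from, pd + s * (prog_p + (1 - prog_p) * det))
    P[S[from], S["Death"]] <<- pd
    P[S[from], S[to_prog]] <<- s * prog_p
    P[S[from], S[to_dx]] <<- s * (1 - prog_p) * det
    P[S[from], S[from]] <<- s * (1 - prog_p) * (1 - det)
  }
  undx_nonsev("UndxMild", tr$p_mild_to_mod, "UndxMod", "DxMild", pd_mild)
  undx_nonsev("UndxMod", tr$p_mod_to_sev, "UndxSevAsym", "DxMod", pd_mod)

  # Undiagnosed severe asymptomatic: die, become symptomatic, else detected
  # (routine 0.0037 or via index hospitalization 0.0046)
  s <- 1 - pd_seva
  det_sev <- tr$p_undx_to_dx_sev_nohosp + tr$p_undx_to_dx_sev_hosp
  prog <- tr$p_sevasym_to_sevsym
  chk("UndxSevAsym", pd_seva + s * (prog + (1 - prog) * det_sev))
  P[S["UndxSevAsym"], S["Death"]] <- pd_seva
  P[S["UndxSevAsym"], S["UndxSevSym"]] <- s * prog
  P[S["UndxSevAsym"], S["DxSevAsym"]] <- s * (1 - prog) * det_sev
  P[S["UndxSevAsym"], S["UndxSevAsym"]] <- s * (1 - prog) * (1 - det_sev)

  # Undiagnosed severe symptomatic: fixed high mortality; detected through
  # symptom recognition (6-12 month delay) or index hospitalization
  s <- 1 - tr$p_sevsym_death
  det_sym <- tr$p_sevsym_undx_to_dx + tr$p_undx_to_dx_sev_hosp
  chk("UndxSevSym", tr$p_sevsym_death + s * det_sym)
  P[S["UndxSevSym"], S["Death"]] <- tr$p_sevsym_death
  P[S["UndxSevSym"], S["DxSevSym"]] <- s * det_sym
  P[S["UndxSevSym"], S["UndxSevSym"]] <- s * (1 - det_sym)

  # Diagnosed mild/moderate: die, progress, stay (under surveillance)
  P[S["DxMild"], S["Death"]] <- pd_mild
  P[S["DxMild"], S["DxMod"]] <- (1 - pd_mild) * tr$p_mild_to_mod
  P[S["DxMild"], S["DxMild"]] <- (1 - pd_mild) * (1 - tr$p_mild_to_mod)

  P[S["DxMod"], S["Death"]] <- pd_mod
  P[S["DxMod"], S["DxSevAsym"]] <- (1 - pd_mod) * tr$p_mod_to_sev
  P[S["DxMod"], S["DxMod"]] <- (1 - pd_mod) * (1 - tr$p_mod_to_sev)

  # Diagnosed severe asymptomatic
  s <- 1 - pd_seva
  P[S["DxSevAsym"], S["Death"]] <- pd_seva
  if (scenario == "early_intervention") {
    P[S["DxSevAsym"], S["TAVRcycle"]] <- s
  } else {
    P[S["DxSevAsym"], S["DxSevSym"]] <- s * tr$p_sevasym_to_sevsym
    P[S["DxSevAsym"], S["DxSevAsym"]] <- s * (1 - tr$p_sevasym_to_sevsym)
  }

  # Diagnosed severe symptomatic: TAVR in the following cycle
  P[S["DxSevSym"], S["Death"]] <- tr$p_sevsym_death
  P[S["DxSevSym"], S["TAVRcycle"]] <- 1 - tr$p_sevsym_death

  # TAVR procedure cycle: fixed split
  p_rest <- 1 - tr$tavr_p_death - tr$tavr_p_stroke
  chk("TAVRcycle", tr$tavr_p_death + tr$tavr_p_stroke)
  P[S["TAVRcycle"], S["Death"]] <- tr$tavr_p_death
  P[S["TAVRcycle"], S["StrokeTunnel1"]] <- tr$tavr_p_stroke
  P[S["TAVRcycle"], S["PostTAVR"]] <- p_rest

  # Post-TAVR without stroke: back to age-adjusted mortality
  P[S["PostTAVR"], S["Death"]] <- pd_gp
  P[S["PostTAVR"], S["PostTAVR"]] <- 1 - pd_gp

  # Post-stroke tunnel (months 1-12, first-year relative risk)
  P[cbind(.TUNNEL, S["Death"])] <- pd_t1
  P[cbind(.TUNNEL, c(.TUNNEL[-1L], S["StrokeChronic"]))] <- 1 - pd_t1

  # Chronic post-stroke
  P[S["StrokeChronic"], S["Death"]] <- pd_chr
  P[S["StrokeChronic"], S["StrokeChronic"]] <- 1 - pd_chr

  P[S["Death"], S["Death"]] <- 1
  P
}

#' Expected one-time cost of a TAVR procedure
#'
#' TAVR cost plus expected non-stroke complication costs (at most one
#' complication per patient) plus the one-time post-procedure follow-up
#' fee. Stroke costs are not included here: they accrue monthly in the
#' post-stroke tunnel states, whose first-year cost includes the index
#' event.
#'
#' @param params An `as_params` object.
#' @return Expected cost (currency) per patient entering the TAVR cycle.
#' @export
expected_tavr_cost <- function(params) {
  tr <- params$transitions
  co <- params$costs
  co$c_tavr + tr$tavr_p_ppm * co$c_ppm + tr$tavr_p_vasc * co$c_vasc +
    tr$tavr_p_bleed * co$c_bleed + co$c_posttavr_fu
}

# Expected one-time transition cost per occupant of each (source) state in
# one cycle at the given age: index hospitalization on the hospitalization
# detection route, and the TAVR bundle on entry to the procedure cycle.
onetime_cost_vector <- function(params, lt, age_months, scenario) {
  tr <- params$transitions
  v <- numeric(.N_STATES)
  etavr <- expected_tavr_cost(params)

  s <- 1 - monthly_mortality(lt, age_months, tr$rr_sevasym)
  v[.S["UndxSevAsym"]] <- s * (1 - tr$p_sevasym_to_sevsym) *
    tr$p_undx_to_dx_sev_hosp * params$costs$c_index_hosp
  v[.S["UndxSevSym"]] <- (1 - tr$p_sevsym_death) *
    tr$p_undx_to_dx_sev_hosp * params$costs$c_index_hosp
  v[.S["DxSevSym"]] <- (1 - tr$p_sevsym_death) * etavr
  if (scenario == "early_intervention") {
    v[.S["DxSevAsym"]] <- (1 - monthly_mortality(lt, age_months, tr$rr_sevasym)) * etavr
  }
  v
}

# Transition matrices and one-time-cost vectors for every completed-years
# age of a run; they change only when the integer age does, so paired arms
# share one precomputation.
precompute_cycles <- function(params, lt, scenario) {
  age0 <- params$screening$cohort_age_years
  years <- age0:(params$econ$horizon_age_years - 1L)
  list(
    years = years,
    P = lapply(years, function(y) build_matrix(params, lt, y * 12, scenario)),
    otc = lapply(years, function(y) onetime_cost_vector(params, lt, y * 12,
                                                        scenario))
  )
}

#' Run the cohort model
#'
#' Iterates the monthly cohort recursion from the cohort age to the
#' horizon age (default 110), accruing discounted costs and QALYs. Costs
#' have a recurring component (state occupancy times the monthly state
#' cost, discounted at the cycle start) and a one-time component charged
#' when the triggering transition completes, discounted at that cycle: the
#' screening TTE for the whole screened cohort at cycle 0, the index
#' hospitalization on the hospitalization detection route, and the
#' expected TAVR bundle on entry to the procedure cycle. QALYs accrue as
#' occupancy times annual utility / 12, discounted at the cycle start. No
#' half-cycle correction is applied (`half_cycle = TRUE` enables the
#' standard first/last half-cycle weights on recurring accruals). Residual
#' mass at the horizon age transitions to death.
#'
#' @param initial Occupancy vector over [state_names()], summing to 1.
#' @param params An `as_params` object.
#' @param lt A `lifetable` covering \[cohort age, horizon age\].
#' @param scenario `"symptomatic_trigger"` or `"early_intervention"`.
#' @param screening Logical: charge the one-time screening TTE at cycle 0.
#' @param half_cycle Logical: apply a half-cycle correction to recurring
#'   accruals (off by default).
#' @param precomp Internal: precomputed per-year matrices (shared between
#'   the paired arms by [evaluate_pair()]).
#' @return A `cohort_trace`: list with `occupancy` (cycles+1 x states
#'   matrix), `cycle_costs`, `cycle_qalys` (discounted, per cycle),
#'   `cum_cost`, `cum_qaly`, `ages` (age in months at each row).
#' @export
run_cohort <- function(initial, params, lt,
                       scenario = c("symptomatic_trigger",
                                    "early_intervention"),
                       screening = FALSE, half_cycle = FALSE,
                       precomp = NULL) {
  scenario <- match.arg(scenario)
  if (length(initial) != .N_STATES) {
    stop("initial must have ", .N_STATES, " entries (see state_names())",
         call. = FALSE)
  }
  if (abs(sum(initial) - 1) > 1e-9) {
    stop("initial occupancy must sum to 1", call. = FALSE)
  }

  age0 <- params$screening$cohort_age_years
  n_cycles <- (params$econ$horizon_age_years - age0) * 12L
  r <- params$econ$discount_rate_annual
  disc <- (1 + r)^(-(0:n_cycles) / 12)

  c_state <- state_costs(params)
  u_state <- state_utilities(params, scenario) / 12

  occ <- matrix(0, n_cycles + 1L, .N_STATES,
                dimnames = list(NULL, .STATE_NAMES))
  occ[1L, ] <- initial
  cycle_costs <- numeric(n_cycles)
  cycle_qalys <- numeric(n_cycles)

  w <- rep(1, n_cycles)
  if (half_cycle) w[1L] <- 0.5  # paired with a terminal half-cycle below

  if (is.null(precomp)) precomp <- precompute_cycles(params, lt, scenario)
  P <- NULL
  otc <- NULL
  cur_year <- -1L
  x <- initial
  for (t in seq_len(n_cycles) - 1L) {
    age_m <- age0 * 12L + t
    yr <- age_m %/% 12L
    if (yr != cur_year) {
      i_yr <- yr - age0 + 1L
      P <- precomp$P[[i_yr]]
      otc <- precomp$otc[[i_yr]]
      cur_year <- yr
    }
    cycle_costs[t + 1L] <- sum(x * c_state) * disc[t + 1L] * w[t + 1L] +
      sum(x * otc) * disc[t + 2L]
    cycle_qalys[t + 1L] <- sum(x * u_state) * disc[t + 1L] * w[t + 1L]
    x <- as.numeric(x %*% P)
    occ[t + 2L, ] <- x
  }
  if (screening) {
    cycle_costs[1L] <- cycle_costs[1L] + params$costs$c_screen_tte
  }
  if (half_cycle) {
    # terminal half-cycle on the final occupancy
    cycle_costs[n_cycles] <- cycle_costs[n_cycles] +
      0.5 * sum(x * c_state) * disc[n_cycles + 1L]
    cycle_qalys[n_cycles] <- cycle_qalys[n_cycles] +
      0.5 * sum(x * u_state) * disc[n_cycles + 1L]
  }

  # lifetime horizon closure: residual mass at the horizon age dies
  occ[n_cycles + 1L, ] <- 0
  occ[n_cycles + 1L, .S["Death"]] <- 1

  structure(
    list(occupancy = occ,
         cycle_costs = cycle_costs,
         cycle_qalys = cycle_qalys,
         cum_cost = sum(cycle_costs),
         cum_qaly = sum(cycle_qalys),
         ages = age0 * 12L + 0:n_cycles,
         scenario = scenario,
         screening = screening),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace>", nrow(x$occupancy) - 1L, "monthly cycles,",
      if (x$screening) "screened arm," else "unscreened arm,",
      x$scenario, "\n")
  cat(sprintf("  discounted totals: cost $%.2f, %.4f QALYs\n",
              x$cum_cost, x$cum_qaly))
  invisible(x)
}

#' Export a cohort trace as a data.frame
#'
#' One row per cycle: age in months, occupancy of every state, and the
#' discounted cost and QALY accrued in the cycle starting there.
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional Ignored (data.frame method signature).
#' @param ... Ignored.
#' @return A data.frame with `cycles + 1` rows.
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  n <- nrow(x$occupancy)
  data.frame(age_months = x$ages,
             x$occupancy,
             disc_cost = c(x$cycle_costs, 0),
             disc_qaly = c(x$cycle_qalys, 0))
}
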