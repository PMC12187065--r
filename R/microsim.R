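#' Individual-level microsimulation of one model arm
#'
#' Simulates individual patients through the same monthly transition
#' matrices and one-time-cost rules as the cohort engine, as an
#' independent cross-check of [run_cohort()]: for large samples the mean
#' discounted cost and QALYs converge to the cohort totals. Transitions
#' are sampled per individual; the index-hospitalization cost is charged
#' to the sampled fraction of detected severe cases that present through
#' hospital, and the expected TAVR bundle is charged on entry to the
#' procedure cycle.
#'
#' @param initial Occupancy vector over [state_names()] (sampling weights
#'   for the initial state).
#' @param params An `as_params` object.
#' @param lt A `lifetable`.
#' @param scenario `"symptomatic_trigger"` or `"early_intervention"`.
#' @param screening Logical: charge the screening TTE at cycle 0.
#' @param n_indiv Number of simulated individuals.
#' @param seed RNG seed.
#' @return A list: `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`,
#'   `n_indiv`.
#' @export
run_microsim <- function(initial, params, lt,
                         scenario = c("symptomatic_trigger",
                                      "early_intervention"),
                         screening = FALSE, n_indiv = 1e5, seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  n <- as.integer(n_indiv)
  tr <- params$transitions

  age0 <- params$screening$cohort_age_years
  n_cycles <- (params$econ$horizon_age_years - age0) * 12L
  r <- params$econ$discount_rate_annual
  disc <- (1 + r)^(-(0:n_cycles) / 12)

  c_state <- state_costs(params)
  u_state <- state_utilities(params, scenario) / 12
  etavr <- expected_tavr_cost(params)

  i_death <- .S[["Death"]]
  i_usa <- .S[["UndxSevAsym"]]; i_dsa <- .S[["DxSevAsym"]]
  i_uss <- .S[["UndxSevSym"]]; i_dss <- .S[["DxSevSym"]]
  i_tavr <- .S[["TAVRcycle"]]
  frac_hosp_asym <- tr$p_undx_to_dx_sev_hosp /
    (tr$p_undx_to_dx_sev_nohosp + tr$p_undx_to_dx_sev_hosp)
  frac_hosp_sym <- tr$p_undx_to_dx_sev_hosp /
    (tr$p_sevsym_undx_to_dx + tr$p_undx_to_dx_sev_hosp)

  state <- sample.int(.N_STATES, n, replace = TRUE, prob = initial)
  cost <- rep(if (screening) params$costs$c_screen_tte else 0, n)
  qaly <- numeric(n)
  active <- which(state != i_death)

  P <- NULL
  cur_year <- -1L
  for (t in seq_len(n_cycles) - 1L) {
    if (!length(active)) break
    age_m <- age0 * 12L + t
    yr <- age_m %/% 12L
    if (yr != cur_year) {
      P <- build_matrix(params, lt, age_m, scenario)
      cur_year <- yr
    }
    st_a <- state[active]
    cost[active] <- cost[active] + c_state[st_a] * disc[t + 1L]
    qaly[active] <- qaly[active] + u_state[st_a] * disc[t + 1L]

    grp <- split(active, st_a)
    for (s_chr in names(grp)) {
      s <- as.integer(s_chr)
      idx <- grp[[s_chr]]
      ns <- sample.int(.N_STATES, length(idx), replace = TRUE, prob = P[s, ])
      state[idx] <- ns
      if (s == i_usa) {
        det <- idx[ns == i_dsa]
        hit <- det[stats::runif(length(det)) < frac_hosp_asym]
        cost[hit] <- cost[hit] + params$costs$c_index_hosp * disc[t + 2L]
      } else if (s == i_uss) {
        det <- idx[ns == i_dss]
        hit <- det[stats::runif(length(det)) < frac_hosp_sym]
        cost[hit] <- cost[hit] + params$costs$c_index_hosp * disc[t + 2L]
      }
      entered <- idx[ns == i_tavr]
      cost[entered] <- cost[entered] + etavr * disc[t + 2L]
    }
    active <- active[state[active] != i_death]
  }

  list(mean_cost = mean(cost), mean_qaly = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n),
       se_qaly = stats::sd(qaly) / sqrt(n),
       n_indiv = n)
}
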