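#' Default model parameters for a screening cohort
#'
#' Assembles the complete parameter set of the screening model: monthly
#' transition probabilities, per-procedure TAVR complication risks,
#' mortality relative risks, costs, utilities, screening-test yield and
#' economic settings. Defaults are the model's published base-case inputs
#' for cohorts screened at 70 or 80 years of age.
#'
#' Severity-progression probabilities (mild to moderate, moderate to
#' severe) are not free inputs: they are derived from the mean annual
#' decline in aortic valve area (AVA) via [ava_band_transition()] and are
#' recomputed whenever the AVA rate changes (see
#' [finalize_parameters()]).
#'
#' Mortality relative risks for mild, moderate and severe asymptomatic
#' disease default to 1 (general-population mortality). The publication
#' behind the model calibrated these against registry relative risks that
#' were not reported numerically, so no effect size is invented here;
#' override them through `parameters_from_config()` or direct assignment
#' when estimates are available.
#'
#' @param cohort_age Age in years at screening; 70 or 80.
#' @return An object of class `as_params`: a list with components
#'   `transitions`, `costs`, `utilities`, `screening` and `econ`.
#' @seealso [finalize_parameters()], [validate_parameters()],
#'   [parameters_from_config()]
#' @examples
#' p <- default_parameters(80)
#' p$screening$screen_positive_rate  # 0.228
#' p$costs$c_tavr                    # 64466
#' @export
default_parameters <- function(cohort_age) {
  if (length(cohort_age) != 1L || !cohort_age %in% c(70, 80)) {
    stop("cohort_age must be 70 or 80 (got ", deparse(cohort_age),
         "); supply a full custom parameter set for other ages", call. = FALSE)
  }

  transitions <- list(
    incidence_gp_to_mild     = 0.0122,
    ava_rate_mean            = 0.07,    # cm^2/year mean AVA decline
    ava_rate_se              = 0.0128,  # cm^2/year
    ava_band_width           = 0.5,     # cm^2 per severity band
    p_mild_to_mod            = NA_real_,  # derived from AVA rate
    p_mod_to_sev             = NA_real_,  # derived from AVA rate
    p_sevasym_to_sevsym      = 0.0153,
    p_undx_to_dx_nonsev      = 0.0037,
    p_undx_to_dx_sev_nohosp  = 0.0037,
    p_undx_to_dx_sev_hosp    = 0.0046,
    p_sevsym_undx_to_dx      = 1 / 9,   # 6-12 month symptom-to-diagnosis delay
    p_sevsym_death           = 0.0305,
    tavr_p_stroke            = 0.022,
    tavr_p_ppm               = 0.116,
    tavr_p_bleed             = 0.076,
    tavr_p_vasc              = 0.093,
    tavr_p_death             = 0.026,
    rr_stroke_y1             = 4.46,
    rr_stroke_y2plus         = 1.99,
    rr_mild                  = 1.0,
    rr_mod                   = 1.0,
    rr_sevasym               = 1.0
  )

  costs <- list(
    c_screen_tte   = 215.15,
    c_mild_m       = 4.48,     # surveillance TTE every 4 years, amortized
    c_mod_m        = 11.95,    # every 18 months
    c_sevdx_m      = 41.35,    # every 9 months + assessment
    c_index_hosp   = 7940,
    c_tavr         = 64466,
    c_ppm          = 11209,
    c_vasc         = 12894.98,
    c_bleed        = 3428.16,
    c_posttavr_fu  = 105.25,
    c_stroke_y1_m  = 6196.08,
    c_stroke_y2_m  = 522.08
  )

  utilities <- list(
    u_base         = 0.83,
    u_sevsym       = 0.57,
    u_stroke_y1    = 0.64,
    u_stroke_y2plus = 0.69
  )

  screening <- if (cohort_age == 70) {
    list(
      cohort_age_years     = 70,
      screen_positive_rate = 0.013,
      severity_split       = c(mild = 0.981, moderate = 0.019, severe = 0),
      n_screened           = 2500,          # OxValve cohort size
      n_positive           = 0.013 * 2500   # screen-positive count behind the rate
    )
  } else {
    list(
      cohort_age_years     = 80,
      screen_positive_rate = 0.228,
      severity_split       = c(mild = 0.300, moderate = 0.429, severe = 0.271),
      n_screened           = 556,           # BELFRAIL cohort size
      n_positive           = 127            # 37 + 57 + 33 screen positives
    )
  }

  econ <- list(
    discount_rate_annual = 0.015,
    wtp_per_qaly         = 50000,
    cycle_length         = 1,     # months; fixed
    horizon_age_years    = 110,
    n_psa_reps           = 5000,
    rng_seed             = 1L
  )

  params <- structure(
    list(transitions = transitions, costs = costs, utilities = utilities,
         screening = screening, econ = econ),
    class = "as_params"
  )
  finalize_parameters(params)
}

#' Recompute derived parameters and validate
#'
#' Derives the monthly severity-progression probabilities from the AVA
#' progression rate and band width, then runs [validate_parameters()].
#' Call after modifying `ava_rate_mean` or `ava_band_width` (the PSA
#' sampler does this automatically).
#'
#' @param params An `as_params` object.
#' @return The validated `as_params` object with `p_mild_to_mod` and
#'   `p_mod_to_sev` filled in.
#' @export
finalize_parameters <- function(params) {
  tr <- params$transitions
  p_band <- ava_band_transition(tr$ava_rate_mean, tr$ava_band_width)
  params$transitions$p_mild_to_mod <- p_band
  params$transitions$p_mod_to_sev  <- p_band
  validate_parameters(params)
  params
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set: probabilities in
#' \[0,1\], TAVR outcome probabilities summing to at most 1, positive
#' relative risks and AVA inputs, non-negative costs, utilities in \[0,1\],
#' severity split summing to 1, and economic settings (monthly cycle,
#' horizon beyond the cohort age).
#'
#' @param params An `as_params` object.
#' @return Invisibly `TRUE`; otherwise an error naming the offending field.
#' @export
validate_parameters <- function(params) {
  tr <- params$transitions
  probs <- c("incidence_gp_to_mild", "p_mild_to_mod", "p_mod_to_sev",
             "p_sevasym_to_sevsym", "p_undx_to_dx_nonsev",
             "p_undx_to_dx_sev_nohosp", "p_undx_to_dx_sev_hosp",
             "p_sevsym_undx_to_dx", "p_sevsym_death",
             "tavr_p_stroke", "tavr_p_ppm", "tavr_p_bleed",
             "tavr_p_vasc", "tavr_p_death")
  for (nm in probs) {
    x <- tr[[nm]]
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop("transitions$", nm, " must be a probability in [0, 1], got ",
           format(x), call. = FALSE)
    }
  }
  tavr_sum <- tr$tavr_p_stroke + tr$tavr_p_ppm + tr$tavr_p_bleed +
    tr$tavr_p_vasc + tr$tavr_p_death
  if (tavr_sum > 1 + 1e-12) {
    stop("TAVR outcome probabilities sum to ", format(tavr_sum),
         " (> 1); states would lose mass", call. = FALSE)
  }
  for (nm in c("rr_stroke_y1", "rr_stroke_y2plus", "rr_mild", "rr_mod",
               "rr_sevasym")) {
    if (!(tr[[nm]] > 0)) {
      stop("transitions$", nm, " must be a positive relative risk",
           call. = FALSE)
    }
  }
  if (!(tr$ava_rate_mean > 0)) stop("transitions$ava_rate_mean must be > 0", call. = FALSE)
  if (!(tr$ava_band_width > 0)) stop("transitions$ava_band_width must be > 0", call. = FALSE)

  for (nm in names(params$costs)) {
    if (!is.numeric(params$costs[[nm]]) || params$costs[[nm]] < 0) {
      stop("costs$", nm, " must be a non-negative cost", call. = FALSE)
    }
  }
  for (nm in names(params$utilities)) {
    u <- params$utilities[[nm]]
    if (!is.numeric(u) || u < 0 || u > 1) {
      stop("utilities$", nm, " must lie in [0, 1], got ", format(u),
           call. = FALSE)
    }
  }

  sc <- params$screening
  if (sc$screen_positive_rate < 0 || sc$screen_positive_rate > 1) {
    stop("screening$screen_positive_rate must lie in [0, 1]", call. = FALSE)
  }
  if (length(sc$severity_split) != 3L || any(sc$severity_split < 0) ||
      abs(sum(sc$severity_split) - 1) > 1e-9) {
    stop("screening$severity_split must be 3 non-negative shares summing to 1",
         call. = FALSE)
  }

  ec <- params$econ
  if (ec$discount_rate_annual < 0) stop("econ$discount_rate_annual must be >= 0", call. = FALSE)
  if (ec$cycle_length != 1) stop("econ$cycle_length is fixed at 1 month", call. = FALSE)
  if (ec$horizon_age_years <= sc$cohort_age_years) {
    stop("econ$horizon_age_years must exceed the cohort age", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert an annual probability to a monthly probability
#'
#' Constant-hazard conversion: `1 - (1 - p)^(1/12)`. Used for
#' user-supplied annual rates; published per-cycle defaults are taken
#' verbatim and never re-converted.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @return Monthly probability.
#' @examples
#' annual_prob_to_monthly(0.045)
#' @export
annual_prob_to_monthly <- function(p_annual) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / 12)
}

#' Amortize a one-time fee over a surveillance interval
#'
#' Spreads a one-time fee (e.g. a surveillance echocardiogram) evenly over
#' the monthly cycles of its repeat interval, rounded to cents. This is how
#' the per-cycle surveillance costs of diagnosed disease are built from the
#' one-time TTE fee.
#'
#' @param one_time_fee Fee in currency units, >= 0.
#' @param interval_months Repeat interval in months, >= 1.
#' @return Monthly cost, rounded to 2 decimals.
#' @examples
#' amortized_monthly_cost(215.15, 48)  # 4.48, mild AS surveillance
#' amortized_monthly_cost(215.15, 18)  # 11.95, moderate AS surveillance
#' @export
amortized_monthly_cost <- function(one_time_fee, interval_months) {
  if (any(interval_months < 1)) {
    stop("interval_months must be >= 1", call. = FALSE)
  }
  if (any(one_time_fee < 0)) stop("one_time_fee must be >= 0", call. = FALSE)
  round(one_time_fee / interval_months, 2)
}

#' Apply overrides to a parameter set
#'
#' Merges a nested list of overrides (sections `transitions`, `costs`,
#' `utilities`, `screening`, `econ`) into a parameter set, rejecting
#' unknown keys, then re-derives dependent values and validates.
#'
#' @param params An `as_params` object.
#' @param overrides Nested named list; e.g.
#'   `list(transitions = list(rr_mild = 1.2))`.
#' @return The modified, validated `as_params` object.
#' @export
modify_parameters <- function(params, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(params)
  bad_sections <- setdiff(names(overrides), names(params))
  if (length(bad_sections)) {
    stop("unknown parameter section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  }
  for (section in names(overrides)) {
    keys <- names(overrides[[section]])
    bad <- setdiff(keys, names(params[[section]]))
    if (length(bad)) {
      stop("unknown key(s) in ", section, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (k in keys) params[[section]][[k]] <- overrides[[section]][[k]]
  }
  finalize_parameters(params)
}

#' Build a parameter set from a configuration file
#'
#' Reads a YAML configuration whose top-level keys mirror the parameter
#' sections and applies it over the defaults for the requested cohort age.
#' A `cohort_age` key in the file selects the default set when the
#' argument is missing.
#'
#' @param path Path to a YAML file.
#' @param cohort_age Optional cohort age (70 or 80) overriding the file.
#' @return A validated `as_params` object.
#' @export
parameters_from_config <- function(path, cohort_age = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading configuration files requires the 'yaml' package",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  age <- cohort_age %||% cfg$cohort_age %||% 80
  cfg$cohort_age <- NULL
  modify_parameters(default_parameters(age), cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.as_params <- function(x, ...) {
  cat("<as_params> aortic stenosis screening model parameters\n")
  cat("  cohort age:", x$screening$cohort_age_years, "years;",
      "screen-positive rate:", x$screening$screen_positive_rate, "\n")
  cat("  severity split (mild/moderate/severe):",
      paste(format(x$screening$severity_split), collapse = " / "), "\n")
  cat("  discount:", x$econ$discount_rate_annual, "per year;",
      "WTP:", x$econ$wtp_per_qaly, "per QALY\n")
  cat("  monthly progression (per AVA band):",
      format(x$transitions$p_mild_to_mod, digits = 4), "\n")
  invisible(x)
}
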