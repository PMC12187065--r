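#' Define a sampling distribution for one parameter
#'
#' Families follow the published input tables: `beta` and `gamma` are
#' parameterized by method of moments from `(mean, se)`, `lognormal`
#' matches `(mean, se)` on the natural scale, `dirichlet` takes a
#' concentration vector `alpha` (zero components stay exactly zero), and
#' `fixed` always returns the mean.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"dirichlet"`,
#'   `"fixed"`.
#' @param mean Mean on the natural scale (ignored for dirichlet).
#' @param se Standard error on the natural scale; `NULL` or 0 degenerates
#'   to the mean.
#' @param alpha Dirichlet concentration vector.
#' @param bounds Optional `c(lower, upper)`; draws outside are rejected
#'   and redrawn (at most 100 times).
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(family, mean = NULL, se = NULL, alpha = NULL,
                      bounds = NULL) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "dirichlet",
                                "fixed"))
  structure(list(family = family, mean = mean, se = se, alpha = alpha,
                 bounds = bounds),
            class = "dist_spec")
}

beta_moments <- function(mean, se, what = "parameter") {
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop("beta moment match infeasible for ", what, ": se ", format(se),
         " too large for mean ", format(mean), call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Draw one value from a distribution spec
#'
#' @param spec A [dist_spec()].
#' @param what Parameter name used in error messages.
#' @return A draw (scalar, or vector for dirichlet).
#' @export
sample_one <- function(spec, what = "parameter") {
  draw <- function() {
    switch(spec$family,
      fixed = spec$mean,
      beta = {
        if (is.null(spec$se) || spec$se == 0) return(spec$mean)
        ab <- beta_moments(spec$mean, spec$se, what)
        stats::rbeta(1, ab[1], ab[2])
      },
      gamma = {
        if (is.null(spec$se) || spec$se == 0) return(spec$mean)
        v <- spec$se^2
        stats::rgamma(1, shape = spec$mean^2 / v, rate = spec$mean / v)
      },
      lognormal = {
        if (is.null(spec$se) || spec$se == 0) return(spec$mean)
        s2 <- log(1 + spec$se^2 / spec$mean^2)
        stats::rlnorm(1, meanlog = log(spec$mean) - s2 / 2, sdlog = sqrt(s2))
      },
      dirichlet = {
        g <- numeric(length(spec$alpha))
        pos <- spec$alpha > 0
        g[pos] <- stats::rgamma(sum(pos), shape = spec$alpha[pos])
        g / sum(g)
      }
    )
  }
  x <- draw()
  if (!is.null(spec$bounds)) {
    tries <- 0L
    while (any(x < spec$bounds[1]) || any(x > spec$bounds[2])) {
      tries <- tries + 1L
      if (tries > 100L) {
        stop("could not draw ", what, " within bounds after 100 attempts",
             call. = FALSE)
      }
      x <- draw()
    }
  }
  x
}

#' Default sampling distributions for the probabilistic analysis
#'
#' One `dist_spec` per uncertain parameter, keyed
#' `"section.field"`. Families follow the published tables: beta for
#' probabilities, gamma for costs and the AVA progression rate, lognormal
#' for utilities and mortality relative risks, fixed for the screening and
#' follow-up fees. The AVA rate carries its published standard error
#' (0.0128); all other standard errors default to `cv` times the mean
#' (20%), since they were not reported. The screen-positive rate is beta
#' with the binomial standard error of its source cohort, and the severity
#' split is Dirichlet with concentration equal to the published split
#' scaled by the screen-positive count of the source cohort (the published
#' gamma label for a probability vector is treated as a typographical
#' artefact). Relative risks for mild/moderate/severe-asymptomatic
#' mortality stay fixed at their configured values.
#'
#' @param params An `as_params` object.
#' @param cv Default coefficient of variation for unreported standard
#'   errors.
#' @return Named list of `dist_spec`s.
#' @export
default_psa_specs <- function(params, cv = 0.2) {
  tr <- params$transitions
  co <- params$costs
  ut <- params$utilities
  sc <- params$screening

  beta_cv <- function(m) dist_spec("beta", m, cv * m)
  gamma_cv <- function(m) dist_spec("gamma", m, cv * m)
  lnorm_u <- function(m) dist_spec("lognormal", m, cv * m, bounds = c(0, 1))

  specs <- list(
    "transitions.incidence_gp_to_mild"    = beta_cv(tr$incidence_gp_to_mild),
    "transitions.ava_rate_mean"           = dist_spec("gamma", tr$ava_rate_mean,
                                                      tr$ava_rate_se),
    "transitions.p_sevasym_to_sevsym"     = beta_cv(tr$p_sevasym_to_sevsym),
    "transitions.p_undx_to_dx_nonsev"     = beta_cv(tr$p_undx_to_dx_nonsev),
    "transitions.p_undx_to_dx_sev_nohosp" = beta_cv(tr$p_undx_to_dx_sev_nohosp),
    "transitions.p_undx_to_dx_sev_hosp"   = beta_cv(tr$p_undx_to_dx_sev_hosp),
    "transitions.p_sevsym_undx_to_dx"     = beta_cv(tr$p_sevsym_undx_to_dx),
    "transitions.p_sevsym_death"          = beta_cv(tr$p_sevsym_death),
    "transitions.tavr_p_stroke"           = beta_cv(tr$tavr_p_stroke),
    "transitions.tavr_p_ppm"              = beta_cv(tr$tavr_p_ppm),
    "transitions.tavr_p_bleed"            = beta_cv(tr$tavr_p_bleed),
    "transitions.tavr_p_vasc"             = beta_cv(tr$tavr_p_vasc),
    "transitions.tavr_p_death"            = beta_cv(tr$tavr_p_death),
    "transitions.rr_stroke_y1"            = dist_spec("lognormal",
                                                      tr$rr_stroke_y1,
                                                      cv * tr$rr_stroke_y1),
    "transitions.rr_stroke_y2plus"        = dist_spec("lognormal",
                                                      tr$rr_stroke_y2plus,
                                                      cv * tr$rr_stroke_y2plus),
    "transitions.rr_mild"                 = dist_spec("fixed", tr$rr_mild),
    "transitions.rr_mod"                  = dist_spec("fixed", tr$rr_mod),
    "transitions.rr_sevasym"              = dist_spec("fixed", tr$rr_sevasym),
    "costs.c_screen_tte"                  = dist_spec("fixed", co$c_screen_tte),
    "costs.c_mild_m"                      = gamma_cv(co$c_mild_m),
    "costs.c_mod_m"                       = gamma_cv(co$c_mod_m),
    "costs.c_sevdx_m"                     = gamma_cv(co$c_sevdx_m),
    "costs.c_index_hosp"                  = gamma_cv(co$c_index_hosp),
    "costs.c_tavr"                        = gamma_cv(co$c_tavr),
    "costs.c_ppm"                         = gamma_cv(co$c_ppm),
    "costs.c_vasc"                        = gamma_cv(co$c_vasc),
    "costs.c_bleed"                       = gamma_cv(co$c_bleed),
    "costs.c_posttavr_fu"                 = dist_spec("fixed", co$c_posttavr_fu),
    "costs.c_stroke_y1_m"                 = gamma_cv(co$c_stroke_y1_m),
    "costs.c_stroke_y2_m"                 = gamma_cv(co$c_stroke_y2_m),
    "utilities.u_base"                    = lnorm_u(ut$u_base),
    "utilities.u_sevsym"                  = lnorm_u(ut$u_sevsym),
    "utilities.u_stroke_y1"               = lnorm_u(ut$u_stroke_y1),
    "utilities.u_stroke_y2plus"           = lnorm_u(ut$u_stroke_y2plus),
    "screening.screen_positive_rate"      = dist_spec(
      "beta", sc$screen_positive_rate,
      sqrt(sc$screen_positive_rate * (1 - sc$screen_positive_rate) /
             sc$n_screened)),
    "screening.severity_split"            = dist_spec(
      "dirichlet", alpha = sc$severity_split * sc$n_positive)
  )
  specs
}

#' Draw one parameter set from its sampling distributions
#'
#' Samples every spec, writes the draws into the base parameter set,
#' re-derives the AVA-based progression probabilities, and validates. If
#' the joint invariants fail (e.g. TAVR outcome probabilities summing past
#' 1), the whole set is redrawn, at most `max_attempts` times.
#'
#' @param specs Named list of `dist_spec`s (keys `"section.field"`), as
#'   from [default_psa_specs()].
#' @param params Base `as_params` object receiving the draws.
#' @param max_attempts Resampling cap for joint-invariant violations.
#' @return A validated `as_params` object.
#' @export
sample_parameters <- function(specs, params, max_attempts = 100L) {
  for (attempt in seq_len(max_attempts)) {
    p <- params
    for (key in names(specs)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2L || is.null(p[[parts[1]]]) ||
          !parts[2] %in% names(p[[parts[1]]])) {
        stop("unknown parameter key in specs: ", key, call. = FALSE)
      }
      val <- sample_one(specs[[key]], what = key)
      if (parts[2] == "severity_split") {
        val <- stats::setNames(val, names(p$screening$severity_split))
      }
      p[[parts[1]]][[parts[2]]] <- val
    }
    ok <- tryCatch({ p <- finalize_parameters(p); TRUE },
                   error = function(e) FALSE)
    if (ok) return(p)
  }
  stop("sampled parameter sets violated joint invariants in ", max_attempts,
       " consecutive attempts", call. = FALSE)
}

#' Probabilistic sensitivity analysis of a screening comparison
#'
#' Monte Carlo PSA: for each replication one parameter set is drawn and
#' shared by both arms (common random parameters), the paired cohort
#' models are run, and per-arm discounted totals are recorded. Each
#' replication uses its own RNG seed derived once from the master seed, so
#' results are reproducible and independent of evaluation order.
#'
#' @param pair A `strategy_pair`.
#' @param params Base `as_params` object.
#' @param lt A `lifetable`.
#' @param specs Sampling distributions; default [default_psa_specs()].
#' @param n_reps Number of replications; default from `params$econ`.
#' @param seed Master seed; default from `params$econ`.
#' @return An `as_psa` object: data.frame `draws` with one row per
#'   replication (`cost_screen`, `qaly_screen`, `cost_noscreen`,
#'   `qaly_noscreen`, `delta_cost`, `delta_qaly`), plus `n_reps`, `seed`,
#'   `wtp`, `pair`.
#' @export
run_psa <- function(pair, params, lt, specs = default_psa_specs(params),
                    n_reps = params$econ$n_psa_reps,
                    seed = params$econ$rng_seed) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  out <- matrix(NA_real_, n_reps, 4,
                dimnames = list(NULL, c("cost_screen", "qaly_screen",
                                        "cost_noscreen", "qaly_noscreen")))
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    p_i <- tryCatch(sample_parameters(specs, params),
                    error = function(e) {
                      stop("replication ", i, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    res <- evaluate_pair(pair, p_i, lt)
    out[i, ] <- c(res$screen$cost, res$screen$qaly,
                  res$noscreen$cost, res$noscreen$qaly)
  }
  draws <- as.data.frame(out)
  draws$delta_cost <- draws$cost_screen - draws$cost_noscreen
  draws$delta_qaly <- draws$qaly_screen - draws$qaly_noscreen
  structure(list(draws = draws, n_reps = n_reps, seed = seed,
                 wtp = params$econ$wtp_per_qaly, pair = pair),
            class = "as_psa")
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly`. For PSA summaries use the ratio of mean
#' increments (see [summary.as_psa()]), not the mean of per-replication
#' ratios. A zero QALY increment has no defined ICER and returns `NA`;
#' report dominance instead (see [ce_classification()]).
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @return Cost per QALY, or `NA` when `delta_qaly` is 0.
#' @examples
#' icer(242, 242 / 156722)
#' @export
icer <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly == 0, NA_real_, delta_cost / delta_qaly)
}

#' Classify an incremental result on the cost-effectiveness plane
#'
#' @param delta_cost,delta_qaly Increments of the screening arm over no
#'   screening.
#' @return `"dominant"` (cheaper, at least as effective), `"dominated"`
#'   (costlier, no more effective), or `"trade-off"`.
#' @export
ce_classification <- function(delta_cost, delta_qaly) {
  if (delta_qaly >= 0 && delta_cost <= 0 && (delta_qaly > 0 || delta_cost < 0)) {
    "dominant"
  } else if (delta_qaly <= 0 && delta_cost >= 0) {
    "dominated"
  } else {
    "trade-off"
  }
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`: positive when the screening arm is
#' cost-effective at the given willingness-to-pay.
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay per QALY (>= 0).
#' @return Net monetary benefit in currency units.
#' @examples
#' nmb(242, 242 / 156722, 50000)   # about -165
#' nmb(1287, 1287 / 28005, 50000)  # about 1011
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA replications with positive incremental net monetary
#' benefit at each willingness-to-pay value.
#'
#' @param result An `as_psa` object.
#' @param wtp_grid Numeric vector of willingness-to-pay values.
#' @return data.frame with columns `wtp` and `p_cost_effective`.
#' @export
ceac <- function(result, wtp_grid) {
  stopifnot(inherits(result, "as_psa"), length(wtp_grid) >= 1)
  d <- result$draws
  p <- vapply(wtp_grid,
              function(w) mean(w * d$delta_qaly - d$delta_cost > 0),
              numeric(1))
  data.frame(wtp = wtp_grid, p_cost_effective = p)
}

#' Summarize a probabilistic sensitivity analysis
#'
#' Mean per-arm discounted costs and QALYs across replications, mean
#' increments, the ratio-of-means ICER, and the net monetary benefit at
#' the configured willingness-to-pay.
#'
#' @param object An `as_psa` object.
#' @param wtp Willingness-to-pay; default the value stored in the result.
#' @param ... Ignored.
#' @return A list of class `summary.as_psa`.
#' @export
summary.as_psa <- function(object, wtp = object$wtp, ...) {
  d <- object$draws
  dc <- mean(d$delta_cost)
  dq <- mean(d$delta_qaly)
  structure(
    list(cohort_age = object$pair$cohort_age,
         scenario = object$pair$scenario,
         n_reps = object$n_reps,
         seed = object$seed,
         wtp = wtp,
         cost_screen = mean(d$cost_screen),
         qaly_screen = mean(d$qaly_screen),
         cost_noscreen = mean(d$cost_noscreen),
         qaly_noscreen = mean(d$qaly_noscreen),
         delta_cost = dc,
         delta_qaly = dq,
         icer = icer(dc, dq),
         classification = ce_classification(dc, dq),
         nmb = nmb(dc, dq, wtp)),
    class = "summary.as_psa"
  )
}

#' @export
print.summary.as_psa <- function(x, ...) {
  cat(sprintf("PSA summary: screening at %d (%s), %d replications, seed %d\n",
              x$cohort_age, x$scenario, x$n_reps, x$seed))
  cat(sprintf("                     %12s %12s\n", "Screening", "No screening"))
  cat(sprintf("  QALY               %12.2f %12.2f\n", x$qaly_screen,
              x$qaly_noscreen))
  cat(sprintf("  Cost               %12s %12s\n",
              sprintf("$%.0f", x$cost_screen),
              sprintf("$%.0f", x$cost_noscreen)))
  cat(sprintf("  Incremental QALY   %12.4f\n", x$delta_qaly))
  cat(sprintf("  Incremental cost   %12s\n", sprintf("$%.0f", x$delta_cost)))
  if (is.na(x$icer)) {
    cat("  ICER               undefined (zero QALY increment);",
        x$classification, "\n")
  } else {
    cat(sprintf("  ICER               %12s per QALY (%s)\n",
                sprintf("$%.0f", x$icer), x$classification))
  }
  cat(sprintf("  NMB (WTP $%.0f) %10s\n", x$wtp, sprintf("$%.0f", x$nmb)))
  invisible(x)
}

#' Cost-effectiveness plane of a PSA
#'
#' Scatter of per-replication (incremental QALY, incremental cost) pairs
#' with the willingness-to-pay line.
#'
#' @param x An `as_psa` object.
#' @param wtp Willingness-to-pay line to draw; default stored value.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.as_psa <- function(x, wtp = x$wtp, ...) {
  d <- x$draws
  graphics::plot(d$delta_qaly, d$delta_cost,
                 xlab = "Incremental QALY", ylab = "Incremental cost ($)",
                 pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}
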