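test_that("default parameters reproduce the published inputs for both cohorts", {
  expect_equal(params70$screening$screen_positive_rate, 0.013)
  expect_equal(unname(params70$screening$severity_split["mild"]), 0.981)
  expect_equal(unname(params70$screening$severity_split["severe"]), 0)
  expect_equal(params80$screening$screen_positive_rate, 0.228)
  expect_equal(unname(params80$screening$severity_split),
               c(0.300, 0.429, 0.271))

  tr <- params80$transitions
  expect_equal(tr$incidence_gp_to_mild, 0.0122)
  expect_equal(tr$p_sevasym_to_sevsym, 0.0153)
  expect_equal(tr$p_undx_to_dx_nonsev, 0.0037)
  expect_equal(tr$p_undx_to_dx_sev_hosp, 0.0046)
  expect_equal(tr$p_sevsym_death, 0.0305)
  expect_equal(c(tr$tavr_p_stroke, tr$tavr_p_ppm, tr$tavr_p_bleed,
                 tr$tavr_p_vasc, tr$tavr_p_death),
               c(0.022, 0.116, 0.076, 0.093, 0.026))
  expect_equal(c(tr$rr_stroke_y1, tr$rr_stroke_y2plus), c(4.46, 1.99))

  co <- params80$costs
  expect_equal(co$c_screen_tte, 215.15)
  expect_equal(c(co$c_mild_m, co$c_mod_m, co$c_sevdx_m),
               c(4.48, 11.95, 41.35))
  expect_equal(co$c_tavr, 64466)
  expect_equal(co$c_index_hosp, 7940)
  expect_equal(c(co$c_stroke_y1_m, co$c_stroke_y2_m), c(6196.08, 522.08))

  expect_equal(unlist(params80$utilities, use.names = FALSE),
               c(0.83, 0.57, 0.64, 0.69))
  expect_equal(params80$econ$discount_rate_annual, 0.015)
  expect_equal(params80$econ$wtp_per_qaly, 50000)

  # monthly progression derived from the AVA decline, equal across bands
  expect_equal(params80$transitions$p_mild_to_mod,
               ava_band_transition(0.07, 0.5))
  expect_equal(params80$transitions$p_mild_to_mod,
               params80$transitions$p_mod_to_sev)

  expect_no_error(validate_parameters(params70))
  expect_no_error(validate_parameters(params80))
})

test_that("unsupported cohort ages and invalid fields are rejected by name", {
  expect_error(default_parameters(75), "cohort_age")
  expect_error(
    modify_parameters(params80, list(transitions = list(p_sevsym_death = 1.2))),
    "p_sevsym_death"
  )
  expect_error(
    modify_parameters(params80, list(utilities = list(u_base = -0.1))),
    "u_base"
  )
  expect_error(
    modify_parameters(params80, list(transitions = list(no_such = 1))),
    "no_such"
  )
  expect_error(
    modify_parameters(params80,
                      list(transitions = list(tavr_p_death = 0.5,
                                              tavr_p_ppm = 0.6))),
    "sum"
  )
})

test_that("annual-to-monthly conversion uses the constant-hazard formula", {
  expect_identical(annual_prob_to_monthly(0), 0)
  expect_identical(annual_prob_to_monthly(1), 1)
  expect_equal(annual_prob_to_monthly(0.045), 0.00382964, tolerance = 1e-6)
  expect_error(annual_prob_to_monthly(1.1), "0, 1")

  # round trip to annual scale
  p_a <- c(0.001, 0.045, 0.3, 0.9)
  expect_equal(1 - (1 - annual_prob_to_monthly(p_a))^12, p_a,
               tolerance = 1e-12)

  # strictly increasing on (0, 1)
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(annual_prob_to_monthly(grid)) > 0))
})

test_that("surveillance fees amortize to the published per-cycle costs", {
  expect_equal(amortized_monthly_cost(215.15, 48), 4.48)
  expect_equal(amortized_monthly_cost(215.15, 18), 11.95)
  expect_equal(amortized_monthly_cost(0, 12), 0)
  expect_error(amortized_monthly_cost(100, 0), "interval_months")
})

test_that("configuration files override defaults and reject unknown keys", {
  skip_if_not_installed("yaml")
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("cohort_age: 80",
               "transitions:",
               "  rr_mild: 1.5",
               "costs:",
               "  c_tavr: 60000"), cfg)
  p <- parameters_from_config(cfg)
  expect_equal(p$transitions$rr_mild, 1.5)
  expect_equal(p$costs$c_tavr, 60000)
  expect_equal(p$screening$cohort_age_years, 80)

  writeLines(c("transitions:", "  not_a_key: 1"), cfg)
  expect_error(parameters_from_config(cfg, cohort_age = 70), "not_a_key")
})
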