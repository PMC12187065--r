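test_that("transition matrices are row-stochastic with the published TAVR split", {
  for (sc in c("symptomatic_trigger", "early_intervention")) {
    for (age in seq(70, 109, by = 13)) {
      P <- build_matrix(params80, lt_default, age * 12, sc)
      expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
      expect_true(all(P >= 0))
    }
  }
  P <- build_matrix(params80, lt_default, 80 * 12)
  # absorbing death
  expect_equal(unname(P["Death", ]),
               as.numeric(colnames(P) == "Death"))
  # TAVR cycle resolves by the fixed procedural split
  expect_equal(P["TAVRcycle", "Death"], 0.026)
  expect_equal(P["TAVRcycle", "StrokeTunnel1"], 0.022)
  expect_equal(P["TAVRcycle", "PostTAVR"], 1 - 0.026 - 0.022)
  # tunnel months only advance or die; month 12 exits to the chronic state
  for (k in 1:11) {
    row <- P[paste0("StrokeTunnel", k), ]
    expect_equal(sum(row[c("Death", paste0("StrokeTunnel", k + 1))]), 1)
  }
  expect_equal(sum(P["StrokeTunnel12", c("Death", "StrokeChronic")]), 1)
  # diagnosed symptomatic patients undergo TAVR in the following cycle
  expect_equal(P["DxSevSym", "TAVRcycle"], 1 - 0.0305)
  # early intervention reroutes diagnosed severe asymptomatic disease
  Pe <- build_matrix(params80, lt_default, 80 * 12, "early_intervention")
  expect_equal(Pe["DxSevAsym", "TAVRcycle"], 1 - Pe["DxSevAsym", "Death"])
  expect_equal(P["DxSevAsym", "TAVRcycle"], 0)
})

test_that("overloaded transition rows fail loudly instead of renormalizing", {
  bad <- params80
  bad$transitions$p_sevsym_undx_to_dx <- 0.999
  # 0.999 + hospitalization detection exceeds 1 conditional on survival
  expect_error(build_matrix(bad, lt_default, 80 * 12), "UndxSevSym")
})

test_that("expected TAVR cost combines procedure, complications and follow-up", {
  expect_equal(expected_tavr_cost(params80), 67331.2673, tolerance = 1e-8)
  bare <- params80
  bare$transitions[c("tavr_p_stroke", "tavr_p_ppm", "tavr_p_bleed",
                     "tavr_p_vasc", "tavr_p_death")] <- 0
  bare$costs[c("c_ppm", "c_vasc", "c_bleed", "c_posttavr_fu")] <- 0
  expect_equal(expected_tavr_cost(bare), 64466)
  more_ppm <- params80
  more_ppm$transitions$tavr_p_ppm <- 2 * params80$transitions$tavr_p_ppm
  expect_gt(expected_tavr_cost(more_ppm), expected_tavr_cost(params80))
})

test_that("cohort accrual identities hold in degenerate runs", {
  init <- setNames(numeric(length(state_names())), state_names())

  # a single never-dying untreated state accrues its utility exactly
  p <- params_no_as
  p$econ$discount_rate_annual <- 0
  p$econ$horizon_age_years <- 81
  lt0 <- structure(data.frame(age = 79:81, qx = c(0, 0, 1)),
                   class = c("lifetable", "data.frame"))
  init["GeneralPop"] <- 1
  tr <- run_cohort(init, p, lt0)
  expect_equal(sum(tr$cycle_qalys), 0.83, tolerance = 1e-12)

  # a dead cohort accrues nothing
  init[] <- 0; init["Death"] <- 1
  tr <- run_cohort(init, params80, lt_default)
  expect_equal(tr$cum_cost, 0)
  expect_equal(tr$cum_qaly, 0)

  # discounting strictly shrinks QALYs
  init[] <- 0; init["GeneralPop"] <- 1
  p_disc <- params80
  p_nodisc <- params80; p_nodisc$econ$discount_rate_annual <- 0
  expect_lt(run_cohort(init, p_disc, lt_default)$cum_qaly,
            run_cohort(init, p_nodisc, lt_default)$cum_qaly)
})

test_that("cohort mass is conserved and death is monotone over a lifetime run", {
  for (params in list(params70, params80)) {
    for (sc in c("symptomatic_trigger", "early_intervention")) {
      init <- initial_distribution(FALSE, params$screening)
      tr <- run_cohort(init, params, lt_default, sc)
      sums <- rowSums(tr$occupancy)
      expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
      expect_true(all(diff(tr$occupancy[, "Death"]) >= -1e-12))
      expect_equal(unname(tr$occupancy[nrow(tr$occupancy), "Death"]), 1)
    }
  }
  # age-70 run covers 480 monthly cycles
  init <- initial_distribution(TRUE, params70$screening)
  tr <- run_cohort(init, params70, lt_default, screening = TRUE)
  expect_equal(nrow(tr$occupancy), 481L)
})

test_that("without aortic stenosis the arms differ only by the screening fee", {
  pair <- strategy_pair(80, params = params_no_as)
  res <- evaluate_pair(pair, params_no_as, lt_default)
  expect_identical(res$delta_qaly, 0)
  expect_identical(res$delta_cost, 215.15)
})

test_that("trace exports one row per cycle with occupancy and accruals", {
  init <- initial_distribution(TRUE, params80$screening)
  tr <- run_cohort(init, params80, lt_default, screening = TRUE)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 361L)
  expect_true(all(state_names() %in% names(df)))
  expect_equal(sum(df$disc_cost), tr$cum_cost)
  expect_equal(sum(df$disc_qaly), tr$cum_qaly)
})

test_that("half-cycle correction changes accruals only modestly at monthly cycles", {
  init <- initial_distribution(TRUE, params80$screening)
  tr0 <- run_cohort(init, params80, lt_default, screening = TRUE)
  tr1 <- run_cohort(init, params80, lt_default, screening = TRUE,
                    half_cycle = TRUE)
  expect_false(isTRUE(all.equal(tr0$cum_qaly, tr1$cum_qaly)))
  expect_lt(abs(tr1$cum_qaly - tr0$cum_qaly) / tr0$cum_qaly, 0.01)
})
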