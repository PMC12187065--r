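test_that("distribution sampling matches the specified moments", {
  set.seed(101)
  n <- 50000

  # fixed family is a point mass
  s <- replicate(5, sample_one(dist_spec("fixed", 215.15)))
  expect_true(all(s == 215.15))

  # beta with se -> 0 degenerates to the mean
  expect_equal(sample_one(dist_spec("beta", 0.5, 0)), 0.5)

  check_moments <- function(spec, mean, se) {
    x <- replicate(n, sample_one(spec))
    expect_lt(abs(mean(x) - mean), 3 * se / sqrt(n))
    expect_lt(abs(stats::sd(x) - se) / se, 0.05)
  }
  check_moments(dist_spec("gamma", 64466, 0.2 * 64466), 64466, 0.2 * 64466)
  check_moments(dist_spec("beta", 0.116, 0.0232), 0.116, 0.0232)
  check_moments(dist_spec("lognormal", 4.46, 0.892), 4.46, 0.892)

  # dirichlet means follow the concentration vector; zeros stay zero
  alpha <- c(mild = 0.3, moderate = 0.429, severe = 0.271) * 127
  d <- t(replicate(n / 5, sample_one(dist_spec("dirichlet", alpha = alpha))))
  expect_equal(colMeans(d), alpha / sum(alpha), tolerance = 0.005,
               ignore_attr = TRUE)
  d0 <- sample_one(dist_spec("dirichlet", alpha = c(10, 5, 0)))
  expect_identical(d0[3], 0)
  expect_equal(sum(d0), 1)

  # infeasible beta moment match is reported with the parameter name
  expect_error(sample_one(dist_spec("beta", 0.981, 0.2), what = "mild_share"),
               "mild_share")
})

test_that("sampled parameter sets respect every invariant", {
  specs <- default_psa_specs(params80)
  set.seed(7)
  for (i in 1:25) {
    p <- sample_parameters(specs, params80)
    expect_no_error(validate_parameters(p))
    # progression probabilities track the sampled AVA rate
    expect_equal(p$transitions$p_mild_to_mod,
                 ava_band_transition(p$transitions$ava_rate_mean, 0.5))
    expect_equal(sum(p$screening$severity_split), 1, tolerance = 1e-12)
  }
})

test_that("degenerate PSA equals the deterministic evaluation", {
  pair <- strategy_pair(80, "symptomatic_trigger", params80)
  det <- evaluate_pair(pair, params80, lt_default)
  psa <- run_psa(pair, params80, lt_default, specs = fixed_specs(params80),
                 n_reps = 1, seed = 3)
  expect_equal(psa$draws$cost_screen, det$screen$cost)
  expect_equal(psa$draws$qaly_noscreen, det$noscreen$qaly)
  expect_equal(psa$draws$delta_cost, det$delta_cost)
})

test_that("PSA results are bit-reproducible under a fixed master seed", {
  pair <- strategy_pair(80, "symptomatic_trigger", params80)
  a <- run_psa(pair, params80, lt_default, n_reps = 5, seed = 11)
  b <- run_psa(pair, params80, lt_default, n_reps = 5, seed = 11)
  expect_identical(a$draws, b$draws)
  c <- run_psa(pair, params80, lt_default, n_reps = 5, seed = 12)
  expect_false(identical(a$draws, c$draws))
})

test_that("a single gamma-distributed cost perturbs the mean increment unbiasedly", {
  specs <- fixed_specs(params80)
  specs[["costs.c_tavr"]] <- dist_spec("gamma", params80$costs$c_tavr,
                                       0.2 * params80$costs$c_tavr)
  pair <- strategy_pair(80, "symptomatic_trigger", params80)
  det <- evaluate_pair(pair, params80, lt_default)
  psa <- run_psa(pair, params80, lt_default, specs = specs, n_reps = 100,
                 seed = 5)
  sem <- stats::sd(psa$draws$delta_cost) / sqrt(100)
  expect_lt(abs(mean(psa$draws$delta_cost) - det$delta_cost), 3 * sem)
  # QALYs are untouched by a cost parameter
  expect_equal(psa$draws$delta_qaly, rep(det$delta_qaly, 100))
})

test_that("ICER and NMB follow their definitions and sign conventions", {
  expect_equal(icer(100, 0.01), 10000)
  expect_equal(icer(242, 242 / 156722), 156722)
  expect_true(is.na(icer(100, 0)))
  expect_lt(icer(-1, 0.1), 0)
  expect_equal(ce_classification(-1, 0.1), "dominant")
  expect_equal(ce_classification(1, -0.1), "dominated")

  expect_equal(nmb(0, 0, 123456), 0)
  expect_equal(nmb(242, 242 / 156722, 50000), -164.8, tolerance = 1e-3)
  expect_equal(nmb(1287, 1287 / 28005, 50000), 1010.8, tolerance = 1e-3)
  expect_error(nmb(1, 1, -5), "wtp")

  # sign(NMB) = sign(wtp - ICER) whenever the QALY increment is positive
  set.seed(9)
  for (i in 1:50) {
    dc <- stats::runif(1, -500, 5000)
    dq <- stats::runif(1, 1e-4, 0.3)
    w <- stats::runif(1, 0, 2e5)
    expect_equal(sign(nmb(dc, dq, w)), sign(w - icer(dc, dq)))
  }
})

test_that("the acceptability curve is the positive-NMB fraction", {
  pair <- strategy_pair(80, "symptomatic_trigger", params80)
  psa <- run_psa(pair, params80, lt_default, specs = fixed_specs(params80),
                 n_reps = 1, seed = 3)
  ic <- icer(psa$draws$delta_cost, psa$draws$delta_qaly)
  cv <- ceac(psa, wtp_grid = c(0, ic * 0.9, ic * 1.1, 2 * ic))
  # a point-mass PSA yields a step function at its ICER
  expect_equal(cv$p_cost_effective, c(0, 0, 1, 1))
  # at wtp = 0 the curve is the probability of cost savings
  expect_equal(cv$p_cost_effective[1],
               mean(psa$draws$delta_cost < 0))
})

test_that("PSA summaries use the ratio of mean increments", {
  pair <- strategy_pair(80, "symptomatic_trigger", params80)
  psa <- run_psa(pair, params80, lt_default, n_reps = 20, seed = 21)
  s <- summary(psa)
  expect_equal(s$icer, mean(psa$draws$delta_cost) / mean(psa$draws$delta_qaly))
  expect_equal(s$nmb, 50000 * s$delta_qaly - s$delta_cost)
  expect_equal(s$n_reps, 20)
})
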