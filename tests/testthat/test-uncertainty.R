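test_that("default one-way ranges are plus/minus 25% with explicit PSA bounds", {
  p <- default_parameters()
  rg <- default_ranges(p)

  r_cost <- rg[rg$path == "costs.imrt20_cost", ]
  expect_equal(r_cost$low, 807135)
  expect_equal(r_cost$high, 1345225)
  expect_identical(r_cost$basis, "plus-minus-25pct")

  for (path in c("clinical.psa_control_imrt", "clinical.psa_control_rarp")) {
    r <- rg[rg$path == path, ]
    expect_identical(r$low, 0.80)
    expect_identical(r$high, 0.95)
    expect_identical(r$basis, "explicit")
  }

  # probabilities stay clipped to [0, 1]
  bounded <- startsWith(rg$path, "clinical.") | startsWith(rg$path, "utilities.")
  expect_true(all(rg$high[bounded] <= 1))
  expect_true(all(rg$low >= 0))
  expect_true(all(rg$low <= rg$base & rg$base <= rg$high))

  # a zero base value yields a degenerate, flagged range
  r_gi <- rg[rg$path == "utilities.dec_gi", ]
  expect_identical(c(r_gi$low, r_gi$high), c(0, 0))
  expect_true(r_gi$degenerate)
})

test_that("tornado analysis honours structural identities and ordering", {
  p <- default_parameters()
  wtp <- p$settings$wtp

  # a degenerate range produces zero spread
  rg0 <- data.frame(path = "costs.salvage_rt", base = 1265110,
                    low = 1265110, high = 1265110,
                    basis = "explicit", degenerate = FALSE)
  t0 <- one_way_dsa(p, rg0, wtp, fixture_life_table)
  expect_identical(t0$spread, 0)

  # raising the IMRT-20 upfront cost by X lowers the INMB by exactly X,
  # so the spread of a cycle-0 cost equals the width of its range
  rg <- default_ranges(p)
  keep <- rg[rg$path %in% c("costs.imrt20_cost", "costs.rarp_surgery",
                            "clinical.psa_control_imrt",
                            "clinical.psa_control_rarp",
                            "utilities.dec_sexual",
                            "utilities.dec_urinary"), ]
  torn <- one_way_dsa(p, keep, wtp, fixture_life_table)
  expect_false(any(torn$failed))
  i20 <- torn[torn$path == "costs.imrt20_cost", ]
  expect_equal(i20$spread, 0.5 * p$costs$imrt20_cost, tolerance = 1e-9)
  expect_equal(i20$inmb_low - i20$inmb_high, i20$spread, tolerance = 1e-9)
  surg <- torn[torn$path == "costs.rarp_surgery", ]
  expect_equal(surg$spread, 0.5 * p$costs$rarp_surgery, tolerance = 1e-9)

  # initial PSA control carries the largest spread, and entries are sorted
  expect_true(torn$path[1] %in% c("clinical.psa_control_imrt",
                                  "clinical.psa_control_rarp"))
  expect_true(all(diff(torn$spread) <= 1e-9))
})

test_that("moment-matched sampling families recover their moments", {
  set.seed(42)
  n <- 10000

  beta_draws <- replicate(n, prostcea:::draw_moment_matched("beta", 0.90, 0.0225))
  expect_true(all(beta_draws > 0 & beta_draws < 1))
  expect_lt(abs(mean(beta_draws) - 0.90), 3 * 0.0225 / sqrt(n))
  expect_lt(abs(sd(beta_draws) - 0.0225), 3 * 0.0225 / sqrt(n))

  m <- 1076180
  gamma_draws <- replicate(n, prostcea:::draw_moment_matched("gamma", m, 0.25 * m))
  expect_true(all(gamma_draws >= 0))
  expect_lt(abs(mean(gamma_draws) - m), 3 * 0.25 * m / sqrt(n))

  ln_draws <- replicate(n, prostcea:::draw_moment_matched("lognormal", 2, 0.5))
  expect_true(all(ln_draws > 0))
  expect_lt(abs(mean(ln_draws) - 2), 3 * 0.5 / sqrt(n))

  # degenerate limit: vanishing sd concentrates on the mean
  tight <- replicate(100, prostcea:::draw_moment_matched("beta", 0.90, 1e-6))
  expect_lt(max(abs(tight - 0.90)), 1e-4)
})

test_that("uncertainty specs validate their moments and name offenders", {
  p <- default_parameters()
  spec <- default_uncertainty_spec(p)
  expect_s3_class(spec, "uncertainty_spec")
  # zero-valued parameters are held fixed rather than sampled
  gi <- spec$entries[spec$entries$path == "utilities.dec_gi", ]
  expect_identical(gi$family, "fixed")

  expect_error(
    default_uncertainty_spec(p, overrides = list(
      "clinical.psa_control_imrt" = list(sd = 0.5))),
    "psa_control_imrt.*infeasible beta")
  expect_error(
    default_uncertainty_spec(p, overrides = list("costs.bogus" = list(sd = 1))),
    "unknown parameter")
})

test_that("sampled parameter sets satisfy every invariant", {
  p <- default_parameters()
  spec <- default_uncertainty_spec(p, seed = 5L)
  set.seed(5)
  for (i in 1:50) {
    s <- sample_parameter_set(p, spec)
    expect_s3_class(validate_parameters(s), "cua_parameters")
    ut <- s$utilities
    expect_lte(ut$dec_psa_failure + ut$dec_urinary + ut$dec_sexual + ut$dec_gi,
               ut$base_utility + 1e-12)
    expect_identical(ut$dec_gi, 0)  # fixed at its zero base
  }
})

test_that("probabilistic sensitivity analysis is seed-reproducible", {
  p <- default_parameters()
  spec <- default_uncertainty_spec(p, n_iterations = 40L, seed = 123L)
  a <- run_prsa(p, spec, p$settings$wtp, fixture_life_table)
  b <- run_prsa(p, spec, p$settings$wtp, fixture_life_table)
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$prob_cost_effective, b$prob_cost_effective)
  expect_identical(a$n, 40L)
  expect_identical(a$n_failed, 0L)
  expect_gte(a$prob_cost_effective, 0)
  expect_lte(a$prob_cost_effective, 1)

  # all-fixed spec collapses every iteration onto the base case
  fixed <- spec
  fixed$entries$family <- "fixed"
  fixed$entries$sd <- 0
  fixed$n_iterations <- 5L
  f <- run_prsa(p, fixed, p$settings$wtp, fixture_life_table)
  expect_identical(length(unique(f$iterations$delta_cost)), 1L)
  expect_identical(length(unique(f$iterations$delta_qalys)), 1L)
  expect_true(f$prob_cost_effective %in% c(0, 1))
})

test_that("the acceptability curve is a pure function of the iteration records", {
  records <- data.frame(
    iteration = 1:4,
    delta_cost = c(-100, 200, 50, -10),
    delta_qalys = c(0.01, 0.002, -0.001, 0))
  lam <- c(0, 5e4, 5e6)
  curve <- ceac(records, lam)
  # threshold zero: the fraction with negative incremental cost
  expect_identical(curve$prob_alternative[1], mean(records$delta_cost < 0))
  # probabilities complement exactly
  expect_identical(curve$prob_alternative + curve$prob_reference,
                   rep(1, length(lam)))
  # hand check at 5e6: inmb = (50000-100, 10000+... ) per record
  expect_identical(curve$prob_alternative[3],
                   mean(records$delta_qalys * 5e6 - records$delta_cost > 0))

  # monotone non-decreasing in the threshold when all delta_qalys >= 0
  pos <- records[records$delta_qalys >= 0, ]
  grid <- seq(0, 1e7, by = 1e6)
  expect_true(all(diff(ceac(pos, grid)$prob_alternative) >= 0))

  expect_error(ceac(records, numeric(0)))
  expect_error(ceac(records, c(-1, 5)))
})
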