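test_that("adverse-event schedules follow the published prevalences", {
  p <- default_parameters()

  # IMRT events hold their one-year value from month 1
  expect_identical(ae_prevalence("IMRT20", "urinary", 6, p), 0.031)
  expect_identical(ae_prevalence("IMRT38", "sexual", 100, p), 0.389)
  # gastrointestinal burden stops after month 36
  expect_identical(ae_prevalence("IMRT20", "gi", 36, p), 0.098)
  expect_identical(ae_prevalence("IMRT20", "gi", 48, p), 0)

  # RARP month-1 prevalence reconstructed from the one-year cure rate
  expect_equal(ae_prevalence("RARP", "sexual", 1, p), 0.540 + 0.890 * 0.460)
  expect_equal(ae_prevalence("RARP", "urinary", 1, p),
               0.098 + 0.645 * (1 - 0.098))
  # linear recovery reaches the one-year value at month 12, then holds
  expect_equal(ae_prevalence("RARP", "sexual", 12, p), 0.540)
  expect_equal(ae_prevalence("RARP", "sexual", 240, p), 0.540)
  m6 <- ae_prevalence("RARP", "sexual", 6, p)
  expect_equal(m6, 0.9494 + (0.540 - 0.9494) * 5 / 11)
  # RARP burden never drops below the IMRT burden for the same event
  cyc <- 1:240
  expect_true(all(ae_prevalence("RARP", "sexual", cyc, p) >=
                  ae_prevalence("IMRT20", "sexual", cyc, p)))

  # no burden during the initial-treatment cycle
  expect_identical(ae_prevalence("RARP", "sexual", 0, p), 0)
  expect_error(ae_prevalence("RARP", "bowel", 1, p))
})

test_that("state utilities combine decrements additively with a floor at zero", {
  p <- default_parameters()
  expect_identical(state_utility("IMRT20", "DEAD", 17, p), 0)

  q <- quiet_params()
  expect_equal(state_utility("RARP", "PSA_CONTROLLED", 6, q), 0.90)
  expect_equal(state_utility("RARP", "ADT", 6, q), 0.90 - 0.17)

  # worked example: urinary 0.031 x 0.17 + sexual 0.389 x 0.11 off base 0.90
  expect_equal(state_utility("IMRT20", "PSA_CONTROLLED", 6, p),
               0.90 - 0.031 * 0.17 - 0.389 * 0.11)
  expect_equal(state_utility("IMRT20", "PSA_CONTROLLED", 6, p), 0.85194)

  # sexual_weight scales only the sexual component
  p0 <- set_param(p, "utilities.sexual_weight", 0)
  expect_equal(state_utility("IMRT20", "PSA_CONTROLLED", 6, p0),
               0.90 - 0.031 * 0.17)

  # monotone non-increasing in each decrement and the weight; floored at 0
  u_base <- state_utility("RARP", "ADT", 1, p)
  p_hi <- set_param(p, "utilities.dec_urinary", 0.9)
  expect_lte(state_utility("RARP", "ADT", 1, p_hi), u_base)
  p_all <- load_config(list(utilities = list(
    dec_psa_failure = 0.9, dec_urinary = 0.9, dec_sexual = 0.9)))
  expect_identical(state_utility("RARP", "ADT", 1, p_all), 0)
  expect_true(all(state_utility("RARP", "PSA_CONTROLLED", 0:240, p) >= 0))
  expect_true(all(state_utility("RARP", "PSA_CONTROLLED", 0:240, p) <= 0.90))
})

test_that("per-cycle costs attach upfront, ADT, and salvage components", {
  p <- default_parameters()
  occ0 <- c(INITIAL_TREATMENT = 1, PSA_CONTROLLED = 0, PSA_FAILURE = 0,
            ADT = 0, DEAD = 0)
  expect_equal(cycle_cost("IMRT20", occ0, 0, 0, p), 1076180)
  expect_equal(cycle_cost("IMRT38", occ0, 0, 0, p), 1445580)
  expect_equal(cycle_cost("RARP", occ0, 0, 0, p), 1313760)

  dead <- c(INITIAL_TREATMENT = 0, PSA_CONTROLLED = 0, PSA_FAILURE = 0,
            ADT = 0, DEAD = 1)
  expect_identical(cycle_cost("RARP", dead, 0, 100, p), 0)

  adt <- c(INITIAL_TREATMENT = 0, PSA_CONTROLLED = 0.9, PSA_FAILURE = 0,
           ADT = 0.10, DEAD = 0)
  expect_equal(cycle_cost("IMRT20", adt, 0, 24, p), 0.10 * 224690 / 12,
               tolerance = 1e-12)
  expect_equal(cycle_cost("IMRT20", adt, 0, 24, p), 1872.4, tolerance = 1e-4)

  # salvage radiotherapy bills new failure entrants in the RARP arm only
  expect_equal(cycle_cost("RARP", adt, 0.02, 24, p),
               0.10 * 224690 / 12 + 0.02 * 1265110)
  expect_equal(cycle_cost("IMRT20", adt, 0.02, 24, p), 0.10 * 224690 / 12)

  expect_error(cycle_cost("RARP", adt, -0.01, 24, p), "negative")
})

test_that("accumulation reproduces the per-cycle sum and the accrual rule", {
  # 1-year horizon, no discounting, no deaths, everyone controlled at 0.90
  p <- quiet_params()
  p <- set_param(p, "clinical.psa_control_imrt", 1)
  p <- set_param(p, "settings.annual_discount", 0)
  p <- set_param(p, "settings.horizon_years", 1L)
  tr <- run_cohort("IMRT20", p, flat_life_table(0))
  res <- accumulate(tr, "IMRT20", p)
  expect_equal(res$total_qalys, 0.90, tolerance = 1e-12)
  expect_identical(res$total_qalys, res$undiscounted_qalys)
  expect_identical(res$total_cost, res$undiscounted_cost)

  # discounted totals never exceed undiscounted ones; per-cycle sum agrees
  p2 <- default_parameters()
  for (arm in c("IMRT20", "RARP")) {
    tr2 <- run_cohort(arm, p2, fixture_life_table)
    res2 <- accumulate(tr2, arm, p2)
    expect_lt(res2$total_cost, res2$undiscounted_cost)
    expect_lt(res2$total_qalys, res2$undiscounted_qalys)
    expect_gt(res2$total_qalys, 0)
    expect_lte(res2$total_qalys, p2$settings$horizon_years)

    # independent route: discounted sum of cycle_cost() slices
    H <- tr2$horizon_cycles
    d <- (1 + p2$settings$annual_discount)^(-(0:(H - 1)) / 12)
    by_cycle <- vapply(seq_len(H), function(i) {
      cycle_cost(arm, tr2$occupancy[i, ], tr2$new_failure[i], i - 1, p2)
    }, numeric(1))
    expect_equal(res2$total_cost, sum(d * by_cycle), tolerance = 1e-10)
  }
})

test_that("ICER arithmetic and dominance labels follow the definitions", {
  # published worked example: 16,724 JPY / 0.1164 QALYs
  ic <- compute_icer(16724, 0.1164)
  expect_identical(ic$dominance, "ICER")
  expect_equal(ic$icer, 16724 / 0.1164)
  expect_equal(ic$icer, 143677, tolerance = 1e-5)

  expect_identical(compute_icer(100, -0.01)$dominance, "DOMINATED")
  expect_identical(compute_icer(-5, 0.1)$dominance, "DOMINANT")
  expect_identical(compute_icer(5, 0)$dominance, "UNDEFINED")
  # both cheaper and less effective: a ratio, not a label
  expect_identical(compute_icer(-100, -0.01)$dominance, "ICER")

  expect_identical(compute_inmb(0, 0, 5e6), 0)
  expect_equal(compute_inmb(0.1164, 16724, 5e6), 565276)
  expect_lt(compute_inmb(-0.0156, 16724, 5e6), 0)
})

test_that("compare() forms increments and enforces shared provenance", {
  p <- default_parameters()
  ref <- accumulate(run_cohort("RARP", p, fixture_life_table), "RARP", p)
  alt <- accumulate(run_cohort("IMRT20", p, fixture_life_table), "IMRT20", p)
  cmp <- compare(ref, alt, wtp = 5e6)
  expect_equal(cmp$delta_cost, alt$total_cost - ref$total_cost)
  expect_equal(cmp$inmb, cmp$delta_qalys * 5e6 - cmp$delta_cost)
  if (cmp$dominance == "ICER" && cmp$delta_qalys > 0) {
    expect_identical(cmp$inmb > 0, cmp$icer < 5e6)
  }

  # identical inputs give a null comparison
  self <- compare(ref, ref, wtp = 5e6)
  expect_identical(self$delta_cost, 0)
  expect_identical(self$inmb, 0)

  p2 <- set_param(p, "costs.adt_annual", 300000)
  other <- accumulate(run_cohort("IMRT20", p2, fixture_life_table),
                      "IMRT20", p2)
  expect_error(compare(ref, other, 5e6), "different parameter sets")
})

test_that("the two IMRT fractionation arms differ only in upfront cost", {
  for (seed in c(2, 11, 23)) {
    p <- random_params(seed)
    r20 <- accumulate(run_cohort("IMRT20", p, fixture_life_table),
                      "IMRT20", p)
    r38 <- accumulate(run_cohort("IMRT38", p, fixture_life_table),
                      "IMRT38", p)
    expect_identical(r20$total_qalys, r38$total_qalys)
    expect_equal(r38$undiscounted_cost - r20$undiscounted_cost,
                 p$costs$imrt38_cost - p$costs$imrt20_cost,
                 tolerance = 1e-9)
    # the upfront cost lands in cycle 0 where the discount factor is 1
    expect_equal(r38$total_cost - r20$total_cost,
                 p$costs$imrt38_cost - p$costs$imrt20_cost,
                 tolerance = 1e-9)
  }
})
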