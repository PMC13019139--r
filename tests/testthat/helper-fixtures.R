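# shared fixtures, built once per test run

# calibrated synthetic life table used wherever realistic mortality is needed
fixture_life_table <- generate_life_table()

# life table with a single flat annual death probability over the model ages
flat_life_table <- function(q_annual = 0, ages = 65:90) {
  structure(data.frame(age = ages, qx = q_annual),
            class = c("life_table", "data.frame"))
}

# annual probability whose monthly equivalent is exactly q_monthly
annual_from_monthly <- function(q_monthly) 1 - (1 - q_monthly)^12

# a random valid parameter set; deterministic in `seed`
random_params <- function(seed) {
  set.seed(seed)
  p <- default_parameters()
  p$clinical$psa_control_imrt <- runif(1, 0.5, 1)
  p$clinical$psa_control_rarp <- runif(1, 0.5, 1)
  p$clinical$salvage_success <- runif(1)
  p$clinical$late_failure_monthly_hazard <- runif(1, 0, 0.02)
  for (grp in c("IMRT", "RARP")) {
    for (ev in c("urinary", "sexual", "gi")) {
      p$clinical$ae_prevalence[[grp]][[ev]] <- runif(1, 0, 0.9)
    }
  }
  p$clinical$cure_urinary_rarp <- runif(1)
  p$clinical$cure_sexual_rarp <- runif(1)
  for (field in c("imrt20_cost", "imrt38_cost", "rarp_surgery",
                  "rarp_hospitalization", "rarp_anesthesia",
                  "salvage_rt", "adt_annual")) {
    p$costs[[field]] <- runif(1, 0, 3e6)
  }
  p$utilities$base_utility <- runif(1, 0.5, 1)
  decs <- runif(4, 0, p$utilities$base_utility / 4)
  p$utilities[c("dec_psa_failure", "dec_urinary",
                "dec_sexual", "dec_gi")] <- as.list(decs)
  p$utilities$sexual_weight <- runif(1)
  p$settings$annual_discount <- runif(1, 0, 0.05)
  p$settings$horizon_years <- sample(1:20, 1)
  validate_parameters(p)
  structure(p, class = "cua_parameters")
}

# parameters stripped of every adverse-event burden (prevalences and the
# post-operative recovery ramp implied by the cure rates)
quiet_params <- function() {
  p <- default_parameters()
  for (grp in c("IMRT", "RARP")) {
    for (ev in c("urinary", "sexual", "gi")) {
      p$clinical$ae_prevalence[[grp]][[ev]] <- 0
    }
  }
  p$clinical$cure_urinary_rarp <- 0
  p$clinical$cure_sexual_rarp <- 0
  validate_parameters(p)
  structure(p, class = "cua_parameters")
}
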