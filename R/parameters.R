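#' Treatment arm labels
#'
#' The model compares three strategies: hypofractionated IMRT (60 Gy in 20
#' fractions), conventionally fractionated IMRT (76 Gy in 38 fractions) and
#' robot-assisted radical prostatectomy. The two IMRT arms differ only in
#' their upfront treatment cost.
#'
#' @return Character vector of the three valid arm labels.
#' @export
arms <- function() c("IMRT20", "IMRT38", "RARP")

#' @rdname arms
#' @param arm An arm label.
#' @return `arm_class()`: `"IMRT"` or `"RARP"` — the class that determines
#'   adverse-event profiles and the salvage pathway.
#' @export
arm_class <- function(arm) {
  arm <- match.arg(arm, arms())
  if (arm == "RARP") "RARP" else "IMRT"
}

ae_events <- function() c("urinary", "sexual", "gi")

#' Base-case model parameters
#'
#' Returns the complete base-case parameter set: clinical probabilities,
#' adverse-event prevalences and cure rates, costs under the 2024 Japanese
#' fee schedule (JPY), health-state utilities and utility decrements, and
#' the model settings (2% annual discount, 20-year horizon, monthly cycles,
#' cohort entry at age 65, willingness-to-pay of 5,000,000 JPY/QALY,
#' 152 JPY per USD).
#'
#' Adverse-event management costs and the gastrointestinal utility
#' decrement default to zero (no published values exist for either); both
#' are configurable via [load_config()].
#'
#' @return A validated object of class `cua_parameters` with elements
#'   `clinical`, `costs`, `utilities`, `settings`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$costs$imrt20_cost
default_parameters <- function() {
  params <- structure(list(
    clinical = list(
      psa_control_imrt = 0.90,
      psa_control_rarp = 0.90,
      salvage_success = 0.50,
      ae_prevalence = list(
        IMRT = list(urinary = 0.031, sexual = 0.389, gi = 0.098),
        RARP = list(urinary = 0.098, sexual = 0.540, gi = 0)
      ),
      cure_urinary_rarp = 0.645,
      cure_sexual_rarp = 0.890,
      late_failure_monthly_hazard = 0
    ),
    costs = list(
      imrt20_cost = 1076180,
      imrt38_cost = 1445580,
      rarp_surgery = 952880,
      rarp_hospitalization = 260880,
      rarp_anesthesia = 100000,
      salvage_rt = 1265110,
      adt_annual = 224690,
      ae_management = list(urinary = 0, sexual = 0, gi = 0)
    ),
    utilities = list(
      base_utility = 0.90,
      dec_psa_failure = 0.17,
      dec_urinary = 0.17,
      dec_sexual = 0.11,
      dec_gi = 0,
      sexual_weight = 1
    ),
    settings = list(
      annual_discount = 0.02,
      horizon_years = 20L,
      cycle_length_months = 1L,
      start_age = 65L,
      wtp = 5e6,
      jpy_per_usd = 152,
      # months over which each adverse event carries a utility burden;
      # Inf = persists for the whole horizon, GI stops after 3 years
      ae_duration_months = list(urinary = Inf, sexual = Inf, gi = 36),
      half_cycle_correction = FALSE,
      multiplicative_utilities = FALSE
    )
  ), class = "cua_parameters")
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every invariant: probabilities and utilities in \[0, 1\], costs
#' non-negative, decrements no larger than the base utility, positive
#' horizon and willingness-to-pay. Errors name the offending field.
#'
#' @param params A `cua_parameters` object (or plain list with the same shape).
#' @return The validated object, invisibly classed `cua_parameters`.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      fail(field, "must be a probability in [0, 1]")
  }
  chk_cost <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !is.finite(x))
      fail(field, "must be a finite non-negative cost")
  }
  cl <- params$clinical
  chk_prob(cl$psa_control_imrt, "clinical.psa_control_imrt")
  chk_prob(cl$psa_control_rarp, "clinical.psa_control_rarp")
  chk_prob(cl$salvage_success, "clinical.salvage_success")
  chk_prob(cl$cure_urinary_rarp, "clinical.cure_urinary_rarp")
  chk_prob(cl$cure_sexual_rarp, "clinical.cure_sexual_rarp")
  chk_prob(cl$late_failure_monthly_hazard, "clinical.late_failure_monthly_hazard")
  for (grp in c("IMRT", "RARP")) {
    for (ev in ae_events()) {
      chk_prob(cl$ae_prevalence[[grp]][[ev]],
               paste0("clinical.ae_prevalence.", grp, ".", ev))
    }
  }
  co <- params$costs
  for (field in c("imrt20_cost", "imrt38_cost", "rarp_surgery",
                  "rarp_hospitalization", "rarp_anesthesia",
                  "salvage_rt", "adt_annual")) {
    chk_cost(co[[field]], paste0("costs.", field))
  }
  for (ev in ae_events()) {
    chk_cost(co$ae_management[[ev]], paste0("costs.ae_management.", ev))
  }
  ut <- params$utilities
  if (!is.numeric(ut$base_utility) || ut$base_utility <= 0 || ut$base_utility > 1)
    fail("utilities.base_utility", "must lie in (0, 1]")
  for (field in c("dec_psa_failure", "dec_urinary", "dec_sexual", "dec_gi")) {
    x <- ut[[field]]
    if (!is.numeric(x) || is.na(x) || x < 0 || x > ut$base_utility)
      fail(paste0("utilities.", field), "must lie in [0, base_utility]")
  }
  chk_prob(ut$sexual_weight, "utilities.sexual_weight")
  st <- params$settings
  if (!is.numeric(st$annual_discount) || st$annual_discount < 0)
    fail("settings.annual_discount", "must be non-negative")
  if (!is.numeric(st$horizon_years) || st$horizon_years < 0 ||
      st$horizon_years != round(st$horizon_years))
    fail("settings.horizon_years", "must be a non-negative integer")
  if (!identical(as.integer(st$cycle_length_months), 1L))
    fail("settings.cycle_length_months", "the model uses fixed monthly cycles")
  if (!is.numeric(st$wtp) || st$wtp <= 0)
    fail("settings.wtp", "must be positive")
  if (!is.numeric(st$jpy_per_usd) || st$jpy_per_usd <= 0)
    fail("settings.jpy_per_usd", "must be positive")
  if (!is.numeric(st$start_age) || st$start_age < 0)
    fail("settings.start_age", "must be non-negative")
  for (ev in ae_events()) {
    d <- st$ae_duration_months[[ev]]
    if (!is.numeric(d) || is.na(d) || d < 0)
      fail(paste0("settings.ae_duration_months.", ev), "must be non-negative (Inf = persistent)")
  }
  class(params) <- "cua_parameters"
  invisible(params)
}

#' Load parameters from a configuration file
#'
#' Reads a YAML (or JSON) document with top-level keys
#' `clinical`/`costs`/`utilities`/`settings` mirroring the fields of
#' [default_parameters()]. Keys that are present override the defaults;
#' unknown keys are rejected; the merged result is validated.
#'
#' @param source Path to a YAML/JSON file, or a named list already parsed.
#' @return A validated `cua_parameters` object.
#' @export
load_config <- function(source) {
  if (is.character(source)) {
    overrides <- yaml::read_yaml(source)
  } else if (is.list(source) || is.null(source)) {
    overrides <- source
  } else {
    stop("config source must be a file path or a named list", call. = FALSE)
  }
  base <- default_parameters()
  merged <- merge_config(unclass(base), overrides, path = character())
  validate_parameters(merged)
  structure(merged, class = "cua_parameters")
}

# recursive override merge; unknown keys error with their dotted path
merge_config <- function(base, overrides, path) {
  if (is.null(overrides) || (is.list(overrides) && length(overrides) == 0))
    return(base)
  if (!is.list(overrides) || is.null(names(overrides)) || any(names(overrides) == ""))
    stop(sprintf("config section '%s' must be a named mapping",
                 paste(path, collapse = ".")), call. = FALSE)
  for (key in names(overrides)) {
    here <- c(path, key)
    if (!key %in% names(base))
      stop(sprintf("unknown config key '%s'", paste(here, collapse = ".")),
           call. = FALSE)
    if (is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], overrides[[key]], here)
    } else {
      val <- overrides[[key]]
      if (!is.numeric(val) && !is.logical(val))
        stop(sprintf("config key '%s' must be numeric", paste(here, collapse = ".")),
             call. = FALSE)
      # keep the default's storage type so config round-trips are identical
      if (is.logical(base[[key]])) {
        val <- as.logical(val)
      } else if (is.integer(base[[key]])) {
        val <- as.integer(val)
      } else {
        val <- as.numeric(val)
      }
      base[[key]] <- val
    }
  }
  base
}

#' Get or set a parameter by dotted path
#'
#' Paths address fields as in a config file, e.g. `"costs.imrt20_cost"` or
#' `"clinical.ae_prevalence.RARP.sexual"`. Used by the sensitivity-analysis
#' machinery to perturb one field at a time.
#'
#' @param params A `cua_parameters` object.
#' @param path Dotted field path.
#' @param value Replacement value (for `set_param`).
#' @return `get_param`: the field value. `set_param`: a new validated
#'   parameter set.
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node))
      stop(sprintf("no parameter at path '%s'", path), call. = FALSE)
    node <- node[[k]]
  }
  node
}

#' @rdname get_param
#' @param validate Validate the modified set (default `TRUE`).
#' @export
set_param <- function(params, path, value, validate = TRUE) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  get_param(params, path)  # errors if absent
  params[[keys]] <- value
  if (validate) validate_parameters(params)
  structure(params, class = "cua_parameters")
}

#' Convert an annual probability to a monthly probability
#'
#' Converts an annual event probability to the per-cycle (monthly)
#' probability `1 - (1 - q)^(1/12)` under a constant hazard within the
#' year, so that compounding over 12 cycles reproduces the annual value.
#'
#' @param q_annual Annual probability, in \[0, 1\] (vectorized).
#' @return Monthly probability.
#' @export
#' @examples
#' annual_to_monthly_prob(0.12)
annual_to_monthly_prob <- function(q_annual) {
  if (!is.numeric(q_annual) || any(is.na(q_annual)) ||
      any(q_annual < 0) || any(q_annual > 1))
    stop("annual probability must lie in [0, 1]", call. = FALSE)
  1 - (1 - q_annual)^(1 / 12)
}

#' Convert JPY to USD
#'
#' @param amount Amount in JPY (vectorized).
#' @param rate Exchange rate in JPY per USD (default 152).
#' @return Amount in USD at full precision; round to one decimal for display.
#' @export
jpy_to_usd <- function(amount, rate = 152) {
  stopifnot(is.numeric(amount), all(is.finite(amount)), rate > 0)
  amount / rate
}

#' Total upfront treatment cost for an arm
#'
#' IMRT arms: the radiotherapy course cost. RARP: surgery +
#' hospitalization + anesthesia (1,313,760 JPY at defaults), accrued in
#' cycle 0.
#'
#' @inheritParams arm_class
#' @param params A `cua_parameters` object.
#' @return Upfront cost in JPY.
#' @export
upfront_cost <- function(arm, params) {
  arm <- match.arg(arm, arms())
  co <- params$costs
  switch(arm,
    IMRT20 = co$imrt20_cost,
    IMRT38 = co$imrt38_cost,
    RARP = co$rarp_surgery + co$rarp_hospitalization + co$rarp_anesthesia
  )
}

#' Write the current parameter set as a config file
#'
#' Serializes a `cua_parameters` object to YAML such that
#' `load_config()` on the result round-trips to an identical set.
#'
#' @inheritParams upfront_cost
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_config <- function(params, file) {
  validate_parameters(params)
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

#' @export
print.cua_parameters <- function(x, ...) {
  cat("<cua_parameters>\n")
  cat(sprintf("  PSA control: IMRT %.3f / RARP %.3f; salvage success %.2f\n",
              x$clinical$psa_control_imrt, x$clinical$psa_control_rarp,
              x$clinical$salvage_success))
  cat(sprintf("  Upfront JPY: IMRT20 %s / IMRT38 %s / RARP %s\n",
              format(x$costs$imrt20_cost, big.mark = ","),
              format(x$costs$imrt38_cost, big.mark = ","),
              format(x$costs$rarp_surgery + x$costs$rarp_hospitalization +
                     x$costs$rarp_anesthesia, big.mark = ",")))
  cat(sprintf("  Base utility %.2f (decrements: PSA %.2f, urinary %.2f, sexual %.2f x weight %.2f, GI %.2f)\n",
              x$utilities$base_utility, x$utilities$dec_psa_failure,
              x$utilities$dec_urinary, x$utilities$dec_sexual,
              x$utilities$sexual_weight, x$utilities$dec_gi))
  cat(sprintf("  Horizon %d y, monthly cycles, discount %.1f%%/y, start age %d, WTP %s JPY/QALY\n",
              x$settings$horizon_years, 100 * x$settings$annual_discount,
              x$settings$start_age, format(x$settings$wtp, big.mark = ",")))
  invisible(x)
}
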