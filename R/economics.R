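#' Adverse-event prevalence schedule
#'
#' Returns the modeled prevalence of an adverse event (`"urinary"`,
#' `"sexual"`, `"gi"`) among alive patients at a given monthly cycle.
#'
#' IMRT arms carry their one-year (three-year for gastrointestinal)
#' prevalence from month 1 onward. For RARP the published one-year
#' cure rates imply a much higher immediate post-operative burden: the
#' month-1 prevalence is reconstructed as
#' `p_1yr + cure * (1 - p_1yr)` (the cured fraction of the initially
#' affected complement recovers within the first year), declining
#' linearly to the one-year value at month 12 and constant thereafter.
#' Each event stops contributing after its configured duration
#' (`settings$ae_duration_months`; gastrointestinal symptoms stop after
#' month 36, urinary and sexual dysfunction persist). No burden is
#' applied in cycle 0, the initial-treatment cycle.
#'
#' @inheritParams upfront_cost
#' @param event One of `"urinary"`, `"sexual"`, `"gi"`.
#' @param cycle Monthly cycle index (0-based; vectorized).
#' @return Prevalence in \[0, 1\] for each cycle.
#' @export
#' @examples
#' p <- default_parameters()
#' ae_prevalence("RARP", "sexual", 1, p)   # 0.540 + 0.890 * 0.460
ae_prevalence <- function(arm, event, cycle, params) {
  cls <- arm_class(arm)
  event <- match.arg(event, ae_events())
  if (any(cycle < 0)) stop("cycle must be non-negative", call. = FALSE)
  p1yr <- params$clinical$ae_prevalence[[cls]][[event]]
  dur <- params$settings$ae_duration_months[[event]]
  out <- rep(p1yr, length(cycle))
  if (cls == "RARP" && event != "gi") {
    cure <- switch(event,
                   urinary = params$clinical$cure_urinary_rarp,
                   sexual = params$clinical$cure_sexual_rarp)
    p1 <- p1yr + cure * (1 - p1yr)
    ramp <- cycle >= 1 & cycle <= 12
    out[ramp] <- p1 + (p1yr - p1) * (cycle[ramp] - 1) / 11
  }
  out[cycle == 0 | cycle > dur] <- 0
  out
}

# prevalence-weighted utility burden among alive patients at each cycle
ae_burden <- function(arm, cycles, params) {
  ut <- params$utilities
  ae_prevalence(arm, "urinary", cycles, params) * ut$dec_urinary +
    ae_prevalence(arm, "sexual", cycles, params) * ut$dec_sexual *
      ut$sexual_weight +
    ae_prevalence(arm, "gi", cycles, params) * ut$dec_gi
}

#' Per-cycle health-state utility
#'
#' Dead patients contribute utility 0. Alive patients start from the base
#' utility (0.90); a decrement of 0.17 applies in the PSA-failure and ADT
#' states; prevalence-weighted adverse-event decrements (urinary 0.17,
#' sexual 0.11 scaled by `sexual_weight`, gastrointestinal `dec_gi`) are
#' subtracted additively; the result is floored at 0. With
#' `settings$multiplicative_utilities = TRUE` the adverse-event burden is
#' instead applied as a relative factor,
#' `(base - state decrement) * (1 - burden / base)`.
#'
#' @inheritParams ae_prevalence
#' @param state A health-state name from [health_states()].
#' @return Utility value(s) in \[0, base_utility\].
#' @export
state_utility <- function(arm, state, cycle, params) {
  state <- match.arg(state, health_states())
  if (state == "DEAD") return(rep(0, length(cycle)))
  ut <- params$utilities
  dec_state <- if (state %in% c("PSA_FAILURE", "ADT")) ut$dec_psa_failure else 0
  burden <- ae_burden(arm, cycle, params)
  if (isTRUE(params$settings$multiplicative_utilities)) {
    u <- (ut$base_utility - dec_state) * (1 - burden / ut$base_utility)
  } else {
    u <- ut$base_utility - dec_state - burden
  }
  pmax(0, u)
}

# (H x 5) utility matrix over cycles 0..H-1 for fast accumulation
utility_matrix <- function(arm, params, H) {
  if (H == 0L) return(matrix(0, 0, 5))
  cyc <- 0:(H - 1L)
  vapply(health_states(),
         function(s) state_utility(arm, s, cyc, params),
         numeric(H))
}

#' Per-cycle cost of one trace slice
#'
#' Cycle 0 carries the full upfront treatment cost (the whole cohort is
#' in `INITIAL_TREATMENT`). Every cycle accrues one-twelfth of the annual
#' ADT cost per unit of ADT occupancy, plus — in the RARP arm only — the
#' salvage radiotherapy course for each new entrant into `PSA_FAILURE`,
#' plus any configured monthly adverse-event management cost weighted by
#' prevalence among the alive. Dead patients accrue nothing.
#'
#' @inheritParams ae_prevalence
#' @param occupancy Named length-5 occupancy vector at this cycle.
#' @param new_failure Proportion newly entering `PSA_FAILURE` this cycle.
#' @return Cost in JPY for this cycle (undiscounted).
#' @export
cycle_cost <- function(arm, occupancy, new_failure, cycle, params) {
  if (new_failure < 0 || any(occupancy < 0))
    stop("negative occupancy or entry flow", call. = FALSE)
  co <- params$costs
  cost <- occupancy[["ADT"]] * co$adt_annual / 12
  if (cycle == 0)
    cost <- cost + upfront_cost(arm, params) * sum(occupancy) # full cohort
  if (arm_class(arm) == "RARP")
    cost <- cost + new_failure * co$salvage_rt
  alive <- sum(occupancy) - occupancy[["DEAD"]]
  for (ev in ae_events()) {
    mgmt <- co$ae_management[[ev]]
    if (mgmt > 0)
      cost <- cost + mgmt * ae_prevalence(arm, ev, cycle, params) * alive
  }
  unname(cost)
}

# monthly discount factors d(t) = (1 + r)^(-t/12) over cycles 0..H-1
discount_factors <- function(params, H) {
  if (H == 0L) return(numeric(0))
  (1 + params$settings$annual_discount)^(-(0:(H - 1L)) / 12)
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' Sums per-cycle costs and utility-weighted occupancy over cycles
#' `0 .. H-1` (occupancy counted at cycle start, no half-cycle
#' correction), each month contributing `1/12` of a quality-adjusted
#' year, discounted at `d(t) = (1 + annual_discount)^(-t/12)`.
#'
#' @param trace A `cohort_trace` from [run_cohort()] for this arm.
#' @inheritParams upfront_cost
#' @return An object of class `arm_result`: `arm`, `total_cost`,
#'   `total_qalys` (discounted), `undiscounted_cost`,
#'   `undiscounted_qalys`, and provenance hashes.
#' @export
accumulate <- function(trace, arm, params) {
  arm <- match.arg(arm, arms())
  stopifnot(inherits(trace, "cohort_trace"))
  if (!identical(trace$arm, arm))
    stop(sprintf("trace was produced for arm %s, not %s", trace$arm, arm),
         call. = FALSE)
  H <- trace$horizon_cycles
  d <- discount_factors(params, H)
  if (H == 0L) {
    res <- list(arm = arm, total_cost = 0, total_qalys = 0,
                undiscounted_cost = 0, undiscounted_qalys = 0,
                param_hash = trace$param_hash,
                life_table_hash = trace$life_table_hash)
    return(structure(res, class = "arm_result"))
  }
  occ <- trace$occupancy[seq_len(H), , drop = FALSE]
  u <- utility_matrix(arm, params, H)
  qaly_t <- rowSums(occ * u) / 12

  co <- params$costs
  cost_t <- occ[, "ADT"] * co$adt_annual / 12
  cost_t[1] <- cost_t[1] + upfront_cost(arm, params) * sum(occ[1, ])
  if (arm_class(arm) == "RARP")
    cost_t <- cost_t + trace$new_failure[seq_len(H)] * co$salvage_rt
  mgmt <- unlist(co$ae_management)
  if (any(mgmt > 0)) {
    alive <- rowSums(occ) - occ[, "DEAD"]
    cyc <- 0:(H - 1L)
    for (ev in ae_events()) {
      if (co$ae_management[[ev]] > 0)
        cost_t <- cost_t + co$ae_management[[ev]] *
          ae_prevalence(arm, ev, cyc, params) * alive
    }
  }
  structure(list(arm = arm,
                 total_cost = sum(d * cost_t),
                 total_qalys = sum(d * qaly_t),
                 undiscounted_cost = sum(cost_t),
                 undiscounted_qalys = sum(qaly_t),
                 param_hash = trace$param_hash,
                 life_table_hash = trace$life_table_hash),
            class = "arm_result")
}

#' Incremental cost-effectiveness ratio with dominance labels
#'
#' `ICER = delta_cost / delta_qalys`. When the incremental QALYs are
#' positive and the incremental cost non-positive the alternative is
#' `DOMINANT` (cheaper and more effective); the mirror case is
#' `DOMINATED`; a zero QALY difference leaves the ratio `UNDEFINED`.
#' Labels are returned, never raised as errors.
#'
#' @param delta_cost Incremental cost (JPY), alternative minus reference.
#' @param delta_qalys Incremental QALYs, alternative minus reference.
#' @return List with `icer` (JPY/QALY, `NA` under a label) and
#'   `dominance` (`"ICER"`, `"DOMINANT"`, `"DOMINATED"`, `"UNDEFINED"`).
#' @export
#' @examples
#' compute_icer(16724, 0.1164)
compute_icer <- function(delta_cost, delta_qalys) {
  if (delta_qalys == 0) {
    list(icer = NA_real_, dominance = "UNDEFINED")
  } else if (delta_qalys > 0 && delta_cost <= 0) {
    list(icer = NA_real_, dominance = "DOMINANT")
  } else if (delta_qalys < 0 && delta_cost >= 0) {
    list(icer = NA_real_, dominance = "DOMINATED")
  } else {
    list(icer = delta_cost / delta_qalys, dominance = "ICER")
  }
}

#' Incremental net monetary benefit
#'
#' `INMB = delta_qalys * wtp - delta_cost`. Unlike the ICER it is
#' well-defined for every sign combination, including dominance.
#'
#' @inheritParams compute_icer
#' @param wtp Willingness-to-pay threshold (JPY/QALY, non-negative).
#' @return INMB in JPY.
#' @export
compute_inmb <- function(delta_qalys, delta_cost, wtp) {
  stopifnot(wtp >= 0)
  delta_qalys * wtp - delta_cost
}

#' Compare two arm results
#'
#' Computes incremental cost and QALYs of `alternative` over `reference`
#' (by convention RARP is the reference), the ICER or dominance label,
#' and the INMB at the stated threshold. Errors if the two results were
#' produced under different parameter sets or life tables.
#'
#' @param reference,alternative `arm_result` objects from [accumulate()].
#' @param wtp Willingness-to-pay threshold (JPY/QALY).
#' @return Object of class `cua_comparison`: `reference`, `alternative`,
#'   `delta_cost`, `delta_qalys`, `icer`, `dominance`, `inmb`, `wtp`.
#' @export
compare <- function(reference, alternative, wtp) {
  stopifnot(inherits(reference, "arm_result"),
            inherits(alternative, "arm_result"))
  if (!identical(reference$param_hash, alternative$param_hash) ||
      !identical(reference$life_table_hash, alternative$life_table_hash))
    stop("arm results come from different parameter sets or life tables",
         call. = FALSE)
  dc <- alternative$total_cost - reference$total_cost
  dq <- alternative$total_qalys - reference$total_qalys
  ic <- compute_icer(dc, dq)
  structure(list(reference = reference$arm, alternative = alternative$arm,
                 delta_cost = dc, delta_qalys = dq,
                 icer = ic$icer, dominance = ic$dominance,
                 inmb = compute_inmb(dq, dc, wtp), wtp = wtp),
            class = "cua_comparison")
}

#' Discounted cumulative sexual-dysfunction exposure
#'
#' The discounted sum over cycles of alive occupancy times
#' sexual-dysfunction prevalence, in month units divided by 12. The INMB
#' is affine in the sexual-disutility weight with model-free slope
#' `wtp * dec_sexual * (exposure_RARP - exposure_IMRT)`; this helper
#' exposes the coefficient for verification.
#'
#' @inheritParams accumulate
#' @return Discounted prevalence-weighted person-years of sexual
#'   dysfunction.
#' @export
sexual_exposure <- function(trace, arm, params) {
  H <- trace$horizon_cycles
  if (H == 0L) return(0)
  occ <- trace$occupancy[seq_len(H), , drop = FALSE]
  alive <- rowSums(occ[, 1:4, drop = FALSE])
  prev <- ae_prevalence(arm, "sexual", 0:(H - 1L), params)
  sum(discount_factors(params, H) * alive * prev) / 12
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost JPY %s, %.4f QALYs (discounted)\n",
              x$arm, format(round(x$total_cost), big.mark = ","),
              x$total_qalys))
  invisible(x)
}

#' @export
print.cua_comparison <- function(x, ...) {
  cat(sprintf("<cua_comparison> %s vs %s (reference)\n",
              x$alternative, x$reference))
  cat(sprintf("  delta cost JPY %s, delta QALYs %.4f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qalys))
  if (x$dominance == "ICER") {
    cat(sprintf("  ICER JPY %s /QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else {
    cat(sprintf("  %s\n", x$dominance))
  }
  cat(sprintf("  INMB JPY %s at WTP %s\n",
              format(round(x$inmb), big.mark = ","),
              format(x$wtp, big.mark = ",")))
  invisible(x)
}
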