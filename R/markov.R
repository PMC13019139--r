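#' Health states of the cohort model
#'
#' Five mutually exclusive states: the initial-treatment cycle, PSA
#' control, PSA failure (a one-cycle tunnel in which the salvage decision
#' is made), uncontrolled disease on androgen deprivation therapy, and
#' death (absorbing, all-cause).
#'
#' @return Character vector of the five state names in model order.
#' @export
health_states <- function() {
  c("INITIAL_TREATMENT", "PSA_CONTROLLED", "PSA_FAILURE", "ADT", "DEAD")
}

# monthly death probability applying to the transition out of each cycle
# t = 0 .. H-1; age advances a whole year every 12 cycles
monthly_death_probs <- function(params, life_table) {
  st <- params$settings
  H <- 12L * as.integer(st$horizon_years)
  if (H == 0L) return(numeric(0))
  validate_life_table(life_table, start_age = st$start_age,
                      horizon_years = st$horizon_years)
  cyc <- 0:(H - 1L)
  age <- st$start_age + cyc %/% 12L
  q_annual <- life_table$qx[match(age, life_table$age)]
  annual_to_monthly_prob(q_annual)
}

# clinical transition ingredients for one arm
arm_dynamics <- function(arm, params) {
  arm <- match.arg(arm, arms())
  cl <- params$clinical
  list(
    p_control = if (arm == "RARP") cl$psa_control_rarp else cl$psa_control_imrt,
    # IMRT failures transition directly to ADT without salvage therapy
    salvage = if (arm == "RARP") cl$salvage_success else 0,
    late_failure = cl$late_failure_monthly_hazard
  )
}

#' Build the one-cycle transition matrix
#'
#' Rows index the origin state, columns the destination, in
#' [health_states()] order. Death competes proportionally with the
#' clinical transitions: every clinical probability is scaled by
#' `1 - q_m`, where `q_m` is the monthly all-cause death probability at
#' the cohort's current age (`start_age + floor(cycle / 12)`).
#'
#' From `INITIAL_TREATMENT`, a fraction `p_control` moves to
#' `PSA_CONTROLLED` and the rest to `PSA_FAILURE`. `PSA_FAILURE` is a
#' one-cycle tunnel: in the RARP arm salvage radiotherapy restores
#' control with probability `salvage_success`, the remainder moving to
#' `ADT`; in the IMRT arms everyone moves to `ADT`. `PSA_CONTROLLED`
#' persists apart from the optional late-failure hazard; `ADT` persists;
#' `DEAD` is absorbing.
#'
#' @inheritParams upfront_cost
#' @param cycle Cycle index (0-based) of the origin row.
#' @param life_table A `life_table` covering the cohort's ages.
#' @return A 5x5 row-stochastic matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(arm, params, cycle, life_table) {
  stopifnot(cycle >= 0)
  st <- params$settings
  age <- st$start_age + cycle %/% 12L
  idx <- match(age, life_table$age)
  if (is.na(idx))
    stop(sprintf("life table does not cover age %d (cycle %d)", age, cycle),
         call. = FALSE)
  qx <- life_table$qx[idx]
  if (qx < 0 || qx > 1) stop("life-table qx outside [0, 1]", call. = FALSE)
  transition_matrix_qm(arm_dynamics(arm, params), annual_to_monthly_prob(qx))
}

transition_matrix_qm <- function(dyn, qm) {
  s <- 1 - qm
  p <- dyn$p_control
  salv <- dyn$salvage
  lf <- dyn$late_failure
  m <- matrix(0, 5, 5, dimnames = list(health_states(), health_states()))
  m[1, ] <- c(0, p * s, (1 - p) * s, 0, qm)
  m[2, ] <- c(0, (1 - lf) * s, lf * s, 0, qm)
  m[3, ] <- c(0, salv * s, 0, (1 - salv) * s, qm)
  m[4, ] <- c(0, 0, 0, s, qm)
  m[5, ] <- c(0, 0, 0, 0, 1)
  m
}

#' Run the monthly cohort simulation for one arm
#'
#' Propagates the state-occupancy distribution through
#' `H = 12 * horizon_years` monthly transitions, starting with the whole
#' cohort in `INITIAL_TREATMENT`. Besides occupancy, the per-cycle inflow
#' into `PSA_FAILURE` and into `ADT` is recorded so that one-time costs
#' (salvage radiotherapy) can be attached to new entrants.
#'
#' @inheritParams build_transition_matrix
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (`(H+1) x 5` matrix, rows = cycles `0..H`), `new_failure`,
#'   `new_adt` (length `H+1` inflow vectors), `arm`, and provenance
#'   hashes of the parameters and life table.
#' @export
run_cohort <- function(arm, params, life_table) {
  arm <- match.arg(arm, arms())
  validate_parameters(params)
  H <- 12L * as.integer(params$settings$horizon_years)
  qm <- monthly_death_probs(params, life_table)
  dyn <- arm_dynamics(arm, params)
  occ <- matrix(0, H + 1L, 5L,
                dimnames = list(0:H, health_states()))
  occ[1L, 1L] <- 1
  new_failure <- numeric(H + 1L)
  new_adt <- numeric(H + 1L)
  p <- dyn$p_control; salv <- dyn$salvage; lf <- dyn$late_failure
  ini <- 1; ctl <- 0; fl <- 0; adt <- 0; dd <- 0
  for (t in seq_len(H)) {
    s <- 1 - qm[t]
    nf <- (ini * (1 - p) + ctl * lf) * s
    nc <- (ini * p + ctl * (1 - lf) + fl * salv) * s
    na <- fl * (1 - salv) * s
    dd <- dd + (ini + ctl + fl + adt) * qm[t]
    ctl <- nc; adt <- adt * s + na; fl <- nf; ini <- 0
    occ[t + 1L, ] <- c(0, ctl, fl, adt, dd)
    new_failure[t + 1L] <- nf
    new_adt[t + 1L] <- na
  }
  structure(list(occupancy = occ, new_failure = new_failure,
                 new_adt = new_adt, arm = arm, horizon_cycles = H,
                 param_hash = rlang::hash(unclass(params)),
                 life_table_hash = rlang::hash(life_table[, c("age", "qx")])),
            class = "cohort_trace")
}

#' Validate a cohort trace
#'
#' Non-mutating diagnostic: checks probability-mass conservation (each
#' row sums to 1 within 1e-10), monotone non-decreasing `DEAD` occupancy,
#' and non-negativity of occupancies and entry flows.
#'
#' @param trace A `cohort_trace`.
#' @return A list with logical fields `conservation`, `dead_monotone`,
#'   `non_negative`, and `ok` (all three).
#' @export
validate_trace <- function(trace) {
  occ <- trace$occupancy
  conservation <- all(abs(rowSums(occ) - 1) <= 1e-10)
  dead <- occ[, "DEAD"]
  dead_monotone <- all(diff(dead) >= -1e-12)
  non_negative <- all(occ >= -1e-12) &&
    all(trace$new_failure >= -1e-12) && all(trace$new_adt >= -1e-12)
  list(conservation = conservation, dead_monotone = dead_monotone,
       non_negative = non_negative,
       ok = conservation && dead_monotone && non_negative)
}

#' Export a cohort trace as CSV
#'
#' Columns: `cycle,initial,controlled,failure,adt,dead,new_failure,new_adt`.
#'
#' @param trace A `cohort_trace`.
#' @param file Destination path.
#' @export
write_trace <- function(trace, file) {
  occ <- trace$occupancy
  df <- data.frame(cycle = 0:trace$horizon_cycles,
                   initial = occ[, 1], controlled = occ[, 2],
                   failure = occ[, 3], adt = occ[, 4], dead = occ[, 5],
                   new_failure = trace$new_failure, new_adt = trace$new_adt)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- x$horizon_cycles
  cat(sprintf("<cohort_trace> arm %s, %d monthly cycles\n", x$arm, H))
  cat(sprintf("  final occupancy: controlled %.4f, ADT %.4f, dead %.4f\n",
              x$occupancy[H + 1, "PSA_CONTROLLED"],
              x$occupancy[H + 1, "ADT"], x$occupancy[H + 1, "DEAD"]))
  invisible(x)
}
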