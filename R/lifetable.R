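#' Specification for a synthetic Gompertz-Makeham life table
#'
#' The cohort model needs an age-indexed schedule of annual all-cause
#' death probabilities for men from the entry age onwards. When no
#' national life table is supplied, one is synthesized from the
#' Gompertz-Makeham mortality law
#' \deqn{q(x) = 1 - \exp\{-(a + b e^{c x})\},}
#' the standard two-parameter description of adult mortality plus a
#' constant background hazard. The scale `b` can be calibrated so that
#' the discrete life expectancy at 65 hits a target (default 19.4 years,
#' typical of contemporary Japanese men).
#'
#' @param makeham_a Age-independent annual hazard floor (>= 0).
#' @param gompertz_b Hazard scale at age 0 (> 0).
#' @param gompertz_c Log-slope of the hazard per year of age (> 0).
#' @param age_range Integer vector `c(min, max)` of ages covered.
#' @param target_ex65 Optional life expectancy at age 65 (years) to
#'   calibrate `b` against; `NULL` skips calibration.
#' @return An object of class `life_table_spec`.
#' @export
life_table_spec <- function(makeham_a = 5e-4, gompertz_b = 2e-5,
                            gompertz_c = 0.095, age_range = c(65L, 110L),
                            target_ex65 = 19.4) {
  stopifnot(is.numeric(makeham_a), makeham_a >= 0,
            is.numeric(gompertz_b), gompertz_b > 0,
            is.numeric(gompertz_c), gompertz_c > 0,
            length(age_range) == 2L, age_range[1] < age_range[2])
  structure(list(model = "gompertz_makeham", makeham_a = makeham_a,
                 gompertz_b = gompertz_b, gompertz_c = gompertz_c,
                 age_range = as.integer(age_range),
                 target_ex65 = target_ex65),
            class = "life_table_spec")
}

gm_qx <- function(ages, a, b, c) 1 - exp(-(a + b * exp(c * ages)))

#' Generate a synthetic life table
#'
#' Evaluates the Gompertz-Makeham annual death probabilities over the
#' spec's age range. If `target_ex65` is set, `gompertz_b` is rescaled by
#' root-finding until the discrete life expectancy at 65 matches the
#' target within 0.05 years (the calibration is idempotent to well below
#' that tolerance).
#'
#' @param spec A [life_table_spec()].
#' @return A `data.frame` with columns `age` and `qx`, classed
#'   `life_table`; attribute `"spec"` holds the (calibrated) spec.
#' @export
generate_life_table <- function(spec = life_table_spec()) {
  stopifnot(inherits(spec, "life_table_spec"))
  ages <- seq(spec$age_range[1], spec$age_range[2])
  if (!is.null(spec$target_ex65)) {
    target <- spec$target_ex65
    f <- function(log_b) {
      qx <- pmin(1, gm_qx(ages, spec$makeham_a, exp(log_b), spec$gompertz_c))
      life_expectancy_qx(qx, ages, at_age = 65) - target
    }
    lo <- log(spec$gompertz_b) - 15
    hi <- log(spec$gompertz_b) + 15
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
      stop(sprintf(paste0("life-table calibration failed: target ex65 = %.2f not ",
                          "bracketed (ex65 in [%.2f, %.2f] over the search range)"),
                   target, target + fhi, target + flo), call. = FALSE)
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
    spec$gompertz_b <- exp(root$root)
  }
  qx <- pmin(1, gm_qx(ages, spec$makeham_a, spec$gompertz_b, spec$gompertz_c))
  out <- data.frame(age = ages, qx = qx)
  class(out) <- c("life_table", "data.frame")
  attr(out, "spec") <- spec
  out
}

# discrete period life expectancy at `at_age` given annual qx over `ages`:
# survivors counted at each later birthday plus a half-year for the death year
life_expectancy_qx <- function(qx, ages, at_age) {
  keep <- ages >= at_age
  lx <- cumprod(1 - qx[keep])
  sum(lx) + 0.5
}

#' Discrete life expectancy from a life table
#'
#' @param life_table A `life_table` data frame (`age`, `qx`).
#' @param at_age Age at which to evaluate (default 65).
#' @return Expected remaining years, counting survivors at whole-year
#'   birthdays plus half a year in the year of death.
#' @export
life_expectancy <- function(life_table, at_age = 65) {
  validate_life_table(life_table)
  life_expectancy_qx(life_table$qx, life_table$age, at_age)
}

validate_life_table <- function(life_table, start_age = NULL,
                                horizon_years = NULL, synthetic = FALSE) {
  if (!is.data.frame(life_table) || !all(c("age", "qx") %in% names(life_table)))
    stop("a life table needs columns 'age' and 'qx'", call. = FALSE)
  ages <- life_table$age
  if (any(diff(ages) != 1))
    stop("life-table ages must be contiguous whole years", call. = FALSE)
  if (any(!is.finite(life_table$qx)) || any(life_table$qx < 0) ||
      any(life_table$qx > 1))
    stop("life-table qx values must lie in [0, 1]", call. = FALSE)
  if (any(diff(life_table$qx) < 0)) {
    if (synthetic)
      stop("synthetic life-table qx must be non-decreasing with age", call. = FALSE)
    warning("life-table qx is not monotone in age; using as supplied", call. = FALSE)
  }
  if (!is.null(start_age)) {
    need <- seq(start_age, start_age + horizon_years)
    if (!all(need %in% ages))
      stop(sprintf("life table must cover ages %d-%d (missing: %s)",
                   min(need), max(need),
                   paste(setdiff(need, ages), collapse = ", ")), call. = FALSE)
  }
  invisible(life_table)
}

#' Read / write a life table as CSV
#'
#' The on-disk format is a two-column CSV with header `age,qx`.
#' `read_life_table()` validates coverage and range and warns on
#' non-monotone `qx`; the pair round-trips exactly on valid tables.
#'
#' @param file Path to the CSV file.
#' @param start_age,horizon_years Optional coverage requirement: the table
#'   must contain ages `start_age .. start_age + horizon_years`.
#' @return A `life_table` data frame.
#' @export
read_life_table <- function(file, start_age = NULL, horizon_years = NULL) {
  tab <- utils::read.csv(file, colClasses = c("integer", "numeric"))
  if (!identical(names(tab)[1:2], c("age", "qx")))
    stop("life-table CSV must have header 'age,qx'", call. = FALSE)
  validate_life_table(tab, start_age = start_age, horizon_years = horizon_years)
  class(tab) <- c("life_table", "data.frame")
  tab
}

#' @rdname read_life_table
#' @param life_table A `life_table` data frame to write.
#' @export
write_life_table <- function(life_table, file) {
  validate_life_table(life_table)
  # %.17g so that read_life_table() round-trips bit-exactly
  out <- data.frame(age = life_table$age,
                    qx = sprintf("%.17g", life_table$qx))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
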