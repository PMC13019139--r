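# canonical sensitivity-analysis parameters: dotted path + distribution family
sa_parameter_table <- function() {
  prob <- c("clinical.psa_control_imrt", "clinical.psa_control_rarp",
            "clinical.salvage_success",
            "clinical.ae_prevalence.IMRT.urinary",
            "clinical.ae_prevalence.IMRT.sexual",
            "clinical.ae_prevalence.IMRT.gi",
            "clinical.ae_prevalence.RARP.urinary",
            "clinical.ae_prevalence.RARP.sexual",
            "clinical.cure_urinary_rarp", "clinical.cure_sexual_rarp")
  util <- c("utilities.base_utility", "utilities.dec_psa_failure",
            "utilities.dec_urinary", "utilities.dec_sexual",
            "utilities.dec_gi")
  cost <- c("costs.imrt20_cost", "costs.imrt38_cost", "costs.rarp_surgery",
            "costs.rarp_hospitalization", "costs.rarp_anesthesia",
            "costs.salvage_rt", "costs.adt_annual")
  data.frame(path = c(prob, util, cost),
             family = c(rep("beta", length(prob) + length(util)),
                        rep("gamma", length(cost))),
             stringsAsFactors = FALSE)
}

#' Default one-way sensitivity ranges
#'
#' One range per sensitivity parameter: plus/minus 25% of the base-case
#' value, except the PSA control probabilities which use the explicit
#' plausible range 0.80 to 0.95. Probabilities and utilities are clipped
#' to \[0, 1\]; a parameter with base value 0 yields a degenerate (0, 0)
#' range and is flagged.
#'
#' @inheritParams upfront_cost
#' @return Data frame with columns `path`, `base`, `low`, `high`,
#'   `basis` (`"plus-minus-25pct"` or `"explicit"`), `degenerate`.
#' @export
default_ranges <- function(params) {
  tab <- sa_parameter_table()
  base <- vapply(tab$path, function(p) get_param(params, p), numeric(1))
  low <- 0.75 * base
  high <- 1.25 * base
  bounded <- tab$family == "beta"
  low[bounded] <- pmax(0, low[bounded])
  high[bounded] <- pmin(1, high[bounded])
  basis <- rep("plus-minus-25pct", nrow(tab))
  psa <- tab$path %in% c("clinical.psa_control_imrt",
                         "clinical.psa_control_rarp")
  low[psa] <- 0.80
  high[psa] <- 0.95
  basis[psa] <- "explicit"
  data.frame(path = tab$path, base = unname(base), low = unname(low),
             high = unname(high), basis = basis,
             degenerate = base == 0, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For every parameter range, rebuilds both arms with the parameter at
#' its low and at its high value (all others held at base) and records
#' the INMB of the alternative (default IMRT-20) versus RARP at the
#' given threshold. Entries are sorted by descending spread
#' `|INMB(high) - INMB(low)|`. A model failure at one extreme marks that
#' entry failed without affecting the others.
#'
#' @inheritParams upfront_cost
#' @param ranges Data frame as returned by [default_ranges()].
#' @param wtp Willingness-to-pay threshold (JPY/QALY).
#' @param life_table A `life_table` covering the horizon.
#' @param alternative Arm compared against RARP (default `"IMRT20"`).
#' @return Data frame `path`, `low`, `high`, `inmb_low`, `inmb_high`,
#'   `spread`, `failed`, sorted by descending spread.
#' @export
one_way_dsa <- function(params, ranges = default_ranges(params), wtp,
                        life_table, alternative = "IMRT20") {
  inmb_at <- function(path, value) {
    p2 <- set_param(params, path, value)
    ref <- accumulate(run_cohort("RARP", p2, life_table), "RARP", p2)
    alt <- accumulate(run_cohort(alternative, p2, life_table),
                      alternative, p2)
    compare(ref, alt, wtp)$inmb
  }
  n <- nrow(ranges)
  inmb_low <- inmb_high <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      c(inmb_at(ranges$path[i], ranges$low[i]),
        inmb_at(ranges$path[i], ranges$high[i])),
      error = function(e) NULL)
    if (is.null(res)) failed[i] <- TRUE
    else { inmb_low[i] <- res[1]; inmb_high[i] <- res[2] }
  }
  out <- data.frame(path = ranges$path, low = ranges$low,
                    high = ranges$high, inmb_low = inmb_low,
                    inmb_high = inmb_high,
                    spread = abs(inmb_high - inmb_low), failed = failed,
                    stringsAsFactors = FALSE)
  out[order(-out$spread, out$path), , drop = FALSE]
}

#' Parameter-uncertainty specification for probabilistic SA
#'
#' Assigns each sensitivity parameter its sampling family — beta for
#' probabilities and utilities, gamma for costs, log-normal available
#' for relative-risk-type inputs — with the base-case value as mean and,
#' by default, a standard deviation of 25% of the mean (the published
#' analysis does not report its standard deviations). Parameters with a
#' zero base value are held fixed. Distributions are parameterized by
#' matching the first two moments.
#'
#' @inheritParams upfront_cost
#' @param sd_frac Standard deviation as a fraction of the mean
#'   (default 0.25), applied to every non-fixed parameter.
#' @param n_iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer RNG seed.
#' @param overrides Optional named list `path -> list(family=, sd=)`
#'   overriding individual entries.
#' @return Object of class `uncertainty_spec`: data frame `entries`
#'   (`path`, `family`, `mean`, `sd`) plus `n_iterations` and `seed`.
#' @export
default_uncertainty_spec <- function(params, sd_frac = 0.25,
                                     n_iterations = 10000L, seed = 1L,
                                     overrides = NULL) {
  stopifnot(sd_frac > 0, n_iterations >= 1)
  tab <- sa_parameter_table()
  tab$mean <- vapply(tab$path, function(p) get_param(params, p), numeric(1))
  tab$sd <- sd_frac * tab$mean
  tab$family[tab$mean == 0] <- "fixed"
  tab$sd[tab$family == "fixed"] <- 0
  if (!is.null(overrides)) {
    for (path in names(overrides)) {
      i <- match(path, tab$path)
      if (is.na(i)) stop(sprintf("unknown parameter '%s' in overrides", path),
                         call. = FALSE)
      ov <- overrides[[path]]
      if (!is.null(ov$family)) tab$family[i] <- ov$family
      if (!is.null(ov$sd)) tab$sd[i] <- ov$sd
    }
  }
  for (i in seq_len(nrow(tab))) check_moments(tab[i, ])
  structure(list(entries = tab, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "uncertainty_spec")
}

check_moments <- function(entry) {
  m <- entry$mean; s <- entry$sd
  if (entry$family == "fixed") return(invisible(TRUE))
  if (s <= 0)
    stop(sprintf("parameter '%s': sd must be positive unless fixed",
                 entry$path), call. = FALSE)
  if (entry$family == "beta") {
    if (m <= 0 || m >= 1)
      stop(sprintf("parameter '%s': beta requires mean in (0, 1)", entry$path),
           call. = FALSE)
    if (s^2 >= m * (1 - m))
      stop(sprintf("parameter '%s': infeasible beta moments (sd^2 = %.4g >= mean(1-mean) = %.4g)",
                   entry$path, s^2, m * (1 - m)), call. = FALSE)
  }
  if (entry$family %in% c("gamma", "lognormal") && m <= 0)
    stop(sprintf("parameter '%s': %s requires a positive mean",
                 entry$path, entry$family), call. = FALSE)
  invisible(TRUE)
}

# one draw from a moment-matched family
draw_moment_matched <- function(family, m, s) {
  switch(family,
    fixed = m,
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      stats::rbeta(1, m * nu, (1 - m) * nu)
    },
    gamma = stats::rgamma(1, shape = (m / s)^2, rate = m / s^2),
    lognormal = {
      sigma2 <- log(1 + (s / m)^2)
      stats::rlnorm(1, log(m) - sigma2 / 2, sqrt(sigma2))
    },
    stop(sprintf("unknown distribution family '%s'", family), call. = FALSE)
  )
}

#' Draw one parameter set from an uncertainty specification
#'
#' Each non-fixed parameter is sampled independently from its family
#' parameterized by matching mean and standard deviation. Sampled
#' utility decrements are truncated (proportionally rescaled) so their
#' sum never exceeds the sampled base utility; the result satisfies all
#' parameter-set invariants. Draws consume the current RNG stream.
#'
#' @inheritParams upfront_cost
#' @param spec An `uncertainty_spec`.
#' @return A validated `cua_parameters` object.
#' @export
sample_parameter_set <- function(params, spec) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  tab <- spec$entries
  out <- params
  for (i in seq_len(nrow(tab))) {
    val <- draw_moment_matched(tab$family[i], tab$mean[i], tab$sd[i])
    out <- set_param(out, tab$path[i], val, validate = FALSE)
  }
  ut <- out$utilities
  decs <- c(ut$dec_psa_failure, ut$dec_urinary, ut$dec_sexual, ut$dec_gi)
  decs <- pmin(decs, ut$base_utility)
  if (sum(decs) > ut$base_utility) decs <- decs * ut$base_utility / sum(decs)
  out$utilities[c("dec_psa_failure", "dec_urinary", "dec_sexual", "dec_gi")] <-
    as.list(decs)
  validate_parameters(out)
  structure(out, class = "cua_parameters")
}

#' Probabilistic sensitivity analysis
#'
#' Runs `spec$n_iterations` Monte Carlo iterations: each samples a
#' parameter set via [sample_parameter_set()], runs both arms through
#' the cohort model, and records the incremental cost and QALYs of the
#' alternative versus RARP. The probability of cost-effectiveness is the
#' fraction of iterations with `delta_qalys * wtp - delta_cost > 0`.
#' Results are bit-reproducible given the seed; an iteration whose model
#' run fails is excluded and counted.
#'
#' @inheritParams one_way_dsa
#' @param spec An `uncertainty_spec` (carries `n_iterations` and `seed`).
#' @return Object of class `prsa_result`: `iterations` data frame
#'   (`iteration`, `delta_cost`, `delta_qalys`), `n`, `n_failed`,
#'   `seed`, `wtp`, `prob_cost_effective`.
#' @export
run_prsa <- function(params, spec, wtp, life_table,
                     alternative = "IMRT20") {
  stopifnot(inherits(spec, "uncertainty_spec"))
  n <- spec$n_iterations
  set.seed(spec$seed)
  dc <- dq <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      p <- sample_parameter_set(params, spec)
      ref <- accumulate(run_cohort("RARP", p, life_table), "RARP", p)
      alt <- accumulate(run_cohort(alternative, p, life_table),
                        alternative, p)
      c(alt$total_cost - ref$total_cost,
        alt$total_qalys - ref$total_qalys)
    }, error = function(e) NULL)
    if (!is.null(res)) { dc[i] <- res[1]; dq[i] <- res[2] }
  }
  ok <- !is.na(dc)
  iters <- data.frame(iteration = seq_len(n)[ok], delta_cost = dc[ok],
                      delta_qalys = dq[ok])
  structure(list(iterations = iters, n = sum(ok), n_failed = sum(!ok),
                 seed = spec$seed, wtp = wtp,
                 prob_cost_effective =
                   mean(iters$delta_qalys * wtp - iters$delta_cost > 0)),
            class = "prsa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold `lambda`, the probability that the alternative is
#' cost-effective is the fraction of PrSA iterations with
#' `delta_qalys * lambda - delta_cost > 0`; the reference strategy's
#' probability is the complement. The CEAC is a deterministic function
#' of the iteration records, so it can be recomputed bit-identically
#' from an exported iterations table.
#'
#' @param result A `prsa_result`, or a data frame with columns
#'   `delta_cost` and `delta_qalys` (e.g. re-read from an export).
#' @param thresholds Non-empty vector of non-negative thresholds
#'   (JPY/QALY); default 0 to 10,000,000 in steps of 100,000.
#' @return Data frame `threshold_jpy`, `prob_alternative`,
#'   `prob_reference`.
#' @export
ceac <- function(result, thresholds = seq(0, 1e7, by = 1e5)) {
  stopifnot(length(thresholds) > 0, all(thresholds >= 0))
  iters <- if (inherits(result, "prsa_result")) result$iterations else result
  stopifnot(is.data.frame(iters),
            all(c("delta_cost", "delta_qalys") %in% names(iters)))
  prob <- vapply(thresholds, function(lambda) {
    mean(iters$delta_qalys * lambda - iters$delta_cost > 0)
  }, numeric(1))
  data.frame(threshold_jpy = thresholds, prob_alternative = prob,
             prob_reference = 1 - prob)
}

#' Export sensitivity-analysis artifacts as CSV
#'
#' `write_prsa_iterations()` writes `iteration,delta_cost_jpy,delta_qalys`
#' at full precision (so the CEAC recomputed from the file is
#' bit-identical); `write_ceac()` writes
#' `threshold_jpy,prob_imrt,prob_rarp`; `write_tornado()` writes
#' `parameter,low,high,inmb_low,inmb_high,spread` sorted by spread.
#'
#' @param result A `prsa_result`.
#' @param file Destination path.
#' @export
write_prsa_iterations <- function(result, file) {
  it <- result$iterations
  df <- data.frame(iteration = it$iteration,
                   delta_cost_jpy = sprintf("%.17g", it$delta_cost),
                   delta_qalys = sprintf("%.17g", it$delta_qalys))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_prsa_iterations
#' @export
read_prsa_iterations <- function(file) {
  df <- utils::read.csv(file)
  data.frame(iteration = df$iteration, delta_cost = df$delta_cost_jpy,
             delta_qalys = df$delta_qalys)
}

#' @rdname write_prsa_iterations
#' @param curve Data frame from [ceac()].
#' @export
write_ceac <- function(curve, file) {
  df <- data.frame(threshold_jpy = curve$threshold_jpy,
                   prob_imrt = curve$prob_alternative,
                   prob_rarp = curve$prob_reference)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_prsa_iterations
#' @param tornado Data frame from [one_way_dsa()].
#' @export
write_tornado <- function(tornado, file) {
  df <- data.frame(parameter = tornado$path, low = tornado$low,
                   high = tornado$high, inmb_low = tornado$inmb_low,
                   inmb_high = tornado$inmb_high, spread = tornado$spread)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.prsa_result <- function(x, ...) {
  cat(sprintf("<prsa_result> %d iterations (seed %d, %d failed)\n",
              x$n, x$seed, x$n_failed))
  cat(sprintf("  P(cost-effective at WTP %s) = %.3f\n",
              format(x$wtp, big.mark = ","), x$prob_cost_effective))
  invisible(x)
}
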