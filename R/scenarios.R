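run_scenario <- function(label, alternative, params, life_table) {
  validate_parameters(params)
  ref <- accumulate(run_cohort("RARP", params, life_table), "RARP", params)
  alt <- accumulate(run_cohort(alternative, params, life_table),
                    alternative, params)
  structure(list(
    label = label,
    arms = stats::setNames(list(alt, ref), c(alternative, "RARP")),
    comparison = compare(ref, alt, params$settings$wtp),
    provenance = list(param_hash = ref$param_hash,
                      life_table_hash = ref$life_table_hash,
                      timestamp = format(Sys.time(), tz = "UTC",
                                         usetz = TRUE))),
    class = "run_report")
}

#' Run the base-case comparison (IMRT-20 vs RARP)
#'
#' Runs both arms through the cohort model and compares IMRT-20 against
#' RARP (the reference strategy) at the configured willingness-to-pay.
#'
#' @inheritParams one_way_dsa
#' @return Object of class `run_report`: `label`, per-arm `arm_result`s,
#'   the `cua_comparison`, and provenance (parameter and life-table
#'   hashes, timestamp).
#' @export
run_base_case <- function(params, life_table) {
  run_scenario("base_case", "IMRT20", params, life_table)
}

#' Run the conventional-fractionation scenario (IMRT-38 vs RARP)
#'
#' Identical to the base case except for the upfront radiotherapy cost:
#' incremental QALYs are unchanged and the incremental cost is larger by
#' exactly the IMRT-38/IMRT-20 price difference (369,400 JPY at
#' defaults).
#'
#' @inheritParams run_base_case
#' @return A `run_report` (see [run_base_case()]).
#' @export
run_imrt38 <- function(params, life_table) {
  run_scenario("imrt38", "IMRT38", params, life_table)
}

#' Sweep the sexual-dysfunction disutility weight
#'
#' Re-runs the IMRT-20 vs RARP comparison with the sexual-dysfunction
#' utility decrement scaled by each weight in the grid (0 disables it,
#' 1 is the base case). The INMB is affine in the weight; the crossing
#' weight at which it changes sign is located by linear interpolation
#' between the bracketing grid points (reported to three decimals,
#' `NA` when the INMB never changes sign on the grid).
#'
#' @inheritParams run_base_case
#' @param weights Ascending grid of weights in \[0, 1\];
#'   default `seq(0, 1, by = 0.1)`.
#' @return List with `rows` (data frame: `sexual_weight`, `delta_qalys`,
#'   `delta_cost`, `icer`, `dominance`, `inmb`) and `crossing_weight`.
#' @export
sweep_sexual_disutility <- function(params, weights = seq(0, 1, by = 0.1),
                                    life_table) {
  stopifnot(all(weights >= 0), all(weights <= 1), !is.unsorted(weights))
  rows <- lapply(weights, function(w) {
    p2 <- set_param(params, "utilities.sexual_weight", w)
    cmp <- run_scenario("sweep", "IMRT20", p2, life_table)$comparison
    data.frame(sexual_weight = w, delta_qalys = cmp$delta_qalys,
               delta_cost = cmp$delta_cost, icer = cmp$icer,
               dominance = cmp$dominance, inmb = cmp$inmb,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  crossing <- NA_real_
  sgn <- sign(rows$inmb)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0 | sgn[-length(sgn)] == 0)
  if (any(sgn == 0)) {
    crossing <- rows$sexual_weight[which(sgn == 0)[1]]
  } else if (length(flip) > 0) {
    i <- flip[1]
    w0 <- rows$sexual_weight[i]; w1 <- rows$sexual_weight[i + 1]
    y0 <- rows$inmb[i]; y1 <- rows$inmb[i + 1]
    crossing <- round(w0 - y0 * (w1 - w0) / (y1 - y0), 3)
  }
  list(rows = rows, crossing_weight = crossing)
}

#' Write report tables for a set of analyses
#'
#' Emits the per-arm results table (`table2.csv`, JPY and USD columns),
#' a comparison JSON per scenario, and — when supplied — `sweep.csv`,
#' `tornado.csv`, `prsa_iterations.csv` and `ceac.csv`, plus a
#' `manifest.json` listing every artifact with the provenance hashes.
#' Re-rendering from the same inputs reproduces identical files
#' (timestamps live only in the manifest).
#'
#' @param out_dir Output directory (created if needed).
#' @param reports List of `run_report` objects.
#' @param sweep Optional result of [sweep_sexual_disutility()].
#' @param tornado Optional result of [one_way_dsa()].
#' @param prsa Optional `prsa_result`.
#' @param thresholds CEAC threshold grid (see [ceac()]).
#' @param jpy_per_usd Exchange rate for the USD columns.
#' @return Invisibly, the manifest list.
#' @export
render_reports <- function(out_dir, reports, sweep = NULL, tornado = NULL,
                           prsa = NULL, thresholds = seq(0, 1e7, by = 1e5),
                           jpy_per_usd = 152) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  artifacts <- character()
  put <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(out_dir, name)
  }
  tab <- do.call(rbind, lapply(reports, function(rep) {
    do.call(rbind, lapply(rep$arms, function(a) {
      data.frame(scenario = rep$label, arm = a$arm,
                 total_cost_jpy = a$total_cost,
                 total_qalys = a$total_qalys,
                 total_cost_usd = round(jpy_to_usd(a$total_cost,
                                                   jpy_per_usd), 1),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(tab, put("table2.csv"), row.names = FALSE, quote = FALSE)
  for (rep in reports) {
    cmp <- rep$comparison
    jsonlite::write_json(
      list(scenario = rep$label, reference = cmp$reference,
           alternative = cmp$alternative, delta_cost = cmp$delta_cost,
           delta_qalys = cmp$delta_qalys, icer = cmp$icer,
           dominance = cmp$dominance, inmb = cmp$inmb, wtp = cmp$wtp),
      put(paste0("comparison_", rep$label, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(sweep)) {
    utils::write.csv(sweep$rows, put("sweep.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(tornado)) write_tornado(tornado, put("tornado.csv"))
  if (!is.null(prsa)) {
    write_prsa_iterations(prsa, put("prsa_iterations.csv"))
    write_ceac(ceac(prsa, thresholds), put("ceac.csv"))
  }
  manifest <- list(
    scenarios = lapply(reports, function(rep) {
      list(label = rep$label, provenance = rep$provenance)
    }),
    sweep_crossing_weight = if (is.null(sweep)) NULL else
      sweep$crossing_weight,
    prsa = if (is.null(prsa)) NULL else
      list(n = prsa$n, n_failed = prsa$n_failed, seed = prsa$seed,
           wtp = prsa$wtp, prob_cost_effective = prsa$prob_cost_effective),
    artifacts = as.list(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario '%s'\n", x$label))
  for (a in x$arms) print(a)
  print(x$comparison)
  invisible(x)
}
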