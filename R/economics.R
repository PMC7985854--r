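#' Event kinds recognised by the cost schedule
#'
#' Every costed clinical event of the simulation. The three shared kinds
#' (`exam_vt`, `bitewing_pair`, `ai_analysis`) are mouth-level fees divided
#' by the shared-cost divisor (the number of teeth covered by one bitewing
#' pair, default 16); all other fees are charged per tooth.
#'
#' @format Character vector of event-kind names.
#' @export
EVENT_KINDS <- c(
  "exam_vt", "bitewing_pair", "ai_analysis",
  "infiltration", "restoration", "re_restoration", "repair",
  "direct_capping", "rct", "crown", "recrown", "recement",
  "nonsurg_retreat", "surg_retreat", "extraction",
  "implant_iscrown", "reimplant", "refix"
)

SHARED_KINDS <- c("exam_vt", "bitewing_pair", "ai_analysis")

#' Load and validate a cost schedule
#'
#' A cost schedule is a JSON file with a `fees` map (euro, 2020) keyed by
#' the non-AI entries of [EVENT_KINDS], a `shared_divisor` (teeth per
#' bitewing pair, default 16) and an `ai_fee_per_bitewing_pair` (euro per AI
#' analysis of one pair, base case 8). The packaged placeholder schedule
#' (`extdata/costs_placeholder.json`) carries `synthetic: true`: its fees
#' are generated stand-ins with realistic ordering, not catalogue-derived
#' amounts, so absolute euro results under it are illustrative only.
#' An empty template (`extdata/costs_appendix_template.json`) can be filled
#' with fee-catalogue amounts to reproduce absolute costs.
#'
#' @param path Path to a JSON cost schedule.
#' @return A list of class `cost_schedule`.
#' @export
load_cost_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_cost_schedule(x)
}

validate_cost_schedule <- function(x) {
  needed <- setdiff(EVENT_KINDS, "ai_analysis")
  missing <- setdiff(needed, names(x$fees))
  if (length(missing) > 0) {
    stop("cost schedule is missing fees for: ", paste(missing, collapse = ", "))
  }
  fees <- unlist(x$fees[needed])
  if (any(!is.finite(fees)) || any(fees < 0)) stop("fees must be finite and >= 0")
  x$shared_divisor <- x$shared_divisor %||% 16
  if (x$shared_divisor < 1) stop("shared_divisor must be >= 1")
  x$ai_fee_per_bitewing_pair <- x$ai_fee_per_bitewing_pair %||% 8
  if (x$ai_fee_per_bitewing_pair < 0) stop("ai fee must be >= 0")
  structure(x, class = "cost_schedule")
}

#' Placeholder cost schedule shipped with the package
#'
#' @return A validated `cost_schedule` (synthetic placeholder fees).
#' @export
caries_costs <- function() {
  load_cost_schedule(system.file("extdata", "costs_placeholder.json",
                                 package = "cariesim", mustWork = TRUE))
}

#' Present-value discount factor
#'
#' @param year Years since simulation start (cycle index of the cost;
#'   vectorised).
#' @param rate Annual discount rate (base case 0.03).
#' @return `(1 + rate)^(-year)`.
#' @examples
#' discount_factor(10, 0.03)  # 0.7441
#' @export
discount_factor <- function(year, rate = 0.03) {
  stopifnot(all(year >= 0), rate > -1)
  (1 + rate)^(-year)
}

#' Per-tooth cost of one clinical event
#'
#' Procedure fees are charged in full; mouth-level fees (visual-tactile
#' assessment, bitewing pair, AI analysis) are divided by the shared-cost
#' divisor.
#'
#' @param kind Event kind (one of [EVENT_KINDS]).
#' @param schedule A `cost_schedule`.
#' @return Euro cost attributed to the simulated tooth.
#' @examples
#' # AI fee 8 euro per pair shared by 16 teeth -> 0.50 per tooth per exam
#' cost_of_event("ai_analysis", caries_costs())
#' @export
cost_of_event <- function(kind, schedule) {
  if (!kind %in% EVENT_KINDS) {
    stop("unknown event kind '", kind, "'")
  }
  fee <- if (kind == "ai_analysis") {
    schedule$ai_fee_per_bitewing_pair
  } else {
    schedule$fees[[kind]]
  }
  if (is.null(fee)) stop("cost schedule has no fee for '", kind, "'")
  if (kind %in% SHARED_KINDS) fee / schedule$shared_divisor else fee
}

# per-tooth fee lookup vector aligned with EVENT_KINDS (engine hot path)
fee_table <- function(schedule) {
  vapply(EVENT_KINDS, cost_of_event, numeric(1), schedule = schedule)
}

#' Incremental cost-effectiveness ratio
#'
#' Computes the ICER on cohort means: difference in mean discounted cost
#' divided by difference in mean (undiscounted) effectiveness. A negative
#' ICER with positive incremental effectiveness means the test strategy
#' dominates (saves money at higher effectiveness); a negative ICER with
#' negative incremental effectiveness means it is dominated.
#'
#' @param test,control `cohort_result` objects ([run_cohort()]), or lists
#'   with elements `mean_cost` and `mean_effect`.
#' @return A list of class `icer` with `delta_cost`, `delta_effect`,
#'   `icer` (`NA` when the effectiveness difference is exactly zero) and a
#'   `dominance` label.
#' @examples
#' icer(list(mean_cost = 10, mean_effect = 2),
#'      list(mean_cost = 20, mean_effect = 1))  # -10
#' @export
icer <- function(test, control) {
  ms <- function(x) {
    if (inherits(x, "cohort_result")) {
      list(cost = mean(x$cost_discounted), effect = mean(x$effect))
    } else {
      list(cost = x$mean_cost, effect = x$mean_effect)
    }
  }
  a <- ms(test); b <- ms(control)
  dc <- a$cost - b$cost
  de <- a$effect - b$effect
  val <- if (de == 0) NA_real_ else dc / de
  dominance <- if (de == 0) {
    if (dc == 0) "equivalent" else if (dc < 0) "cost_saving_equal_effect" else "costlier_equal_effect"
  } else if (dc <= 0 && de > 0) {
    "test_dominant"
  } else if (dc >= 0 && de < 0) {
    "test_dominated"
  } else {
    "trade_off"
  }
  structure(list(delta_cost = dc, delta_effect = de, icer = val,
                 dominance = dominance), class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  cat(sprintf("ICER: %s euro/year (dC = %.2f, dE = %.3f; %s)\n",
              if (is.na(x$icer)) "undefined" else sprintf("%.1f", x$icer),
              x$delta_cost, x$delta_effect, x$dominance))
  invisible(x)
}

#' Cost-effectiveness plane quadrant fractions
#'
#' Fractions of paired incremental samples falling into the four quadrants
#' of the cost-effectiveness plane. Boundary samples are assigned by a fixed
#' tie rule: a zero cost increment counts as "less costly", a zero
#' effectiveness increment as "less effective". The four fractions sum to 1
#' exactly.
#'
#' @param delta_cost,delta_effect Equal-length numeric vectors of per-sample
#'   increments (test minus control).
#' @return Named numeric vector with elements
#'   `more_costly_more_effective` (upper right),
#'   `less_costly_more_effective` (lower right),
#'   `more_costly_less_effective` (upper left),
#'   `less_costly_less_effective` (lower left).
#' @export
quadrant_fractions <- function(delta_cost, delta_effect) {
  if (length(delta_cost) != length(delta_effect)) {
    stop("delta_cost and delta_effect must have equal length")
  }
  n <- length(delta_cost)
  if (n == 0) stop("no samples supplied")
  costly <- delta_cost > 0
  effective <- delta_effect > 0
  c(
    more_costly_more_effective = sum(costly & effective) / n,
    less_costly_more_effective = sum(!costly & effective) / n,
    more_costly_less_effective = sum(costly & !effective) / n,
    less_costly_less_effective = sum(!costly & !effective) / n
  )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, computes each strategy's
#' probability of being the cost-effective choice: the fraction of paired
#' samples in which its net monetary benefit (`wtp * effectiveness - cost`)
#' is strictly larger, with exact ties split evenly. The two strategies'
#' probabilities sum to 1 at every threshold.
#'
#' @param test,control `cohort_result` objects, paired by tooth index.
#' @param wtp_grid Willingness-to-pay thresholds, euro per retention year.
#' @return A data.frame with columns `wtp`, `p_test`, `p_control`.
#' @export
acceptability_curve <- function(test, control, wtp_grid = seq(0, 100, by = 5)) {
  stopifnot(length(wtp_grid) > 0, all(wtp_grid >= 0))
  e_t <- test$effect; c_t <- test$cost_discounted
  e_c <- control$effect; c_c <- control$cost_discounted
  if (length(e_t) != length(e_c)) stop("cohorts must be paired (equal n)")
  p_test <- vapply(wtp_grid, function(l) {
    nb_t <- l * e_t - c_t
    nb_c <- l * e_c - c_c
    mean(nb_t > nb_c) + 0.5 * mean(nb_t == nb_c)
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_test = p_test, p_control = 1 - p_test)
}

summary_stats <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(x), p2.5 = q[1], p97.5 = q[2])
}

#' Full cost-effectiveness comparison of two simulated cohorts
#'
#' Summarises the paired cohorts (mean and 2.5/97.5 percentiles of cost and
#' effectiveness), and computes the ICER on means, the quadrant fractions of
#' the per-sample incremental cloud, and the acceptability curves.
#'
#' @param test,control `cohort_result` objects simulated with the same seed
#'   (paired by tooth index; common random numbers).
#' @param wtp_grid Thresholds for [acceptability_curve()].
#' @return A list of class `ce_result`.
#' @export
ce_analysis <- function(test, control, wtp_grid = seq(0, 100, by = 5)) {
  stopifnot(inherits(test, "cohort_result"), inherits(control, "cohort_result"))
  if (test$n != control$n) stop("cohorts must have equal size for pairing")
  dc <- test$cost_discounted - control$cost_discounted
  de <- test$effect - control$effect
  structure(list(
    n = test$n,
    summary = data.frame(
      strategy = c(test$strategy, control$strategy),
      cost = c(mean(test$cost_discounted), mean(control$cost_discounted)),
      cost_lo = c(summary_stats(test$cost_discounted)[2],
                  summary_stats(control$cost_discounted)[2]),
      cost_hi = c(summary_stats(test$cost_discounted)[3],
                  summary_stats(control$cost_discounted)[3]),
      effect = c(mean(test$effect), mean(control$effect)),
      effect_lo = c(summary_stats(test$effect)[2],
                    summary_stats(control$effect)[2]),
      effect_hi = c(summary_stats(test$effect)[3],
                    summary_stats(control$effect)[3])
    ),
    icer = icer(test, control),
    quadrants = quadrant_fractions(dc, de),
    ceac = acceptability_curve(test, control, wtp_grid),
    increments = data.frame(delta_cost = dc, delta_effect = de)
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> paired samples:", x$n, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s cost %6.1f (%.1f-%.1f) euro, effect %5.2f (%.1f-%.1f) y\n",
                s$strategy[i], s$cost[i], s$cost_lo[i], s$cost_hi[i],
                s$effect[i], s$effect_lo[i], s$effect_hi[i]))
  }
  print(x$icer)
  q <- x$quadrants
  cat(sprintf("  quadrants: ++ %.1f%%, -+ %.1f%%, +- %.1f%%, -- %.1f%%\n",
              100 * q[1], 100 * q[2], 100 * q[3], 100 * q[4]))
  invisible(x)
}

#' Univariate sensitivity table
#'
#' Runs the AI and control arms under each named preset and tabulates mean
#' cost and effectiveness (with 2.5/97.5 percentiles) per strategy and the
#' ICER, one row per analysis, mirroring a one-way sensitivity table.
#'
#' @param presets Character vector of preset names
#'   (default: all of [scenario_presets()]).
#' @param n Teeth per cohort.
#' @param seed Root seed; each preset row reuses the same seed for both arms
#'   (common random numbers) so rows differ only through the varied input.
#' @param level `"tooth"` (one parameter draw per tooth) or `"sample"`
#'   (two-loop: outer parameter draws, inner cohorts; see [run_psa()]).
#' @param n_inner Inner cohort size when `level = "sample"`.
#' @param params,costs Shared configurations passed to every scenario.
#' @return A data.frame with one row per preset.
#' @export
sensitivity_table <- function(presets = names(scenario_presets()),
                              n = 1000, seed = 1, level = "tooth",
                              n_inner = 50,
                              params = caries_parameters(),
                              costs = caries_costs()) {
  unknown <- setdiff(presets, names(scenario_presets()))
  if (length(unknown) > 0) {
    stop("unknown preset(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(presets, function(nm) {
    ce <- compare_strategies(nm, n = n, seed = seed, level = level,
                             n_inner = n_inner, params = params,
                             costs = costs)
    s <- ce$summary
    it <- which(s$strategy == "ai")
    ic <- which(s$strategy == "control")
    data.frame(
      analysis = nm,
      cost_ai = s$cost[it], cost_ai_lo = s$cost_lo[it], cost_ai_hi = s$cost_hi[it],
      effect_ai = s$effect[it], effect_ai_lo = s$effect_lo[it],
      effect_ai_hi = s$effect_hi[it],
      cost_control = s$cost[ic], cost_control_lo = s$cost_lo[ic],
      cost_control_hi = s$cost_hi[ic],
      effect_control = s$effect[ic], effect_control_lo = s$effect_lo[ic],
      effect_control_hi = s$effect_hi[ic],
      icer = ce$icer$icer
    )
  })
  do.call(rbind, rows)
}

#' Write the standard CEA output files
#'
#' Writes `summary.json` (summaries, ICER, quadrant fractions),
#' `ce_plane.csv` (paired increments) and `ceac.csv` (acceptability curves)
#' for one `ce_result`.
#'
#' @param ce A `ce_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ce_outputs <- function(ce, dir) {
  stopifnot(inherits(ce, "ce_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(n = ce$n, summary = ce$summary,
         icer = unclass(ce$icer), quadrants = as.list(ce$quadrants)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(ce$increments, file.path(dir, "ce_plane.csv"),
                   row.names = FALSE)
  utils::write.csv(ce$ceac, file.path(dir, "ceac.csv"), row.names = FALSE)
  invisible(dir)
}
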