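#' Build one runnable scenario configuration
#'
#' A scenario is one complete arm of the model: risk profile, detection
#' strategy, exam schedule, treatment policy, horizon, discounting, and the
#' parameter and fee configurations. Two scenarios that differ only in
#' `strategy` form a comparison pair (the AI arm differs from the control
#' arm solely in the radiographic accuracy profile and the per-use AI fee).
#'
#' @param strategy `"ai"` (radiographs read with AI assistance) or
#'   `"control"` (radiographs read by dentists alone).
#' @param risk Population caries risk profile, `"low"` (base case) or
#'   `"high"`.
#' @param policy Action on detected initial lesions: `"infiltrate"` (base)
#'   or `"restore"`.
#' @param control_accuracy Accuracy source for the control arm:
#'   `"meta"` (meta-analytic, base case) or `"primary_study"` (the dentists
#'   who read the same test radiographs as the network).
#' @param ai_fee Fee per AI analysis of one bitewing pair, euro (base 8;
#'   4 and 12 in sensitivity analyses). Shared across the teeth covered by
#'   the pair.
#' @param replacement Probability that an extracted tooth is replaced by an
#'   implant-supported crown (base 0.8). `NULL` keeps the value in `params`.
#' @param discount_rate Annual discount rate for costs (base 0.03).
#' @param horizon Number of annual cycles (default 65: ages 12 to 77).
#' @param schedule An [exam_schedule()].
#' @param psa Sample parameters per tooth (`TRUE`) or run at distribution
#'   modes (`FALSE`).
#' @param refp_repeat If `TRUE`, a sound surface already infiltrated after a
#'   false positive can be falsely detected and infiltrated again at later
#'   exams; default `FALSE` (one false-positive infiltration per surface).
#' @param redetect How repeated examinations of the same untreated lesion
#'   behave. `"per_stage"` (default): each method grades a lesion once per
#'   radiographic stage, and a missed lesion is re-assessed only after it
#'   progresses - reader error on an unchanged lesion is treated as
#'   persistent, which is what lets low early-lesion sensitivity leave
#'   lesions undetected long-term. `"per_exam"`: every scheduled exam is an
#'   independent Bernoulli redraw, so any persistent lesion is eventually
#'   detected by either method. False-positive readings of sound surfaces
#'   are independent per exam in both modes.
#' @param params Parameter configuration ([caries_parameters()]).
#' @param costs Cost schedule ([caries_costs()]).
#' @return A list of class `caries_scenario`.
#' @export
build_scenario <- function(strategy = c("ai", "control"),
                           risk = c("low", "high"),
                           policy = c("infiltrate", "restore"),
                           control_accuracy = c("meta", "primary_study"),
                           ai_fee = NULL,
                           replacement = NULL,
                           discount_rate = 0.03,
                           horizon = 65,
                           schedule = exam_schedule(),
                           psa = TRUE,
                           refp_repeat = FALSE,
                           redetect = c("per_stage", "per_exam"),
                           params = caries_parameters(),
                           costs = caries_costs()) {
  strategy <- match.arg(strategy)
  risk <- match.arg(risk)
  policy <- match.arg(policy)
  control_accuracy <- match.arg(control_accuracy)
  redetect <- match.arg(redetect)
  stopifnot(horizon >= 1, discount_rate > -1)
  if (!is.null(ai_fee)) {
    stopifnot(ai_fee >= 0)
    costs$ai_fee_per_bitewing_pair <- ai_fee
  }
  if (!is.null(replacement)) {
    stopifnot(replacement >= 0, replacement <= 1)
    params$clinical$replacement <- param_dist("point", replacement)
  }
  radiograph <- if (strategy == "ai") {
    "radiograph_ai"
  } else if (control_accuracy == "meta") {
    "radiograph_meta"
  } else {
    "radiograph_primary"
  }
  structure(list(
    strategy = strategy,
    risk = risk,
    policy = policy,
    control_accuracy = control_accuracy,
    radiograph = radiograph,
    discount_rate = discount_rate,
    horizon = horizon,
    schedule = schedule,
    psa = psa,
    refp_repeat = refp_repeat,
    redetect = redetect,
    params = validate_parameters(params),
    costs = costs
  ), class = "caries_scenario")
}

#' @export
print.caries_scenario <- function(x, ...) {
  cat("<caries_scenario>\n")
  cat(sprintf("  strategy: %s (%s)\n", x$strategy, x$radiograph))
  cat(sprintf("  risk: %s, policy: %s\n", x$risk, x$policy))
  cat(sprintf("  horizon: %d annual cycles from age %g, discount %g%%\n",
              x$horizon, x$params$age$start, 100 * x$discount_rate))
  cat(sprintf("  AI fee %g euro/pair, replacement %g, PSA %s\n",
              x$costs$ai_fee_per_bitewing_pair,
              dist_from_list(x$params$clinical$replacement)$mode,
              if (x$psa) "on" else "off"))
  invisible(x)
}

#' Scenario presets of the univariate sensitivity analysis
#'
#' The ten preset names cover the base case and the nine one-way variants
#' of the sensitivity table: high-risk population, restore-everything
#' treatment policy, the alternative (primary-study) dentist accuracies in
#' the control arm, low/high AI fees (4/12 euro), 0%/100% tooth replacement
#' after extraction, and 1%/5% discount rates.
#'
#' @return Named list of override lists (keys are [build_scenario()]
#'   arguments).
#' @export
scenario_presets <- function() {
  list(
    base_case = list(),
    high_risk = list(risk = "high"),
    restorative_policy = list(policy = "restore"),
    dentist_accuracy_primary_study = list(control_accuracy = "primary_study"),
    ai_fee_low = list(ai_fee = 4),
    ai_fee_high = list(ai_fee = 12),
    replace_0 = list(replacement = 0),
    replace_100 = list(replacement = 1),
    discount_1pct = list(discount_rate = 0.01),
    discount_5pct = list(discount_rate = 0.05)
  )
}

#' Build a preset scenario
#'
#' Applies one named preset from [scenario_presets()] on top of the base
#' configuration for the given strategy arm.
#'
#' @param name Preset name.
#' @param strategy `"ai"` or `"control"`.
#' @param ... Further arguments passed to [build_scenario()] (e.g. shared
#'   `params`/`costs` objects, `psa`).
#' @return A `caries_scenario`.
#' @examples
#' scenario("ai_fee_high")$costs$ai_fee_per_bitewing_pair  # 12
#' @export
scenario <- function(name = "base_case", strategy = "ai", ...) {
  presets <- scenario_presets()
  if (!name %in% names(presets)) {
    stop("unknown scenario preset '", name, "'; choose one of: ",
         paste(names(presets), collapse = ", "))
  }
  args <- c(presets[[name]], list(strategy = strategy), list(...))
  do.call(build_scenario, args)
}
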