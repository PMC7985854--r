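#' Detection methods due at a cycle
#'
#' Both strategies receive a visual-tactile caries assessment every annual
#' cycle and a pair of bitewing radiographs every second cycle (both starting
#' at cycle 0). In the AI strategy the radiographs are additionally analysed
#' by the diagnostic-assistance software; the radiographic accuracy profile
#' and the per-use fee are the only differences between strategies.
#'
#' @param cycle_index Zero-based cycle index (vectorised not supported;
#'   single integer).
#' @param schedule A list with `vt_interval`, `bw_interval` (cycles, >= 1;
#'   `Inf` disables a method) and optional `vt_offset`, `bw_offset`
#'   (first-exam cycle, default 0).
#' @return Character vector: subset of
#'   `c("visual_tactile", "radiograph")`.
#' @examples
#' exams_due(0, exam_schedule())          # both
#' exams_due(1, exam_schedule())          # visual-tactile only
#' @export
exams_due <- function(cycle_index, schedule = exam_schedule()) {
  stopifnot(cycle_index >= 0)
  out <- character(0)
  vt_off <- schedule$vt_offset %||% 0
  bw_off <- schedule$bw_offset %||% 0
  if (is.finite(schedule$vt_interval) && cycle_index >= vt_off &&
      (cycle_index - vt_off) %% schedule$vt_interval == 0) {
    out <- c(out, "visual_tactile")
  }
  if (is.finite(schedule$bw_interval) && cycle_index >= bw_off &&
      (cycle_index - bw_off) %% schedule$bw_interval == 0) {
    out <- c(out, "radiograph")
  }
  out
}

#' Exam schedule constructor
#'
#' @param vt_interval Cycles between visual-tactile assessments. The model
#'   cycle is annual, so the twice-yearly routine assessment enters as one
#'   assessment per cycle (interval 1).
#' @param bw_interval Cycles between bitewing examinations (default 2).
#' @param vt_offset,bw_offset Cycle of the first exam of each method.
#' @return A list of class `exam_schedule`.
#' @export
exam_schedule <- function(vt_interval = 1, bw_interval = 2,
                          vt_offset = 0, bw_offset = 0) {
  if (vt_interval < 1 || bw_interval < 1) stop("exam intervals must be >= 1")
  structure(list(vt_interval = vt_interval, bw_interval = bw_interval,
                 vt_offset = vt_offset, bw_offset = bw_offset),
            class = "exam_schedule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realized accuracy profile for one detection method
#'
#' Extracts the per-stage sensitivity/specificity of a method from the
#' parameter configuration as plain numerics, either at the distribution
#' modes or as one PSA draw.
#'
#' @param method One of `"visual_tactile"`, `"radiograph_meta"`,
#'   `"radiograph_primary"`, `"radiograph_ai"`.
#' @param params Parameter configuration.
#' @param draw If `TRUE`, sample each value from its distribution (uses the
#'   current RNG stream); otherwise use the modes.
#' @return List with numeric vectors `sensitivity` and `specificity`, each
#'   named `E2`, `D1`, `advanced`. `D3` lesions are assessed with the
#'   `advanced` column.
#' @export
test_profile <- function(method, params = caries_parameters(), draw = FALSE) {
  prof <- params$accuracy[[method]]
  if (is.null(prof)) {
    stop("no accuracy profile for method '", method, "'; available: ",
         paste(names(params$accuracy), collapse = ", "))
  }
  get <- function(d) {
    d <- dist_from_list(d)
    if (draw) sample_dist(d, clamp01 = TRUE) else d$mode
  }
  list(
    method = method,
    sensitivity = vapply(prof$sensitivity, get, numeric(1)),
    specificity = vapply(prof$specificity, get, numeric(1))
  )
}

profile_column <- function(stage) {
  if (stage %in% ADVANCED_STAGES) "advanced" else stage
}

#' Apply due detection methods to a tooth's true state
#'
#' Each due method fires independently: on a diseased surface with its
#' stage-specific sensitivity (`D3` is assessed with the advanced-lesion
#' column), on a sound surface with one minus its specificity at the
#' initial-lesion grade (`E2` column). The surface counts as detected at its
#' true stage if any method fires; false positives are always graded as
#' initial lesions. No stage misgrading is modelled.
#'
#' @param truth True state: `"SOUND"` or a stage in [LESION_STAGES].
#' @param methods Character vector of due methods (names matching
#'   `profiles`).
#' @param profiles Named list of realized [test_profile()]s, one per due
#'   method.
#' @return A `detection_outcome` list: `detected_stage` (`NA` if nothing
#'   detected, `"initial"` for false positives, otherwise the true stage),
#'   `truth`, and `is_false_positive`.
#' @examples
#' prof <- list(radiograph = test_profile("radiograph_ai"))
#' set.seed(1)
#' apply_tests("D1", "radiograph", prof)
#' @export
apply_tests <- function(truth, methods, profiles) {
  missing <- setdiff(methods, names(profiles))
  if (length(missing) > 0) {
    stop("no test profile supplied for method(s): ",
         paste(missing, collapse = ", "))
  }
  fired <- FALSE
  if (truth == "SOUND") {
    for (m in methods) {
      p_fp <- 1 - profiles[[m]]$specificity[["E2"]]
      if (p_fp > 0 && stats::runif(1) < p_fp) fired <- TRUE
    }
    detected <- if (fired) "initial" else NA_character_
    out <- list(detected_stage = detected, truth = truth,
                is_false_positive = fired)
  } else {
    col <- profile_column(truth)
    for (m in methods) {
      sens <- profiles[[m]]$sensitivity[[col]]
      if (sens > 0 && stats::runif(1) < sens) fired <- TRUE
    }
    out <- list(detected_stage = if (fired) truth else NA_character_,
                truth = truth, is_false_positive = FALSE)
  }
  structure(out, class = "detection_outcome")
}

#' Map a detection outcome to a treatment action
#'
#' Under the base policy, detected initial lesions (and false positives,
#' which are always graded initial) receive resin infiltration and detected
#' advanced lesions receive a restoration. Under the restorative policy
#' every detection - initial, advanced or false positive - receives a
#' restoration; this is the setting in which a highly sensitive detection
#' method becomes harmful, as sound and noncavitated surfaces are drawn
#' into the restorative cascade.
#'
#' @param outcome A `detection_outcome` from [apply_tests()].
#' @param policy `"infiltrate"` (base) or `"restore"`: the action taken on
#'   detected initial lesions.
#' @return One of `"none"`, `"infiltrate"`, `"restore"`.
#' @export
decide_treatment <- function(outcome, policy = c("infiltrate", "restore")) {
  policy <- match.arg(policy)
  if (is.na(outcome$detected_stage)) return("none")
  if (outcome$detected_stage %in% c("initial", INITIAL_STAGES)) {
    return(policy)
  }
  "restore"
}
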