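# Synthetic fixtures: the base parameter file, scenario presets, and a
# placeholder fee schedule. The placeholder lets the whole pipeline run and
# be tested end-to-end without the catalogue-derived fee data; it is
# explicitly non-authoritative (flagged `synthetic: true`).

# Plausible euro-2020 ranges for German mixed-payer fees per procedure.
# Chosen once for realistic magnitude and strict ordering
# infiltration < restoration < crown < implant-supported crown.
PLACEHOLDER_FEE_RANGES <- list(
  exam_vt = c(10, 20),
  bitewing_pair = c(10, 16),
  infiltration = c(70, 100),
  restoration = c(105, 140),
  re_restoration = c(105, 140),
  repair = c(40, 70),
  direct_capping = c(15, 35),
  rct = c(200, 350),
  crown = c(250, 350),
  recrown = c(250, 350),
  recement = c(15, 30),
  refix = c(15, 30),
  nonsurg_retreat = c(250, 400),
  surg_retreat = c(300, 450),
  extraction = c(30, 50),
  implant_iscrown = c(1500, 2500),
  reimplant = c(1500, 2500)
)

#' Generate a cost schedule
#'
#' `"placeholder"` mode draws one fee per procedure reproducibly from
#' realistic euro-2020 ranges with the strict ordering
#' infiltration < restoration < crown < implant-supported crown, and flags
#' the result `synthetic: true`. `"template"` mode emits the same structure
#' with zeroed fees for manual entry of catalogue-derived amounts.
#' In both modes the AI fee defaults to the base-case 8 euro per bitewing
#' pair and the shared-cost divisor to 16 teeth per pair.
#'
#' @param mode `"placeholder"` or `"template"`.
#' @param seed Seed for the placeholder draws.
#' @return A validated `cost_schedule`.
#' @export
generate_cost_schedule <- function(mode = c("placeholder", "template"),
                                   seed = 42L) {
  mode <- match.arg(mode)
  fees <- if (mode == "placeholder") {
    set.seed(seed)
    lapply(PLACEHOLDER_FEE_RANGES, function(r) {
      round(stats::runif(1, r[1], r[2]), 2)
    })
  } else {
    lapply(PLACEHOLDER_FEE_RANGES, function(r) 0)
  }
  validate_cost_schedule(list(
    currency = "EUR-2020",
    synthetic = mode == "placeholder",
    template = mode == "template",
    shared_divisor = 16,
    ai_fee_per_bitewing_pair = 8,
    fees = fees
  ))
}

#' Write the packaged fixture files
#'
#' Emits the base parameter file, the placeholder cost schedule, the empty
#' cost template and the scenario-preset catalogue as plain JSON, each with
#' a flat CSV rendering for human review.
#'
#' @param dir Output directory (created if needed).
#' @param what Subset of
#'   `c("table1", "costs_placeholder", "costs_template", "presets")`.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir,
                           what = c("table1", "costs_placeholder",
                                    "costs_template", "presets")) {
  what <- match.arg(what, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) {
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if ("table1" %in% what) {
    cfg <- build_table1_config()
    wj(params_to_list(cfg), "table1_base.json")
    utils::write.csv(flatten_config(params_to_list(cfg)),
                     file.path(dir, "table1_base.csv"), row.names = FALSE)
  }
  if ("costs_placeholder" %in% what) {
    cs <- generate_cost_schedule("placeholder")
    wj(unclass(cs), "costs_placeholder.json")
    utils::write.csv(
      data.frame(item = names(cs$fees), fee_eur = unlist(cs$fees)),
      file.path(dir, "costs_placeholder.csv"), row.names = FALSE)
  }
  if ("costs_template" %in% what) {
    cs <- generate_cost_schedule("template")
    wj(unclass(cs), "costs_appendix_template.json")
  }
  if ("presets" %in% what) {
    wj(scenario_presets(), "scenario_presets.json")
    pr <- scenario_presets()
    utils::write.csv(
      data.frame(
        preset = names(pr),
        overrides = vapply(pr, function(d) {
          if (length(d) == 0) "" else
            paste(names(d), unlist(d), sep = "=", collapse = "; ")
        }, character(1))
      ),
      file.path(dir, "scenario_presets.csv"), row.names = FALSE)
  }
  invisible(dir)
}

# flatten a nested list into path/value rows
flatten_config <- function(x, prefix = character(0)) {
  if (!is.list(x)) {
    return(data.frame(key = paste(prefix, collapse = "."),
                      value = paste(format(x), collapse = " "),
                      stringsAsFactors = FALSE))
  }
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  do.call(rbind, lapply(seq_along(x), function(i) {
    flatten_config(x[[i]], c(prefix, nm[i]))
  }))
}
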