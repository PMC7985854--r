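#' Lesion stages
#'
#' Ordered proximal caries lesion stages used throughout the model. `E2`
#' (inner third of enamel) and `D1` (outer third of dentin) are "initial"
#' lesions, presumed noncavitated and manageable micro-invasively by resin
#' infiltration; `D2` (middle third of dentin) and `D3` (inner third) are
#' "advanced" lesions requiring restorative care. Radiographic E1 lesions
#' (outer enamel) are folded into E2: the parameter set supplies no separate
#' E1 prevalence or hazard, so the initial stratum is `{E2, D1}`.
#'
#' @format Character vector of the four lesion stages in progression order.
#' @export
LESION_STAGES <- c("E2", "D1", "D2", "D3")

#' @rdname LESION_STAGES
#' @export
INITIAL_STAGES <- c("E2", "D1")

#' @rdname LESION_STAGES
#' @export
ADVANCED_STAGES <- c("D2", "D3")

stage_index <- function(stage) {
  i <- match(stage, LESION_STAGES)
  if (anyNA(i)) stop("unknown lesion stage: ", paste(stage[is.na(i)], collapse = ", "))
  i
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Base epidemiological parameter set
#'
#' Builds the full base parameter configuration as a nested list: stage
#' prevalences for low- and high-risk populations, per-stage accuracies of
#' visual-tactile and radiographic caries detection (with and without AI
#' assistance), age-dependent hazard functions for lesion development and
#' progression, annual failure probabilities and allocation maps of every
#' restorative/endodontic/prosthetic health state, and scalar clinical
#' constants (pulp-exposure risks, capping fraction, tooth-replacement
#' probability). A copy is shipped as `extdata/table1_base.json`.
#'
#' Hazard conventions: lesion development on a sound surface follows
#' `m * a * 2.7^(b * 2*age)` (exponential decay in attained age, evaluated
#' with the literal base 2.7); lesion progression follows
#' `m * c * (2*age)^(-k)` (power-law decay). Both are clamped into
#' `[0, 1]` before use as per-cycle probabilities. The factor 2 on age and
#' the base 2.7 are configurable (`age_factor`, `exp_base`).
#'
#' @return A nested list of class `caries_params`.
#' @seealso [load_parameters()], [development_probability()],
#'   [progression_probability()], [sample_parameter_set()]
#' @export
build_table1_config <- function() {
  p <- list(
    meta = list(
      description = "Base epidemiological inputs for the proximal-caries microsimulation",
      currency_year = 2020
    ),
    age = list(start = 12, factor = 2, exp_base = 2.7),
    prevalence = list(
      low = list(E2 = 0.14, D1 = 0.025, D2 = 0.005),
      high_multiplier = list(E2 = 2.14, D1 = 1.66, D2 = 1.66)
    ),
    accuracy = list(
      visual_tactile = list(
        sensitivity = list(
          E2 = param_dist("point", 0),
          D1 = param_dist("point", 0),
          advanced = param_dist("triangular", 0.270, 0.311, 0.353)
        ),
        specificity = list(
          E2 = param_dist("point", 1),
          D1 = param_dist("point", 1),
          advanced = param_dist("triangular", 0.892, 0.922, 0.945)
        )
      ),
      radiograph_meta = list(
        sensitivity = list(
          E2 = param_dist("triangular", 0.21, 0.24, 0.26),
          D1 = param_dist("triangular", 0.24, 0.36, 0.49),
          advanced = param_dist("triangular", 0.59, 0.64, 0.70)
        ),
        specificity = list(
          E2 = param_dist("triangular", 0.95, 0.97, 0.98),
          D1 = param_dist("triangular", 0.89, 0.94, 0.97),
          advanced = param_dist("triangular", 0.97, 0.98, 0.98)
        )
      ),
      # Pooled accuracies of the individual dentists who read the same test
      # radiographs as the network (mean and min-max range); no per-stage
      # breakdown is available, so the pooled initial-lesion values are
      # applied to E2 and D1 and the advanced column is carried over from
      # the meta-analytic profile.
      radiograph_primary = list(
        sensitivity = list(
          E2 = param_dist("triangular", 0.19, 0.36, 0.65),
          D1 = param_dist("triangular", 0.19, 0.36, 0.65),
          advanced = param_dist("triangular", 0.59, 0.64, 0.70)
        ),
        specificity = list(
          E2 = param_dist("triangular", 0.69, 0.91, 0.98),
          D1 = param_dist("triangular", 0.69, 0.91, 0.98),
          advanced = param_dist("triangular", 0.97, 0.98, 0.98)
        )
      ),
      radiograph_ai = list(
        sensitivity = list(
          E2 = param_dist("point", 0.68),
          D1 = param_dist("point", 0.68),
          advanced = param_dist("point", 0.58)
        ),
        specificity = list(
          E2 = param_dist("point", 0.86),
          D1 = param_dist("point", 0.86),
          advanced = param_dist("point", 0.96)
        )
      )
    ),
    development = list(
      # Incidence of new lesions on sound surfaces, arriving directly at
      # stage E2, D1 or D2 (competing risks, at most one event per cycle).
      multiplier = param_dist("uniform", 1.24, 1.26, 1.29),
      E2 = list(a = 0.57252, b = -0.1472),
      D1 = list(a = 0.0426, b = -0.0521),
      D2 = list(a = 0.57 * 0.0426, b = -0.0521)
    ),
    progression = list(
      risk_multiplier = list(low = 2.13, high = 2.63),
      untreated = list(
        E2 = list(c = 3.0984, k = 1.343),
        D1 = list(c = 161.52, k = 2.078),
        # D2 -> D3 uses a fixed multiplier instead of the risk multiplier
        D2 = list(c = 161.52, k = 2.078, fixed_multiplier = 1.32)
      ),
      # sampled multiplicative spread P*0.87 .. P*1.13 around each
      # untreated hazard (independent draw per stage column)
      untreated_spread = param_dist("uniform", 0.87, 1.00, 1.13),
      infiltrated = list(
        E2 = list(c = 0.4289, k = 1.391,
                  spread = param_dist("triangular", 0.23, 1.00, 5.15)),
        D1 = list(c = 68.869, k = 2.078,
                  spread = param_dist("triangular", 0.23, 1.00, 4.17))
      )
    ),
    transitions = list(
      composite = list(
        p = param_dist("point", 0.016),
        alloc = list(composite = 0.45, crown = 0.10, repair = 0.10,
                     rct = 0.25, extraction = 0.10)
      ),
      direct_capping = list(
        p = param_dist("point", 0.111),
        alloc = list(rct = 0.95, extraction = 0.05)
      ),
      crown_vital = list(
        p = param_dist("point", 0.036),
        alloc = list(rct = 0.25, recement = 0.15, repair = 0.10,
                     recrown = 0.40, extraction = 0.10)
      ),
      # endodontic complications of root-filled (nonvital, crowned) teeth
      rct = list(
        p = param_dist("point", 0.021),
        alloc = list(nonsurg_retreat = 0.20, surg_retreat = 0.30,
                     extraction = 0.50)
      ),
      crown_nonvital = list(
        p = param_dist("point", 0.029),
        alloc = list(recement = 0.20, repair = 0.10, recrown = 0.60,
                     extraction = 0.10)
      ),
      nonsurg_retreat = list(
        p = param_dist("point", 0.085),
        alloc = list(surg_retreat = 0.25, extraction = 0.75)
      ),
      surg_retreat = list(
        p = param_dist("point", 0.061),
        alloc = list(extraction = 1.00)
      ),
      implant = list(
        p = param_dist("point", 0.010),
        alloc = list(refix = 0.60, recrown = 0.20, reimplant = 0.20)
      )
    ),
    clinical = list(
      pulp_exposure_d3 = param_dist("point", 0.3),
      pulp_exposure_rerestoration = param_dist("point", 0.10),
      capping_fraction = param_dist("point", 0.95),
      replacement = param_dist("point", 0.8)
    )
  )
  structure(p, class = "caries_params")
}

#' Validate a parameter configuration
#'
#' Checks every structural invariant of the parameter set: prevalences are
#' non-negative and sum to at most 1, all probability distributions live in
#' `[0, 1]`, distribution bounds are ordered, hazard decay coefficients have
#' the sign that makes hazards decrease with age, and every allocation map
#' sums to 1 exactly. Called by [load_parameters()]; a violating
#' configuration refuses to load.
#'
#' @param params A `caries_params` list.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  prev <- unlist(params$prevalence$low)
  if (any(prev < 0)) stop("prevalences must be non-negative")
  if (sum(prev) > 1) stop("low-risk prevalences sum to more than 1")
  hm <- unlist(params$prevalence$high_multiplier)
  if (sum(prev * hm) > 1) stop("high-risk prevalences sum to more than 1")

  check_prob_dist <- function(d, what) {
    d <- dist_from_list(d)
    if (d$low < 0 || d$high > 1) {
      stop("probability distribution out of [0,1]: ", what)
    }
  }
  for (prof in names(params$accuracy)) {
    for (kind in c("sensitivity", "specificity")) {
      for (stg in names(params$accuracy[[prof]][[kind]])) {
        check_prob_dist(params$accuracy[[prof]][[kind]][[stg]],
                        paste(prof, kind, stg))
      }
    }
  }
  for (row in names(params$transitions)) {
    tr <- params$transitions[[row]]
    check_prob_dist(tr$p, paste("transition", row))
    s <- sum(unlist(tr$alloc))
    if (abs(s - 1) > 1e-9) {
      stop("allocation map for '", row, "' sums to ", s, ", not 1")
    }
    if (any(unlist(tr$alloc) < 0)) stop("negative allocation in '", row, "'")
  }
  for (nm in names(params$clinical)) {
    check_prob_dist(params$clinical[[nm]], paste("clinical", nm))
  }
  if (params$development$E2$b >= 0 || params$development$D1$b >= 0 ||
      params$development$D2$b >= 0) {
    stop("development decay coefficients must be negative")
  }
  for (stg in names(params$progression$untreated)) {
    if (params$progression$untreated[[stg]]$k <= 0) {
      stop("progression power-law exponents must be positive")
    }
  }
  invisible(params)
}

#' Default parameters shipped with the package
#'
#' Loads and validates the packaged base parameter file
#' (`extdata/table1_base.json`).
#'
#' @return A validated `caries_params` list.
#' @export
caries_parameters <- function() {
  load_parameters(system.file("extdata", "table1_base.json",
                              package = "cariesim", mustWork = TRUE))
}

#' Load a parameter configuration from JSON
#'
#' @param path Path to a JSON parameter file with the structure produced by
#'   [write_fixtures()] / [build_table1_config()].
#' @return A validated `caries_params` list.
#' @export
load_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  params <- params_from_list(raw)
  validate_parameters(params)
  params
}

# Recursively rebuild param_dist objects from their JSON representation
# (any list carrying a "kind" field) and unbox length-1 values.
params_from_list <- function(x) {
  if (is.list(x) && !is.null(x$kind) &&
      is.character(unlist(x$kind)) &&
      unlist(x$kind) %in% c("point", "uniform", "triangular")) {
    return(param_dist(unlist(x$kind), unlist(x$low), unlist(x$mode),
                      unlist(x$high)))
  }
  if (is.list(x)) {
    out <- lapply(x, params_from_list)
    return(out)
  }
  if (length(x) == 1) unlist(x) else x
}

params_to_list <- function(x) {
  if (is_param_dist(x)) return(dist_to_list(x))
  if (is.list(x)) return(lapply(x, params_to_list))
  x
}

#' Per-cycle probability of lesion development on a sound surface
#'
#' Evaluates the age-dependent incidence hazard of a new lesion arriving
#' directly at stage `E2`, `D1` or `D2` on a sound proximal surface:
#' `m * a * base^(b * f * age)` with stage-specific coefficients `(a, b)`,
#' exponential base 2.7 and age factor `f = 2` by default, clamped to
#' `[0, 1]`. The hazard decays with attained age: caries incidence on
#' proximal surfaces is concentrated in adolescence.
#'
#' @param age Attained age in years (vectorised); must be >= the model
#'   start age of 12.
#' @param stage Target stage, one of `"E2"`, `"D1"`, `"D2"`.
#' @param params Parameter configuration (see [caries_parameters()]).
#' @param multiplier Realized hazard multiplier; defaults to the mode of the
#'   development multiplier distribution (1.26).
#' @return Per-cycle probability, same length as `age`.
#' @examples
#' development_probability(12, "E2") # about 0.0216
#' @export
development_probability <- function(age, stage = c("E2", "D1", "D2"),
                                    params = caries_parameters(),
                                    multiplier = NULL) {
  stage <- match.arg(stage)
  if (any(age < params$age$start)) {
    stop("age must be >= model start age (", params$age$start, ")")
  }
  if (is.null(multiplier)) multiplier <- dist_from_list(params$development$multiplier)$mode
  cf <- params$development[[stage]]
  clamp01(multiplier * cf$a *
            params$age$exp_base^(cf$b * params$age$factor * age))
}

#' Per-cycle probability of lesion progression
#'
#' Evaluates the age-dependent per-cycle probability that an existing lesion
#' advances one stage. Untreated initial lesions (`E2 -> D1`, `D1 -> D2`)
#' progress with a power-law hazard `m_risk * c * (f*age)^(-k)` scaled by the
#' population risk multiplier (2.13 low risk, 2.63 high risk); `D2 -> D3`
#' uses a fixed multiplier of 1.32 instead of the risk multiplier.
#' Lesions arrested by resin infiltration progress with separate, much lower
#' hazards and no risk multiplier; infiltration hazards exist only for `E2`
#' and `D1` (a `D2` lesion cannot be infiltrated).
#'
#' @param age Attained age in years (vectorised).
#' @param from_stage Current stage, one of `"E2"`, `"D1"`, `"D2"`.
#' @param infiltrated Logical; progression under resin infiltration.
#' @param risk `"low"` or `"high"` population risk profile.
#' @param params Parameter configuration.
#' @param multiplier Realized spread multiplier around the hazard (PSA draw);
#'   defaults to 1.
#' @return Per-cycle probability, clamped to `[0, 1]`.
#' @examples
#' progression_probability(12, "E2", risk = "low")  # about 0.0925
#' progression_probability(12, "E2", infiltrated = TRUE)  # about 0.0052
#' @export
progression_probability <- function(age, from_stage = c("E2", "D1", "D2"),
                                    infiltrated = FALSE,
                                    risk = c("low", "high"),
                                    params = caries_parameters(),
                                    multiplier = 1) {
  from_stage <- match.arg(from_stage)
  risk <- match.arg(risk)
  if (any(age < params$age$start)) {
    stop("age must be >= model start age (", params$age$start, ")")
  }
  f <- params$age$factor
  if (infiltrated) {
    if (from_stage == "D2") {
      stop("no infiltration hazard is defined for D2 lesions")
    }
    cf <- params$progression$infiltrated[[from_stage]]
    return(clamp01(multiplier * cf$c * (f * age)^(-cf$k)))
  }
  cf <- params$progression$untreated[[from_stage]]
  m <- if (!is.null(cf$fixed_multiplier)) {
    cf$fixed_multiplier
  } else {
    params$progression$risk_multiplier[[risk]]
  }
  clamp01(multiplier * m * cf$c * (f * age)^(-cf$k))
}

#' Draw one probabilistic-sensitivity-analysis parameter realization
#'
#' Draws every distributed quantity of the model once, independently:
#' the development-hazard multiplier, the multiplicative spreads of the
#' untreated and infiltrated progression hazards, the sensitivities and
#' specificities of the active detection methods, the annual failure
#' probability of every health state, and the scalar clinical constants.
#' Point distributions return their point. Probability draws are clamped
#' to `[0, 1]`. With `psa = FALSE`, every quantity is fixed at its mode.
#'
#' A fixed number of uniforms is consumed in a fixed order regardless of the
#' distribution kinds, so two strategies simulated from the same seed share
#' their parameter draws (common random numbers).
#'
#' @param params Parameter configuration.
#' @param radiograph One of `"radiograph_ai"`, `"radiograph_meta"`,
#'   `"radiograph_primary"`: the active radiographic accuracy profile.
#' @param psa Logical; sample (TRUE) or use modes (FALSE).
#' @return A flat named list of realized numeric parameters.
#' @export
sample_parameter_set <- function(params = caries_parameters(),
                                 radiograph = "radiograph_ai",
                                 psa = TRUE) {
  stopifnot(radiograph %in% c("radiograph_ai", "radiograph_meta",
                              "radiograph_primary"))
  take <- function(d, clamp = FALSE) {
    d <- dist_from_list(d)
    if (psa) sample_dist(d, clamp01 = clamp) else d$mode
  }
  acc <- params$accuracy
  rad <- acc[[radiograph]]
  vt <- acc$visual_tactile
  ps <- list(
    m_dev = take(params$development$multiplier),
    sp_E2 = take(params$progression$untreated_spread),
    sp_D1 = take(params$progression$untreated_spread),
    sp_D2 = take(params$progression$untreated_spread),
    si_E2 = take(params$progression$infiltrated$E2$spread),
    si_D1 = take(params$progression$infiltrated$D1$spread),
    vt_sens_E2 = take(vt$sensitivity$E2, TRUE),
    vt_sens_D1 = take(vt$sensitivity$D1, TRUE),
    vt_sens_adv = take(vt$sensitivity$advanced, TRUE),
    vt_spec_E2 = take(vt$specificity$E2, TRUE),
    vt_spec_D1 = take(vt$specificity$D1, TRUE),
    vt_spec_adv = take(vt$specificity$advanced, TRUE),
    rad_sens_E2 = take(rad$sensitivity$E2, TRUE),
    rad_sens_D1 = take(rad$sensitivity$D1, TRUE),
    rad_sens_adv = take(rad$sensitivity$advanced, TRUE),
    rad_spec_E2 = take(rad$specificity$E2, TRUE),
    rad_spec_D1 = take(rad$specificity$D1, TRUE),
    rad_spec_adv = take(rad$specificity$advanced, TRUE),
    p_composite = take(params$transitions$composite$p, TRUE),
    p_capping = take(params$transitions$direct_capping$p, TRUE),
    p_crown_vital = take(params$transitions$crown_vital$p, TRUE),
    p_endo = take(params$transitions$rct$p, TRUE),
    p_crown_nonvital = take(params$transitions$crown_nonvital$p, TRUE),
    p_nonsurg = take(params$transitions$nonsurg_retreat$p, TRUE),
    p_surg = take(params$transitions$surg_retreat$p, TRUE),
    p_implant = take(params$transitions$implant$p, TRUE),
    pulp_exposure_d3 = take(params$clinical$pulp_exposure_d3, TRUE),
    pulp_exposure_rerestoration = take(params$clinical$pulp_exposure_rerestoration, TRUE),
    capping_fraction = take(params$clinical$capping_fraction, TRUE),
    replacement = take(params$clinical$replacement, TRUE)
  )
  ps
}
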