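# Tooth-level Markov microsimulation engine.
#
# Structural states of one posterior tooth (one proximal surface is
# simulated per tooth; at most one lesion per tooth):
#   SOUND -> LESION(E2/D1/D2/D3, infiltrated or not) -> RESTORED ->
#   CAPPED / CROWN (vital or nonvital) -> retreatments -> EXTRACTED ->
#   IMPLANT (replaced) or GONE (not replaced / care exhausted).
# Within a cycle the order is: (1) lesion development/progression,
# (2) scheduled exams and treatment, (3) failure of work placed in earlier
# cycles. Restorations placed this cycle cannot fail this cycle.

S_SOUND <- 1L; S_LESION <- 2L; S_REST <- 3L; S_CAP <- 4L
S_CRV <- 5L; S_CRN <- 6L; S_NSR <- 7L; S_SSR <- 8L
S_IMP <- 9L; S_GONE <- 10L

# event codes index into EVENT_KINDS
EV <- as.list(seq_along(EVENT_KINDS))
names(EV) <- EVENT_KINDS

# Precompute everything that is constant across the teeth of one cohort.
build_ctx <- function(scenario) {
  p <- scenario$params
  H <- scenario$horizon
  ages <- p$age$start + 0:(H - 1)
  two_alpha <- p$age$factor * ages
  cyc <- 0:(H - 1)
  vt_due <- vapply(cyc, function(t) {
    "visual_tactile" %in% exams_due(t, scenario$schedule)
  }, logical(1))
  bw_due <- vapply(cyc, function(t) {
    "radiograph" %in% exams_due(t, scenario$schedule)
  }, logical(1))
  alloc_of <- function(row) {
    a <- unlist(p$transitions[[row]]$alloc)
    list(outcomes = names(a), cum = cumsum(as.numeric(a)))
  }
  df <- discount_factor(cyc, scenario$discount_rate)
  list(
    H = H,
    two_alpha = two_alpha,
    exp_base = p$age$exp_base,
    df = df,
    df_cum = cumsum(df),
    vt_cycles = cyc[vt_due],
    bw_cycles = cyc[bw_due],
    vt_due = vt_due,
    bw_due = bw_due,
    ai_on = scenario$strategy == "ai",
    redetect_per_exam = identical(scenario$redetect, "per_exam"),
    fee = fee_table(scenario$costs),
    policy_restore = scenario$policy == "restore",
    refp_repeat = isTRUE(scenario$refp_repeat),
    psa = isTRUE(scenario$psa),
    radiograph = scenario$radiograph,
    risk_mult = p$progression$risk_multiplier[[scenario$risk]],
    prev_cum = {
      pr <- unlist(p$prevalence$low)
      if (scenario$risk == "high") pr <- pr * unlist(p$prevalence$high_multiplier)
      cumsum(as.numeric(pr[c("E2", "D1", "D2")]))
    },
    dev = p$development,
    prog = p$progression,
    alloc_composite = alloc_of("composite"),
    alloc_capping = alloc_of("direct_capping"),
    alloc_crv = alloc_of("crown_vital"),
    alloc_endo = alloc_of("rct"),
    alloc_crn = alloc_of("crown_nonvital"),
    alloc_nsr = alloc_of("nonsurg_retreat"),
    alloc_ssr = alloc_of("surg_retreat"),
    alloc_imp = alloc_of("implant"),
    params = p
  )
}

pick_alloc <- function(alloc, u) {
  alloc$outcomes[[which(u < alloc$cum)[1]]]
}

# Simulate one tooth. `u_init` is the uniform deviate for the initial state;
# `ps` a realized parameter set. Returns a numeric record plus (optionally)
# the event ledger.
#
# All path randomness is pre-drawn as per-purpose, per-cycle streams in a
# fixed order (disease, visual-tactile reading, radiographic reading,
# failure occurrence, failure allocation, two auxiliary draws, replacement).
# Two strategies simulated from the same tooth seed therefore see identical
# lesion trajectories and reader draws, and their paths diverge only where
# a detection or treatment difference intervenes (synchronized common
# random numbers).
sim_tooth <- function(ctx, ps, u_init, store_events = FALSE) {
  H <- ctx$H
  u_dis <- stats::runif(H)    # lesion development / progression
  u_vt <- stats::runif(H)     # visual-tactile reading
  u_bw <- stats::runif(H)     # radiographic reading
  u_fail <- stats::runif(H)   # failure occurrence of current work
  u_alloc <- stats::runif(H)  # allocation of the failure outcome
  u_x1 <- stats::runif(H)     # pulp exposure / endodontic complication
  u_x2 <- stats::runif(H)     # capping split / complication allocation
  u_rep <- stats::runif(H)    # replacement of an extracted tooth
  ta <- ctx$two_alpha
  eb <- ctx$exp_base

  dev_E2 <- clamp01(ps$m_dev * ctx$dev$E2$a * eb^(ctx$dev$E2$b * ta))
  dev_D1 <- clamp01(ps$m_dev * ctx$dev$D1$a * eb^(ctx$dev$D1$b * ta))
  dev_D2 <- clamp01(ps$m_dev * ctx$dev$D2$a * eb^(ctx$dev$D2$b * ta))
  un <- ctx$prog$untreated
  prog_E2 <- clamp01(ctx$risk_mult * ps$sp_E2 * un$E2$c * ta^(-un$E2$k))
  prog_D1 <- clamp01(ctx$risk_mult * ps$sp_D1 * un$D1$c * ta^(-un$D1$k))
  prog_D2 <- clamp01(un$D2$fixed_multiplier * ps$sp_D2 * un$D2$c * ta^(-un$D2$k))
  inf <- ctx$prog$infiltrated
  inf_E2 <- clamp01(ps$si_E2 * inf$E2$c * ta^(-inf$E2$k))
  inf_D1 <- clamp01(ps$si_D1 * inf$D1$c * ta^(-inf$D1$k))

  vt_sens <- c(ps$vt_sens_E2, ps$vt_sens_D1, ps$vt_sens_adv)
  rad_sens <- c(ps$rad_sens_E2, ps$rad_sens_D1, ps$rad_sens_adv)
  p_fp_bw <- 1 - ps$rad_spec_E2
  p_fp_vt <- 1 - ps$vt_spec_E2

  # initial state: categorical over SOUND / E2 / D1 / D2 prevalence
  pc <- ctx$prev_cum
  state <- S_SOUND; stage <- 0L; infil <- FALSE
  if (u_init < pc[1]) { state <- S_LESION; stage <- 1L }
  else if (u_init < pc[2]) { state <- S_LESION; stage <- 2L }
  else if (u_init < pc[3]) { state <- S_LESION; stage <- 3L }

  rgen <- 0L      # restoration generation: 0 first, 1 repaired, 2 re-restored
  cgen <- 0L      # crown generation (replaced at most once)
  igen <- 0L      # implant generation (re-implanted at most once)
  fp_done <- FALSE
  redraw <- ctx$redetect_per_exam
  tried_vt <- FALSE; tried_bw <- FALSE  # method has already graded this stage
  extract_t <- NA_integer_
  gone_t <- NA_integer_

  ne <- 0L
  cap <- 16L
  ev_k <- integer(cap); ev_t <- integer(cap)
  rec <- function(code, t) {
    if (ne == cap) {
      cap <<- cap * 2L
      length(ev_k) <<- cap; length(ev_t) <<- cap
    }
    ne <<- ne + 1L
    ev_k[ne] <<- code; ev_t[ne] <<- t
  }

  policy_restore <- ctx$policy_restore
  refp_repeat <- ctx$refp_repeat

  for (t in 0:(H - 1)) {
    i <- t + 1L
    treated <- FALSE
    do_extract <- FALSE

    # (1) lesion dynamics
    if (state == S_SOUND) {
      u <- u_dis[i]
      if (u < dev_E2[i]) { state <- S_LESION; stage <- 1L; infil <- FALSE }
      else if (u < dev_E2[i] + dev_D1[i]) { state <- S_LESION; stage <- 2L; infil <- FALSE }
      else if (u < dev_E2[i] + dev_D1[i] + dev_D2[i]) { state <- S_LESION; stage <- 3L; infil <- FALSE }
    } else if (state == S_LESION && stage < 4L) {
      pp <- if (stage == 1L) { if (infil) inf_E2[i] else prog_E2[i] }
            else if (stage == 2L) { if (infil) inf_D1[i] else prog_D1[i] }
            else prog_D2[i]
      if (pp > 0 && u_dis[i] < pp) {
        stage <- stage + 1L
        tried_vt <- FALSE; tried_bw <- FALSE  # new radiographic appearance
      }
    }

    # (2) scheduled exams and treatment
    vt <- ctx$vt_due[i]; bw <- ctx$bw_due[i]
    if (state == S_LESION) {
      col <- if (stage > 3L) 3L else stage
      det <- FALSE
      if (vt && (redraw || !tried_vt)) {
        if (vt_sens[col] > 0 && u_vt[i] < vt_sens[col]) det <- TRUE
        tried_vt <- TRUE
      }
      if (bw && (redraw || !tried_bw)) {
        if (rad_sens[col] > 0 && u_bw[i] < rad_sens[col]) det <- TRUE
        tried_bw <- TRUE
      }
      if (det) {
        if (stage <= 2L) {
          if (!infil) {
            if (policy_restore) {
              rec(5L, t)  # restoration
              state <- S_REST; rgen <- 0L; treated <- TRUE
            } else {
              rec(4L, t)  # infiltration
              infil <- TRUE
            }
          }
        } else {
          rec(5L, t)  # restoration
          if (stage == 4L && u_x1[i] < ps$pulp_exposure_d3) {
            if (u_x2[i] < ps$capping_fraction) {
              rec(8L, t)  # direct_capping
              state <- S_CAP
            } else {
              rec(9L, t); rec(10L, t)  # rct + crown
              state <- S_CRN; cgen <- 1L
            }
          } else {
            state <- S_REST; rgen <- 0L
          }
          treated <- TRUE
        }
      }
    } else if (state == S_SOUND) {
      fp <- FALSE
      if (bw && p_fp_bw > 0 && u_bw[i] < p_fp_bw) fp <- TRUE
      if (vt && p_fp_vt > 0 && u_vt[i] < p_fp_vt) fp <- TRUE
      if (fp) {
        if (policy_restore) {
          rec(5L, t)  # restoration of a sound surface
          state <- S_REST; rgen <- 0L; treated <- TRUE
        } else if (!fp_done || refp_repeat) {
          rec(4L, t)  # infiltration without effectiveness gain
          fp_done <- TRUE
        }
      }
    }

    # (3) failure of existing restorative / endodontic / prosthetic work
    if (!treated) {
      if (state == S_REST) {
        if (u_fail[i] < ps$p_composite) {
          if (rgen > 0L) {
            rec(10L, t)  # crowning after previous repair/re-restoration
            state <- S_CRV; cgen <- 1L
          } else {
            out <- pick_alloc(ctx$alloc_composite, u_alloc[i])
            if (out == "composite") {
              rec(6L, t)  # re_restoration
              if (u_x1[i] < ps$pulp_exposure_rerestoration) {
                if (u_x2[i] < ps$capping_fraction) {
                  rec(8L, t); state <- S_CAP
                } else {
                  rec(9L, t); rec(10L, t); state <- S_CRN; cgen <- 1L
                }
              } else {
                rgen <- 2L
              }
            } else if (out == "crown") {
              rec(10L, t); state <- S_CRV; cgen <- 1L
            } else if (out == "repair") {
              rec(7L, t); rgen <- 1L
            } else if (out == "rct") {
              rec(9L, t); rec(10L, t); state <- S_CRN; cgen <- 1L
            } else do_extract <- TRUE
          }
        }
      } else if (state == S_CAP) {
        if (u_fail[i] < ps$p_capping) {
          out <- pick_alloc(ctx$alloc_capping, u_alloc[i])
          if (out == "rct") {
            rec(9L, t); rec(10L, t); state <- S_CRN; cgen <- max(cgen, 1L)
          } else do_extract <- TRUE
        }
      } else if (state == S_CRV) {
        if (u_fail[i] < ps$p_crown_vital) {
          out <- pick_alloc(ctx$alloc_crv, u_alloc[i])
          if (out == "rct") {
            rec(9L, t); state <- S_CRN
          } else if (out == "recement") {
            rec(12L, t)
          } else if (out == "repair") {
            rec(7L, t)
          } else if (out == "recrown") {
            if (cgen < 2L) { rec(11L, t); cgen <- 2L } else do_extract <- TRUE
          } else do_extract <- TRUE
        }
      } else if (state == S_CRN) {
        if (u_fail[i] < ps$p_crown_nonvital) {
          out <- pick_alloc(ctx$alloc_crn, u_alloc[i])
          if (out == "recement") {
            rec(12L, t)
          } else if (out == "repair") {
            rec(7L, t)
          } else if (out == "recrown") {
            if (cgen < 2L) { rec(11L, t); cgen <- 2L } else do_extract <- TRUE
          } else do_extract <- TRUE
        }
        if (!do_extract && state == S_CRN &&
            u_x1[i] < ps$p_endo) {
          out <- pick_alloc(ctx$alloc_endo, u_x2[i])
          if (out == "nonsurg_retreat") {
            rec(13L, t); state <- S_NSR
          } else if (out == "surg_retreat") {
            rec(14L, t); state <- S_SSR
          } else do_extract <- TRUE
        }
      } else if (state == S_NSR) {
        if (u_fail[i] < ps$p_nonsurg) {
          out <- pick_alloc(ctx$alloc_nsr, u_alloc[i])
          if (out == "surg_retreat") {
            rec(14L, t); state <- S_SSR
          } else do_extract <- TRUE
        }
      } else if (state == S_SSR) {
        if (u_fail[i] < ps$p_surg) do_extract <- TRUE
      } else if (state == S_IMP) {
        if (u_fail[i] < ps$p_implant) {
          out <- pick_alloc(ctx$alloc_imp, u_alloc[i])
          if (out == "refix") {
            rec(18L, t)
          } else if (out == "recrown") {
            rec(11L, t)
          } else {
            if (igen < 2L) {
              rec(17L, t); igen <- 2L
            } else {
              state <- S_GONE; gone_t <- t
            }
          }
        }
      }
    }

    if (do_extract) {
      rec(15L, t)  # extraction
      extract_t <- t
      if (u_rep[i] < ps$replacement) {
        rec(16L, t)  # implant-supported crown
        state <- S_IMP; igen <- 1L
      } else {
        state <- S_GONE; gone_t <- t
      }
    }
    if (state == S_GONE) break
  }

  # scheduled exam events while the tooth (or its replacement) is in care
  care_end <- if (is.na(gone_t)) H - 1L else gone_t
  vt_c <- ctx$vt_cycles[ctx$vt_cycles <= care_end]
  bw_c <- ctx$bw_cycles[ctx$bw_cycles <= care_end]
  k_all <- c(ev_k[seq_len(ne)],
             rep.int(1L, length(vt_c)),
             rep.int(2L, length(bw_c)),
             if (ctx$ai_on) rep.int(3L, length(bw_c)) else integer(0))
  t_all <- c(ev_t[seq_len(ne)], vt_c, bw_c,
             if (ctx$ai_on) bw_c else integer(0))

  fee <- ctx$fee
  cost_undisc <- sum(fee[k_all])
  cost_disc <- sum(fee[k_all] * ctx$df[t_all + 1L])
  retention <- if (is.na(extract_t)) H else extract_t
  effect_disc <- if (retention > 0) ctx$df_cum[retention] else 0

  out <- list(effect = retention, effect_discounted = effect_disc,
              cost_discounted = cost_disc, cost_undiscounted = cost_undisc,
              extracted = !is.na(extract_t))
  if (store_events) {
    ord <- order(t_all, k_all)
    out$events <- data.frame(cycle = t_all[ord],
                             kind = EVENT_KINDS[k_all[ord]],
                             stringsAsFactors = FALSE)
  }
  out
}

#' Draw initial tooth states from the prevalence profile
#'
#' At model start (age 12) a proximal surface is sound or carries an E2, D1
#' or D2 lesion according to the risk profile's prevalences (high-risk
#' prevalences are the low-risk values times the stage-specific high-risk
#' multipliers).
#'
#' @param risk `"low"` or `"high"`.
#' @param params Parameter configuration.
#' @param n Number of draws.
#' @return Character vector in `c("SOUND", "E2", "D1", "D2")`.
#' @export
initial_state <- function(risk = c("low", "high"),
                          params = caries_parameters(), n = 1) {
  risk <- match.arg(risk)
  pr <- unlist(params$prevalence$low)[c("E2", "D1", "D2")]
  if (risk == "high") {
    pr <- pr * unlist(params$prevalence$high_multiplier)[c("E2", "D1", "D2")]
  }
  if (sum(pr) > 1) stop("prevalences sum to more than 1")
  cum <- cumsum(as.numeric(pr))
  u <- stats::runif(n)
  out <- rep("SOUND", n)
  out[u < cum[3]] <- "D2"
  out[u < cum[2]] <- "D1"
  out[u < cum[1]] <- "E2"
  out
}

#' Simulate one tooth and return its full history
#'
#' Draws one parameter realization (PSA on) or uses point values (PSA off),
#' advances the tooth through the scenario horizon, and returns the
#' time-stamped event ledger together with retention and cost totals.
#'
#' @param scenario A [build_scenario()] configuration.
#' @param seed Integer seed for this tooth.
#' @return A `tooth_history` list: `events` (data.frame of cycle and event
#'   kind), `retention_years`, `effect_discounted`, `cost_discounted`,
#'   `cost_undiscounted`, `extracted`.
#' @export
simulate_tooth <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "caries_scenario"))
  ctx <- build_ctx(scenario)
  set.seed(seed)
  u0 <- stats::runif(1)
  ps <- sample_parameter_set(scenario$params, ctx$radiograph, psa = ctx$psa)
  r <- sim_tooth(ctx, ps, u0, store_events = TRUE)
  structure(list(events = r$events,
                 retention_years = r$effect,
                 effect_discounted = r$effect_discounted,
                 cost_discounted = r$cost_discounted,
                 cost_undiscounted = r$cost_undiscounted,
                 extracted = r$extracted),
            class = "tooth_history")
}

#' Run a Monte-Carlo cohort of independent teeth
#'
#' Simulates `n` independent teeth under one scenario. Each tooth gets a
#' deterministic child seed derived from the root seed, so cohorts are
#' reproducible and two strategies run from the same root seed share their
#' per-tooth random streams (common random numbers) until their paths
#' diverge. With PSA on, each tooth draws its own parameter realization,
#' mixing first-order (path) and parameter uncertainty.
#'
#' @param scenario A [build_scenario()] configuration.
#' @param n Number of teeth (>= 1).
#' @param seed Integer root seed.
#' @param store_events Keep the per-tooth event ledgers (slower; used for
#'   audits and tests).
#' @return A `cohort_result` with per-tooth vectors `effect` (retention
#'   years, undiscounted), `effect_discounted`, `cost_discounted`,
#'   `cost_undiscounted`, `extracted`, and (optionally) `events`.
#' @export
run_cohort <- function(scenario, n = 1000, seed = 1L, store_events = FALSE) {
  stopifnot(inherits(scenario, "caries_scenario"))
  if (n < 1) stop("n must be >= 1")
  ctx <- build_ctx(scenario)
  set.seed(seed)
  tooth_seeds <- sample.int(2147483646L, n)
  effect <- numeric(n); effect_d <- numeric(n)
  cost_d <- numeric(n); cost_u <- numeric(n)
  extracted <- logical(n)
  events <- if (store_events) vector("list", n) else NULL
  for (j in seq_len(n)) {
    set.seed(tooth_seeds[j])
    u0 <- stats::runif(1)
    ps <- sample_parameter_set(scenario$params, ctx$radiograph, psa = ctx$psa)
    r <- sim_tooth(ctx, ps, u0, store_events = store_events)
    effect[j] <- r$effect
    effect_d[j] <- r$effect_discounted
    cost_d[j] <- r$cost_discounted
    cost_u[j] <- r$cost_undiscounted
    extracted[j] <- r$extracted
    if (store_events) {
      ev <- r$events
      ev$tooth <- j
      events[[j]] <- ev
    }
  }
  structure(list(
    strategy = scenario$strategy,
    n = n,
    seed = seed,
    effect = effect,
    effect_discounted = effect_d,
    cost_discounted = cost_d,
    cost_undiscounted = cost_u,
    extracted = extracted,
    events = if (store_events) do.call(rbind, events) else NULL
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  se <- summary_stats(x$effect)
  sc <- summary_stats(x$cost_discounted)
  cat(sprintf("<cohort_result> %s, n = %d, seed = %d\n",
              x$strategy, x$n, x$seed))
  cat(sprintf("  retention %5.2f y (2.5-97.5%%: %.1f-%.1f), extracted %.1f%%\n",
              se[1], se[2], se[3], 100 * mean(x$extracted)))
  cat(sprintf("  discounted cost %6.1f euro (2.5-97.5%%: %.1f-%.1f)\n",
              sc[1], sc[2], sc[3]))
  invisible(x)
}

#' @export
summary.cohort_result <- function(object, ...) {
  data.frame(
    strategy = object$strategy,
    n = object$n,
    mean_effect = mean(object$effect),
    effect_lo = summary_stats(object$effect)[2],
    effect_hi = summary_stats(object$effect)[3],
    mean_cost = mean(object$cost_discounted),
    cost_lo = summary_stats(object$cost_discounted)[2],
    cost_hi = summary_stats(object$cost_discounted)[3],
    p_extracted = mean(object$extracted),
    row.names = NULL
  )
}

#' Two-loop probabilistic sensitivity analysis
#'
#' Outer loop: one parameter realization per PSA sample. Inner loop: a
#' cohort of `n_inner` teeth sharing that realization (first-order noise).
#' Each PSA sample is summarised by its inner-cohort means, which is the
#' classic second-order PSA design and yields much tighter per-sample
#' increments than per-tooth pairing.
#'
#' @param scenario A `caries_scenario`.
#' @param n_samples Number of outer parameter draws.
#' @param n_inner Teeth per inner cohort.
#' @param seed Root seed (sample-level child seeds are shared across
#'   strategies run from the same root seed).
#' @return A `cohort_result` whose "per-tooth" vectors hold per-sample
#'   inner-cohort means (so all downstream CEA statistics apply unchanged).
#' @export
run_psa <- function(scenario, n_samples = 200, n_inner = 50, seed = 1L) {
  stopifnot(inherits(scenario, "caries_scenario"))
  if (n_samples < 1 || n_inner < 1) stop("n_samples and n_inner must be >= 1")
  ctx <- build_ctx(scenario)
  set.seed(seed)
  sample_seeds <- sample.int(2147483646L, n_samples)
  effect <- numeric(n_samples); effect_d <- numeric(n_samples)
  cost_d <- numeric(n_samples); cost_u <- numeric(n_samples)
  extracted <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    set.seed(sample_seeds[s])
    ps <- sample_parameter_set(scenario$params, ctx$radiograph, psa = ctx$psa)
    eff <- 0; effd <- 0; cd <- 0; cu <- 0; ex <- 0
    for (j in seq_len(n_inner)) {
      u0 <- stats::runif(1)
      r <- sim_tooth(ctx, ps, u0, store_events = FALSE)
      eff <- eff + r$effect; effd <- effd + r$effect_discounted
      cd <- cd + r$cost_discounted; cu <- cu + r$cost_undiscounted
      ex <- ex + r$extracted
    }
    effect[s] <- eff / n_inner; effect_d[s] <- effd / n_inner
    cost_d[s] <- cd / n_inner; cost_u[s] <- cu / n_inner
    extracted[s] <- ex / n_inner
  }
  structure(list(
    strategy = scenario$strategy,
    n = n_samples,
    n_inner = n_inner,
    seed = seed,
    effect = effect,
    effect_discounted = effect_d,
    cost_discounted = cost_d,
    cost_undiscounted = cost_u,
    extracted = extracted,
    events = NULL
  ), class = "cohort_result")
}

#' Compare the AI and no-AI strategies under one preset
#'
#' Builds the AI and control scenarios for a named preset, simulates both
#' from the same root seed (common random numbers) and returns the full
#' cost-effectiveness analysis.
#'
#' @param preset Name from [scenario_presets()].
#' @param n Teeth per cohort (`level = "tooth"`) or PSA samples
#'   (`level = "sample"`).
#' @param seed Root seed used for both arms.
#' @param level `"tooth"`: one parameter draw per tooth, per-tooth pairing;
#'   `"sample"`: two-loop PSA ([run_psa()]), per-sample pairing.
#' @param n_inner Inner cohort size for `level = "sample"`.
#' @param params,costs Shared configurations.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curves.
#' @param ... Further arguments to [build_scenario()].
#' @return A `ce_result` with cohorts attached as `$cohorts`.
#' @export
compare_strategies <- function(preset = "base_case", n = 1000, seed = 1L,
                               level = c("tooth", "sample"), n_inner = 50,
                               params = caries_parameters(),
                               costs = caries_costs(),
                               wtp_grid = seq(0, 100, by = 5), ...) {
  level <- match.arg(level)
  test <- scenario(preset, strategy = "ai", params = params, costs = costs, ...)
  ctrl <- scenario(preset, strategy = "control", params = params,
                   costs = costs, ...)
  if (level == "tooth") {
    ct <- run_cohort(test, n = n, seed = seed)
    cc <- run_cohort(ctrl, n = n, seed = seed)
  } else {
    ct <- run_psa(test, n_samples = n, n_inner = n_inner, seed = seed)
    cc <- run_psa(ctrl, n_samples = n, n_inner = n_inner, seed = seed)
  }
  out <- ce_analysis(ct, cc, wtp_grid = wtp_grid)
  out$cohorts <- list(test = ct, control = cc)
  out
}
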