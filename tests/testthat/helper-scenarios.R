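# Shared fixture builders. Everything is generated in code; no stored data.

# Parameter set with all disease and failure hazards switched off and
# perfect specificity: nothing ever happens to any tooth.
zero_hazard_params <- function() {
  p <- build_table1_config()
  p$prevalence$low <- list(E2 = 0, D1 = 0, D2 = 0)
  for (s in c("E2", "D1", "D2")) p$development[[s]]$a <- 0
  for (s in c("E2", "D1", "D2")) p$progression$untreated[[s]]$c <- 0
  for (s in c("E2", "D1")) p$progression$infiltrated[[s]]$c <- 0
  for (row in names(p$transitions)) p$transitions[[row]]$p <- param_dist("point", 0)
  for (m in names(p$accuracy)) {
    for (s in names(p$accuracy[[m]]$specificity)) {
      p$accuracy[[m]]$specificity[[s]] <- param_dist("point", 1)
    }
  }
  p
}

# Three-state collapse with effectively constant hazards:
# SOUND --p1--> E2 --p2--> D1 (absorbing). The decay coefficients are set to
# a negligible magnitude (validation requires strictly decaying forms), so
# the per-cycle probabilities are constant to ~1e-9.
const_chain_params <- function(p1, p2) {
  p <- zero_hazard_params()
  for (m in names(p$accuracy)) {
    for (s in names(p$accuracy[[m]]$sensitivity)) {
      p$accuracy[[m]]$sensitivity[[s]] <- param_dist("point", 0)
    }
  }
  p$development$multiplier <- param_dist("point", 1)
  p$development$E2$a <- p1
  p$development$E2$b <- -1e-12
  p$progression$risk_multiplier$low <- 1
  p$progression$untreated$E2$c <- p2
  p$progression$untreated$E2$k <- 1e-12
  p$progression$untreated_spread <- param_dist("point", 1)
  p
}

# closed-form occupancy of the 3-state chain after t cycles
chain_occupancy <- function(p1, p2, t) {
  P <- matrix(c(1 - p1, p1, 0,
                0, 1 - p2, p2,
                0, 0, 1), nrow = 3, byrow = TRUE)
  occ <- c(1, 0, 0)
  for (k in seq_len(t)) occ <- occ %*% P
  drop(occ)
}

# cost schedule with every fee distinct and easy to audit
unit_cost_schedule <- function(fee = 100) {
  cs <- generate_cost_schedule("template")
  cs$fees <- lapply(cs$fees, function(x) fee)
  validate_cost_schedule(unclass(cs))
}

base_pair <- function(preset = "base_case", n = 500, seed = 1, ...) {
  list(
    ai = run_cohort(scenario(preset, "ai", ...), n = n, seed = seed),
    control = run_cohort(scenario(preset, "control", ...), n = n, seed = seed)
  )
}
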