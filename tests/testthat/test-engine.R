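test_that("initial states follow the prevalence profile", {
  p <- caries_parameters()
  set.seed(10)
  n <- 2e4
  draws <- initial_state("low", p, n)
  expected <- c(E2 = 0.14, D1 = 0.025, D2 = 0.005)
  for (s in names(expected)) {
    se <- sqrt(expected[[s]] * (1 - expected[[s]]) / n)
    expect_lt(abs(mean(draws == s) - expected[[s]]), 3 * se)
  }
  hi <- initial_state("high", p, n)
  expect_lt(abs(mean(hi == "E2") - 2.14 * 0.14),
            3 * sqrt(0.2996 * (1 - 0.2996) / n))
  # zero prevalence: always sound
  expect_true(all(initial_state("low", zero_hazard_params(), 500) == "SOUND"))
})

test_that("cohorts are bit-identical for equal seeds", {
  sc <- scenario("base_case", "ai")
  a <- run_cohort(sc, n = 80, seed = 99)
  b <- run_cohort(sc, n = 80, seed = 99)
  expect_identical(a$effect, b$effect)
  expect_identical(a$cost_discounted, b$cost_discounted)
  expect_identical(a$cost_undiscounted, b$cost_undiscounted)
  d <- run_cohort(sc, n = 80, seed = 100)
  expect_false(identical(a$effect, d$effect) &&
                 identical(a$cost_discounted, d$cost_discounted))
})

test_that("retention is bounded by the horizon and costs are non-negative", {
  co <- run_cohort(scenario("high_risk", "control"), n = 400, seed = 2)
  expect_true(all(co$effect >= 0 & co$effect <= 65))
  expect_true(all(co$cost_discounted >= 0))
  expect_true(all(co$cost_discounted <= co$cost_undiscounted))
  expect_true(all(co$effect_discounted <= co$effect))
})

test_that("zero hazards leave every tooth retained with exam-only costs", {
  costs <- caries_costs()
  sc <- build_scenario("ai", params = zero_hazard_params(), costs = costs)
  co <- run_cohort(sc, n = 60, seed = 5, store_events = TRUE)
  expect_true(all(co$effect == 65))
  expect_false(any(co$extracted))
  expect_setequal(unique(co$events$kind),
                  c("exam_vt", "bitewing_pair", "ai_analysis"))
  df <- discount_factor(0:64, 0.03)
  bw <- seq(0, 64, by = 2)
  exam_cost <- sum(df) * cost_of_event("exam_vt", costs) +
    sum(df[bw + 1]) * (cost_of_event("bitewing_pair", costs) +
                         cost_of_event("ai_analysis", costs))
  expect_equal(unique(co$cost_discounted), exam_cost, tolerance = 1e-9)
  # control arm pays no AI fee
  sc2 <- build_scenario("control", params = zero_hazard_params(), costs = costs)
  co2 <- run_cohort(sc2, n = 10, seed = 5)
  expect_equal(unique(co2$cost_discounted),
               exam_cost - sum(df[bw + 1]) * cost_of_event("ai_analysis", costs),
               tolerance = 1e-9)
})

test_that("event ledgers are internally consistent", {
  co <- run_cohort(scenario("base_case", "ai"), n = 400, seed = 8,
                   store_events = TRUE)
  ev <- co$events
  ext <- ev[ev$kind == "extraction", ]
  # at most one extraction per tooth, and it matches the retention record
  expect_true(all(table(ext$tooth) == 1))
  expect_equal(sort(unique(ext$tooth)), which(co$extracted))
  expect_equal(ext$cycle[order(ext$tooth)], co$effect[co$extracted])
  # implants appear only on extracted teeth, in the extraction cycle
  imp <- ev[ev$kind == "implant_iscrown", ]
  expect_true(all(imp$tooth %in% ext$tooth))
  m <- match(imp$tooth, ext$tooth)
  expect_identical(imp$cycle, ext$cycle[m])
  # re-implantation requires an implant
  reimp <- ev[ev$kind == "reimplant", ]
  expect_true(all(reimp$tooth %in% imp$tooth))
  # once restored, a surface is never infiltrated again
  for (tooth in intersect(ev$tooth[ev$kind == "restoration"],
                          ev$tooth[ev$kind == "infiltration"])) {
    te <- ev[ev$tooth == tooth, ]
    expect_lt(max(te$cycle[te$kind == "infiltration"]),
              min(te$cycle[te$kind == "restoration"]) + 1)
  }
})

test_that("disease dynamics match the closed-form chain occupancy", {
  # SOUND -> E2 -> D1 with constant hazards; D1 is announced by an
  # infiltration event through a perfectly sensitive D1-only radiograph
  # read every cycle, so the infiltration time equals the D1 arrival time.
  p1 <- 0.08; p2 <- 0.15
  p <- const_chain_params(p1, p2)
  p$accuracy$radiograph_ai$sensitivity$D1 <- param_dist("point", 1)
  sc <- build_scenario("ai", params = p, psa = FALSE, horizon = 30,
                       schedule = exam_schedule(vt_interval = Inf,
                                                bw_interval = 1))
  n <- 4000
  co <- run_cohort(sc, n = n, seed = 31, store_events = TRUE)
  inf <- co$events[co$events$kind == "infiltration", ]
  expect_true(all(table(inf$tooth) == 1))
  arrival <- rep(Inf, n)
  arrival[inf$tooth] <- inf$cycle
  for (t in c(4, 9, 14, 19, 29)) {
    p_d1 <- chain_occupancy(p1, p2, t + 1)[3]
    se <- sqrt(p_d1 * (1 - p_d1) / n)
    expect_lt(abs(mean(arrival <= t) - p_d1), 3 * se)
  }
})

test_that("the restorative cascade matches a transition-matrix oracle", {
  # every tooth starts D2 and is detected and restored in cycle 0 (perfect
  # accuracy, D2->D3 progression switched off); the subsequent failure
  # cascade must reproduce the absorption behaviour of the annual chain
  # assembled directly from the transition and allocation rows.
  p <- build_table1_config()
  p$prevalence$low <- list(E2 = 0, D1 = 0, D2 = 1)
  p$prevalence$high_multiplier <- list(E2 = 1, D1 = 1, D2 = 1)
  for (m in names(p$accuracy)) {
    for (s in names(p$accuracy[[m]]$sensitivity)) {
      p$accuracy[[m]]$sensitivity[[s]] <- param_dist("point", 1)
      p$accuracy[[m]]$specificity[[s]] <- param_dist("point", 1)
    }
  }
  p$progression$untreated$D2$c <- 0
  sc <- build_scenario("ai", params = p, psa = FALSE)
  n <- 4000
  co <- run_cohort(sc, n = n, seed = 17)

  # independent oracle: annual Markov chain over the cascade states
  states <- c("R0", "R1", "CAP", "CRV1", "CRV2", "CRN1", "CRN2",
              "NSR", "SSR", "EXT")
  P <- matrix(0, 10, 10, dimnames = list(states, states))
  f <- 0.016
  P["R0", "R1"] <- f * (0.45 * 0.9 + 0.10)
  P["R0", "CAP"] <- f * 0.45 * 0.1 * 0.95
  P["R0", "CRN1"] <- f * (0.45 * 0.1 * 0.05 + 0.25)
  P["R0", "CRV1"] <- f * 0.10
  P["R0", "EXT"] <- f * 0.10
  P["R0", "R0"] <- 1 - sum(P["R0", ])
  P["R1", "CRV1"] <- f; P["R1", "R1"] <- 1 - f
  P["CAP", "CRN1"] <- 0.111 * 0.95; P["CAP", "EXT"] <- 0.111 * 0.05
  P["CAP", "CAP"] <- 1 - 0.111
  P["CRV1", "CRN1"] <- 0.036 * 0.25; P["CRV1", "CRV2"] <- 0.036 * 0.40
  P["CRV1", "EXT"] <- 0.036 * 0.10; P["CRV1", "CRV1"] <- 1 - 0.036 * 0.75
  P["CRV2", "CRN2"] <- 0.036 * 0.25; P["CRV2", "EXT"] <- 0.036 * 0.50
  P["CRV2", "CRV2"] <- 1 - 0.036 * 0.75
  pe <- 0.021
  stay <- 1 - 0.029 * 0.7  # no prosthetic failure, or a benign outcome
  P["CRN1", "EXT"] <- 0.029 * 0.1 + stay * pe * 0.5 + 0.029 * 0.6 * pe * 0.5
  P["CRN1", "NSR"] <- (stay + 0.029 * 0.6) * pe * 0.2
  P["CRN1", "SSR"] <- (stay + 0.029 * 0.6) * pe * 0.3
  P["CRN1", "CRN2"] <- 0.029 * 0.6 * (1 - pe)
  P["CRN1", "CRN1"] <- stay * (1 - pe)
  P["CRN2", "EXT"] <- 0.029 * 0.7 + stay * pe * 0.5
  P["CRN2", "NSR"] <- stay * pe * 0.2
  P["CRN2", "SSR"] <- stay * pe * 0.3
  P["CRN2", "CRN2"] <- stay * (1 - pe)
  P["NSR", "SSR"] <- 0.085 * 0.25; P["NSR", "EXT"] <- 0.085 * 0.75
  P["NSR", "NSR"] <- 1 - 0.085
  P["SSR", "EXT"] <- 0.061; P["SSR", "SSR"] <- 1 - 0.061
  P["EXT", "EXT"] <- 1
  expect_equal(rowSums(P), setNames(rep(1, 10), states), tolerance = 1e-12)

  occ <- c(1, rep(0, 9))
  ext_by <- numeric(64)
  for (t in 1:64) {
    occ <- occ %*% P
    ext_by[t] <- occ[10]
  }
  for (t in c(16, 32, 48, 64)) {
    se <- sqrt(ext_by[t] * (1 - ext_by[t]) / n)
    expect_lt(abs(mean(co$effect <= t) - ext_by[t]), 3 * se)
  }
  oracle_mean <- 65 - sum(ext_by)
  expect_lt(abs(mean(co$effect) - oracle_mean),
            3 * stats::sd(co$effect) / sqrt(n))
})

test_that("retention cannot improve when restorations fail more often", {
  p2 <- caries_parameters()
  p2$transitions$composite$p <- param_dist("point", 0.032)
  n <- 3000
  base <- run_cohort(scenario("base_case", "ai"), n = n, seed = 12)
  worse <- run_cohort(build_scenario("ai", params = p2), n = n, seed = 12)
  d <- worse$effect - base$effect
  expect_lt(mean(d), 0 + 3 * stats::sd(d) / sqrt(n))
})

test_that("the more sensitive AI profile does not lose retention years", {
  n <- 4000
  pair <- base_pair(n = n, seed = 21)
  d <- pair$ai$effect - pair$control$effect
  expect_gt(mean(d), 0 - 3 * stats::sd(d) / sqrt(n))
})

test_that("single-tooth histories expose the full event ledger", {
  th <- simulate_tooth(scenario("base_case", "ai"), seed = 4)
  expect_s3_class(th, "tooth_history")
  expect_true(all(c("cycle", "kind") %in% names(th$events)))
  expect_true(all(th$events$kind %in% EVENT_KINDS))
  expect_true(all(diff(th$events$cycle) >= 0))
  expect_lte(th$retention_years, 65)
  expect_gte(th$cost_undiscounted, th$cost_discounted)
})
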