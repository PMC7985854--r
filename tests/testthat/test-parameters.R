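test_that("development hazard matches its closed form at the start age", {
  # direct evaluation of m * a * 2.7^(b * 2*age) with the printed coefficients
  expect_equal(development_probability(12, "E2", multiplier = 1.26),
               1.26 * 0.57252 * 2.7^(-0.1472 * 24), tolerance = 1e-12)
  expect_equal(development_probability(12, "D1", multiplier = 1.26),
               1.26 * 0.0426 * 2.7^(-0.0521 * 24), tolerance = 1e-12)
  expect_equal(development_probability(12, "D2", multiplier = 1.26),
               1.26 * 0.57 * 0.0426 * 2.7^(-0.0521 * 24), tolerance = 1e-12)
  # frozen reference values
  expect_equal(development_probability(12, "E2", multiplier = 1.26),
               0.0216, tolerance = 1e-3)
  expect_equal(development_probability(12, "D1", multiplier = 1.26),
               0.0155, tolerance = 1e-3)
  expect_error(development_probability(10, "E2"), "start age")
})

test_that("progression hazard matches its closed form, per stage and status", {
  expect_equal(progression_probability(12, "E2", risk = "low"),
               2.13 * 3.0984 * 24^(-1.343), tolerance = 1e-12)
  expect_equal(progression_probability(12, "D1", risk = "low"),
               2.13 * 161.52 * 24^(-2.078), tolerance = 1e-12)
  expect_equal(progression_probability(12, "D2"),
               1.32 * 161.52 * 24^(-2.078), tolerance = 1e-12)
  expect_equal(progression_probability(12, "E2", infiltrated = TRUE),
               0.4289 * 24^(-1.391), tolerance = 1e-12)
  expect_equal(progression_probability(12, "D1", infiltrated = TRUE),
               68.869 * 24^(-2.078), tolerance = 1e-12)
  # frozen spot values
  expect_equal(progression_probability(12, "E2", risk = "low"), 0.0925,
               tolerance = 1e-3)
  expect_equal(progression_probability(12, "D1", risk = "low"), 0.466,
               tolerance = 1e-3)
  expect_equal(progression_probability(12, "D2"), 0.289, tolerance = 1e-3)
  expect_equal(progression_probability(12, "E2", infiltrated = TRUE), 0.0052,
               tolerance = 1e-2)
  # the D2 column has no infiltration hazard
  expect_error(progression_probability(12, "D2", infiltrated = TRUE),
               "no infiltration hazard")
})

test_that("hazards are valid probabilities and decay over ages 12-120", {
  ages <- 12:120
  p <- caries_parameters()
  for (stage in c("E2", "D1", "D2")) {
    h <- development_probability(ages, stage, p, multiplier = 1.29)
    expect_true(all(h >= 0 & h <= 1))
    expect_true(all(diff(h) < 0))
  }
  for (stage in c("E2", "D1", "D2")) {
    for (risk in c("low", "high")) {
      h <- progression_probability(ages, stage, risk = risk, params = p,
                                   multiplier = 1.13)
      expect_true(all(h >= 0 & h <= 1))
      expect_true(all(diff(h) < 0))
    }
  }
  for (stage in c("E2", "D1")) {
    h <- progression_probability(ages, stage, infiltrated = TRUE, params = p,
                                 multiplier = 5.15)
    expect_true(all(h >= 0 & h <= 1))
    expect_true(all(diff(h) < 0))
  }
})

test_that("high-risk progression dominates low risk; infiltration lowers it", {
  ages <- 12:120
  for (stage in c("E2", "D1")) {
    lo <- progression_probability(ages, stage, risk = "low")
    hi <- progression_probability(ages, stage, risk = "high")
    inf <- progression_probability(ages, stage, infiltrated = TRUE)
    expect_true(all(hi >= lo))
    expect_true(all(inf <= lo))
  }
})

test_that("parameter sampling honours the distribution kinds", {
  # a point distribution returns the point exactly
  set.seed(1)
  expect_identical(sample_dist(param_dist("point", 0.016)), 0.016)
  ps <- sample_parameter_set(caries_parameters(), "radiograph_ai", psa = TRUE)
  expect_identical(ps$p_composite, 0.016)
  # degenerate triangular collapses to its point
  expect_identical(sample_dist(param_dist("triangular", 0.3, 0.3, 0.3)), 0.3)
  # uniform(1.24, 1.29): sample mean within 3 s.e. of 1.265
  set.seed(42)
  d <- param_dist("uniform", 1.24, 1.26, 1.29)
  draws <- replicate(1e5, sample_dist(d))
  se <- (0.05 / sqrt(12)) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 1.265), 3 * se)
  expect_true(all(draws >= 1.24 & draws <= 1.29))
  # triangular draws respect their support and mode region
  d <- param_dist("triangular", 0.23, 1, 5.15)
  tr <- replicate(2e4, sample_dist(d))
  expect_true(all(tr >= 0.23 & tr <= 5.15))
  expect_lt(abs(mean(tr) - (0.23 + 1 + 5.15) / 3), 0.05)
  # invalid specifications refuse to build
  expect_error(param_dist("uniform", 2, high = 1), "low > high")
  expect_error(param_dist("triangular", 0, 2, 1), "mode outside")
  # probability draws are clamped into [0, 1]
  expect_true(all(replicate(100, sample_dist(param_dist("uniform", -0.5, high = 1.5),
                                             clamp01 = TRUE)) >= 0))
})

test_that("PSA realizations are probability-valid and mode-exact when off", {
  p <- caries_parameters()
  set.seed(7)
  for (i in 1:20) {
    ps <- sample_parameter_set(p, "radiograph_meta", psa = TRUE)
    probs <- ps[grep("^(vt|rad)_|^p_|pulp|capping|replacement", names(ps))]
    expect_true(all(unlist(probs) >= 0 & unlist(probs) <= 1))
  }
  off <- sample_parameter_set(p, "radiograph_meta", psa = FALSE)
  expect_identical(off$rad_sens_E2, 0.24)
  expect_identical(off$m_dev, 1.26)
})

test_that("configurations violating invariants refuse to load", {
  p <- build_table1_config()
  p$transitions$composite$alloc$crown <- 0.2  # sum now 1.1
  expect_error(validate_parameters(p), "sums to")
  p <- build_table1_config()
  p$prevalence$low$E2 <- 0.9  # low-risk fine, high-risk impossible
  expect_error(validate_parameters(p), "more than 1")
  p <- build_table1_config()
  p$accuracy$radiograph_ai$sensitivity$E2 <- param_dist("point", 1.3)
  expect_error(validate_parameters(p), "out of")
  p <- build_table1_config()
  p$development$E2$b <- 0.1
  expect_error(validate_parameters(p), "negative")
  # a violating file refuses to load end to end
  p <- build_table1_config()
  p$transitions$surg_retreat$alloc$extraction <- 0.5
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(cariesim:::params_to_list(p), tf, auto_unbox = TRUE,
                       digits = NA)
  expect_error(load_parameters(tf), "sums to")
})
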