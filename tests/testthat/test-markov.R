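test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0), 1)
  expect_equal(discount_factor(2, 0.03), 1 / 1.03^2)
  expect_equal(discount_factor(2, 0.03), 0.942596, tolerance = 1e-6)
  expect_error(discount_factor(-1, 0.03), class = "baricea_validation_error")
  expect_error(discount_factor(1, -0.01), class = "baricea_validation_error")
})

test_that("decision tree deposits the arm's year-1 vector and prices year 1", {
  cfg <- default_config()
  dt_s <- decision_tree_year1(cfg, "surgery")
  expect_equal(round(dt_s$state_vector[["remission"]] * 1.0100, 4), 0.8356)
  expect_equal(dt_s$entry_cost, 150000)
  expect_equal(dt_s$year1_cost,
               150000 + sum(dt_s$state_vector * cfg$derived$state_costs))

  dt_n <- decision_tree_year1(cfg, "no_surgery")
  expect_equal(dt_n$state_vector[["uncontrolled"]], 0.5998)
  expect_equal(dt_n$entry_cost, 0)

  expect_error(decision_tree_year1(cfg, "banding"), "banding",
               class = "baricea_validation_error")

  # all mass dead: no state-cost contribution in year 1
  raw <- unclass(toy_config())
  raw$derived <- NULL
  raw$arms$no_surgery$year1_probabilities <-
    c(remission = 0, improved = 0, persistent = 0, uncontrolled = 0, dead = 1)
  cfg2 <- as_cea_config(raw)
  expect_equal(decision_tree_year1(cfg2, "no_surgery")$year1_cost, 0)
})

test_that("undiscounted QALYs with identity dynamics equal mass times horizon", {
  P <- diag(5)
  dimnames(P) <- list(state_names(), state_names())
  u1 <- c(remission = 1, improved = 1, persistent = 1, uncontrolled = 1,
          dead = 0)
  cfg <- matrix_config(P, horizon = 12, utilities = u1, discount = 0)
  tr <- run_markov(cfg, "surgery")
  alive0 <- 1 - tr$occ_dead[1]
  expect_equal(attr(tr, "totals")[["qaly"]], 12 * alive0)
  expect_equal(attr(tr, "totals")[["ly"]], 12 * alive0)
})

test_that("discounted QALYs with unit utility equal the annuity closed form", {
  P <- diag(5)
  dimnames(P) <- list(state_names(), state_names())
  u1 <- c(remission = 1, improved = 1, persistent = 1, uncontrolled = 1,
          dead = 0)
  all_alive <- c(remission = 1, improved = 0, persistent = 0,
                 uncontrolled = 0, dead = 0)
  cfg <- matrix_config(P, horizon = 50, utilities = u1, discount = 0.03,
                       init_surgery = all_alive)
  tr <- run_markov(cfg, "surgery")
  annuity <- (1 - 1.03^-50) / 0.03   # sum_{t=1}^{50} 1.03^-t
  expect_equal(attr(tr, "totals")[["qaly"]], annuity)
  expect_equal(attr(tr, "totals")[["ly"]], annuity)
})

test_that("the trace equals an independent step-by-step iteration", {
  set.seed(11)
  for (rep in 1:3) {
    P <- random_stochastic_matrix()
    cfg <- matrix_config(P, horizon = 10)
    for (arm in c("surgery", "no_surgery")) {
      tr <- run_markov(cfg, arm)
      oracle <- naive_trace(cfg$derived$arms[[arm]]$init, P,
                            cfg$derived$state_costs, cfg$utilities,
                            0.03, 10,
                            entry_cost = cfg$derived$arms[[arm]]$entry_cost)
      expect_equal(as.matrix(tr[, paste0("occ_", state_names())]),
                   oracle[, state_names()], ignore_attr = TRUE,
                   tolerance = 1e-12)
      expect_equal(tr$disc_cost, unname(oracle[, "disc_cost"]))
      expect_equal(tr$disc_ly, unname(oracle[, "disc_ly"]))
      expect_equal(tr$disc_qaly, unname(oracle[, "disc_qaly"]))
    }
  }
})

test_that("occupancy conserves mass, keeps dead monotone, equals matrix powers", {
  set.seed(12)
  for (rep in 1:4) {
    P <- random_stochastic_matrix()
    cfg <- matrix_config(P, horizon = 25)
    tr <- run_markov(cfg, "surgery")
    occ <- as.matrix(tr[, paste0("occ_", state_names())])
    expect_true(all(abs(rowSums(occ) - 1) <= 1e-9))
    expect_true(all(occ >= -1e-15))
    expect_true(all(diff(tr$occ_dead) >= -1e-12))
    # matrix-power equivalence, occupancy(cycle t) = init P^(t-1)
    init <- cfg$derived$arms$surgery$init
    Pk <- diag(5)
    for (t in 1:25) {
      expect_true(max(abs(occ[t, ] - as.numeric(init %*% Pk))) <= 1e-9)
      Pk <- Pk %*% P
    }
    # cumulative series are non-decreasing; discounted <= undiscounted
    expect_true(all(diff(tr$cum_disc_cost) >= 0))
    expect_true(all(diff(tr$cum_disc_qaly) >= 0))
    expect_true(all(tr$disc_qaly <= tr$qaly + 1e-12))
    # QALYs cannot exceed life-years while utilities are bounded by 1
    expect_true(all(tr$qaly <= tr$ly + 1e-12))
  }
})

test_that("non-stochastic dynamics are rejected before iteration", {
  cfg <- toy_config()
  cfg$derived$arms$surgery$transition_matrix[1, 1] <- 2  # corrupt post-load
  expect_error(run_markov(cfg, "surgery"), "stochastic",
               class = "baricea_validation_error")
  expect_error(run_markov(toy_config(), "surgery",
                          initial = c(0.5, 0.1, 0.1, 0.1, 0.1)),
               "sum to 1", class = "baricea_validation_error")
})

test_that("half-cycle accrual averages adjacent occupancies", {
  cfg <- toy_config(horizon = 8)
  full <- run_markov(cfg, "surgery")
  half <- run_markov(cfg, "surgery", half_cycle = TRUE)
  # cycle 1 identical (entry cost and decision-tree year untouched)
  expect_equal(half$disc_cost[1], full$disc_cost[1])
  # later cycles: hand-average the occupancy rows of the plain trace
  occ <- as.matrix(full[, paste0("occ_", state_names())])
  u <- cfg$utilities
  t <- 5
  expected <- sum((occ[t - 1, ] + occ[t, ]) / 2 * u) * 1.03^(-t)
  expect_equal(half$disc_qaly[t], expected)
})

test_that("the two-arm fit carries totals, increments and a WTP verdict", {
  cfg <- toy_config(horizon = 20)
  fit <- cea(cfg)
  expect_s3_class(fit, "cea_fit")
  expect_equal(fit$totals$cost[1], attr(fit$traces$surgery, "totals")[["cost"]])
  expect_equal(fit$results$qaly$incremental_cost,
               fit$totals$cost[1] - fit$totals$cost[2])
  expect_true(fit$verdict %in% c("cost-effective at low WTP",
                                 "cost-effective at high WTP only",
                                 "not cost-effective", "dominant",
                                 "dominated", "equivalent"))
  cf <- coef(fit)
  expect_named(cf, c("delta_cost", "delta_ly", "delta_qaly", "icer", "icur"))

  # identical arms: every incremental quantity is exactly zero
  eq <- cea(equal_arm_config())
  expect_identical(eq$results$qaly$incremental_cost, 0)
  expect_identical(eq$results$qaly$incremental_effect, 0)
  expect_identical(eq$results$ly$incremental_effect, 0)
  expect_equal(eq$verdict, "equivalent")
})
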