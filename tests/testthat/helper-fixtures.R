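# Shared in-code fixtures. Everything is built programmatically so tests
# carry no binary or external data.

state_names <- function() {
  c("remission", "improved", "persistent", "uncontrolled", "dead")
}

# Small fully hand-specified two-arm configuration; year-1 vectors sum to
# exactly 1 so no renormalization warning fires.
toy_config <- function(horizon = 10, relapse = 0.1, death = 0.01,
                       surgery_cost = 1000, wtp = c(1000, 2000),
                       discount = 0.03) {
  as_cea_config(list(
    arms = list(
      surgery = list(
        year1_probabilities = c(remission = 0.7, improved = 0.1,
                                persistent = 0.1, uncontrolled = 0.05,
                                dead = 0.05),
        one_time_cost_items = "surgery",
        transition = list(relapse_probability = relapse,
                          death_probability = death)),
      no_surgery = list(
        year1_probabilities = c(remission = 0.05, improved = 0.2,
                                persistent = 0.3, uncontrolled = 0.4,
                                dead = 0.05),
        one_time_cost_items = character(0),
        transition = list(relapse_probability = relapse,
                          death_probability = death))),
    unit_costs = c(surgery = surgery_cost, metformin = 50, sulfonylurea = 20,
                   insulin = 300, supplementation = 10,
                   complication_management = 500),
    state_cost_composition = list(
      remission = "supplementation",
      improved = "metformin",
      persistent = c("metformin", "sulfonylurea"),
      uncontrolled = c("metformin", "sulfonylurea", "insulin",
                       "complication_management"),
      dead = character(0)),
    utilities = c(remission = 0.9, improved = 0.85, persistent = 0.8,
                  uncontrolled = 0.7, dead = 0),
    discount_rate = discount,
    horizon_years = horizon,
    wtp_band = wtp))
}

# Both arms identical: every incremental quantity must be exactly zero.
equal_arm_config <- function(horizon = 10) {
  cfg <- toy_config(horizon = horizon)
  raw <- unclass(cfg)
  raw$derived <- NULL
  raw$arms$surgery <- raw$arms$no_surgery
  as_cea_config(raw)
}

# Configuration with explicit transition matrices (same matrix both arms).
matrix_config <- function(P, horizon = 10, utilities = NULL, discount = 0.03,
                          init_surgery = NULL) {
  cfg <- toy_config(horizon = horizon, discount = discount)
  raw <- unclass(cfg)
  raw$derived <- NULL
  for (a in names(raw$arms)) raw$arms[[a]]$transition <- list(matrix = P)
  if (!is.null(utilities)) raw$utilities <- utilities
  if (!is.null(init_surgery)) {
    raw$arms$surgery$year1_probabilities <- init_surgery
  }
  as_cea_config(raw)
}

# Random row-stochastic 5x5 matrix with an absorbing dead state.
random_stochastic_matrix <- function() {
  m <- matrix(stats::runif(25), 5, 5)
  m <- m / rowSums(m)
  m[5, ] <- c(0, 0, 0, 0, 1)
  dimnames(m) <- list(state_names(), state_names())
  m
}

# Independent step-by-step trace oracle: explicit loops, no matrix powers,
# no shared code with run_markov.
naive_trace <- function(init, P, state_costs, utilities, r, T,
                        entry_cost = 0) {
  occ <- init
  out <- data.frame(cycle = integer(0))
  rows <- vector("list", T)
  for (t in seq_len(T)) {
    if (t > 1) {
      nxt <- numeric(5)
      for (j in 1:5) {
        acc <- 0
        for (i in 1:5) acc <- acc + occ[i] * P[i, j]
        nxt[j] <- acc
      }
      occ <- nxt
    }
    cost <- 0
    qaly <- 0
    ly <- 0
    for (i in 1:5) {
      cost <- cost + occ[i] * state_costs[i]
      qaly <- qaly + occ[i] * utilities[i]
    }
    for (i in 1:4) ly <- ly + occ[i]
    if (t == 1) cost <- cost + entry_cost
    df <- (1 + r)^(-t)
    rows[[t]] <- c(occ, cost * df, ly * df, qaly * df)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c(state_names(), "disc_cost", "disc_ly", "disc_qaly")
  m
}

# Tiny hand-written cohort as a data.frame in the read_cohort() layout.
hand_cohort <- function(baseline_bmi, year1_bmi, baseline_hba1c, year1_hba1c,
                        meds = NULL, deceased = NULL) {
  n <- length(baseline_bmi)
  data.frame(
    id = sprintf("H%02d", seq_len(n)),
    sex = rep("female", n),
    age = rep(45, n),
    baseline_bmi = baseline_bmi,
    year1_bmi = year1_bmi,
    baseline_hba1c = baseline_hba1c,
    year1_hba1c = year1_hba1c,
    year1_medications = I(meds %||% rep(list(character(0)), n)),
    deceased_by_year1 = deceased %||% rep(FALSE, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
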