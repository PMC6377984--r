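#' Model configuration for the two-arm cost-utility analysis
#'
#' A `cea_config` bundles every numeric parameter of the analysis: the
#' year-1 state probabilities of each strategy arm (the decision-tree
#' outputs), the years-2+ annual transition dynamics, unit healthcare costs
#' and the per-state annual cost composition, state utilities, discount
#' rates, time horizon, the willingness-to-pay band and the parameter
#' ranges used by the one-way sensitivity analysis.
#'
#' @details
#' The on-disk dialect is JSON (see the bundled baseline returned by
#' [default_config()] for a complete example). Top-level fields:
#'
#' * `arms`: named list of strategy arms. Each arm carries
#'   `year1_probabilities` (named over the five states; vectors whose sum
#'   is within ±0.015 of 1 are renormalized with a warning, anything
#'   further off is an error), `one_time_cost_items` (unit-cost names
#'   charged once at entry, e.g. the surgery fee) and `transition` —
#'   either a full 5x5 row-stochastic `matrix` (rows/columns in state
#'   order) or the parametric form `relapse_probability` (annual
#'   remission to improved) plus `death_probability` (flat annual
#'   mortality from every alive state), from which the matrix is built.
#' * `unit_costs`: THB per year (drugs, supplementation, complication
#'   management) or THB per event (surgery).
#' * `state_cost_composition`: which unit costs each alive state accrues
#'   annually; evaluated at load into a flat per-state cost vector, so the
#'   Markov engine sees `state_costs`. The dead state must compose to 0.
#' * `utilities`: per-state utility weight in `[0, 1]`; dead must be 0.
#' * `discount_rate`, `effect_discount_rate`: annual proportions (both
#'   default 0.03; effects fall back to the cost rate when omitted).
#' * `horizon_years`: number of annual cycles (integer >= 1).
#' * `wtp_band`: `(low, high)` THB per QALY.
#' * `cpi_base_year`: calendar year costs are expressed in.
#' * `parameter_ranges`: named `(low, high)` pairs keyed by parameter path
#'   (see [set_parameter()]) for the deterministic sensitivity analysis.
#'
#' Derived quantities (renormalized initial vectors, transition matrices,
#' per-state annual costs, per-arm entry costs) are recomputed by
#' [finalize_config()] and stored under `$derived`; they are never written
#' back to disk.
#'
#' @param x a named list with the fields described under Details.
#' @param quiet suppress the renormalization warning (validation errors are
#'   never suppressed).
#' @return `as_cea_config()` returns a validated `cea_config` object.
#' @seealso [load_config()], [write_config()], [default_config()],
#'   [set_parameter()]
#' @export
as_cea_config <- function(x, quiet = FALSE) {
  if (!is.list(x)) stop_validation("config must be a list")
  required <- c("arms", "unit_costs", "state_cost_composition", "utilities",
                "discount_rate", "horizon_years", "wtp_band")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop_validation("config is missing required field(s): ",
                    paste(missing, collapse = ", "))
  }
  x$effect_discount_rate <- x$effect_discount_rate %||% x$discount_rate
  x$cpi_base_year <- x$cpi_base_year %||% 2017
  x$parameter_ranges <- x$parameter_ranges %||% list()
  class(x) <- "cea_config"
  finalize_config(x, quiet = quiet)
}

#' Read a model configuration from a JSON file
#'
#' Parses and validates the documented JSON dialect (see [as_cea_config()]).
#' Year-1 probability vectors summing within ±0.015 of 1 are renormalized
#' with a warning naming the arm; sums outside that band are errors, as are
#' missing fields, probabilities or utilities outside `[0, 1]`, negative
#' costs, and non-row-stochastic transition matrices.
#'
#' @param path path to a JSON configuration file.
#' @param quiet suppress the renormalization warning.
#' @return a validated [cea_config][as_cea_config] object.
#' @examples
#' cfg <- default_config(quiet = TRUE)
#' cfg$derived$arms$surgery$init["remission"]
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_cea_config(raw, quiet = quiet)
}

#' Write a model configuration to a JSON file
#'
#' Serializes the primitive fields of a `cea_config` (derived quantities are
#' dropped and recomputed on load). `load_config(write_config(cfg, p))`
#' yields a configuration equal to `cfg`.
#'
#' @param config a [cea_config][as_cea_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  out <- unclass(config)
  out$derived <- NULL
  # named atomic vectors must become JSON objects, not bare arrays
  as_obj <- function(x) if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  out$utilities <- as_obj(out$utilities)
  out$unit_costs <- as_obj(out$unit_costs)
  for (a in names(out$arms)) {
    out$arms[[a]]$year1_probabilities <-
      as_obj(out$arms[[a]]$year1_probabilities)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' The bundled baseline configuration
#'
#' Loads the package's baseline parameter set for the Thai healthcare
#' setting: year-1 outcome probabilities for the surgery and no-surgery
#' arms, unit costs in 2017 THB with sensitivity ranges, state utilities,
#' a 3% annual discount rate, a 50-year horizon and a willingness-to-pay
#' band of 150,000–200,000 THB/QALY. The surgery arm's printed year-1
#' vector sums to 1.0100 and is renormalized at load (warning suppressed
#' by default here; `load_config()` on the same file shows it).
#'
#' The years-2+ transition dynamics and the persistent/uncontrolled drug
#' bundles are modelling assumptions documented in the configuration file
#' and in `vignette("bariatric-cea-methods")`.
#'
#' @param quiet suppress the renormalization warning (default `TRUE`).
#' @return a validated [cea_config][as_cea_config] object.
#' @export
default_config <- function(quiet = TRUE) {
  path <- system.file("extdata", "baseline_config.json", package = "baricea",
                      mustWork = TRUE)
  load_config(path, quiet = quiet)
}

#' Recompute derived quantities and validate a configuration
#'
#' Called by [as_cea_config()] and after every [set_parameter()]. Populates
#' `config$derived`: per-state annual costs composed from unit costs,
#' renormalized year-1 initial vectors, annual transition matrices and
#' per-arm entry costs; then checks every invariant.
#'
#' @inheritParams write_config
#' @param quiet suppress the renormalization warning.
#' @param check_ranges verify that every sensitivity range brackets its
#'   current baseline. On by default; [set_parameter()] turns it off so a
#'   parameter may legitimately be pushed to (or beyond) the edge of its
#'   own declared range during sensitivity exploration.
#' @return the configuration with `$derived` rebuilt.
#' @export
finalize_config <- function(config, quiet = FALSE, check_ranges = TRUE) {
  states <- .states()

  # --- scalar fields -------------------------------------------------------
  for (f in c("discount_rate", "effect_discount_rate")) {
    r <- config[[f]]
    if (!is.numeric(r) || length(r) != 1 || r < 0) {
      stop_validation(f, " must be a single non-negative number")
    }
  }
  h <- config$horizon_years
  if (!is.numeric(h) || length(h) != 1 || h < 1 || h != round(h)) {
    stop_validation("horizon_years must be a whole number >= 1")
  }
  config$horizon_years <- as.integer(h)
  wtp <- unlist(config$wtp_band, use.names = FALSE)
  if (length(wtp) != 2 || any(wtp <= 0) || wtp[1] > wtp[2]) {
    stop_validation("wtp_band must be (low, high) with 0 < low <= high")
  }
  config$wtp_band <- as.numeric(wtp)

  # --- utilities -----------------------------------------------------------
  u <- unlist(config$utilities)
  if (!all(states %in% names(u))) {
    stop_validation("utilities must name every state: ",
                    paste(setdiff(states, names(u)), collapse = ", "))
  }
  u <- u[states]
  if (any(u < 0 | u > 1)) stop_validation("utilities must lie in [0, 1]")
  if (u[["dead"]] != 0) stop_validation("the dead state must have utility 0")
  config$utilities <- u

  # --- unit costs and state composition ------------------------------------
  uc <- unlist(config$unit_costs)
  if (is.null(names(uc)) || any(!nzchar(names(uc)))) {
    stop_validation("unit_costs must be a named map")
  }
  if (any(uc < 0)) stop_validation("unit costs must be non-negative")
  config$unit_costs <- uc

  comp <- config$state_cost_composition
  if (!all(states %in% names(comp))) {
    stop_validation("state_cost_composition must name every state")
  }
  state_costs <- vapply(states, function(s) {
    items <- as.character(unlist(comp[[s]]))
    unknown <- setdiff(items, names(uc))
    if (length(unknown)) {
      stop_validation("state_cost_composition for '", s,
                      "' references unknown unit cost(s): ",
                      paste(unknown, collapse = ", "))
    }
    sum(uc[items])
  }, numeric(1))
  if (state_costs[["dead"]] != 0) {
    stop_validation("the dead state must have annual cost 0")
  }

  # --- arms ----------------------------------------------------------------
  if (!is.list(config$arms) || length(config$arms) < 1 ||
      is.null(names(config$arms))) {
    stop_validation("arms must be a named list of strategy arms")
  }
  derived_arms <- lapply(names(config$arms), function(a) {
    arm <- config$arms[[a]]
    p <- unlist(arm$year1_probabilities)
    if (!all(states %in% names(p))) {
      stop_validation("arm '", a, "': year1_probabilities must name every state")
    }
    p <- p[states]
    if (any(p < 0 | p > 1)) {
      stop_validation("arm '", a, "': year-1 probabilities must lie in [0, 1]")
    }
    s <- sum(p)
    if (abs(s - 1) > .prob_sum_tol) {
      stop_validation("arm '", a, "': year-1 probability vector sums to ",
                      format(s), ", outside the accepted band 1 ± ",
                      .prob_sum_tol)
    }
    if (abs(s - 1) > 1e-9 && !quiet) {
      warn_classed("baricea_renormalized",
                   "arm '", a, "': year-1 probability vector sums to ",
                   format(s), "; renormalized to 1")
    }
    init <- p / s

    items <- as.character(unlist(arm$one_time_cost_items))
    unknown <- setdiff(items, names(config$unit_costs))
    if (length(unknown)) {
      stop_validation("arm '", a, "': unknown one-time cost item(s): ",
                      paste(unknown, collapse = ", "))
    }
    entry_cost <- if (length(items)) sum(config$unit_costs[items]) else 0

    P <- build_transition_matrix(arm$transition, arm = a)
    list(init = init, transition_matrix = P, entry_cost = entry_cost)
  })
  names(derived_arms) <- names(config$arms)

  config$derived <- list(state_costs = state_costs, arms = derived_arms)

  # --- sensitivity ranges (need derived baselines to validate) -------------
  pr <- config$parameter_ranges
  if (length(pr) && check_ranges) {
    if (is.null(names(pr))) stop_validation("parameter_ranges must be named")
    config$parameter_ranges <- lapply(names(pr), function(nm) {
      rng <- as.numeric(unlist(pr[[nm]]))
      if (length(rng) != 2 || rng[1] > rng[2]) {
        stop_validation("parameter range for '", nm, "' must be (low, high)")
      }
      base <- get_parameter(config, nm)
      if (base < rng[1] || base > rng[2]) {
        stop_validation("parameter range for '", nm, "' (", rng[1], ", ",
                        rng[2], ") does not bracket its baseline ", base)
      }
      rng
    })
    names(config$parameter_ranges) <- names(pr)
  }

  config
}

# Build (or validate) an arm's annual 5x5 transition matrix for cycles 2+.
# Parametric form: alive states persist except an annual remission->improved
# relapse and a flat annual death probability from every alive state; dead
# is absorbing. A fully specified matrix is validated row-stochastic
# (within 1e-9) and then exactly renormalized.
build_transition_matrix <- function(transition, arm = "?") {
  states <- .states()
  if (is.null(transition)) {
    stop_validation("arm '", arm, "': transition is missing")
  }
  m <- transition$matrix
  if (!is.null(m)) {
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    m <- as.matrix(m)
    if (!all(dim(m) == c(5, 5))) {
      stop_validation("arm '", arm, "': transition matrix must be 5x5")
    }
    storage.mode(m) <- "double"
    dimnames(m) <- list(states, states)
    if (any(m < 0)) {
      stop_validation("arm '", arm, "': transition probabilities must be >= 0")
    }
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-9)) {
      stop_validation("arm '", arm, "': transition matrix rows must sum to 1 ",
                      "(worst deviation ", format(max(abs(rs - 1))), ")")
    }
    m <- m / rs
    if (!identical(unname(m["dead", ] != 0), c(FALSE, FALSE, FALSE, FALSE, TRUE))) {
      stop_validation("arm '", arm, "': the dead state must be absorbing")
    }
    return(m)
  }
  relapse <- transition$relapse_probability
  death <- transition$death_probability %||% 0
  if (is.null(relapse)) {
    stop_validation("arm '", arm, "': transition needs either a matrix or ",
                    "relapse_probability (+ death_probability)")
  }
  if (relapse < 0 || relapse > 1 || death < 0 || death > 1 ||
      relapse + death > 1) {
    stop_validation("arm '", arm, "': relapse and death probabilities must ",
                    "lie in [0, 1] with relapse + death <= 1")
  }
  m <- diag(1 - death, 5)
  dimnames(m) <- list(states, states)
  m[, "dead"] <- death
  m["remission", "remission"] <- 1 - relapse - death
  m["remission", "improved"] <- relapse
  m["dead", ] <- c(0, 0, 0, 0, 1)
  m
}

#' Resolve or modify a single model parameter by path
#'
#' Parameters are addressed by dotted paths, the same keys used in
#' `parameter_ranges` and reported by [one_way_dsa()]:
#'
#' * `cost.<item>` — a unit cost (e.g. `cost.surgery`, `cost.metformin`);
#'   per-state annual costs and entry costs are recomposed.
#' * `utility.<state>` — a state utility weight.
#' * `prob.<arm>.<state>` — an arm's (renormalized) year-1 probability for
#'   one state; the remaining states are rescaled proportionally so the
#'   vector still sums to 1.
#' * `transition.<arm>.relapse_probability` /
#'   `transition.<arm>.death_probability` — parametric transition inputs
#'   (only for arms specified parametrically).
#' * `discount_rate`, `effect_discount_rate`.
#'
#' @param config a [cea_config][as_cea_config].
#' @param name a parameter path.
#' @param value the new value.
#' @return `get_parameter()` the current (derived-scale) value;
#'   `set_parameter()` a revalidated configuration with the value applied.
#' @examples
#' cfg <- default_config()
#' get_parameter(cfg, "cost.surgery")
#' cfg2 <- set_parameter(cfg, "cost.surgery", 126200)
#' @export
get_parameter <- function(config, name) {
  stopifnot(inherits(config, "cea_config"))
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  bad <- function() stop_validation("cannot resolve parameter '", name, "'")
  if (length(parts) == 1) {
    if (!parts %in% c("discount_rate", "effect_discount_rate")) bad()
    return(config[[parts]])
  }
  switch(parts[1],
    cost = {
      if (length(parts) != 2 || !parts[2] %in% names(config$unit_costs)) bad()
      unname(config$unit_costs[[parts[2]]])
    },
    utility = {
      if (length(parts) != 2 || !parts[2] %in% .states()) bad()
      unname(config$utilities[[parts[2]]])
    },
    prob = {
      if (length(parts) != 3 || !parts[2] %in% names(config$arms) ||
          !parts[3] %in% .states()) bad()
      unname(config$derived$arms[[parts[2]]]$init[[parts[3]]])
    },
    transition = {
      if (length(parts) != 3 || !parts[2] %in% names(config$arms)) bad()
      tr <- config$arms[[parts[2]]]$transition
      if (!parts[3] %in% c("relapse_probability", "death_probability") ||
          is.null(tr[[parts[3]]])) bad()
      tr[[parts[3]]]
    },
    bad()
  )
}

#' @rdname get_parameter
#' @export
set_parameter <- function(config, name, value) {
  stopifnot(inherits(config, "cea_config"), is.numeric(value),
            length(value) == 1)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  bad <- function() stop_validation("cannot resolve parameter '", name, "'")
  if (length(parts) == 1) {
    if (!parts %in% c("discount_rate", "effect_discount_rate")) bad()
    config[[parts]] <- value
  } else if (parts[1] == "cost") {
    if (length(parts) != 2 || !parts[2] %in% names(config$unit_costs)) bad()
    config$unit_costs[[parts[2]]] <- value
  } else if (parts[1] == "utility") {
    if (length(parts) != 2 || !parts[2] %in% .states()) bad()
    config$utilities[[parts[2]]] <- value
  } else if (parts[1] == "prob") {
    if (length(parts) != 3 || !parts[2] %in% names(config$arms) ||
        !parts[3] %in% .states()) bad()
    if (value < 0 || value > 1) {
      stop_validation("probability '", name, "' must lie in [0, 1]")
    }
    p <- config$derived$arms[[parts[2]]]$init
    old <- p[[parts[3]]]
    if (old >= 1 && value < 1) {
      stop_validation("cannot rescale '", name, "': no complement mass")
    }
    scale <- if (old < 1) (1 - value) / (1 - old) else 1
    p <- p * scale
    p[[parts[3]]] <- value
    config$arms[[parts[2]]]$year1_probabilities <- p
  } else if (parts[1] == "transition") {
    if (length(parts) != 3 || !parts[2] %in% names(config$arms) ||
        !parts[3] %in% c("relapse_probability", "death_probability")) bad()
    if (is.null(config$arms[[parts[2]]]$transition[[parts[3]]])) bad()
    config$arms[[parts[2]]]$transition[[parts[3]]] <- value
  } else {
    bad()
  }
  finalize_config(config, quiet = TRUE, check_ranges = FALSE)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("Cost-utility model configuration\n")
  cat("  arms:          ", paste(names(x$arms), collapse = ", "), "\n")
  cat("  horizon:       ", x$horizon_years, "annual cycles\n")
  cat("  discounting:   ", sprintf("%.1f%% costs, %.1f%% effects",
      100 * x$discount_rate, 100 * x$effect_discount_rate), "\n")
  cat("  WTP band:      ", sprintf("%s - %s THB/QALY",
      format(x$wtp_band[1], big.mark = ",", scientific = FALSE),
      format(x$wtp_band[2], big.mark = ",", scientific = FALSE)), "\n")
  cat("  state costs (THB/yr):\n")
  print(round(x$derived$state_costs, 2))
  cat("  utilities:\n")
  print(x$utilities)
  invisible(x)
}

#' Read a consumer-price-index table
#'
#' Two-column CSV (`year`, `index`); all index values must be positive.
#'
#' @param path path to the CSV file.
#' @return a data.frame with columns `year` and `index`.
#' @export
read_cpi <- function(path) {
  if (!file.exists(path)) stop_validation("CPI file not found: ", path)
  cpi <- utils::read.csv(path)
  if (!all(c("year", "index") %in% names(cpi))) {
    stop_validation("CPI table must have columns 'year' and 'index'")
  }
  if (any(!is.finite(cpi$index)) || any(cpi$index <= 0)) {
    stop_validation("CPI index values must be positive")
  }
  cpi[c("year", "index")]
}

#' Rebase a cost to another calendar year using a CPI table
#'
#' Returns `amount * index(base_year) / index(from_year)`.
#'
#' @param amount cost in THB (vectorized).
#' @param from_year calendar year the amount is expressed in.
#' @param cpi a CPI table as returned by [read_cpi()], or a named numeric
#'   vector `year -> index`.
#' @param base_year target calendar year.
#' @return the rebased amount(s) in THB.
#' @examples
#' cpi <- data.frame(year = c(2016, 2017), index = c(100, 102))
#' cpi_adjust(100, 2016, cpi, 2017)  # 102
#' @export
cpi_adjust <- function(amount, from_year, cpi, base_year) {
  if (is.data.frame(cpi)) {
    idx <- stats::setNames(cpi$index, cpi$year)
  } else {
    idx <- cpi
  }
  for (y in c(from_year, base_year)) {
    if (!as.character(y) %in% names(idx)) {
      stop_validation("CPI table has no entry for year ", y)
    }
  }
  amount * unname(idx[as.character(base_year)] / idx[as.character(from_year)])
}
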