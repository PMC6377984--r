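#' Discount factor for an annual cycle
#'
#' `(1 + r)^(-t)`: the present-value weight of a quantity accrued at the
#' end of cycle `t` under annual rate `r`. Cycle 0 (the present) has
#' factor 1.
#'
#' @param t cycle index (non-negative, vectorized).
#' @param r annual discount rate as a proportion (>= 0).
#' @return the discount factor(s).
#' @examples
#' discount_factor(2, 0.03)  # 1 / 1.03^2
#' @export
discount_factor <- function(t, r) {
  if (any(t < 0)) stop_validation("cycle index must be non-negative")
  if (any(r < 0)) stop_validation("discount rate must be non-negative")
  (1 + r)^(-t)
}

#' Year-1 decision tree for one strategy arm
#'
#' The decision tree deposits the arm's cohort into the five diabetes
#' states at the end of year 1 using the arm's (renormalized) year-1
#' probability vector, and prices that first year: any one-time entry cost
#' (the surgery fee in the surgery arm) plus the expected state annual
#' costs.
#'
#' @param config a [cea_config][as_cea_config].
#' @param arm arm name (must exist in `config$arms`).
#' @return a list with `state_vector` (named occupancy probabilities
#'   summing to 1), `entry_cost` (one-time THB), `year1_cost`
#'   (undiscounted THB: entry cost + expected state costs) and `arm`.
#' @examples
#' dt <- decision_tree_year1(default_config(), "surgery")
#' round(dt$state_vector["remission"], 4)
#' @export
decision_tree_year1 <- function(config, arm) {
  stopifnot(inherits(config, "cea_config"))
  if (!arm %in% names(config$arms)) {
    stop_validation("unknown strategy arm '", arm, "'; available: ",
                    paste(names(config$arms), collapse = ", "))
  }
  d <- config$derived$arms[[arm]]
  list(state_vector = d$init,
       entry_cost = d$entry_cost,
       year1_cost = d$entry_cost + sum(d$init * config$derived$state_costs),
       arm = arm)
}

#' Run the annual-cycle Markov cohort trace for one arm
#'
#' Cycle 1 is the decision-tree year: its occupancy is the year-1 state
#' vector and its cost includes the arm's one-time entry cost. From cycle 2
#' on, occupancy evolves by the arm's annual transition matrix,
#' `occ(t) = occ(t-1) %*% P`. Costs, life-years and QALYs accrue at the end
#' of each cycle and are discounted by `(1 + r)^(-t)` with `t` the cycle
#' number (so the decision-tree year is discounted at exponent 1); costs
#' use `discount_rate`, life-years and QALYs `effect_discount_rate`. With
#' `half_cycle = TRUE`, accrual in cycles 2+ uses the mean of the start-
#' and end-of-cycle occupancy instead (entry cost unaffected).
#'
#' This is a deterministic expected-value cohort simulation; no random
#' numbers are used.
#'
#' @param config a [cea_config][as_cea_config].
#' @param arm arm name.
#' @param initial optional initial state vector (named or in state order,
#'   non-negative, summing to 1 within 1e-9); defaults to the arm's
#'   decision-tree output.
#' @param half_cycle use the half-cycle accrual correction (default off).
#' @return a `markov_trace`: a data.frame with one row per cycle
#'   (`cycle`, per-state `occ_*`, undiscounted and discounted `cost`,
#'   `ly`, `qaly`, and cumulative discounted columns), with attributes
#'   `arm` and `totals` (total discounted cost, life-years and QALYs).
#' @examples
#' tr <- run_markov(default_config(), "surgery")
#' attr(tr, "totals")
#' @export
run_markov <- function(config, arm, initial = NULL, half_cycle = FALSE) {
  stopifnot(inherits(config, "cea_config"))
  if (!arm %in% names(config$arms)) {
    stop_validation("unknown strategy arm '", arm, "'")
  }
  states <- .states()
  d <- config$derived$arms[[arm]]
  P <- d$transition_matrix
  rs <- rowSums(P)
  if (any(P < 0) || any(abs(rs - 1) > 1e-9)) {
    stop_validation("arm '", arm, "': transition matrix is not row-stochastic")
  }

  if (is.null(initial)) {
    init <- d$init
    entry_cost <- d$entry_cost
  } else {
    init <- unlist(initial)
    if (!is.null(names(init))) {
      if (!all(states %in% names(init))) {
        stop_validation("initial state vector must name every state")
      }
      init <- init[states]
    } else if (length(init) != 5) {
      stop_validation("initial state vector must have five entries")
    }
    if (any(init < 0) || abs(sum(init) - 1) > 1e-9) {
      stop_validation("initial state vector must be non-negative and sum to 1")
    }
    names(init) <- states
    entry_cost <- d$entry_cost
  }

  T <- config$horizon_years
  occ <- matrix(NA_real_, nrow = T, ncol = 5, dimnames = list(NULL, states))
  occ[1, ] <- init
  if (T > 1) {
    for (t in 2:T) occ[t, ] <- occ[t - 1, ] %*% P
  }

  # accrual occupancy: end-of-cycle by default; averaged under half-cycle
  acc <- occ
  if (half_cycle && T > 1) {
    acc[2:T, ] <- (occ[1:(T - 1), , drop = FALSE] + occ[2:T, , drop = FALSE]) / 2
  }

  sc <- config$derived$state_costs
  ut <- config$utilities
  cycles <- seq_len(T)
  dfc <- discount_factor(cycles, config$discount_rate)
  dfe <- discount_factor(cycles, config$effect_discount_rate)

  cost <- as.numeric(acc %*% sc)
  cost[1] <- cost[1] + entry_cost
  ly <- as.numeric(acc[, .alive_states(), drop = FALSE] %*%
                     rep(1, length(.alive_states())))
  qaly <- as.numeric(acc %*% ut)

  trace <- data.frame(cycle = cycles, check.names = FALSE)
  for (s in states) trace[[paste0("occ_", s)]] <- occ[, s]
  trace$cost <- cost
  trace$disc_cost <- cost * dfc
  trace$ly <- ly
  trace$disc_ly <- ly * dfe
  trace$qaly <- qaly
  trace$disc_qaly <- qaly * dfe
  trace$cum_disc_cost <- cumsum(trace$disc_cost)
  trace$cum_disc_ly <- cumsum(trace$disc_ly)
  trace$cum_disc_qaly <- cumsum(trace$disc_qaly)

  structure(trace,
            class = c("markov_trace", "data.frame"),
            arm = arm,
            half_cycle = half_cycle,
            totals = c(cost = sum(trace$disc_cost),
                       ly = sum(trace$disc_ly),
                       qaly = sum(trace$disc_qaly)))
}

#' @export
print.markov_trace <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("Markov cohort trace, arm '%s': %d annual cycles\n",
              attr(x, "arm"), nrow(x)))
  cat(sprintf("  total discounted: cost %.2f THB, %.4f LY, %.4f QALY\n",
              tot[["cost"]], tot[["ly"]], tot[["qaly"]]))
  cat(sprintf("  dead mass at horizon: %.4f\n", x$occ_dead[nrow(x)]))
  invisible(x)
}

#' Write a Markov trace to CSV
#'
#' One row per cycle with occupancy, per-cycle discounted accruals and
#' cumulative columns; byte-identical across re-runs on identical inputs.
#'
#' @param trace a [markov_trace][run_markov].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Fit the two-arm cost-utility model
#'
#' Runs the year-1 decision tree and the annual-cycle Markov chain for the
#' intervention and comparator arms, then computes incremental discounted
#' cost, life-years and QALYs, the ICER (per life-year) and ICUR (per
#' QALY), and the verdict against the configuration's willingness-to-pay
#' band.
#'
#' @param config a [cea_config][as_cea_config].
#' @param arms length-2 character vector: intervention arm first,
#'   comparator second.
#' @param half_cycle passed to [run_markov()].
#' @return a `cea_fit` object: list with `traces` (per-arm
#'   [markov_trace][run_markov]), `totals` (data.frame of per-arm
#'   discounted totals), `results` (list of [cea_result][icer] objects
#'   keyed `qaly` and `ly`), `verdict` (the QALY result judged against the
#'   WTP band), `arms` and `config`. Methods: `print`, `summary`, `coef`,
#'   `plot`.
#' @examples
#' fit <- cea(default_config())
#' coef(fit)
#' @export
cea <- function(config, arms = NULL, half_cycle = FALSE) {
  stopifnot(inherits(config, "cea_config"))
  if (is.null(arms)) arms <- names(config$arms)[1:2]
  if (length(arms) != 2 || !all(arms %in% names(config$arms))) {
    stop_validation("arms must name two strategy arms present in the config")
  }
  traces <- lapply(arms, function(a) run_markov(config, a, half_cycle = half_cycle))
  names(traces) <- arms
  tot <- t(vapply(traces, attr, numeric(3), "totals"))
  totals <- data.frame(arm = arms, cost = tot[, "cost"], ly = tot[, "ly"],
                       qaly = tot[, "qaly"], row.names = NULL)

  res_qaly <- icer(totals$cost[1], totals$cost[2],
                   totals$qaly[1], totals$qaly[2], effect_label = "QALY")
  res_ly <- icer(totals$cost[1], totals$cost[2],
                 totals$ly[1], totals$ly[2], effect_label = "LY")
  verdict <- verdict_against_wtp(res_qaly, config$wtp_band)

  structure(list(traces = traces, totals = totals,
                 results = list(qaly = res_qaly, ly = res_ly),
                 verdict = verdict, arms = arms, config = config,
                 half_cycle = half_cycle),
            class = "cea_fit")
}

#' @export
print.cea_fit <- function(x, ...) {
  cat(sprintf("Cost-utility analysis: %s vs %s (%d-year horizon)\n",
              x$arms[1], x$arms[2], x$config$horizon_years))
  tot <- x$totals
  for (i in 1:2) {
    cat(sprintf("  %-12s cost %14.2f THB   %7.4f LY   %7.4f QALY\n",
                tot$arm[i], tot$cost[i], tot$ly[i], tot$qaly[i]))
  }
  q <- x$results$qaly
  cat(sprintf("  incremental: %14.2f THB   %7.4f LY   %7.4f QALY\n",
              q$incremental_cost, x$results$ly$incremental_effect,
              q$incremental_effect))
  if (is.na(q$ratio)) {
    cat(sprintf("  ICUR: %s\n", q$dominance))
  } else {
    cat(sprintf("  ICUR: %.2f THB/QALY\n", q$ratio))
  }
  cat(sprintf("  verdict at WTP %s-%s: %s\n",
              format(x$config$wtp_band[1], big.mark = ",", scientific = FALSE),
              format(x$config$wtp_band[2], big.mark = ",", scientific = FALSE), x$verdict))
  invisible(x)
}

#' @export
summary.cea_fit <- function(object, ...) {
  print(object)
  cat("\nPer-arm year-1 state occupancy:\n")
  occ <- t(vapply(object$traces,
                  function(tr) unlist(tr[1, paste0("occ_", .states())]),
                  numeric(5)))
  colnames(occ) <- .states()
  print(round(occ, 4))
  invisible(object)
}

#' @export
coef.cea_fit <- function(object, ...) {
  q <- object$results$qaly
  l <- object$results$ly
  c(delta_cost = q$incremental_cost,
    delta_ly = l$incremental_effect,
    delta_qaly = q$incremental_effect,
    icer = l$ratio,
    icur = q$ratio)
}

#' @export
plot.cea_fit <- function(x, which = c("occupancy", "incremental"), ...) {
  which <- match.arg(which)
  states <- .states()
  if (which == "occupancy") {
    old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    for (a in x$arms) {
      tr <- x$traces[[a]]
      graphics::matplot(tr$cycle, as.matrix(tr[paste0("occ_", states)]),
                        type = "l", lty = 1, lwd = 2, col = seq_along(states),
                        xlab = "cycle (years)", ylab = "occupancy", main = a,
                        ylim = c(0, 1), ...)
      graphics::legend("right", legend = states, col = seq_along(states),
                       lty = 1, lwd = 2, bty = "n", cex = 0.8)
    }
  } else {
    d_cost <- x$traces[[1]]$cum_disc_cost - x$traces[[2]]$cum_disc_cost
    d_qaly <- x$traces[[1]]$cum_disc_qaly - x$traces[[2]]$cum_disc_qaly
    old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    graphics::plot(x$traces[[1]]$cycle, d_cost, type = "l", lwd = 2,
                   xlab = "horizon (years)",
                   ylab = "cumulative incremental cost (THB)", ...)
    graphics::abline(h = 0, lty = 3)
    graphics::plot(x$traces[[1]]$cycle, d_qaly, type = "l", lwd = 2,
                   xlab = "horizon (years)",
                   ylab = "cumulative incremental QALY", ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
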