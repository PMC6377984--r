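# Lifetime ICUR of a config, summarised for DSA bookkeeping: the numeric
# ratio plus its dominance label (NA ratio under dominance/equivalence).
.icur_of <- function(config) {
  fit <- cea(config)
  r <- fit$results$qaly
  list(ratio = r$ratio, dominance = r$dominance, verdict = fit$verdict)
}

#' One-way deterministic sensitivity analysis
#'
#' For each named parameter, reruns the full two-arm model twice — once
#' with the parameter at the low end of its range, once at the high end,
#' all other parameters held at baseline — and records the lifetime ICUR
#' at each end. The baseline model is evaluated once. Dominant outcomes
#' carry no ratio; for the swing `|ICUR_high - ICUR_low|` a dominant end
#' is counted as ratio 0 (a dominated end leaves the swing `NA`).
#'
#' @param config a [cea_config][as_cea_config].
#' @param parameters character vector of parameter paths (see
#'   [set_parameter()]); defaults to every entry of
#'   `config$parameter_ranges`.
#' @param ranges optional named list of `(low, high)` overrides; defaults
#'   to `config$parameter_ranges`.
#' @return a `cea_dsa` data.frame: `parameter`, `baseline`, `low`, `high`,
#'   `icur_low`, `icur_high`, `outcome_low`, `outcome_high`, `swing`;
#'   attributes `baseline_icur`, `baseline_outcome`, `wtp_band`.
#' @examples
#' dsa <- one_way_dsa(default_config())
#' head(tornado_order(dsa))
#' @export
one_way_dsa <- function(config, parameters = NULL, ranges = NULL) {
  stopifnot(inherits(config, "cea_config"))
  ranges <- ranges %||% config$parameter_ranges
  parameters <- parameters %||% names(ranges)
  if (!length(parameters)) stop_validation("no parameters to vary")
  missing_rng <- setdiff(parameters, names(ranges))
  if (length(missing_rng)) {
    stop_validation("no range available for parameter(s): ",
                    paste(missing_rng, collapse = ", "))
  }
  base <- .icur_of(config)

  rows <- lapply(parameters, function(p) {
    rng <- as.numeric(ranges[[p]])
    baseline <- get_parameter(config, p)
    ends <- lapply(rng, function(v) .icur_of(set_parameter(config, p, v)))
    swing_val <- function(e) {
      if (!is.na(e$dominance)) {
        if (e$dominance == "dominant") 0 else NA_real_
      } else {
        e$ratio
      }
    }
    s <- vapply(ends, swing_val, numeric(1))
    data.frame(parameter = p, baseline = baseline,
               low = rng[1], high = rng[2],
               icur_low = ends[[1]]$ratio, icur_high = ends[[2]]$ratio,
               outcome_low = ends[[1]]$dominance %||% NA_character_,
               outcome_high = ends[[2]]$dominance %||% NA_character_,
               swing = abs(s[2] - s[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("cea_dsa", "data.frame"),
            baseline_icur = base$ratio, baseline_outcome = base$dominance,
            wtp_band = config$wtp_band)
}

#' Order sensitivity rows for a tornado diagram
#'
#' Rows sorted by swing, largest first; ties (and `NA` swings, placed
#' last) broken by parameter name ascending, so the order is
#' deterministic.
#'
#' @param rows a [cea_dsa][one_way_dsa] data.frame.
#' @return the same rows, reordered.
#' @export
tornado_order <- function(rows) {
  key <- ifelse(is.na(rows$swing), -Inf, rows$swing)
  ord <- order(-key, rows$parameter)
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check sensitivity rows against a willingness-to-pay threshold
#'
#' A row passes when both of its ICURs stay at or below `wtp`; a dominant
#' end counts as below the threshold, a dominated end never does.
#'
#' @param rows a [cea_dsa][one_way_dsa] data.frame.
#' @param wtp threshold in THB/QALY.
#' @return logical vector, one entry per row.
#' @export
dsa_threshold_check <- function(rows, wtp) {
  end_ok <- function(ratio, outcome) {
    ifelse(!is.na(outcome),
           outcome == "dominant" | outcome == "equivalent",
           ratio <= wtp)
  }
  end_ok(rows$icur_low, rows$outcome_low) &
    end_ok(rows$icur_high, rows$outcome_high)
}

#' @export
print.cea_dsa <- function(x, ...) {
  base <- attr(x, "baseline_icur")
  cat("One-way deterministic sensitivity analysis\n")
  if (is.na(base)) {
    cat(sprintf("  baseline outcome: %s\n", attr(x, "baseline_outcome")))
  } else {
    cat(sprintf("  baseline ICUR: %.2f THB/QALY\n", base))
  }
  print(as.data.frame(x))
  invisible(x)
}

#' Tornado diagram of a sensitivity analysis
#'
#' Horizontal bars spanning each parameter's low/high ICURs (dominant ends
#' drawn at 0), ordered by swing. Rows whose swing is undefined are
#' dropped from the plot.
#'
#' @param x a [cea_dsa][one_way_dsa] data.frame.
#' @param wtp optional threshold(s) to draw as vertical reference lines;
#'   defaults to the config's WTP band.
#' @param ... passed to [graphics::plot()].
#' @return the plotted rows, invisibly.
#' @export
plot.cea_dsa <- function(x, wtp = attr(x, "wtp_band"), ...) {
  rows <- tornado_order(x)
  rows <- rows[!is.na(rows$swing), , drop = FALSE]
  rows <- rows[rev(seq_len(nrow(rows))), , drop = FALSE]
  lo <- ifelse(is.na(rows$icur_low), 0, rows$icur_low)
  hi <- ifelse(is.na(rows$icur_high), 0, rows$icur_high)
  base <- attr(x, "baseline_icur")
  if (is.na(base)) base <- 0
  xlim <- range(c(lo, hi, base, wtp), finite = TRUE)
  old <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(old))
  n <- nrow(rows)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICUR (THB/QALY)", ylab = "", ...)
  graphics::axis(2, at = seq_len(n), labels = rows$parameter, las = 1,
                 cex.axis = 0.8)
  graphics::segments(pmin(lo, hi), seq_len(n), pmax(lo, hi), seq_len(n),
                     lwd = 8, col = "steelblue", lend = 1)
  graphics::abline(v = base, lty = 2)
  if (!is.null(wtp)) graphics::abline(v = wtp, lty = 3, col = "firebrick")
  invisible(rows)
}

#' Time-horizon threshold analysis
#'
#' For every candidate horizon `h` from 1 to the configured horizon,
#' accumulates the discounted incremental cost and QALYs through cycle
#' `h` and forms their ratio. The threshold year is the smallest `h` at
#' which the intervention is cost-effective: cumulative incremental QALYs
#' strictly positive and either the cumulative ratio at or below `wtp`
#' or the intervention already cost-saving (cumulative incremental cost
#' <= 0). Absence of a crossing is a valid result (`NA`).
#'
#' @param config a [cea_config][as_cea_config].
#' @param wtp threshold in THB/QALY; defaults to the low end of the
#'   config's WTP band.
#' @param arms length-2 arms vector as in [cea()].
#' @return a `cea_threshold` data.frame: `horizon_year`,
#'   `cum_delta_cost`, `cum_delta_qaly`, `icur`, `below_wtp`; attributes
#'   `threshold_year` (integer or `NA`) and `wtp`.
#' @examples
#' th <- threshold_year(default_config())
#' attr(th, "threshold_year")
#' @export
threshold_year <- function(config, wtp = config$wtp_band[1], arms = NULL) {
  stopifnot(inherits(config, "cea_config"))
  if (is.null(arms)) arms <- names(config$arms)[1:2]
  tr_new <- run_markov(config, arms[1])
  tr_ref <- run_markov(config, arms[2])
  d_cost <- tr_new$cum_disc_cost - tr_ref$cum_disc_cost
  d_qaly <- tr_new$cum_disc_qaly - tr_ref$cum_disc_qaly
  icur <- ifelse(d_qaly > 0, d_cost / d_qaly, NA_real_)
  below <- d_qaly > 0 & (d_cost <= 0 | icur <= wtp)
  out <- data.frame(horizon_year = tr_new$cycle,
                    cum_delta_cost = d_cost,
                    cum_delta_qaly = d_qaly,
                    icur = icur,
                    below_wtp = below)
  yr <- if (any(below)) min(out$horizon_year[below]) else NA_integer_
  structure(out, class = c("cea_threshold", "data.frame"),
            threshold_year = yr, wtp = wtp, arms = arms)
}

#' @export
print.cea_threshold <- function(x, ...) {
  yr <- attr(x, "threshold_year")
  cat(sprintf("Time-horizon threshold analysis (%s vs %s, WTP %s THB/QALY)\n",
              attr(x, "arms")[1], attr(x, "arms")[2],
              format(attr(x, "wtp"), big.mark = ",", scientific = FALSE)))
  if (is.na(yr)) {
    cat("  no horizon at which the intervention is cost-effective\n")
  } else {
    cat(sprintf("  cost-effective from year %d onward\n", yr))
  }
  invisible(x)
}

#' @export
plot.cea_threshold <- function(x, ...) {
  yr <- attr(x, "threshold_year")
  graphics::plot(x$horizon_year, x$icur, type = "l", lwd = 2,
                 xlab = "horizon (years)", ylab = "cumulative ICUR (THB/QALY)",
                 ...)
  graphics::abline(h = attr(x, "wtp"), lty = 3, col = "firebrick")
  if (!is.na(yr)) graphics::abline(v = yr, lty = 2)
  invisible(x)
}

#' Write sensitivity outputs to CSV
#'
#' Deterministic CSV writers for [one_way_dsa()] rows (with a
#' `below_threshold` column judged against `wtp`) and
#' [threshold_year()] curves.
#'
#' @param rows a [cea_dsa][one_way_dsa] data.frame.
#' @param curve a [cea_threshold][threshold_year] data.frame.
#' @param wtp threshold in THB/QALY for the `below_threshold` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dsa <- function(rows, path, wtp = attr(rows, "wtp_band")[2]) {
  out <- as.data.frame(rows)
  out$below_threshold <- dsa_threshold_check(rows, wtp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dsa
#' @export
write_threshold <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
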