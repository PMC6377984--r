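#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes the incremental cost `dC = cost_new - cost_ref` and incremental
#' effect `dE = effect_new - effect_ref`, classifies dominance, and forms
#' the ratio `dC / dE` when the two increments share a sign. Every sign
#' combination maps to a defined outcome:
#'
#' * *dominant* — cheaper and at least as effective (`dC <= 0, dE > 0` or
#'   `dC < 0, dE >= 0`): no ratio is reported (a signed ratio is
#'   uninterpretable).
#' * *dominated* — the mirror case: costlier and no more effective.
#' * both increments zero — the strategies are *equivalent*; no ratio.
#' * same-signed increments — the ratio is reported (north-east quadrant:
#'   cost per unit gained; south-west: saving per unit forgone).
#'
#' @param cost_new,cost_ref total costs (THB) of the new strategy and the
#'   comparator.
#' @param effect_new,effect_ref effects in `effect_label` units.
#' @param effect_label unit of the effect (e.g. `"QALY"`, `"LY"`,
#'   `"HbA1C"`, `"BMI"`).
#' @return a `cea_result`: list with `incremental_cost`,
#'   `incremental_effect`, `effect_label`, `ratio` (THB per effect unit;
#'   `NA` under dominance/equivalence) and `dominance`
#'   (`"dominant"`, `"dominated"`, `"equivalent"` or `NA`).
#' @examples
#' icer(436928.72, 360810.89, 13.57, 10.75, effect_label = "QALY")
#' @export
icer <- function(cost_new, cost_ref, effect_new, effect_ref,
                 effect_label = "QALY") {
  dc <- cost_new - cost_ref
  de <- effect_new - effect_ref
  dominance <- NA_character_
  ratio <- NA_real_
  if ((dc <= 0 && de > 0) || (dc < 0 && de >= 0)) {
    dominance <- "dominant"
  } else if ((dc >= 0 && de < 0) || (dc > 0 && de <= 0)) {
    dominance <- "dominated"
  } else if (dc == 0 && de == 0) {
    dominance <- "equivalent"
  } else {
    ratio <- dc / de
  }
  structure(list(incremental_cost = dc, incremental_effect = de,
                 effect_label = effect_label, ratio = ratio,
                 dominance = dominance),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Incremental comparison (%s):\n", x$effect_label))
  cat(sprintf("  incremental cost:   %.2f THB\n", x$incremental_cost))
  cat(sprintf("  incremental effect: %.4f %s\n", x$incremental_effect,
              x$effect_label))
  if (!is.na(x$dominance)) {
    cat(sprintf("  outcome: %s\n", x$dominance))
  } else {
    cat(sprintf("  ratio: %.2f THB per %s\n", x$ratio, x$effect_label))
  }
  invisible(x)
}

#' Judge a QALY-denominated result against a willingness-to-pay band
#'
#' The band `(low, high)` is in THB/QALY. A ratio at or below `low` is
#' cost-effective at the conservative threshold; above `low` but at or
#' below `high` is cost-effective only at the upper threshold; above
#' `high` is not cost-effective. Boundaries count as cost-effective (the
#' `<=` convention). Dominance labels pass through unchanged: a dominant
#' strategy is cost-effective at any willingness-to-pay, a dominated one
#' at none.
#'
#' @param result a [cea_result][icer] with `effect_label = "QALY"`, or a
#'   bare numeric ratio in THB/QALY.
#' @param wtp_band numeric `(low, high)` in THB/QALY.
#' @return a verdict string: `"cost-effective at low WTP"`,
#'   `"cost-effective at high WTP only"`, `"not cost-effective"`,
#'   `"dominant"`, `"dominated"` or `"equivalent"`.
#' @examples
#' verdict_against_wtp(26907.76, c(150000, 200000))
#' @export
verdict_against_wtp <- function(result, wtp_band) {
  wtp <- as.numeric(wtp_band)
  if (length(wtp) != 2 || wtp[1] > wtp[2]) {
    stop_validation("wtp_band must be (low, high) with low <= high")
  }
  if (is.numeric(result)) {
    result <- structure(list(ratio = result, dominance = NA_character_,
                             effect_label = "QALY"), class = "cea_result")
  }
  stopifnot(inherits(result, "cea_result"))
  if (!identical(result$effect_label, "QALY")) {
    stop_validation("WTP verdicts require a QALY-denominated result, got '",
                    result$effect_label, "'")
  }
  if (!is.na(result$dominance)) return(result$dominance)
  r <- result$ratio
  if (r <= wtp[1]) {
    "cost-effective at low WTP"
  } else if (r <= wtp[2]) {
    "cost-effective at high WTP only"
  } else {
    "not cost-effective"
  }
}

#' One-year clinical cost-effectiveness ratios
#'
#' Cost per unit of one-year clinical benefit (HbA1C percentage points and
#' BMI kg/m² reduced), computed as the year-1 incremental cost divided by
#' each incremental clinical effect.
#'
#' @param effects named numeric of positive incremental clinical effects
#'   (reductions), e.g. `c(hba1c = 1.78, bmi = 14.05)`; or a
#'   [summarize_clinical()] data.frame, whose `mean_diff` (baseline minus
#'   year 1) supplies the reductions.
#' @param incremental_cost year-1 incremental cost in THB.
#' @return a data.frame with one row per endpoint: `endpoint`,
#'   `incremental_cost`, `incremental_effect`, `icer`.
#' @examples
#' one_year_clinical_icers(c(hba1c = 1.78, bmi = 14.05), 133947.9)
#' @export
one_year_clinical_icers <- function(effects, incremental_cost) {
  if (is.data.frame(effects)) {
    eff <- stats::setNames(effects$mean_diff, effects$parameter)
  } else {
    eff <- effects
  }
  if (is.null(names(eff)) || any(!nzchar(names(eff)))) {
    stop_validation("clinical effects must be named")
  }
  rows <- lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    if (e > 0 && incremental_cost >= 0) {
      # a zero incremental cost over a real clinical gain is a ratio of 0,
      # not a dominance label: the cost per unit gained is genuinely zero
      ratio <- incremental_cost / e
      dominance <- NA_character_
    } else {
      r <- icer(incremental_cost, 0, e, 0, effect_label = nm)
      ratio <- r$ratio
      dominance <- r$dominance
    }
    data.frame(endpoint = nm, incremental_cost = incremental_cost,
               incremental_effect = e, icer = ratio, dominance = dominance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cost-effectiveness results from externally supplied arm totals
#'
#' Builds the incremental comparison (cost, LY, QALY, ratios, WTP verdict)
#' directly from per-arm discounted totals instead of a model run — a
#' reporting mode for totals taken from an external analysis.
#'
#' @param totals a data.frame with columns `arm`, `cost`, `ly`, `qaly`;
#'   first row is the intervention, second the comparator.
#' @param wtp_band numeric `(low, high)` THB/QALY.
#' @return a list with `totals`, `results` (`qaly` and `ly`
#'   [cea_result][icer]s) and `verdict`.
#' @examples
#' tot <- data.frame(arm = c("surgery", "no_surgery"),
#'                   cost = c(436928.72, 360810.89),
#'                   ly = c(17.45, 14.15), qaly = c(13.57, 10.75))
#' cea_from_totals(tot, c(150000, 200000))$results$qaly
#' @export
cea_from_totals <- function(totals, wtp_band) {
  need <- c("arm", "cost", "ly", "qaly")
  if (!is.data.frame(totals) || !all(need %in% names(totals)) ||
      nrow(totals) != 2) {
    stop_validation("totals must be a 2-row data.frame with columns ",
                    paste(need, collapse = ", "))
  }
  res_qaly <- icer(totals$cost[1], totals$cost[2], totals$qaly[1],
                   totals$qaly[2], effect_label = "QALY")
  res_ly <- icer(totals$cost[1], totals$cost[2], totals$ly[1],
                 totals$ly[2], effect_label = "LY")
  list(totals = totals, results = list(qaly = res_qaly, ly = res_ly),
       verdict = verdict_against_wtp(res_qaly, wtp_band))
}
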