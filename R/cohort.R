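#' Classify a patient's one-year diabetes outcome
#'
#' Maps a patient's year-1 glycated haemoglobin (HbA1C), antidiabetic
#' medication list and vital status to one of the five diabetes outcome
#' states:
#'
#' * dead — `deceased` is `TRUE` (checked first);
#' * remission — HbA1C < 6.5% with no antidiabetic agent;
#' * improved — HbA1C < 6.5% on metformin monotherapy;
#' * persistent — on exactly two antidiabetic drug classes;
#' * uncontrolled — on more than two drug classes.
#'
#' The four clinical definitions do not cover every combination. The
#' fallback rule assigns *persistent* to the remainder (HbA1C >= 6.5% on
#' at most one agent, or HbA1C < 6.5% on a single non-metformin agent) —
#' a conservative, more-diseased assignment. Every fallback classification
#' is logged via a condition of class `baricea_fallback` so callers can
#' audit them. Two-class regimens are persistent whether or not metformin
#' is one of the two; HbA1C plays no role once two or more classes are
#' used.
#'
#' @param hba1c year-1 HbA1C in percent (> 0 unless deceased).
#' @param medications character vector of antidiabetic drug-class labels
#'   from the closed vocabulary `metformin`, `sulfonylurea`,
#'   `thiazolidinedione`, `alpha-glucosidase-inhibitor`, `insulin`,
#'   `other`. Duplicated labels count once.
#' @param deceased `TRUE` if the patient died before the 1-year visit.
#' @return one of `"remission"`, `"improved"`, `"persistent"`,
#'   `"uncontrolled"`, `"dead"`.
#' @examples
#' classify_status(6.0, character(0), FALSE)              # remission
#' classify_status(7.2, c("metformin", "insulin", "sulfonylurea"), FALSE)
#' @export
classify_status <- function(hba1c, medications = character(0),
                            deceased = FALSE) {
  if (isTRUE(deceased)) return("dead")
  meds <- unique(as.character(medications))
  meds <- meds[nzchar(meds)]
  unknown <- setdiff(meds, .drug_classes())
  if (length(unknown)) {
    stop_validation("unknown drug-class label(s): ",
                    paste(unknown, collapse = ", "),
                    " (vocabulary: ", paste(.drug_classes(), collapse = ", "), ")")
  }
  if (!is.finite(hba1c) || hba1c <= 0) {
    stop_validation("HbA1C must be a positive percentage for living patients")
  }
  k <- length(meds)
  if (hba1c < 6.5 && k == 0) return("remission")
  if (hba1c < 6.5 && k == 1 && meds == "metformin") return("improved")
  if (k > 2) return("uncontrolled")
  if (k == 2) return("persistent")
  # remainder: elevated HbA1C on <= 1 agent, or controlled on one
  # non-metformin agent -> conservative fallback
  message(structure(class = c("baricea_fallback", "message", "condition"),
                    list(message = sprintf(
                      "fallback classification: HbA1C %.2f with %d agent(s) -> persistent\n",
                      hba1c, k),
                      call = NULL)))
  "persistent"
}

# Vectorized classification over a cohort data.frame; one summary message
# for all fallback rows instead of one message each.
classify_cohort <- function(cohort) {
  n <- nrow(cohort)
  out <- character(n)
  fallback_ids <- character(0)
  for (i in seq_len(n)) {
    out[i] <- withCallingHandlers(
      classify_status(cohort$year1_hba1c[i], cohort$year1_medications[[i]],
                      cohort$deceased_by_year1[i]),
      baricea_fallback = function(m) {
        fallback_ids <<- c(fallback_ids, as.character(cohort$id[i]))
        invokeRestart("muffleMessage")
      })
  }
  if (length(fallback_ids)) {
    message(structure(class = c("baricea_fallback", "message", "condition"),
                      list(message = sprintf(
                        "fallback classification (-> persistent) for %d record(s): %s\n",
                        length(fallback_ids),
                        paste(fallback_ids, collapse = ", ")),
                        call = NULL)))
  }
  out
}

#' Estimate year-1 outcome probabilities from a cohort
#'
#' Classifies every record with [classify_status()] and returns the state
#' counts and the maximum-likelihood probability vector `counts / n`.
#'
#' @param cohort a cohort data.frame as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @return an `outcome_estimate`: list with `counts` (named integers),
#'   `probabilities` (named, sums to 1), `states` (per-record
#'   classifications) and `n`.
#' @examples
#' co <- exact_count_cohort(73, c(remission = 61, improved = 3,
#'                                persistent = 0, uncontrolled = 9, dead = 0))
#' round(estimate_outcome_probabilities(co)$probabilities, 4)
#' @export
estimate_outcome_probabilities <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop_validation("cohort must be a non-empty data.frame")
  }
  states <- classify_cohort(cohort)
  counts <- vapply(.states(), function(s) sum(states == s), integer(1))
  structure(list(counts = counts, probabilities = counts / nrow(cohort),
                 states = states, n = nrow(cohort)),
            class = "outcome_estimate")
}

#' @export
print.outcome_estimate <- function(x, ...) {
  cat(sprintf("Year-1 outcome estimate (n = %d):\n", x$n))
  df <- data.frame(state = .states(), count = x$counts,
                   probability = round(x$probabilities, 4),
                   percent = round(100 * x$probabilities, 1),
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' Paired clinical effectiveness summary (BMI and HbA1C)
#'
#' Baseline and year-1 means and sample standard deviations (n-1
#' denominator), the mean reduction (baseline minus year 1) and the
#' two-sided paired t-test p-value, for BMI and HbA1C. Records missing
#' either timepoint (e.g. patients deceased by year 1) are dropped
#' per endpoint. When the paired differences have zero variance the
#' t statistic is undefined and the p-value is `NA` (with a mean
#' difference of 0 this means "no evidence of any change", not
#' significance).
#'
#' @param cohort a cohort data.frame (see [read_cohort()]).
#' @return a data.frame with one row per endpoint: `parameter`, `n`,
#'   `baseline_mean`, `baseline_sd`, `year1_mean`, `year1_sd`,
#'   `mean_diff`, `p_value`.
#' @export
summarize_clinical <- function(cohort) {
  endpoints <- list(bmi = c("baseline_bmi", "year1_bmi"),
                    hba1c = c("baseline_hba1c", "year1_hba1c"))
  rows <- lapply(names(endpoints), function(nm) {
    cols <- endpoints[[nm]]
    x0 <- cohort[[cols[1]]]
    x1 <- cohort[[cols[2]]]
    keep <- is.finite(x0) & is.finite(x1)
    x0 <- x0[keep]
    x1 <- x1[keep]
    if (length(x0) < 2) {
      stop_validation("need at least 2 records with both timepoints for ", nm)
    }
    d <- x0 - x1
    p <- if (stats::sd(d) == 0) NA_real_ else {
      stats::t.test(x0, x1, paired = TRUE)$p.value
    }
    data.frame(parameter = nm, n = length(x0),
               baseline_mean = mean(x0), baseline_sd = stats::sd(x0),
               year1_mean = mean(x1), year1_sd = stats::sd(x1),
               mean_diff = mean(d), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and write the cohort CSV dialect
#'
#' One header row, columns `id`, `sex` (`female`/`male`), `age`,
#' `baseline_bmi`, `year1_bmi`, `baseline_hba1c`, `year1_hba1c`,
#' `year1_medications` (semicolon-separated drug-class labels, empty for
#' none) and `deceased_by_year1` (`true`/`false`). In R the medication
#' column is a list-column of character vectors.
#'
#' @param path CSV path.
#' @param cohort a cohort data.frame.
#' @return `read_cohort()` the cohort data.frame; `write_cohort()` `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_validation("cohort file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop_validation("cannot parse cohort CSV '", path, "': ",
                                   conditionMessage(e))
                 })
  need <- c("id", "sex", "age", "baseline_bmi", "year1_bmi",
            "baseline_hba1c", "year1_hba1c", "year1_medications",
            "deceased_by_year1")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_validation("cohort CSV is missing column(s): ",
                    paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop_validation("cohort CSV '", path, "' has no records")
  meds <- strsplit(ifelse(is.na(df$year1_medications), "",
                          df$year1_medications), ";", fixed = TRUE)
  meds <- lapply(meds, function(m) m[nzchar(m)])
  for (i in seq_along(meds)) {
    unknown <- setdiff(meds[[i]], .drug_classes())
    if (length(unknown)) {
      stop_validation("row ", i, " (id ", df$id[i],
                      "): unknown drug-class label(s): ",
                      paste(unknown, collapse = ", "))
    }
  }
  df$year1_medications <- meds
  df$deceased_by_year1 <- as.logical(df$deceased_by_year1)
  alive <- !df$deceased_by_year1
  for (col in c("baseline_bmi", "baseline_hba1c")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop_validation("row ", bad[1], " (id ", df$id[bad[1]], "): ", col,
                      " must be strictly positive")
    }
  }
  for (col in c("year1_bmi", "year1_hba1c")) {
    bad <- which(alive & (!is.finite(df[[col]]) | df[[col]] <= 0))
    if (length(bad)) {
      stop_validation("row ", bad[1], " (id ", df$id[bad[1]], "): ", col,
                      " must be strictly positive for living patients")
    }
  }
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$year1_medications <- vapply(cohort$year1_medications,
                                  paste, character(1), collapse = ";")
  out$deceased_by_year1 <- ifelse(cohort$deceased_by_year1, "true", "false")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
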