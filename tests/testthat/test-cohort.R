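test_that("classification implements the five clinical definitions", {
  expect_equal(classify_status(6.0, character(0), FALSE), "remission")
  expect_equal(classify_status(6.0, "metformin", FALSE), "improved")
  expect_equal(classify_status(8.0, c("metformin", "insulin"), FALSE),
               "persistent")
  expect_equal(classify_status(7.2, c("metformin", "insulin", "sulfonylurea"),
                               FALSE), "uncontrolled")
  expect_equal(classify_status(5.0, "metformin", TRUE), "dead")
  # deceased wins regardless of other fields
  expect_equal(classify_status(NA, character(0), TRUE), "dead")
  # duplicated labels count once
  expect_equal(classify_status(7.0, c("metformin", "metformin", "insulin"),
                               FALSE), "persistent")
})

test_that("remission boundary at 6.5% is strict and fallbacks are logged", {
  # 6.5 exactly, no drugs: not remission; conservative fallback to persistent
  expect_message(s <- classify_status(6.5, character(0), FALSE),
                 class = "baricea_fallback")
  expect_equal(s, "persistent")
  # elevated HbA1C on metformin monotherapy is also a fallback
  expect_message(s2 <- classify_status(8.1, "metformin", FALSE),
                 class = "baricea_fallback")
  expect_equal(s2, "persistent")
  # controlled on one non-metformin agent: fallback
  expect_message(s3 <- classify_status(6.0, "insulin", FALSE),
                 class = "baricea_fallback")
  expect_equal(s3, "persistent")
  # two classes without metformin still persistent (no message: covered rule)
  expect_equal(classify_status(7.0, c("insulin", "sulfonylurea"), FALSE),
               "persistent")
})

test_that("classification rejects bad inputs by name", {
  expect_error(classify_status(7.0, "aspirin", FALSE), "aspirin",
               class = "baricea_validation_error")
  expect_error(classify_status(-1, character(0), FALSE), "HbA1C",
               class = "baricea_validation_error")
})

test_that("outcome probabilities equal a brute-force tally for random cohorts", {
  set.seed(202)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    cohort <- generate_cohort(cohort_spec(n = n, seed = sample.int(1e6, 1)))
    est <- estimate_outcome_probabilities(cohort)

    # independent oracle: tally classifications record by record
    tally <- c(remission = 0, improved = 0, persistent = 0,
               uncontrolled = 0, dead = 0)
    for (i in seq_len(n)) {
      s <- classify_status(cohort$year1_hba1c[i],
                           cohort$year1_medications[[i]],
                           cohort$deceased_by_year1[i])
      tally[s] <- tally[s] + 1
    }
    expect_equal(unname(est$counts), unname(tally))
    expect_equal(est$probabilities, est$counts / n)
    expect_equal(sum(est$probabilities), 1)
    # probabilities times N are exact integer counts
    expect_equal(est$probabilities * n, as.numeric(est$counts),
                 ignore_attr = TRUE)
  }
  expect_error(estimate_outcome_probabilities(hand_cohort(
    numeric(0), numeric(0), numeric(0), numeric(0))),
    class = "baricea_validation_error")
})

test_that("degenerate single-state cohorts give a unit probability vector", {
  co <- exact_count_cohort(5, c(remission = 5, improved = 0, persistent = 0,
                                uncontrolled = 0, dead = 0))
  est <- estimate_outcome_probabilities(co)
  expect_equal(unname(est$probabilities), c(1, 0, 0, 0, 0))
})

test_that("clinical summary matches a hand-computed paired t statistic", {
  # five pairs with differences 1, 2, 0, 1, 1:
  # mean d = 1, sd d = sqrt(0.5), t = 1 / (sqrt(0.5)/sqrt(5)) = sqrt(10),
  # df = 4, two-sided p = 0.0341094 (frozen from the closed form)
  co <- hand_cohort(
    baseline_bmi = c(41, 42, 40, 43, 44),
    year1_bmi = c(40, 40, 40, 42, 43),
    baseline_hba1c = c(7, 8, 7.5, 9, 6.5),
    year1_hba1c = c(6, 6, 7.5, 8, 6.4))
  out <- summarize_clinical(co)
  bmi <- out[out$parameter == "bmi", ]
  expect_equal(bmi$mean_diff, 1)
  expect_equal(bmi$baseline_mean, 42)
  expect_equal(bmi$baseline_sd, sd(c(41, 42, 40, 43, 44)))
  expect_equal(bmi$p_value, 0.0341094232, tolerance = 1e-6)
})

test_that("zero change gives mean difference 0 and an undefined p-value", {
  co <- hand_cohort(baseline_bmi = c(40, 45, 50), year1_bmi = c(40, 45, 50),
                    baseline_hba1c = c(7, 8, 9), year1_hba1c = c(7, 8, 9))
  out <- summarize_clinical(co)
  expect_equal(out$mean_diff, c(0, 0))
  expect_true(all(is.na(out$p_value)))
  expect_error(summarize_clinical(co[1, ]), "at least 2",
               class = "baricea_validation_error")
})

test_that("synthetic 73-patient cohorts recover the target clinical effect", {
  co <- generate_cohort(cohort_spec(n = 73, seed = 7))
  out <- summarize_clinical(co)
  bmi <- out[out$parameter == "bmi", ]
  hba <- out[out$parameter == "hba1c", ]
  # baseline means within 2 SE of the generator targets (truncation shifts
  # the BMI mean up slightly; 2 SE comfortably covers it at n = 73)
  expect_lt(abs(bmi$baseline_mean - 50.1), 2 * 10.3 / sqrt(bmi$n) + 1.1)
  expect_lt(abs(hba$baseline_mean - 7.6), 2 * 1.9 / sqrt(hba$n) + 0.2)
  # the surgery effect is large and unambiguous
  expect_gt(bmi$mean_diff, 5)
  expect_gt(hba$mean_diff, 0.5)
  expect_lt(bmi$p_value, 0.001)
  expect_lt(hba$p_value, 0.001)
})

test_that("cohort CSVs round-trip and reject unknown drug labels by row", {
  co <- generate_cohort(cohort_spec(n = 15, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$id, co$id)
  expect_equal(co2$year1_bmi, co$year1_bmi)
  expect_equal(unclass(co2$year1_medications),
               unclass(co$year1_medications), ignore_attr = TRUE)
  expect_equal(co2$deceased_by_year1, co$deceased_by_year1)

  bad <- co
  bad$year1_medications[[3]] <- c("metformin", "statin")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(bad, path2)
  expect_error(read_cohort(path2), "row 3.*statin",
               class = "baricea_validation_error")
})
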