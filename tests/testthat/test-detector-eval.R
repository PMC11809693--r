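# Analysis seconds reproducing a given contingency layout.
seconds_from_counts <- function(tp, fp, fn, tn, device_id = "phone1",
                                session_id = "s1") {
  n <- tp + fp + fn + tn
  data.frame(
    session_id = session_id,
    second_index = seq_len(n),
    gold_class = rep(c("TRUE_COUGH", "TRUE_COUGH", "NON_COUGH", "NON_COUGH"),
                     c(tp, fn, fp, tn)),
    device_id = device_id,
    detected = rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fn, fp, tn)),
    max_score = NA_real_,
    stringsAsFactors = FALSE
  )
}

test_that("contingency counts split cough and non-cough seconds", {
  sec <- seconds_from_counts(tp = 615, fp = 7, fn = 57, tn = 1000)
  ct <- contingency(sec, "phone1")
  expect_equal(ct$tp + ct$fn, 672L)
  expect_equal(ct$fp + ct$tn, 1007L)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]),
               c(tp = 615L, fp = 7L, fn = 57L, tn = 1000L))

  none <- sec
  none$detected <- FALSE
  ct0 <- contingency(none)
  expect_equal(ct0$tp, 0L)
  expect_equal(ct0$fp, 0L)

  perfect <- sec
  perfect$detected <- perfect$gold_class == "TRUE_COUGH"
  ctp <- contingency(perfect)
  expect_equal(ctp$fn, 0L)
  expect_equal(ctp$fp, 0L)
})

test_that("disputed seconds never enter the contingency table", {
  sec <- seconds_from_counts(tp = 5, fp = 1, fn = 2, tn = 10)
  disp <- sec[1:3, ]
  disp$second_index <- disp$second_index + 1000
  disp$gold_class <- c("DISPUTED", "COUGH_LIKE_NONCONSENSUS", "DISPUTED")
  ct <- contingency(rbind(sec, disp))
  expect_equal(ct$tp + ct$fn + ct$fp + ct$tn, 18L)
})

test_that("sensitivity and specificity follow their defining ratios", {
  expect_equal(sensitivity(new_contingency(615, 0, 57, 0)), 615 / 672)
  expect_equal(round(100 * sensitivity(new_contingency(615, 0, 57, 0)), 1),
               91.5)
  expect_equal(sensitivity(new_contingency(622, 0, 50, 0)), 622 / 672)
  expect_equal(sensitivity(new_contingency(0, 0, 10, 0)), 0)
  expect_equal(specificity(new_contingency(0, 7, 0, 1000)), 1 - 7 / 1007)
  expect_equal(round(100 * specificity(new_contingency(0, 7, 0, 1000)), 1),
               99.3)
  expect_equal(specificity(new_contingency(0, 13, 0, 994)), 1 - 13 / 1007)
  expect_equal(specificity(new_contingency(0, 0, 0, 50)), 1)
  expect_error(sensitivity(new_contingency(0, 1, 0, 1)), "undefined")
  expect_error(specificity(new_contingency(1, 0, 1, 0)), "undefined")
})

test_that("pooled contingency equals the sum of per-session tables", {
  set.seed(301)
  secs <- do.call(rbind, lapply(1:5, function(i) {
    seconds_from_counts(tp = sample(5:20, 1), fp = sample(0:3, 1),
                        fn = sample(0:5, 1), tn = sample(10:40, 1),
                        session_id = paste0("s", i))
  }))
  pooled <- contingency(secs, "phone1")
  per <- lapply(split(secs, secs$session_id), contingency)
  summed <- pool_contingency(per)
  expect_equal(unclass(pooled)[c("tp", "fp", "fn", "tn")],
               unclass(summed)[c("tp", "fp", "fn", "tn")])
  # metric invariance under row shuffling
  shuffled <- secs[sample(nrow(secs)), ]
  expect_equal(sensitivity(contingency(shuffled)), sensitivity(pooled))
  expect_equal(specificity(contingency(shuffled)), specificity(pooled))
})

test_that("exact binomial interval hits its boundary cases", {
  ci0 <- exact_binomial_ci(0, 20)
  expect_equal(ci0$lower, 0)
  expect_equal(ci0$estimate, 0)
  cin <- exact_binomial_ci(20, 20)
  expect_equal(cin$upper, 1)
  ci <- exact_binomial_ci(8, 10)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  expect_equal(ci$method, "clopper_pearson")
  expect_error(exact_binomial_ci(11, 10), "successes")
})

test_that("exact interval agrees with the tail-inversion oracle", {
  oracle <- oracle_exact_ci(8, 10)
  ci <- exact_binomial_ci(8, 10)
  expect_equal(ci$lower, unname(oracle["lower"]), tolerance = 1e-9)
  expect_equal(ci$upper, unname(oracle["upper"]), tolerance = 1e-9)
  # and with the stock implementation on a second case
  bt <- binom.test(615, 672)$conf.int
  ci2 <- exact_binomial_ci(615, 672)
  expect_equal(ci2$lower, bt[1], tolerance = 1e-9)
  expect_equal(ci2$upper, bt[2], tolerance = 1e-9)
})

test_that("per-session metrics summarize with interpolated quartiles", {
  secs <- rbind(
    seconds_from_counts(tp = 5, fp = 0, fn = 5, tn = 20, session_id = "s1"),
    seconds_from_counts(tp = 9, fp = 1, fn = 1, tn = 19, session_id = "s2"),
    seconds_from_counts(tp = 10, fp = 0, fn = 0, tn = 20, session_id = "s3")
  )
  psm <- per_session_metrics(secs)
  expect_equal(psm$per_session$sensitivity, c(0.5, 0.9, 1.0))
  s <- psm$summary
  sens <- s[s$metric == "sensitivity", ]
  expect_equal(sens$median, 0.9)
  expect_equal(sens$minimum, 0.5)
  expect_equal(sens$maximum, 1.0)
  expect_equal(sens$q1, unname(quantile(c(0.5, 0.9, 1), 0.25)))
  # all-perfect case collapses the summary to 1
  perfect <- secs
  perfect$detected <- perfect$gold_class == "TRUE_COUGH"
  ps <- per_session_metrics(perfect)$summary
  expect_true(all(ps[ps$metric == "sensitivity",
                     c("minimum", "q1", "median", "q3", "maximum")] == 1))
})

test_that("sessions without gold coughs are skipped with a warning", {
  no_cough <- seconds_from_counts(tp = 0, fp = 1, fn = 0, tn = 10,
                                  session_id = "s_badqc")
  with_cough <- seconds_from_counts(tp = 8, fp = 0, fn = 2, tn = 10,
                                    session_id = "s_ok")
  expect_warning(psm <- per_session_metrics(rbind(no_cough, with_cough)),
                 "no gold cough-seconds")
  expect_true(is.na(
    psm$per_session$sensitivity[psm$per_session$session_id == "s_badqc"]))
})

test_that("simulated cohorts center per-session sensitivity near truth", {
  p <- clean_params(31, n_sessions = 8,
                    detector = detector_params(time_jitter_sd = 0,
                                               spurious_rate = 0))
  co <- simulate_cohort(p)
  ev <- analyze_sessions(co$sessions, run_config(seed = 31))
  med <- ev$summary$median[ev$summary$metric == "sensitivity"]
  expect_gte(med, 0.85)
  expect_lte(med, 1.0)
})
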