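gold_df <- function(secs) {
  data.frame(second_index = as.integer(secs),
             gold_class = rep("TRUE_COUGH", length(secs)),
             stringsAsFactors = FALSE)
}

det_df <- function(secs) {
  data.frame(second_index = as.integer(secs),
             max_score = rep(0.95, length(secs)),
             detected = rep(TRUE, length(secs)))
}

test_that("a ten-minute session yields ten one-minute segments", {
  sc <- segment_counts(gold_df(integer(0)), det_df(integer(0)), 600)
  expect_equal(nrow(sc), 10L)
  expect_true(all(sc$gold_count == 0))
  expect_true(all(sc$device_count == 0))
})

test_that("counts bin by minute and keep only long-enough tails", {
  sc <- segment_counts(gold_df(c(5, 65, 66)), det_df(integer(0)), 600)
  expect_equal(sc$gold_count, c(1, 2, 0, 0, 0, 0, 0, 0, 0, 0))
  # 629 s: the 29 s tail is dropped; 635 s: the 35 s tail is kept
  expect_equal(nrow(segment_counts(gold_df(5), det_df(5), 629)), 10L)
  expect_equal(nrow(segment_counts(gold_df(5), det_df(5), 635)), 11L)
})

test_that("segment tallies match a brute-force per-minute count", {
  set.seed(501)
  p <- clean_params(11, n_sessions = 1)
  co <- simulate_cohort(p)
  s <- co$sessions[[1]]
  det <- apply_offset(s$detections[[1]], s$ground_truth$offsets[1])
  built <- build_analysis_seconds(s$labels, list(phone1 = det))
  sc <- segment_counts(built$gold, built$device_seconds$phone1, s$duration)
  gold_secs <- built$gold$second_index[built$gold$gold_class == "TRUE_COUGH"]
  det_secs <- built$device_seconds$phone1$second_index[
    built$device_seconds$phone1$detected]
  for (k in sc$segment_index) {
    expect_equal(sc$gold_count[sc$segment_index == k],
                 sum(gold_secs >= 60 * k & gold_secs < 60 * (k + 1)))
    expect_equal(sc$device_count[sc$segment_index == k],
                 sum(det_secs >= 60 * k & det_secs < 60 * (k + 1)))
  }
  # conservation: segment sums equal the session totals
  expect_equal(sum(sc$gold_count), length(gold_secs))
})

test_that("identity rate series gives the perfect-monitor line", {
  set.seed(502)
  counts <- rpois(20, 3)
  series <- data.frame(session_id = "s1", device_id = "phone1",
                       segment_index = 0:19, gold_count = counts,
                       device_count = counts)
  fit <- correlate(series)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$slope, 1)
  double <- transform(series, device_count = 2 * gold_count)
  fit2 <- correlate(double)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$pearson_r, 1)
})

test_that("correlation demands enough segments and gold variance", {
  series <- data.frame(session_id = "s1", device_id = "phone1",
                       segment_index = 0:1, gold_count = c(1, 2),
                       device_count = c(1, 2))
  expect_error(correlate(series), "at least 3")
  flat <- data.frame(session_id = "s1", device_id = "phone1",
                     segment_index = 0:4, gold_count = rep(2, 5),
                     device_count = 1:5)
  expect_error(correlate(flat), "variance")
})

test_that("correlation is invariant under segment permutation", {
  set.seed(503)
  series <- data.frame(session_id = "s1", device_id = "phone1",
                       segment_index = 0:29, gold_count = rpois(30, 2),
                       device_count = rpois(30, 2))
  base <- correlate(series)
  perm <- correlate(series[sample(30), ])
  expect_equal(perm$pearson_r, base$pearson_r)
  expect_equal(perm$slope, base$slope)
  expect_equal(perm$intercept, base$intercept)
})

test_that("Bland-Altman percentage error has mean zero for exact agreement", {
  series <- data.frame(session_id = "s1", device_id = "phone1",
                       segment_index = 0:9, gold_count = rep(2:6, 2),
                       device_count = rep(2:6, 2))
  ba <- bland_altman_pct(series)
  expect_equal(ba$mean_pct_error, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)
  expect_equal(ba$n_segments_used, 10L)
})

test_that("symmetric errors give mean zero and symmetric limits", {
  series <- data.frame(session_id = "s1", device_id = "phone1",
                       segment_index = 0:3,
                       gold_count = c(10, 10, 10, 10),
                       device_count = c(11, 9, 11, 9))
  ba <- bland_altman_pct(series)
  expect_equal(ba$mean_pct_error, 0)
  expect_equal(ba$loa_upper, -ba$loa_lower)
})

test_that("Bland-Altman matches direct formula recomputation", {
  set.seed(504)
  series <- data.frame(session_id = "s1", device_id = "phone1",
                       segment_index = 0:24,
                       gold_count = rpois(25, 4),
                       device_count = rpois(25, 4))
  ba <- bland_altman_pct(series)
  keep <- series$gold_count > 0
  pct <- 100 * (series$device_count[keep] - series$gold_count[keep]) /
    series$gold_count[keep]
  expect_equal(ba$mean_pct_error, mean(pct))
  expect_equal(ba$loa_lower, mean(pct) - 1.96 * sd(pct))
  expect_equal(ba$loa_upper, mean(pct) + 1.96 * sd(pct))
  expect_equal(ba$n_segments_used, sum(keep))
  expect_equal(ba$n_zero_gold_excluded, sum(!keep))
  expect_error(bland_altman_pct(series[series$gold_count == 0, ]),
               "nonzero gold")
})

test_that("simulated cohorts correlate strongly at high sensitivity", {
  rs <- vapply(1:5, function(seed) {
    p <- clean_params(seed, n_sessions = 4)
    co <- simulate_cohort(p)
    ev <- analyze_sessions(co$sessions, run_config(seed = seed))
    ev$agreement$pearson_r[ev$agreement$device_id == "pooled"]
  }, numeric(1))
  expect_true(all(rs > 0.9))
})
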