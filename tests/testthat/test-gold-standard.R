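test_that("events within a second merge into a single cough-second", {
  expect_equal(merge_events_to_seconds(c(10.2, 10.8)), 10L)
  expect_equal(merge_events_to_seconds(45.0), 45L)
  # chained cluster: 10.0-10.9-11.7 links up, 14.0 stands alone
  expect_equal(merge_events_to_seconds(c(10.0, 10.9, 11.7, 14.0)),
               c(10L, 14L))
  expect_equal(merge_events_to_seconds(numeric(0)), integer(0))
})

test_that("event clustering matches the brute-force oracle", {
  set.seed(201)
  for (rep in 1:50) {
    times <- sort(runif(sample(1:25, 1), 0, 60))
    expect_equal(merge_events_to_seconds(times),
                 oracle_cluster_seconds(times))
  }
})

test_that("merging never grows the event set and is idempotent", {
  set.seed(202)
  for (rep in 1:20) {
    times <- runif(sample(2:30, 1), 0, 120)
    secs <- merge_events_to_seconds(times)
    expect_lte(length(secs), length(times))
    expect_equal(merge_events_to_seconds(as.numeric(secs)), secs)
  }
})

test_that("pooled detections keep the maximum score per second", {
  det <- make_detections(c(12.3, 12.6), c(0.30, 0.91))
  pooled <- pool_detections(det)
  expect_equal(pooled$second_index, 12L)
  expect_equal(pooled$max_score, 0.91)
  expect_true(pooled$detected)

  # threshold is inclusive: a minimal score of exactly 0.85 detects
  pooled <- pool_detections(make_detections(5.0, 0.85))
  expect_true(pooled$detected)
  pooled <- pool_detections(make_detections(5.0, 0.8499))
  expect_false(pooled$detected)

  pooled <- pool_detections(make_detections(c(7.1, 7.4), c(0.2, 0.5)))
  expect_false(pooled$detected)
  expect_equal(pooled$max_score, max(0.2, 0.5))
})

test_that("per-second maxima agree with a brute-force tally", {
  set.seed(203)
  ts <- sort(runif(40, 0, 120))
  ts <- ts[c(TRUE, diff(ts) > 1.2)]  # isolate clusters at second level
  sc <- runif(length(ts))
  pooled <- pool_detections(make_detections(ts, sc))
  for (i in seq_len(nrow(pooled))) {
    s <- pooled$second_index[i]
    members <- sc[floor(ts) == s]
    expect_equal(pooled$max_score[i], max(members))
    expect_equal(pooled$detected[i], max(members) >= 0.85)
  }
})

test_that("consensus rule classifies unanimity, agreement and disputes", {
  expect_equal(consensus_classify(c(3, 3, 3)), "TRUE_COUGH")
  expect_equal(consensus_classify(c(0, 0, 0)), "NON_COUGH")
  expect_equal(consensus_classify(c(0, NA, 0)), "NON_COUGH")
  expect_equal(consensus_classify(c(3, 3, 2)), "DISPUTED")
  expect_equal(consensus_classify(c(2, 2, 2)), "COUGH_LIKE_NONCONSENSUS")
  expect_equal(consensus_classify(c(1, 1, 1)), "COUGH_LIKE_NONCONSENSUS")
  # a silent annotator counts as tier 0 in a cough-like second
  expect_equal(consensus_classify(c(3, 3, NA)), "DISPUTED")
  expect_equal(consensus_classify(c(1, 0, 0)), "DISPUTED")
  expect_error(consensus_classify(c(NA, NA, NA)), "universe")
})

test_that("every labeled second receives exactly one gold class", {
  set.seed(204)
  times <- seq(5, 275, by = 9) + runif(31)
  tiers <- matrix(sample(0:3, 31 * 3, replace = TRUE,
                         prob = c(0.4, 0.1, 0.1, 0.4)), ncol = 3)
  labels <- do.call(rbind, lapply(1:3, function(a) {
    make_labels(paste0("a", a), times, tiers[, a])
  }))
  built <- build_analysis_seconds(labels,
                                  list(phone1 = make_detections(numeric(0))))
  gold <- built$gold
  expect_equal(nrow(gold), length(unique(floor(times))))
  expect_true(all(gold$gold_class %in%
                    c("TRUE_COUGH", "NON_COUGH", "DISPUTED",
                      "COUGH_LIKE_NONCONSENSUS")))
  n_true <- sum(gold$gold_class == "TRUE_COUGH")
  n_non <- sum(gold$gold_class == "NON_COUGH")
  n_excl <- sum(gold$gold_class %in%
                  c("DISPUTED", "COUGH_LIKE_NONCONSENSUS"))
  expect_equal(n_true + n_non + n_excl, nrow(gold))
})

test_that("identical annotator tracks never produce disputed seconds", {
  set.seed(205)
  for (rep in 1:10) {
    times <- seq(5, 200, by = 8) + runif(25)
    tiers <- sample(0:3, 25, replace = TRUE)
    labels <- do.call(rbind, lapply(1:3, function(a) {
      make_labels(paste0("a", a), times, tiers)
    }))
    built <- build_analysis_seconds(
      labels, list(phone1 = make_detections(numeric(0))))
    expect_false(any(built$gold$gold_class == "DISPUTED"))
  }
})

test_that("interval labels touch every second they overlap", {
  labels <- do.call(rbind, lapply(1:3, function(a) {
    make_labels(paste0("a", a), 10.4, 3, end = 12.3)
  }))
  built <- build_analysis_seconds(
    labels, list(phone1 = make_detections(numeric(0))))
  expect_equal(built$gold$second_index, c(10L, 11L, 12L))
  expect_equal(built$gold$gold_class, rep("TRUE_COUGH", 3))
})

test_that("detections in unlabeled silence are reported out of universe", {
  labels <- unanimous_labels(c(10.5, 30.5))
  det <- make_detections(c(10.6, 300.0), c(0.95, 0.95))
  built <- build_analysis_seconds(labels, list(phone1 = det))
  expect_equal(unname(built$out_of_universe["phone1"]), 1L)
  sec <- built$seconds
  expect_equal(sort(sec$second_index), c(10L, 30L))
  expect_equal(sec$detected[sec$second_index == 10], TRUE)
  expect_equal(sec$detected[sec$second_index == 30], FALSE)
})

test_that("session QC applies the 10-cough bar inclusively", {
  gold9 <- data.frame(second_index = 1:9,
                      gold_class = rep("TRUE_COUGH", 9))
  qc <- session_qc(gold9, synchronizable = TRUE)
  expect_false(qc$included)
  expect_equal(qc$exclusion_reason, "too_few_coughs")

  gold10 <- data.frame(second_index = 1:10,
                       gold_class = rep("TRUE_COUGH", 10))
  qc <- session_qc(gold10, synchronizable = TRUE)
  expect_true(qc$included)
  expect_equal(qc$exclusion_reason, "none")

  qc <- session_qc(gold10, synchronizable = FALSE)
  expect_false(qc$included)
  expect_equal(qc$exclusion_reason, "sync_failure")
})
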