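# Independent oracles and small builders used across the suite.

# Brute-force greedy matcher with an explicit availability set: scan
# references in ascending time, each takes the earliest unused candidate
# within tolerance. O(n^2), independent of the package's two-pointer code.
oracle_match_count <- function(ref, cand, tol) {
  ref <- sort(ref); cand <- sort(cand)
  used <- rep(FALSE, length(cand))
  m <- 0L
  for (r in ref) {
    ok <- which(!used & abs(cand - r) <= tol)
    if (length(ok) > 0L) {
      used[ok[1L]] <- TRUE
      m <- m + 1L
    }
  }
  m
}

# Exhaustive event clustering: all partitions of sorted times into runs,
# checked against the gap rule, then floor of each run's first time.
oracle_cluster_seconds <- function(times, merge_gap = 1.0) {
  times <- sort(times)
  secs <- integer(0)
  start <- 1L
  for (i in seq_along(times)) {
    if (i > 1L && times[i] - times[i - 1L] >= merge_gap) {
      secs <- c(secs, floor(times[start]))
      start <- i
    }
  }
  if (length(times) > 0L) secs <- c(secs, floor(times[start]))
  sort(unique(as.integer(secs)))
}

# Clopper-Pearson bounds by bisection on the binomial CDF, independent of
# qbeta: lower p solves P(X >= x | p) = alpha/2, upper solves
# P(X <= x | p) = alpha/2.
oracle_exact_ci <- function(x, n, conf = 0.95, tol = 1e-12) {
  alpha <- 1 - conf
  bisect <- function(f, lo, hi) {
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) (1 - stats::pbinom(x - 1, n, p)) - alpha / 2, 0, 1)
  upper <- if (x == n) 1 else
    bisect(function(p) alpha / 2 - stats::pbinom(x, n, p), 0, 1)
  c(lower = lower, upper = upper)
}

# Label data frame builder.
make_labels <- function(annotator_id, start, tier, end = start) {
  data.frame(annotator_id = rep_len(annotator_id, length(start)),
             start = start, end = end,
             tier = as.integer(tier), raw_text = as.character(tier),
             stringsAsFactors = FALSE)
}

# Three identical annotator tracks at the given cough times.
unanimous_labels <- function(times, tier = 3) {
  do.call(rbind, lapply(1:3, function(a) {
    make_labels(paste0("a", a), times, rep(tier, length(times)))
  }))
}

make_detections <- function(timestamp, score = 0.95,
                            device_id = "phone1") {
  data.frame(device_id = rep_len(device_id, length(timestamp)),
             timestamp = timestamp,
             score = rep_len(score, length(timestamp)),
             stringsAsFactors = FALSE)
}

# Compact simulator setups.
clean_params <- function(seed, n_sessions = 2, n_devices = 1, ...) {
  simulator_params(seed = seed, n_sessions = n_sessions,
                   n_devices = n_devices,
                   annotator = annotator_params(perfect = TRUE),
                   p_atypical_subject = 0, p_degenerate_session = 0, ...)
}
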