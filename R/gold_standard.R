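#' Collapse time-stamped events into analysis seconds
#'
#' Events occurring within `merge_gap` seconds of one another are treated as
#' a single event: events are clustered greedily in time order (a new
#' cluster starts when the gap from the previous event is at least
#' `merge_gap`), and each cluster contributes exactly one second index, the
#' floor of its first event time. This is how repeated annotation clicks or
#' multiple explosive phases of one cough become a single cough-second.
#'
#' @param times Numeric event times in seconds (any order).
#' @param merge_gap Gap in seconds at which a new cluster starts
#'   (default 1.0).
#' @return Sorted unique integer second indices, one per cluster.
#' @export
merge_events_to_seconds <- function(times, merge_gap = 1.0) {
  stopifnot(merge_gap > 0)
  if (length(times) == 0L) return(integer(0))
  times <- sort(times)
  cl <- event_clusters(times, merge_gap)
  firsts <- times[!duplicated(cl)]
  sort(unique(as.integer(floor(firsts))))
}

# Cluster ids for sorted times: new cluster when gap >= merge_gap.
event_clusters <- function(times, merge_gap) {
  if (length(times) == 0L) return(integer(0))
  cumsum(c(TRUE, diff(times) >= merge_gap))
}

#' Pool a device's detections into per-second detection states
#'
#' Detections are clustered with the same merge rule as annotations
#' ([merge_events_to_seconds()]); each cluster is assigned to the second of
#' its first event, and the highest prediction score among the cluster's
#' members becomes the second's score. A second counts as detected when its
#' score reaches the classification threshold (inclusive: a score exactly
#' at the minimal threshold is a detection).
#'
#' @param detections Detection data frame, already offset-corrected onto
#'   the annotation timeline.
#' @param threshold Minimal prediction score classifying a sound as cough
#'   (default 0.85).
#' @param merge_gap Cluster gap in seconds (default 1.0).
#' @return Data frame `second_index, max_score, detected`, sorted by
#'   second, one row per detection-second.
#' @export
pool_detections <- function(detections, threshold = 0.85, merge_gap = 1.0) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(detections) == 0L) {
    return(data.frame(second_index = integer(0), max_score = numeric(0),
                      detected = logical(0)))
  }
  ord <- order(detections$timestamp)
  ts <- detections$timestamp[ord]
  sc <- detections$score[ord]
  cl <- event_clusters(ts, merge_gap)
  sec <- as.integer(floor(ts[!duplicated(cl)]))
  max_score <- as.numeric(tapply(sc, cl, max))
  # several clusters can map to the same second; keep the per-second max
  agg <- tapply(max_score, sec, max)
  out <- data.frame(second_index = as.integer(names(agg)),
                    max_score = as.numeric(agg))
  out <- out[order(out$second_index), , drop = FALSE]
  out$detected <- out$max_score >= threshold
  rownames(out) <- NULL
  out
}

#' Consensus class of one analysis second from three annotators' tiers
#'
#' Implements the three-listener consensus rule over a single second:
#' \itemize{
#'   \item all three tiers equal 3: `TRUE_COUGH` (unanimous definite cough);
#'   \item every label placed in the second is tier 0 (and at least one
#'     exists): `NON_COUGH`;
#'   \item any cough-like tier (1--3) without unanimity on 3:
#'     excluded from contingency counting, as `COUGH_LIKE_NONCONSENSUS`
#'     when all three listeners agree on the same sub-definite tier
#'     (e.g. 2,2,2) and `DISPUTED` otherwise.
#' }
#' An annotator who placed no label in a cough-like second counts as
#' tier 0, i.e. as disagreement.
#'
#' @param tiers Numeric/integer vector of length 3: each annotator's
#'   (maximum) tier in the second, `NA` when the annotator placed no label.
#' @return One of `"TRUE_COUGH"`, `"NON_COUGH"`, `"DISPUTED"`,
#'   `"COUGH_LIKE_NONCONSENSUS"`.
#' @export
consensus_classify <- function(tiers) {
  stopifnot(length(tiers) == 3L)
  present <- tiers[!is.na(tiers)]
  if (length(present) == 0L) {
    stop("second has no labels from any annotator; outside the analysis ",
         "universe", call. = FALSE)
  }
  stopifnot(all(present %in% 0:3))
  if (!any(present >= 1)) return("NON_COUGH")
  full <- ifelse(is.na(tiers), 0L, as.integer(tiers))
  if (all(full == 3L)) return("TRUE_COUGH")
  if (length(unique(full)) == 1L) return("COUGH_LIKE_NONCONSENSUS")
  "DISPUTED"
}

# Per-annotator, per-second maximum tier. Point labels (end == start) are
# clustered with the merge rule before being assigned to the second of the
# cluster's first label; interval labels contribute to every second they
# overlap (half-open [s, s+1) bins).
annotator_second_tiers <- function(labels, merge_gap = 1.0) {
  if (nrow(labels) == 0L) {
    return(data.frame(annotator_id = character(0), second_index = integer(0),
                      tier = integer(0), stringsAsFactors = FALSE))
  }
  pieces <- lapply(split(labels, labels$annotator_id), function(df) {
    sec <- integer(0); tier <- integer(0)
    pts <- df[df$end == df$start, , drop = FALSE]
    if (nrow(pts) > 0L) {
      ord <- order(pts$start)
      ts <- pts$start[ord]; tr <- pts$tier[ord]
      cl <- event_clusters(ts, merge_gap)
      sec <- c(sec, as.integer(floor(ts[!duplicated(cl)])))
      tier <- c(tier, as.integer(tapply(tr, cl, max)))
    }
    iv <- df[df$end > df$start, , drop = FALSE]
    if (nrow(iv) > 0L) {
      for (k in seq_len(nrow(iv))) {
        s0 <- as.integer(floor(iv$start[k]))
        s1 <- as.integer(ceiling(iv$end[k])) - 1L
        ss <- s0:max(s0, s1)
        sec <- c(sec, ss)
        tier <- c(tier, rep(as.integer(iv$tier[k]), length(ss)))
      }
    }
    mx <- tapply(tier, sec, max)
    data.frame(annotator_id = df$annotator_id[1L],
               second_index = as.integer(names(mx)),
               tier = as.integer(mx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Build the per-second evaluable dataset for one session
#'
#' Combines three annotators' label tracks and each device's
#' offset-corrected detections into analysis seconds. The analysis universe
#' is the set of seconds containing at least one annotation; detector
#' events falling in unlabeled silence are tallied separately as
#' out-of-universe detections and excluded from contingency counting.
#'
#' @param labels Label data frame holding all three annotators' labels
#'   (column `annotator_id` distinguishes them), or a list of three label
#'   data frames.
#' @param detections Named list of offset-corrected detection data frames,
#'   one per device.
#' @param session_id Session identifier stamped on every row.
#' @param threshold Detection score threshold (default 0.85).
#' @param merge_gap Event merge gap in seconds (default 1.0).
#' @return List with elements:
#'   \describe{
#'     \item{seconds}{long data frame `session_id, second_index,
#'       gold_class, device_id, detected, max_score` (one row per analysis
#'       second per device).}
#'     \item{gold}{data frame `second_index, gold_class` (one row per
#'       analysis second).}
#'     \item{device_seconds}{named list of pooled per-second detection
#'       tables per device (all detection-seconds, in or out of universe).}
#'     \item{out_of_universe}{named integer vector: per device, the number
#'       of detected seconds outside the analysis universe.}
#'   }
#' @export
build_analysis_seconds <- function(labels, detections, session_id = "session",
                                   threshold = 0.85, merge_gap = 1.0) {
  if (is.list(labels) && !is.data.frame(labels)) {
    labels <- do.call(rbind, labels)
  }
  validate_labels(labels)
  annotators <- unique(labels$annotator_id)
  if (length(annotators) != 3L) {
    stop("three annotators are required for consensus, got ",
         length(annotators), call. = FALSE)
  }
  tiers <- annotator_second_tiers(labels, merge_gap)
  universe <- sort(unique(tiers$second_index))
  tier_mat <- matrix(NA_integer_, nrow = length(universe), ncol = 3L,
                     dimnames = list(NULL, annotators))
  for (a in annotators) {
    at <- tiers[tiers$annotator_id == a, , drop = FALSE]
    tier_mat[match(at$second_index, universe), a] <- at$tier
  }
  gold_class <- vapply(seq_along(universe),
                       function(i) consensus_classify(tier_mat[i, ]), "")
  gold <- data.frame(second_index = universe, gold_class = gold_class,
                     stringsAsFactors = FALSE)

  stopifnot(is.list(detections), length(detections) >= 1L,
            !is.null(names(detections)))
  device_seconds <- lapply(detections, pool_detections,
                           threshold = threshold, merge_gap = merge_gap)
  rows <- lapply(names(device_seconds), function(dev) {
    ds <- device_seconds[[dev]]
    idx <- match(universe, ds$second_index)
    data.frame(
      session_id = session_id, second_index = universe,
      gold_class = gold_class, device_id = dev,
      detected = !is.na(idx) & ds$detected[idx],
      max_score = ds$max_score[idx],
      stringsAsFactors = FALSE
    )
  })
  seconds <- do.call(rbind, rows)
  rownames(seconds) <- NULL
  oou <- vapply(device_seconds, function(ds) {
    sum(ds$detected & !(ds$second_index %in% universe))
  }, integer(1))
  list(seconds = seconds, gold = gold, device_seconds = device_seconds,
       out_of_universe = oou)
}

#' Session quality control
#'
#' A session enters the performance analysis only if its detector streams
#' could be synchronized and at least `min_coughs` of its sounds were
#' unanimously labeled definite coughs (tier 3 by all three listeners).
#'
#' @param gold Data frame `second_index, gold_class` for the session (the
#'   `gold` element of [build_analysis_seconds()]).
#' @param synchronizable Logical: could every device stream be aligned?
#' @param session_id Session identifier.
#' @param min_coughs Minimum unanimous cough-seconds (default 10,
#'   inclusive).
#' @return One-row data frame `session_id, n_unanimous_coughs,
#'   n_disputed_seconds, synchronizable, included, exclusion_reason`.
#'   `n_disputed_seconds` counts all consensus-excluded seconds (disputed
#'   plus unanimous-sub-definite).
#' @export
session_qc <- function(gold, synchronizable, session_id = "session",
                       min_coughs = 10L) {
  n_coughs <- sum(gold$gold_class == "TRUE_COUGH")
  n_disp <- sum(gold$gold_class %in%
                  c("DISPUTED", "COUGH_LIKE_NONCONSENSUS"))
  reason <- if (!synchronizable) {
    "sync_failure"
  } else if (n_coughs < min_coughs) {
    "too_few_coughs"
  } else {
    "none"
  }
  data.frame(
    session_id = session_id, n_unanimous_coughs = n_coughs,
    n_disputed_seconds = n_disp, synchronizable = synchronizable,
    included = reason == "none", exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}
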