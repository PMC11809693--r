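#' Offset error between a label track and a detection stream
#'
#' Measures how badly a candidate clock offset aligns detector events with
#' cough-like annotations (tier >= 1). A detection matches a label when
#' `|timestamp + offset - label_start| <= tolerance`; matching is greedy and
#' one-to-one: labels are scanned in ascending time and each takes the
#' earliest unmatched detection within tolerance. The error is
#' `1 - matched / max(n_labels, n_detections)`, so 0 means every event on
#' the larger stream found a partner and 1 means none did.
#'
#' The default tolerance of 2 s reflects manual synchronization accuracy
#' achievable when solicited sounds are separated by at least 5 s of
#' silence.
#'
#' @param labels Label data frame ([read_label_track()]); only tier >= 1
#'   labels take part in matching, and labels from different annotators
#'   marking the same sound (within the 1 s merge window) count as one
#'   reference event.
#' @param detections Detection data frame ([read_detections()]). Callers
#'   aligning a full detector log typically pass only at-threshold
#'   detections, since sub-threshold log entries have no annotated
#'   counterpart.
#' @param offset Candidate offset in seconds (detector time + offset =
#'   annotation time).
#' @param tolerance Matching tolerance in seconds (> 0).
#' @return Non-negative scalar error in \[0,1\].
#' @export
offset_error <- function(labels, detections, offset, tolerance = 2.0) {
  stopifnot(tolerance > 0, is.finite(offset))
  lab <- label_event_times(labels)
  det <- sort(detections$timestamp)
  if (length(lab) == 0L && length(det) == 0L) {
    stop("offset error undefined: no cough-like labels and no detections",
         call. = FALSE)
  }
  m <- greedy_match_count(lab, det + offset, tolerance)
  1 - m / max(length(lab), length(det))
}

# Cough-like (tier >= 1) label reference times, ascending. Labels from
# different annotators marking the same sound are collapsed to a single
# reference time (cluster mean) with the standard 1 s merge rule, so each
# cough-like event counts once however many listeners labeled it.
label_event_times <- function(labels, merge_gap = 1.0) {
  t <- sort(labels$start[labels$tier >= 1L])
  if (length(t) == 0L) return(t)
  cl <- event_clusters(t, merge_gap)
  as.numeric(tapply(t, cl, mean))
}

# Greedy one-to-one matching of two ascending streams: each reference time
# takes the earliest unused candidate within tolerance.
greedy_match_count <- function(ref, cand, tol) {
  greedy_match(ref, cand, tol)[1L]
}

# As above, returning c(match count, summed |residual|) over matched pairs.
greedy_match <- function(ref, cand, tol) {
  gm <- greedy_match_pairs(ref, cand, tol)
  c(gm$m, sum(abs(gm$resid)))
}

# Full greedy matching bookkeeping: match count and the signed residuals
# ref - cand of the matched pairs.
greedy_match_pairs <- function(ref, cand, tol) {
  n_r <- length(ref); n_c <- length(cand)
  resid <- numeric(0)
  if (n_r == 0L || n_c == 0L) return(list(m = 0L, resid = resid))
  j <- 1L
  for (i in seq_len(n_r)) {
    lo <- ref[i] - tol
    while (j <= n_c && cand[j] < lo) j <- j + 1L
    if (j > n_c) break
    if (cand[j] <= ref[i] + tol) {
      resid <- c(resid, ref[i] - cand[j])
      j <- j + 1L
    }
  }
  list(m = length(resid), resid = resid)
}

#' Estimate the clock offset of a device relative to the annotation timeline
#'
#' Exhaustive grid search for the offset best aligning detections with
#' cough-like labels. The search minimizes a truncated absolute loss over
#' greedy one-to-one matches (each matched pair costs its time residual,
#' each unmatched event the full tolerance): this agrees with minimizing
#' [offset_error()] except where a coincidental match would tip the flat
#' match-fraction plateau toward a wrong offset, and it localizes the
#' optimum to a single grid step. Ties are broken toward the smallest
#' absolute offset, then toward the negative side, so the result is
#' deterministic. If even the best candidate leaves
#' more than half of the events unmatched (error > 0.5) the session/device
#' pair is flagged unsynchronizable, mirroring quality exclusion of
#' sessions with too few labels or detections to align.
#'
#' @param labels,detections As in [offset_error()].
#' @param grid Numeric `c(min, max, step)` in seconds; default -60..60 by
#'   0.1.
#' @param tolerance Matching tolerance in seconds.
#' @param session_id,device_id Identifiers carried into the result.
#' @param refine If `TRUE` (default), polish the winning grid point below
#'   grid resolution by the median signed residual of its matched pairs,
#'   clamped to the grid range.
#' @return An object of class `offset_estimate`: list with `session_id`,
#'   `device_id`, `offset`, `error`, `method` (`"automatic"`),
#'   `synchronizable`, `search_grid`.
#' @export
estimate_offset <- function(labels, detections, grid = c(-60, 60, 0.1),
                            tolerance = 2.0, session_id = NA_character_,
                            device_id = NA_character_, refine = TRUE) {
  stopifnot(length(grid) == 3L, grid[2] >= grid[1], grid[3] > 0)
  candidates <- round(seq(grid[1], grid[2], by = grid[3]), 6)
  lab <- label_event_times(labels)
  det <- sort(detections$timestamp)
  if (length(lab) == 0L || length(det) == 0L) {
    return(new_offset_estimate(session_id, device_id, NA_real_, 1,
                               "automatic", FALSE, grid))
  }
  n_norm <- max(length(lab), length(det))
  match_at <- vapply(candidates, function(o) {
    greedy_match(lab, det + o, tolerance)
  }, numeric(2))
  # The match fraction alone is flat across a plateau as wide as the
  # tolerance and a single coincidental match can tip it toward a wrong
  # offset; the search instead minimizes a truncated absolute loss — each
  # matched pair costs its |residual|, each unmatched event the full
  # tolerance — which agrees with the match fraction up to coincidences
  # and is sharp at the true offset. Ties break toward the smallest
  # |offset|, then the negative side.
  loss <- match_at[2L, ] + tolerance * (n_norm - match_at[1L, ])
  ties <- candidates[loss == min(loss)]
  pick <- ties[order(abs(ties), ties)][1L]
  if (refine) {
    # polish below grid resolution: shift by the median signed residual of
    # the matched pairs; the median ignores the odd coincidentally matched
    # spurious detection, so the polish is exact when timestamps are clean
    gm <- greedy_match_pairs(lab, det + pick, tolerance)
    if (gm$m > 0L) {
      pick <- min(max(pick + stats::median(gm$resid), grid[1]), grid[2])
    }
  }
  err <- 1 - greedy_match(lab, det + pick, tolerance)[1L] / n_norm
  new_offset_estimate(session_id, device_id, pick, err, "automatic",
                      err <= 0.5, grid)
}

new_offset_estimate <- function(session_id, device_id, offset, error,
                                method, synchronizable, grid) {
  structure(
    list(session_id = session_id, device_id = device_id, offset = offset,
         error = error, method = method, synchronizable = synchronizable,
         search_grid = grid),
    class = "offset_estimate"
  )
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat("Clock offset estimate (", x$method, ")\n", sep = "")
  cat("  session ", x$session_id, ", device ", x$device_id, "\n", sep = "")
  if (x$synchronizable) {
    cat(sprintf("  offset %+.1f s (match error %.3f)\n", x$offset, x$error))
  } else {
    cat("  UNSYNCHRONIZABLE (best match error ",
        sprintf("%.3f", x$error), ")\n", sep = "")
  }
  invisible(x)
}

#' Override an automatic offset with a manually reviewed value
#'
#' Automatic offsets are reviewed and occasionally corrected by hand; the
#' override is recorded as `method = "manual_override"` so reports preserve
#' provenance.
#'
#' @param estimate An `offset_estimate`.
#' @param offset The manually determined offset in seconds.
#' @return The updated `offset_estimate`.
#' @export
manual_offset <- function(estimate, offset) {
  stopifnot(inherits(estimate, "offset_estimate"), is.finite(offset))
  estimate$offset <- offset
  estimate$method <- "manual_override"
  estimate$synchronizable <- TRUE
  estimate
}

#' Apply an offset estimate to a detection stream
#'
#' Shifts every detector timestamp onto the annotation timeline
#' (`timestamp + offset`); event order is preserved.
#'
#' @param detections Detection data frame.
#' @param estimate An `offset_estimate` (must be synchronizable), or a
#'   bare numeric offset in seconds.
#' @return The detections with shifted timestamps.
#' @export
apply_offset <- function(detections, estimate) {
  if (inherits(estimate, "offset_estimate")) {
    if (!isTRUE(estimate$synchronizable)) {
      stop("cannot apply an unsynchronizable offset estimate", call. = FALSE)
    }
    offset <- estimate$offset
  } else {
    stopifnot(is.numeric(estimate), length(estimate) == 1L, is.finite(estimate))
    offset <- estimate
  }
  detections$timestamp <- detections$timestamp + offset
  detections
}

#' Offset estimates as a report table
#'
#' @param estimates List of `offset_estimate` objects.
#' @return Data frame `session_id, device_id, offset, error, method,
#'   synchronizable`.
#' @export
offsets_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(session_id = e$session_id, device_id = e$device_id,
               offset = e$offset, error = e$error, method = e$method,
               synchronizable = e$synchronizable, stringsAsFactors = FALSE)
  }))
}
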