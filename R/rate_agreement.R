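#' Per-segment cough counts for one session and device
#'
#' Cuts the observation period into fixed-length segments (one minute by
#' default) and counts, per segment, the gold-standard cough-seconds
#' (unanimous definite coughs) and the device's detected cough-seconds.
#' Every segment of the session is present, including zero-count ones. A
#' final partial segment is kept only when it covers at least half the
#' segment length (30 s for one-minute segments).
#'
#' @param gold Data frame `second_index, gold_class` for the session.
#' @param device_seconds Pooled per-second detection table for the device
#'   ([pool_detections()]); all detected seconds count, labeled or not.
#' @param duration Session duration in seconds.
#' @param segment_length Segment length in seconds (default 60).
#' @param session_id,device_id Identifiers stamped on the rows.
#' @return Data frame `session_id, device_id, segment_index, gold_count,
#'   device_count` of class `minute_rate_series`.
#' @export
segment_counts <- function(gold, device_seconds, duration,
                           segment_length = 60, session_id = "session",
                           device_id = "device") {
  stopifnot(duration > 0, segment_length > 0)
  n_full <- floor(duration / segment_length)
  remainder <- duration - n_full * segment_length
  n_seg <- n_full + as.integer(remainder >= segment_length / 2)
  if (n_seg == 0L) {
    stop("session shorter than half a segment; no usable segments",
         call. = FALSE)
  }
  gold_secs <- gold$second_index[gold$gold_class == "TRUE_COUGH"]
  det_secs <- device_seconds$second_index[device_seconds$detected]
  seg_of <- function(secs) {
    k <- floor(secs / segment_length)
    k[k >= 0 & k < n_seg]
  }
  out <- data.frame(
    session_id = session_id, device_id = device_id,
    segment_index = seq_len(n_seg) - 1L,
    gold_count = as.integer(tabulate(seg_of(gold_secs) + 1L, nbins = n_seg)),
    device_count = as.integer(tabulate(seg_of(det_secs) + 1L, nbins = n_seg)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("minute_rate_series", "data.frame")
  out
}

#' Rate agreement: Pearson correlation and linear fit
#'
#' Compares per-segment device counts against gold counts with the Pearson
#' correlation coefficient and an ordinary-least-squares fit
#' `device_count = intercept + slope * gold_count`. A perfect monitor lies
#' on the identity line (r = 1, intercept 0, slope 1).
#'
#' @param series A `minute_rate_series` (rows from one or many sessions
#'   and devices).
#' @param pooled If `TRUE`, fit once over all rows regardless of device;
#'   otherwise fit per device.
#' @return Data frame `device_id, n_segments, pearson_r, intercept, slope`
#'   (device `"pooled"` for the pooled fit).
#' @export
correlate <- function(series, pooled = FALSE) {
  groups <- if (pooled) list(pooled = series) else
    split(series, series$device_id)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    if (nrow(df) < 3L) {
      stop("need at least 3 segments to correlate (", g, " has ",
           nrow(df), ")", call. = FALSE)
    }
    if (stats::var(df$gold_count) == 0) {
      stop("gold counts have zero variance for ", g,
           "; correlation undefined", call. = FALSE)
    }
    fit <- stats::lm(device_count ~ gold_count, data = df)
    data.frame(device_id = g, n_segments = nrow(df),
               pearson_r = stats::cor(df$gold_count, df$device_count),
               intercept = unname(stats::coef(fit)[1L]),
               slope = unname(stats::coef(fit)[2L]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bland-Altman analysis on percentage error
#'
#' Per segment with a nonzero gold count, the percentage error is
#' `100 * (device_count - gold_count) / gold_count`. Reports the mean
#' error (bias) and the 1.96-standard-deviation limits of agreement.
#' Zero-gold segments cannot contribute a percentage and are excluded
#' (their number is reported).
#'
#' @param series A `minute_rate_series`.
#' @return List `mean_pct_error`, `sd_pct_error`, `loa_lower`,
#'   `loa_upper`, `n_segments_used`, `n_zero_gold_excluded`.
#' @export
bland_altman_pct <- function(series) {
  usable <- series[series$gold_count > 0, , drop = FALSE]
  if (nrow(usable) == 0L) {
    stop("no segments with nonzero gold count; percentage error undefined",
         call. = FALSE)
  }
  pct <- 100 * (usable$device_count - usable$gold_count) / usable$gold_count
  m <- mean(pct)
  s <- if (length(pct) > 1L) stats::sd(pct) else 0
  list(mean_pct_error = m, sd_pct_error = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       n_segments_used = nrow(usable),
       n_zero_gold_excluded = nrow(series) - nrow(usable))
}
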