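#' Contingency table of detection outcomes for one device
#'
#' Counts analysis seconds by gold class and detection state. Only
#' consensus seconds enter: `TRUE_COUGH` seconds split into true positives
#' (detected) and false negatives, `NON_COUGH` seconds into false positives
#' (detected) and true negatives. Disputed and non-consensus seconds are
#' excluded upstream and ignored here.
#'
#' @param seconds Long analysis-second data frame (`seconds` element of
#'   [build_analysis_seconds()], possibly row-bound over sessions).
#' @param device_id Device to tabulate; `NULL` (default) uses all rows,
#'   which is only meaningful if `seconds` holds a single device.
#' @return Object of class `contingency_table`: list with integer `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
contingency <- function(seconds, device_id = NULL) {
  if (!is.null(device_id)) {
    seconds <- seconds[seconds$device_id == device_id, , drop = FALSE]
  }
  cough <- seconds$gold_class == "TRUE_COUGH"
  clean <- seconds$gold_class == "NON_COUGH"
  det <- seconds$detected
  new_contingency(
    tp = sum(cough & det), fn = sum(cough & !det),
    fp = sum(clean & det), tn = sum(clean & !det)
  )
}

#' Construct a contingency table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `contingency_table`.
#' @export
new_contingency <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$tp + x$fn, x$fp, x$tn, x$fp + x$tn),
              nrow = 3,
              dimnames = list(c("detected", "not detected", "total"),
                              c("cough seconds", "non-cough seconds")))
  print(m)
  invisible(x)
}

#' Combine contingency tables by element-wise sum
#'
#' @param ... `contingency_table` objects (or a single list of them).
#' @return The pooled `contingency_table`.
#' @export
pool_contingency <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1L]], "contingency_table")) {
    tabs <- tabs[[1L]]
  }
  sums <- Reduce(function(a, b) {
    Map(`+`, a[c("tp", "fp", "fn", "tn")], b[c("tp", "fp", "fn", "tn")])
  }, tabs)
  new_contingency(sums$tp, sums$fp, sums$fn, sums$tn)
}

#' Sensitivity: fraction of gold cough-seconds detected
#'
#' @param ct A `contingency_table`.
#' @return `tp / (tp + fn)`.
#' @export
sensitivity <- function(ct) {
  n <- ct$tp + ct$fn
  if (n == 0L) {
    stop("sensitivity undefined: no gold cough-seconds", call. = FALSE)
  }
  ct$tp / n
}

#' Specificity: one minus the false-positive fraction of non-cough seconds
#'
#' @param ct A `contingency_table`.
#' @return `1 - fp / (fp + tn)`.
#' @export
specificity <- function(ct) {
  n <- ct$fp + ct$tn
  if (n == 0L) {
    stop("specificity undefined: no gold non-cough seconds", call. = FALSE)
  }
  1 - ct$fp / n
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities via the beta-quantile closed
#' form: with `x` successes out of `n`, the lower bound is the
#' `alpha/2` quantile of Beta(`x`, `n - x + 1`) (0 when `x = 0`) and the
#' upper bound the `1 - alpha/2` quantile of Beta(`x + 1`, `n - x`)
#' (1 when `x = n`).
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return Object of class `binomial_ci`: list with `estimate`, `lower`,
#'   `upper`, `confidence`, `successes`, `n`, `method =
#'   "clopper_pearson"`.
#' @export
exact_binomial_ci <- function(successes, n, confidence = 0.95) {
  stopifnot(length(successes) == 1L, length(n) == 1L,
            n >= 1, n == round(n),
            successes >= 0, successes <= n, successes == round(successes),
            confidence > 0, confidence < 1)
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  structure(
    list(estimate = successes / n, lower = lower, upper = upper,
         confidence = confidence, successes = as.integer(successes),
         n = as.integer(n), method = "clopper_pearson"),
    class = "binomial_ci"
  )
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%.1f%% (%d/%d; %d%% CI: %.1f%%-%.1f%%, %s)\n",
              100 * x$estimate, x$successes, x$n,
              round(100 * x$confidence), 100 * x$lower, 100 * x$upper,
              x$method))
  invisible(x)
}

#' Per-session sensitivity and specificity with five-number summaries
#'
#' Computes sensitivity and specificity for every (session, device)
#' combination and summarizes each metric per device by minimum, quartiles
#' and maximum (quantiles by linear interpolation between order
#' statistics). A session-device pair with no gold cough-seconds has
#' undefined sensitivity; it is skipped for that metric with a warning
#' rather than failing the whole analysis (likewise for specificity with
#' no non-cough seconds).
#'
#' @param seconds Long analysis-second data frame over included sessions.
#' @return List with `per_session` (data frame `session_id, device_id,
#'   n_cough_seconds, n_noncough_seconds, sensitivity, specificity`) and
#'   `summary` (data frame `device_id, metric, minimum, q1, median, q3,
#'   maximum`).
#' @export
per_session_metrics <- function(seconds) {
  combos <- unique(seconds[c("session_id", "device_id")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- seconds$session_id == combos$session_id[i] &
      seconds$device_id == combos$device_id[i]
    ct <- contingency(seconds[sel, , drop = FALSE])
    se <- if (ct$tp + ct$fn > 0) sensitivity(ct) else {
      warning("sensitivity not evaluated for session ",
              combos$session_id[i], " / ", combos$device_id[i],
              ": no gold cough-seconds", call. = FALSE)
      NA_real_
    }
    sp <- if (ct$fp + ct$tn > 0) specificity(ct) else {
      warning("specificity not evaluated for session ",
              combos$session_id[i], " / ", combos$device_id[i],
              ": no non-cough seconds", call. = FALSE)
      NA_real_
    }
    data.frame(session_id = combos$session_id[i],
               device_id = combos$device_id[i],
               n_cough_seconds = ct$tp + ct$fn,
               n_noncough_seconds = ct$fp + ct$tn,
               sensitivity = se, specificity = sp,
               stringsAsFactors = FALSE)
  })
  per_session <- do.call(rbind, rows)
  rownames(per_session) <- NULL
  summ <- do.call(rbind, lapply(split(per_session, per_session$device_id),
    function(df) {
      do.call(rbind, lapply(c("sensitivity", "specificity"), function(metric) {
        v <- df[[metric]]
        v <- v[!is.na(v)]
        q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                             names = FALSE)
        data.frame(device_id = df$device_id[1L], metric = metric,
                   minimum = q[1], q1 = q[2], median = q[3], q3 = q[4],
                   maximum = q[5], stringsAsFactors = FALSE)
      }))
    }))
  rownames(summ) <- NULL
  list(per_session = per_session, summary = summ)
}
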