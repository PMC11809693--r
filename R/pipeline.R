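#' Pipeline run configuration
#'
#' Bundles every tunable of the evaluation pipeline with its standard
#' default: detection score threshold 0.85, quality bar of 10 unanimous
#' coughs per session, one-minute rate segments, 95% confidence, 2 s
#' matching tolerance and a -60..+60 s offset search grid at 0.1 s.
#'
#' @param manifest Path to a session manifest (YAML), or `NULL` when the
#'   sessions are supplied in memory.
#' @param out_dir Output directory for the report bundle.
#' @param threshold Detection score threshold.
#' @param qc_min_coughs Minimum unanimous cough-seconds per session.
#' @param segment_length Rate-agreement segment length, seconds.
#' @param confidence Confidence level for binomial intervals.
#' @param tolerance Offset-matching tolerance, seconds.
#' @param grid Offset search grid `c(min, max, step)`, seconds.
#' @param merge_gap Event merge gap, seconds.
#' @param seed Seed recorded for provenance (and used by any simulation
#'   step).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir = "results",
                       threshold = 0.85, qc_min_coughs = 10L,
                       segment_length = 60, confidence = 0.95,
                       tolerance = 2.0, grid = c(-60, 60, 0.1),
                       merge_gap = 1.0, seed = 1L) {
  stopifnot(threshold >= 0, threshold <= 1, qc_min_coughs >= 0,
            segment_length > 0, confidence > 0, confidence < 1,
            tolerance > 0, length(grid) == 3L)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full evaluation over a set of sessions
#'
#' The computational core of the pipeline: synchronizes every device
#' stream, builds the per-second gold standard, applies session quality
#' control, tabulates pooled and per-session sensitivity/specificity with
#' exact intervals, and computes minute-level rate agreement.
#'
#' Devices are pooled across sessions by their position in each session's
#' device list (`phone1`, `phone2`, ...), matching a design where the same
#' physical devices record every session.
#'
#' @param sessions List of session objects, each with `session_id`,
#'   `duration`, `labels` (three annotators' labels in one data frame) and
#'   `detections` (list of detection data frames, one per device). The
#'   `sessions` element of [simulate_cohort()] has this shape, as does the
#'   result of [load_sessions()].
#' @param config A [run_config()].
#' @return List of class `cough_evaluation` with elements `offsets`, `qc`,
#'   `seconds`, `contingency`, `metrics`, `per_session`, `summary`,
#'   `rate_segments`, `agreement`, `bland_altman`, `out_of_universe`,
#'   `exclusion_flow`.
#' @export
analyze_sessions <- function(sessions, config = run_config()) {
  offsets <- list()
  qc_rows <- list()
  seconds <- list()
  segments <- list()
  oou <- list()
  for (s in sessions) {
    roles <- paste0("phone", seq_along(s$detections))
    ests <- lapply(seq_along(s$detections), function(d) {
      det <- s$detections[[d]]
      # align on classified detections; sub-threshold log entries have no
      # annotated counterpart and would only dilute the match fraction
      det <- det[det$score >= config$threshold, , drop = FALSE]
      estimate_offset(s$labels, det, grid = config$grid,
                      tolerance = config$tolerance,
                      session_id = s$session_id, device_id = roles[d])
    })
    offsets <- c(offsets, ests)
    sync_ok <- all(vapply(ests, `[[`, logical(1), "synchronizable"))
    if (sync_ok) {
      shifted <- lapply(seq_along(s$detections), function(d) {
        apply_offset(s$detections[[d]], ests[[d]])
      })
      names(shifted) <- roles
      built <- build_analysis_seconds(s$labels, shifted,
                                      session_id = s$session_id,
                                      threshold = config$threshold,
                                      merge_gap = config$merge_gap)
    } else {
      # gold standard needs no detector stream; still computed for QC counts
      built <- NULL
      gold <- gold_only(s$labels, config$merge_gap)
    }
    gold <- if (sync_ok) built$gold else gold
    qc <- session_qc(gold, sync_ok, session_id = s$session_id,
                     min_coughs = config$qc_min_coughs)
    qc_rows[[s$session_id]] <- qc
    if (qc$included) {
      seconds[[s$session_id]] <- built$seconds
      oou[[s$session_id]] <- data.frame(
        session_id = s$session_id, device_id = roles,
        n_out_of_universe = as.integer(built$out_of_universe),
        stringsAsFactors = FALSE)
      segments[[s$session_id]] <- do.call(rbind, lapply(roles, function(r) {
        segment_counts(gold, built$device_seconds[[r]], s$duration,
                       segment_length = config$segment_length,
                       session_id = s$session_id, device_id = r)
      }))
    }
  }
  qc <- do.call(rbind, qc_rows); rownames(qc) <- NULL
  if (length(seconds) == 0L) {
    stop("no session passed quality control; nothing to evaluate",
         call. = FALSE)
  }
  seconds <- do.call(rbind, seconds); rownames(seconds) <- NULL
  segments <- do.call(rbind, segments); rownames(segments) <- NULL
  class(segments) <- c("minute_rate_series", "data.frame")

  roles <- sort(unique(seconds$device_id))
  cts <- lapply(roles, function(r) contingency(seconds, r))
  names(cts) <- roles
  metrics <- do.call(rbind, lapply(roles, function(r) {
    ct <- cts[[r]]
    se <- exact_binomial_ci(ct$tp, ct$tp + ct$fn, config$confidence)
    sp <- exact_binomial_ci(ct$tn, ct$fp + ct$tn, config$confidence)
    data.frame(device_id = r, tp = ct$tp, fp = ct$fp, fn = ct$fn,
               tn = ct$tn,
               sensitivity = se$estimate, sens_lower = se$lower,
               sens_upper = se$upper,
               specificity = sp$estimate, spec_lower = sp$lower,
               spec_upper = sp$upper, stringsAsFactors = FALSE)
  }))
  psm <- per_session_metrics(seconds)
  agreement <- rbind(correlate(segments, pooled = FALSE),
                     correlate(segments, pooled = TRUE))
  ba <- bland_altman_pct(segments)
  flow <- exclusion_flow(qc)
  structure(
    list(offsets = offsets_table(offsets), qc = qc, seconds = seconds,
         contingency = cts, metrics = metrics,
         per_session = psm$per_session, summary = psm$summary,
         rate_segments = segments, agreement = agreement,
         bland_altman = ba,
         out_of_universe = do.call(rbind, c(oou, make.row.names = FALSE)),
         exclusion_flow = flow, config = config),
    class = "cough_evaluation"
  )
}

# Gold classes from labels alone (no detector join).
gold_only <- function(labels, merge_gap = 1.0) {
  tiers <- annotator_second_tiers(labels, merge_gap)
  universe <- sort(unique(tiers$second_index))
  annotators <- unique(labels$annotator_id)
  tier_mat <- matrix(NA_integer_, length(universe), length(annotators),
                     dimnames = list(NULL, annotators))
  for (a in annotators) {
    at <- tiers[tiers$annotator_id == a, , drop = FALSE]
    tier_mat[match(at$second_index, universe), a] <- at$tier
  }
  data.frame(
    second_index = universe,
    gold_class = vapply(seq_along(universe),
                        function(i) consensus_classify(tier_mat[i, ]), ""),
    stringsAsFactors = FALSE
  )
}

# Session accounting in the shape of a study flow chart.
exclusion_flow <- function(qc) {
  c(total_sessions = nrow(qc),
    excluded_sync_failure = sum(qc$exclusion_reason == "sync_failure"),
    excluded_too_few_coughs = sum(qc$exclusion_reason == "too_few_coughs"),
    included_sessions = sum(qc$included))
}

#' Load sessions listed in a manifest
#'
#' Reads every annotator label track and device detection log referenced
#' by a manifest into the session-list shape [analyze_sessions()] expects.
#'
#' @param manifest A `session_manifest` ([read_manifest()]) or a path to
#'   one.
#' @return List of session objects.
#' @export
load_sessions <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(manifest, function(m) {
    labels <- do.call(rbind, lapply(m$annotators, read_label_track))
    class(labels) <- c("cough_labels", "data.frame")
    detections <- lapply(m$devices, read_detections)
    names(detections) <- vapply(seq_along(detections), function(d) {
      ids <- unique(detections[[d]]$device_id)
      if (length(ids) == 1L) ids else sprintf("device%d", d)
    }, "")
    list(session_id = m$session_id, participant_id = m$participant_id,
         duration = m$duration, labels = labels, detections = detections)
  })
}

#' Run the evaluation pipeline and write the report bundle
#'
#' End-to-end driver: loads the sessions from `config$manifest` (or takes
#' them pre-loaded), runs [analyze_sessions()], and writes the report
#' bundle under `config$out_dir`: clock offsets, session QC, the evaluable
#' per-second dataset, contingency tables, pooled metrics with exact
#' intervals, per-session metrics and five-number summaries, per-minute
#' rate segments with correlation/linear-fit/Bland-Altman results, an
#' exclusion flow chart in text form, and a machine-readable JSON of all
#' metrics stamped with the seed and a hash of the configuration.
#'
#' @param config A [run_config()] or path to a YAML file of its fields.
#' @param sessions Optional pre-loaded session list (overrides
#'   `config$manifest`).
#' @return The `cough_evaluation`, invisibly.
#' @export
run_pipeline <- function(config, sessions = NULL) {
  if (is.character(config)) {
    fields <- yaml::read_yaml(config)
    if (!is.null(fields$grid)) fields$grid <- as.numeric(unlist(fields$grid))
    config <- do.call(run_config, fields)
  }
  stopifnot(inherits(config, "run_config"))
  if (is.null(sessions)) {
    if (is.null(config$manifest)) {
      stop("config names no manifest and no sessions were supplied",
           call. = FALSE)
    }
    sessions <- load_sessions(config$manifest)
  }
  ev <- analyze_sessions(sessions, config)
  write_report_bundle(ev, config)
  invisible(ev)
}

write_report_bundle <- function(ev, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
  }
  wcsv(ev$offsets, "offsets.csv")
  wcsv(ev$qc, "session_qc.csv")
  wcsv(ev$seconds, "analysis_seconds.csv")
  wcsv(ev$metrics, "pooled_metrics.csv")
  wcsv(ev$per_session, "per_session_metrics.csv")
  wcsv(ev$summary, "metric_summary.csv")
  wcsv(ev$rate_segments, "rate_segments.csv")
  wcsv(ev$agreement, "agreement.csv")
  flow <- ev$exclusion_flow
  writeLines(c(
    sprintf("sessions recorded:              %d", flow["total_sessions"]),
    sprintf("  excluded, unsynchronizable:   %d",
            flow["excluded_sync_failure"]),
    sprintf("  excluded, <%d unanimous coughs: %d", config$qc_min_coughs,
            flow["excluded_too_few_coughs"]),
    sprintf("sessions analyzed:              %d", flow["included_sessions"])
  ), file.path(out, "exclusion_flow.txt"))
  cfg <- config
  cfg$manifest <- NULL  # paths are machine-specific; hash covers parameters
  cfg$out_dir <- NULL
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  tf <- tempfile(); writeLines(cfg_yaml, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  payload <- list(
    seed = config$seed, config_hash = cfg_hash,
    config = unclass(cfg),
    exclusion_flow = as.list(flow),
    pooled_metrics = ev$metrics,
    metric_summary = ev$summary,
    agreement = ev$agreement,
    bland_altman = ev$bland_altman
  )
  jsonlite::write_json(payload, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.cough_evaluation <- function(x, ...) {
  flow <- x$exclusion_flow
  cat("Cough monitor evaluation\n")
  cat(sprintf("  sessions: %d analyzed of %d (%d sync failures, %d below cough quality bar)\n",
              flow["included_sessions"], flow["total_sessions"],
              flow["excluded_sync_failure"], flow["excluded_too_few_coughs"]))
  for (i in seq_len(nrow(x$metrics))) {
    m <- x$metrics[i, ]
    cat(sprintf("  %s: sensitivity %.1f%% (%.1f-%.1f), specificity %.1f%% (%.1f-%.1f) [tp=%d fp=%d fn=%d tn=%d]\n",
                m$device_id, 100 * m$sensitivity, 100 * m$sens_lower,
                100 * m$sens_upper, 100 * m$specificity,
                100 * m$spec_lower, 100 * m$spec_upper,
                m$tp, m$fp, m$fn, m$tn))
  }
  pooled <- x$agreement[x$agreement$device_id == "pooled", ]
  cat(sprintf("  rate agreement (pooled): r = %.3f, intercept %.3f, slope %.3f over %d minute segments\n",
              pooled$pearson_r, pooled$intercept, pooled$slope,
              pooled$n_segments))
  cat(sprintf("  Bland-Altman: bias %.1f%%, LoA [%.1f%%, %.1f%%] over %d segments\n",
              x$bland_altman$mean_pct_error, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper, x$bland_altman$n_segments_used))
  invisible(x)
}
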