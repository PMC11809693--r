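#' Detector parameters for the session simulator
#'
#' The simulated detector is parameterized at its operating point:
#' `p_detect_cough` is the probability that a cough yields a detection at
#' or above the score threshold, so it is directly the sensitivity the
#' evaluation pipeline should recover. Scores for counting detections are
#' drawn from the cough-class Beta truncated to `[threshold, 1]`; sounds
#' the detector "heard" but scored below threshold appear in the log with
#' scores truncated below the threshold, so the threshold is exercised
#' from both sides.
#'
#' @param p_detect_cough Probability a cough becomes an at-threshold
#'   detection (default 0.92).
#' @param p_detect_other Probability a non-cough solicited sound becomes a
#'   false at-threshold detection (default 0.007).
#' @param spurious_rate False at-threshold detections per minute of
#'   silence (Poisson; default 0.1).
#' @param p_subthreshold Probability a non-detected sound still appears in
#'   the log with a below-threshold score (default 0.3).
#' @param score_given_cough,score_given_noncough `c(shape1, shape2)` of
#'   the Beta score distributions by class (defaults Beta(8,1) and
#'   Beta(1,6)).
#' @param score_threshold Classification threshold (default 0.85).
#' @param clock_offset_range Range the true device clock offset is drawn
#'   from, seconds (default c(-30, 30)); detector time + offset =
#'   annotation time.
#' @param time_jitter_sd SD of the detection timestamp noise, seconds
#'   (default 0.1).
#' @return Named list of detector parameters.
#' @export
detector_params <- function(p_detect_cough = 0.92, p_detect_other = 0.007,
                            spurious_rate = 0.1, p_subthreshold = 0.3,
                            score_given_cough = c(8, 1),
                            score_given_noncough = c(1, 6),
                            score_threshold = 0.85,
                            clock_offset_range = c(-30, 30),
                            time_jitter_sd = 0.1) {
  stopifnot(p_detect_cough >= 0, p_detect_cough <= 1,
            p_detect_other >= 0, p_detect_other <= 1,
            spurious_rate >= 0, p_subthreshold >= 0, p_subthreshold <= 1,
            all(score_given_cough > 0), all(score_given_noncough > 0),
            score_threshold > 0, score_threshold < 1,
            clock_offset_range[2] >= clock_offset_range[1],
            time_jitter_sd >= 0)
  as.list(environment())
}

#' Annotator parameters for the session simulator
#'
#' Each of the three annotators assigns a tier (0--3) to every solicited
#' sound by drawing from a per-kind confusion row. Typical subjects
#' produce coughs that are almost always rated 3 by everyone; atypical
#' subjects (whose solicited coughs do not sound like coughs) use a much
#' flatter cough row, which is what drives sessions below the
#' 10-unanimous-cough quality bar.
#'
#' @param perfect If `TRUE`, annotators always assign tier 3 to coughs and
#'   0 to everything else, with no timing jitter.
#' @param confusion 4-column matrix (tiers 0..3), one row per sound kind
#'   (`cough`, `sneeze`, `throat_clear`, `word`); rows sum to 1.
#' @param atypical_cough_row Replacement cough row for atypical subjects.
#' @param time_jitter Half-width of the uniform annotation-time jitter in
#'   seconds (default 0.05).
#' @param disagreement_rate Probability that a cough's labels are forced
#'   to fail unanimity (one random annotator assigns tier 1 or 2, the
#'   others 3); used by [degrade_annotators()].
#' @return Named list of annotator parameters.
#' @export
annotator_params <- function(perfect = FALSE, confusion = NULL,
                             atypical_cough_row = c(0.15, 0.20, 0.30, 0.35),
                             time_jitter = 0.05, disagreement_rate = 0) {
  if (is.null(confusion)) {
    confusion <- rbind(
      cough        = c(0.01, 0.01, 0.02, 0.96),
      sneeze       = c(0.97, 0.03, 0.00, 0.00),
      throat_clear = c(0.96, 0.03, 0.01, 0.00),
      word         = c(0.99, 0.01, 0.00, 0.00)
    )
  }
  if (perfect) {
    confusion <- rbind(
      cough        = c(0, 0, 0, 1),
      sneeze       = c(1, 0, 0, 0),
      throat_clear = c(1, 0, 0, 0),
      word         = c(1, 0, 0, 0)
    )
    atypical_cough_row <- c(0, 0, 0, 1)
    time_jitter <- 0
  }
  colnames(confusion) <- paste0("tier", 0:3)
  stopifnot(all(abs(rowSums(confusion) - 1) < 1e-9),
            all(confusion >= 0),
            abs(sum(atypical_cough_row) - 1) < 1e-9,
            time_jitter >= 0,
            disagreement_rate >= 0, disagreement_rate <= 1)
  list(perfect = perfect, confusion = confusion,
       atypical_cough_row = atypical_cough_row, time_jitter = time_jitter,
       disagreement_rate = disagreement_rate)
}

#' Simulation parameters for a solicited-sound study cohort
#'
#' Defaults emulate the acquisition setting of a solicited-cough
#' validation study: 49 ten-minute sessions, two devices per session,
#' scripts of 46 isolated sounds plus a text passage (20 coughs total),
#' roughly one in five subjects producing atypical coughs and a small
#' fraction of sessions with too few detections to synchronize.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_sessions Number of sessions (default 49).
#' @param session_duration Session length in seconds (default 600).
#' @param n_devices Devices recording each session (default 2).
#' @param composition Script composition
#'   ([default_script_composition()]).
#' @param detector [detector_params()].
#' @param annotator [annotator_params()].
#' @param p_atypical_subject Probability a subject's coughs are atypical
#'   (default 10/49).
#' @param p_degenerate_session Probability a session's detectors record
#'   almost nothing, making synchronization fail (default 2/49).
#' @return Named list of class `simulator_params`.
#' @export
simulator_params <- function(seed = 1L, n_sessions = 49L,
                             session_duration = 600,
                             n_devices = 2L,
                             composition = default_script_composition(),
                             detector = detector_params(),
                             annotator = annotator_params(),
                             p_atypical_subject = 10 / 49,
                             p_degenerate_session = 2 / 49) {
  stopifnot(n_sessions >= 1, session_duration > 0, n_devices >= 1,
            p_atypical_subject >= 0, p_atypical_subject <= 1,
            p_degenerate_session >= 0, p_degenerate_session <= 1)
  structure(as.list(environment()), class = "simulator_params")
}

#' Inject annotator disagreement into simulation parameters
#'
#' Returns parameters under which a stated fraction of coughs fail
#' unanimity: for each cough, with probability `disagreement_rate` one
#' randomly chosen annotator assigns tier 1 or 2 while the others assign
#' 3; all other labeling is perfect. Sessions whose unanimous-cough count
#' drops below the quality bar are then excluded downstream.
#'
#' @param params A `simulator_params`.
#' @param disagreement_rate Fraction of coughs failing unanimity, in
#'   \[0,1\].
#' @return Modified `simulator_params`.
#' @export
degrade_annotators <- function(params, disagreement_rate) {
  stopifnot(inherits(params, "simulator_params"),
            disagreement_rate >= 0, disagreement_rate <= 1)
  params$annotator <- annotator_params(perfect = TRUE,
                                       disagreement_rate = disagreement_rate)
  params$p_atypical_subject <- 0
  params
}

# Run code with the global RNG state saved and restored afterwards, so
# seeded simulation never leaks into the caller's random stream.
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Beta(a, b) draws truncated to [lo, hi] by inverse-CDF sampling.
rbeta_trunc <- function(n, shape, lo = 0, hi = 1) {
  p <- stats::pbeta(c(lo, hi), shape[1], shape[2])
  stats::qbeta(stats::runif(n, p[1], p[2]), shape[1], shape[2])
}

# Schedule one session's true events from a script: a short lead-in, then
# each instruction after its planned gap, with up-to-1 s human jitter.
# Embedded passage coughs land 15 s and 40 s into the passage.
schedule_events <- function(script, duration, lead_in = 10) {
  t <- lead_in
  time <- numeric(0); kind <- character(0); embedded <- logical(0)
  for (k in seq_len(nrow(script))) {
    t <- t + script$gap_s[k]
    if (script$kind[k] == "text_passage") {
      for (off in c(15, 40)) {
        time <- c(time, t + off + stats::runif(1))
        kind <- c(kind, "cough")
        embedded <- c(embedded, TRUE)
      }
      t <- t + script$duration_s[k]
    } else {
      time <- c(time, t + stats::runif(1))
      kind <- c(kind, script$kind[k])
      embedded <- c(embedded, FALSE)
      t <- t + script$duration_s[k]
    }
  }
  if (t > duration) {
    stop("session duration ", duration, " s too short for script (needs ",
         ceiling(t), " s)", call. = FALSE)
  }
  data.frame(event = seq_along(time), time = time, kind = kind,
             is_cough = kind == "cough", embedded = embedded,
             stringsAsFactors = FALSE)
}

# Draw one annotator's tier for each event.
draw_tiers <- function(events, ann, atypical) {
  vapply(seq_len(nrow(events)), function(i) {
    kind <- events$kind[i]
    row <- if (kind == "cough" && atypical) ann$atypical_cough_row
           else ann$confusion[kind, ]
    sample(0:3, 1L, prob = row)
  }, integer(1))
}

# Simulate one session: true events, three annotator label tracks, one
# detection log per device, and the ground truth. Uses the current RNG
# stream (callers seed it).
simulate_session <- function(params, session_id, participant_id,
                             script_version) {
  det <- params$detector
  ann <- params$annotator
  script <- generate_script(script_version, params$composition)
  events <- schedule_events(script, params$session_duration)
  n_ev <- nrow(events)

  atypical <- !ann$perfect && stats::runif(1) < params$p_atypical_subject
  degenerate <- stats::runif(1) < params$p_degenerate_session

  # annotator tiers: 3 x n_events
  tiers <- sapply(1:3, function(a) draw_tiers(events, ann, atypical))
  if (ann$disagreement_rate > 0) {
    coughs <- which(events$is_cough)
    for (i in coughs) {
      if (stats::runif(1) < ann$disagreement_rate) {
        tiers[i, ] <- 3L
        tiers[i, sample.int(3L, 1L)] <- sample(1:2, 1L)
      }
    }
  }
  labels <- do.call(rbind, lapply(1:3, function(a) {
    jit <- if (ann$time_jitter > 0)
      stats::runif(n_ev, -ann$time_jitter, ann$time_jitter) else 0
    t0 <- pmax(0, events$time + jit)
    data.frame(annotator_id = sprintf("%s_annotator%d", session_id, a),
               start = t0, end = t0, tier = as.integer(tiers[, a]),
               raw_text = as.character(tiers[, a]),
               stringsAsFactors = FALSE)
  }))
  labels <- labels[order(labels$annotator_id, labels$start), , drop = FALSE]
  rownames(labels) <- NULL
  class(labels) <- c("cough_labels", "data.frame")

  p_dc <- if (degenerate) 0.02 else det$p_detect_cough
  p_do <- if (degenerate) 0 else det$p_detect_other
  sp_rate <- if (degenerate) 0 else det$spurious_rate

  detections <- list(); offsets <- numeric(0)
  outcomes <- list()
  for (d in seq_len(params$n_devices)) {
    dev_id <- sprintf("%s_phone%d", session_id, d)
    offset <- stats::runif(1, det$clock_offset_range[1],
                           det$clock_offset_range[2])
    p_hit <- ifelse(events$is_cough, p_dc, p_do)
    hit <- stats::runif(n_ev) < p_hit
    sub <- !hit & stats::runif(n_ev) < det$p_subthreshold
    score <- rep(NA_real_, n_ev)
    cls <- ifelse(events$is_cough, "cough", "other")
    for (who in c("cough", "other")) {
      shape <- if (who == "cough") det$score_given_cough
               else det$score_given_noncough
      sel <- hit & cls == who
      score[sel] <- rbeta_trunc(sum(sel), shape, det$score_threshold, 1)
      sel <- sub & cls == who
      score[sel] <- rbeta_trunc(sum(sel), shape, 0, det$score_threshold)
    }
    emitted <- hit | sub
    t_det <- events$time[emitted] +
      stats::rnorm(sum(emitted), 0, det$time_jitter_sd)
    s_det <- score[emitted]
    n_spur <- stats::rpois(1, sp_rate * params$session_duration / 60)
    if (n_spur > 0) {
      t_det <- c(t_det, stats::runif(n_spur, 0, params$session_duration))
      s_det <- c(s_det, rbeta_trunc(n_spur, det$score_given_noncough,
                                    det$score_threshold, 1))
    }
    df <- data.frame(device_id = dev_id,
                     timestamp = t_det - offset, score = pmin(1, pmax(0, s_det)),
                     stringsAsFactors = FALSE)
    df <- df[order(df$timestamp), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("cough_detections", "data.frame")
    detections[[dev_id]] <- df
    offsets[dev_id] <- offset
    outcomes[[dev_id]] <- data.frame(
      device_id = dev_id, event = events$event,
      outcome = ifelse(hit, "detected", ifelse(sub, "subthreshold", "none")),
      stringsAsFactors = FALSE)
  }

  list(
    session_id = session_id, participant_id = participant_id,
    script_version = script_version, duration = params$session_duration,
    labels = labels, detections = detections,
    ground_truth = list(
      events = events, tiers = tiers, atypical = atypical,
      degenerate = degenerate, offsets = offsets,
      event_outcomes = do.call(rbind, outcomes)
    )
  )
}

#' Simulate a complete solicited-sound study cohort
#'
#' Generates every artifact the evaluation pipeline consumes: per session,
#' three annotator label tracks, one detection log per device (with an
#' unknown clock offset), and the ground truth that produced them. With
#' `dir` set, files are written in exactly the formats the readers expect
#' (label tracks, detection logs, a YAML manifest, and ground-truth CSVs),
#' byte-identically for a given seed.
#'
#' @param params A `simulator_params`.
#' @param dir Optional output directory; created if needed.
#' @return List of class `simulated_cohort`: `sessions` (list as produced
#'   per session: labels, detections, ground truth), `params`, and — when
#'   `dir` is given — `manifest_path`.
#' @export
simulate_cohort <- function(params = simulator_params(), dir = NULL) {
  stopifnot(inherits(params, "simulator_params"))
  sessions <- with_preserved_seed({
    set.seed(params$seed)
    lapply(seq_len(params$n_sessions), function(i) {
      simulate_session(params,
                       session_id = sprintf("s%02d", i),
                       participant_id = sprintf("p%02d", i),
                       script_version = sample.int(5L, 1L))
    })
  })
  names(sessions) <- vapply(sessions, `[[`, "", "session_id")
  out <- structure(list(sessions = sessions, params = params),
                   class = "simulated_cohort")
  if (!is.null(dir)) {
    out$manifest_path <- write_cohort(out, dir)
  }
  out
}

#' Write a simulated cohort to disk in pipeline input formats
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory.
#' @return Path to the written manifest, invisibly usable by
#'   [read_manifest()].
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$sessions, function(s) {
    ann_files <- vapply(1:3, function(a) {
      f <- sprintf("%s_annotator%d.txt", s$session_id, a)
      aid <- sprintf("%s_annotator%d", s$session_id, a)
      write_label_track(
        s$labels[s$labels$annotator_id == aid, , drop = FALSE],
        file.path(dir, f))
      f
    }, "")
    dev_files <- vapply(names(s$detections), function(dv) {
      f <- sprintf("%s.csv", dv)
      write_detections(s$detections[[dv]], file.path(dir, f))
      f
    }, "")
    list(session_id = s$session_id, participant_id = s$participant_id,
         script_version = s$script_version, duration = s$duration,
         annotators = as.list(unname(ann_files)),
         devices = as.list(unname(dev_files)))
  })
  manifest <- file.path(dir, "manifest.yaml")
  write_manifest(entries, manifest)
  truth <- do.call(rbind, lapply(cohort$sessions, function(s) {
    ev <- s$ground_truth$events
    ev$session_id <- s$session_id
    ev
  }))
  utils::write.csv(truth, file.path(dir, "true_events_synthetic.csv"),
                   row.names = FALSE)
  offs <- do.call(rbind, lapply(cohort$sessions, function(s) {
    data.frame(session_id = s$session_id,
               device_id = names(s$ground_truth$offsets),
               offset = unname(s$ground_truth$offsets),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(offs, file.path(dir, "true_offsets_synthetic.csv"),
                   row.names = FALSE)
  manifest
}
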