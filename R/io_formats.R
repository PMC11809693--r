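#' Read an annotation label track
#'
#' Parses a tab-separated label-track text file as exported by common audio
#' editors: one label per line, `start<TAB>end<TAB>text`. Times are seconds
#' from the recording origin. Lines beginning with a backslash (the
#' frequency-range continuation dialect some exports append) are skipped.
#' The annotation tier is the first integer token found in the label text
#' and must lie in 0--3 (0 = definitely not a cough, 1 = disputable,
#' 2 = definite but distant/muffled, 3 = definite cough).
#'
#' @param path Path to a label-track text file.
#' @param annotator_id Identifier recorded on every returned label;
#'   defaults to the file name without extension.
#' @return A data frame of class `cough_labels` with columns
#'   `annotator_id`, `start`, `end`, `tier`, `raw_text`, sorted by `start`.
#'   Point labels have `end == start`; interval labels `end > start`.
#' @export
read_label_track <- function(path, annotator_id = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("label track file does not exist: ", path, call. = FALSE)
  }
  if (is.null(annotator_id)) {
    annotator_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "\\") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_labels(annotator_id))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop("malformed label line ", bad, " in ", path,
         ": expected at least 3 tab-separated fields", call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  end   <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  text  <- vapply(parts, `[[`, "", 3L)
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end < start)
  if (length(bad) > 0L) {
    stop("malformed label line ", lineno[bad[1L]], " in ", path,
         ": invalid start/end times", call. = FALSE)
  }
  tier <- parse_tier(text)
  bad <- which(is.na(tier))
  if (length(bad) > 0L) {
    stop("label line ", lineno[bad[1L]], " in ", path,
         ": no tier 0-3 found in label text ", dQuote(text[bad[1L]]),
         call. = FALSE)
  }
  out <- data.frame(
    annotator_id = annotator_id, start = start, end = end,
    tier = tier, raw_text = text, stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cough_labels", "data.frame")
  out
}

empty_labels <- function(annotator_id = character(0)) {
  out <- data.frame(
    annotator_id = character(0), start = numeric(0), end = numeric(0),
    tier = integer(0), raw_text = character(0), stringsAsFactors = FALSE
  )
  class(out) <- c("cough_labels", "data.frame")
  out
}

# First integer token in the label text; NA if absent or outside 0-3.
parse_tier <- function(text) {
  m <- regmatches(text, regexpr("-?[0-9]+", text))
  tier <- rep(NA_integer_, length(text))
  has <- regexpr("-?[0-9]+", text) > 0L
  val <- suppressWarnings(as.integer(m))
  tier[has] <- val
  tier[!is.na(tier) & (tier < 0L | tier > 3L)] <- NA_integer_
  tier
}

#' Write an annotation label track
#'
#' Inverse of [read_label_track()]: writes tab-separated
#' `start<TAB>end<TAB>text` lines with times in 6-decimal fixed point, so
#' that reading the file back reproduces the labels up to that formatting.
#'
#' @param labels A label data frame as returned by [read_label_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(labels, path) {
  validate_labels(labels)
  lines <- sprintf("%.6f\t%.6f\t%s", labels$start, labels$end, labels$raw_text)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

validate_labels <- function(labels) {
  stopifnot(is.data.frame(labels))
  req <- c("annotator_id", "start", "end", "tier", "raw_text")
  missing <- setdiff(req, names(labels))
  if (length(missing) > 0L) {
    stop("labels missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(labels) > 0L) {
    stopifnot(all(labels$end >= labels$start), all(labels$start >= 0),
              all(labels$tier %in% 0:3))
  }
  invisible(labels)
}

#' Read a detector event log
#'
#' Reads a delimited text log with header `device_id,timestamp,score`: one
#' row per detected explosive sound, `timestamp` in seconds on the device
#' clock and `score` the classifier's cough prediction score in \[0,1\].
#' Events are sorted by timestamp after ingestion.
#'
#' @param path Path to the log file.
#' @return A data frame of class `cough_detections` with columns
#'   `device_id`, `timestamp`, `score`, sorted by `timestamp`.
#' @export
read_detections <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("detection log does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("device_id", "timestamp", "score")
  if (!all(req %in% names(df))) {
    stop("detection log ", path, " must have header: ",
         paste(req, collapse = ","), call. = FALSE)
  }
  df <- df[req]
  df$device_id <- as.character(df$device_id)
  if (nrow(df) > 0L) {
    if (any(!is.finite(df$timestamp))) {
      stop("non-numeric timestamp in ", path, call. = FALSE)
    }
    bad <- which(!is.finite(df$score) | df$score < 0 | df$score > 1)
    if (length(bad) > 0L) {
      stop("score outside [0,1] at record ", bad[1L], " in ", path,
           call. = FALSE)
    }
    df <- df[order(df$timestamp), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("cough_detections", "data.frame")
  df
}

#' Write a detector event log
#'
#' @param detections A data frame with `device_id`, `timestamp`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  stopifnot(all(c("device_id", "timestamp", "score") %in% names(detections)))
  if (nrow(detections) > 0L) {
    stopifnot(all(detections$score >= 0), all(detections$score <= 1))
  }
  df <- data.frame(
    device_id = detections$device_id,
    timestamp = sprintf("%.6f", detections$timestamp),
    score = sprintf("%.6f", detections$score),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session manifest
#'
#' A manifest is a YAML file listing recording sessions. Each session entry
#' carries `session_id`, `participant_id`, `script_version` (1--5),
#' `duration` (seconds), exactly three `annotators` (paths to label-track
#' files) and at least one `devices` entry (paths to detection logs).
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the YAML manifest.
#' @return A list of class `session_manifest`: one element per session.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest does not exist: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$sessions)) {
    stop("manifest has no 'sessions' entry: ", path, call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  sessions <- lapply(raw$sessions, function(s) {
    req <- c("session_id", "participant_id", "script_version", "duration",
             "annotators", "devices")
    missing <- setdiff(req, names(s))
    if (length(missing) > 0L) {
      stop("manifest session missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (length(s$annotators) != 3L) {
      stop("session ", s$session_id, ": exactly three annotator files are ",
           "required (three-listener consensus), got ", length(s$annotators),
           call. = FALSE)
    }
    if (length(s$devices) < 1L) {
      stop("session ", s$session_id, ": at least one device log required",
           call. = FALSE)
    }
    stopifnot(s$duration > 0, s$script_version %in% 1:5)
    s$annotators <- resolve_paths(unlist(s$annotators), base)
    s$devices <- resolve_paths(unlist(s$devices), base)
    s
  })
  names(sessions) <- vapply(sessions, function(s) as.character(s$session_id), "")
  structure(sessions, class = "session_manifest")
}

resolve_paths <- function(paths, base) {
  ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
}

#' Write a session manifest
#'
#' @param sessions A `session_manifest` or plain list of session entries.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sessions, path) {
  yaml::write_yaml(list(sessions = unname(unclass(sessions))), path)
  invisible(path)
}
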