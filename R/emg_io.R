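#' Construct and validate a multichannel sEMG recording
#'
#' A recording is an `n_samples x 10` numeric matrix in microvolts plus
#' acquisition metadata. Channels are stored in the canonical montage
#' order (see [canonical_channels()]); a recording built from permuted
#' columns is re-ordered on construction. Time is in seconds, 0-based
#' from the first sample; windows are half-open `[start_s, end_s)` and
#' the sample index of time `t` is `floor(t * fs)`.
#'
#' @param samples Numeric matrix, one column per channel, column names
#'   must be the 10 montage labels (any order).
#' @param fs Sampling rate in Hz (> 0); acquisition default is 1500.
#' @param notch_flags Logical vector (length 10 or named subset) marking
#'   channels that showed 50 Hz contamination and must be notch filtered.
#' @param subject_id Opaque subject identifier.
#' @param session `"test"` or `"retest"`.
#' @param require_baseline_window If `TRUE` (default) the recording must
#'   be at least 3 s long so a quiet-baseline window exists.
#' @return An object of class `emg_recording` with elements `samples`
#'   (canonically ordered), `fs`, `channels`, `notch_flags`,
#'   `subject_id`, `session`.
#' @export
emg_recording <- function(samples, fs = 1500, notch_flags = NULL,
                          subject_id = "anonymous", session = "test",
                          require_baseline_window = TRUE) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  canon <- canonical_channels()
  labs <- colnames(samples)
  if (is.null(labs)) {
    stop("samples must carry channel labels as column names", call. = FALSE)
  }
  missing_ch <- setdiff(canon, labs)
  if (length(missing_ch) > 0L) {
    stop("montage error: missing channel(s) ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  dup <- labs[duplicated(labs)]
  if (length(dup) > 0L) {
    stop("montage error: duplicated channel(s) ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(labs, canon)
  if (length(extra) > 0L) {
    stop("montage error: unknown channel(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  samples <- samples[, canon, drop = FALSE]
  if (!all(is.finite(samples))) {
    stop("recording contains non-finite sample values", call. = FALSE)
  }
  if (require_baseline_window && nrow(samples) < fs * 3) {
    stop("recording shorter than 3 s: no baseline window exists",
         call. = FALSE)
  }
  if (is.null(notch_flags)) {
    notch_flags <- stats::setNames(rep(FALSE, 10L), canon)
  } else {
    if (is.null(names(notch_flags))) {
      if (length(notch_flags) != 10L) {
        stop("unnamed notch_flags must have length 10", call. = FALSE)
      }
      notch_flags <- stats::setNames(as.logical(notch_flags), labs)[canon]
    } else {
      full <- stats::setNames(rep(FALSE, 10L), canon)
      bad <- setdiff(names(notch_flags), canon)
      if (length(bad) > 0L) {
        stop("notch_flags name(s) not in montage: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      full[names(notch_flags)] <- as.logical(notch_flags)
      notch_flags <- full
    }
  }
  session <- match.arg(session, c("test", "retest"))
  structure(
    list(samples = samples, fs = fs, channels = canon,
         notch_flags = notch_flags, subject_id = as.character(subject_id),
         session = session),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s (%s): %d samples x %d channels, %.4g s @ %g Hz\n",
              x$subject_id, x$session, nrow(x$samples), ncol(x$samples),
              recording_duration(x), x$fs))
  if (any(x$notch_flags)) {
    cat("  notch-flagged:", paste(names(which(x$notch_flags)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `emg_recording`.
#' @return Numeric scalar, `n_samples / fs`.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Read a recording from a delimited signal file plus JSON sidecar
#'
#' The signal file is comma-delimited UTF-8 with a header row of channel
#' labels (`"TA_r"`, ... in any order); the sidecar is a flat JSON object
#' with keys `fs`, `notch_flags` (named by channel), `subject_id`,
#' `session`. Columns are re-ordered to the canonical montage on read.
#'
#' @param signal_path Path to the CSV signal table.
#' @param sidecar_path Path to the JSON sidecar; defaults to the signal
#'   path with extension `.json`.
#' @return An `emg_recording`.
#' @export
read_recording <- function(signal_path,
                           sidecar_path = sub("\\.[^.]+$", ".json", signal_path)) {
  df <- utils::read.csv(signal_path, check.names = FALSE)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop("parse error in '", names(df)[j], "' at data row ", bad,
           ": non-numeric value", call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  emg_recording(
    samples = as.matrix(df),
    fs = as.numeric(meta$fs %||% 1500),
    notch_flags = if (!is.null(meta$notch_flags)) unlist(meta$notch_flags),
    subject_id = meta$subject_id %||% "anonymous",
    session = meta$session %||% "test"
  )
}

#' Write a recording to a delimited signal file plus JSON sidecar
#'
#' Inverse of [read_recording()]; numeric samples are written at full
#' precision so a read-back round trip reproduces the values.
#'
#' @param rec An `emg_recording`.
#' @param signal_path Output CSV path.
#' @param sidecar_path Output JSON path (default: signal path with
#'   `.json` extension).
#' @return Invisibly, `signal_path`.
#' @export
write_recording <- function(rec, signal_path,
                            sidecar_path = sub("\\.[^.]+$", ".json", signal_path)) {
  stopifnot(inherits(rec, "emg_recording"))
  utils::write.csv(as.data.frame(rec$samples), signal_path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, notch_flags = as.list(rec$notch_flags),
         subject_id = rec$subject_id, session = rec$session),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(signal_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct and validate an event table
#'
#' Events delimit the three repetitions of each joint task. Each task must
#' have exactly 3 non-overlapping, ordered repetitions; windows are
#' half-open `[start_s, end_s)`.
#'
#' @param df Data frame with columns `task`, `repetition`, `start_s`,
#'   `end_s`.
#' @param duration_s Optional recording duration; when given, windows must
#'   lie inside `[0, duration_s]`.
#' @return A validated data frame of class `event_table`, sorted by
#'   `(task, repetition)`.
#' @export
event_table <- function(df, duration_s = NULL) {
  need <- c("task", "repetition", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("event table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$task, df$repetition), need, drop = FALSE]
  rownames(df) <- NULL
  bad_task <- setdiff(unique(df$task), all_tasks())
  if (length(bad_task) > 0L) {
    stop("unknown task(s): ", paste(bad_task, collapse = ", "), call. = FALSE)
  }
  if (any(df$end_s <= df$start_s)) {
    stop("validation error: empty or inverted event window(s)", call. = FALSE)
  }
  if (!is.null(duration_s) && (any(df$start_s < 0) || any(df$end_s > duration_s))) {
    stop("event window outside the recording", call. = FALSE)
  }
  for (tk in unique(df$task)) {
    sub <- df[df$task == tk, ]
    if (nrow(sub) != 3L || !identical(sort(sub$repetition), 1:3)) {
      stop("completeness error: task '", tk,
           "' does not have exactly repetitions 1..3", call. = FALSE)
    }
    if (any(sub$start_s[-1] < sub$end_s[-3])) {
      stop("ordering error: overlapping repetitions in task '", tk, "'",
           call. = FALSE)
    }
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read an event table from CSV
#'
#' @param path CSV with columns `task`, `repetition`, `start_s`, `end_s`.
#' @param duration_s Optional recording duration for bounds checking.
#' @return An `event_table`.
#' @export
read_events <- function(path, duration_s = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$repetition <- as.integer(df$repetition)
  event_table(df, duration_s = duration_s)
}

#' Write an event table to CSV
#' @param events An `event_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Construct and validate an artifact table
#'
#' Artifact segments are either global (`scope = "all"`, excised from the
#' time axis) or scoped to one channel (that channel's overlapping
#' repetitions are excluded from RMS averaging).
#'
#' @param df Data frame with columns `start_s`, `end_s`, `scope`,
#'   `reason` (reason optional).
#' @param duration_s Optional recording duration for bounds checking.
#' @return A data frame of class `artifact_table` sorted by `start_s`.
#' @export
artifact_table <- function(df, duration_s = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     scope = character(0), reason = character(0))
    class(df) <- c("artifact_table", "data.frame")
    return(df)
  }
  if (!all(c("start_s", "end_s", "scope") %in% names(df))) {
    stop("artifact table needs columns start_s, end_s, scope", call. = FALSE)
  }
  if (is.null(df$reason)) df$reason <- ""
  df <- df[order(df$start_s), c("start_s", "end_s", "scope", "reason")]
  rownames(df) <- NULL
  if (any(df$end_s <= df$start_s)) {
    stop("validation error: empty or inverted artifact window(s)", call. = FALSE)
  }
  if (!is.null(duration_s) && (any(df$start_s < 0) || any(df$end_s > duration_s))) {
    stop("artifact window outside the recording", call. = FALSE)
  }
  bad <- setdiff(unique(df$scope), c("all", canonical_channels()))
  if (length(bad) > 0L) {
    stop("artifact scope must be 'all' or a montage channel; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("artifact_table", "data.frame")
  df
}

#' Read an artifact table from CSV
#' @inheritParams read_events
#' @return An `artifact_table`.
#' @export
read_artifacts <- function(path, duration_s = NULL) {
  artifact_table(utils::read.csv(path, stringsAsFactors = FALSE),
                 duration_s = duration_s)
}

score_table_columns <- function() {
  c("subject_id", "session", "group", "affected_side",
    paste0("si_", all_tasks()), "si_leg_r", "si_leg_l", "si_total")
}

#' Validate a per-subject score table
#'
#' One row per subject and session: the 8 per-task similarity indices,
#' the two leg means, the overall mean, plus grouping metadata and
#' (optionally) ordinal clinical joint scores in columns
#' `scale_<joint>_<side>` (values 0, 1, 2 or missing).
#'
#' @param df Data frame holding at least `subject_id`, `session`, `group`
#'   and the SI columns (`si_<task>`, `si_leg_r`, `si_leg_l`, `si_total`).
#' @return A data frame of class `score_table` with a stable column order.
#' @export
score_table <- function(df) {
  cols <- score_table_columns()
  if (is.null(df$affected_side)) df$affected_side <- NA_character_
  miss <- setdiff(setdiff(cols, "affected_side"), names(df))
  if (length(miss) > 0L && nrow(df) > 0L) {
    stop("score table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), cols)
  extra <- extra[order(extra)]
  scale_cols <- grep("^scale_", extra, value = TRUE)
  if (nrow(df) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    out <- df[, c(cols, scale_cols), drop = FALSE]
    si_cols <- grep("^si_", cols, value = TRUE)
    si_vals <- unlist(out[si_cols])
    if (any(!is.na(si_vals) & (si_vals < 0 | si_vals > 1))) {
      stop("validation error: SI values must lie in [0, 1] or be missing",
           call. = FALSE)
    }
    if (length(scale_cols) > 0L) {
      sc <- unlist(out[scale_cols])
      if (any(!is.na(sc) & !(sc %in% 0:2))) {
        stop("validation error: clinical joint scores must be 0, 1, 2 or missing",
             call. = FALSE)
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Write a score table to CSV
#'
#' Columns are emitted in the stable canonical order so the file
#' round-trips through [read_scores()] unchanged.
#'
#' @param scores A `score_table` (or coercible data frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  scores <- score_table(as.data.frame(scores))
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Read a score table from CSV
#' @param path CSV written by [write_scores()].
#' @return A `score_table`.
#' @export
read_scores <- function(path) {
  score_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
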