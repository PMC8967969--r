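#' Build the 10-muscle response vector of one joint task
#'
#' For each channel, the RMS is computed over each of the task's three
#' repetition windows, the channel's background-activity estimate is
#' subtracted (floored at 0), and the corrected values are averaged over
#' the usable repetitions (repetitions lost to channel-scoped artifacts
#' are dropped per channel).
#'
#' @param rec A preprocessed `emg_recording`.
#' @param events An [event_table()].
#' @param task Task identifier, e.g. `"ankle_r"`.
#' @param baseline A [estimate_baseline()] profile, or `NULL` for no
#'   background correction.
#' @param exclusions Data frame `task`, `repetition`, `channel` as
#'   returned by [cut_artifacts()] (may be empty).
#' @return An object of class `response_vector`: list with `values`
#'   (named 10-vector of nonnegative microvolt RMS in canonical channel
#'   order), `task`, `subject_id`, `n_reps_used` (per channel).
#' @export
response_vector <- function(rec, events, task, baseline = NULL,
                            exclusions = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  parse_task(task)
  ev <- as.data.frame(events)
  ev <- ev[ev$task == task, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events for task '", task, "'", call. = FALSE)
  base <- rep(0, 10)
  if (!is.null(baseline)) {
    base <- baseline$baseline_rms[match(rec$channels, baseline$channel)]
  }
  values <- numeric(10)
  n_used <- integer(10)
  for (j in 1:10) {
    ch <- rec$channels[j]
    drop_reps <- integer(0)
    if (!is.null(exclusions) && nrow(exclusions) > 0L) {
      drop_reps <- exclusions$repetition[exclusions$task == task &
                                           exclusions$channel == ch]
    }
    use <- ev[!(ev$repetition %in% drop_reps), , drop = FALSE]
    if (nrow(use) == 0L) {
      stop("exclusion error: no usable repetition for channel ", ch,
           " in task '", task, "'", call. = FALSE)
    }
    rep_rms <- vapply(seq_len(nrow(use)), function(k) {
      window_rms(rec, use$start_s[k], use$end_s[k], j)
    }, numeric(1))
    values[j] <- mean(pmax(rep_rms - base[j], 0))
    n_used[j] <- nrow(use)
  }
  structure(list(values = stats::setNames(values, rec$channels),
                 task = task, subject_id = rec$subject_id,
                 n_reps_used = stats::setNames(n_used, rec$channels)),
            class = "response_vector")
}

rv_values <- function(rv) {
  if (inherits(rv, "response_vector") || inherits(rv, "prototype_response_vector")) {
    rv$values
  } else {
    as.numeric(rv)
  }
}

#' Euclidean magnitude of a response vector
#'
#' The square root of the sum of squares of the 10 per-muscle RMS
#' entries — the length of the vector in muscle-activation space.
#'
#' @param rv A `response_vector`, `prototype_response_vector`, or bare
#'   numeric vector of length 10.
#' @return Nonnegative scalar (microvolts).
#' @export
rv_magnitude <- function(rv) {
  v <- rv_values(rv)
  stopifnot(length(v) == 10L)
  sqrt(sum(v^2))
}

#' Prototype response vector of a reference cohort
#'
#' The elementwise arithmetic mean of the reference subjects' response
#' vectors for one task — the "normal" activation pattern the similarity
#' index compares against.
#'
#' @param rvs List of `response_vector`s for the same task (enforced),
#'   or bare numeric 10-vectors.
#' @param task Task identifier; inferred from the first element when
#'   missing.
#' @return Object of class `prototype_response_vector`: list with
#'   `values`, `task`, `n_reference`.
#' @export
prototype_response_vector <- function(rvs, task = NULL) {
  if (length(rvs) == 0L) stop("no response vectors supplied", call. = FALSE)
  tasks <- unlist(lapply(rvs, function(r) {
    if (inherits(r, "response_vector")) r$task else NULL
  }))
  if (is.null(task)) {
    if (length(tasks) == 0L) stop("task must be given for bare vectors", call. = FALSE)
    task <- tasks[1]
  }
  if (length(tasks) > 0L && !all(tasks == task)) {
    stop("response vectors from different tasks cannot be pooled", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(rvs, rv_values))
  stopifnot(ncol(mat) == 10L)
  values <- colMeans(mat)
  if (sqrt(sum(values^2)) == 0) {
    stop("degenerate reference: prototype response vector has zero magnitude",
         call. = FALSE)
  }
  structure(list(values = stats::setNames(values, canonical_channels()),
                 task = task, n_reference = nrow(mat)),
            class = "prototype_response_vector")
}

#' Similarity index between a response vector and the prototype
#'
#' The normalized scalar product (cosine) of the participant's response
#' vector and the reference prototype: `SI = (rv . prv) / (|rv| |prv|)`,
#' clamped to `[0, 1]` against round-off. Because both vectors are
#' nonnegative the cosine cannot be negative; 1 means the activation
#' pattern has the reference's direction, values near 0 mean activity is
#' concentrated in muscles silent in the reference.
#'
#' A degenerate participant vector (zero magnitude, i.e. no activity
#' above background) yields `NA` with a warning rather than 0: "no
#' activity" is not evidence of a maximally abnormal pattern.
#'
#' @param rv Participant `response_vector` (or numeric 10-vector).
#' @param prv Reference `prototype_response_vector` (or numeric
#'   10-vector); must have positive magnitude.
#' @return SI in `[0, 1]`, or `NA` for a degenerate participant vector.
#' @export
similarity_index <- function(rv, prv) {
  v <- rv_values(rv); p <- rv_values(prv)
  stopifnot(length(v) == 10L, length(p) == 10L)
  if (any(v < 0) || any(p < 0)) {
    stop("response vectors must be nonnegative", call. = FALSE)
  }
  np <- sqrt(sum(p^2))
  if (np == 0) {
    stop("degenerate reference: zero-magnitude prototype", call. = FALSE)
  }
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    warning("degenerate response vector (no activity above background): SI is NA")
    return(NA_real_)
  }
  min(max(sum(v * p) / (nv * np), 0), 1)
}

#' Aggregate per-task similarity indices to leg and total scores
#'
#' Leg means average the 4 joint SIs of one leg; the total score averages
#' all 8 task SIs. Missing task SIs propagate: under the strict default a
#' leg (or the total) is missing as soon as one of its tasks is missing;
#' `min_tasks` relaxes this to "mean over the observed tasks, provided at
#' least `min_tasks` per leg (`2 * min_tasks` for the total) are present".
#'
#' @param si Named numeric vector of per-task SIs; names are task
#'   identifiers (all 8 expected, `NA` allowed).
#' @param min_tasks Minimum observed joints per leg required to report a
#'   mean (default 4 = strict).
#' @return Object of class `si_scores`: list with `per_task`, `leg_mean`
#'   (named `r`, `l`), `total_mean`.
#' @export
aggregate_si <- function(si, min_tasks = 4L) {
  tasks <- all_tasks()
  full <- stats::setNames(rep(NA_real_, 8L), tasks)
  unknown <- setdiff(names(si), tasks)
  if (length(unknown) > 0L) {
    stop("unknown task(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  full[names(si)] <- as.numeric(si)
  mean_if <- function(x, k) {
    if (sum(!is.na(x)) >= k) mean(x, na.rm = TRUE) else NA_real_
  }
  leg <- c(r = mean_if(full[grep("_r$", tasks)], min_tasks),
           l = mean_if(full[grep("_l$", tasks)], min_tasks))
  structure(list(per_task = full, leg_mean = leg,
                 total_mean = mean_if(full, 2L * min_tasks)),
            class = "si_scores")
}

#' Decompose a response vector into target, co-activation and mirror shares
#'
#' Splits the squared magnitude of a response vector into the fraction
#' carried by (i) the task's target agonist/antagonist pair, (ii) the
#' remaining ipsilateral (off-target) muscles — co-activation — and
#' (iii) the contralateral muscles — mirror activity. The three shares
#' sum to 1 for a nonzero vector and indicate whether an impaired
#' pattern stems from co-activation, mirror activity, or both.
#'
#' @param rv A `response_vector` (or numeric 10-vector in canonical
#'   order).
#' @param task Task identifier; inferred from a `response_vector`.
#' @return Object of class `rv_decomposition`: list with `target_share`,
#'   `ipsilateral_offtarget_share`, `contralateral_share`, `task`.
#'   All `NA` (with warning) for a zero vector.
#' @export
decompose_rv <- function(rv, task = NULL) {
  v <- rv_values(rv)
  stopifnot(length(v) == 10L)
  if (is.null(task) && inherits(rv, "response_vector")) task <- rv$task
  if (is.null(task)) stop("task must be given", call. = FALSE)
  p <- parse_task(task)
  tot <- sum(v^2)
  if (tot == 0) {
    warning("degenerate response vector: decomposition is NA")
    return(structure(list(target_share = NA_real_,
                          ipsilateral_offtarget_share = NA_real_,
                          contralateral_share = NA_real_, task = task),
                     class = "rv_decomposition"))
  }
  tgt <- target_channel_index(task)
  ipsi <- setdiff(side_channel_index(p$side), tgt)
  contra <- side_channel_index(if (p$side == "r") "l" else "r")
  structure(list(
    target_share = sum(v[tgt]^2) / tot,
    ipsilateral_offtarget_share = sum(v[ipsi]^2) / tot,
    contralateral_share = sum(v[contra]^2) / tot,
    task = task), class = "rv_decomposition")
}
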