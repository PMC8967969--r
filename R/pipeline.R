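#' Run the full preprocessing chain on one recording
#'
#' High-pass filtering, selective notch filtering, artifact minimal
#' cutting, and baseline estimation, in that order.
#'
#' @param rec An `emg_recording`.
#' @param events An [event_table()].
#' @param artifacts Optional [artifact_table()].
#' @param spec A [filter_spec()].
#' @param baseline_window_s,baseline_step_s Baseline scan parameters,
#'   see [estimate_baseline()].
#' @return List with `recording`, `events`, `exclusions`, `baseline`.
#' @export
preprocess_recording <- function(rec, events, artifacts = NULL,
                                 spec = filter_spec(),
                                 baseline_window_s = 3.0,
                                 baseline_step_s = 0.1) {
  rec <- highpass(rec, spec)
  rec <- notch(rec, spec)
  if (!is.null(artifacts) && nrow(artifacts) > 0L) {
    cut <- cut_artifacts(rec, artifacts, events)
  } else {
    cut <- list(recording = rec,
                events = event_table(as.data.frame(events),
                                     duration_s = recording_duration(rec)),
                exclusions = data.frame(task = character(0),
                                        repetition = integer(0),
                                        channel = character(0)))
  }
  cut$baseline <- estimate_baseline(cut$recording,
                                    window_s = baseline_window_s,
                                    step_s = baseline_step_s)
  cut
}

#' Response vectors of every task in a preprocessed recording
#'
#' @param prep Output of [preprocess_recording()].
#' @return Named list of `response_vector`s, one per task present in
#'   the event table.
#' @export
subject_response_vectors <- function(prep) {
  tasks <- unique(as.data.frame(prep$events)$task)
  rvs <- lapply(tasks, function(tk) {
    response_vector(prep$recording, prep$events, tk,
                    baseline = prep$baseline, exclusions = prep$exclusions)
  })
  stats::setNames(rvs, tasks)
}

mirror_rv_values <- function(v) stats::setNames(v[mirror_index()],
                                                canonical_channels())

#' Build prototype response vectors from a reference cohort
#'
#' Computes each reference subject's response vectors and averages them
#' elementwise into one prototype per task. With `pool_sides = TRUE`
#' (default) the left-leg response vectors are mirrored into right-leg
#' coordinates and pooled with the right-leg ones, doubling the
#' reference data per joint; the pooled prototype is mirrored back for
#' the left-leg tasks. `pool_sides = FALSE` keeps strictly per-side
#' prototypes.
#'
#' @param subjects List of subject datasets: each a list with
#'   `recording`, `events`, optional `artifacts` (the shape returned by
#'   [generate_subject()]).
#' @param pool_sides Pool left and right legs per joint (default TRUE).
#' @param spec A [filter_spec()].
#' @param ... Passed to [preprocess_recording()].
#' @return Named list (by task) of `prototype_response_vector`s.
#' @export
build_reference <- function(subjects, pool_sides = TRUE,
                            spec = filter_spec(), ...) {
  if (length(subjects) == 0L) stop("empty reference cohort", call. = FALSE)
  rv_sets <- lapply(subjects, function(s) {
    prep <- preprocess_recording(s$recording, s$events,
                                 artifacts = s$artifacts, spec = spec, ...)
    subject_response_vectors(prep)
  })
  tasks <- all_tasks()
  prvs <- list()
  if (pool_sides) {
    for (joint in montage_joints()) {
      tr <- paste0(joint, "_r"); tl <- paste0(joint, "_l")
      vals <- list()
      for (rvs in rv_sets) {
        if (!is.null(rvs[[tr]])) vals[[length(vals) + 1L]] <- rvs[[tr]]$values
        if (!is.null(rvs[[tl]])) {
          vals[[length(vals) + 1L]] <- mirror_rv_values(rvs[[tl]]$values)
        }
      }
      if (length(vals) == 0L) next
      prv_r <- prototype_response_vector(vals, task = tr)
      prvs[[tr]] <- prv_r
      prvs[[tl]] <- structure(list(values = mirror_rv_values(prv_r$values),
                                   task = tl, n_reference = prv_r$n_reference),
                              class = "prototype_response_vector")
    }
  } else {
    for (tk in tasks) {
      vals <- lapply(rv_sets, function(rvs) rvs[[tk]])
      vals <- vals[!vapply(vals, is.null, logical(1))]
      if (length(vals) == 0L) next
      prvs[[tk]] <- prototype_response_vector(vals, task = tk)
    }
  }
  if (length(prvs) == 0L) stop("reference cohort produced no prototypes",
                               call. = FALSE)
  prvs
}

#' Write / read a prototype response vector set as CSV
#'
#' One row per task: `task`, `n_reference`, then the 10 canonical
#' channel columns. A `provenance` comment column records the cohort or
#' generator identity.
#'
#' @param prvs Named list of `prototype_response_vector`s.
#' @param path CSV path.
#' @param provenance Free-text provenance string.
#' @return `write_prvs()` returns `path` invisibly; `read_prvs()` the
#'   named list of prototypes.
#' @export
write_prvs <- function(prvs, path, provenance = "unspecified") {
  df <- do.call(rbind, lapply(prvs, function(p) {
    data.frame(task = p$task, n_reference = p$n_reference,
               as.list(p$values), provenance = provenance,
               check.names = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prvs
#' @export
read_prvs <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  prvs <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(values = stats::setNames(as.numeric(df[i, canonical_channels()]),
                                            canonical_channels()),
                   task = df$task[i], n_reference = df$n_reference[i]),
              class = "prototype_response_vector")
  })
  stats::setNames(prvs, df$task)
}

#' Score one subject against a prototype set
#'
#' Preprocesses the recording, computes per-task response vectors and
#' similarity indices, and aggregates them to leg and total means.
#' Degenerate (zero) response vectors yield missing SIs.
#'
#' @param subject Subject dataset (list with `recording`, `events`,
#'   optional `artifacts`, optional `profile`).
#' @param prvs Named list of `prototype_response_vector`s (by task).
#' @param group Group label for the score row (defaults to the profile's
#'   group when present).
#' @param affected_side `"r"`, `"l"` or `NA`: the more affected (or
#'   non-dominant) side, used by the validation battery.
#' @param min_tasks See [aggregate_si()].
#' @param ... Passed to [preprocess_recording()].
#' @return A one-row [score_table()].
#' @export
score_subject <- function(subject, prvs, group = NULL, affected_side = NA,
                          min_tasks = 4L, ...) {
  prep <- preprocess_recording(subject$recording, subject$events,
                               artifacts = subject$artifacts, ...)
  rvs <- subject_response_vectors(prep)
  si <- vapply(names(rvs), function(tk) {
    if (is.null(prvs[[tk]])) return(NA_real_)
    suppressWarnings(similarity_index(rvs[[tk]], prvs[[tk]]))
  }, numeric(1))
  agg <- aggregate_si(si, min_tasks = min_tasks)
  if (is.null(group)) {
    group <- if (!is.null(subject$profile)) subject$profile$group else "control"
  }
  row <- data.frame(subject_id = subject$recording$subject_id,
                    session = subject$recording$session,
                    group = group, affected_side = affected_side,
                    stringsAsFactors = FALSE)
  for (tk in all_tasks()) row[[paste0("si_", tk)]] <- unname(agg$per_task[tk])
  row$si_leg_r <- unname(agg$leg_mean["r"])
  row$si_leg_l <- unname(agg$leg_mean["l"])
  row$si_total <- unname(agg$total_mean)
  score_table(row)
}

#' Score a cohort of subjects
#'
#' @param cohort List of subject datasets.
#' @param prvs Prototype set.
#' @param affected_sides Optional vector of per-subject affected sides.
#' @param ... Passed to [score_subject()].
#' @return A [score_table()] with one row per subject.
#' @export
score_cohort <- function(cohort, prvs, affected_sides = NULL, ...) {
  rows <- lapply(seq_along(cohort), function(i) {
    score_subject(cohort[[i]], prvs,
                  affected_side = if (is.null(affected_sides)) NA
                                  else affected_sides[i], ...)
  })
  score_table(do.call(rbind, rows))
}

#' Run the clinimetric validation battery on score tables
#'
#' Executes whichever analysis blocks the inputs support, skipping the
#' rest with an explicit reason (never silently): Mann-Whitney
#' group-difference tests with Bonferroni control over the 11 score
#' columns; Spearman / Kendall correlations against ordinal clinical
#' joint scores when `scale_*` columns are present; Wilcoxon tests
#' between the less and more affected leg when `affected_side` is
#' labelled; ROC with Youden cutpoint for separating normal
#' (clinical score 2) from impaired joints; and the test-retest
#' reliability block (ICC(2,1), SEM, MDC95, systematic error) when a
#' retest table is supplied.
#'
#' @param scores A [score_table()] for the test session.
#' @param retest Optional [score_table()] for the retest session.
#' @param alpha Family-wise error rate (default 0.05).
#' @param roc_seed Seed for the ROC bootstrap CI.
#' @return A list of class `validation_report` with elements
#'   `group_tests`, `correlations`, `leg_comparison`, `roc`,
#'   `reliability`; skipped blocks hold a `skip` reason string.
#' @export
validate_scores <- function(scores, retest = NULL, alpha = 0.05,
                            roc_seed = 1L) {
  scores <- score_table(as.data.frame(scores))
  si_cols <- c(paste0("si_", all_tasks()), "si_leg_r", "si_leg_l", "si_total")
  report <- list()

  groups <- unique(scores$group)
  if (all(c("CP", "control") %in% groups)) {
    res <- lapply(si_cols, function(cl) {
      a <- scores[[cl]][scores$group == "CP"]
      b <- scores[[cl]][scores$group == "control"]
      if (sum(!is.na(a)) == 0 || sum(!is.na(b)) == 0) return(NULL)
      mann_whitney(a, b)
    })
    names(res) <- si_cols
    res <- res[!vapply(res, is.null, logical(1))]
    p <- vapply(res, `[[`, numeric(1), "p_value")
    bf <- bonferroni(p, alpha)
    report$group_tests <- list(tests = res, p_values = p,
                               adjusted_alpha = bf$adjusted_alpha,
                               significant = bf$significant)
  } else {
    report$group_tests <- list(skip = "needs both CP and control groups")
  }

  scale_cols <- grep("^scale_", names(scores), value = TRUE)
  if (length(scale_cols) > 0L) {
    scale_total <- rowSums(scores[scale_cols], na.rm = FALSE)
    corr <- list()
    corr$total <- tryCatch(cor_spearman(scores$si_total, scale_total),
                           error = function(e) list(skip = conditionMessage(e)))
    joint <- list()
    for (sc in scale_cols) {
      tk <- sub("^scale_", "", sc)
      si_c <- paste0("si_", tk)
      if (si_c %in% names(scores)) {
        joint[[tk]] <- tryCatch(cor_kendall_tau_b(scores[[si_c]], scores[[sc]]),
                                error = function(e) list(skip = conditionMessage(e)))
      }
    }
    report$correlations <- list(total = corr$total, per_joint = joint)

    long_si <- unlist(scores[paste0("si_", sub("^scale_", "", scale_cols))])
    long_scale <- unlist(scores[scale_cols])
    ok <- !is.na(long_si) & !is.na(long_scale)
    if (length(unique(long_scale[ok] == 2)) == 2) {
      report$roc <- roc_youden(long_si[ok], long_scale[ok] == 2,
                               seed = roc_seed)
    } else {
      report$roc <- list(skip = "needs both normal and impaired joints")
    }
  } else {
    report$correlations <- list(skip = "no clinical joint score columns")
    report$roc <- list(skip = "no clinical joint score columns")
  }

  cp <- scores[scores$group == "CP" & !is.na(scores$affected_side), ]
  if (nrow(cp) >= 3) {
    more <- ifelse(cp$affected_side == "r", cp$si_leg_r, cp$si_leg_l)
    less <- ifelse(cp$affected_side == "r", cp$si_leg_l, cp$si_leg_r)
    report$leg_comparison <- wilcoxon_signed_rank(more, less)
  } else {
    report$leg_comparison <- list(skip = "needs >= 3 CP subjects with a labelled affected side")
  }

  if (!is.null(retest)) {
    retest <- score_table(as.data.frame(retest))
    merged <- merge(scores, retest, by = "subject_id",
                    suffixes = c("_t1", "_t2"))
    rel <- lapply(si_cols, function(cl) {
      tryCatch(reliability(merged[[paste0(cl, "_t1")]],
                           merged[[paste0(cl, "_t2")]]),
               error = function(e) list(skip = conditionMessage(e)))
    })
    report$reliability <- stats::setNames(rel, si_cols)
  } else {
    report$reliability <- list(skip = "single-session input: no retest table")
  }

  class(report) <- c("validation_report", "list")
  report
}
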