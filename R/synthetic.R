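#' Uniform within-leg co-activation leakage matrix
#'
#' A 10 x 10 nonnegative matrix mapping intended activation of each
#' channel onto the others: unit diagonal, `level` on every within-leg
#' off-diagonal entry, zero across legs (contralateral spill is modelled
#' separately as mirror activity). The effective off-target gain during
#' generation is `(1 - selectivity) * level`, so with the default
#' `level = 1` the subject's selectivity is the single co-activation
#' dial.
#'
#' @param level Leakage fraction in `[0, 1]` (default 1).
#' @return 10 x 10 numeric matrix in canonical channel order.
#' @export
coactivation_matrix <- function(level = 1) {
  stopifnot(level >= 0)
  m <- diag(10)
  for (s in list(1:5, 6:10)) m[s, s][m[s, s] == 0] <- level
  dimnames(m) <- list(canonical_channels(), canonical_channels())
  m
}

#' Synthetic subject profile
#'
#' Ground-truth parameters of one simulated participant: selectivity
#' (1 = fully selective, 0 = intended activation spills fully onto the
#' within-leg off-target muscles), a co-activation leakage matrix,
#' mirror gain (fraction of each envelope copied onto the contralateral
#' homologous muscle), background-noise and mains amplitudes.
#'
#' @param selectivity Number in `[0, 1]`.
#' @param coactivation 10 x 10 leakage matrix, unit diagonal
#'   (default [coactivation_matrix()]).
#' @param mirror_gain Nonnegative contralateral leakage gain.
#' @param baseline_noise_uv Background-noise RMS per channel, microvolts
#'   (scalar or length 10; default 3).
#' @param mains_amplitude_uv 50 Hz mains peak amplitude per channel
#'   (scalar or length 10; default 0). Channels with mains are
#'   notch-flagged in the generated recording.
#' @param activation_uv Peak activation envelope amplitude of target
#'   muscles, microvolts (default 80).
#' @param group `"CP"`, `"control"` or `"reference_adult"`.
#' @param subject_id Identifier string.
#' @param seed Integer seed for this subject's noise.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(selectivity, coactivation = coactivation_matrix(),
                            mirror_gain = 0, baseline_noise_uv = 3,
                            mains_amplitude_uv = 0, activation_uv = 80,
                            group = "control", subject_id = "synth",
                            seed = 1L) {
  stopifnot(selectivity >= 0, selectivity <= 1, mirror_gain >= 0,
            activation_uv > 0)
  if (!is.matrix(coactivation) || any(dim(coactivation) != 10) ||
      any(coactivation < 0) || any(abs(diag(coactivation) - 1) > 1e-12)) {
    stop("coactivation must be a nonnegative 10 x 10 matrix with unit diagonal",
         call. = FALSE)
  }
  expand10 <- function(x) if (length(x) == 1L) rep(x, 10) else {
    stopifnot(length(x) == 10L); x
  }
  group <- match.arg(group, c("CP", "control", "reference_adult"))
  structure(list(selectivity = selectivity, coactivation = coactivation,
                 mirror_gain = mirror_gain,
                 baseline_noise_uv = expand10(baseline_noise_uv),
                 mains_amplitude_uv = expand10(mains_amplitude_uv),
                 activation_uv = activation_uv, group = group,
                 subject_id = subject_id, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Task script: timing of the 8 joint tasks
#'
#' Tasks run in the testing order knee, ankle, subtalar, hip (right leg
#' then left). Each task comprises 3 repetitions of a bidirectional
#' movement; each repetition lasts `rep_s` seconds (one second per
#' movement direction by default), separated by short pauses, with a
#' rest before the first task long enough to hold a quiet 3-s baseline
#' window.
#'
#' @param rep_s Repetition duration in seconds (default 2).
#' @param inter_rep_s Pause between repetitions (default 0.75).
#' @param inter_task_s Rest between tasks (default 1.5).
#' @param lead_in_s Initial rest (default 3.5).
#' @param tail_s Final rest (default 1).
#' @return A list of class `task_script` with the timing fields and the
#'   task order.
#' @export
task_script <- function(rep_s = 2, inter_rep_s = 0.75, inter_task_s = 1.5,
                        lead_in_s = 3.5, tail_s = 1) {
  stopifnot(rep_s > 0, inter_rep_s >= 0, inter_task_s >= 0,
            lead_in_s >= 3, tail_s >= 0)
  structure(list(tasks = all_tasks(), n_reps = 3L, rep_s = rep_s,
                 inter_rep_s = inter_rep_s, inter_task_s = inter_task_s,
                 lead_in_s = lead_in_s, tail_s = tail_s),
            class = "task_script")
}

script_events <- function(script) {
  t <- script$lead_in_s
  rows <- list()
  for (task in script$tasks) {
    for (r in seq_len(script$n_reps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, repetition = r, start_s = t, end_s = t + script$rep_s)
      t <- t + script$rep_s + if (r < script$n_reps) script$inter_rep_s else 0
    }
    t <- t + script$inter_task_s
  }
  list(events = do.call(rbind, rows), duration_s = t - script$inter_task_s + script$tail_s)
}

# Unit-RMS band-limited (30-500 Hz) Gaussian carrier, the standard
# interference-pattern surrogate for surface EMG. Synthesized in the
# frequency domain: white Gaussian noise shaped by a flat band with
# 10 Hz raised-cosine edges (much faster than time-domain filtering and
# statistically equivalent for a stationary carrier).
bandlimited_noise <- function(n, fs, band = c(30, 500)) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                   # fold to [0, fs/2]
  w <- 10                                # transition width, Hz
  hi <- min(band[2], fs / 2 * 0.98)
  ramp_up <- pmin(pmax((f - (band[1] - w / 2)) / w, 0), 1)
  ramp_dn <- pmin(pmax(((hi + w / 2) - f) / w, 0), 1)
  g <- sin(ramp_up * pi / 2)^2 * sin(ramp_dn * pi / 2)^2
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Raised-cosine bump over one movement direction (half the repetition).
half_cycle_bump <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

#' Generate one synthetic subject recording
#'
#' Each channel is envelope-modulated band-limited (30-500 Hz) Gaussian
#' noise. During a task, the joint's agonist gets a raised-cosine burst
#' in the first movement direction of every repetition and the
#' antagonist in the second; intended bursts leak onto within-leg
#' off-target channels through the co-activation matrix scaled by
#' `(1 - selectivity)`, and every channel's envelope is copied onto its
#' contralateral homologue scaled by `mirror_gain`. Background noise and
#' (optionally) 50 Hz mains are added throughout.
#'
#' @param profile A [subject_profile()].
#' @param script A [task_script()].
#' @param fs Sampling rate in Hz (default 1500).
#' @param session `"test"` or `"retest"`.
#' @param seed Noise seed; defaults to `profile$seed`.
#' @return A list: `recording` (`emg_recording`), `events`
#'   (`event_table`), `ground_truth` (data frame `task`, `channel`,
#'   `activation_rms` — the analytic noise-free activation RMS averaged
#'   over the 3 repetitions), `profile`.
#' @export
generate_subject <- function(profile, script = task_script(), fs = 1500,
                             session = "test", seed = profile$seed) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(script, "task_script"))
  set.seed(seed)
  se <- script_events(script)
  n <- ceiling(se$duration_s * fs)
  env <- matrix(0, n, 10)

  n_rep <- floor(script$rep_s * fs)
  n_half <- floor(n_rep / 2)
  bump <- half_cycle_bump(n_half)
  leak <- profile$coactivation
  off <- leak * (1 - profile$selectivity)
  diag(off) <- 1

  for (i in seq_len(nrow(se$events))) {
    task <- se$events$task[i]
    tgt <- target_channel_index(task)  # (agonist, antagonist)
    i0 <- floor(se$events$start_s[i] * fs)
    # per-direction channel gains: the agonist drives movement direction
    # 1 and the antagonist direction 2; each spreads through within-leg
    # leakage, then mirrors onto the contralateral homologues
    g1 <- profile$activation_uv * off[tgt[1], ]
    g2 <- profile$activation_uv * off[tgt[2], ]
    g1 <- g1 + profile$mirror_gain * g1[mirror_index()]
    g2 <- g2 + profile$mirror_gain * g2[mirror_index()]
    ag_idx <- i0 + seq_len(n_half)
    an_idx <- i0 + n_half + seq_len(n_half)
    env[ag_idx, ] <- env[ag_idx, ] + outer(bump, g1)
    env[an_idx, ] <- env[an_idx, ] + outer(bump, g2)
  }

  samples <- matrix(0, n, 10)
  tvec <- (seq_len(n) - 1) / fs
  for (j in 1:10) {
    x <- env[, j] * bandlimited_noise(n, fs)
    if (profile$baseline_noise_uv[j] > 0) {
      x <- x + profile$baseline_noise_uv[j] * bandlimited_noise(n, fs)
    }
    if (profile$mains_amplitude_uv[j] > 0) {
      x <- x + profile$mains_amplitude_uv[j] * sin(2 * pi * 50 * tvec)
    }
    samples[, j] <- x
  }
  colnames(samples) <- canonical_channels()

  rec <- emg_recording(samples, fs = fs,
                       notch_flags = profile$mains_amplitude_uv > 0,
                       subject_id = profile$subject_id, session = session)
  events <- event_table(se$events, duration_s = recording_duration(rec))

  gt <- expand.grid(task = script$tasks, channel = canonical_channels(),
                    stringsAsFactors = FALSE)
  gt$activation_rms <- vapply(seq_len(nrow(gt)), function(k) {
    ev <- se$events[se$events$task == gt$task[k], ]
    j <- match(gt$channel[k], canonical_channels())
    mean(vapply(seq_len(nrow(ev)), function(r) {
      i0 <- floor(ev$start_s[r] * fs) + 1L
      i1 <- floor(ev$end_s[r] * fs)
      sqrt(mean(env[i0:i1, j]^2))
    }, numeric(1)))
  }, numeric(1))

  list(recording = rec, events = events, ground_truth = gt, profile = profile)
}

#' Default group parameter distributions for synthetic cohorts
#'
#' Profile parameters are drawn uniformly from these ranges: reference
#' adults and neurologically intact children are highly selective with
#' at most trace mirror activity; the CP group spans moderate-to-poor
#' selectivity with substantial mirror activity, so cohort medians
#' separate the way impaired and intact groups do clinically.
#'
#' @return Named list of per-group ranges.
#' @export
default_group_params <- function() {
  list(
    reference_adult = list(selectivity = c(0.90, 0.99), mirror = c(0, 0.05)),
    control         = list(selectivity = c(0.85, 0.98), mirror = c(0, 0.10)),
    CP              = list(selectivity = c(0.20, 0.70), mirror = c(0.10, 0.60))
  )
}

#' Generate a reproducible synthetic cohort
#'
#' Subject seeds and profile parameters are derived deterministically
#' from the master seed, so the same call yields bit-identical data.
#'
#' @param n Number of subjects.
#' @param group `"CP"`, `"control"` or `"reference_adult"`.
#' @param seed Master seed.
#' @param group_params Parameter ranges, see [default_group_params()].
#' @param script A [task_script()].
#' @param fs Sampling rate.
#' @param session `"test"` or `"retest"`. A retest re-uses each
#'   subject's profile but draws fresh noise.
#' @param id_prefix Prefix for subject identifiers.
#' @return List of subject datasets as returned by [generate_subject()].
#' @export
generate_cohort <- function(n, group = "control", seed = 1L,
                            group_params = default_group_params(),
                            script = task_script(), fs = 1500,
                            session = "test", id_prefix = group) {
  stopifnot(n >= 1)
  gp <- group_params[[group]]
  if (is.null(gp)) stop("no parameters for group '", group, "'", call. = FALSE)
  set.seed(seed)
  sel <- stats::runif(n, gp$selectivity[1], gp$selectivity[2])
  mir <- stats::runif(n, gp$mirror[1], gp$mirror[2])
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  retest_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    prof <- subject_profile(selectivity = sel[i], mirror_gain = mir[i],
                            group = group,
                            subject_id = sprintf("%s_%03d", id_prefix, i),
                            seed = seeds[i])
    generate_subject(prof, script = script, fs = fs, session = session,
                     seed = if (session == "retest") retest_seeds[i] else seeds[i])
  })
}

#' Artifact injection specification
#'
#' @param n_artifacts Number of segments to inject.
#' @param dur_range Duration range in seconds.
#' @param scope `"all"` for global segments or a channel label.
#' @param amplitude_uv RMS amplitude of the injected transient.
#' @param avoid_full_rep If `TRUE` (default) re-draw positions that
#'   would cover an entire repetition (which would make that repetition
#'   unusable downstream).
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(n_artifacts = 1, dur_range = c(0.2, 0.5),
                          scope = "all", amplitude_uv = 2000,
                          avoid_full_rep = TRUE) {
  stopifnot(n_artifacts >= 0, dur_range[1] > 0, dur_range[2] >= dur_range[1])
  structure(list(n_artifacts = n_artifacts, dur_range = dur_range,
                 scope = scope, amplitude_uv = amplitude_uv,
                 avoid_full_rep = avoid_full_rep),
            class = "artifact_spec")
}

#' Inject large-amplitude artifact transients into a recording
#'
#' Adds band-limited high-amplitude transients (cable-contact-like
#' bursts) at random positions and returns the matching artifact table,
#' so that [cut_artifacts()] can be validated against the pristine twin
#' recording.
#'
#' @param subject A subject dataset (list with `recording`, `events`) or
#'   an `emg_recording` (then pass `events`).
#' @param spec An [artifact_spec()].
#' @param seed Integer seed.
#' @param events Event table when `subject` is a bare recording.
#' @return List with `recording` (contaminated) and `artifacts`
#'   (an [artifact_table()]).
#' @export
inject_artifacts <- function(subject, spec = artifact_spec(), seed = 1L,
                             events = NULL) {
  if (inherits(subject, "emg_recording")) {
    rec <- subject
  } else {
    rec <- subject$recording
    events <- events %||% subject$events
  }
  set.seed(seed)
  dur <- recording_duration(rec)
  fs <- rec$fs
  rows <- list()
  if (spec$n_artifacts > 0) {
    ev <- as.data.frame(events)
    for (i in seq_len(spec$n_artifacts)) {
      for (try in 1:100) {
        d <- stats::runif(1, spec$dur_range[1], spec$dur_range[2])
        s <- stats::runif(1, 0, dur - d)
        covers <- !is.null(ev) && nrow(ev) > 0 &&
          any(s <= ev$start_s & ev$end_s <= s + d)
        if (!spec$avoid_full_rep || !covers) break
      }
      i0 <- floor(s * fs) + 1L
      i1 <- min(floor((s + d) * fs), nrow(rec$samples))
      burst <- spec$amplitude_uv * bandlimited_noise(i1 - i0 + 1L, fs)
      if (identical(spec$scope, "all")) {
        rec$samples[i0:i1, ] <- rec$samples[i0:i1, ] + burst
      } else {
        j <- match(spec$scope, rec$channels)
        if (is.na(j)) stop("unknown artifact scope channel", call. = FALSE)
        rec$samples[i0:i1, j] <- rec$samples[i0:i1, j] + burst
      }
      rows[[i]] <- data.frame(start_s = s, end_s = s + d,
                              scope = spec$scope, reason = "synthetic transient")
    }
  }
  list(recording = rec,
       artifacts = artifact_table(if (length(rows)) do.call(rbind, rows) else NULL,
                                  duration_s = dur))
}
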