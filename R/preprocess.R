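#' Filter specification for the sEMG preprocessing chain
#'
#' The chain applies a linear-phase FIR high-pass (default cutoff 20 Hz)
#' to every channel, and a second-order IIR notch at the mains frequency
#' (default 50 Hz) only to channels flagged as contaminated.
#'
#' @param highpass_cutoff_hz High-pass cutoff in Hz (default 20).
#' @param fir_order FIR order, or `"auto"` for
#'   `4 * ceiling(fs / cutoff)` rounded to even — about four transition
#'   periods of the cutoff, a standard windowed-sinc sizing.
#' @param notch_freq_hz Notch centre frequency in Hz (default 50).
#' @param notch_q Notch quality factor (default 30, i.e. ~1.7 Hz
#'   bandwidth at 50 Hz).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(highpass_cutoff_hz = 20, fir_order = "auto",
                        notch_freq_hz = 50, notch_q = 30) {
  stopifnot(highpass_cutoff_hz > 0, notch_freq_hz > 0, notch_q > 0)
  if (!identical(fir_order, "auto")) {
    stopifnot(is.numeric(fir_order), fir_order > 0)
    if (fir_order %% 2 != 0) {
      stop("fir_order must be even (linear phase, integer group delay)",
           call. = FALSE)
    }
  }
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 fir_order = fir_order,
                 notch_freq_hz = notch_freq_hz,
                 notch_q = notch_q),
            class = "filter_spec")
}

resolve_fir_order <- function(spec, fs) {
  if (identical(spec$fir_order, "auto")) {
    n <- 4L * as.integer(ceiling(fs / spec$highpass_cutoff_hz))
    if (n %% 2L != 0L) n <- n + 1L
    n
  } else {
    as.integer(spec$fir_order)
  }
}

highpass_coefficients <- function(spec, fs) {
  if (spec$highpass_cutoff_hz >= fs / 2) {
    stop("high-pass cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  n <- resolve_fir_order(spec, fs)
  signal::fir1(n, spec$highpass_cutoff_hz / (fs / 2), type = "high")
}

#' Frequency response of the designed filters
#'
#' Returns the magnitude response of the high-pass FIR (single pass; the
#' filter is linear-phase so this is the gain after delay compensation)
#' or of the notch biquad as applied forward-backward (i.e. squared
#' single-pass magnitude).
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @return Numeric vector of magnitudes.
#' @export
highpass_response <- function(spec, fs, freq_hz) {
  h <- highpass_coefficients(spec, fs)
  w <- 2 * pi * freq_hz / fs
  vapply(w, function(wi) Mod(sum(h * exp(-1i * wi * (seq_along(h) - 1)))),
         numeric(1))
}

notch_coefficients <- function(spec, fs) {
  # RBJ audio-EQ biquad notch
  w0 <- 2 * pi * spec$notch_freq_hz / fs
  alpha <- sin(w0) / (2 * spec$notch_q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' @rdname highpass_response
#' @export
notch_response <- function(spec, fs, freq_hz) {
  co <- notch_coefficients(spec, fs)
  w <- 2 * pi * freq_hz / fs
  vapply(w, function(wi) {
    z <- exp(-1i * wi * (0:2))
    Mod(sum(co$b * z) / sum(co$a * z))^2  # forward-backward pass
  }, numeric(1))
}

# Zero-phase FIR filtering: reflect-pad, convolve, compensate the n/2
# group delay of the linear-phase kernel. Length-preserving.
fir_zero_phase <- function(x, h) {
  n <- length(h) - 1L
  delay <- n %/% 2L
  p <- n
  nx <- length(x)
  if (nx <= p) stop("signal too short for the FIR order", call. = FALSE)
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[nx] - rev(x[(nx - p):(nx - 1)]))
  yf <- stats::convolve(xp, rev(h), type = "open")
  yf[(p + delay + 1):(p + delay + nx)]
}

#' High-pass filter a recording
#'
#' Applies the designed linear-phase FIR high-pass identically to every
#' channel with group-delay compensation (zero net phase) and
#' antisymmetric edge padding, preserving signal length.
#'
#' @param rec An `emg_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `emg_recording`.
#' @export
highpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- resolve_fir_order(spec, rec$fs)
  if (n >= nrow(rec$samples) / 3) {
    stop("FIR order too large for this recording length", call. = FALSE)
  }
  h <- highpass_coefficients(spec, rec$fs)
  rec$samples <- apply(rec$samples, 2, fir_zero_phase, h = h)
  rec
}

#' Selectively notch-filter mains-contaminated channels
#'
#' Channels whose `notch_flags` entry is `TRUE` are filtered with the
#' second-order IIR notch applied forward-backward (zero phase);
#' unflagged channels are returned bit-identical.
#'
#' @inheritParams highpass
#' @return The `emg_recording` with flagged channels notch-filtered.
#' @export
notch <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"))
  flagged <- which(rec$notch_flags)
  if (length(flagged) == 0L) return(rec)
  co <- notch_coefficients(spec, rec$fs)
  for (j in flagged) {
    rec$samples[, j] <- signal::filtfilt(co$b, co$a, rec$samples[, j])
  }
  rec
}

#' Remove documented artifact segments (minimal cutting)
#'
#' Global segments (`scope = "all"`) are excised from the time axis of
#' all channels and every event window is shifted (and, if it straddles a
#' cut, shortened) accordingly. Channel-scoped segments do not cut the
#' time axis — the overlapped `(channel, repetition)` pairs are instead
#' marked for exclusion from later RMS averaging, keeping the
#' multichannel matrix rectangular.
#'
#' @param rec An `emg_recording`.
#' @param artifacts An [artifact_table()].
#' @param events An [event_table()].
#' @return A list with elements `recording` (cut), `events` (shifted,
#'   still valid) and `exclusions` (data frame `task`, `repetition`,
#'   `channel`).
#' @export
cut_artifacts <- function(rec, artifacts, events) {
  stopifnot(inherits(rec, "emg_recording"))
  artifacts <- artifact_table(as.data.frame(artifacts),
                              duration_s = recording_duration(rec))
  fs <- rec$fs
  nsamp <- nrow(rec$samples)
  exclusions <- data.frame(task = character(0), repetition = integer(0),
                           channel = character(0))

  ev <- as.data.frame(events)
  ev_lo <- floor(ev$start_s * fs)  # 0-based, inclusive
  ev_hi <- floor(ev$end_s * fs)    # 0-based, exclusive

  glob <- artifacts[artifacts$scope == "all", , drop = FALSE]
  chan <- artifacts[artifacts$scope != "all", , drop = FALSE]

  if (nrow(chan) > 0L) {
    for (i in seq_len(nrow(chan))) {
      a_lo <- floor(chan$start_s[i] * fs); a_hi <- floor(chan$end_s[i] * fs)
      hit <- which(ev_lo < a_hi & a_lo < ev_hi)
      if (length(hit) > 0L) {
        exclusions <- rbind(exclusions, data.frame(
          task = ev$task[hit], repetition = ev$repetition[hit],
          channel = chan$scope[i]))
      }
    }
    exclusions <- unique(exclusions)
  }

  if (nrow(glob) > 0L) {
    cut_lo <- floor(glob$start_s * fs); cut_hi <- floor(glob$end_s * fs)
    covered <- vapply(seq_along(ev_lo), function(k) {
      any(cut_lo <= ev_lo[k] & ev_hi[k] <= cut_hi)
    }, logical(1))
    if (any(covered)) {
      k <- which(covered)[1]
      stop("exclusion error: artifact covers all channels of task '",
           ev$task[k], "' repetition ", ev$repetition[k], call. = FALSE)
    }
    keep <- rep(TRUE, nsamp)
    for (i in seq_along(cut_lo)) {
      lo <- max(cut_lo[i], 0L); hi <- min(cut_hi[i], nsamp)
      if (hi > lo) keep[(lo + 1):hi] <- FALSE
    }
    removed_before <- cumsum(!keep)      # removed among indices 1..i (1-based)
    shift_idx <- function(i0) {          # 0-based index -> removed strictly before
      ifelse(i0 <= 0, 0L, removed_before[pmin(i0, nsamp)])
    }
    new_lo <- ev_lo - shift_idx(ev_lo)
    new_hi <- ev_hi - shift_idx(ev_hi)
    if (any(new_hi <= new_lo)) {
      k <- which(new_hi <= new_lo)[1]
      stop("exclusion error: artifact cutting emptied task '", ev$task[k],
           "' repetition ", ev$repetition[k], call. = FALSE)
    }
    ev$start_s <- new_lo / fs
    ev$end_s <- new_hi / fs
    rec$samples <- rec$samples[keep, , drop = FALSE]
  }

  list(recording = rec,
       events = event_table(ev, duration_s = recording_duration(rec)),
       exclusions = exclusions)
}

sliding_window_rms <- function(x, n_win, starts) {
  cs <- c(0, cumsum(x^2))
  sqrt((cs[starts + n_win] - cs[starts]) / n_win)
}

#' Locate each channel's quietest 3-second window
#'
#' Scans every channel with a sliding window (default 3 s, stride 0.1 s,
#' final window always included) and reports the minimum window RMS as
#' that channel's background-activity estimate, together with the window
#' start. The minimum over the whole measurement stands in for a rest
#' baseline, which in practice often carries more muscle activity than
#' the quietest task pauses.
#'
#' @param rec An `emg_recording` (preprocessed).
#' @param window_s Window length in seconds (default 3).
#' @param step_s Stride in seconds; set to `1/rec$fs` for an exhaustive
#'   scan (default 0.1 s, which stays within ~2% of exhaustive on
#'   smooth-envelope signals while being two orders of magnitude faster).
#' @return A data frame of class `baseline_profile` with columns
#'   `channel`, `baseline_rms`, `window_start_s`.
#' @export
estimate_baseline <- function(rec, window_s = 3.0, step_s = 0.1) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec$fs
  n <- nrow(rec$samples)
  n_win <- floor(window_s * fs)
  if (n < n_win) {
    stop("recording shorter than the baseline window", call. = FALSE)
  }
  stride <- max(1L, round(step_s * fs))
  starts <- unique(c(seq(1L, n - n_win + 1L, by = stride), n - n_win + 1L))
  out <- lapply(seq_along(rec$channels), function(j) {
    r <- sliding_window_rms(rec$samples[, j], n_win, starts)
    k <- which.min(r)
    c(baseline_rms = r[k], window_start_s = (starts[k] - 1) / fs)
  })
  df <- data.frame(channel = rec$channels,
                   baseline_rms = vapply(out, `[[`, numeric(1), "baseline_rms"),
                   window_start_s = vapply(out, `[[`, numeric(1), "window_start_s"))
  class(df) <- c("baseline_profile", "data.frame")
  df
}

#' Root-mean-square amplitude over a time window
#'
#' @param rec An `emg_recording`.
#' @param start_s,end_s Half-open window `[start_s, end_s)` in seconds.
#' @param channel Channel label or index.
#' @return RMS in microvolts.
#' @export
window_rms <- function(rec, start_s, end_s, channel) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec$fs
  if (is.character(channel)) channel <- match(channel, rec$channels)
  if (is.na(channel) || channel < 1 || channel > 10) {
    stop("unknown channel", call. = FALSE)
  }
  i0 <- floor(start_s * fs) + 1L
  i1 <- floor(end_s * fs)
  if (i0 < 1 || i1 > nrow(rec$samples)) {
    stop("window outside the recording", call. = FALSE)
  }
  if (i1 < i0) stop("empty window", call. = FALSE)
  sqrt(mean(rec$samples[i0:i1, channel]^2))
}
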