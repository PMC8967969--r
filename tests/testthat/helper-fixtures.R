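# Small in-code fixture builders and independent brute-force oracles.

# recording with every channel set to the same vector (or a per-channel
# list of vectors); short recordings allowed
const_rec <- function(x, fs = 100, per_channel = NULL) {
  if (is.null(per_channel)) per_channel <- rep(list(x), 10)
  m <- do.call(cbind, per_channel)
  colnames(m) <- canonical_channels()
  emg_recording(m, fs = fs, require_baseline_window = FALSE)
}

# events for one task: 3 reps of rep_s seconds separated by gap_s
one_task_events <- function(task = "ankle_r", start = 0, rep_s = 1,
                            gap_s = 0.5) {
  t0 <- start + (0:2) * (rep_s + gap_s)
  event_table(data.frame(task = task, repetition = 1:3,
                         start_s = t0, end_s = t0 + rep_s))
}

# full 8-task event grid (24 rows)
full_events <- function(rep_s = 1, gap_s = 0.5, task_gap_s = 1) {
  rows <- list(); t <- 0
  for (tk in all_tasks()) {
    for (r in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(task = tk, repetition = r,
                                              start_s = t, end_s = t + rep_s)
      t <- t + rep_s + gap_s
    }
    t <- t + task_gap_s
  }
  event_table(do.call(rbind, rows))
}

flat_baseline <- function(value = 0) {
  data.frame(channel = canonical_channels(), baseline_rms = value,
             window_start_s = 0)
}

# --- independent oracles -------------------------------------------------

tau_b_oracle <- function(x, y) {
  n <- length(x); conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx * sy > 0) conc <- conc + 1 else if (sx * sy < 0) disc <- disc + 1
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

icc21_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  msr <- k * sum((rowMeans(m) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - g)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, u_of)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# exact two-sided Wilcoxon signed-rank p by full sign-flip enumeration
wsr_enum_oracle <- function(pre, post) {
  d <- post - pre
  nz <- d[d != 0]
  r <- rank(abs(nz))
  v_obs <- sum(r[nz > 0])
  n <- length(nz)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(v_all <= v_obs + eps), mean(v_all >= v_obs - eps)))
}
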