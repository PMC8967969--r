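#' Rank correlations for ordinal validity analyses
#'
#' `cor_spearman()` computes Spearman's rho (Pearson correlation of
#' midranks) with a two-sided p-value, exact for small tie-free samples.
#' `cor_kendall_tau_b()` computes Kendall's tau-b, which corrects the
#' denominator for ties and is therefore suited to few-level ordinal
#' scores; its two-sided p-value uses the tie-adjusted normal
#' approximation when ties are present.
#'
#' @param x,y Paired numeric vectors (pairs with missing values are
#'   dropped); at least 3 complete pairs, neither variable constant.
#' @return A list of class `correlation_result`: `method`, `estimate`,
#'   `p_value`, `n`.
#' @export
cor_spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(method = "spearman_rho", estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = n),
            class = "correlation_result")
}

#' @rdname cor_spearman
#' @export
cor_kendall_tau_b <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined correlation: all pairs tied in one variable", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  structure(list(method = "kendall_tau_b", estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = n),
            class = "correlation_result")
}

#' Non-parametric group-difference tests
#'
#' `mann_whitney()` compares two independent samples via the
#' Mann-Whitney U statistic on midranks; `wilcoxon_signed_rank()`
#' compares paired samples, dropping zero differences (classic Wilcoxon
#' rule). Exact two-sided p-values are used for small tie-free samples
#' (`n1 * n2 <= 400` for Mann-Whitney, `n <= 12` nonzero differences for
#' Wilcoxon); otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param a,b Independent samples (Mann-Whitney).
#' @param pre,post Paired samples (Wilcoxon).
#' @return A list of class `group_test_result`: `method`, `statistic`
#'   (U, resp. V = sum of positive signed ranks), `p_value`, `n`
#'   (per-group sizes, resp. effective pair count).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty group", call. = FALSE)
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(method = "mann_whitney_u", statistic = unname(wt$statistic),
                 p_value = wt$p.value, n = c(n_a = length(a), n_b = length(b))),
            class = "group_test_result")
}

#' @rdname mann_whitney
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  ok <- stats::complete.cases(pre, post)
  d <- post[ok] - pre[ok]
  if (length(d) == 0L) stop("no complete pairs", call. = FALSE)
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero: degenerate test, p = 1")
    return(structure(list(method = "wilcoxon_signed_rank", statistic = 0,
                          p_value = 1, n = c(n_pairs = 0L)),
                     class = "group_test_result"))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  n_eff <- length(nz)
  if (n_eff <= 12) {
    # exact two-sided p by full sign-flip enumeration; midranks make
    # this valid with tied |differences|, where the classic
    # signed-rank distribution does not apply
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n_eff)))
    v_all <- as.vector(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(v_all <= v + eps), mean(v_all >= v - eps)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(post[ok], pre[ok], paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  structure(list(method = "wilcoxon_signed_rank", statistic = v,
                 p_value = p, n = c(n_pairs = n_eff)),
            class = "group_test_result")
}

#' ROC analysis with Youden-index cutpoint
#'
#' Builds the empirical ROC curve for separating "normal" from
#' "impaired" observations by a score where higher means more normal
#' (classification rule: `score >= cutoff` is called normal). The AUC is
#' the trapezoidal area under the empirical curve (equal to the
#' midrank Mann-Whitney U divided by `n1 * n2`); the reported cutoff
#' maximizes the Youden index J = sensitivity + specificity - 1, ties
#' resolved in favour of the higher sensitivity. The 95% AUC confidence
#' interval is a stratified percentile bootstrap.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) vector, `TRUE` = normal.
#' @param n_boot Bootstrap resamples for the AUC CI (default 2000; 0
#'   disables the CI).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list of class `roc_result`: `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   `n` (named: normal, impaired).
#' @export
roc_youden <- function(scores, labels, n_boot = 2000, seed = NULL) {
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  pos <- scores[labels]    # normal
  neg <- scores[!labels]   # impaired
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  emp_auc <- function(pos, neg) {
    thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
    tpr <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
    fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1)))
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  auc <- emp_auc(pos, neg)

  cand <- sort(unique(scores))  # ascending: later = higher cutoff
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]  # highest sensitivity among ties

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old_seed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    boot <- vapply(seq_len(n_boot), function(i) {
      emp_auc(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  }
  structure(list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
                 cutoff = cand[best], sensitivity = sens[best],
                 specificity = spec[best], youden_j = j[best],
                 n = c(normal = length(pos), impaired = length(neg))),
            class = "roc_result")
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measurement
#'
#' Decomposes an `n x k` score matrix (subjects by sessions) by two-way
#' ANOVA into subject, session and residual mean squares and computes
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' with the F-based 95% confidence interval for single-measure absolute
#' agreement. Variance components are reported (negative estimates
#' clamped to 0 with a warning).
#'
#' @param scores Numeric matrix, rows = subjects (n >= 3), columns =
#'   sessions/raters (k >= 2), complete.
#' @param conf_level Confidence level for the ICC interval (default
#'   0.95).
#' @return A list of class `icc_result`: `icc`, `icc_ci_low`,
#'   `icc_ci_high`, `ms` (MSR, MSC, MSE), `var_components` (subject,
#'   trial, error), `n`, `k`.
#' @export
icc_2_1 <- function(scores, conf_level = 0.95) {
  scores <- as.matrix(scores)
  if (any(is.na(scores))) stop("score matrix must be complete", call. = FALSE)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 sessions", call. = FALSE)

  df <- data.frame(value = as.vector(scores),
                   subject = factor(rep(seq_len(n), times = k)),
                   session = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ subject + session, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]

  if (stats::var(as.vector(scores)) == 0) {
    warning("zero total variance: ICC undefined")
    icc <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # McGraw & Wong F-based interval for single-measure absolute agreement
    alpha <- 1 - conf_level
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }

  vc <- c(subject = (msr - mse) / k,
          trial = (msc - mse) / n,
          error = mse)
  if (any(vc < 0)) {
    warning("negative variance component estimate clamped to 0")
    vc <- pmax(vc, 0)
  }
  structure(list(icc = icc, icc_ci_low = ci[1], icc_ci_high = ci[2],
                 ms = c(MSR = msr, MSC = msc, MSE = mse),
                 var_components = vc, n = n, k = k),
            class = "icc_result")
}

#' Standard error of measurement and minimal detectable change
#'
#' `SEM = sqrt(sigma_trial^2 + sigma_error^2)` from the trial (session)
#' and residual variance components of the two-way ANOVA, and
#' `MDC95 = SEM * sqrt(2) * 1.96` — the smallest change exceeding
#' measurement noise of a test-retest pair at 95% confidence.
#'
#' @param var_trial Trial/session variance component (or an
#'   `icc_result`, from which both components are taken).
#' @param var_error Residual variance component.
#' @return List with `sem` and `mdc95` (score units).
#' @export
sem_mdc <- function(var_trial, var_error = NULL) {
  if (inherits(var_trial, "icc_result")) {
    vc <- var_trial$var_components
    var_trial <- vc[["trial"]]; var_error <- vc[["error"]]
  }
  if (var_trial < 0 || var_error < 0) {
    warning("negative variance component clamped to 0")
    var_trial <- max(var_trial, 0); var_error <- max(var_error, 0)
  }
  sem <- sqrt(var_trial + var_error)
  list(sem = sem, mdc95 = sem * sqrt(2) * 1.96)
}

#' Test-retest reliability battery for one score column
#'
#' Combines ICC(2,1) with its confidence interval, SEM and MDC95, and a
#' Wilcoxon signed-rank test for systematic error between sessions.
#'
#' @param test,retest Paired score vectors (pairs with missing values
#'   dropped).
#' @param sem_method `"trial_error"` (default): SEM from the trial and
#'   residual variance components; `"sd_icc"`: the alternative
#'   `SD * sqrt(1 - ICC)` form.
#' @return A list of class `reliability_result`: `icc`, `icc_ci_low`,
#'   `icc_ci_high`, `sem`, `mdc95`, `systematic_p`, `n`,
#'   `var_components`.
#' @export
reliability <- function(test, retest, sem_method = c("trial_error", "sd_icc")) {
  sem_method <- match.arg(sem_method)
  ok <- stats::complete.cases(test, retest)
  m <- cbind(test[ok], retest[ok])
  ic <- icc_2_1(m)
  if (sem_method == "trial_error") {
    sm <- sem_mdc(ic)
  } else {
    sem <- stats::sd(as.vector(m)) * sqrt(1 - ic$icc)
    sm <- list(sem = sem, mdc95 = sem * sqrt(2) * 1.96)
  }
  sys <- wilcoxon_signed_rank(m[, 1], m[, 2])
  structure(list(icc = ic$icc, icc_ci_low = ic$icc_ci_low,
                 icc_ci_high = ic$icc_ci_high,
                 sem = sm$sem, mdc95 = sm$mdc95,
                 systematic_p = sys$p_value, n = nrow(m),
                 var_components = ic$var_components),
            class = "reliability_result")
}

#' Bonferroni correction for a family of tests
#'
#' @param p_values Numeric vector of p-values (length m >= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `adjusted_alpha` (`alpha / m`) and `significant`
#'   (logical flags, `p < alpha / m`).
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  stopifnot(m >= 1)
  adj <- alpha / m
  list(adjusted_alpha = adj, significant = !is.na(p_values) & p_values < adj)
}
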