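test_that("response vectors average baseline-corrected repetition RMS", {
  # rep RMS 4, 6, 8 with baseline 1 -> (3 + 5 + 7) / 3 = 5
  amp <- rep(0, 600)
  amp[101:200] <- 4; amp[251:350] <- 6; amp[401:500] <- 8
  rec <- const_rec(amp)
  ev <- one_task_events(start = 1, rep_s = 1, gap_s = 0.5)
  rv <- response_vector(rec, ev, "ankle_r", baseline = flat_baseline(1))
  expect_equal(unname(rv$values["TA_r"]), 5.0)
  expect_s3_class(rv, "response_vector")
  expect_equal(unname(rv$n_reps_used["TA_r"]), 3L)

  # baseline above all repetition RMS floors the entry at 0
  rv0 <- response_vector(rec, ev, "ankle_r", baseline = flat_baseline(10))
  expect_equal(unname(rv0$values["TA_r"]), 0)

  # all repetitions excluded for a channel is an error
  excl <- data.frame(task = "ankle_r", repetition = 1:3, channel = "TA_r")
  expect_error(response_vector(rec, ev, "ankle_r", exclusions = excl),
               "no usable repetition")
})

test_that("magnitude is the Euclidean norm", {
  expect_equal(rv_magnitude(rep(0, 10)), 0)
  expect_equal(rv_magnitude(c(3, 4, rep(0, 8))), 5)
  set.seed(31)
  for (i in 1:20) {
    v <- runif(10, 0, 50)
    expect_equal(rv_magnitude(v), sqrt(sum(v^2)))
  }
})

test_that("prototype response vectors are elementwise means", {
  v <- c(2, rep(0, 9)); w <- c(0, 2, rep(0, 8))
  prv <- prototype_response_vector(list(v, w), task = "hip_r")
  expect_equal(unname(prv$values), c(1, 1, rep(0, 8)))
  expect_equal(prv$n_reference, 2L)

  prv1 <- prototype_response_vector(list(v, v, v), task = "hip_r")
  expect_equal(unname(prv1$values), v)

  set.seed(32)
  rvs <- lapply(1:31, function(i) runif(10, 0, 40))
  prv31 <- prototype_response_vector(rvs, task = "knee_l")
  mat <- do.call(rbind, rvs)
  for (j in 1:10) expect_equal(unname(prv31$values[j]), mean(mat[, j]))

  expect_error(prototype_response_vector(list(), task = "hip_r"), "no response")
  expect_error(prototype_response_vector(list(rep(0, 10)), task = "hip_r"),
               "degenerate reference")
})

test_that("similarity index is the clamped cosine with degenerate handling", {
  prv <- c(5, 1, 0.5, 4, 0.5, rep(0.2, 5))
  expect_equal(similarity_index(prv, prv), 1.0)
  expect_equal(similarity_index(3.7 * prv, prv), 1.0)  # scale invariance
  # disjoint supports are orthogonal
  expect_equal(similarity_index(c(rep(0, 5), rep(1, 5)), c(rep(1, 5), rep(0, 5))), 0)

  set.seed(33)
  for (i in 1:50) {
    v <- runif(10); p <- runif(10)
    expect_equal(similarity_index(v, p),
                 sum(v * p) / (sqrt(sum(v^2)) * sqrt(sum(p^2))),
                 tolerance = 1e-14)
  }

  expect_warning(si <- similarity_index(rep(0, 10), prv), "degenerate")
  expect_true(is.na(si))
  expect_error(similarity_index(prv, rep(0, 10)), "degenerate reference")
  expect_error(similarity_index(-prv, prv), "nonnegative")
})

test_that("SI is within [0,1] and decreases when off-reference mass is added", {
  set.seed(34)
  for (i in 1:30) {
    v <- runif(10) * rbinom(10, 1, 0.7)
    p <- runif(10) * rbinom(10, 1, 0.7)
    if (sum(v) == 0 || sum(p) == 0) next
    si <- similarity_index(v, p)
    expect_gte(si, 0); expect_lte(si, 1)
    expect_equal(si, similarity_index(v * runif(1, 0.01, 100), p))
  }
  # monotonicity: starting from rv = prv, adding mass where prv is 0
  # strictly decreases SI, for every such channel
  prv <- c(4, 2, 0, 1, 0, 3, 0, 0.5, 0, 0)
  for (j in which(prv == 0)) {
    v <- prv; v[j] <- 1
    expect_lt(similarity_index(v, prv), 1)
  }
})

test_that("aggregation produces leg and total means with strict missingness", {
  si <- stats::setNames(rep(1, 8), all_tasks())
  agg <- aggregate_si(si)
  expect_equal(unname(agg$leg_mean), c(1, 1))
  expect_equal(agg$total_mean, 1)

  si2 <- si
  si2[c("hip_r", "knee_r", "ankle_r", "STJ_r")] <- c(0.77, 0.79, 0.91, 0.85)
  expect_equal(unname(aggregate_si(si2)$leg_mean["r"]), 0.83)

  # permutation invariance within a leg
  si3 <- si2
  si3[c("hip_r", "knee_r", "ankle_r", "STJ_r")] <- c(0.91, 0.85, 0.77, 0.79)
  expect_equal(aggregate_si(si3)$leg_mean, aggregate_si(si2)$leg_mean)

  si4 <- si2; si4["knee_r"] <- NA
  agg4 <- aggregate_si(si4)
  expect_true(is.na(agg4$leg_mean["r"]))
  expect_false(is.na(agg4$leg_mean["l"]))
  expect_true(is.na(agg4$total_mean))
  # relaxed coverage rule
  agg5 <- aggregate_si(si4, min_tasks = 3)
  expect_equal(unname(agg5$leg_mean["r"]), mean(c(0.77, 0.91, 0.85)))
})

test_that("decomposition splits squared magnitude into three shares", {
  # activity only in the target pair
  v <- rep(0, 10); v[target_channel_index("ankle_r")] <- c(3, 4)
  d <- decompose_rv(v, "ankle_r")
  expect_equal(d$target_share, 1)
  expect_equal(d$ipsilateral_offtarget_share, 0)
  expect_equal(d$contralateral_share, 0)

  # equal RMS everywhere: contralateral 5 of 10 equal squares
  d2 <- decompose_rv(rep(2, 10), "knee_l")
  expect_equal(d2$contralateral_share, 0.5)
  expect_equal(d2$target_share, 0.2)
  expect_equal(d2$ipsilateral_offtarget_share, 0.3)

  set.seed(35)
  for (i in 1:20) {
    v <- runif(10, 0, 30)
    task <- sample(all_tasks(), 1)
    d3 <- decompose_rv(v, task)
    tgt <- target_channel_index(task)
    expect_equal(d3$target_share, sum(v[tgt]^2) / sum(v^2))
    expect_equal(d3$target_share + d3$ipsilateral_offtarget_share +
                   d3$contralateral_share, 1, tolerance = 1e-12)
  }

  expect_warning(dz <- decompose_rv(rep(0, 10), "hip_r"), "degenerate")
  expect_true(is.na(dz$target_share))
})
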