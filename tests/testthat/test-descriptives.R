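test_that("confidence reclassification is total and order-preserving", {
  expect_identical(reclassify_confidence(c(1, 2, 3, 4)),
                   c("not_confident", "not_confident", "confident",
                     "confident"))
  expect_identical(reclassify_confidence(NA_integer_), NA_character_)
  expect_error(reclassify_confidence(0), "1..4")
  expect_error(reclassify_confidence(5), "1..4")
  # order preserved: the confident set is exactly the upper half of the scale
  lv <- reclassify_confidence(1:4)
  expect_true(all(which(lv == "confident") > which(lv == "not_confident")))
})

# hand-built trial set for the exclusion and mean-confidence rules
make_participant_trials <- function(id, n_famous = 20, n_catch = 10,
                                    recall_k, correct_k) {
  # recall_k famous trials recalled; of the famous recall failures, the first
  # correct_k get an accurate recognition response
  fam_cond <- rep(c("correct_name", "incorrect_name"), length.out = n_famous)
  cond <- c(fam_cond, rep("catch", n_catch))
  n <- length(cond)
  recalled <- c(rep(TRUE, recall_k), rep(FALSE, n_famous - recall_k),
                rep(FALSE, n_catch))
  failed_fam <- which(!recalled & cond != "catch")
  resp <- rep(NA_character_, n)
  resp[!recalled] <- "incorrect"
  acc_target <- failed_fam[seq_len(correct_k)]
  resp[acc_target] <- ifelse(cond[acc_target] == "correct_name",
                             "correct", "incorrect")
  resp[setdiff(failed_fam, acc_target)] <-
    ifelse(cond[setdiff(failed_fam, acc_target)] == "correct_name",
           "incorrect", "correct")
  acc <- ifelse(cond == "catch" | recalled, NA,
                ifelse(cond == "correct_name", resp == "correct",
                       resp == "incorrect"))
  tibble::tibble(
    participant_id = id, session = 1L, block = 1L, trial = seq_len(n),
    condition = cond, recalled = recalled,
    tot = ifelse(recalled, NA, rep(c("yes", "no"), length.out = n)),
    fok = ifelse(recalled, NA, rep(c("high", "low"), length.out = n)),
    recog_response = resp,
    recog_accurate = acc,
    confidence4 = ifelse(recalled, NA_integer_,
                         rep(1:4, length.out = n)))
}

test_that("exclusion rules use strict thresholds on the famous trials", {
  trials <- dplyr::bind_rows(
    make_participant_trials("hi_recall", recall_k = 17, correct_k = 3),  # 85%
    make_participant_trials("lo_recog", recall_k = 0, correct_k = 10),   # 50%
    make_participant_trials("boundary", recall_k = 16, correct_k = 3),   # 80%, 75%
    make_participant_trials("ok", recall_k = 4, correct_k = 12))
  ex <- apply_exclusions(trials)
  expect_identical(ex$reason[ex$participant_id == "hi_recall"], "recall")
  expect_identical(ex$reason[ex$participant_id == "lo_recog"], "recognition")
  expect_false(ex$excluded[ex$participant_id == "boundary"])  # exactly 80%
  expect_false(ex$excluded[ex$participant_id == "ok"])
  # participant at exactly 51% accuracy is retained (strict "less than")
  t51 <- make_participant_trials("at51", n_famous = 100, recall_k = 0,
                                 correct_k = 51)
  expect_false(apply_exclusions(t51)$excluded)
  # idempotent: re-applying to the retained set changes nothing
  kept <- dplyr::filter(trials,
                        participant_id %in% ex$participant_id[!ex$excluded])
  ex2 <- apply_exclusions(kept)
  expect_false(any(ex2$excluded))
})

test_that("state mean confidence averages the raw scale per state", {
  trials <- make_participant_trials("p1", recall_k = 0, correct_k = 10)
  # overwrite to a hand-computable pattern: tot yes -> {4, 3}, no -> {1, 2}
  trials <- trials[1:4, ]
  trials$tot <- c("yes", "yes", "no", "no")
  trials$fok <- c("high", "high", "low", "low")
  trials$confidence4 <- c(4L, 3L, 1L, 2L)
  sm <- state_mean_confidence(trials, "tot")
  expect_equal(sm$mean_present, 3.5)
  expect_equal(sm$mean_absent, 1.5)
  # catch trials enter the means by default and can be switched off
  tc <- make_participant_trials("p2", recall_k = 0, correct_k = 10)
  with_catch <- state_mean_confidence(tc, "tot")
  without <- state_mean_confidence(tc, "tot", include_catch = FALSE)
  expect_equal(with_catch$n_present + with_catch$n_absent, 30)
  expect_equal(without$n_present + without$n_absent, 20)
  # all-equal confidences: equal means
  te <- dplyr::mutate(tc, confidence4 = ifelse(recalled, NA_integer_, 2L))
  sm2 <- state_mean_confidence(te, "fok")
  expect_equal(sm2$mean_present, sm2$mean_absent)
})

test_that("Friedman test matches closed forms and reference implementations", {
  # complete separation, n = 10, k = 2: chi2 = n, p from the chi2(1) tail
  m <- cbind(a = 2:11, b = 1:10)
  res <- friedman_test(m)
  expect_equal(res$statistic, 10)
  expect_identical(res$df, 1L)
  expect_lt(abs(res$p.value - 0.001565), 1e-6)
  expect_equal(res$p.value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # all values identical: defined degenerate case
  res0 <- friedman_test(matrix(3, 5, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  # invariance under strictly monotone transformation
  set.seed(3)
  m2 <- matrix(rnorm(24), 8, 3)
  expect_equal(friedman_test(m2)$statistic,
               friedman_test(exp(m2))$statistic, tolerance = 1e-12)
  # agreement with stats::friedman.test, tie-free and with ties
  for (s in 1:5) {
    set.seed(s)
    m3 <- matrix(rnorm(21), 7, 3)
    ref <- stats::friedman.test(m3)
    expect_equal(friedman_test(m3)$statistic, unname(ref$statistic),
                 tolerance = 1e-10)
    m4 <- matrix(sample(1:3, 24, replace = TRUE), 8, 3)  # heavy ties
    if (stats::sd(m4) > 0 && is.finite(stats::friedman.test(m4)$statistic))
      expect_equal(friedman_test(m4)$statistic,
                   unname(stats::friedman.test(m4)$statistic),
                   tolerance = 1e-10)
  }
  # exact k = 2 sign-pattern closed form: chi2 = (sum of signs)^2 / n
  for (s in 1:10) {
    set.seed(100 + s)
    m5 <- matrix(rnorm(12), 6, 2)
    expect_equal(friedman_test(m5)$statistic, friedman_k2_exact(m5),
                 tolerance = 1e-10)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(friedman_test(matrix(1:3, 3, 1)), "at least 2")
})

test_that("confidence_by_state bundles means, summary and test coherently", {
  cfg <- study_config(n_participants = 8, trials_per_condition = 30, seed = 91)
  st <- generate_study(cfg)
  out <- confidence_by_state(st$trials, "tot")
  expect_equal(nrow(out$means), 8)
  expect_identical(out$test$df, 1L)
  # in the generating model confident responses track |x| beyond criteria and
  # state-present trials have higher evidence, so present-mean must dominate
  expect_gt(out$summary$mean[out$summary$state == "present"],
            out$summary$mean[out$summary$state == "absent"])
})
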