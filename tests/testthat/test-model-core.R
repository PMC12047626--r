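test_that("participant covariance follows the scaling convention", {
  expect_equal(participant_covariance(0, 2, 0.5), diag(2))
  expect_equal(participant_covariance(0.5, 2, 0.5),
               matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(participant_covariance(0, 1, 0.5), diag(c(2, 2)))
  # general case: variances 1/(kappa lambda), 1/(kappa (1 - lambda))
  S <- participant_covariance(-0.3, 4, 0.25)
  expect_equal(diag(S), c(1, 1 / 3), tolerance = 1e-12)
  expect_equal(S[1, 2], -0.3 * sqrt(1 / 3), tolerance = 1e-12)
  # out-of-range parameters name the offender
  expect_error(participant_covariance(1.2, 2, 0.5), "rho")
  expect_error(participant_covariance(0, -1, 0.5), "kappa")
  expect_error(participant_covariance(0, 2, 1), "lambda")
})

test_that("cell probabilities match univariate products under independence", {
  g <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
  # catch at the origin, unit participant variances, c_y = 0, c_x = (-1, 1)
  p <- participant_params("p1", 2, 0.5, 0, -1, 1)
  cp <- cell_probabilities(g, p, "catch")
  expect_equal(cp$prob[cp$metacog == "present" & cp$confcat == "conf_correct"],
               0.5 * (1 - pnorm(1)), tolerance = 1e-9)
  # correct-name at (1, 1), c_y = 0.5
  p2 <- participant_params("p1", 2, 0.5, 0.5, -1, 1)
  cp2 <- cell_probabilities(g, p2, "correct_name")
  expect_equal(cp2$prob[cp2$metacog == "present" & cp2$confcat == "conf_correct"],
               (1 - pnorm(-0.5)) * (1 - pnorm(0)), tolerance = 1e-9)
  # with rho = 0 every cell is a product of interval probabilities
  xs <- c(-Inf, -1, 1, Inf); ys <- c(-Inf, 0.5, Inf)
  for (s in c("correct_name", "incorrect_name", "catch")) {
    row <- g[g$stimulus == s, ]
    cp3 <- cell_probabilities(g, p2, s)
    for (i in 1:2) for (j in 1:3) {
      want <- (pnorm(ys[i + 1] - row$mu_y) - pnorm(ys[i] - row$mu_y)) *
        (pnorm(xs[j + 1] - row$mu_x) - pnorm(xs[j] - row$mu_x))
      got <- cp3$prob[cp3$metacog == c("absent", "present")[i] &
                        cp3$confcat == c("conf_incorrect", "not_conf",
                                         "conf_correct")[j]]
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("cell probabilities are a valid distribution for random parameters", {
  for (s in 1:60) {
    tr <- random_triple(s)
    cp <- cell_probabilities(tr$group, tr$participant, tr$stimulus)
    expect_true(all(cp$prob >= 0))
    expect_true(all(cp$prob <= 1))
    expect_lt(abs(sum(cp$prob) - 1), 1e-8)
  }
})

test_that("log-likelihood sums n log p and is structurally safe", {
  g <- group_model(c(1, -1), c(1, 1), c(0.3, -0.3, 0))
  p <- participant_params("p1", 2, 0.5, 0.5, -1, 1)
  base <- tidyr::expand_grid(participant_id = "p1",
                             stimulus = c("correct_name", "incorrect_name",
                                          "catch"),
                             metacog = c("absent", "present"),
                             confcat = c("conf_incorrect", "not_conf",
                                         "conf_correct"))
  # one count per cell in one stimulus row: sum of log cell probabilities
  counts <- dplyr::mutate(base, n = as.integer(stimulus == "catch"))
  probs <- cell_probabilities(g, p, "catch")
  expect_equal(log_likelihood(counts, g, p), sum(log(probs$prob)),
               tolerance = 1e-10)
  # all-zero counts: empty sum
  expect_equal(log_likelihood(dplyr::mutate(base, n = 0L), g, p), 0)
  # linearity in counts
  c1 <- dplyr::mutate(base, n = sample.int(10, 18, replace = TRUE))
  c2 <- dplyr::mutate(c1, n = 2L * n)
  expect_equal(log_likelihood(c2, g, p), 2 * log_likelihood(c1, g, p),
               tolerance = 1e-10)
  # invariance to row order
  expect_equal(log_likelihood(c1[sample.int(18), ], g, p),
               log_likelihood(c1, g, p))
  # mismatched participants
  expect_error(log_likelihood(c1, g, participant_params("zz", 2, .5, 0, -1, 1)),
               "ids")
})

test_that("group model enforces its invariants", {
  expect_error(group_model(c(1, -1), c(1, 1), c(1, 0, 0)), "rho")
  expect_error(group_model(1, c(1, 1), c(0, 0, 0)), "length 2")
  g <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
  g$mu_x[3] <- 0.2
  expect_error(metagrt:::validate_group(g), "catch")
  expect_error(participant_params("a", 2, 0.5, 0, 1, -1), "c_x1")
  expect_error(participant_params(c("a", "a"), 2, 0.5, 0, -1, 1), "unique")
})
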