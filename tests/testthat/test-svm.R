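test_that("relative likelihood matches the density-ratio closed form", {
  g0 <- group_model(c(1, -1), c(0, 0), c(0, 0, 0))
  expect_equal(relative_likelihood(g0, seq(-3, 3, by = 0.5)),
               rep(1, 13))                        # identical densities
  g1 <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
  expect_equal(relative_likelihood(g1, 1), exp(0.5), tolerance = 1e-12)
  g2 <- group_model(c(1, -1), c(1, 1.5), c(0, 0, 0))
  expect_equal(relative_likelihood(g2, 0),
               0.5 * exp(-0.5) + 0.5 * exp(-1.125), tolerance = 1e-12)
  # strictly increasing whenever both famous means are positive
  for (s in 1:25) {
    set.seed(s)
    g <- group_model(c(1, -1), runif(2, 0.05, 3), c(0, 0, 0))
    L <- relative_likelihood(g, seq(-4, 4, length.out = 200))
    expect_true(all(diff(L) > 0))
  }
})

test_that("objective criterion solves L(y) = 1", {
  g1 <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
  expect_equal(objective_criterion(g1), 0.5, tolerance = 1e-8)
  g2 <- group_model(c(1, -1), c(2, 2), c(0, 0, 0))
  expect_equal(objective_criterion(g2), 1.0, tolerance = 1e-8)
  # unequal famous means: compare with an independent bisection oracle
  g3 <- group_model(c(1, -1), c(1, 1.5), c(0, 0, 0))
  f <- function(y) 0.5 * exp(y - 0.5) + 0.5 * exp(1.5 * y - 1.125) - 1
  lo <- -5; hi <- 5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  y3 <- objective_criterion(g3)
  expect_equal(y3, (lo + hi) / 2, tolerance = 1e-8)
  expect_lt(abs(relative_likelihood(g3, y3) - 1), 1e-8)
  # degenerate model: no unique root
  expect_error(objective_criterion(group_model(c(1, -1), c(0, 0), c(0, 0, 0))),
               "no unique")
})

test_that("conditional distributions follow Gaussian conditioning", {
  g <- group_model(c(1, -1), c(1, 1), c(0.5, -0.5, 0))
  d <- conditional_distribution(g, "correct_name", 2)
  expect_equal(d$mean, 1.5)
  expect_equal(d$sd, sqrt(0.75))
  # rho = 0: independent of y
  g0 <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
  d0 <- conditional_distribution(g0, "incorrect_name", c(-2, 0, 2))
  expect_equal(d0$mean, rep(-1, 3))
  expect_equal(d0$sd, rep(1, 3))
})

test_that("conditional category probabilities split the normal correctly", {
  p <- conditional_category_probs(0, 1, -1, 1)
  expect_equal(unname(p), c(pnorm(-1), pnorm(1) - pnorm(-1), pnorm(-1)),
               tolerance = 1e-12)
  expect_equal(sum(p), 1)
  # extreme criteria concentrate mass in the middle
  p2 <- conditional_category_probs(0, 1, -40, 40)
  expect_equal(unname(p2), c(0, 1, 0), tolerance = 1e-12)
  # mirror symmetry
  pa <- conditional_category_probs(0.7, 1.3, -0.4, 1.1)
  pb <- conditional_category_probs(-0.7, 1.3, -1.1, 0.4)
  expect_equal(unname(pa), unname(rev(pb)), tolerance = 1e-12)
  expect_error(conditional_category_probs(0, 1, 1, -1), "inverted")
  expect_error(conditional_category_probs(0, 0, -1, 1), "sd")
})

test_that("conditional meta-d' recovers the closed form for equal conditional sds", {
  rc <- list(c_x1 = -1, c_x2 = 1)
  # no discriminability: identical conditional distributions
  gsame <- group_model(c(1e-12, -1e-12), c(1, 1), c(0, 0, 0))
  f0 <- fit_conditional_metad(gsame, rc, y = 0.8)
  expect_lt(abs(f0$meta_d), 1e-5)
  expect_lt(f0$loss, 1e-10)
  # rho = 0, mu_x = +/-1: the conditional model is itself an SDT observer
  g1 <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
  for (y in c(-1, 0.3, 2)) {
    f <- fit_conditional_metad(g1, rc, y)
    expect_equal(f$meta_d, 2, tolerance = 1e-6)
    expect_lt(f$loss, 1e-10)
    expect_lt(f$t1, f$t2)
  }
  # equal correlations 0.5: meta-d' = 2 / sqrt(0.75), constant in y
  g2 <- group_model(c(1, -1), c(1, 1), c(0.5, 0.5, 0))
  for (y in c(-0.5, 1, 2.5)) {
    f <- fit_conditional_metad(g2, rc, y)
    expect_equal(f$meta_d, 2 / sqrt(0.75), tolerance = 1e-6)
    expect_lt(f$loss, 1e-10)
  }
})

test_that("conditional meta-d' matches the dense grid-search oracle", {
  set.seed(77)
  done <- 0
  while (done < 6) {
    g <- group_model(c(runif(1, 0.3, 1.5), runif(1, -1.5, -0.3)),
                     runif(2, 0.3, 2), runif(3, -0.7, 0.7))
    rc <- list(c_x1 = runif(1, -1.5, -0.2), c_x2 = runif(1, 0.2, 1.5))
    y <- runif(1, -1, 2.5)
    dc <- conditional_distribution(g, "correct_name", y)
    di <- conditional_distribution(g, "incorrect_name", y)
    if (dc$mean - di$mean < 0.1) next   # oracle grid covers meta_d >= 0
    done <- done + 1
    f <- fit_conditional_metad(g, rc, y)
    oracle <- metad_grid_oracle(metad_targets(g, rc, y))
    expect_lt(abs(f$meta_d - oracle$meta_d), 0.02)
    expect_lte(f$loss, oracle$loss + 1e-8)
  }
})

test_that("reflecting the confidence axis negates meta-d'", {
  rc <- list(c_x1 = -0.8, c_x2 = 1.1)
  g <- group_model(c(1.2, -0.7), c(1, 1.4), c(0.4, -0.2, 0))
  gr <- group_model(-c(1.2, -0.7), c(1, 1.4), -c(0.4, -0.2, 0))
  rcr <- list(c_x1 = -1.1, c_x2 = 0.8)
  f <- fit_conditional_metad(g, rc, y = 0.9)
  fr <- fit_conditional_metad(gr, rcr, y = 0.9)
  expect_equal(fr$meta_d, -f$meta_d, tolerance = 1e-4)
})

test_that("reference criteria average the rescaled participant criteria", {
  m <- toy_model(5)
  rc <- reference_criteria(m)
  p <- m$participants
  expect_equal(rc$c_x1, mean(p$c_x1 * sqrt(p$kappa * p$lambda)))
  expect_equal(rc$c_x2, mean(p$c_x2 * sqrt(p$kappa * p$lambda)))
  expect_equal(rc$participants$c_y_group,
               p$c_y * sqrt(p$kappa * (1 - p$lambda)))
  expect_lt(rc$c_x1, rc$c_x2)
})

test_that("SvM curves have the documented structure and degenerate behavior", {
  m <- toy_model(3)
  curve <- build_svm_curve(m, n_grid = 41)
  expect_s3_class(curve, "svm_curve")
  expect_equal(nrow(curve$curve), 41)
  expect_true(all(diff(curve$curve$y) > 0))
  expect_true(all(curve$curve$rel_likelihood > 0))
  expect_lt(abs(curve$L_star - 1), 1e-8)
  expect_equal(curve$y_star, 0.5, tolerance = 1e-8)  # both famous mu_y = 1
  expect_equal(nrow(curve$participants), 3)
  # equal-correlation model: flat meta-d' column
  meq <- toy_model(3)
  meq$group <- group_model(c(1, -1), c(1, 1), c(0.5, 0.5, 0))
  ceq <- build_svm_curve(meq, n_grid = 31)
  expect_lt(max(ceq$curve$meta_d) - min(ceq$curve$meta_d), 1e-6)
  expect_equal(ceq$curve$meta_d[1], 2 / sqrt(0.75), tolerance = 1e-4)
  # headline-structure model: strictly increasing meta-d'
  expect_true(all(diff(curve$curve$meta_d) > 0))
  # degenerate model is rejected
  mdeg <- toy_model(2)
  mdeg$group <- group_model(c(1, -1), c(0, 0), c(0, 0, 0))
  expect_error(build_svm_curve(mdeg), "no unique")
})

test_that("SvM curves round-trip through delimited text", {
  m <- toy_model(3)
  curve <- build_svm_curve(m, n_grid = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_svm_curve(curve, path)
  back <- read_svm_curve(path)
  expect_equal(back$curve$y, curve$curve$y, tolerance = 1e-12)
  expect_equal(back$curve$meta_d, curve$curve$meta_d, tolerance = 1e-12)
  expect_equal(back$y_star, curve$y_star, tolerance = 1e-12)
  expect_equal(back$participants$position, curve$participants$position,
               tolerance = 1e-12)
  expect_identical(back$judgment, "tot")
})
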