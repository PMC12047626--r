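test_that("parameter packing round-trips and maps zero to the neutral model", {
  m <- toy_model(4)
  th <- pack_parameters(m$group, m$participants)
  u <- unpack_parameters(th, sort(m$participants$participant_id))
  expect_equal(pack_parameters(u$group, u$participants), th, tolerance = 1e-12)
  expect_equal(u$group$mu_x, m$group$mu_x, tolerance = 1e-12)
  # the zero vector: rho = 0, kappa = 1, lambda = 0.5, unit criterion gap
  u0 <- unpack_parameters(rep(0, 12), "a")
  expect_equal(u0$group$rho, c(0, 0, 0))
  expect_equal(u0$participants$kappa, 1)
  expect_equal(u0$participants$lambda, 0.5)
  expect_equal(u0$participants$c_x2 - u0$participants$c_x1, 1)
  # criteria always ordered after unpacking any vector
  set.seed(5)
  for (i in 1:50) {
    u <- unpack_parameters(rnorm(12, sd = 2), "a")
    expect_lt(u$participants$c_x1, u$participants$c_x2)
  }
  expect_error(unpack_parameters(rep(0, 11), "a"), "length")
})

test_that("random starts are deterministic and always valid", {
  expect_identical(random_start(7, 3), random_start(7, 3))
  expect_false(identical(random_start(7, 3), random_start(8, 3)))
  for (s in 1:200) {
    u <- unpack_parameters(random_start(s, 2), c("a", "b"))
    expect_true(all(abs(u$group$rho) < 1))
    expect_gte(min(u$group$mu_y[1:2]), 0)
    expect_gt(u$group$mu_x[1], 0)
    expect_lt(u$group$mu_x[2], 0)
    expect_true(all(u$participants$kappa > 0))
    expect_true(all(u$participants$lambda > 0 & u$participants$lambda < 1))
    expect_true(all(u$participants$c_x1 < u$participants$c_x2))
  }
})

test_that("the scale anchor moves along the likelihood-flat orbit", {
  m <- toy_model(3)
  counts <- simulate_counts(m, row_totals = matrix(200, 3, 3,
                              dimnames = list(m$participants$participant_id,
                                              NULL)),
                            seed = 9)
  th <- pack_parameters(m$group, m$participants)
  th2 <- metagrt:::anchor_scale(th, 3)
  u <- unpack_parameters(th2, sort(m$participants$participant_id))
  # anchored representative satisfies both geometric-mean constraints
  expect_equal(mean(log(u$participants$kappa * u$participants$lambda)), 0,
               tolerance = 1e-10)
  expect_equal(mean(log(u$participants$kappa * (1 - u$participants$lambda))),
               0, tolerance = 1e-10)
  # and the likelihood (hence every cell probability) is unchanged
  expect_equal(log_likelihood(counts, u$group, u$participants),
               log_likelihood(counts, m$group, m$participants),
               tolerance = 1e-8)
  # anchoring an anchored vector is a no-op
  expect_equal(metagrt:::anchor_scale(th2, 3), th2, tolerance = 1e-10)
})

small_fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config(n_participants = 4, trials_per_condition = 60,
                          seed = 31)
      st <- generate_study(cfg)
      counts <- aggregate_counts(st$trials, "tot")
      cache <<- list(study = st, counts = counts,
                     fit = fit_grt_wind(counts, n_restarts = 4, seed = 17))
    }
    cache
  }
})

test_that("maximum-likelihood refit dominates the generating parameters", {
  fx <- small_fit_fixture()
  ll_truth <- log_likelihood(fx$counts, fx$study$truth$group,
                             fx$study$truth$participants)
  expect_gte(fx$fit$loglik, ll_truth)
  expect_equal(fx$fit$loglik, max(fx$fit$restart_logliks, na.rm = TRUE))
  # fitted parameters inside their open domains
  p <- fx$fit$participants
  expect_true(all(p$kappa > 0))
  expect_true(all(p$lambda > 0 & p$lambda < 1))
  expect_true(all(p$c_x1 < p$c_x2))
  expect_true(all(abs(fx$fit$group$rho) < 1))
})

test_that("fitting is deterministic and restart-monotone", {
  fx <- small_fit_fixture()
  f1 <- fit_grt_wind(fx$counts, n_restarts = 2, seed = 99)
  f2 <- fit_grt_wind(fx$counts, n_restarts = 2, seed = 99)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$group, f2$group)
  expect_identical(f1$participants, f2$participants)
  # same seed stream: best of 4 restarts >= best of the first 2
  f4 <- fit_grt_wind(fx$counts, n_restarts = 4, seed = 99)
  expect_identical(f4$restart_logliks[1:2], f1$restart_logliks)
  expect_gte(f4$loglik, f1$loglik)
})

test_that("variance accounted for behaves at its extremes", {
  fx <- small_fit_fixture()
  # simulating huge samples from the fitted model reproduces its
  # probabilities, so the fit explains nearly all variance
  big <- simulate_counts(fx$fit, row_totals = matrix(
    2e5, nrow(fx$fit$participants), 3,
    dimnames = list(fx$fit$participants$participant_id, NULL)), seed = 4)
  expect_gt(variance_accounted(fx$fit, big), 99.8)
  expect_lte(variance_accounted(fx$fit, big), 100)
  expect_error(fit_grt_wind(dplyr::mutate(fx$counts, n = 0L)), "positive total")
})

test_that("fitted models serialize to JSON losslessly", {
  fx <- small_fit_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_grt_fit(fx$fit, path)
  back <- read_grt_fit(path)
  expect_equal(back$group, fx$fit$group, tolerance = 1e-12)
  expect_equal(back$participants, fx$fit$participants, tolerance = 1e-12)
  expect_equal(back$loglik, fx$fit$loglik, tolerance = 1e-12)
  expect_equal(back$restart_logliks, fx$fit$restart_logliks, tolerance = 1e-12)
  expect_identical(back$judgment, "tot")
  expect_equal(dplyr::arrange(back$data, participant_id, stimulus, metacog,
                              confcat)$n,
               dplyr::arrange(fx$fit$data, participant_id, stimulus, metacog,
                              confcat)$n)
})
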