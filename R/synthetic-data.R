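## Synthetic two-stage metamemory studies with known ground truth.
##
## The generator emulates the experimental design the analysis assumes: per
## participant, equal numbers of correct-name, incorrect-name and catch
## trials in blocks of 30 (10 per condition) over three sessions; famous
## trials drop out of the metacognitive stage when recall succeeds (an
## independent coin flip -- the recall process itself is not modeled, only
## its censoring effect); catch items have no correct answer, so catch
## trials are never recalled. For every recall failure, a bivariate evidence
## draw from the participant's scaled stimulus distribution produces the
## state report (y against c_y), the recognition response (x against the
## criteria midpoint), and the 4-level confidence (x against the confidence
## criteria and sub-criteria). TOT and FOK are driven by the same y draw
## with offset criteria, so a high FOK is at least as frequent as a TOT.

#' Configuration of a synthetic study
#'
#' Defaults follow the design of the motivating experiments: 70 participants,
#' 200 trials per condition (600 total), and a group decision space in which
#' the two famous conditions sit at `mu_x = +/-1`, `mu_y = 1` with
#' correlations `+0.5` and `-0.5` -- the configuration that produces a
#' rising SvM curve. Individual differences: `kappa` log-normal around 2,
#' `lambda` uniform on `[0.35, 0.65]`, criteria equal to the population
#' anchors plus Gaussian noise.
#'
#' @param n_participants Number of participants.
#' @param trials_per_condition Trials per stimulus condition per participant.
#' @param recall_rate_famous Probability a famous trial is recalled (and thus
#'   carries no metacognitive data), in `[0, 1)`.
#' @param group True group model.
#' @param kappa_meanlog,kappa_sdlog Log-normal hyperparameters for `kappa`.
#' @param lambda_range Uniform range for `lambda` (inside (0, 1)).
#' @param criterion_sd SD of Gaussian noise added to the anchor criteria.
#' @param anchor_criteria Named list `c_y`, `c_x1`, `c_x2`: population
#'   criterion anchors.
#' @param fok_offset Positive offset `delta`: FOK is "high" when
#'   `y > c_y - delta`, so FOK-high is more liberal than TOT-yes.
#' @param sub_criteria Named list `lo`, `hi`: distances that split each
#'   2-level confidence region into the 4 raw levels.
#' @param seed Master seed for the study.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_participants = 70,
                         trials_per_condition = 200,
                         recall_rate_famous = 0.35,
                         group = group_model(mu_x = c(1, -1), mu_y = c(1, 1),
                                             rho = c(0.5, -0.5, 0)),
                         kappa_meanlog = log(2),
                         kappa_sdlog = 0.3,
                         lambda_range = c(0.35, 0.65),
                         criterion_sd = 0.3,
                         anchor_criteria = list(c_y = 0.5, c_x1 = -1, c_x2 = 1),
                         fok_offset = 0.4,
                         sub_criteria = list(lo = 0.3, hi = 0.5),
                         seed = 1) {
  check_scalar(n_participants, "n_participants", 1, Inf)
  check_scalar(trials_per_condition, "trials_per_condition", 1, Inf)
  check_scalar(recall_rate_famous, "recall_rate_famous", 0, 1,
               strict = c(FALSE, TRUE))
  check_scalar(kappa_sdlog, "kappa_sdlog", 0, Inf)
  check_scalar(criterion_sd, "criterion_sd", 0, Inf)
  check_scalar(fok_offset, "fok_offset", 0, Inf, strict = c(TRUE, FALSE))
  stopifnot(length(lambda_range) == 2, lambda_range[1] > 0,
            lambda_range[2] < 1, lambda_range[1] <= lambda_range[2])
  if (anchor_criteria$c_x1 >= anchor_criteria$c_x2)
    abort("anchor `c_x1` must be below `c_x2`.")
  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_condition = as.integer(trials_per_condition),
    recall_rate_famous = recall_rate_famous,
    group = validate_group(group),
    kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog,
    lambda_range = lambda_range, criterion_sd = criterion_sd,
    anchor_criteria = anchor_criteria,
    fok_offset = fok_offset, sub_criteria = sub_criteria,
    seed = as.integer(seed)), class = "study_config")
}

#' Draw a participant population from the study hyperparameters
#'
#' @param config A [study_config()].
#' @param seed Seed (defaults to the config's master seed).
#' @return A [participant_params()] tibble with ids `p001`, `p002`, ...
#' @export
sample_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_participants
  with_seed(seed, {
    kappa <- rlnorm(n, config$kappa_meanlog, config$kappa_sdlog)
    lambda <- runif(n, config$lambda_range[1], config$lambda_range[2])
    c_y <- config$anchor_criteria$c_y + rnorm(n, 0, config$criterion_sd)
    cx <- rbind(config$anchor_criteria$c_x1 + rnorm(n, 0, config$criterion_sd),
                config$anchor_criteria$c_x2 + rnorm(n, 0, config$criterion_sd))
    cx <- apply(cx, 2, sort)
    cx[2, ] <- pmax(cx[2, ], cx[1, ] + 1e-6)
    participant_params(sprintf("p%03d", seq_len(n)), kappa, lambda,
                       c_y, cx[1, ], cx[2, ])
  })
}

## 4-level confidence from evidence x and criteria:
## outside [c_x1, c_x2] -> confident (4 if beyond the criterion by more than
## sub hi, else 3); inside -> not confident (1 if deeper than sub lo from
## both criteria, else 2)
confidence4_from_x <- function(x, c_x1, c_x2, sub) {
  confident <- x < c_x1 | x > c_x2
  excess <- pmax(c_x1 - x, x - c_x2)
  depth <- pmin(x - c_x1, c_x2 - x)
  ifelse(confident,
         ifelse(excess > sub$hi, 4L, 3L),
         ifelse(depth > sub$lo, 1L, 2L))
}

#' Simulate the trial sequence for one participant
#'
#' @param group Group model (the truth).
#' @param participant One row of participant parameters.
#' @param config A [study_config()].
#' @param seed Integer seed for this participant's trials.
#' @return A trial-level tibble (see [read_trials()] for the schema).
#' @export
simulate_trials <- function(group, participant, config, seed = 1) {
  group <- validate_group(group)
  participant <- validate_participants(participant)
  stopifnot(nrow(participant) == 1, inherits(config, "study_config"))
  tpc <- config$trials_per_condition
  with_seed(seed, {
    ## block structure: 30 trials per block, 10 per condition, when possible
    if (tpc %% 10 == 0) {
      n_blocks <- 3 * tpc / 30
      cond <- unlist(lapply(seq_len(n_blocks),
                            function(b) sample(rep(STIMULI, each = 10))))
    } else {
      cond <- sample(rep(STIMULI, each = tpc))
      n_blocks <- ceiling(length(cond) / 30)
    }
    n_tr <- length(cond)
    block <- ceiling(seq_len(n_tr) / 30)
    sess_of_block <- sort(rep_len(1:3, n_blocks))
    session <- sess_of_block[block]
    recalled <- ifelse(cond == "catch", FALSE,
                       runif(n_tr) < config$recall_rate_famous)
    ## evidence draws for recall failures
    si <- match(cond, STIMULI)
    sx <- 1 / sqrt(participant$kappa * participant$lambda)
    sy <- 1 / sqrt(participant$kappa * (1 - participant$lambda))
    rho <- group$rho[si]
    z1 <- rnorm(n_tr); z2 <- rnorm(n_tr)
    x <- group$mu_x[si] + sx * z1
    y <- group$mu_y[si] + sy * (rho * z1 + sqrt(1 - rho^2) * z2)
    mid <- (participant$c_x1 + participant$c_x2) / 2
    tot <- ifelse(y > participant$c_y, "yes", "no")
    fok <- ifelse(y > participant$c_y - config$fok_offset, "high", "low")
    resp <- ifelse(x > mid, "correct", "incorrect")
    conf4 <- confidence4_from_x(x, participant$c_x1, participant$c_x2,
                                config$sub_criteria)
    acc <- dplyr::case_when(
      cond == "catch" ~ NA,
      cond == "correct_name" ~ resp == "correct",
      cond == "incorrect_name" ~ resp == "incorrect")
    tibble::tibble(
      participant_id = participant$participant_id,
      session = as.integer(session),
      block = as.integer(block),
      trial = seq_len(n_tr),
      condition = cond,
      recalled = recalled,
      tot = ifelse(recalled, NA_character_, tot),
      fok = ifelse(recalled, NA_character_, fok),
      recog_response = ifelse(recalled, NA_character_, resp),
      recog_accurate = ifelse(recalled, NA, acc),
      confidence4 = ifelse(recalled, NA_integer_, conf4))
  })
}

#' Generate a full synthetic study with ground truth
#'
#' Draws the participant population and simulates every participant's trial
#' sequence. All randomness is derived from the config's master seed.
#'
#' @param config A [study_config()].
#' @return A list of class `study`: `trials` (all participants), `truth`
#'   (`group`, `participants`, `config`, `seed`).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seeds <- seed_stream(config$seed, config$n_participants + 1)
  parts <- sample_population(config, seed = seeds[1])
  trials <- purrr::map_dfr(seq_len(config$n_participants), function(i)
    simulate_trials(config$group, parts[i, ], config, seed = seeds[i + 1]))
  structure(list(
    trials = trials,
    truth = list(group = config$group, participants = parts,
                 config = config, seed = config$seed)),
    class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d participants x %d trials (%d per condition)\n",
              x$truth$config$n_participants,
              3 * x$truth$config$trials_per_condition,
              x$truth$config$trials_per_condition))
  cat(sprintf("  recall rate (famous): %.2f   master seed: %d\n",
              x$truth$config$recall_rate_famous, x$truth$seed))
  invisible(x)
}

#' Write / read the ground-truth record of a synthetic study
#'
#' Serializes the true group model, participant parameters and the scalar
#' study configuration as JSON; round-trips losslessly.
#'
#' @param truth The `truth` element of a [generate_study()] result.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  cfg <- truth$config
  doc <- list(
    type = "ground_truth",
    version = as.character(utils::packageVersion("metagrt")),
    seed = truth$seed,
    group = as.data.frame(truth$group),
    participants = as.data.frame(truth$participants),
    config = cfg[setdiff(names(cfg), "group")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "ground_truth"))
    abort(sprintf("'%s' is not a serialized ground-truth document.", path))
  g <- doc$group
  cfg <- doc$config
  config <- study_config(
    n_participants = cfg$n_participants,
    trials_per_condition = cfg$trials_per_condition,
    recall_rate_famous = cfg$recall_rate_famous,
    group = group_model(g$mu_x[1:2], g$mu_y[1:2], g$rho),
    kappa_meanlog = cfg$kappa_meanlog, kappa_sdlog = cfg$kappa_sdlog,
    lambda_range = unlist(cfg$lambda_range),
    criterion_sd = cfg$criterion_sd,
    anchor_criteria = as.list(cfg$anchor_criteria),
    fok_offset = cfg$fok_offset,
    sub_criteria = as.list(cfg$sub_criteria),
    seed = cfg$seed)
  list(group = config$group,
       participants = validate_participants(tibble::as_tibble(doc$participants)),
       config = config, seed = doc$seed)
}

#' Parameter-recovery study
#'
#' Generates a synthetic study, aggregates it into count tables, refits the
#' model, and scores the recovered parameters and SvM curve against the
#' ground truth.
#'
#' @param config A [study_config()].
#' @param judgment `"tot"` or `"fok"`.
#' @param n_restarts Restarts for the refit.
#' @param seed Seed for the refit's restart stream (defaults to the config's
#'   master seed).
#' @param L_window Relative-likelihood window over which the recovered curve
#'   is compared to the true curve.
#' @param n_L Number of (log-spaced) comparison points in the window.
#' @return A list of class `recovery_report`: the fit, the true and
#'   recovered group tables, `rmse_means`, `rho_errors` (per-stimulus
#'   absolute error), `max_abs_rho_error`, and `max_metad_dev` (largest
#'   absolute meta-d' deviation over the window), plus the two curves.
#' @export
recovery_harness <- function(config = study_config(), judgment = "tot",
                             n_restarts = 20, seed = config$seed,
                             L_window = c(0.5, 5), n_L = 41) {
  study <- generate_study(config)
  counts <- aggregate_counts(study$trials, judgment = judgment)
  fit <- fit_grt_wind(counts, n_restarts = n_restarts, seed = seed)
  truth <- study$truth
  true_means <- unlist(truth$group[1:2, c("mu_x", "mu_y")])
  est_means <- unlist(fit$group[1:2, c("mu_x", "mu_y")])
  rmse_means <- sqrt(mean((true_means - est_means)^2))
  rho_errors <- abs(fit$group$rho - truth$group$rho)
  names(rho_errors) <- STIMULI
  ## curve comparison on a shared relative-likelihood axis
  L_pts <- exp(seq(log(L_window[1]), log(L_window[2]), length.out = n_L))
  eval_curve <- function(model) {
    y_lo <- invert_L(model$group, min(L_pts))
    y_hi <- invert_L(model$group, max(L_pts))
    curve <- build_svm_curve(model, y_grid = seq(y_lo, y_hi,
                                                 length.out = 101))
    list(curve = curve,
         metad = approx(curve$curve$rel_likelihood, curve$curve$meta_d,
                        xout = L_pts, rule = 2)$y)
  }
  true_model <- list(group = truth$group, participants = truth$participants,
                     judgment = judgment)
  tc <- eval_curve(true_model)
  fc <- eval_curve(fit)
  structure(list(
    fit = fit,
    true_group = truth$group,
    est_group = fit$group,
    rmse_means = rmse_means,
    rho_errors = rho_errors,
    max_abs_rho_error = max(rho_errors),
    L_points = L_pts,
    metad_true = tc$metad,
    metad_est = fc$metad,
    max_metad_dev = max(abs(tc$metad - fc$metad)),
    true_curve = tc$curve,
    est_curve = fc$curve,
    judgment = judgment),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report\n")
  cat(sprintf("  group-mean RMSE: %.4f\n", x$rmse_means))
  cat(sprintf("  max |rho error|: %.4f\n", x$max_abs_rho_error))
  cat(sprintf("  max |meta-d' deviation| on L in [%.2g, %.2g]: %.4f\n",
              min(x$L_points), max(x$L_points), x$max_metad_dev))
  cat(sprintf("  fit: loglik %.2f, %.2f%% variance accounted for\n",
              x$fit$loglik, x$fit$pct_variance))
  invisible(x)
}

#' @rdname recovery_harness
#' @param x,object A `recovery_report`.
#' @param ... Unused.
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    rmse_means = x$rmse_means,
    max_abs_rho_error = x$max_abs_rho_error,
    max_metad_dev = x$max_metad_dev,
    loglik = x$fit$loglik,
    pct_variance = x$fit$pct_variance,
    n_participants = nrow(x$fit$participants))
}
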