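## Trial-level file format, aggregation to count tables, and the pipeline
## driver.
##
## Trial files are comma-separated text with a fixed header:
##   participant_id, session, block, trial, condition, recalled, tot, fok,
##   recog_response, recog_accurate, confidence4
## Booleans are written as 0/1, missing values as empty fields, categorical
## codes lowercase: condition in {correct_name, incorrect_name, catch},
## tot in {yes, no}, fok in {high, low}, recog_response in
## {correct, incorrect}, confidence4 in 1..4.

TRIAL_COLS <- c("participant_id", "session", "block", "trial", "condition",
                "recalled", "tot", "fok", "recog_response", "recog_accurate",
                "confidence4")

## enforce the trial-record invariants; `where` labels rows in messages
validate_trials <- function(trials, where = "row") {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    abort("`trials` must be a non-empty data frame of trial records.")
  missing_cols <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_cols) > 0)
    abort(sprintf("missing trial columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  bad_rows <- function(cond) which(cond %in% TRUE)
  fail <- function(rows, what) {
    abort(sprintf("invalid trial records (%s): %s %s.",
                  what, where, paste(head(rows, 10), collapse = ", ")))
  }
  r <- bad_rows(!trials$condition %in% STIMULI)
  if (length(r)) fail(r, "unknown condition code")
  r <- bad_rows(!trials$tot %in% c("yes", "no") & !is.na(trials$tot))
  if (length(r)) fail(r, "unknown tot code")
  r <- bad_rows(!trials$fok %in% c("high", "low") & !is.na(trials$fok))
  if (length(r)) fail(r, "unknown fok code")
  r <- bad_rows(!trials$recog_response %in% c("correct", "incorrect") &
                  !is.na(trials$recog_response))
  if (length(r)) fail(r, "unknown recognition response code")
  r <- bad_rows(!is.na(trials$confidence4) & !(trials$confidence4 %in% 1:4))
  if (length(r)) fail(r, "confidence rating outside 1..4")
  meta_present <- !is.na(trials$tot) | !is.na(trials$fok) |
    !is.na(trials$recog_response) | !is.na(trials$confidence4)
  meta_complete <- !is.na(trials$tot) & !is.na(trials$fok) &
    !is.na(trials$recog_response) & !is.na(trials$confidence4)
  r <- bad_rows(trials$recalled & meta_present)
  if (length(r)) fail(r, "recalled trial carries metacognitive responses")
  r <- bad_rows(!trials$recalled & !meta_complete)
  if (length(r)) fail(r, "recall-failure trial with incomplete metacognitive responses")
  r <- bad_rows(trials$condition == "catch" & !is.na(trials$recog_accurate))
  if (length(r)) fail(r, "catch trial with defined recognition accuracy")
  r <- bad_rows(trials$condition == "catch" & trials$recalled)
  if (length(r)) fail(r, "recalled catch trial (catch items have no correct answer)")
  expected_acc <- ifelse(trials$condition == "correct_name",
                         trials$recog_response == "correct",
                         trials$recog_response == "incorrect")
  r <- bad_rows(!trials$recalled & trials$condition != "catch" &
                  trials$recog_accurate != expected_acc)
  if (length(r)) fail(r, "recognition accuracy inconsistent with condition and response")
  invisible(trials)
}

#' Write / read trial-level records as delimited text
#'
#' See the package's format notes: comma-separated, booleans as 0/1, missing
#' values as empty fields, lowercase categorical codes. `read_trials()`
#' validates every record and reports offending line numbers; an empty file
#' is an error, not an empty dataset.
#'
#' @param trials Trial-level tibble.
#' @param path File path.
#' @return `read_trials()` returns the validated tibble.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- dplyr::mutate(trials[, TRIAL_COLS],
                       recalled = as.integer(.data$recalled),
                       recog_accurate = as.integer(.data$recog_accurate))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  raw <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session = readr::col_integer(),
      block = readr::col_integer(),
      trial = readr::col_integer(),
      condition = readr::col_character(),
      recalled = readr::col_integer(),
      tot = readr::col_character(),
      fok = readr::col_character(),
      recog_response = readr::col_character(),
      recog_accurate = readr::col_integer(),
      confidence4 = readr::col_integer()),
    show_col_types = FALSE)
  if (nrow(raw) == 0)
    abort(sprintf("'%s' contains no trial records.", path))
  missing_cols <- setdiff(TRIAL_COLS, names(raw))
  if (length(missing_cols) > 0)
    abort(sprintf("'%s' is missing columns: %s.", path,
                  paste(missing_cols, collapse = ", ")))
  trials <- dplyr::mutate(raw,
                          recalled = .data$recalled == 1L,
                          recog_accurate = ifelse(is.na(.data$recog_accurate),
                                                  NA, .data$recog_accurate == 1L))
  ## +1 for the header: report physical line numbers
  validate_trials(trials, where = "line (1-based, header = line 1)")
  trials
}

#' Aggregate trial records into per-participant count tables
#'
#' Keeps recall-failure trials only. The metacognitive axis is the chosen
#' judgment (TOT: yes = present; FOK: high = present). The confidence
#' category combines the 2-level reclassified confidence with the
#' recognition response: confident + "correct" is `conf_correct`, confident
#' + "incorrect" is `conf_incorrect`, anything not confident is `not_conf`.
#' Participants with an all-zero stimulus row are dropped with a warning
#' (the model cannot be fitted for them).
#'
#' @param trials Trial-level tibble.
#' @param judgment `"tot"` or `"fok"`.
#' @return A long count tibble (`participant_id`, `stimulus`, `metacog`,
#'   `confcat`, `n`; 18 rows per participant) with a `judgment` attribute.
#' @export
aggregate_counts <- function(trials, judgment = c("tot", "fok")) {
  judgment <- match.arg(judgment)
  validate_trials(trials)
  d <- dplyr::filter(trials, !.data$recalled)
  d$metacog <- if (judgment == "tot") {
    ifelse(d$tot == "yes", "present", "absent")
  } else {
    ifelse(d$fok == "high", "present", "absent")
  }
  conf2 <- reclassify_confidence(d$confidence4)
  d$confcat <- dplyr::case_when(
    conf2 == "confident" & d$recog_response == "correct" ~ "conf_correct",
    conf2 == "confident" & d$recog_response == "incorrect" ~ "conf_incorrect",
    TRUE ~ "not_conf")
  counts <- d |>
    dplyr::count(.data$participant_id, stimulus = .data$condition,
                 .data$metacog, .data$confcat, name = "n") |>
    tidyr::complete(.data$participant_id,
                    stimulus = STIMULI, metacog = METACOG, confcat = CONFCAT,
                    fill = list(n = 0L))
  empty <- counts |>
    dplyr::group_by(.data$participant_id, .data$stimulus) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop") |>
    dplyr::filter(.data$total == 0)
  if (nrow(empty) > 0) {
    drop_ids <- unique(empty$participant_id)
    warn(sprintf("dropping %d participant(s) with an all-zero stimulus row: %s",
                 length(drop_ids), paste(drop_ids, collapse = ", ")))
    counts <- dplyr::filter(counts, !.data$participant_id %in% drop_ids)
  }
  if (nrow(counts) == 0) abort("no usable participants after aggregation.")
  attr(counts, "judgment") <- judgment
  counts
}

#' Assemble and validate a pipeline configuration
#'
#' @param trials Trial-level tibble, or `NULL` to read from `trials_path` or
#'   simulate from `study`.
#' @param trials_path Path to a trial file (used when `trials` is `NULL`).
#' @param study A [study_config()] to simulate from (used when both `trials`
#'   and `trials_path` are `NULL`).
#' @param out_dir Output directory for all artifacts.
#' @param judgment `"tot"` or `"fok"`.
#' @param seed Master seed for the run.
#' @param exclusions List: `recall_max`, `recog_min`.
#' @param fit List: `n_restarts`, `max_iter`, `tol`.
#' @param curve List: `n_grid`, `n_starts`.
#' @param bootstrap List: `n_boot`, `level`, `restarts_per_refit`, `n_grid`;
#'   set `n_boot = 0` to skip the bootstrap stage.
#' @param descriptives List: `include_catch`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(trials = NULL, trials_path = NULL, study = NULL,
                            out_dir, judgment = c("tot", "fok"), seed = 1,
                            exclusions = list(recall_max = 0.80,
                                              recog_min = 0.51),
                            fit = list(n_restarts = 100, max_iter = 2000,
                                       tol = 1e-8),
                            curve = list(n_grid = 201, n_starts = 10),
                            bootstrap = list(n_boot = 1000, level = 0.99,
                                             restarts_per_refit = 10,
                                             n_grid = 101),
                            descriptives = list(include_catch = TRUE)) {
  judgment <- match.arg(judgment)
  if (is.null(trials) && is.null(trials_path) && is.null(study))
    abort("provide `trials`, `trials_path`, or a `study` config to simulate from.")
  if (!is.null(study) && !inherits(study, "study_config"))
    abort("`study` must be a study_config object.")
  fit <- utils::modifyList(list(n_restarts = 100, max_iter = 2000, tol = 1e-8),
                           fit)
  curve <- utils::modifyList(list(n_grid = 201, n_starts = 10), curve)
  bootstrap <- utils::modifyList(list(n_boot = 1000, level = 0.99,
                                      restarts_per_refit = 10, n_grid = 101),
                                 bootstrap)
  exclusions <- utils::modifyList(list(recall_max = 0.80, recog_min = 0.51),
                                  exclusions)
  descriptives <- utils::modifyList(list(include_catch = TRUE), descriptives)
  check_scalar(seed, "seed")
  structure(list(trials = trials, trials_path = trials_path, study = study,
                 out_dir = out_dir, judgment = judgment, seed = seed,
                 exclusions = exclusions, fit = fit, curve = curve,
                 bootstrap = bootstrap, descriptives = descriptives),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes read (or simulate) -> exclusions -> aggregation -> model fit ->
#' SvM curve -> bootstrap band -> descriptives, writing every artifact to
#' `out_dir`: the trial file (if simulated), the exclusion report, the
#' fitted-model JSON, curve and band delimited text, the descriptive report,
#' and a JSON run manifest with seeds, versions, a config echo and per-stage
#' timings. Any stage failure halts the run with the stage name; the
#' manifest is still written, marked incomplete.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's result and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metagrt")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    judgment = config$judgment,
    config = config[c("judgment", "seed", "exclusions", "fit", "curve",
                      "bootstrap", "descriptives")],
    status = "incomplete", stages = list())
  results <- list()
  stage_seeds <- seed_stream(config$seed, 3)  # simulate, fit, bootstrap
  path_of <- function(name) file.path(config$out_dir, name)
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    inform(sprintf("[%s] started", name))
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, path_of("manifest.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    dt <- as.numeric(Sys.time() - t0, units = "secs")
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(dt, 3))
    inform(sprintf("[%s] done (%.1f s)", name, dt))
    res
  }

  results$trials <- run_stage("input", {
    if (!is.null(config$trials)) {
      validate_trials(config$trials)
    } else if (!is.null(config$trials_path)) {
      read_trials(config$trials_path)
    } else {
      study <- config$study
      study$seed <- as.integer(stage_seeds[1])
      st <- generate_study(study)
      write_trials(st$trials, path_of("trials.csv"))
      write_ground_truth(st$truth, path_of("ground_truth.json"))
      st$trials
    }
  })

  results$exclusions <- run_stage("exclusions", {
    ex <- apply_exclusions(results$trials,
                           recall_max = config$exclusions$recall_max,
                           recog_min = config$exclusions$recog_min)
    readr::write_tsv(ex, path_of("exclusions.tsv"))
    ex
  })
  retained <- results$exclusions$participant_id[!results$exclusions$excluded]
  kept <- dplyr::filter(results$trials, .data$participant_id %in% retained)

  results$counts <- run_stage("aggregate",
    aggregate_counts(kept, judgment = config$judgment))

  results$fit <- run_stage("fit", {
    fit <- fit_grt_wind(results$counts, n_restarts = config$fit$n_restarts,
                        seed = stage_seeds[2],
                        max_iter = config$fit$max_iter, tol = config$fit$tol)
    write_grt_fit(fit, path_of("fit.json"))
    fit
  })

  results$curve <- run_stage("curve", {
    curve <- build_svm_curve(results$fit, n_grid = config$curve$n_grid,
                             n_starts = config$curve$n_starts)
    write_svm_curve(curve, path_of(sprintf("curve_%s.tsv", config$judgment)))
    curve
  })

  if (config$bootstrap$n_boot > 0) {
    results$band <- run_stage("bootstrap", {
      band <- bootstrap_svm_band(
        results$fit, n_boot = config$bootstrap$n_boot,
        level = config$bootstrap$level, seed = stage_seeds[3],
        restarts_per_refit = config$bootstrap$restarts_per_refit,
        n_grid = config$bootstrap$n_grid)
      write_svm_band(band, path_of(sprintf("band_%s.tsv", config$judgment)))
      band
    })
  }

  results$descriptives <- run_stage("descriptives", {
    de <- confidence_by_state(kept, judgment = config$judgment,
                              include_catch = config$descriptives$include_catch)
    readr::write_tsv(de$means,
                     path_of(sprintf("descriptives_%s.tsv", config$judgment)))
    jsonlite::write_json(list(summary = de$summary, test = de$test),
                         path_of(sprintf("descriptives_%s.json",
                                         config$judgment)),
                         auto_unbox = TRUE, digits = NA, na = "null")
    de
  })

  manifest$status <- "complete"
  manifest$stage_seeds <- as.integer(stage_seeds)
  jsonlite::write_json(manifest, path_of("manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  results$manifest <- manifest
  invisible(results)
}
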