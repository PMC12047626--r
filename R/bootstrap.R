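## Parametric bootstrap for the SvM curve.
##
## Each replicate simulates multinomial count tables from the fitted model
## (same per-row trial totals as the data), refits the model with a reduced
## number of restarts, rebuilds the SvM curve, and evaluates its meta-d' as a
## function of the relative likelihood L on a fixed logarithmically spaced
## L grid -- L is the plotted x axis, and refits live on different y scales,
## so L is the only common axis. Pointwise simple percentiles over replicates
## give the band; band endpoints are actual replicate values.

#' Simulate count tables from a fitted model
#'
#' For every participant x stimulus row, draws a multinomial sample of the
#' requested total with the model's cell probabilities.
#'
#' @param fit A `grt_fit`.
#' @param row_totals Matrix of trial totals (participants x 3 stimuli, rows
#'   named by participant id) or `NULL` to reuse the fitted data's totals.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A long count tibble in the same format as [aggregate_counts()].
#' @export
simulate_counts <- function(fit, row_totals = NULL, seed = 1) {
  stopifnot(inherits(fit, "grt_fit") || (is.list(fit) &&
              all(c("group", "participants") %in% names(fit))))
  parts <- validate_participants(fit$participants)
  parts <- parts[order(parts$participant_id), ]
  group <- validate_group(fit$group)
  if (is.null(row_totals)) {
    ca <- counts_array(fit$data)
    row_totals <- apply(ca$arr, c(1, 2), sum)
    row_totals <- row_totals[match(parts$participant_id, rownames(row_totals)), ,
                             drop = FALSE]
  } else {
    if (!is.matrix(row_totals) || ncol(row_totals) != 3)
      abort("`row_totals` must be a participants x 3 matrix.")
    if (is.null(rownames(row_totals)))
      rownames(row_totals) <- parts$participant_id
    row_totals <- row_totals[match(parts$participant_id, rownames(row_totals)), ,
                             drop = FALSE]
  }
  if (any(row_totals <= 0) || anyNA(row_totals))
    abort("all row totals must be positive.")
  pr <- model_prob_array(group, parts)
  with_seed(seed, {
    out <- vector("list", nrow(parts) * 3)
    k <- 0
    for (i in seq_len(nrow(parts))) {
      for (s in seq_len(3)) {
        k <- k + 1
        draw <- as.integer(rmultinom(1, row_totals[i, s], pr[i, s, ]))
        out[[k]] <- tibble::tibble(
          participant_id = parts$participant_id[i],
          stimulus = STIMULI[s],
          metacog = rep(METACOG, each = 3),
          confcat = rep(CONFCAT, 2),
          n = draw)
      }
    }
    counts <- dplyr::bind_rows(out)
    attr(counts, "judgment") <- fit$judgment %||% NA_character_
    counts
  })
}

## invert L(y) = target on the monotone branch (both famous means > 0)
invert_L <- function(group, target) {
  f <- function(y) relative_likelihood(group, y) - target
  lo <- -50; hi <- max(group$mu_y) + 50
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Parametric-bootstrap percentile band for the SvM curve
#'
#' @param fit A `grt_fit` (point estimate).
#' @param n_boot Number of bootstrap replicates (the full-scale analysis uses
#'   1000).
#' @param level Band level, default 0.99 (simple pointwise percentiles).
#' @param seed Master seed; two child seeds per replicate (simulation, refit)
#'   are derived from it, so replicate `b` is reproducible in isolation.
#' @param restarts_per_refit Random restarts per bootstrap refit (default 10).
#' @param L_grid Common relative-likelihood grid; default 101 log-spaced
#'   points on `[0.1, 20]`.
#' @param n_grid Curve grid size per replicate.
#' @param metad_starts Optimization starts per grid point within replicates.
#' @return An object of class `svm_band`: the band tibble (`L`, `lower`,
#'   `upper`), the replicate matrix, the point-estimate curve evaluated on
#'   `L_grid`, and counts of failed refits. Replicates whose refitted model
#'   has a non-monotone relative likelihood (a famous metacognitive mean at
#'   or below zero) are dropped and counted as failures; more than 20%
#'   failures is an error.
#' @export
bootstrap_svm_band <- function(fit, n_boot = 1000, level = 0.99, seed = 1,
                               restarts_per_refit = 10, L_grid = NULL,
                               n_grid = 201, metad_starts = 3) {
  stopifnot(inherits(fit, "grt_fit"))
  check_scalar(level, "level", 0, 1, strict = c(TRUE, TRUE))
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  if (is.null(L_grid))
    L_grid <- exp(seq(log(0.1), log(20), length.out = 101))
  ca <- counts_array(fit$data)
  row_totals <- apply(ca$arr, c(1, 2), sum)
  seeds <- matrix(seed_stream(seed, 2 * n_boot), ncol = 2)
  reps <- matrix(NA_real_, n_boot, length(L_grid))
  failed <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    res <- tryCatch(suppressWarnings({
      sim <- simulate_counts(fit, row_totals = row_totals,
                             seed = seeds[b, 1])
      refit <- fit_grt_wind(sim, n_restarts = restarts_per_refit,
                            seed = seeds[b, 2])
      if (min(refit$group$mu_y[1:2]) <= 0)
        abort("refit has a non-positive famous metacognitive mean; L is not invertible.")
      y_lo <- invert_L(refit$group, min(L_grid))
      y_hi <- invert_L(refit$group, max(L_grid))
      curve <- build_svm_curve(refit,
                               y_grid = seq(y_lo, y_hi, length.out = n_grid),
                               n_starts = metad_starts)
      approx(curve$curve$rel_likelihood, curve$curve$meta_d,
             xout = L_grid, rule = 2)$y
    }), error = function(e) NULL)
    if (is.null(res)) failed[b] <- TRUE else reps[b, ] <- res
  }
  n_failed <- sum(failed)
  if (n_failed > 0.2 * n_boot)
    abort(sprintf("%d of %d bootstrap refits failed (> 20%%); the model or data are too unstable for a band.",
                  n_failed, n_boot))
  keep <- reps[!failed, , drop = FALSE]
  band <- band_from_replicates(keep, L_grid, level)
  ## point-estimate curve on the same grid
  pt <- tryCatch({
    y_lo <- invert_L(fit$group, min(L_grid))
    y_hi <- invert_L(fit$group, max(L_grid))
    curve <- build_svm_curve(fit, y_grid = seq(y_lo, y_hi,
                                               length.out = n_grid))
    approx(curve$curve$rel_likelihood, curve$curve$meta_d,
           xout = L_grid, rule = 2)$y
  }, error = function(e) rep(NA_real_, length(L_grid)))
  structure(list(
    band = dplyr::mutate(band, point = pt),
    replicates = keep,
    L_grid = L_grid,
    level = level,
    n_boot = n_boot,
    n_failed = n_failed,
    seed = seed,
    restarts_per_refit = restarts_per_refit),
    class = "svm_band")
}

#' Pointwise percentile band from a replicate matrix
#'
#' Simple percentiles (type-1 quantiles, i.e. actual replicate values) at
#' `(1 - level) / 2` and `1 - (1 - level) / 2`, per grid point.
#'
#' @param replicates Matrix, replicates x grid points.
#' @param L_grid Grid labels (one per column).
#' @param level Band level in (0, 1).
#' @return A tibble with columns `L`, `lower`, `upper`.
#' @export
band_from_replicates <- function(replicates, L_grid, level = 0.99) {
  check_scalar(level, "level", 0, 1, strict = c(TRUE, TRUE))
  alpha <- (1 - level) / 2
  tibble::tibble(
    L = L_grid,
    lower = apply(replicates, 2, quantile, probs = alpha, type = 1,
                  names = FALSE),
    upper = apply(replicates, 2, quantile, probs = 1 - alpha, type = 1,
                  names = FALSE))
}

#' @export
print.svm_band <- function(x, ...) {
  cat(sprintf("SvM bootstrap band: level %.2f, %d replicates (%d failed)\n",
              x$level, x$n_boot, x$n_failed))
  cat(sprintf("  L grid: %d points on [%.3g, %.3g]\n",
              length(x$L_grid), min(x$L_grid), max(x$L_grid)))
  invisible(x)
}

#' @rdname bootstrap_svm_band
#' @param x,object An `svm_band`.
#' @param ... Unused.
#' @method tidy svm_band
#' @export
tidy.svm_band <- function(x, ...) x$band

#' Write an SvM bootstrap band as annotated delimited text
#'
#' Tab-separated columns `L`, `lower`, `upper`, `point`, with a `#`-prefixed
#' metadata header recording the number of replicates, failures, level and
#' master seed.
#'
#' @param band An `svm_band`.
#' @param path File path.
#' @export
write_svm_band <- function(band, path) {
  stopifnot(inherits(band, "svm_band"))
  hdr <- c(sprintf("# svm_band v%s", utils::packageVersion("metagrt")),
           sprintf("# level: %g", band$level),
           sprintf("# n_boot: %d", band$n_boot),
           sprintf("# n_failed: %d", band$n_failed),
           sprintf("# seed: %d", band$seed))
  writeLines(hdr, path)
  readr::write_tsv(band$band, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
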