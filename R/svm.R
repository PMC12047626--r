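## Type-2 sensitivity-versus-metacognition (SvM) curves.
##
## Along the metacognitive-evidence axis y, two quantities are computed from
## the group model: (1) the relative likelihood L(y) that a famous-condition
## stimulus (rather than a catch stimulus) produced evidence y -- the curve's
## x axis, turning the binary state report into a graded strength -- and
## (2) the conditional meta-d', the sensitivity of an equal-variance SDT
## observer whose 3-category confidence probabilities best match the
## model-implied ones at height y. The objective criterion y* is where
## L(y*) = 1: with equal priors an optimal observer categorizes the
## metacognitive state there.

## conditional mean / sd of x given Y = y (unit marginal variances)
cond_ms <- function(mu_x, mu_y, rho, y) {
  list(mean = mu_x + rho * (y - mu_y), sd = sqrt(1 - rho^2))
}

#' Relative likelihood of the metacognitive state at evidence level y
#'
#' The equal-weight mixture of the two famous conditions' metacognitive
#' marginal densities, divided by the catch marginal density (group level,
#' unit variances). Values above 1 mean evidence y is better explained by a
#' famous stimulus (a "true" TOT/FOK state) than by a catch stimulus.
#'
#' @param group Group model.
#' @param y Numeric vector of metacognitive-evidence values.
#' @return Positive numeric vector, same length as `y`.
#' @examples
#' g <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
#' relative_likelihood(g, c(0, 0.5, 1))
#' @export
relative_likelihood <- function(group, y) {
  group <- validate_group(group)
  a <- group$mu_y[1]; b <- group$mu_y[2]
  ## density ratio N(y; mu, 1) / N(y; 0, 1) = exp(mu * y - mu^2 / 2)
  0.5 * exp(a * y - a^2 / 2) + 0.5 * exp(b * y - b^2 / 2)
}

#' Objective criterion of the optimal metacognitive observer
#'
#' Locates `y*` with `L(y*) = 1` by bracketed root finding on
#' `[-10, max(mu_y) + 10]` (tolerance 1e-10). With equal priors and unit
#' variances this boundary maximizes correct categorization of the
#' metacognitive state. If the famous and catch metacognitive distributions
#' coincide (`L` identically 1) there is no unique root and an error is
#' raised. If several roots exist (possible when the two famous means
#' straddle zero), the largest is returned with a warning.
#'
#' @param group Group model; at least one famous metacognitive mean should be
#'   positive.
#' @return The evidence level `y*` (a single number).
#' @examples
#' g <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
#' objective_criterion(g)  # 0.5: midpoint of equal-variance normals
#' @export
objective_criterion <- function(group) {
  group <- validate_group(group)
  a <- group$mu_y[1]; b <- group$mu_y[2]
  if (a == 0 && b == 0)
    abort("both famous metacognitive means are zero: L(y) is identically 1 and no unique objective criterion exists.")
  g <- function(y) relative_likelihood(group, y) - 1
  lo <- -10; hi <- max(group$mu_y) + 10
  ys <- seq(lo, hi, length.out = 4001)
  gv <- g(ys)
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(gv == 0)
  roots <- ys[exact]
  for (i in flips)
    roots <- c(roots, uniroot(g, c(ys[i], ys[i + 1]), tol = 1e-10)$root)
  roots <- sort(unique(roots))
  if (length(roots) == 0)
    abort("no root of L(y) = 1 found in the search interval.")
  if (length(roots) > 1)
    warn(sprintf("L(y) = 1 has %d roots; returning the largest (the operative low/high boundary).",
                 length(roots)))
  max(roots)
}

#' Conditional distribution of recognition evidence at a metacognitive level
#'
#' For each requested `y`, the distribution of x given Y = y under the
#' stimulus's bivariate normal: mean `mu_x + rho * (y - mu_y)`, standard
#' deviation `sqrt(1 - rho^2)` (constant in `y`).
#'
#' @param group Group model.
#' @param stimulus One stimulus condition.
#' @param y Numeric vector of evidence levels.
#' @return A tibble with columns `stimulus`, `y`, `mean`, `sd`.
#' @export
conditional_distribution <- function(group, stimulus, y) {
  group <- validate_group(group)
  stimulus <- match.arg(stimulus, STIMULI)
  s <- group[group$stimulus == stimulus, ]
  m <- cond_ms(s$mu_x, s$mu_y, s$rho, y)
  tibble::tibble(stimulus = stimulus, y = y, mean = m$mean, sd = m$sd)
}

#' Three-category confidence probabilities of a univariate normal
#'
#' Splits a normal distribution at the two confidence criteria:
#' `P(x < c_x1)`, `P(c_x1 <= x <= c_x2)`, `P(x > c_x2)`.
#'
#' @param mean,sd Distribution parameters (`sd > 0`).
#' @param c_x1,c_x2 Criteria with `c_x1 < c_x2`.
#' @return Named numeric 3-vector summing to 1.
#' @export
conditional_category_probs <- function(mean, sd, c_x1, c_x2) {
  if (sd <= 0) abort("`sd` must be positive.")
  if (c_x1 >= c_x2) abort("inverted criteria: `c_x1` must be below `c_x2`.")
  p1 <- pnorm((c_x1 - mean) / sd)
  p2 <- pnorm((c_x2 - mean) / sd)
  setNames(c(p1, p2 - p1, 1 - p2), CONFCAT)
}

#' Group-coordinate reference criteria of a fitted model
#'
#' Each participant's criteria are rescaled into group coordinates by the
#' per-dimension standard-deviation ratio implied by their scaling
#' (`sqrt(kappa * lambda)` for the x criteria, `sqrt(kappa * (1 - lambda))`
#' for the metacognitive criterion) and then averaged arithmetically.
#'
#' @param fit A `grt_fit`, or any list with `group` and `participants`.
#' @return A list with `c_x1`, `c_x2`, and the per-participant tibble
#'   `participants` (`participant_id`, `c_y_group`).
#' @export
reference_criteria <- function(fit) {
  p <- validate_participants(fit$participants)
  sx <- sqrt(p$kappa * p$lambda)
  sy <- sqrt(p$kappa * (1 - p$lambda))
  list(c_x1 = mean(p$c_x1 * sx),
       c_x2 = mean(p$c_x2 * sx),
       participants = tibble::tibble(participant_id = p$participant_id,
                                     c_y_group = p$c_y * sy))
}

## least-squares / KL discrepancy between SDT-observer and model-implied
## 3-category probabilities (2 stimuli x 3 categories)
## build a lean objective closure over the 6 target probabilities
## (correct-name categories then incorrect-name categories)
metad_objective <- function(q, disc) {
  q <- as.numeric(q)
  function(par) {
    d2 <- par[1] / 2
    t1 <- par[2]
    t2 <- t1 + exp(par[3])
    pc1 <- pnorm(t1 - d2); pc2 <- pnorm(t2 - d2)
    pi1 <- pnorm(t1 + d2); pi2 <- pnorm(t2 + d2)
    p <- c(pc1, pc2 - pc1, 1 - pc2, pi1, pi2 - pi1, 1 - pi2)
    if (disc == "ls") {
      sum((p - q)^2)
    } else {
      sum(q * (log(pmax(q, 1e-12)) - log(pmax(p, 1e-12))))
    }
  }
}

#' Conditional meta-d' at a metacognitive-evidence level
#'
#' Computes the model-implied 3-category confidence probabilities of the
#' correct-name and incorrect-name conditions at height `y` (bivariate-normal
#' conditioning plus the reference criteria), then finds the equal-variance
#' SDT observer -- means at `+/- meta_d / 2`, unit standard deviations, free
#' ordered criteria -- whose category probabilities are closest to them.
#' `meta_d` is positive when confident-correct responses are more probable
#' under the correct-name condition. The discrepancy is unweighted least
#' squares over the six probabilities by default; a KL-divergence variant is
#' available.
#'
#' @param group Group model.
#' @param ref_criteria List or numeric with `c_x1`, `c_x2` (group-coordinate
#'   reference criteria; see [reference_criteria()]).
#' @param y Evidence level (single number).
#' @param n_starts Number of deterministic optimization starts (default 10).
#' @param method `"ls"` (default) or `"kl"`.
#' @param extra_starts Optional list of additional `c(meta_d, t1, t2)` starts
#'   (used internally for warm starts along a grid).
#' @return A list of class `sdt_fit`: `meta_d`, `t1`, `t2`, `loss`,
#'   `converged`.
#' @export
fit_conditional_metad <- function(group, ref_criteria, y, n_starts = 10,
                                  method = c("ls", "kl"),
                                  extra_starts = NULL) {
  method <- match.arg(method)
  group <- validate_group(group)
  c1 <- ref_criteria$c_x1 %||% ref_criteria[[1]]
  c2 <- ref_criteria$c_x2 %||% ref_criteria[[2]]
  if (c1 >= c2) abort("inverted reference criteria: `c_x1` must be below `c_x2`.")
  dc <- cond_ms(group$mu_x[1], group$mu_y[1], group$rho[1], y)
  di <- cond_ms(group$mu_x[2], group$mu_y[2], group$rho[2], y)
  q <- c(conditional_category_probs(dc$mean, dc$sd, c1, c2),
         conditional_category_probs(di$mean, di$sd, c1, c2))
  obj <- metad_objective(q, method)
  ## deterministic start set: a moment-matched guess plus dispersed points
  sbar <- (dc$sd + di$sd) / 2
  mbar <- (dc$mean + di$mean) / 2
  d0 <- (dc$mean - di$mean) / sbar
  t0 <- sort(c((c1 - mbar) / sbar, (c2 - mbar) / sbar))
  starts <- list(
    c(d0, t0), c(0, -0.5, 0.5), c(1, -1, 1), c(2, -1, 1), c(4, -2, 2),
    c(-d0, t0), c(0.5, 0, 0.5), c(3, -0.5, 1.5), c(d0 / 2, t0 / 2),
    c(d0 * 2, t0))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  starts <- c(extra_starts, starts)
  best <- NULL
  for (s in starts) {
    gap <- max(s[3] - s[2], 1e-6)
    par0 <- c(s[1], s[2], log(gap))
    res <- tryCatch(
      optim(par0, obj, method = "BFGS",
            control = list(maxit = 100, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value < 1e-16) break   # exact fit reached; remaining starts moot
  }
  if (is.null(best))
    abort("conditional meta-d' optimization failed from every start.")
  structure(list(meta_d = best$par[1], t1 = best$par[2],
                 t2 = best$par[2] + exp(best$par[3]),
                 loss = best$value, converged = best$convergence == 0),
            class = "sdt_fit")
}

#' Build a type-2 SvM curve from a fitted model
#'
#' Evaluates the relative likelihood and the conditional meta-d' on a grid of
#' metacognitive-evidence values (default: 201 points on
#' `[-3, max(mu_y) + 3]`), locates the objective criterion, and maps each
#' participant's metacognitive criterion onto the relative-likelihood axis.
#'
#' @param fit A `grt_fit` (or any list with `group` and `participants`).
#' @param y_grid Optional explicit grid (ascending numeric vector).
#' @param n_grid Grid size when `y_grid` is `NULL`.
#' @param y_range Grid range when `y_grid` is `NULL`; default
#'   `c(-3, max(mu_y) + 3)`.
#' @param n_starts,method Passed to [fit_conditional_metad()]; the solution at
#'   the previous grid point is reused as a warm start.
#' @return An object of class `svm_curve`: the curve tibble (`y`,
#'   `rel_likelihood`, `meta_d`, `loss`), `y_star`, the reference criteria,
#'   and per-participant criterion positions.
#' @export
build_svm_curve <- function(fit, y_grid = NULL, n_grid = 201, y_range = NULL,
                            n_starts = 10, method = c("ls", "kl")) {
  method <- match.arg(method)
  group <- validate_group(fit$group)
  y_star <- objective_criterion(group)      # errors on the degenerate model
  rc <- reference_criteria(fit)
  if (is.null(y_grid)) {
    if (is.null(y_range)) y_range <- c(-3, max(group$mu_y) + 3)
    y_grid <- seq(y_range[1], y_range[2], length.out = n_grid)
  }
  if (is.unsorted(y_grid, strictly = TRUE))
    abort("`y_grid` must be strictly increasing.")
  meta_d <- loss <- numeric(length(y_grid))
  warm <- NULL
  for (i in seq_along(y_grid)) {
    sf <- fit_conditional_metad(group, rc, y_grid[i], n_starts = n_starts,
                                method = method, extra_starts = warm)
    meta_d[i] <- sf$meta_d
    loss[i] <- sf$loss
    warm <- list(c(sf$meta_d, sf$t1, sf$t2))
  }
  pos <- dplyr::mutate(rc$participants,
                       position = relative_likelihood(group, .data$c_y_group))
  structure(list(
    curve = tibble::tibble(y = y_grid,
                           rel_likelihood = relative_likelihood(group, y_grid),
                           meta_d = meta_d, loss = loss),
    y_star = y_star,
    L_star = relative_likelihood(group, y_star),
    ref_criteria = rc[c("c_x1", "c_x2")],
    participants = pos,
    judgment = fit$judgment %||% NA_character_,
    group = group),
    class = "svm_curve")
}

#' @export
print.svm_curve <- function(x, ...) {
  cat("Type-2 SvM curve\n")
  cat(sprintf("  grid: %d points on [%.3f, %.3f]   judgment: %s\n",
              nrow(x$curve), min(x$curve$y), max(x$curve$y),
              if (is.na(x$judgment)) "?" else x$judgment))
  cat(sprintf("  objective criterion y* = %.6f (L = %.6f)\n",
              x$y_star, x$L_star))
  cat(sprintf("  meta-d' range: [%.4f, %.4f]\n",
              min(x$curve$meta_d), max(x$curve$meta_d)))
  invisible(x)
}

#' @rdname build_svm_curve
#' @param x,object An `svm_curve`.
#' @param ... Unused.
#' @method tidy svm_curve
#' @export
tidy.svm_curve <- function(x, ...) x$curve

#' @rdname build_svm_curve
#' @method glance svm_curve
#' @export
glance.svm_curve <- function(x, ...) {
  tibble::tibble(
    y_star = x$y_star,
    L_star = x$L_star,
    meta_d_at_y_star = approx(x$curve$y, x$curve$meta_d, x$y_star)$y,
    meta_d_min = min(x$curve$meta_d),
    meta_d_max = max(x$curve$meta_d),
    n_grid = nrow(x$curve))
}

#' Write / read an SvM curve as annotated delimited text
#'
#' Tab-separated columns `y`, `rel_likelihood`, `meta_d`, `loss`, preceded by
#' `#`-prefixed header lines recording the objective criterion, the reference
#' criteria, the judgment label, and each participant's criterion position.
#'
#' @param curve An `svm_curve`.
#' @param path File path.
#' @export
write_svm_curve <- function(curve, path) {
  stopifnot(inherits(curve, "svm_curve"))
  hdr <- c(
    sprintf("# svm_curve v%s", utils::packageVersion("metagrt")),
    sprintf("# judgment: %s", curve$judgment),
    sprintf("# y_star: %.17g", curve$y_star),
    sprintf("# c_x1: %.17g", curve$ref_criteria$c_x1),
    sprintf("# c_x2: %.17g", curve$ref_criteria$c_x2),
    sprintf("# participant: %s %.17g %.17g", curve$participants$participant_id,
            curve$participants$c_y_group, curve$participants$position))
  writeLines(hdr, path)
  readr::write_tsv(curve$curve, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_svm_curve
#' @export
read_svm_curve <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get1 <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    sub(paste0("^# ", key, ": *"), "", ln[1])
  }
  pl <- hdr[startsWith(hdr, "# participant:")]
  pf <- do.call(rbind, strsplit(sub("^# participant: *", "", pl), " "))
  curve_tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  structure(list(
    curve = curve_tbl,
    y_star = as.numeric(get1("y_star")),
    L_star = 1,
    ref_criteria = list(c_x1 = as.numeric(get1("c_x1")),
                        c_x2 = as.numeric(get1("c_x2"))),
    participants = tibble::tibble(participant_id = pf[, 1],
                                  c_y_group = as.numeric(pf[, 2]),
                                  position = as.numeric(pf[, 3])),
    judgment = get1("judgment"),
    group = NULL),
    class = "svm_curve")
}
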