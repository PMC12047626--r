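## The 2-D decision space.
##
## Each stimulus condition (correct name, incorrect name, catch) is a
## bivariate Gaussian over (x = recognition/confidence evidence,
## y = metacognitive evidence). The group model holds the shared stimulus
## means and per-stimulus correlations; marginal variances are fixed at 1 and
## the catch distribution is anchored at the origin, which together remove
## the usual location/scale indeterminacies of the space. Each participant
## sees a scaled copy of the space (global scale kappa, attention share
## lambda) and carries three axis-parallel decision criteria: c_y separating
## state-absent from state-present reports, and c_x1 < c_x2 carving the x
## axis into confident-incorrect / not-confident / confident-correct.

#' Construct a group-level decision-space model
#'
#' @param mu_x,mu_y Numeric length-2 vectors: evidence means of the
#'   correct-name and incorrect-name conditions (in that order) on the
#'   recognition (x) and metacognitive (y) axes. The catch condition is fixed
#'   at the origin and is not a parameter.
#' @param rho Numeric length-3 vector of within-stimulus correlations for
#'   correct-name, incorrect-name and catch, each strictly inside (-1, 1).
#' @return A tibble with one row per stimulus condition and columns
#'   `stimulus`, `mu_x`, `mu_y`, `rho`, of class `grt_group`.
#' @examples
#' group_model(mu_x = c(1, -1), mu_y = c(1, 1), rho = c(0.5, -0.5, 0))
#' @export
group_model <- function(mu_x, mu_y, rho) {
  if (length(mu_x) != 2 || length(mu_y) != 2)
    abort("`mu_x` and `mu_y` must have length 2 (correct-name, incorrect-name); the catch mean is fixed at the origin.")
  if (length(rho) != 3)
    abort("`rho` must have length 3 (correct-name, incorrect-name, catch).")
  if (any(!is.finite(c(mu_x, mu_y, rho))))
    abort("group parameters must be finite.")
  if (any(abs(rho) >= 1))
    abort("every `rho` must satisfy |rho| < 1.")
  out <- tibble::tibble(
    stimulus = STIMULI,
    mu_x = c(mu_x, 0),
    mu_y = c(mu_y, 0),
    rho = rho)
  class(out) <- c("grt_group", class(out))
  out
}

## validate an object that should be a group model (tibble or grt_group)
validate_group <- function(group) {
  need <- c("stimulus", "mu_x", "mu_y", "rho")
  if (!is.data.frame(group) || !all(need %in% names(group)))
    abort("`group` must be a data frame with columns stimulus, mu_x, mu_y, rho.")
  if (!setequal(group$stimulus, STIMULI) || nrow(group) != 3)
    abort(sprintf("`group` must contain exactly the three stimulus conditions: %s.",
                  paste(STIMULI, collapse = ", ")))
  group <- group[match(STIMULI, group$stimulus), ]
  k <- group[group$stimulus == "catch", ]
  if (k$mu_x != 0 || k$mu_y != 0)
    abort("the catch condition mean must be exactly (0, 0).")
  if (any(abs(group$rho) >= 1)) abort("every `rho` must satisfy |rho| < 1.")
  group
}

#' Construct a table of participant-level parameters
#'
#' @param participant_id Vector of unique participant identifiers.
#' @param kappa Global scaling, `kappa > 0`. Larger values shrink the
#'   participant's perceptual noise relative to the group space.
#' @param lambda Attention share in (0, 1): the fraction of scaling allotted
#'   to the recognition (x) axis; `1 - lambda` goes to the metacognitive axis.
#' @param c_y Metacognitive criterion: evidence above it is reported as
#'   state-present (TOT yes / FOK high).
#' @param c_x1,c_x2 Confidence criteria on the x axis, `c_x1 < c_x2`.
#' @return A tibble of class `grt_participants`.
#' @examples
#' participant_params("p1", kappa = 2, lambda = 0.5, c_y = 0, c_x1 = -1, c_x2 = 1)
#' @export
participant_params <- function(participant_id, kappa, lambda, c_y, c_x1, c_x2) {
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    kappa = as.numeric(kappa), lambda = as.numeric(lambda),
    c_y = as.numeric(c_y), c_x1 = as.numeric(c_x1), c_x2 = as.numeric(c_x2))
  validate_participants(out)
}

validate_participants <- function(parts) {
  need <- c("participant_id", "kappa", "lambda", "c_y", "c_x1", "c_x2")
  if (!is.data.frame(parts) || !all(need %in% names(parts)))
    abort("participant parameters must have columns participant_id, kappa, lambda, c_y, c_x1, c_x2.")
  if (anyDuplicated(parts$participant_id))
    abort("participant ids must be unique.")
  if (any(parts$kappa <= 0)) abort("`kappa` must be > 0 for every participant.")
  if (any(parts$lambda <= 0 | parts$lambda >= 1))
    abort("`lambda` must lie strictly in (0, 1) for every participant.")
  if (any(parts$c_x1 >= parts$c_x2))
    abort("`c_x1` must be strictly below `c_x2` for every participant.")
  if (!inherits(parts, "grt_participants"))
    class(parts) <- c("grt_participants", class(parts))
  parts
}

#' Participant-specific covariance matrix
#'
#' In the individual-differences scaling convention, participant `i` perceives
#' the shared space with marginal variances `1 / (kappa * lambda)` on the
#' recognition axis and `1 / (kappa * (1 - lambda))` on the metacognitive
#' axis; the stimulus correlation `rho` is shared with the group.
#'
#' @param rho Stimulus correlation, `|rho| < 1`.
#' @param kappa Global scaling, `> 0`.
#' @param lambda Attention share, in `(0, 1)`.
#' @return A 2x2 symmetric positive-definite covariance matrix.
#' @examples
#' participant_covariance(rho = 0, kappa = 2, lambda = 0.5)  # identity
#' @export
participant_covariance <- function(rho, kappa, lambda) {
  check_scalar(rho, "rho", -1, 1, strict = c(TRUE, TRUE))
  check_scalar(kappa, "kappa", 0, Inf, strict = c(TRUE, FALSE))
  check_scalar(lambda, "lambda", 0, 1, strict = c(TRUE, TRUE))
  vx <- 1 / (kappa * lambda)
  vy <- 1 / (kappa * (1 - lambda))
  cxy <- rho * sqrt(vx * vy)
  matrix(c(vx, cxy, cxy, vy), 2, 2)
}

## Vectorized 6-cell probabilities.
##
## All arguments are parallel vectors (one element per participant x stimulus
## combination). Returns a matrix with one row per element and the 6 columns
## in canonical CELLS order. Cells are axis-aligned rectangles, so the whole
## grid needs just two bivariate CDF values per element plus univariate
## marginals.
cell_prob_core <- function(mu_x, mu_y, rho, kappa, lambda, c_y, c_x1, c_x2) {
  sx <- 1 / sqrt(kappa * lambda)
  sy <- 1 / sqrt(kappa * (1 - lambda))
  zx1 <- (c_x1 - mu_x) / sx
  zx2 <- (c_x2 - mu_x) / sx
  zy <- (c_y - mu_y) / sy
  a1 <- pbvnorm(zx1, zy, rho)     # P(x <= c_x1, y <= c_y)
  a2 <- pbvnorm(zx2, zy, rho)     # P(x <= c_x2, y <= c_y)
  px1 <- pnorm(zx1); px2 <- pnorm(zx2); py <- pnorm(zy)
  p <- cbind(
    a1,                            # absent,  conf_incorrect
    a2 - a1,                       # absent,  not_conf
    py - a2,                       # absent,  conf_correct
    px1 - a1,                      # present, conf_incorrect
    (px2 - px1) - (a2 - a1),       # present, not_conf
    1 - px2 - py + a2)             # present, conf_correct
  p[p < 0] <- 0                    # guard against cancellation at the edges
  colnames(p) <- CELLS
  p
}

#' Joint response-category probabilities for one participant and stimulus
#'
#' The three criteria (`c_y`; `c_x1 < c_x2`) tile the plane into 2 x 3
#' axis-aligned rectangles; this returns the probability mass of each under
#' the participant's scaled bivariate normal for the given stimulus.
#'
#' @param group A group model (see [group_model()]).
#' @param participant A single row of participant parameters (see
#'   [participant_params()]).
#' @param stimulus One of `"correct_name"`, `"incorrect_name"`, `"catch"`.
#' @return A tibble with columns `metacog`, `confcat`, `prob` (6 rows summing
#'   to 1).
#' @examples
#' g <- group_model(c(1, -1), c(1, 1), c(0, 0, 0))
#' p <- participant_params("p1", 2, 0.5, 0, -1, 1)
#' cell_probabilities(g, p, "catch")
#' @export
cell_probabilities <- function(group, participant, stimulus) {
  group <- validate_group(group)
  participant <- validate_participants(participant)
  if (nrow(participant) != 1)
    abort("`participant` must be a single row of parameters.")
  stimulus <- match.arg(stimulus, STIMULI)
  s <- group[group$stimulus == stimulus, ]
  p <- cell_prob_core(s$mu_x, s$mu_y, s$rho,
                      participant$kappa, participant$lambda,
                      participant$c_y, participant$c_x1, participant$c_x2)
  tibble::tibble(
    metacog = rep(METACOG, each = 3),
    confcat = rep(CONFCAT, 2),
    prob = as.numeric(p))
}

## counts tibble (long) -> list(ids, arr[n_participants, 3 stimuli, 6 cells])
counts_array <- function(counts) {
  need <- c("participant_id", "stimulus", "metacog", "confcat", "n")
  if (!is.data.frame(counts) || !all(need %in% names(counts)))
    abort("`counts` must have columns participant_id, stimulus, metacog, confcat, n.")
  if (any(counts$n < 0) || any(counts$n != round(counts$n)))
    abort("counts must be non-negative integers.")
  ids <- sort(unique(as.character(counts$participant_id)))
  arr <- array(0, dim = c(length(ids), 3, 6),
               dimnames = list(ids, STIMULI, CELLS))
  cell <- paste(counts$metacog, counts$confcat, sep = ".")
  bad <- !(cell %in% CELLS) | !(counts$stimulus %in% STIMULI)
  if (any(bad))
    abort("unknown stimulus/metacog/confcat codes in `counts`.")
  idx <- cbind(match(as.character(counts$participant_id), ids),
               match(counts$stimulus, STIMULI),
               match(cell, CELLS))
  if (anyDuplicated(idx))
    abort("duplicated participant x stimulus x cell rows in `counts`.")
  arr[idx] <- counts$n
  list(ids = ids, arr = arr)
}

## arr counterpart of cell_prob_core for a whole model:
## returns [n_participants, 3, 6] probability array in canonical order
model_prob_array <- function(group, parts) {
  n <- length(parts$kappa)
  ## expand participant x stimulus grid (stimulus fast)
  i <- rep(seq_len(n), each = 3)
  s <- rep(seq_len(3), n)
  p <- cell_prob_core(group$mu_x[s], group$mu_y[s], group$rho[s],
                      parts$kappa[i], parts$lambda[i],
                      parts$c_y[i], parts$c_x1[i], parts$c_x2[i])
  arr <- array(0, dim = c(n, 3, 6),
               dimnames = list(parts$participant_id, STIMULI, CELLS))
  for (cc in 1:6) arr[cbind(i, s, cc)] <- p[, cc]
  arr
}

#' Multinomial log-likelihood of count tables under a decision-space model
#'
#' Sums `n * log(p)` over participants, stimuli and the six joint response
#' cells, with cell probabilities from the model. The multinomial coefficient
#' is omitted (it does not depend on the parameters). Probabilities are
#' clamped at 1e-300 before taking logs, so a positive count on a
#' numerically-zero cell contributes a large negative penalty rather than
#' `-Inf`, keeping optimization finite.
#'
#' @param counts Long count table: columns `participant_id`, `stimulus`,
#'   `metacog`, `confcat`, `n` (see [aggregate_counts()]).
#' @param group Group model.
#' @param participants Participant parameter table; ids must match `counts`.
#' @return A single number (the data log-likelihood up to the multinomial
#'   constant).
#' @export
log_likelihood <- function(counts, group, participants) {
  group <- validate_group(group)
  participants <- validate_participants(participants)
  ca <- counts_array(counts)
  if (!setequal(ca$ids, participants$participant_id))
    abort("participant ids in `counts` and `participants` do not match.")
  parts <- participants[match(ca$ids, participants$participant_id), ]
  pr <- model_prob_array(group, parts)
  sum(ca$arr * log(pmax(pr, 1e-300)))
}

## fast path used inside the optimizer: counts already an array aligned with
## parts row order
ll_array <- function(arr, group, parts) {
  pr <- model_prob_array(group, parts)
  sum(arr * log(pmax(pr, 1e-300)))
}
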