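## Maximum-likelihood fitting.
##
## The optimizer works on an unconstrained parameter vector: correlations via
## atanh, kappa via log, lambda via logit, and the upper confidence criterion
## as c_x1 plus an exponentiated gap, so every vector unpacks to a valid
## model. Layout (length 7 + 5 * n_participants):
##   [1:4]  mu_x, mu_y of correct-name; mu_x, mu_y of incorrect-name
##   [5:7]  atanh(rho) for correct-name, incorrect-name, catch
##   then per participant (ids in sorted order):
##          log(kappa), qlogis(lambda), c_y, c_x1, log(c_x2 - c_x1)

N_GROUP_PAR <- 7L
N_PART_PAR <- 5L

#' Pack a model into the unconstrained optimizer vector
#'
#' @param group Group model (see [group_model()]).
#' @param participants Participant parameter table.
#' @return Numeric vector of length `7 + 5 * n_participants`. Participants are
#'   packed in sorted id order.
#' @seealso [unpack_parameters()] for the inverse.
#' @export
pack_parameters <- function(group, participants) {
  group <- validate_group(group)
  participants <- validate_participants(participants)
  parts <- participants[order(participants$participant_id), ]
  c(group$mu_x[1], group$mu_y[1], group$mu_x[2], group$mu_y[2],
    atanh(group$rho),
    as.numeric(t(cbind(log(parts$kappa), qlogis(parts$lambda),
                       parts$c_y, parts$c_x1,
                       log(parts$c_x2 - parts$c_x1)))))
}

## fast unpack used in the optimizer: plain lists, no validation
unpack_fast <- function(theta, ids) {
  n <- length(ids)
  pp <- matrix(theta[-seq_len(N_GROUP_PAR)], nrow = N_PART_PAR)
  gap <- exp(pp[5, ])
  list(
    group = list(mu_x = c(theta[1], theta[3], 0),
                 mu_y = c(theta[2], theta[4], 0),
                 rho = tanh(theta[5:7])),
    parts = list(participant_id = ids,
                 kappa = exp(pp[1, ]), lambda = plogis(pp[2, ]),
                 c_y = pp[3, ], c_x1 = pp[4, ], c_x2 = pp[4, ] + gap))
}

#' Unpack the unconstrained optimizer vector into a model
#'
#' @param theta Numeric vector as produced by [pack_parameters()].
#' @param participant_ids Character vector of participant ids (defines the
#'   number of participants and the row order).
#' @return A list with elements `group` (a [group_model()] tibble) and
#'   `participants` (a [participant_params()] tibble).
#' @export
unpack_parameters <- function(theta, participant_ids) {
  n <- length(participant_ids)
  if (length(theta) != N_GROUP_PAR + N_PART_PAR * n)
    abort(sprintf("`theta` must have length %d for %d participants, got %d.",
                  N_GROUP_PAR + N_PART_PAR * n, n, length(theta)))
  u <- unpack_fast(theta, as.character(participant_ids))
  list(
    group = group_model(mu_x = u$group$mu_x[1:2], mu_y = u$group$mu_y[1:2],
                        rho = u$group$rho),
    participants = participant_params(u$parts$participant_id, u$parts$kappa,
                                      u$parts$lambda, u$parts$c_y,
                                      u$parts$c_x1, u$parts$c_x2))
}

#' Draw a random starting vector for the optimizer
#'
#' Group means are uniform on `[-3, 3]` with the metacognitive means of the
#' two famous conditions forced non-negative and the recognition means
#' sign-assigned by the axis convention (correct-name positive,
#' incorrect-name negative); correlations are uniform on `(-0.8, 0.8)`;
#' `kappa` is log-uniform on `[0.5, 8]`; `lambda` uniform on `(0.2, 0.8)`;
#' criteria uniform on `[-2, 2]` with the two confidence criteria ordered.
#'
#' @param seed Integer seed; the start is a deterministic function of it.
#' @param n_participants Number of participants (`>= 1`).
#' @return Unconstrained parameter vector (see [pack_parameters()]).
#' @export
random_start <- function(seed, n_participants) {
  stopifnot(n_participants >= 1)
  with_seed(seed, {
    mu_x <- c(runif(1, 0, 3), runif(1, -3, 0))
    mu_y <- runif(2, 0, 3)
    rho <- runif(3, -0.8, 0.8)
    kappa <- exp(runif(n_participants, log(0.5), log(8)))
    lambda <- runif(n_participants, 0.2, 0.8)
    c_y <- runif(n_participants, -2, 2)
    cx <- matrix(runif(2 * n_participants, -2, 2), nrow = 2)
    cx <- apply(cx, 2, sort)
    cx[2, ] <- cx[1, ] + pmax(cx[2, ] - cx[1, ], 1e-3)  # strict ordering
    c(mu_x[1], mu_y[1], mu_x[2], mu_y[2], atanh(rho),
      as.numeric(rbind(log(kappa), qlogis(lambda), c_y, cx[1, ],
                       log(cx[2, ] - cx[1, ]))))
  })
}

## Scale anchor. The fixed catch mean and unit group variances do not pin
## the space: each axis can be rescaled separately, with the factor absorbed
## jointly by the participants' (kappa, lambda) -- a two-parameter orbit
## along which the likelihood is exactly flat. Pin it by forcing the
## geometric means over participants of kappa*lambda (x precision) and
## kappa*(1-lambda) (y precision) both to 1: the average participant sees
## unit variances, consistent with the unit group variances (and implying
## kappa = 2 for a lambda = 0.5 participant). Applying the transformation
## changes no cell probability.
anchor_scale <- function(theta, n) {
  pp <- matrix(theta[-seq_len(N_GROUP_PAR)], nrow = N_PART_PAR)
  kappa <- exp(pp[1, ]); lambda <- plogis(pp[2, ])
  a <- sqrt(exp(mean(log(kappa * lambda))))         # x-axis factor
  b <- sqrt(exp(mean(log(kappa * (1 - lambda)))))   # y-axis factor
  theta[c(1, 3)] <- theta[c(1, 3)] * a              # mu_x
  theta[c(2, 4)] <- theta[c(2, 4)] * b              # mu_y
  px <- kappa * lambda / a^2
  py <- kappa * (1 - lambda) / b^2
  pp[1, ] <- log(px + py)                           # kappa'
  pp[2, ] <- qlogis(px / (px + py))                 # lambda'
  pp[3, ] <- pp[3, ] * b                            # c_y
  pp[4, ] <- pp[4, ] * a                            # c_x1
  pp[5, ] <- pp[5, ] + log(a)                       # log gap
  c(theta[1:4], theta[5:7], as.numeric(pp))
}

#' Fit the individual-differences decision-space model by maximum likelihood
#'
#' Runs a quasi-Newton (BFGS) maximization of the multinomial log-likelihood
#' over the unconstrained parameter vector, restarted from `n_restarts`
#' random configurations, and keeps the best. A scale anchor (geometric mean
#' of `kappa * lambda` and of `kappa * (1 - lambda)` both 1, so the average
#' participant sees unit variances) is applied to every restart's solution;
#' it changes no cell probability. The result is deterministic given
#' `(counts, seed, n_restarts)`.
#'
#' @param counts Long count table (`participant_id`, `stimulus`, `metacog`,
#'   `confcat`, `n`); every participant x stimulus row must have a positive
#'   total.
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Master seed; one child seed per restart is derived from it.
#' @param max_iter Maximum BFGS iterations per restart.
#' @param tol Relative convergence tolerance on the objective.
#' @return An object of class `grt_fit`: group and participant estimates,
#'   the attained log-likelihood, per-restart diagnostics, the percentage of
#'   variance in observed cell proportions accounted for, and the data.
#' @export
fit_grt_wind <- function(counts, n_restarts = 100, seed = 1,
                         max_iter = 2000, tol = 1e-8) {
  ca <- counts_array(counts)
  n <- length(ca$ids)
  if (n < 1) abort("`counts` contains no participants.")
  row_tot <- apply(ca$arr, c(1, 2), sum)
  if (any(row_tot <= 0))
    abort(paste0("every participant x stimulus row must have a positive total; ",
                 "offending participants: ",
                 paste(unique(ca$ids[which(row_tot <= 0, arr.ind = TRUE)[, 1]]),
                       collapse = ", ")))
  if (n_restarts < 1) abort("`n_restarts` must be >= 1.")
  ## count matrix in the row layout of the vectorized probability kernel
  ## (participant slow, stimulus fast), one column per cell
  cnt <- matrix(aperm(ca$arr, c(3, 2, 1)), ncol = 6, byrow = TRUE)
  i_of <- rep(seq_len(n), each = 3)
  s_of <- rep(seq_len(3), n)
  prob_rows <- function(theta) {
    u <- unpack_fast(theta, ca$ids)
    g <- u$group; p <- u$parts
    cell_prob_core(g$mu_x[s_of], g$mu_y[s_of], g$rho[s_of],
                   p$kappa[i_of], p$lambda[i_of],
                   p$c_y[i_of], p$c_x1[i_of], p$c_x2[i_of])
  }
  ll_rows <- function(theta) rowSums(cnt * log(pmax(prob_rows(theta), 1e-300)))
  nll <- function(theta) -sum(ll_rows(theta))
  ll_by_part <- function(theta) colSums(matrix(ll_rows(theta), nrow = 3))
  ## central-difference gradient exploiting the likelihood's structure: a
  ## participant's parameters affect only their own rows, so one batched
  ## evaluation per parameter type yields every participant's partial
  gr <- function(theta) {
    eps <- 1e-6
    g <- numeric(length(theta))
    for (j in seq_len(N_GROUP_PAR)) {
      tp <- theta; tp[j] <- tp[j] + eps
      tm <- theta; tm[j] <- tm[j] - eps
      g[j] <- (nll(tp) - nll(tm)) / (2 * eps)
    }
    for (k in seq_len(N_PART_PAR)) {
      idx <- N_GROUP_PAR + k + N_PART_PAR * (seq_len(n) - 1)
      tp <- theta; tp[idx] <- tp[idx] + eps
      tm <- theta; tm[idx] <- tm[idx] - eps
      g[idx] <- -(ll_by_part(tp) - ll_by_part(tm)) / (2 * eps)
    }
    g
  }
  restart_seeds <- seed_stream(seed, n_restarts)
  thetas <- vector("list", n_restarts)
  vals <- rep(NA_real_, n_restarts)
  conv <- rep(FALSE, n_restarts)
  for (r in seq_len(n_restarts)) {
    start <- random_start(restart_seeds[r], n)
    res <- tryCatch(
      optim(start, nll, gr = gr, method = "BFGS",
            control = list(maxit = max_iter, reltol = tol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    thetas[[r]] <- anchor_scale(res$par, n)
    vals[r] <- -res$value
    conv[r] <- res$convergence == 0
  }
  if (all(is.na(vals)))
    abort(sprintf("all %d restarts failed to produce a finite likelihood.",
                  n_restarts))
  best <- which.max(vals)
  u <- unpack_parameters(thetas[[best]], ca$ids)
  if (u$group$mu_x[1] < u$group$mu_x[2])
    warn("fitted recognition means violate the axis convention (correct-name should exceed incorrect-name); inspect the data.")
  fit <- structure(list(
    group = u$group,
    participants = u$participants,
    loglik = vals[best],
    n_restarts = n_restarts,
    restart_logliks = vals,
    converged = conv,
    best_restart = best,
    seed = seed,
    judgment = attr(counts, "judgment", exact = TRUE) %||% NA_character_,
    data = tibble::as_tibble(counts),
    version = as.character(utils::packageVersion("metagrt"))),
    class = "grt_fit")
  fit$pct_variance <- variance_accounted(fit)
  fit
}

#' Percentage of variance in observed cell proportions accounted for
#'
#' Computes `100 * r^2`, where `r` is the Pearson correlation between the
#' observed cell proportions (per participant x stimulus x cell) and the
#' model-predicted probabilities, pooled over all cells. Rows with a zero
#' total are excluded.
#'
#' @param fit A `grt_fit` object.
#' @param counts Count table; defaults to the data the model was fitted to.
#' @return A percentage in `[0, 100]`.
#' @export
variance_accounted <- function(fit, counts = fit$data) {
  stopifnot(inherits(fit, "grt_fit"))
  ca <- counts_array(counts)
  parts <- fit$participants[match(ca$ids, fit$participants$participant_id), ]
  if (anyNA(parts$kappa))
    abort("`counts` contains participants absent from the fitted model.")
  pr <- model_prob_array(validate_group(fit$group), parts)
  tot <- apply(ca$arr, c(1, 2), sum)
  keep <- array(rep(tot > 0, 6), dim = dim(ca$arr))
  obs <- (ca$arr / array(rep(pmax(tot, 1), 6), dim = dim(ca$arr)))[keep]
  pred <- pr[keep]
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    abort("observed or predicted proportions are constant; variance accounted for is undefined.")
  100 * cor(obs, pred)^2
}

#' @export
print.grt_fit <- function(x, ...) {
  cat("Decision-space model fit (GRT with individual differences)\n")
  cat(sprintf("  participants: %d   judgment: %s\n",
              nrow(x$participants),
              if (is.na(x$judgment)) "?" else x$judgment))
  cat(sprintf("  log-likelihood: %.4f  (best of %d restarts, %d converged)\n",
              x$loglik, x$n_restarts, sum(x$converged)))
  cat(sprintf("  variance accounted for: %.2f%%\n", x$pct_variance))
  cat("  group means / correlations:\n")
  print(as.data.frame(x$group), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_grt_wind
#' @param x,object A `grt_fit` object.
#' @param ... Unused.
#' @method tidy grt_fit
#' @export
tidy.grt_fit <- function(x, ...) {
  g <- tidyr::pivot_longer(x$group, cols = c("mu_x", "mu_y", "rho"),
                           names_to = "term", values_to = "estimate")
  g <- dplyr::mutate(g, level = "group", participant_id = NA_character_)
  p <- tidyr::pivot_longer(x$participants,
                           cols = c("kappa", "lambda", "c_y", "c_x1", "c_x2"),
                           names_to = "term", values_to = "estimate")
  p <- dplyr::mutate(p, level = "participant", stimulus = NA_character_)
  dplyr::bind_rows(g, p)[, c("level", "participant_id", "stimulus",
                             "term", "estimate")]
}

#' @rdname fit_grt_wind
#' @method glance grt_fit
#' @export
glance.grt_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_participants = nrow(x$participants),
    n_restarts = x$n_restarts,
    n_converged = sum(x$converged),
    pct_variance = x$pct_variance,
    seed = x$seed)
}

#' Write / read a fitted model as JSON
#'
#' The document stores group means and correlations, per-participant
#' parameters, the attained log-likelihood, restart diagnostics, the package
#' version, the seed, and the fitted count data, and round-trips losslessly
#' (to within floating-point serialization accuracy).
#'
#' @param fit A `grt_fit` object.
#' @param path File path.
#' @return `write_grt_fit()` returns `path` invisibly; `read_grt_fit()`
#'   returns the reconstructed `grt_fit`.
#' @export
write_grt_fit <- function(fit, path) {
  stopifnot(inherits(fit, "grt_fit"))
  doc <- list(
    type = "grt_fit",
    version = fit$version,
    seed = fit$seed,
    judgment = fit$judgment,
    loglik = fit$loglik,
    n_restarts = fit$n_restarts,
    restart_logliks = fit$restart_logliks,
    converged = fit$converged,
    best_restart = fit$best_restart,
    pct_variance = fit$pct_variance,
    group = as.data.frame(fit$group),
    participants = as.data.frame(fit$participants),
    data = as.data.frame(fit$data))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_grt_fit
#' @export
read_grt_fit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "grt_fit"))
    abort(sprintf("'%s' is not a serialized grt_fit document.", path))
  g <- doc$group
  fit <- structure(list(
    group = group_model(mu_x = g$mu_x[1:2], mu_y = g$mu_y[1:2], rho = g$rho),
    participants = validate_participants(tibble::as_tibble(doc$participants)),
    loglik = doc$loglik,
    n_restarts = doc$n_restarts,
    restart_logliks = as.numeric(doc$restart_logliks),
    converged = as.logical(doc$converged),
    best_restart = doc$best_restart,
    seed = doc$seed,
    judgment = doc$judgment %||% NA_character_,
    data = tibble::as_tibble(doc$data),
    version = doc$version,
    pct_variance = doc$pct_variance),
    class = "grt_fit")
  fit
}
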