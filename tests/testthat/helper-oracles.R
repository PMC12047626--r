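# Independent oracles and small fixtures shared across the suite.
# Every oracle here deliberately avoids the package's own computational path.

# Monte-Carlo rectangle probability under a bivariate normal (independent of
# the quadrature-based implementation). Returns the estimate and its SE.
mc_rectangle_prob <- function(mean, cov, x_lo, x_hi, y_lo, y_hi,
                              n = 1e6, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  sx <- sqrt(cov[1, 1]); sy <- sqrt(cov[2, 2])
  rho <- cov[1, 2] / (sx * sy)
  x <- mean[1] + sx * z1
  y <- mean[2] + sy * (rho * z1 + sqrt(1 - rho^2) * z2)
  inside <- x > x_lo & x <= x_hi & y > y_lo & y <= y_hi
  p <- mean(inside)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# Dense grid-search oracle for the conditional meta-d' fit: coarse 0.05 grid
# over meta_d in [0, 6] x t1, t2 in [-5, 5] (t1 < t2), then a 0.01 refinement
# around the coarse optimum. Operates directly on the six target category
# probabilities (correct-name categories then incorrect-name categories).
metad_grid_oracle <- function(q) {
  q <- as.numeric(q)
  search <- function(dg, tg) {
    best <- c(Inf, NA, NA, NA)
    np <- length(tg)
    for (d in dg) {
      pc <- pnorm(tg - d / 2)   # P(x <= t) under S+ mean d/2
      pi_ <- pnorm(tg + d / 2)
      # loss over all ordered (t1, t2) pairs via outer sums
      l1 <- (pc - q[1])^2 + (pi_ - q[4])^2              # depends on t1
      l3 <- (1 - pc - q[3])^2 + (1 - pi_ - q[6])^2      # depends on t2
      m2 <- (outer(-pc, pc, "+") - q[2])^2 +
        (outer(-pi_, pi_, "+") - q[5])^2                 # [t1, t2]
      tot <- outer(l1, l3, "+") + m2
      tot[!upper.tri(tot)] <- Inf                        # enforce t1 < t2
      i <- arrayInd(which.min(tot), dim(tot))
      if (tot[i] < best[1]) best <- c(tot[i], d, tg[i[1]], tg[i[2]])
    }
    best
  }
  coarse <- search(seq(0, 6, by = 0.05), seq(-5, 5, by = 0.05))
  fine <- search(seq(max(0, coarse[2] - 0.06), min(6, coarse[2] + 0.06),
                     by = 0.01),
                 seq(-5, 5, by = 0.01))
  # local polish: the 0.01 t-grid quantizes the loss enough to bias the
  # d-argmin on flat surfaces; a final window at t-step 0.002 resolves it
  t_win <- sort(unique(c(seq(fine[3] - 0.03, fine[3] + 0.03, by = 0.002),
                         seq(fine[4] - 0.03, fine[4] + 0.03, by = 0.002))))
  polish <- search(seq(max(0, fine[2] - 0.02), min(6, fine[2] + 0.02),
                       by = 0.0025), t_win)
  list(meta_d = polish[2], t1 = polish[3], t2 = polish[4], loss = polish[1])
}

# model-implied conditional category probabilities used as grid-oracle input
metad_targets <- function(group, ref_criteria, y) {
  qs <- lapply(c("correct_name", "incorrect_name"), function(s) {
    d <- conditional_distribution(group, s, y)
    conditional_category_probs(d$mean, d$sd, ref_criteria$c_x1,
                               ref_criteria$c_x2)
  })
  c(qs[[1]], qs[[2]])
}

# Closed-form Friedman statistic for k = 2 without ties: chi2 = (sum s_i)^2/n
# with s_i = +1 when column 2 beats column 1.
friedman_k2_exact <- function(m) {
  s <- sign(m[, 2] - m[, 1])
  stopifnot(all(s != 0))
  sum(s)^2 / nrow(m)
}

# a small fabricated model (not fitted) usable wherever a grt_fit-shaped
# object is needed
toy_model <- function(n_participants = 3, seed = 42) {
  set.seed(seed)
  list(
    group = group_model(mu_x = c(1, -1), mu_y = c(1, 1),
                        rho = c(0.5, -0.5, 0)),
    participants = participant_params(
      sprintf("p%02d", seq_len(n_participants)),
      kappa = exp(rnorm(n_participants, log(2), 0.2)),
      lambda = runif(n_participants, 0.4, 0.6),
      c_y = rnorm(n_participants, 0.5, 0.2),
      c_x1 = rnorm(n_participants, -1, 0.1),
      c_x2 = rnorm(n_participants, 1, 0.1)),
    judgment = "tot")
}

# draw valid random model parameters for property tests
random_triple <- function(seed) {
  set.seed(seed)
  list(
    group = group_model(mu_x = c(runif(1, 0, 2.5), runif(1, -2.5, 0)),
                        mu_y = runif(2, 0, 2.5),
                        rho = runif(3, -0.85, 0.85)),
    participant = participant_params(
      "p1", kappa = exp(runif(1, log(0.5), log(6))),
      lambda = runif(1, 0.25, 0.75), c_y = runif(1, -1.5, 1.5),
      c_x1 = runif(1, -2, 0), c_x2 = runif(1, 0.05, 2)),
    stimulus = sample(c("correct_name", "incorrect_name", "catch"), 1))
}
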