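## ggplot2 views of the three result types: the fitted decision space
## (stimulus ellipses plus reference criteria), the SvM curve, and the
## bootstrap band.

## parametric path of the 1-SD covariance ellipse of one stimulus
ellipse_path <- function(mu_x, mu_y, rho, n = 121) {
  th <- seq(0, 2 * pi, length.out = n)
  ## unit-variance bivariate normal: principal axes at 45 degrees
  x <- cos(th); y <- sin(th)
  tibble::tibble(x = mu_x + x,
                 y = mu_y + rho * x + sqrt(1 - rho^2) * y)
}

#' Plot the fitted decision space
#'
#' One 1-SD ellipse per stimulus condition in the group space (unit marginal
#' variances), with the group-coordinate reference criteria as dashed lines:
#' two vertical confidence criteria, one horizontal metacognitive criterion
#' per participant (faint), and the objective criterion.
#'
#' @param object A `grt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grt_fit
#' @export
autoplot.grt_fit <- function(object, ...) {
  g <- validate_group(object$group)
  paths <- purrr::map_dfr(seq_len(3), function(i)
    dplyr::mutate(ellipse_path(g$mu_x[i], g$mu_y[i], g$rho[i]),
                  stimulus = g$stimulus[i]))
  rc <- reference_criteria(object)
  y_star <- tryCatch(objective_criterion(g), error = function(e) NA_real_)
  p <- ggplot2::ggplot(paths, ggplot2::aes(x = .data$x, y = .data$y,
                                           colour = .data$stimulus)) +
    ggplot2::geom_path() +
    ggplot2::geom_hline(data = rc$participants,
                        ggplot2::aes(yintercept = .data$c_y_group),
                        colour = "darkgreen", alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(rc$c_x1, rc$c_x2),
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::scale_colour_manual(values = c(correct_name = "firebrick",
                                            incorrect_name = "steelblue",
                                            catch = "grey30")) +
    ggplot2::labs(x = "recognition / confidence evidence (x)",
                  y = "metacognitive evidence (y)",
                  colour = "stimulus",
                  title = "Fitted decision space") +
    ggplot2::theme_minimal()
  if (is.finite(y_star))
    p <- p + ggplot2::geom_hline(yintercept = y_star, linetype = "dotted",
                                 colour = "blue")
  p
}

#' Plot a type-2 SvM curve
#'
#' Conditional meta-d' against the relative likelihood of the metacognitive
#' state, with the objective criterion (vertical line at L = 1) and each
#' participant's criterion position (faint vertical lines).
#'
#' @param object An `svm_curve`.
#' @param band Optional `svm_band` to draw as a ribbon.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svm_curve
#' @export
autoplot.svm_curve <- function(object, band = NULL, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$rel_likelihood,
                                    y = .data$meta_d))
  if (!is.null(band)) {
    stopifnot(inherits(band, "svm_band"))
    p <- p + ggplot2::geom_ribbon(
      data = band$band,
      ggplot2::aes(x = .data$L, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2)
  }
  p +
    ggplot2::geom_vline(data = object$participants,
                        ggplot2::aes(xintercept = .data$position),
                        colour = "darkgreen", alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$L_star, colour = "blue") +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = sprintf("relative likelihood of %s",
                              if (is.na(object$judgment)) "the state"
                              else toupper(object$judgment)),
                  y = "conditional meta-d'",
                  title = "Type-2 SvM curve") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap band with its point-estimate curve
#'
#' @param object An `svm_band`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svm_band
#' @export
autoplot.svm_band <- function(object, ...) {
  ggplot2::ggplot(object$band, ggplot2::aes(x = .data$L)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "firebrick", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$point), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 1, colour = "blue") +
    ggplot2::labs(x = "relative likelihood", y = "conditional meta-d'",
                  title = sprintf("SvM curve with %d%% bootstrap band",
                                  round(100 * object$level))) +
    ggplot2::theme_minimal()
}
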