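#' Scatter plot of a harmonised set with estimator fits
#'
#' SNP-outcome against SNP-exposure effects with error bars and the fitted
#' causal slopes of one or more estimators.
#'
#' @param h Harmonised set with one exposure.
#' @param estimates A list of `mr_estimate` objects to overlay (default:
#'   fixed-effect IVW and MR-Egger where possible).
#' @return A ggplot object.
#' @export
plot_scatter <- function(h, estimates = NULL) {
  if (is.null(estimates)) {
    estimates <- list(mr_ivw(h, "fixed"))
    if (nrow(h) >= 3) estimates <- c(estimates, list(mr_egger(h)$estimate))
  }
  lines <- purrr::map_dfr(estimates, function(e) {
    tibble::tibble(method = e$method, slope = e$beta,
                   intercept = e$intercept %||% 0)
  })
  d <- tibble::as_tibble(h)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bx_1, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$sey,
                                        ymax = .data$by + .data$sey),
                           colour = "grey60", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx_1 - .data$sex_1,
                                         xmax = .data$bx_1 + .data$sex_1),
                            colour = "grey60", height = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Forest plot of a grid of MR estimates
#'
#' Odds-ratio forest plot of the total-effect estimates from [run_grid()],
#' annotated by evidence tier.
#'
#' @param grid An `mr_grid` object (or its `effects` tibble).
#' @return A ggplot object.
#' @export
plot_forest <- function(grid) {
  d <- if (inherits(grid, "mr_grid")) grid$effects else tibble::as_tibble(grid)
  d$label <- paste(d$exposure, "→", d$outcome)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label,
                                  colour = .data$tier)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low,
                                         xmax = .data$or_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = "Evidence") +
    ggplot2::theme_minimal()
}

#' Leave-one-out plot
#'
#' Per-omission estimates against the full-sample estimate.
#'
#' @param loo Output of [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  d <- loo$loo
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$omitted)) +
    ggplot2::geom_vline(xintercept = loo$full$beta, colour = "red") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Estimate with SNP omitted", y = "Omitted SNP") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_scatter
#' @param object,... ggplot2 autoplot interface.
autoplot.mr_harm <- function(object, ...) plot_scatter(object, ...)

#' @export
#' @rdname plot_forest
autoplot.mr_grid <- function(object, ...) plot_forest(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
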