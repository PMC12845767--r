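#' Plot pathway contributions
#'
#' Horizontal bar chart of the percentage contribution of each exposure
#' pathway to the population mean total dose.
#'
#' @param x An `ias_run` or a contribution tibble from
#'   [contribution_summary()].
#' @return A ggplot object.
#' @export
plot_contributions <- function(x) {
  contrib <- if (inherits(x, "ias_run")) x$contributions else x
  scn <- attr(contrib, "scenario")
  ggplot2::ggplot(contrib,
                  ggplot2::aes(x = .data$percent,
                               y = stats::reorder(.data$pathway,
                                                  .data$percent))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "Contribution to mean total iAs dose (%)", y = NULL,
                  title = if (is.null(scn)) "Pathway contributions"
                          else paste("Pathway contributions,", scn, "scenario")) +
    ggplot2::theme_minimal()
}

#' Plot the dose distribution of a run
#'
#' Violin plot of the total daily iAs dose by sex (and any flagged
#' subgroup), with the oral reference dose marked.
#'
#' @param run An `ias_run`.
#' @param rfd Reference dose to mark, ug/kg-day.
#' @return A ggplot object.
#' @export
plot_dose_distribution <- function(run, rfd = run$params$risk$rfd) {
  d <- run$doses %>%
    mutate(group = ifelse(.data$subgroup == "general", .data$sex,
                          .data$subgroup))
  d <- bind_rows(d, d %>% mutate(group = "all"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$total_dose)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = rfd, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Total iAs dose (ug/kg bw/day, log scale)",
                  title = paste("Aggregate iAs dose,", run$scenario,
                                "scenario")) +
    ggplot2::theme_minimal()
}

#' Plot cumulative risk distributions
#'
#' Empirical cumulative distribution of HQ (or ECR) for one or more runs,
#' with the conventional benchmark marked.
#'
#' @param runs An `ias_run` or a named list of them.
#' @param metric `"HQ"` or `"ECR"`.
#' @return A ggplot object.
#' @export
plot_risk_cdf <- function(runs, metric = c("HQ", "ECR")) {
  metric <- match.arg(metric)
  if (inherits(runs, "ias_run")) runs <- setNames(list(runs), runs$scenario)
  d <- purrr::imap_dfr(runs, function(r, nm) {
    tibble(scenario = nm, value = r$risk[[metric]])
  })
  bench <- if (metric == "HQ") 1 else 1e-6
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  colour = .data$scenario)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = bench, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(metric, " (log scale)"),
                  y = "Cumulative probability", colour = "Scenario",
                  title = paste("Cumulative distribution of", metric)) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot.ias_run()` shows the dose distribution;
#' `autoplot.ias_sensitivity()` draws tornado plots of both methods.
#'
#' @param object An `ias_run` or `ias_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-arsrisk
NULL

#' @rdname autoplot-arsrisk
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ias_run <- function(object, ...) {
  plot_dose_distribution(object)
}

#' @rdname autoplot-arsrisk
#' @export
autoplot.ias_sensitivity <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(method = toupper(.data$method))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coefficient,
                                  y = stats::reorder(.data$input,
                                                     abs(.data$coefficient)),
                                  fill = .data$p_value < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "Coefficient", y = NULL, fill = "p < 0.05",
                  title = paste("Sensitivity of total iAs dose,",
                                object$scenario[1], "scenario")) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
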