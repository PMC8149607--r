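#' Volcano-style plot of within-pair differences
#'
#' Plots each (site, pair) record's within-pair difference against the
#' coefficient of variation of the unaffected group, with the two DMS
#' thresholds drawn as dashed lines.
#'
#' @param object A `twin_dms` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twin_dms
#' @export
autoplot.twin_dms <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta,
                               y = pmin(.data$cv_unaffected, 1),
                               colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * th$delta_min,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = th$cv_max, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * beta ~ "(affected - unaffected)"),
                  y = "CV of unaffected group (capped at 1)",
                  colour = "DMS") +
    ggplot2::theme_minimal()
}

#' Region size versus effect plot for DMR calls
#'
#' @param object A `twin_dmr` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twin_dmr
#' @export
autoplot.twin_dmr <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_cpgs, y = .data$mean_delta,
                               colour = .data$direction)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "member CpGs", y = "region mean Δβ",
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' Correlation structure of a pipeline run
#'
#' Boxplots of per-pair Pearson correlations by relationship, before and
#' after masking the simulated VMR blocks.
#'
#' @param object A `twin_pipeline` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twin_pipeline
#' @export
autoplot.twin_pipeline <- function(object, ...) {
  df <- bind_rows(
    mutate(object$correlations$pairs, set = "all sites"),
    mutate(object$correlations_masked$pairs, set = "VMRs masked")
  ) |>
    filter(!is.na(.data$r)) |>
    mutate(group = if_else(.data$relationship == "co-twin",
                           "co-twin", "unrelated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$r,
                                   fill = .data$set)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Pearson r", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
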