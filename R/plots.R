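#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_histogram geom_abline labs theme_minimal scale_color_manual
NULL

#' Plot a QC report
#'
#' Total reads against relative standard deviation, colored by the final
#' pass/fail call, with the filter thresholds drawn.
#'
#' @param object A `qc_report` tibble.
#' @param min_total_reads,min_rel_sd Thresholds to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_report <- function(object, min_total_reads = 1.5e6, min_rel_sd = 0.1, ...) {
  stopifnot(all(c("total_reads", "rel_sd") %in% names(object)))
  status <- if ("final_pass" %in% names(object)) object$final_pass else object$seq_pass
  ggplot(dplyr::mutate(object, pass = status),
         aes(x = .data$total_reads, y = .data$rel_sd, color = .data$pass)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = min_total_reads, linetype = "dashed") +
    geom_hline(yintercept = min_rel_sd, linetype = "dashed") +
    scale_color_manual(values = c(`TRUE` = "#2b8cbe", `FALSE` = "#de2d26")) +
    labs(x = "total reads", y = "relative SD of probe counts", color = "pass") +
    theme_minimal()
}

#' Plot subtype call margins
#'
#' Histogram of the argmax margin (best minus second-best signature score),
#' faceted by assigned subtype; weak, ambiguous calls pile up near zero.
#'
#' @param object A `subtype_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subtype_calls <- function(object, ...) {
  ggplot(object, aes(x = .data$margin)) +
    geom_histogram(bins = 30, fill = "#2b8cbe") +
    ggplot2::facet_wrap(~assigned_subtype) +
    labs(x = "margin (best - second best score)", y = "samples") +
    theme_minimal()
}

#' Plot amplicon calls
#'
#' Mean neighborhood z-score per sample with the calling threshold.
#'
#' @param object An `amplicon_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amplicon_calls <- function(object, ...) {
  thr <- attr(object, "z_threshold") %||% 1.5
  ggplot(object, aes(x = .data$mean_neighborhood_z, fill = .data$amplified)) +
    geom_histogram(bins = 40) +
    geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#de2d26", `FALSE` = "grey60")) +
    labs(x = "mean neighborhood z-score", y = "samples", fill = "amplified") +
    theme_minimal()
}

#' Plot per-gene cross-platform concordance
#'
#' Slope against correlation, colored by the platform-bias flag.
#'
#' @param object A `platform_concordance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.platform_concordance <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$slope, color = .data$bias_flag)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "Pearson r", y = "OLS slope (platform 2 on platform 1)", color = "bias") +
    theme_minimal()
}

#' Plot group-level mRNA-protein agreement
#'
#' Median H-score against median log2 expression per group; discordant
#' groups (when flagged) are labelled.
#'
#' @param object A `group_protein` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_protein <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$median_mrna, y = .data$median_hscore)) +
    geom_point(size = 2, color = "#2b8cbe") +
    ggplot2::geom_text(aes(label = .data$group), vjust = -0.8, size = 3) +
    labs(x = "median log2 expression", y = "median H-score") +
    theme_minimal()
  if ("discordance" %in% names(object)) {
    p <- p + ggplot2::aes(color = .data$discordance) +
      scale_color_manual(values = c(none = "grey40",
                                    high_mrna_low_protein = "#de2d26",
                                    low_mrna_high_protein = "#756bb1"))
  }
  p
}
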