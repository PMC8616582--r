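#' Volcano plot of an enrichment table
#'
#' log2 fold change against -log10 p, with the call thresholds drawn as
#' dashed lines and enriched proteins highlighted.
#'
#' @param object An `"enrichment_tbl"` from [call_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_tbl <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                               colour = .data$enriched)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = cfg$min_log2fc, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "forestgreen")) +
    ggplot2::labs(x = "log2 fold change (bait / control)",
                  y = "-log10 p", colour = "enriched") +
    ggplot2::theme_classic()
}

#' Boxplot of target versus random-control mean disorder
#'
#' @param object A `"disorder_comparison"` from [compare_to_random()].
#'   The control box shows the first draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disorder_comparison <- function(object, ...) {
  df <- tibble(
    group = c(rep("target", length(object$target_values)),
              rep("random control", length(object$control_values))),
    mean_disorder = c(object$target_values, object$control_values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$mean_disorder,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "mean disorder",
                  subtitle = sprintf("Wilcoxon rank-sum p = %.3g",
                                     object$p_value)) +
    ggplot2::theme_classic()
}

#' Boxplot of rachis/edge ratios per genotype
#'
#' @param object A `"roi_summary"` from [ratio_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roi_summary <- function(object, ...) {
  df <- tidyr::unnest(
    object$groups |> select("genotype", "ratios"),
    "ratios"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$ratios)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "rachis / edge ratio") +
    ggplot2::theme_classic()
}
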