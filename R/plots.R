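#' Volcano plot of differential phosphosite results
#'
#' @param object Output of [differential_test()].
#' @param ... Unused.
#' @return A ggplot: -log10 q against log2 fold change, faceted by time
#'   point, targets highlighted.
#' @export
plot_differential <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$q),
                               colour = .data$is_target)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~time_min, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (stimulated / mock)",
                  y = expression(-log[10] ~ q), colour = "target") +
    ggplot2::theme_minimal()
}

#' Cluster time-course plot for a fuzzy c-means model
#'
#' @param object A `cluster_model` from [fuzzy_cmeans()].
#' @param profiles The profile matrix the model was fitted to.
#' @param ... Unused.
#' @return A ggplot of member profiles per cluster with cluster centers
#'   overlaid.
#' @export
autoplot.cluster_model <- function(object, profiles, ...) {
  prof <- as_tibble(profiles, rownames = "site_id") |>
    mutate(cluster = object$cluster) |>
    tidyr::pivot_longer(-c("site_id", "cluster"), names_to = "time_min",
                        values_to = "z") |>
    mutate(time_min = as.numeric(.data$time_min))
  centers <- as_tibble(object$centers) |>
    mutate(cluster = seq_len(object$k)) |>
    tidyr::pivot_longer(-"cluster", names_to = "time_min", values_to = "z") |>
    mutate(time_min = as.numeric(.data$time_min))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$time_min, y = .data$z)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$site_id),
                       alpha = 0.25, colour = "grey50") +
    ggplot2::geom_line(data = centers, colour = "firebrick",
                       linewidth = 1) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (min)", y = "z-scored abundance") +
    ggplot2::theme_minimal()
}

#' Consensus-weight overview of a solution network
#'
#' @param object A `solution_network`.
#' @param ... Unused.
#' @return A ggplot: per-edge bootstrap weight trajectories over time,
#'   coloured by interaction class, with the consensus threshold marked.
#' @export
autoplot.solution_network <- function(object, ...) {
  long <- tidy(object)
  thr <- object$weight_threshold %||% 1L
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time_min, y = .data$weight,
                               group = paste(.data$source, .data$target),
                               colour = .data$interaction_class)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "time (min)", y = paste0("bootstrap weight (of ",
                                               object$n_runs, " runs)"),
                  colour = "edge class") +
    ggplot2::theme_minimal()
}

#' Kinase-activity heatmap-style dot plot
#'
#' @param object A `kinase_activity` tibble.
#' @param ... Unused.
#' @return A ggplot of normalized enrichment values per kinase and time
#'   point, sized by significance.
#' @export
autoplot.kinase_activity <- function(object, ...) {
  dat <- filter(object, !.data$excluded, !is.na(.data$nev))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = factor(.data$time_min),
                               y = .data$kinase_id, fill = .data$nev)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  fill = "normalized\nenrichment") +
    ggplot2::theme_minimal()
}
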