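#' Tidy a solution network into a long edge table
#'
#' @param x A `solution_network`.
#' @param ... Unused.
#' @return Tibble with one row per (edge, time point): edge columns,
#'   `time_min`, `weight` and `entry_time`.
#' @export
tidy.solution_network <- function(x, ...) {
  et <- entry_times(x)
  long <- as_tibble(x$weights) |>
    mutate(.edge = seq_len(nrow(x$weights))) |>
    tidyr::pivot_longer(-".edge", names_to = "time_min",
                        values_to = "weight") |>
    mutate(time_min = as.numeric(.data$time_min))
  bind_cols_strict(et[long$.edge, , drop = FALSE],
                   long[, c("time_min", "weight")])
}

#' One-row summary of a solution network
#'
#' @param x A `solution_network`.
#' @param ... Unused.
#' @return Tibble with edge counts, run counts and the mean final objective.
#' @export
glance.solution_network <- function(x, ...) {
  thr <- x$weight_threshold %||% 1L
  last <- ncol(x$weights)
  obj <- x$objectives
  tibble(
    n_edges_any = nrow(x$edges),
    n_edges_consensus = sum(x$weights[, last] >= thr),
    n_runs = x$n_runs,
    n_failed_runs = x$n_failed,
    n_time_points = length(x$time_points),
    mean_final_objective = mean(obj$objective[obj$time_min ==
                                                max(obj$time_min)]),
    mean_unique_site_fraction = if (length(x$unique_fraction) > 0)
      mean(x$unique_fraction) else NA_real_
  )
}

#' Tidy a fuzzy c-means model into site memberships
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return Tibble `site_id`, `cluster` (argmax), `membership` (long over
#'   clusters).
#' @export
tidy.cluster_model <- function(x, ...) {
  memb <- as_tibble(x$membership, .name_repair = ~ as.character(seq_len(x$k)))
  bind_cols_strict(tibble(site_id = x$site_id, cluster = x$cluster), memb) |>
    tidyr::pivot_longer(-c("site_id", "cluster"), names_to = "component",
                        values_to = "membership") |>
    mutate(component = as.integer(.data$component))
}

#' One-row summary of a fuzzy c-means model
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return Tibble with sizes, iterations and the final objective.
#' @export
glance.cluster_model <- function(x, ...) {
  tibble(n_sites = length(x$site_id), k = x$k, m = x$m,
         iterations = x$iterations,
         objective = x$objective[length(x$objective)])
}
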