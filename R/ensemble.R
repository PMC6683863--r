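#' Evolve the subnetwork across ordered time points
#'
#' Solves the selection ILP for the first time point unconstrained, then for
#' every later time point forces the previous solution's edges into the model
#' (cost-free) while only that time point's scores enter the objective. Edge
#' sets are therefore nested across time by construction: the network grows
#' new branches as later sites become regulated, mirroring a signal spreading
#' outward from the receptor.
#'
#' @param pruned_graph A pruned [pkn].
#' @param scores Tibble `site_id`, `time_min`, `score` (e.g. `site_id`,
#'   `time_min`, `score` columns of [differential_test()] output).
#' @param epsilon Parsimony cost per new edge, default 0.01.
#' @param node_budget Per-solve search budget (see [solve_ilp()]).
#' @return A `solution_network` with one run: per-edge 0/1 weights per time
#'   point and per-time objectives.
#' @export
evolve_time_course <- function(pruned_graph, scores, epsilon = 0.01,
                               node_budget = 1e7) {
  times <- sort(unique(scores$time_min))
  forced <- character(0)
  sel_keys <- list()
  objectives <- numeric(length(times))
  optimal <- logical(length(times))
  for (i in seq_along(times)) {
    sc <- scores[scores$time_min == times[i], c("site_id", "score")]
    prob <- build_ilp(pruned_graph, sc, forced_edges = forced,
                      epsilon = epsilon)
    sol <- solve_ilp(prob, node_budget = node_budget)
    forced <- edge_keys(sol$edges)
    sel_keys[[i]] <- forced
    objectives[i] <- sol$objective
    optimal[i] <- sol$optimal
  }
  solution_network(pruned_graph, times, list(sel_keys), n_runs = 1L,
                   objectives = tibble(run = 1L, time_min = times,
                                       objective = objectives,
                                       optimal = optimal),
                   params = list(epsilon = epsilon))
}

# Assemble the consensus container from per-run, per-time selected edge keys.
solution_network <- function(graph, time_points, runs_keys, n_runs,
                             objectives, params,
                             weight_threshold = NULL, seed = NULL,
                             n_failed = 0L, unique_fraction = numeric(0)) {
  all_keys <- sort(unique(unlist(runs_keys)))
  weights <- matrix(0L, nrow = length(all_keys), ncol = length(time_points),
                    dimnames = list(all_keys, as.character(time_points)))
  for (run in runs_keys) {
    for (i in seq_along(time_points)) {
      weights[run[[i]], i] <- weights[run[[i]], i] + 1L
    }
  }
  keys_all_graph <- edge_keys(graph$edges)
  edges <- graph$edges[match(all_keys, keys_all_graph), , drop = FALSE]
  structure(
    list(edges = edges, weights = weights, runs = runs_keys,
         time_points = time_points, n_runs = n_runs,
         objectives = objectives, params = params,
         weight_threshold = weight_threshold, seed = seed,
         n_failed = n_failed, unique_fraction = unique_fraction,
         receptor = graph$receptor,
         node_class = setNames(graph$nodes$node_class, graph$nodes$node_id)),
    class = "solution_network"
  )
}

#' @export
print.solution_network <- function(x, ...) {
  cat("Solution network: ", nrow(x$edges), " distinct edge(s) over ",
      length(x$time_points), " time point(s), ", x$n_runs, " run(s)\n",
      sep = "")
  if (!is.null(x$weight_threshold)) {
    et <- entry_times(x, x$weight_threshold)
    cat("  consensus edges (weight >= ", x$weight_threshold, "): ",
        sum(!is.na(et$entry_time)), "\n", sep = "")
  }
  invisible(x)
}

#' Per-edge entry times at a consensus weight threshold
#'
#' The entry time of an edge is the earliest time point at which its
#' bootstrap weight reaches the threshold (20 of 100 runs by default);
#' edges that never reach it have `NA`.
#'
#' @param solution A `solution_network`.
#' @param weight_threshold Weight threshold; defaults to the ensemble's.
#' @return Tibble `source`, `interaction_class`, `target`, `sign`,
#'   `entry_time`.
#' @export
entry_times <- function(solution, weight_threshold = NULL) {
  thr <- weight_threshold %||% solution$weight_threshold %||% 1L
  w <- solution$weights
  entry <- apply(w >= thr, 1, function(hit) {
    i <- which(hit)[1]
    if (is.na(i)) NA_real_ else solution$time_points[i]
  })
  bind_cols_strict(solution$edges,
                   tibble(entry_time = unname(entry)))
}

#' Bootstrap consensus network with edge weights
#'
#' Repeats the full time-evolving network selection `n_runs` times; on each
#' run the measured site identifiers are resampled with replacement to their
#' original count and deduplicated, so each run sees roughly 63% of the
#' sites. Edge weights count how many runs' time-t networks contain each
#' edge; the consensus keeps multiple alternative solutions visible, with the
#' most consistently selected interactions carrying the highest weights.
#'
#' @param pruned_graph A pruned [pkn].
#' @param scores Tibble `site_id`, `time_min`, `score`.
#' @param n_runs Number of downsampling runs, default 100.
#' @param weight_threshold Consensus threshold used for entry times, default
#'   20.
#' @param seed Master seed; per-run resampling seeds are derived from it.
#' @param epsilon,node_budget Passed to the per-time solves.
#' @return A `solution_network` with integer weights in `[0, n_runs]`,
#'   per-run objectives, per-run unique-site fractions and entry times at
#'   `weight_threshold`. Runs that fail are skipped and counted; more than
#'   10% failures aborts.
#' @export
bootstrap_ensemble <- function(pruned_graph, scores, n_runs = 100,
                               weight_threshold = 20, seed = NULL,
                               epsilon = 0.01, node_budget = 1e7) {
  if (weight_threshold <= 0 || weight_threshold > n_runs) {
    abort_bad_arg("weight_threshold must be in (0, n_runs]")
  }
  site_ids <- sort(unique(scores$site_id))
  seeds <- derive_seeds(seed %||% 1L, n_runs)
  times <- sort(unique(scores$time_min))
  runs_keys <- list()
  objectives <- list()
  uniq_frac <- numeric(0)
  n_failed <- 0L
  for (r in seq_len(n_runs)) {
    kept <- resample_site_ids(site_ids, seed = seeds[r])
    run <- tryCatch(
      evolve_time_course(pruned_graph,
                         scores[scores$site_id %in% kept, , drop = FALSE],
                         epsilon = epsilon, node_budget = node_budget),
      error = function(e) NULL
    )
    if (is.null(run)) {
      n_failed <- n_failed + 1L
      next
    }
    uniq_frac <- c(uniq_frac, length(kept) / length(site_ids))
    runs_keys[[length(runs_keys) + 1L]] <-
      lapply(seq_along(times), function(i) {
        rownames(run$weights)[run$weights[, i] > 0]
      })
    objectives[[length(objectives) + 1L]] <-
      mutate(run$objectives, run = r)
  }
  if (n_failed > 0.1 * n_runs) {
    abort_bad_arg(paste0(n_failed, " of ", n_runs, " bootstrap runs failed"))
  }
  solution_network(pruned_graph, times, runs_keys,
                   n_runs = length(runs_keys),
                   objectives = bind_rows(objectives),
                   params = list(epsilon = epsilon),
                   weight_threshold = weight_threshold, seed = seed,
                   n_failed = n_failed, unique_fraction = uniq_frac)
}

#' Resample site identifiers with replacement and keep the unique set
#'
#' Draws `length(site_ids)` identifiers with replacement and returns the
#' distinct ones -- the downsampling step of each bootstrap run. With n
#' distinct identifiers the expected retained fraction is
#' `1 - (1 - 1/n)^n`, about 63% for large n.
#'
#' @param site_ids Character vector of site identifiers.
#' @param seed RNG seed.
#' @return Character vector of unique resampled identifiers.
#' @export
resample_site_ids <- function(site_ids, seed = NULL) {
  with_seed(seed, unique(sample(site_ids, length(site_ids), replace = TRUE)))
}

#' Randomized-data control: re-key regulated profiles to decoy identifiers
#'
#' Assigns the quantitative profiles of the regulated sites to identifiers
#' sampled without replacement from the non-regulated pool, producing a
#' dataset with the same signal strength but biologically arbitrary site
#' identities. A network built from it shows how much structure the modelling
#' approach would impose on noise alone.
#'
#' @param site_table Site table from [peptides_to_sites()].
#' @param regulated_ids Identifiers of the regulated (target) sites.
#' @param nonregulated_ids Pool of non-regulated identifiers to draw from;
#'   must be at least as large as `regulated_ids`.
#' @param seed RNG seed (fixed seed gives an identical reassignment).
#' @return A site table in which the sampled non-regulated rows carry the
#'   regulated profiles and the original regulated rows are removed.
#' @export
randomized_control <- function(site_table, regulated_ids, nonregulated_ids,
                               seed = NULL) {
  nonregulated_ids <- setdiff(nonregulated_ids, regulated_ids)
  if (length(nonregulated_ids) < length(regulated_ids)) {
    abort_bad_arg("non-regulated pool is smaller than the regulated set")
  }
  if (!all(regulated_ids %in% site_table$site_id)) {
    abort_bad_arg("regulated_ids missing from the site table")
  }
  decoys <- with_seed(seed,
                      sample(nonregulated_ids, length(regulated_ids)))
  value_cols <- setdiff(names(site_table),
                        c("site_id", "protein_id", "localized"))
  out <- site_table[!site_table$site_id %in% regulated_ids, , drop = FALSE]
  src_rows <- match(regulated_ids, site_table$site_id)
  dst_rows <- match(decoys, out$site_id)
  out[dst_rows, value_cols] <- site_table[src_rows, value_cols]
  out
}

#' Sites downstream of a node in a solution network
#'
#' Returns all site nodes reachable from `node_id` through edges selected at
#' the given time point (weight at least `weight_threshold`), e.g. the
#' predicted direct and downstream targets abolished by inhibiting a kinase.
#'
#' @param solution A `solution_network`.
#' @param node_id Query node (kinase, G protein or receptor).
#' @param time_min Time point; default the last.
#' @param weight_threshold Minimum weight for an edge to count; defaults to
#'   the ensemble's threshold (1 for a single run).
#' @return Character vector of site identifiers (empty, with a warning, when
#'   the node is absent).
#' @export
downstream_targets <- function(solution, node_id, time_min = NULL,
                               weight_threshold = NULL) {
  time_min <- time_min %||% max(solution$time_points)
  thr <- weight_threshold %||% solution$weight_threshold %||% 1L
  col <- match(as.character(time_min), colnames(solution$weights))
  if (is.na(col)) abort_bad_arg("time_min is not a modelled time point")
  keep <- solution$weights[, col] >= thr
  edges <- solution$edges[keep, , drop = FALSE]
  nodes <- unique(c(edges$source, edges$target))
  if (!node_id %in% nodes) {
    warning("node '", node_id, "' is not part of the selected network",
            call. = FALSE)
    return(character(0))
  }
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = TRUE)
  reach <- setdiff(names(igraph::subcomponent(g, node_id, mode = "out")),
                   node_id)
  sites <- names(solution$node_class)[solution$node_class == "site"]
  sort(intersect(reach, sites))
}
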