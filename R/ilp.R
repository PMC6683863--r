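#' Build the subnetwork-selection ILP for one time point
#'
#' Encodes the Boolean model-selection problem over a pruned prior-knowledge
#' network as an integer linear program: binary edge variables `x_e`,
#' protein-activity variables `y_v`, site-inclusion variables `z_s` and depth
#' variables `d_v`, with constraints (i) the receptor is active at depth 0,
#' (ii) a selected edge needs an active source (`x_e <= y_src`, or `z_src`
#' for edges leaving a site), (iii) a non-receptor protein is active only
#' with a selected incoming edge (`y_v <= sum x_in`), (iv) a site is included
#' only with a selected incoming edge (`z_s <= sum x_in`), (v) selected edges
#' respect a depth ordering (`d_tgt >= d_src + 1 - |V| (1 - x_e)`), ruling
#' out cycles, and (vi) forced edges are fixed at 1. The objective minimises
#' `sum_s score(s) z_s + epsilon * sum_{e not forced} x_e`, so regulated
#' sites (negative scores) reward inclusion, non-regulated measured sites
#' penalise being wired through, and `epsilon` enforces parsimony. Activation
#' is propagated Boolean-OR style; edge signs are carried but do not gate
#' propagation.
#'
#' @param pruned_graph A pruned [pkn] (see [prune_to_reachable()]).
#' @param scores Tibble `site_id`, `score` for the measured sites at this
#'   time point (see [ilp_scores()]). Sites absent from the graph are dropped
#'   and reported via attribute `dropped_sites`.
#' @param forced_edges Character vector of edge keys
#'   (`"source|interaction_class|target"`) fixed to 1, e.g. the previous time
#'   point's solution. An unknown forced edge is an error.
#' @param epsilon Per-edge parsimony cost, default 0.01. Must stay below the
#'   smallest `|score|` among regulated (negative-score) sites so that
#'   parsimony can never override data; otherwise an error is raised.
#' @return An `ilp_problem` object.
#' @export
build_ilp <- function(pruned_graph, scores, forced_edges = NULL,
                      epsilon = 0.01) {
  edges <- pruned_graph$edges
  nodes <- pruned_graph$nodes
  if (is.null(pruned_graph$receptor)) abort_bad_arg("network has no receptor")
  dropped <- setdiff(scores$site_id, nodes$node_id)
  scores <- filter(scores, .data$site_id %in% nodes$node_id)
  node_score <- setNames(rep(0, nrow(nodes)), nodes$node_id)
  node_score[scores$site_id] <- scores$score
  neg <- scores$score[scores$score < 0]
  if (length(neg) > 0 && epsilon >= min(abs(neg))) {
    abort_bad_arg(paste0("epsilon (", epsilon, ") must be smaller than the ",
                         "smallest |score| among regulated sites (",
                         signif(min(abs(neg)), 4), ")"))
  }
  keys <- edge_keys(edges)
  forced <- keys %in% (forced_edges %||% character(0))
  unknown <- setdiff(forced_edges %||% character(0), keys)
  if (length(unknown) > 0) {
    abort_bad_arg(paste0("forced edge(s) absent from the graph: ",
                         paste(unknown, collapse = ", ")))
  }
  out <- structure(
    list(edges = edges, nodes = nodes, receptor = pruned_graph$receptor,
         node_score = unname(node_score),
         is_site = nodes$node_class == "site",
         forced = forced, epsilon = epsilon),
    class = "ilp_problem"
  )
  attr(out, "dropped_sites") <- dropped
  out
}

edge_keys <- function(edges) {
  paste(edges$source, edges$interaction_class, edges$target, sep = "|")
}

#' @export
print.ilp_problem <- function(x, ...) {
  cat("Subnetwork-selection ILP: ", nrow(x$edges), " edge variables, ",
      nrow(x$nodes), " nodes, ", sum(x$node_score < 0),
      " regulated site(s), ", sum(x$forced), " forced edge(s), epsilon = ",
      x$epsilon, "\n", sep = "")
  invisible(x)
}

#' Solve a subnetwork-selection ILP to optimality
#'
#' Runs the package's exact branch-and-bound solver. The solution is provably
#' optimal (gap 0) unless the search-node budget is exhausted, in which case
#' the best incumbent is returned with `optimal = FALSE`. Edge reporting is
#' deterministic (sorted edge order, first-found incumbent among ties).
#'
#' @param problem An `ilp_problem` from [build_ilp()].
#' @param node_budget Branch-and-bound search-node budget (the time-limit
#'   analogue), default 1e7.
#' @return List with `edges` (selected edges tibble, sorted), `objective`,
#'   `optimal`, `nodes_explored`.
#' @export
solve_ilp <- function(problem, node_budget = 1e7) {
  nodes <- problem$nodes
  edges <- problem$edges
  idx <- setNames(seq_len(nrow(nodes)) - 1L, nodes$node_id)
  if (nrow(edges) == 0) {
    return(list(edges = edges, objective = 0, optimal = TRUE,
                nodes_explored = 0))
  }
  res <- .solve_subnetwork_cpp(
    n_nodes = nrow(nodes),
    edge_src = unname(idx[edges$source]),
    edge_dst = unname(idx[edges$target]),
    node_score = problem$node_score,
    is_site = problem$is_site,
    root = unname(idx[problem$receptor]),
    forced = problem$forced,
    epsilon = problem$epsilon,
    node_budget = node_budget
  )
  sel <- edges[res$selected, , drop = FALSE]
  sel <- arrange(sel, .data$source, .data$target, .data$interaction_class)
  if (!res$optimal) {
    warning("search-node budget exhausted; returning best incumbent",
            call. = FALSE)
  }
  list(edges = sel, objective = res$objective, optimal = res$optimal,
       nodes_explored = res$nodes_explored)
}
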