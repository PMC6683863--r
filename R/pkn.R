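#' Prior-knowledge network objects
#'
#' A `pkn` is a typed, signed, directed multigraph held as two tibbles:
#' `nodes` (`node_id`, `node_class` in receptor/protein/site, `host_protein`
#' for site nodes) and `edges` (`source`, `target`, `interaction_class` in
#' kinase_site/site_protein/ppi, `sign` in +1/-1, `references`). Site
#' identifiers follow the `"<protein>_<residue letter><1-based position>"`
#' convention (e.g. `AKT1_S473`), and a site's host protein is recovered from
#' its identifier.
#'
#' @param edges Edge tibble as described above.
#' @param receptor Identifier of the receptor node (optional at construction;
#'   required before pruning). At most one receptor exists per network.
#' @return A `pkn` object.
#' @export
pkn <- function(edges, receptor = NULL) {
  required <- c("source", "target", "interaction_class", "sign")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0) {
    abort_bad_arg(paste0("edge table is missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  if (!"references" %in% names(edges)) edges$references <- ""
  edges$sign <- normalize_sign(edges$sign)
  bad_class <- !edges$interaction_class %in% c("kinase_site", "site_protein", "ppi")
  if (any(bad_class)) {
    abort_bad_arg(paste0("unknown interaction_class in edge row(s): ",
                         paste(which(bad_class), collapse = ", ")))
  }
  edges <- dedupe_edges(as_tibble(edges[, c("source", "target",
                                            "interaction_class", "sign",
                                            "references")]))
  g <- new_pkn(edges, receptor)
  validate_pkn(g)
  g
}

new_pkn <- function(edges, receptor, hosts = NULL) {
  site_ids <- unique(c(edges$target[edges$interaction_class == "kinase_site"],
                       edges$source[edges$interaction_class == "site_protein"]))
  all_ids <- unique(c(edges$source, edges$target, receptor))
  host_of <- function(ids) {
    out <- site_host(ids)
    if (!is.null(hosts)) {
      known <- unname(hosts[ids])
      out[!is.na(known)] <- known[!is.na(known)]
    }
    out
  }
  nodes <- tibble(
    node_id = all_ids,
    node_class = dplyr::if_else(all_ids %in% site_ids, "site", "protein"),
    host_protein = dplyr::if_else(all_ids %in% site_ids,
                                  host_of(all_ids), NA_character_)
  )
  if (!is.null(receptor)) {
    if (!receptor %in% nodes$node_id) {
      nodes <- bind_rows(nodes, tibble(node_id = receptor,
                                       node_class = "receptor",
                                       host_protein = NA_character_))
    } else {
      nodes$node_class[nodes$node_id == receptor] <- "receptor"
    }
  }
  structure(list(nodes = arrange(nodes, .data$node_id),
                 edges = arrange(edges, .data$source, .data$target,
                                 .data$interaction_class),
                 receptor = receptor),
            class = "pkn")
}

normalize_sign <- function(sign) {
  s <- suppressWarnings(as.integer(gsub("^\\+", "", as.character(sign))))
  bad <- is.na(s) | !s %in% c(1L, -1L)
  if (any(bad)) {
    abort_bad_arg(paste0("unknown sign in edge row(s): ",
                         paste(which(bad), collapse = ", ")))
  }
  s
}

# Host protein encoded in a site identifier: strip the trailing residue tag.
site_host <- function(site_id) sub("_[STY][0-9]+$", "", site_id)

dedupe_edges <- function(edges) {
  edges |>
    group_by(.data$source, .data$target, .data$interaction_class, .data$sign) |>
    summarise(references = paste(
      unique(unlist(strsplit(paste(.data$references, collapse = ";"), ";"))) |>
        (\(x) x[nzchar(x)])() |> paste(collapse = ";")),
      .groups = "drop")
}

validate_pkn <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  cls <- setNames(nodes$node_class, nodes$node_id)
  ks <- edges[edges$interaction_class == "kinase_site", ]
  if (any(cls[ks$target] != "site")) {
    abort_bad_arg(paste0("kinase_site edge(s) targeting non-site node(s): ",
                         paste(unique(ks$target[cls[ks$target] != "site"]),
                               collapse = ", ")))
  }
  if (any(cls[ks$source] == "site")) {
    abort_bad_arg("kinase_site edge(s) with a site-class source")
  }
  sp <- edges[edges$interaction_class == "site_protein", ]
  if (nrow(sp) > 0) {
    host <- setNames(nodes$host_protein, nodes$node_id)
    bad <- sp$target != host[sp$source]
    if (any(bad)) {
      abort_bad_arg(paste0("site_protein edge(s) not pointing at the site's ",
                           "host protein: ",
                           paste(sp$source[bad], collapse = ", ")))
    }
  }
  ppi <- edges[edges$interaction_class == "ppi", ]
  if (any(cls[ppi$source] == "site" | cls[ppi$target] == "site")) {
    abort_bad_arg("ppi edge(s) touching site-class node(s)")
  }
  invisible(g)
}

#' @export
print.pkn <- function(x, ...) {
  cat("Prior-knowledge network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("  receptor: ", x$receptor %||% "<unset>", "\n", sep = "")
  cat("  edge classes:",
      paste(names(table(x$edges$interaction_class)),
            table(x$edges$interaction_class), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Load a prior-knowledge network from SIF-like TSV files
#'
#' Both files share the dialect `source<TAB>interaction_class<TAB>target<TAB>
#' sign<TAB>references` (references semicolon-separated, possibly empty).
#' The kinase-substrate file carries `kinase_site` (and optionally
#' `site_protein`) edges; the protein-protein file carries signed directed
#' `ppi` edges. Duplicate (source, target, class, sign) rows are merged with
#' the union of their references. Malformed rows raise an error naming the
#' file and line.
#'
#' @param ks_file Path to the kinase->site edge file.
#' @param ppi_file Path to the signed directed protein-protein edge file.
#' @param receptor Optional receptor node identifier.
#' @return A [pkn] object.
#' @export
load_pkn <- function(ks_file, ppi_file, receptor = NULL) {
  edges <- bind_rows(read_sif(ks_file), read_sif(ppi_file))
  pkn(edges, receptor = receptor)
}

read_sif <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (length(lines) > 0 && grepl("^source\t", lines[1])) {
    keep[1] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(source = character(0), target = character(0),
                  interaction_class = character(0), sign = integer(0),
                  references = character(0)))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  n_fields <- vapply(parts, length, integer(1))
  bad <- n_fields < 4
  if (any(bad)) {
    abort_bad_arg(paste0("malformed row in ", path, " at line ",
                         paste(idx[bad], collapse = ", ")))
  }
  tibble(
    source = vapply(parts, `[[`, character(1), 1),
    interaction_class = vapply(parts, `[[`, character(1), 2),
    target = vapply(parts, `[[`, character(1), 3),
    sign = vapply(parts, `[[`, character(1), 4),
    references = vapply(parts, function(x) if (length(x) >= 5) x[[5]] else "",
                        character(1))
  )
}

#' Read an isoform / G-protein grouping map
#' @param path Two-column TSV `member_id`, `group_id`.
#' @return Tibble with those columns; a member maps to exactly one group.
#' @export
read_grouping_map <- function(path) {
  gm <- read_tsv_quiet(path)
  if (!all(c("member_id", "group_id") %in% names(gm))) {
    abort_bad_arg("grouping map needs columns member_id, group_id")
  }
  if (anyDuplicated(gm$member_id)) {
    abort_bad_arg("a member maps to more than one group")
  }
  gm
}

#' Merge grouped isoforms and G-protein subunits into group nodes
#'
#' Member nodes are replaced by their group node; edge endpoints are
#' rewritten, parallel edges merged with reference union, and self-loops
#' created by the merge dropped (their reference count is reported in the
#' attribute `dropped_self_loop_refs`). Site hosts are rewritten alongside.
#' Members absent from the network are ignored. Grouping the receptor
#' together with any other existing node is an error.
#'
#' @param graph A [pkn] object.
#' @param grouping Tibble `member_id`, `group_id` (see [read_grouping_map()]).
#' @return The grouped [pkn].
#' @export
apply_grouping <- function(graph, grouping) {
  if (nrow(grouping) == 0) return(graph)
  map <- setNames(grouping$group_id, grouping$member_id)
  if (!is.null(graph$receptor)) {
    rec_group <- map[graph$receptor]
    if (!is.na(rec_group)) {
      others <- grouping$member_id[grouping$group_id == rec_group &
                                     grouping$member_id != graph$receptor]
      if (any(others %in% graph$nodes$node_id) ||
          rec_group %in% setdiff(graph$nodes$node_id, graph$receptor)) {
        abort_bad_arg("grouping would merge the receptor with another node")
      }
    }
  }
  rename_id <- function(id) {
    out <- unname(map[id])
    ifelse(is.na(out), id, out)
  }
  edges <- graph$edges
  edges$source <- rename_id(edges$source)
  edges$target <- rename_id(edges$target)
  # A site on a grouped protein keeps its identifier but its host (and the
  # target of its coupling edge) moves to the group node; identifiers stay
  # untouched because they key the measured data.
  self <- edges$source == edges$target
  dropped_refs <- sum(nzchar(edges$references[self]))
  edges <- dedupe_edges(edges[!self, , drop = FALSE])
  receptor <- if (!is.null(graph$receptor)) {
    unname(ifelse(is.na(map[graph$receptor]), graph$receptor,
                  map[graph$receptor]))
  }
  out <- new_pkn(edges, receptor)
  # Site identifiers key the measured data and stay untouched, so the host
  # encoded in the id may now be a grouped member: rewrite hosts through the
  # same map instead of re-deriving them from the identifier.
  is_site <- out$nodes$node_class == "site"
  out$nodes$host_protein[is_site] <-
    rename_id(site_host(out$nodes$node_id[is_site]))
  attr(out, "dropped_self_loop_refs") <- dropped_refs
  out
}

#' Attach site-to-host coupling edges
#'
#' Realizes the path convention kinase -> site -> host protein: for every
#' site node whose host protein has outgoing edges, a `site_protein` coupling
#' edge from the site to its host is added (so perturbation can traverse
#' intermediary kinases through their regulatory sites). The default sign is
#' +1 (activating); an annotation table can override individual sites as
#' inhibitory. Sites on terminal proteins (no outgoing edges) gain no
#' coupling edge.
#'
#' @param graph A [pkn] object.
#' @param measured_sites Restrict coupling to these site identifiers
#'   (default: all site nodes in the graph).
#' @param sign_overrides Optional tibble `site_id`, `sign` for inhibitory
#'   sites.
#' @return The augmented [pkn].
#' @export
attach_site_coupling <- function(graph, measured_sites = NULL,
                                 sign_overrides = NULL) {
  sites <- graph$nodes$node_id[graph$nodes$node_class == "site"]
  if (!is.null(measured_sites)) sites <- intersect(sites, measured_sites)
  if (length(sites) == 0) return(graph)
  hosts <- graph$nodes$host_protein[match(sites, graph$nodes$node_id)]
  has_out <- hosts %in% graph$edges$source
  existing <- paste(graph$edges$source, graph$edges$target,
                    graph$edges$interaction_class)
  todo <- has_out & !paste(sites, hosts, "site_protein") %in% existing &
    hosts %in% graph$nodes$node_id
  if (!any(todo)) return(graph)
  sign <- rep(1L, sum(todo))
  if (!is.null(sign_overrides)) {
    ov <- match(sites[todo], sign_overrides$site_id)
    sign[!is.na(ov)] <- normalize_sign(sign_overrides$sign[ov[!is.na(ov)]])
  }
  new_edges <- tibble(source = sites[todo], target = hosts[todo],
                      interaction_class = "site_protein", sign = sign,
                      references = "")
  host_map <- setNames(graph$nodes$host_protein, graph$nodes$node_id)
  new_pkn(dedupe_edges(bind_rows(graph$edges, new_edges)), graph$receptor,
          hosts = host_map)
}

#' Prune a network to receptor-to-site paths
#'
#' Retains exactly the nodes and edges lying on at least one directed path
#' from the receptor to at least one regulated site: an edge (u, v) survives
#' iff u is reachable from the receptor and a regulated site is reachable
#' from v. Regulated sites that cannot be reached at all are reported in the
#' attribute `unreachable_sites` rather than being fatal. The operation is
#' idempotent.
#'
#' @param graph A [pkn] object.
#' @param receptor Receptor node identifier (defaults to the graph's).
#' @param regulated_sites Character vector of regulated site identifiers.
#' @return The pruned [pkn], with attribute `unreachable_sites`.
#' @export
prune_to_reachable <- function(graph, receptor = NULL, regulated_sites) {
  receptor <- receptor %||% graph$receptor
  if (is.null(receptor) || !receptor %in% graph$nodes$node_id) {
    abort_bad_arg("receptor is absent from the network")
  }
  ig <- pkn_igraph(graph)
  fwd <- names(igraph::subcomponent(ig, receptor, mode = "out"))
  present <- intersect(regulated_sites, graph$nodes$node_id)
  unreachable <- setdiff(regulated_sites, intersect(present, fwd))
  targets <- intersect(present, fwd)
  host_map <- setNames(graph$nodes$host_protein, graph$nodes$node_id)
  if (length(targets) == 0) {
    out <- new_pkn(graph$edges[0, ], receptor, hosts = host_map)
    attr(out, "unreachable_sites") <- sort(unreachable)
    return(out)
  }
  bwd <- unique(unlist(lapply(targets, function(s) {
    names(igraph::subcomponent(ig, s, mode = "in"))
  })))
  keep <- graph$edges$source %in% intersect(fwd, bwd) &
    graph$edges$target %in% intersect(fwd, bwd)
  out <- new_pkn(graph$edges[keep, , drop = FALSE], receptor,
                 hosts = host_map)
  attr(out, "unreachable_sites") <- sort(unreachable)
  out
}

pkn_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("source", "target")],
    directed = TRUE,
    vertices = graph$nodes$node_id
  )
}

#' Export a network's edges and node attributes to TSV
#'
#' Writes the SIF-like edge dialect consumed by [load_pkn()] plus a
#' node-attribute table.
#'
#' @param graph A [pkn] object.
#' @param edge_path,node_path Output paths.
#' @return `edge_path`, invisibly.
#' @export
write_pkn <- function(graph, edge_path, node_path = NULL) {
  write_tsv_quiet(graph$edges[, c("source", "interaction_class", "target",
                                  "sign", "references")], edge_path)
  if (!is.null(node_path)) write_tsv_quiet(graph$nodes, node_path)
  invisible(edge_path)
}
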