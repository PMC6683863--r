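#' Assemble and validate a pipeline configuration
#'
#' A configuration is a flat named list (or a YAML file with the same keys):
#' input paths (`peptide_table`, `annotation`, `ks_network`, `ppi_network`,
#' optional `grouping_map`, optional `kinase_sets`), `receptor_id`, optional
#' `time_points`, the analysis thresholds (`qThresh` 0.1, `fcThresh` 1.5,
#' `flr_threshold` 0.01), `n_perm` (10000), `k_clusters` (6), `n_runs`
#' (100), `weight_threshold` (20), `epsilon` (0.01), `seed` and `out_dir`.
#' All thresholds are range-checked here, before any stage runs.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(qThresh = 0.1, fcThresh = 1.5, flr_threshold = 0.01,
                   n_perm = 10000, k_clusters = 6, n_runs = 100,
                   weight_threshold = 20, epsilon = 0.01, seed = 1L,
                   grouping_map = NULL, kinase_sets = NULL,
                   time_points = NULL)
  config <- modifyList(defaults, config, keep.null = TRUE)
  required <- c("peptide_table", "annotation", "ks_network", "ppi_network",
                "receptor_id", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort_bad_arg(paste0("config is missing: ", paste(missing, collapse = ", ")))
  }
  target_call_params(config$qThresh, config$fcThresh)  # range checks
  if (config$flr_threshold <= 0 || config$flr_threshold >= 1) {
    abort_bad_arg("flr_threshold must be in (0, 1)")
  }
  if (config$weight_threshold <= 0 ||
      config$weight_threshold > config$n_runs) {
    abort_bad_arg("weight_threshold must be in (0, n_runs]")
  }
  if (config$epsilon <= 0) abort_bad_arg("epsilon must be > 0")
  config
}

#' Run the full analysis pipeline
#'
#' Executes, in order: localization filtering and spike-in normalization of
#' the peptide table, peptide-to-site conversion and replicate CVs;
#' per-time-point differential testing with target calling and ILP scores;
#' kinase-activity inference and time-course clustering with per-cluster
#' enrichment (when kinase sets are provided); prior-knowledge network
#' assembly (grouping, site coupling, pruning to receptor-target paths); and
#' the bootstrap ILP ensemble. Every stage writes its outputs into
#' `out_dir`, and a machine-readable manifest records the configuration, the
#' derived per-stage seeds and the MD5 hash of every artifact; a rerun with
#' the same configuration is byte-identical. A failing stage aborts with the
#' stage name; outputs of completed stages are preserved.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with the main result objects and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 3)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(name) file.path(config$out_dir, name)

  # -- normalization ---------------------------------------------------------
  norm <- stage("normalize", {
    peptides <- read_peptide_table(config$peptide_table)
    annotation <- read_sample_annotation(config$annotation)
    sites <- peptides |>
      filter_localization(config$flr_threshold) |>
      normalize_peptides() |>
      peptides_to_sites()
    write_site_table(sites, out("site_table.tsv"))
    cvs <- compute_cv(sites, annotation)
    write_tsv_quiet(cvs, out("replicate_cv.tsv"))
    list(sites = sites, annotation = annotation, cvs = cvs)
  })
  paths$site_table <- out("site_table.tsv")
  paths$replicate_cv <- out("replicate_cv.tsv")

  # -- differential ----------------------------------------------------------
  diff <- stage("differential", {
    params <- target_call_params(config$qThresh, config$fcThresh)
    d <- differential_test(norm$sites, norm$annotation,
                           time_points = config$time_points,
                           params = params)
    write_differential(d, out("differential.tsv"))
    d
  })
  paths$differential <- out("differential.tsv")
  targets <- target_union(diff)

  # -- kinase activity + clustering -----------------------------------------
  kin <- NULL
  clust <- NULL
  enrich <- NULL
  if (!is.null(config$kinase_sets)) {
    kin <- stage("kinase_activity", {
      sets <- read_kinase_sets(config$kinase_sets)
      ka <- kinase_activity(diff, sets, n_perm = config$n_perm,
                            seed = seeds[1])
      write_tsv_quiet(ka, out("kinase_activity.tsv"))
      ka
    })
    paths$kinase_activity <- out("kinase_activity.tsv")
    clust <- stage("clustering", {
      prof <- site_profiles(norm$sites, norm$annotation, sites = targets)
      if (nrow(prof) >= config$k_clusters) {
        cm <- fuzzy_cmeans(prof, k = config$k_clusters, seed = seeds[2])
        memb <- bind_cols_strict(tibble(site_id = cm$site_id,
                                        cluster = cm$cluster),
                                 as_tibble(cm$membership))
        write_tsv_quiet(memb, out("cluster_membership.tsv"))
        cm
      }
    })
    if (!is.null(clust)) {
      paths$cluster_membership <- out("cluster_membership.tsv")
      enrich <- stage("cluster_enrichment", {
        sets <- read_kinase_sets(config$kinase_sets)
        ce <- cluster_enrichment(clust, sets, background = norm$sites$site_id)
        write_tsv_quiet(ce, out("cluster_enrichment.tsv"))
        ce
      })
      paths$cluster_enrichment <- out("cluster_enrichment.tsv")
    }
  }

  # -- prior-knowledge network ----------------------------------------------
  pruned <- stage("build_pkn", {
    graph <- load_pkn(config$ks_network, config$ppi_network,
                      receptor = config$receptor_id)
    if (!is.null(config$grouping_map)) {
      graph <- apply_grouping(graph, read_grouping_map(config$grouping_map))
    }
    graph <- attach_site_coupling(graph,
                                  measured_sites = norm$sites$site_id)
    pruned <- prune_to_reachable(graph, regulated_sites = targets)
    write_pkn(pruned, out("pruned_pkn.tsv"), out("pruned_pkn_nodes.tsv"))
    pruned
  })
  paths$pruned_pkn <- out("pruned_pkn.tsv")

  # -- network inference -----------------------------------------------------
  solution <- stage("infer_network", {
    scores <- diff[, c("site_id", "time_min", "score")]
    sol <- bootstrap_ensemble(pruned, scores, n_runs = config$n_runs,
                              weight_threshold = config$weight_threshold,
                              seed = seeds[3], epsilon = config$epsilon)
    write_solution(sol, config$out_dir)
    sol
  })
  paths$solution_edges <- out("solution_edges.tsv")
  paths$solution_edge_attributes <- out("solution_edge_attributes.tsv")
  paths$solution <- out("solution.json")

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    stage_seeds = list(kinase_activity = seeds[1], clustering = seeds[2],
                       bootstrap = seeds[3]),
    artifacts = lapply(paths, function(p) {
      unname(tools::md5sum(p))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sites = norm$sites, cvs = norm$cvs, differential = diff,
                 kinase_activity = kin, clusters = clust,
                 cluster_enrichment = enrich, pruned_pkn = pruned,
                 solution = solution, manifest = manifest,
                 paths = c(paths, manifest = out("manifest.json"))))
}

#' Export a solution network to TSV and JSON
#'
#' Writes the selected edge list (SIF-like), an edge-attribute table with
#' per-time-point weights and entry times, and a single JSON document with
#' nodes, edges, weights, objectives, seed and parameters for import into
#' graph viewers.
#'
#' @param solution A `solution_network`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_solution <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_quiet(solution$edges[, c("source", "interaction_class", "target",
                                     "sign")],
                  file.path(dir, "solution_edges.tsv"))
  attrs <- as_tibble(solution$weights)
  names(attrs) <- paste0("weight_t", colnames(solution$weights))
  attrs <- bind_cols_strict(entry_times(solution), attrs)
  write_tsv_quiet(attrs, file.path(dir, "solution_edge_attributes.tsv"))
  doc <- list(
    receptor = solution$receptor,
    time_points = solution$time_points,
    n_runs = solution$n_runs,
    weight_threshold = solution$weight_threshold,
    seed = solution$seed,
    params = solution$params,
    nodes = unique(c(solution$edges$source, solution$edges$target)),
    edges = as.data.frame(attrs),
    objectives = as.data.frame(solution$objectives),
    n_failed_runs = solution$n_failed,
    unique_site_fraction = solution$unique_fraction
  )
  jsonlite::write_json(doc, file.path(dir, "solution.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Summarize pipeline outputs
#'
#' Produces the run-level overview tables: targets per time point (with the
#' union count), significant kinases per time point, network size and the
#' consensus weight histogram. Sections whose stage outputs are absent are
#' marked absent rather than failing.
#'
#' @param results The list returned by [run_pipeline()].
#' @param path Optional path for a plain-text report.
#' @return A list of summary tibbles.
#' @export
summarize_pipeline <- function(results, path = NULL) {
  sections <- list()
  if (!is.null(results$differential)) {
    tp <- results$differential |>
      group_by(time_min = .data$time_min) |>
      summarise(n_targets = sum(.data$is_target), .groups = "drop")
    sections$targets_per_time <- tp
    sections$target_union <- tibble(
      n_union = length(target_union(results$differential)))
  }
  if (!is.null(results$kinase_activity)) {
    sections$kinases_per_time <- results$kinase_activity |>
      filter(!.data$excluded) |>
      group_by(time_min = .data$time_min) |>
      summarise(n_significant = sum(.data$q < 0.1, na.rm = TRUE),
                .groups = "drop")
  }
  if (!is.null(results$solution)) {
    sol <- results$solution
    thr <- sol$weight_threshold %||% 1L
    last <- ncol(sol$weights)
    sections$network_size <- tibble(
      n_edges_any = nrow(sol$edges),
      n_edges_consensus = sum(sol$weights[, last] >= thr),
      n_runs = sol$n_runs
    )
    sections$weight_histogram <- tibble(weight = sol$weights[, last]) |>
      count(.data$weight)
  }
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(sections)) {
      writeLines(paste0("## ", nm), con)
      writeLines(utils::capture.output(print(as.data.frame(sections[[nm]]))),
                 con)
      writeLines("", con)
    }
    absent <- setdiff(c("targets_per_time", "kinases_per_time",
                        "network_size"), names(sections))
    for (nm in absent) writeLines(paste0("## ", nm, ": absent"), con)
  }
  sections
}

#' Write a synthetic study to disk in the pipeline's input dialects
#'
#' Emits the peptide table, annotation, kinase-site and protein-protein
#' network files, a validated kinase-substrate set file (each kinase's
#' written sites) and the ground truth as JSON, ready to be referenced from a
#' [pipeline_config()].
#'
#' @param study Output of [synthetic_study()].
#' @param dir Output directory.
#' @return Named list of file paths.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    peptide_table = file.path(dir, "peptides.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    ks_network = file.path(dir, "pkn_ks.tsv"),
    ppi_network = file.path(dir, "pkn_ppi.tsv"),
    kinase_sets = file.path(dir, "kinase_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_tsv_quiet(study$data$peptides, p$peptide_table)
  write_tsv_quiet(study$data$annotation, p$annotation)
  edges <- study$spkn$pkn$edges
  sif_cols <- c("source", "interaction_class", "target", "sign", "references")
  write_tsv_quiet(edges[edges$interaction_class != "ppi", sif_cols],
                  p$ks_network)
  write_tsv_quiet(edges[edges$interaction_class == "ppi", sif_cols],
                  p$ppi_network)
  sets <- study$spkn$sites |>
    group_by(kinase_id = .data$writer) |>
    summarise(sites = list(.data$site_id), .groups = "drop") |>
    mutate(source = "validated") |>
    select("kinase_id", "source", "sites")
  write_kinase_sets(sets, p$kinase_sets)
  jsonlite::write_json(
    list(true_edges = as.data.frame(study$truth$true_edges),
         schedule = as.data.frame(study$truth$schedule),
         decoy_sites = study$truth$decoy_sites,
         modules = study$truth$modules),
    p$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  p
}
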