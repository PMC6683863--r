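#' Parameters of the synthetic study generator
#'
#' Defaults emulate the design of a receptor-stimulation phosphoproteomic
#' time course: five time points (2-90 min), biological triplicates,
#' mock/stimulated conditions in wild-type and receptor-knockout genotypes, a
#' pooled heavy spike-in channel, ~12% multiplicative replicate noise after
#' normalization, per-sample loading and standard-mixing errors removed by
#' the two-step normalization, and regulated sites stepping to a 2.5-fold
#' change at their onset time.
#'
#' @param n_branches Receptor-proximal branches (signalling modules) in the
#'   generated network, default 5.
#' @param n_kinases Kinases distributed round-robin over the branches and
#'   chained within each branch through regulatory sites, default 10.
#' @param substrates_per_kinase Phosphosites written by each kinase (a chain
#'   link uses one of them as the downstream kinase's regulatory site),
#'   default 4.
#' @param extra_edges Additional random protein-protein edges creating
#'   shortcuts and crosstalk, default 4.
#' @param time_points Sampling times in minutes, default `c(2,10,30,60,90)`.
#' @param replicates Biological replicates per condition, default 3.
#' @param cv Multiplicative light-channel noise (lognormal coefficient of
#'   variation), default 0.12.
#' @param cv_heavy Technical noise of the pooled heavy standard, default
#'   0.03.
#' @param fold_change Regulated-site fold change at onset, default 2.5.
#' @param down_fraction Fraction of regulated sites going down (multiplied by
#'   `1/fold_change`), default 0.2.
#' @param sample_loading_sd Lognormal sigma of the per-sample loading factor
#'   shared by both channels, default 0.3.
#' @param mixing_sd Lognormal sigma of the per-sample light-to-standard
#'   mixing error (hits the heavy channel), default 0.15.
#' @param n_background_sites Measured sites on proteins outside the network,
#'   default 150.
#' @param include_ko Also simulate the receptor-knockout genotype, default
#'   TRUE.
#' @return Validated parameter list of class `generator_params`.
#' @export
generator_params <- function(n_branches = 5, n_kinases = 10,
                             substrates_per_kinase = 4, extra_edges = 4,
                             time_points = c(2, 10, 30, 60, 90),
                             replicates = 3, cv = 0.12, cv_heavy = 0.03,
                             fold_change = 2.5, down_fraction = 0.2,
                             sample_loading_sd = 0.3, mixing_sd = 0.15,
                             n_background_sites = 150, include_ko = TRUE) {
  p <- as.list(environment())
  counts <- c(p$n_branches, p$n_kinases, p$substrates_per_kinase,
              p$replicates)
  if (any(counts < 1)) abort_bad_arg("all counts must be positive")
  if (p$cv <= 0) abort_bad_arg("cv must be > 0")
  if (p$fold_change <= 1) abort_bad_arg("fold_change must be > 1")
  if (p$n_kinases < p$n_branches) {
    abort_bad_arg("need at least one kinase per branch")
  }
  structure(p, class = "generator_params")
}

#' Generate a layered random prior-knowledge network
#'
#' Builds a receptor-rooted graph: the receptor connects by ppi edges to
#' first-layer proteins (G-protein/adaptor stand-ins), each heading a branch
#' of chained kinases. Consecutive kinases in a chain are linked through a
#' regulatory site (kinase_site edge into the site, site_protein coupling
#' into the downstream kinase); remaining substrate quota becomes terminal
#' sites on otherwise unconnected proteins. `extra_edges` random ppi edges
#' between proteins add shortcuts. Fully reproducible given the seed.
#'
#' @param params A [generator_params()] list.
#' @param seed RNG seed.
#' @return A `synthetic_pkn`: list with `pkn` (a [pkn] rooted at `"RCPT"`),
#'   `kinases` (tibble `kinase_id`, `branch`, `chain_pos`) and `sites`
#'   (tibble `site_id`, `writer` kinase, `branch`, `depth`).
#' @export
generate_pkn <- function(params = generator_params(), seed = 1L) {
  with_seed(seed, {
    receptor <- "RCPT"
    branches <- paste0("GP", seq_len(params$n_branches))
    kin <- tibble(
      kinase_id = paste0("K", seq_len(params$n_kinases)),
      branch = rep(seq_len(params$n_branches),
                   length.out = params$n_kinases)
    ) |>
      group_by(.data$branch) |>
      mutate(chain_pos = row_number()) |>
      ungroup()
    edges <- list(tibble(source = receptor, target = branches,
                         interaction_class = "ppi", sign = 1L,
                         references = "synthetic"))
    sites <- list()
    term_counter <- 0L
    for (b in seq_len(params$n_branches)) {
      chain <- kin$kinase_id[kin$branch == b]
      if (length(chain) == 0) next
      edges[[length(edges) + 1L]] <-
        tibble(source = branches[b], target = chain[1],
               interaction_class = "ppi", sign = 1L,
               references = "synthetic")
      for (ci in seq_along(chain)) {
        k <- chain[ci]
        n_sub <- params$substrates_per_kinase
        if (ci < length(chain)) {
          # regulatory site on the next kinase in the chain
          pos <- sample(30:900, 1)
          reg_site <- paste0(chain[ci + 1], "_S", pos)
          edges[[length(edges) + 1L]] <- bind_rows(
            tibble(source = k, target = reg_site,
                   interaction_class = "kinase_site", sign = 1L,
                   references = "synthetic"),
            tibble(source = reg_site, target = chain[ci + 1],
                   interaction_class = "site_protein", sign = 1L,
                   references = "synthetic")
          )
          sites[[length(sites) + 1L]] <-
            tibble(site_id = reg_site, writer = k, branch = b, depth = ci)
          n_sub <- n_sub - 1L
        }
        if (n_sub > 0) {
          term_counter_new <- term_counter + n_sub
          prot <- paste0("P", (term_counter + 1L):term_counter_new)
          term_counter <- term_counter_new
          pos <- sample(30:900, n_sub, replace = TRUE)
          res <- sample(c("S", "T", "Y"), n_sub, replace = TRUE,
                        prob = c(0.83, 0.15, 0.02))
          term_sites <- paste0(prot, "_", res, pos)
          edges[[length(edges) + 1L]] <-
            tibble(source = k, target = term_sites,
                   interaction_class = "kinase_site", sign = 1L,
                   references = "synthetic")
          sites[[length(sites) + 1L]] <-
            tibble(site_id = term_sites, writer = k, branch = b, depth = ci)
        }
      }
    }
    edge_tbl <- bind_rows(edges)
    proteins <- c(branches, kin$kinase_id)
    if (params$extra_edges > 0) {
      pool <- expand.grid(source = proteins, target = proteins,
                          stringsAsFactors = FALSE)
      pool <- pool[pool$source != pool$target, ]
      existing <- paste(edge_tbl$source, edge_tbl$target)
      pool <- pool[!paste(pool$source, pool$target) %in% existing, ]
      take <- pool[sample.int(nrow(pool), min(params$extra_edges,
                                              nrow(pool))), ]
      edge_tbl <- bind_rows(edge_tbl,
                            tibble(source = take$source,
                                   target = take$target,
                                   interaction_class = "ppi", sign = 1L,
                                   references = "synthetic_extra"))
    }
    structure(
      list(pkn = pkn(edge_tbl, receptor = receptor),
           kinases = kin, sites = bind_rows(sites)),
      class = "synthetic_pkn"
    )
  })
}

#' Choose a ground-truth active subnetwork and regulation schedule
#'
#' Selects `n_modules` of the generated branches as the truly active
#' signalling modules. The true edge set is the union of those branches'
#' receptor-rooted chains (shortcut ppi edges are never part of the truth);
#' every site written within a chosen module is scheduled as regulated, with
#' onset time increasing with the writing kinase's depth in its chain
#' (depth-1 substrates switch at the first time point), so later-entering
#' edges sit farther from the receptor. A configurable fraction of sites is
#' down-regulated.
#'
#' @param spkn A `synthetic_pkn` from [generate_pkn()].
#' @param n_modules Number of active modules, default 3.
#' @param params The [generator_params()] (fold change, down fraction,
#'   time points).
#' @param seed RNG seed.
#' @return A `synthetic_truth`: list with `true_edges` (tibble), `schedule`
#'   (tibble `site_id`, `onset_time`, `direction`, `fold_change`),
#'   `decoy_sites`, `modules` and the underlying `pkn`.
#' @export
choose_truth <- function(spkn, n_modules = 3, params = generator_params(),
                         seed = 1L) {
  avail <- sort(unique(spkn$kinases$branch))
  if (n_modules > length(avail)) {
    abort_bad_arg("fewer populated branches than requested modules")
  }
  with_seed(seed, {
    modules <- sort(sample(avail, n_modules))
    edges <- spkn$pkn$edges
    mod_kin <- spkn$kinases$kinase_id[spkn$kinases$branch %in% modules]
    mod_sites <- spkn$sites[spkn$sites$branch %in% modules, ]
    root_edges <- edges$interaction_class == "ppi" &
      edges$source == spkn$pkn$receptor &
      edges$target %in% paste0("GP", modules)
    heads <- spkn$kinases |>
      filter(.data$branch %in% modules, .data$chain_pos == 1)
    branch_edges <- edges$interaction_class == "ppi" &
      paste(edges$source, edges$target) %in%
        paste(paste0("GP", heads$branch), heads$kinase_id)
    ks_edges <- edges$interaction_class == "kinase_site" &
      edges$source %in% mod_kin & edges$target %in% mod_sites$site_id
    sp_edges <- edges$interaction_class == "site_protein" &
      edges$source %in% mod_sites$site_id & edges$target %in% mod_kin
    true_edges <- edges[root_edges | branch_edges | ks_edges | sp_edges, ]
    tp <- params$time_points
    schedule <- mod_sites |>
      mutate(
        onset_time = tp[pmin(.data$depth, length(tp))],
        direction = ifelse(runif(n()) < params$down_fraction, "down", "up"),
        fold_change = params$fold_change
      ) |>
      select("site_id", "onset_time", "direction", "fold_change")
    structure(
      list(pkn = spkn$pkn, true_edges = true_edges, schedule = schedule,
           decoy_sites = setdiff(spkn$sites$site_id, schedule$site_id),
           modules = modules),
      class = "synthetic_truth"
    )
  })
}

#' Simulate a spike-in phosphoproteomic time-course dataset
#'
#' Draws a lognormal baseline abundance per site; wild-type stimulated
#' samples multiply scheduled sites by their fold change from onset onward
#' (step kinetics); knockout and mock samples carry no signal. The light
#' channel receives a per-sample loading factor shared with the heavy
#' channel (removed by the light/heavy ratio), the heavy channel a
#' per-sample standard-mixing error (removed by the median-normalization
#' step), and both channels multiplicative lognormal noise. Measured sites
#' are all network sites plus unregulated background sites. Byte-identical
#' output given the same seed.
#'
#' @param truth A `synthetic_truth` from [choose_truth()].
#' @param params The [generator_params()].
#' @param seed RNG seed.
#' @return List with `peptides` (a phosphopeptide tibble in the
#'   [read_peptide_table()] layout) and `annotation` (sample annotation
#'   tibble).
#' @export
simulate_dataset <- function(truth, params = generator_params(), seed = 1L) {
  with_seed(seed, {
    net_sites <- sort(unique(
      truth$pkn$nodes$node_id[truth$pkn$nodes$node_class == "site"]))
    n_bg <- params$n_background_sites
    bg_sites <- if (n_bg > 0) {
      paste0("BG", seq_len(n_bg), "_",
             sample(c("S", "T", "Y"), n_bg, replace = TRUE,
                    prob = c(0.83, 0.15, 0.02)),
             sample(30:900, n_bg, replace = TRUE))
    } else character(0)
    site_ids <- c(net_sites, bg_sites)
    n_sites <- length(site_ids)

    genotypes <- if (params$include_ko) c("WT", "KO") else "WT"
    annotation <- expand.grid(
      genotype = genotypes, treatment = c("stimulated", "mock"),
      time_min = params$time_points,
      replicate = seq_len(params$replicates),
      stringsAsFactors = FALSE
    ) |>
      as_tibble() |>
      mutate(cell_line = "SYN1",
             sample_id = paste0(.data$genotype, "_",
                                substr(.data$treatment, 1, 4), "_t",
                                .data$time_min, "_r", .data$replicate)) |>
      select("sample_id", "cell_line", "genotype", "treatment",
             "time_min", "replicate")

    baseline <- 2^rnorm(n_sites, mean = 20, sd = 1.5)
    names(baseline) <- site_ids
    onset <- setNames(truth$schedule$onset_time, truth$schedule$site_id)
    effect <- setNames(
      ifelse(truth$schedule$direction == "down",
             1 / truth$schedule$fold_change, truth$schedule$fold_change),
      truth$schedule$site_id
    )

    loading <- rlnorm(nrow(annotation), 0, params$sample_loading_sd)
    mixing <- rlnorm(nrow(annotation), 0, params$mixing_sd)
    sig_l <- sqrt(log(1 + params$cv^2))
    sig_h <- sqrt(log(1 + params$cv_heavy^2))

    light <- matrix(0, n_sites, nrow(annotation))
    heavy <- matrix(0, n_sites, nrow(annotation))
    for (j in seq_len(nrow(annotation))) {
      mean_true <- baseline
      if (annotation$genotype[j] == "WT" &&
          annotation$treatment[j] == "stimulated") {
        on <- names(onset)[onset <= annotation$time_min[j]]
        mean_true[on] <- mean_true[on] * effect[on]
      }
      light[, j] <- mean_true * loading[j] *
        rlnorm(n_sites, -sig_l^2 / 2, sig_l)
      heavy[, j] <- baseline * loading[j] * mixing[j] *
        rlnorm(n_sites, -sig_h^2 / 2, sig_h)
    }
    colnames(light) <- paste0("light:", annotation$sample_id)
    colnames(heavy) <- paste0("heavy:", annotation$sample_id)

    residue <- sub("^.*_([STY])[0-9]+$", "\\1", site_ids)
    position <- as.integer(sub("^.*_[STY]([0-9]+)$", "\\1", site_ids))
    peptides <- tibble(
      peptide_id = paste0("pep", seq_len(n_sites)),
      backbone_sequence = vapply(seq_len(n_sites), function(i) {
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                     sample(9:16, 1), replace = TRUE), collapse = "")
      }, character(1)),
      protein_id = site_host(site_ids),
      positions = as.character(position),
      residues = residue,
      n_phospho = 1L,
      flr = 0.001,
      localization_score = round(runif(n_sites, 5, 60), 2)
    )
    peptides <- bind_cols_strict(peptides, as_tibble(light))
    peptides <- bind_cols_strict(peptides, as_tibble(heavy))
    list(peptides = peptides, annotation = annotation)
  })
}

#' One-call synthetic study: network, truth and dataset
#'
#' @param params A [generator_params()].
#' @param n_modules Active modules passed to [choose_truth()].
#' @param seed Master seed; sub-seeds for network, truth and data are
#'   derived from it.
#' @return List `spkn`, `truth`, `data` (peptides + annotation).
#' @export
synthetic_study <- function(params = generator_params(), n_modules = 3,
                            seed = 1L) {
  seeds <- derive_seeds(seed, 3)
  spkn <- generate_pkn(params, seed = seeds[1])
  truth <- choose_truth(spkn, n_modules = n_modules, params = params,
                        seed = seeds[2])
  data <- simulate_dataset(truth, params, seed = seeds[3])
  list(spkn = spkn, truth = truth, data = data)
}

#' Score an inferred network against the synthetic truth
#'
#' True positives are the consensus edges (bootstrap weight at least
#' `weight_threshold` at the last time point) that belong to the true active
#' subnetwork. Precision is 1 by convention when nothing is inferred.
#' Target-site sensitivity is the fraction of scheduled sites wired into the
#' consensus network as kinase_site edge targets.
#'
#' @param solution A `solution_network`.
#' @param truth A `synthetic_truth`.
#' @param weight_threshold Consensus weight threshold; defaults to the
#'   ensemble's.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `site_sensitivity`.
#' @export
evaluate_recovery <- function(solution, truth, weight_threshold = NULL) {
  thr <- weight_threshold %||% solution$weight_threshold %||% 1L
  last <- ncol(solution$weights)
  inferred <- rownames(solution$weights)[solution$weights[, last] >= thr]
  true_keys <- edge_keys(truth$true_edges)
  tp <- length(intersect(inferred, true_keys))
  fp <- length(setdiff(inferred, true_keys))
  fn <- length(setdiff(true_keys, inferred))
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  inferred_edges <- solution$edges[edge_keys(solution$edges) %in% inferred, ]
  wired <- inferred_edges$target[inferred_edges$interaction_class ==
                                   "kinase_site"]
  sens <- mean(truth$schedule$site_id %in% wired)
  tibble(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1, site_sensitivity = sens)
}
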