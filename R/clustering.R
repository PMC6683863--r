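#' Replicate-averaged, z-scored time-course profiles of target sites
#'
#' Averages stimulated-sample abundances over replicates for each time point
#' and z-scores each site's time course (mean 0, sd 1 across time points), the
#' representation clustered by [fuzzy_cmeans()].
#'
#' @param site_table Site table from [peptides_to_sites()].
#' @param annotation Sample annotation tibble.
#' @param sites Sites to profile (e.g. the target union); default all.
#' @param genotype,treatment Sample group profiled (default WT stimulated).
#' @return Numeric matrix, sites x time points (columns named by time in
#'   minutes). Sites with missing time points or zero variance are dropped.
#' @export
site_profiles <- function(site_table, annotation, sites = NULL,
                          genotype = "WT", treatment = "stimulated") {
  ann <- filter(annotation, .data$genotype == !!genotype,
                .data$treatment == !!treatment,
                .data$sample_id %in% names(site_table))
  if (nrow(ann) == 0) abort_bad_arg("no matching samples in annotation")
  times <- sort(unique(ann$time_min))
  keep <- if (is.null(sites)) rep(TRUE, nrow(site_table)) else
    site_table$site_id %in% sites
  tab <- site_table[keep, , drop = FALSE]
  prof <- vapply(times, function(tp) {
    ids <- ann$sample_id[ann$time_min == tp]
    rowMeans(as.matrix(tab[, ids, drop = FALSE]), na.rm = TRUE)
  }, numeric(nrow(tab)))
  rownames(prof) <- tab$site_id
  colnames(prof) <- as.character(times)
  ok <- apply(prof, 1, function(x) all(is.finite(x)) && sd(x) > 0)
  prof <- prof[ok, , drop = FALSE]
  t(scale(t(prof)))[, , drop = FALSE]
}

#' Fuzzy c-means clustering of time-course profiles
#'
#' Standard fuzzy c-means with fuzzifier `m`: memberships and centers are
#' updated alternately until the maximal center shift falls below `tol`. The
#' objective `sum_i sum_k u_ik^m ||x_i - c_k||^2` is recorded after every
#' iteration (attribute-accessible via the returned object) and is
#' non-increasing. Initialization draws `k` distinct profiles as starting
#' centers under `seed`, so results are deterministic given the seed.
#'
#' @param profiles Numeric site x time matrix (z-scored per site, see
#'   [site_profiles()]).
#' @param k Number of clusters, default 6.
#' @param m Fuzzifier (> 1), default 2.
#' @param seed RNG seed for center initialization.
#' @param max_iter Iteration cap, default 200.
#' @param tol Center-shift convergence tolerance, default 1e-8.
#' @return A `cluster_model` object: list with `membership` (site x k, rows
#'   sum to 1), `centers` (k x time), `objective` (per-iteration trace),
#'   `cluster` (argmax hard assignment per site), `k`, `m`, `seed`.
#' @export
fuzzy_cmeans <- function(profiles, k = 6, m = 2, seed = NULL,
                         max_iter = 200, tol = 1e-8) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k > n) abort_bad_arg("k exceeds the number of profiles")
  if (m <= 1) abort_bad_arg("fuzzifier m must be > 1")
  centers <- profiles[with_seed(seed, sample.int(n, k)), , drop = FALSE]
  objective <- numeric(0)
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- pairwise_sqdist(profiles, centers)
    u <- memberships_from_dist(d2, m)
    um <- u^m
    new_centers <- (t(um) %*% profiles) / colSums(um)
    objective <- c(objective, sum(um * pairwise_sqdist(profiles, new_centers)))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  rownames(centers) <- NULL
  structure(
    list(membership = u, centers = centers, objective = objective,
         cluster = apply(u, 1, which.max), k = k, m = m, seed = seed,
         site_id = rownames(profiles), iterations = iter),
    class = "cluster_model"
  )
}

pairwise_sqdist <- function(x, centers) {
  cross <- x %*% t(centers)
  outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * cross
}

memberships_from_dist <- function(d2, m) {
  d2 <- pmax(d2, 0)
  exact <- d2 < .Machine$double.eps
  inv <- d2^(-1 / (m - 1))
  u <- inv / rowSums(inv)
  hit <- rowSums(exact) > 0
  if (any(hit)) {
    u[hit, ] <- exact[hit, , drop = FALSE] /
      rowSums(exact[hit, , drop = FALSE])
  }
  u
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Fuzzy c-means model: ", length(x$site_id), " profiles, k = ", x$k,
      ", m = ", x$m, ", ", x$iterations, " iterations\n", sep = "")
  cat("Cluster sizes (argmax membership):",
      paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Kinase-substrate enrichment per cluster (Fisher's exact test)
#'
#' For every (cluster, kinase) pair, builds the 2x2 table of in-cluster
#' substrates (a), in-cluster non-substrates (b), out-of-cluster substrates
#' (c) and out-of-cluster non-substrates (d) against the full identified-site
#' background, tests one-sided enrichment with Fisher's exact test and
#' BH-adjusts over all pairs. Kinases without measured substrates in the
#' background are skipped.
#'
#' @param model A `cluster_model` from [fuzzy_cmeans()] (argmax hard
#'   assignments are used), or a tibble with `site_id` and `cluster`.
#' @param kinase_sets Tibble with `kinase_id` and list-column `sites`.
#' @param background Character vector of all identified sites in the data
#'   set; `a + b + c + d` equals its length.
#' @return Tibble `cluster`, `kinase_id`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`, `q`.
#' @export
cluster_enrichment <- function(model, kinase_sets, background) {
  assign_tbl <- if (inherits(model, "cluster_model")) {
    tibble(site_id = model$site_id, cluster = model$cluster)
  } else {
    model
  }
  background <- unique(background)
  if (!all(assign_tbl$site_id %in% background)) {
    abort_bad_arg("all clustered sites must be part of the background")
  }
  clusters <- sort(unique(assign_tbl$cluster))
  rows <- purrr::map(seq_len(nrow(kinase_sets)), function(i) {
    subs <- intersect(kinase_sets$sites[[i]], background)
    if (length(subs) == 0) return(NULL)
    purrr::map(clusters, function(cl) {
      in_cl <- assign_tbl$site_id[assign_tbl$cluster == cl]
      a <- length(intersect(in_cl, subs))
      b <- length(in_cl) - a
      cc <- length(subs) - a
      d <- length(background) - a - b - cc
      ft <- fisher_enrichment(a, b, cc, d)
      tibble(cluster = cl, kinase_id = kinase_sets$kinase_id[i],
             a = a, b = b, c = cc, d = d,
             odds_ratio = ft$odds_ratio, p = ft$p)
    }) |> bind_rows()
  })
  out <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0) {
    return(tibble(cluster = integer(0), kinase_id = character(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), odds_ratio = numeric(0), p = numeric(0),
                  q = numeric(0)))
  }
  out$q <- bh_adjust(out$p)
  out
}

#' One-sided Fisher enrichment test of a 2x2 table
#'
#' The elementary test behind [cluster_enrichment()]: `a` in-cluster
#' substrates, `b` in-cluster non-substrates, `c` out-of-cluster substrates,
#' `d` out-of-cluster non-substrates, alternative "greater" (enrichment).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `odds_ratio` (conditional MLE) and `p`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                    alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}
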