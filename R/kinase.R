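#' Read kinase-substrate set files (GMT-like)
#'
#' Each line is `kinase_id<TAB>source<TAB>site_1<TAB>site_2...` with
#' `source` either `validated` or `predicted`.
#'
#' @param path Path to the file.
#' @return Tibble `kinase_id`, `source`, `sites` (list-column of character
#'   vectors). Empty substrate sets are rejected.
#' @export
read_kinase_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) {
    abort_bad_arg(paste0("kinase set line(s) without substrates: line ",
                         paste(which(bad), collapse = ", ")))
  }
  tibble(
    kinase_id = vapply(parts, `[[`, character(1), 1),
    source = vapply(parts, `[[`, character(1), 2),
    sites = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Write kinase-substrate sets in the GMT-like dialect
#' @param sets Tibble as returned by [read_kinase_sets()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_kinase_sets <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(kinase_id, source, sites, ...) {
    paste(c(kinase_id, source, sites), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Rank measured sites by differential metric at one time point
#'
#' Sites are ordered by descending log2 fold change with a deterministic
#' lexicographic tie-break on `site_id`, giving the ranked list the running-sum
#' statistic walks down.
#'
#' @param diff_results Differential results for a single time point.
#' @return Tibble `site_id`, `metric`, in ranked order.
#' @export
rank_sites <- function(diff_results) {
  if (nrow(diff_results) == 0) {
    return(tibble(site_id = character(0), metric = numeric(0)))
  }
  if (length(unique(diff_results$time_min)) > 1) {
    abort_bad_arg("rank_sites expects results from a single time point")
  }
  diff_results |>
    select(site_id = "site_id", metric = "log2fc") |>
    arrange(dplyr::desc(.data$metric), .data$site_id)
}

#' Weighted running-sum enrichment score of a substrate set
#'
#' Walks the ranked site list accumulating `|metric|`-weighted increments at
#' substrate hits and uniform decrements at misses (a weighted
#' Kolmogorov-Smirnov statistic in the GSEA tradition). The enrichment score
#' is the signed maximal deviation of the running sum, in `[-1, 1]`: positive
#' when substrates concentrate among the most up-regulated sites (kinase
#' activation), negative when they concentrate at the bottom (inhibition).
#'
#' @param ranked Ranked tibble from [rank_sites()].
#' @param substrates Character vector of substrate site identifiers.
#' @param min_substrates Kinases with fewer measured substrates are excluded
#'   (default 3).
#' @return The enrichment score, or `NA` with attribute `excluded = TRUE` and
#'   an attribute `reason` when the kinase has too few measured substrates.
#' @export
enrichment_score <- function(ranked, substrates, min_substrates = 3) {
  if (nrow(ranked) == 0) abort_bad_arg("ranked list is empty")
  hit <- ranked$site_id %in% substrates
  n_hit <- sum(hit)
  if (n_hit < min_substrates) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    attr(out, "reason") <- if (n_hit == 0) "no measured substrates" else
      paste0("only ", n_hit, " measured substrate(s)")
    return(out)
  }
  running_sum_es(ranked$metric, hit)
}

# Core running-sum statistic: hit steps proportional to |metric| (uniform if
# all hit weights are zero), miss steps uniform; returns the signed maximal
# deviation.
running_sum_es <- function(metric, hit) {
  w <- abs(metric[hit])
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else rep(1 / sum(hit), sum(hit))
  n_miss <- sum(!hit)
  dec <- if (n_miss > 0) 1 / n_miss else 0
  step <- numeric(length(hit))
  step[hit] <- inc
  step[!hit] <- -dec
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Permutation-normalized enrichment of one substrate set
#'
#' Builds a permutation null by recomputing the running-sum score on random
#' substrate sets of equal size drawn from the measured sites (substrate-set
#' permutation; sample permutation is not an option at n = 3 replicates).
#' The normalized enrichment value is `nev = es / mean(|es_perm|)` over
#' same-sign permutations, so its sign carries direction: positive for
#' activation, negative for inhibition. The permutation p-value uses the
#' add-one estimator `p = (1 + #{|es_perm| >= |es|, same sign}) /
#' (n_same_sign + 1)`.
#'
#' @param ranked Ranked tibble from [rank_sites()].
#' @param substrates Substrate site identifiers.
#' @param n_perm Number of permutations, default 10000.
#' @param seed RNG seed.
#' @param min_substrates Passed to [enrichment_score()].
#' @return Tibble with one row: `n_sites`, `es`, `nev`, `p_perm`, `excluded`.
#'   `nev` is `NA` (flagged) when no permutation matches the observed sign.
#' @export
normalized_enrichment <- function(ranked, substrates, n_perm = 10000,
                                  seed = NULL, min_substrates = 3) {
  es <- enrichment_score(ranked, substrates, min_substrates)
  n_hit <- sum(ranked$site_id %in% substrates)
  if (isTRUE(attr(es, "excluded"))) {
    return(tibble(n_sites = n_hit, es = NA_real_, nev = NA_real_,
                  p_perm = NA_real_, excluded = TRUE))
  }
  hit0 <- logical(nrow(ranked))
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    hit <- hit0
    hit[sample.int(nrow(ranked), n_hit)] <- TRUE
    running_sum_es(ranked$metric, hit)
  }, numeric(1)))
  same_sign <- perm * es > 0 | (perm == 0 & es == 0)
  n_same <- sum(same_sign)
  if (n_same == 0) {
    return(tibble(n_sites = n_hit, es = as.numeric(es), nev = NA_real_,
                  p_perm = 1 / (n_perm + 1), excluded = FALSE))
  }
  nev <- es / mean(abs(perm[same_sign]))
  p_perm <- (1 + sum(same_sign & abs(perm) >= abs(es))) / (n_same + 1)
  tibble(n_sites = n_hit, es = as.numeric(es), nev = as.numeric(nev),
         p_perm = p_perm, excluded = FALSE)
}

#' Kinase-activity inference across time points
#'
#' Runs [normalized_enrichment()] for every kinase substrate set at every
#' time point of a differential result table and BH-adjusts the permutation
#' p-values across kinases within each time point.
#'
#' @param diff_results Output of [differential_test()].
#' @param kinase_sets Tibble from [read_kinase_sets()] (or equivalent with
#'   `kinase_id` and list-column `sites`).
#' @param n_perm Permutations per kinase/time point, default 10000.
#' @param seed Master seed; per-(kinase, time) seeds are derived from it.
#' @param min_substrates Minimum measured substrates per kinase, default 3.
#' @return A `kinase_activity` tibble: `kinase_id`, `time_min`, `n_sites`,
#'   `es`, `nev`, `p_perm`, `q`, `excluded`.
#' @export
kinase_activity <- function(diff_results, kinase_sets, n_perm = 10000,
                            seed = NULL, min_substrates = 3) {
  times <- sort(unique(diff_results$time_min))
  seeds <- derive_seeds(seed %||% 1L, length(times) * nrow(kinase_sets))
  k <- 0L
  out <- purrr::map(times, function(tp) {
    ranked <- rank_sites(filter(diff_results, .data$time_min == tp))
    rows <- purrr::map(seq_len(nrow(kinase_sets)), function(i) {
      k <<- k + 1L
      normalized_enrichment(ranked, kinase_sets$sites[[i]], n_perm = n_perm,
                            seed = seeds[k], min_substrates = min_substrates) |>
        mutate(kinase_id = kinase_sets$kinase_id[i], time_min = tp)
    }) |> bind_rows()
    rows$q <- NA_real_
    ok <- !rows$excluded & !is.na(rows$p_perm)
    rows$q[ok] <- bh_adjust(rows$p_perm[ok])
    rows
  }) |> bind_rows() |>
    select("kinase_id", "time_min", "n_sites", "es", "nev", "p_perm", "q",
           "excluded")
  class(out) <- c("kinase_activity", class(out))
  out
}
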