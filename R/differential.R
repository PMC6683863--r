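#' Per-time-point differential phosphosite testing
#'
#' Compares stimulated against mock samples at each time point with two-sided
#' unpaired Student's t-tests (pooled variance) on normalized site
#' abundances, and computes `log2fc = log2(mean_stimulated / mean_mock)`.
#' P-values are adjusted with [bh_adjust()] within each time point (one
#' Benjamini-Hochberg family per time point), targets are flagged with
#' [call_targets()] and ILP scores attached with [ilp_scores()].
#'
#' Degenerate variance cases, which triplicate MS data can produce, are
#' handled rather than erroring: zero pooled variance with equal means gives
#' `p = 1`; zero pooled variance with unequal means gives the smallest
#' representable positive p-value. Sites with fewer than `min_replicates`
#' finite values in either group at a time point are dropped from that time
#' point's family; the count dropped is attached as attribute `n_dropped`.
#'
#' @param site_table Site table from [peptides_to_sites()].
#' @param annotation Sample annotation tibble.
#' @param time_points Time points to test; default all in the annotation.
#' @param genotype Genotype whose stimulated/mock contrast is tested
#'   (default `"WT"`; use `"KO"` for the receptor-knockout null control).
#' @param params Target-calling parameters from [target_call_params()].
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @param min_replicates Minimum finite replicates per group (default 2).
#' @return Tibble with one row per (site, time point): `site_id`, `time_min`,
#'   `log2fc`, `t_stat`, `p`, `q`, `is_target`, `score`.
#' @export
differential_test <- function(site_table, annotation, time_points = NULL,
                              genotype = "WT",
                              params = target_call_params(),
                              var_equal = TRUE, min_replicates = 2) {
  ann <- filter(annotation, .data$genotype == !!genotype)
  if (nrow(ann) == 0) abort_bad_arg(paste0("no samples with genotype ", genotype))
  time_points <- sort(time_points %||% unique(ann$time_min))
  n_dropped <- 0L
  res <- purrr::map(time_points, function(tp) {
    stim <- ann$sample_id[ann$treatment == "stimulated" & ann$time_min == tp]
    mock <- ann$sample_id[ann$treatment == "mock" & ann$time_min == tp]
    stim <- intersect(stim, names(site_table))
    mock <- intersect(mock, names(site_table))
    if (length(stim) < min_replicates || length(mock) < min_replicates) {
      abort_bad_arg(paste0("fewer than ", min_replicates,
                           " replicates per group at time ", tp))
    }
    xs <- as.matrix(site_table[, stim, drop = FALSE])
    xm <- as.matrix(site_table[, mock, drop = FALSE])
    keep <- rowSums(is.finite(xs)) >= min_replicates &
      rowSums(is.finite(xm)) >= min_replicates
    n_dropped <<- n_dropped + sum(!keep)
    tt <- t_test_rows(xs[keep, , drop = FALSE], xm[keep, , drop = FALSE],
                      var_equal = var_equal)
    tibble(site_id = site_table$site_id[keep], time_min = tp,
           log2fc = tt$log2fc, t_stat = tt$t, p = tt$p) |>
      mutate(q = bh_adjust(.data$p))
  }) |> bind_rows()
  res <- call_targets(res, params)
  res$score <- ilp_scores(res$q, params$qThresh)
  attr(res, "n_dropped") <- n_dropped
  res
}

# Row-wise two-sample t-tests; x, y matrices with replicates in columns.
t_test_rows <- function(x, y, var_equal = TRUE) {
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  nx <- rowSums(is.finite(x))
  ny <- rowSums(is.finite(y))
  vx <- apply(x, 1, stats::var, na.rm = TRUE)
  vy <- apply(y, 1, stats::var, na.rm = TRUE)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  zero_se <- is.finite(mx) & is.finite(my) & (!is.finite(se) | se == 0)
  eq <- zero_se & mx == my
  ne <- zero_se & mx != my
  t[eq] <- 0
  p[eq] <- 1
  t[ne] <- sign(mx[ne] - my[ne]) * Inf
  p[ne] <- .Machine$double.xmin
  list(t = t, p = p, log2fc = log2(mx / my))
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` kept as the module
#' surface so every correction in the package goes through one place.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values (monotone in p-rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_bad_arg("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Target-calling parameters
#'
#' @param qThresh q-value threshold, default 0.1.
#' @param fcThresh fold-change threshold (ratio scale), default 1.5; targets
#'   must change more than this factor up or down.
#' @return A named list of validated parameters.
#' @export
target_call_params <- function(qThresh = 0.1, fcThresh = 1.5) {
  if (!is.numeric(qThresh) || qThresh <= 0 || qThresh >= 1) {
    abort_bad_arg("qThresh must be in (0, 1)")
  }
  if (!is.numeric(fcThresh) || fcThresh <= 1) {
    abort_bad_arg("fcThresh must be > 1")
  }
  list(qThresh = qThresh, fcThresh = fcThresh)
}

#' Flag regulated target sites
#'
#' A site is a target at a time point when `q < qThresh` and its fold change
#' exceeds `fcThresh` up or down (`|log2fc| > log2(fcThresh)`).
#'
#' @param results Tibble with `q` and `log2fc` columns.
#' @param params See [target_call_params()].
#' @return `results` with a logical `is_target` column added or replaced. The
#'   union of sites flagged at one or more time points is available through
#'   [target_union()].
#' @export
call_targets <- function(results, params = target_call_params()) {
  mutate(results,
         is_target = .data$q < params$qThresh &
           abs(.data$log2fc) > log2(params$fcThresh) &
           is.finite(.data$log2fc))
}

#' Union of target sites over time points
#'
#' @param results Output of [differential_test()] (or any tibble with
#'   `site_id` and `is_target`).
#' @return Character vector of sites flagged at >= 1 time point.
#' @export
target_union <- function(results) {
  sort(unique(results$site_id[results$is_target]))
}

#' ILP measurement scores from q-values
#'
#' `s = log2(q / qThresh)`: zero at the threshold, negative for regulated
#' sites (the reward the network optimiser seeks) and positive for
#' non-regulated sites (the penalty paid when they are wired into the
#' network). Strictly increasing in q. Zero q-values are clamped to the
#' smallest representable positive double with a warning.
#'
#' @param q Vector of adjusted q-values in `(0, 1]`.
#' @param qThresh Threshold in `(0, 1)`, default 0.1.
#' @return Numeric score vector.
#' @export
ilp_scores <- function(q, qThresh = 0.1) {
  if (qThresh <= 0 || qThresh >= 1) abort_bad_arg("qThresh must be in (0, 1)")
  if (any(q < 0 | q > 1, na.rm = TRUE)) abort_bad_arg("q-values must lie in [0, 1]")
  if (any(q == 0, na.rm = TRUE)) {
    warning("q-values of 0 clamped to smallest positive double", call. = FALSE)
    q[!is.na(q) & q == 0] <- .Machine$double.xmin
  }
  log2(q / qThresh)
}

#' Write differential results to TSV
#' @param results Output of [differential_test()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_differential <- function(results, path) write_tsv_quiet(results, path)
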