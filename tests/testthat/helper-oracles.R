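# Independent oracles and fixture builders shared across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package's code paths.

# Step-up false-discovery-rate adjustment written out from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j) on the sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Hypergeometric upper-tail sum for the one-sided Fisher test of the table
# (a, b, c, d), via binomial coefficients only.
hyper_tail_oracle <- function(a, b, c, d) {
  n_cluster <- a + b
  n_sub <- a + c
  n <- a + b + c + d
  ks <- a:min(n_cluster, n_sub)
  sum(choose(n_sub, ks) * choose(n - n_sub, n_cluster - ks)) /
    choose(n, n_cluster)
}

# Exhaustive weighted running-sum maximum deviation, step by step.
running_sum_oracle <- function(metric, hit) {
  n <- length(metric)
  tot_hit <- sum(abs(metric[hit]))
  n_miss <- sum(!hit)
  rs <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      rs <- rs + if (tot_hit > 0) abs(metric[i]) / tot_hit else 1 / sum(hit)
    } else {
      rs <- rs - 1 / n_miss
    }
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# ---- brute-force oracle for the subnetwork-selection ILP -------------------
# Enumerates every edge subset containing the forced edges, keeps the
# feasible ones (grounded in the root and acyclic) and minimises the
# objective with the implied optimal site inclusions.

ilp_feasible <- function(sel, src, dst, root) {
  if (!any(sel)) return(TRUE)
  es <- which(sel)
  # grounded: grow the active node set from the root
  active <- root
  repeat {
    add <- es[src[es] %in% active & !dst[es] %in% active]
    if (length(add) == 0) break
    active <- c(active, dst[add])
  }
  if (!all(src[es] %in% active)) return(FALSE)
  # acyclic: Kahn peeling on the selected subgraph
  nodes <- unique(c(src[es], dst[es]))
  ecur <- es
  repeat {
    if (length(ecur) == 0) return(TRUE)
    has_in <- unique(dst[ecur])
    srcs_only <- setdiff(unique(src[ecur]), has_in)
    if (length(srcs_only) == 0) return(FALSE)
    ecur <- ecur[!src[ecur] %in% srcs_only]
  }
}

ilp_cost <- function(sel, src, dst, score, is_site, eps, forced) {
  cost <- eps * sum(sel & !forced)
  for (v in which(is_site)) {
    out_sel <- any(sel & src == v)
    in_sel <- any(sel & dst == v)
    if (out_sel) {
      cost <- cost + score[v]
    } else if (in_sel && score[v] < 0) {
      cost <- cost + score[v]
    }
  }
  cost
}

brute_force_ilp <- function(n_nodes, src, dst, score, is_site, root,
                            forced = rep(FALSE, length(src)), eps = 0.01) {
  ne <- length(src)
  free <- which(!forced)
  best <- Inf
  best_sel <- NULL
  for (mask in 0:(2^length(free) - 1)) {
    sel <- forced
    if (length(free) > 0) {
      sel[free] <- bitwAnd(mask, 2^(seq_along(free) - 1)) > 0
    }
    if (!ilp_feasible(sel, src, dst, root)) next
    cost <- ilp_cost(sel, src, dst, score, is_site, eps, forced)
    if (cost < best - 1e-12) {
      best <- cost
      best_sel <- sel
    }
    if (length(free) == 0) break
  }
  list(objective = best, selected = best_sel)
}

# Random small instance for solver-vs-oracle comparisons: a loose DAG-ish
# directed graph with a handful of measured sites carrying mixed scores.
random_ilp_instance <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(5:8, 1)
  root <- 1L
  ne <- sample(6:10, 1)
  src <- sample.int(n_nodes, ne, replace = TRUE)
  dst <- sample.int(n_nodes, ne, replace = TRUE)
  keep <- src != dst & dst != root
  src <- src[keep]; dst <- dst[keep]
  is_site <- rep(FALSE, n_nodes)
  sites <- setdiff(sample.int(n_nodes, min(4, n_nodes - 1)), root)
  is_site[sites] <- TRUE
  score <- rep(0, n_nodes)
  score[sites] <- round(runif(length(sites), -5, 3), 2)
  list(n_nodes = n_nodes, src = src, dst = dst, score = score,
       is_site = is_site, root = root)
}

solve_instance <- function(inst, forced = rep(FALSE, length(inst$src)),
                           eps = 0.01) {
  phosphonet:::.solve_subnetwork_cpp(
    n_nodes = inst$n_nodes, edge_src = inst$src - 1L,
    edge_dst = inst$dst - 1L, node_score = inst$score,
    is_site = inst$is_site, root = inst$root - 1L,
    forced = forced, epsilon = eps, node_budget = 1e7
  )
}

# ---- small shared fixtures -------------------------------------------------

# Hand-written phosphopeptide table: three confident peptides (one doubly
# phosphorylated), one ambiguous isomer pair.
peptide_fixture <- function() {
  tibble::tibble(
    peptide_id = paste0("pep", 1:5),
    backbone_sequence = c("AAASAAK", "CCCSCCK", "DDDSDTK", "EEESEEK",
                          "EEESEEK"),
    protein_id = c("P1", "P2", "P3", "P4", "P4"),
    positions = c("473", "112", "1134;1137", "88", "90"),
    residues = c("S", "S", "S;T", "S", "S"),
    n_phospho = c(1L, 1L, 2L, 1L, 1L),
    flr = c(0.005, 0.002, 0.008, 0.05, 0.08),
    localization_score = c(20, 30, 25, 7.1, 3.2),
    `light:s1` = c(10, 20, 40, 8, 9),
    `light:s2` = c(12, 22, 44, 9, 10),
    `heavy:s1` = c(5, 10, 20, 4, 4),
    `heavy:s2` = c(6, 11, 22, 5, 5)
  )
}

# Minimal receptor -> kinase -> site chain network.
chain_pkn <- function() {
  edges <- tibble::tibble(
    source = c("R", "K1"),
    target = c("K1", "P1_S10"),
    interaction_class = c("ppi", "kinase_site"),
    sign = 1L,
    references = c("r1", "r2")
  )
  pkn(edges, receptor = "R")
}

small_study <- function(seed = 1, n_modules = 2, ...) {
  p <- generator_params(n_branches = 4, n_kinases = 7,
                        substrates_per_kinase = 3,
                        n_background_sites = 40, ...)
  list(params = p, study = synthetic_study(p, n_modules = n_modules,
                                           seed = seed))
}
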