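test_that("the generator is fully deterministic given a seed", {
  p <- generator_params(n_branches = 3, n_kinases = 5,
                        substrates_per_kinase = 3, n_background_sites = 20)
  a <- synthetic_study(p, n_modules = 2, seed = 11)
  b <- synthetic_study(p, n_modules = 2, seed = 11)
  expect_identical(a$spkn$pkn$edges, b$spkn$pkn$edges)
  expect_identical(a$truth$schedule, b$truth$schedule)
  expect_identical(a$data$peptides, b$data$peptides)
  c <- synthetic_study(p, n_modules = 2, seed = 12)
  expect_false(identical(a$data$peptides, c$data$peptides))
})

test_that("node and edge counts follow the construction's closed forms", {
  p <- generator_params(n_branches = 3, n_kinases = 7,
                        substrates_per_kinase = 4, extra_edges = 2,
                        n_background_sites = 0)
  spkn <- generate_pkn(p, seed = 5)
  k_per_branch <- tabulate(rep(1:3, length.out = 7), 3)
  n_links <- sum(k_per_branch - 1)
  n_sites <- 7 * 4
  edges <- spkn$pkn$edges
  expect_equal(sum(edges$interaction_class == "kinase_site"), n_sites)
  expect_equal(sum(edges$interaction_class == "site_protein"), n_links)
  expect_equal(sum(edges$interaction_class == "ppi"),
               3 + sum(k_per_branch > 0) + 2)
  # nodes: receptor, branch heads, kinases and the site nodes themselves
  # (terminal host proteins carry no edges and so are not graph nodes)
  expect_equal(nrow(spkn$pkn$nodes), 1 + 3 + 7 + n_sites)
  # without extra edges the graph is a receptor-rooted forest of chains
  spkn0 <- generate_pkn(generator_params(n_branches = 3, n_kinases = 7,
                                         substrates_per_kinase = 4,
                                         extra_edges = 0), seed = 5)
  ig <- igraph::graph_from_data_frame(
    spkn0$pkn$edges[, c("source", "target")], directed = TRUE)
  expect_true(igraph::is_dag(ig))
  expect_true(all(igraph::degree(ig, mode = "in")[igraph::V(ig)$name !=
                                                    "RCPT"] == 1))
})

test_that("the scheduled truth is reachable and onsets increase with depth", {
  fix <- small_study(seed = 29)
  truth <- fix$study$truth
  ig <- igraph::graph_from_data_frame(
    truth$true_edges[, c("source", "target")], directed = TRUE)
  reach <- names(igraph::subcomponent(ig, "RCPT", mode = "out"))
  expect_true(all(truth$schedule$site_id %in% reach))
  # depth-1 sites onset at the first time point
  d1 <- fix$study$spkn$sites |>
    dplyr::filter(depth == 1, site_id %in% truth$schedule$site_id)
  expect_true(all(truth$schedule$onset_time[
    match(d1$site_id, truth$schedule$site_id)] == 2))
  expect_error(choose_truth(fix$study$spkn, n_modules = 99),
               "fewer populated branches")
})

test_that("the noise-free limit reproduces the programmed fold changes exactly", {
  p <- generator_params(n_branches = 2, n_kinases = 3,
                        substrates_per_kinase = 2, cv = 1e-9,
                        cv_heavy = 1e-9, sample_loading_sd = 0,
                        mixing_sd = 0, n_background_sites = 5,
                        include_ko = FALSE)
  st <- synthetic_study(p, n_modules = 1, seed = 3)
  sites <- st$data$peptides |> filter_localization() |>
    normalize_peptides() |> peptides_to_sites()
  sched <- st$truth$schedule
  ann <- st$data$annotation
  for (i in seq_len(nrow(sched))) {
    row <- sites[sites$site_id == sched$site_id[i], ]
    stim <- ann$sample_id[ann$treatment == "stimulated" &
                            ann$time_min >= sched$onset_time[i]]
    mock <- ann$sample_id[ann$treatment == "mock" &
                            ann$time_min >= sched$onset_time[i]]
    ratio <- mean(as.numeric(row[1, stim])) / mean(as.numeric(row[1, mock]))
    want <- if (sched$direction[i] == "down") 1 / sched$fold_change[i] else
      sched$fold_change[i]
    expect_equal(ratio, want, tolerance = 1e-5)
  }
})

test_that("scheduled sites are recovered as targets from their onset onward", {
  fix <- small_study(seed = 31)
  d <- fix$study$data
  sites <- d$peptides |> filter_localization() |> normalize_peptides() |>
    peptides_to_sites()
  diff <- differential_test(sites, d$annotation)
  sched <- fix$study$truth$schedule
  called <- vapply(seq_len(nrow(sched)), function(i) {
    any(diff$is_target[diff$site_id == sched$site_id[i] &
                         diff$time_min >= sched$onset_time[i]])
  }, logical(1))
  expect_gte(mean(called), 0.9)
})

test_that("recovery metrics count edges the way a hand tally does", {
  fix <- small_study(seed = 41)
  truth <- fix$study$truth
  keys <- paste(truth$true_edges$source, truth$true_edges$interaction_class,
                truth$true_edges$target, sep = "|")
  fake <- list(
    edges = truth$true_edges,
    weights = matrix(100L, nrow(truth$true_edges), 1,
                     dimnames = list(keys, "90")),
    weight_threshold = 20, time_points = 90,
    node_class = stats::setNames(fix$study$spkn$pkn$nodes$node_class,
                                 fix$study$spkn$pkn$nodes$node_id)
  )
  class(fake) <- "solution_network"
  perfect <- evaluate_recovery(fake, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  # empty inference: precision 1 by convention, recall and F1 zero
  empty <- fake
  empty$weights[] <- 0L
  sc <- evaluate_recovery(empty, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 0)
  expect_equal(sc$f1, 0)
  # 3 true + 2 spurious inferred edges: precision 3/5
  spur <- tibble::tibble(source = c("X1", "X2"), target = c("Y1_S1", "Y2_S2"),
                         interaction_class = "kinase_site", sign = 1L,
                         references = "")
  mixed_edges <- dplyr::bind_rows(truth$true_edges[1:3, ], spur)
  mkeys <- paste(mixed_edges$source, mixed_edges$interaction_class,
                 mixed_edges$target, sep = "|")
  mixed <- fake
  mixed$edges <- mixed_edges
  mixed$weights <- matrix(100L, 5, 1, dimnames = list(mkeys, "90"))
  sc2 <- evaluate_recovery(mixed, truth)
  expect_equal(sc2$precision, 3 / 5)
})

test_that("resampling site identifiers keeps about 63 percent unique", {
  ids <- paste0("P", 1:1000, "_S1")
  fr <- vapply(1:50, function(s) {
    length(resample_site_ids(ids, seed = s)) / 1000
  }, numeric(1))
  expect_gt(mean(fr), 0.61)
  expect_lt(mean(fr), 0.65)
  expect_identical(resample_site_ids(ids, seed = 4),
                   resample_site_ids(ids, seed = 4))
})

test_that("entry time is the first time the weight reaches the threshold", {
  w <- matrix(c(5L, 25L, 60L, 80L, 90L), 1,
              dimnames = list("K|kinase_site|P_S1",
                              c("2", "10", "30", "60", "90")))
  sol <- structure(list(
    edges = tibble::tibble(source = "K", interaction_class = "kinase_site",
                           target = "P_S1", sign = 1L, references = ""),
    weights = w, time_points = c(2, 10, 30, 60, 90), n_runs = 100L,
    weight_threshold = 20), class = "solution_network")
  expect_equal(entry_times(sol)$entry_time, 10)
  expect_true(is.na(entry_times(sol, weight_threshold = 95)$entry_time))
})

test_that("the randomized control is deterministic and strips regulated identities", {
  fix <- small_study(seed = 51)
  d <- fix$study$data
  sites <- d$peptides |> filter_localization() |> normalize_peptides() |>
    peptides_to_sites()
  reg <- fix$study$truth$schedule$site_id
  pool <- setdiff(sites$site_id, reg)
  ctrl <- randomized_control(sites, reg, pool, seed = 9)
  ctrl2 <- randomized_control(sites, reg, pool, seed = 9)
  expect_identical(ctrl, ctrl2)
  expect_false(any(reg %in% ctrl$site_id))
  expect_equal(nrow(ctrl), nrow(sites) - length(reg))
  expect_error(randomized_control(sites, reg, pool[1:2], seed = 1),
               "smaller")
})

test_that("the control network misses most of the true structure", {
  fix <- small_study(seed = 61)
  d <- fix$study$data
  sites <- d$peptides |> filter_localization() |> normalize_peptides() |>
    peptides_to_sites()
  ann <- d$annotation
  truth <- fix$study$truth
  g <- attach_site_coupling(truth$pkn)
  run_net <- function(tbl) {
    diff <- differential_test(tbl, ann)
    targets <- target_union(diff)
    pr <- prune_to_reachable(g, regulated_sites = targets)
    if (nrow(pr$edges) == 0) return(character(0))
    sol <- evolve_time_course(pr, diff[, c("site_id", "time_min", "score")])
    rownames(sol$weights)[sol$weights[, ncol(sol$weights)] > 0]
  }
  true_keys <- paste(truth$true_edges$source,
                     truth$true_edges$interaction_class,
                     truth$true_edges$target, sep = "|")
  real_hits <- length(intersect(run_net(sites), true_keys))
  reg <- truth$schedule$site_id
  ctrl <- randomized_control(sites, reg, setdiff(sites$site_id, reg),
                             seed = 13)
  ctrl_hits <- length(intersect(run_net(ctrl), true_keys))
  expect_gt(real_hits, 0)
  expect_lt(ctrl_hits, 0.5 * real_hits)
})
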