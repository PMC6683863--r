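scores_tbl <- function(...) {
  v <- c(...)
  tibble::tibble(site_id = names(v), score = unname(v))
}

test_that("an all-positive score profile yields the empty network", {
  g <- chain_pkn()
  prob <- build_ilp(g, scores_tbl(P1_S10 = 2))
  sol <- solve_ilp(prob)
  expect_equal(nrow(sol$edges), 0)
  expect_equal(sol$objective, 0)
  expect_true(sol$optimal)
})

test_that("a regulated site pulls in its chain at score plus epsilon cost", {
  g <- chain_pkn()
  sol <- solve_ilp(build_ilp(g, scores_tbl(P1_S10 = -2), epsilon = 0.01))
  expect_equal(nrow(sol$edges), 2)
  expect_equal(sol$objective, -2 + 0.02)
})

test_that("epsilon breaks ties toward the shorter route", {
  edges <- tibble::tibble(
    source = c("R", "K1", "R", "A", "B", "K2", "K1"),
    target = c("K1", "P_S1", "A", "B", "K2", "P_S1", "X_S2"),
    interaction_class = c("ppi", "kinase_site", "ppi", "ppi", "ppi",
                          "kinase_site", "kinase_site"),
    sign = 1L, references = ""
  )
  g <- pkn(edges, receptor = "R")
  sol <- solve_ilp(build_ilp(g, scores_tbl(P_S1 = -3), epsilon = 0.01))
  expect_equal(sort(unique(sol$edges$source)), c("K1", "R"))
  expect_equal(sol$objective, -3 + 0.02)
})

test_that("routing through a penalised site happens only when it pays", {
  # R -> K1 -> s1(+1) -> K2 -> s2(score), only path to s2 crosses s1
  edges <- tibble::tibble(
    source = c("R", "K1", "K2_S1", "K2"),
    target = c("K1", "K2_S1", "K2", "P_S2"),
    interaction_class = c("ppi", "kinase_site", "site_protein",
                          "kinase_site"),
    sign = 1L, references = ""
  )
  g <- pkn(edges, receptor = "R")
  sol_pay <- solve_ilp(build_ilp(g, scores_tbl(K2_S1 = 1, P_S2 = -5)))
  expect_equal(nrow(sol_pay$edges), 4)
  expect_equal(sol_pay$objective, -5 + 1 + 4 * 0.01)
  sol_skip <- solve_ilp(build_ilp(g, scores_tbl(K2_S1 = 1, P_S2 = -0.9)))
  expect_equal(nrow(sol_skip$edges), 0)
})

test_that("the exact solver matches brute-force enumeration on random instances", {
  for (s in 1:100) {
    inst <- random_ilp_instance(s)
    got <- solve_instance(inst)
    want <- brute_force_ilp(inst$n_nodes, inst$src, inst$dst, inst$score,
                            inst$is_site, inst$root)
    expect_equal(got$objective, want$objective, tolerance = 1e-9,
                 info = paste("instance", s))
    expect_true(got$optimal)
  }
})

test_that("forced edges are honoured and unknown forced edges error", {
  g <- chain_pkn()
  keys <- paste(g$edges$source, g$edges$interaction_class, g$edges$target,
                sep = "|")
  prob <- build_ilp(g, scores_tbl(P1_S10 = 2), forced_edges = keys)
  sol <- solve_ilp(prob)
  expect_equal(nrow(sol$edges), 2)  # kept despite the positive score
  expect_error(build_ilp(g, scores_tbl(P1_S10 = 2),
                         forced_edges = "A|ppi|B"), "absent")
})

test_that("epsilon must stay below the weakest regulated-site score", {
  g <- chain_pkn()
  expect_error(build_ilp(g, scores_tbl(P1_S10 = -0.005), epsilon = 0.01),
               "epsilon")
})

test_that("measured sites missing from the network are dropped with a report", {
  g <- chain_pkn()
  prob <- build_ilp(g, scores_tbl(P1_S10 = -1, GHOST_S9 = -4))
  expect_equal(attr(prob, "dropped_sites"), "GHOST_S9")
})

test_that("time evolution is idempotent, extends branches and carries structure forward", {
  # two-branch network; s1 regulated from t1, s2 only from t2, s1 relaxes at t2
  edges <- tibble::tibble(
    source = c("R", "K1", "R", "K2"),
    target = c("K1", "P_S1", "K2", "Q_S2"),
    interaction_class = c("ppi", "kinase_site", "ppi", "kinase_site"),
    sign = 1L, references = ""
  )
  g <- pkn(edges, receptor = "R")
  sc <- dplyr::bind_rows(
    tibble::tibble(site_id = c("P_S1", "Q_S2"), time_min = 2,
                   score = c(-3, 2)),
    tibble::tibble(site_id = c("P_S1", "Q_S2"), time_min = 10,
                   score = c(2, -3))
  )
  sol <- evolve_time_course(g, sc)
  w <- sol$weights
  # t1: only the s1 branch; t2 adds the s2 branch and keeps s1's
  expect_equal(sum(w[, "2"]), 2)
  expect_equal(sum(w[, "10"]), 4)
  expect_true(all(w[, "10"] >= w[, "2"]))
  # identical scores at both times give identical nested networks
  sc_same <- dplyr::bind_rows(
    tibble::tibble(site_id = "P_S1", time_min = c(2, 10), score = -3))
  sol_same <- evolve_time_course(g, sc_same)
  expect_equal(sol_same$weights[, "2"], sol_same$weights[, "10"])
})

test_that("downstream target queries follow selected edges only", {
  edges <- tibble::tibble(
    source = c("R", "K1", "K2_S1", "K2"),
    target = c("K1", "K2_S1", "K2", "P_S2"),
    interaction_class = c("ppi", "kinase_site", "site_protein",
                          "kinase_site"),
    sign = 1L, references = ""
  )
  g <- pkn(edges, receptor = "R")
  sol <- evolve_time_course(g, tibble::tibble(
    site_id = c("K2_S1", "P_S2"), time_min = 2, score = c(-2, -5)))
  expect_setequal(downstream_targets(sol, "K1", 2), c("K2_S1", "P_S2"))
  expect_setequal(downstream_targets(sol, "K2", 2), "P_S2")
  expect_equal(downstream_targets(sol, "P_S2", 2), character(0))
  expect_warning(out <- downstream_targets(sol, "NOPE", 2), "not part")
  expect_equal(out, character(0))
})
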