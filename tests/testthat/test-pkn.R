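write_sif_file <- function(lines, path) {
  writeLines(lines, path)
  path
}

test_that("network files load with typing, deduplication and reference union", {
  ks <- write_sif_file(c("K1\tkinase_site\tP1_S10\t1\t111",
                         "K1\tkinase_site\tP1_S10\t1\t222",
                         "P1_S10\tsite_protein\tP1\t1\t"),
                       withr::local_tempfile(fileext = ".tsv"))
  ppi <- write_sif_file("R\tppi\tK1\t+1\t333",
                        withr::local_tempfile(fileext = ".tsv"))
  g <- load_pkn(ks, ppi, receptor = "R")
  expect_equal(nrow(g$edges), 3)
  dup <- g$edges[g$edges$interaction_class == "kinase_site", ]
  expect_setequal(strsplit(dup$references, ";")[[1]], c("111", "222"))
  expect_equal(g$nodes$node_class[g$nodes$node_id == "P1_S10"], "site")
  expect_equal(g$nodes$host_protein[g$nodes$node_id == "P1_S10"], "P1")
  expect_equal(g$nodes$node_class[g$nodes$node_id == "R"], "receptor")
  # empty files give an empty network
  e1 <- write_sif_file(character(0), withr::local_tempfile())
  e2 <- write_sif_file(character(0), withr::local_tempfile())
  expect_equal(nrow(load_pkn(e1, e2)$edges), 0)
})

test_that("malformed rows, bad signs and class violations are rejected", {
  bad <- write_sif_file(c("K1\tkinase_site\tP1_S10\t1\tx", "K2\tppi"),
                        withr::local_tempfile())
  ok <- write_sif_file(character(0), withr::local_tempfile())
  expect_error(load_pkn(bad, ok), "line 2")
  badsign <- write_sif_file("R\tppi\tK1\t2\t", withr::local_tempfile())
  expect_error(load_pkn(ok, badsign), "sign")
  # kinase_site edge targeting a protein-class node violates typing
  edges <- tibble::tibble(source = c("K1", "K2"),
                          target = c("K2", "P_S5"),
                          interaction_class = c("kinase_site", "ppi"),
                          sign = 1L, references = "")
  expect_error(pkn(edges), "non-site|site-class|touching")
})

test_that("grouping merges isoforms, unions substrates and drops self-loops", {
  edges <- tibble::tibble(
    source = c("R", "R", "K1a", "K1b", "K1a"),
    target = c("K1a", "K1b", "P1_S1", "P2_S2", "K1b_S9"),
    interaction_class = c("ppi", "ppi", "kinase_site", "kinase_site",
                          "kinase_site"),
    sign = 1L,
    references = c("a", "b", "c", "d", "e")
  )
  edges <- dplyr::bind_rows(edges,
                            tibble::tibble(source = "K1b_S9", target = "K1b",
                                           interaction_class = "site_protein",
                                           sign = 1L, references = "f"))
  g <- pkn(edges, receptor = "R")
  grouping <- tibble::tibble(member_id = c("K1a", "K1b"), group_id = "K1")
  gg <- apply_grouping(g, grouping)
  # identity under empty grouping
  expect_equal(apply_grouping(g, grouping[0, ])$edges, g$edges)
  # both receptor edges collapse onto the group with unioned references
  rk <- gg$edges[gg$edges$source == "R", ]
  expect_equal(nrow(rk), 1)
  expect_setequal(strsplit(rk$references, ";")[[1]], c("a", "b"))
  # substrate sets union on the group node
  subs <- gg$edges$target[gg$edges$source == "K1" &
                            gg$edges$interaction_class == "kinase_site"]
  expect_setequal(subs, c("P1_S1", "P2_S2", "K1b_S9"))
  # the site-to-host coupling became a self-loop via its host and is dropped
  expect_false(any(gg$edges$source == gg$edges$target))
  # reference conservation: total refs = kept refs + dropped self-loop refs
  n_refs <- function(e) sum(lengths(strsplit(e$references[nzchar(e$references)],
                                             ";")))
  expect_equal(n_refs(g$edges),
               n_refs(gg$edges) + attr(gg, "dropped_self_loop_refs"))
  # the site's host follows the grouping
  expect_equal(gg$nodes$host_protein[gg$nodes$node_id == "K1b_S9"], "K1")
})

test_that("grouping that swallows the receptor is refused", {
  g <- chain_pkn()
  expect_error(apply_grouping(g, tibble::tibble(member_id = c("R", "K1"),
                                                group_id = "G")),
               "receptor")
})

test_that("site coupling is added only for hosts with outgoing edges, with sign overrides", {
  edges <- tibble::tibble(
    source = c("R", "K1", "K1", "K2"),
    target = c("K1", "K2_S5", "P9_S1", "P8_S2"),
    interaction_class = c("ppi", "kinase_site", "kinase_site",
                          "kinase_site"),
    sign = 1L, references = ""
  )
  g <- pkn(edges, receptor = "R")
  out <- attach_site_coupling(g)
  sp <- out$edges[out$edges$interaction_class == "site_protein", ]
  # K2_S5 couples into K2 (which has outgoing edges); terminal sites do not
  expect_equal(sp$source, "K2_S5")
  expect_equal(sp$target, "K2")
  # inhibitory override flips the sign
  out2 <- attach_site_coupling(g, sign_overrides = tibble::tibble(
    site_id = "K2_S5", sign = -1L))
  sp2 <- out2$edges[out2$edges$interaction_class == "site_protein", ]
  expect_equal(sp2$sign, -1L)
  # graph without site nodes is unchanged
  bare <- pkn(edges[1, ], receptor = "R")
  expect_equal(attach_site_coupling(bare)$edges, bare$edges)
})

test_that("pruning keeps exactly the edges on receptor-to-site paths", {
  # chain stays, isolated branches go
  edges <- dplyr::bind_rows(
    chain_pkn()$edges,
    tibble::tibble(source = "K9", target = "P9_S9",
                   interaction_class = "kinase_site", sign = 1L,
                   references = "")
  )
  g <- pkn(edges, receptor = "R")
  pr <- prune_to_reachable(g, regulated_sites = "P1_S10")
  expect_equal(sort(pr$edges$source), c("K1", "R"))
  expect_false("K9" %in% pr$nodes$node_id)
  # unreachable regulated sites are reported, not fatal
  pr2 <- prune_to_reachable(g, regulated_sites = c("P1_S10", "P9_S9"))
  expect_equal(attr(pr2, "unreachable_sites"), "P9_S9")
  expect_error(prune_to_reachable(g, receptor = "NOPE",
                                  regulated_sites = "P1_S10"), "receptor")
})

test_that("pruning equals exhaustive path enumeration on random acyclic networks", {
  for (s in 1:20) {
    spkn <- generate_pkn(generator_params(n_branches = 3, n_kinases = 5,
                                          substrates_per_kinase = 2,
                                          extra_edges = 0,
                                          n_background_sites = 0), seed = s)
    g <- spkn$pkn
    set.seed(s)
    sites <- sample(spkn$sites$site_id, 3)
    pr <- prune_to_reachable(g, regulated_sites = sites)
    ig <- igraph::graph_from_data_frame(g$edges[, c("source", "target")],
                                        directed = TRUE,
                                        vertices = g$nodes$node_id)
    expected <- unique(unlist(lapply(sites, function(sid) {
      paths <- igraph::all_simple_paths(ig, from = "RCPT", to = sid,
                                        mode = "out")
      unlist(lapply(paths, function(p) {
        v <- names(p)
        paste(v[-length(v)], v[-1])
      }))
    })))
    got <- paste(pr$edges$source, pr$edges$target)
    expect_setequal(got, expected)
    # idempotence
    pr2 <- prune_to_reachable(pr, regulated_sites = sites)
    expect_equal(pr2$edges, pr$edges)
    # every surviving edge sees the receptor behind it and a site ahead
    igp <- igraph::graph_from_data_frame(pr$edges[, c("source", "target")],
                                         directed = TRUE,
                                         vertices = pr$nodes$node_id)
    for (i in seq_len(nrow(pr$edges))) {
      back <- names(igraph::subcomponent(igp, pr$edges$source[i],
                                         mode = "in"))
      fwd <- names(igraph::subcomponent(igp, pr$edges$target[i],
                                        mode = "out"))
      expect_true("RCPT" %in% back)
      expect_true(any(sites %in% fwd))
    }
  }
})
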