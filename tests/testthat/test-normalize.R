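test_that("localization filtering passes confident peptides and collapses isomer groups", {
  pep <- peptide_fixture()
  out <- filter_localization(pep)
  # confident records pass unchanged and localized
  expect_true(all(out$localized[out$flr <= 0.01]))
  expect_equal(sum(out$flr <= 0.01), 3)
  # the ambiguous pair collapses to the higher-scoring member's positions
  amb <- out[!out$localized, ]
  expect_equal(nrow(amb), 1)
  expect_equal(amb$positions, "88")
  expect_equal(amb$`light:s1`, 8)
  # output size = confident + number of ambiguous groups
  expect_equal(nrow(out),
               sum(pep$flr <= 0.01) +
                 length(unique(paste(pep$backbone_sequence,
                                     pep$n_phospho)[pep$flr > 0.01])))
  # empty input is the identity
  expect_equal(nrow(filter_localization(pep[0, ])), 0)
})

test_that("isomer groups without localization scores are rejected with a diagnostic", {
  pep <- peptide_fixture()
  pep$localization_score[4:5] <- NA
  expect_warning(out <- filter_localization(pep), "rejected 1 ambiguous")
  expect_equal(nrow(out), 3)
})

test_that("spike-in normalization matches the hand-computed two-step formula", {
  L <- matrix(c(10, 30, 20, 80), 2)
  H <- matrix(c(5, 15, 5, 20), 2)
  expect_equal(gist_normalize(L, H, anchor = "global_median"),
               matrix(3, 2, 2))
  # unit anchor divides out each sample's median ratio instead
  expect_equal(gist_normalize(L, H), matrix(1, 2, 2))
  # heavy identical to light: all ratios one under either anchor
  expect_equal(gist_normalize(L, L), matrix(1, 2, 2))
  expect_equal(gist_normalize(L, L, anchor = "global_median"),
               matrix(1, 2, 2))
})

test_that("spike-in normalization is exactly invariant to per-sample light factors", {
  set.seed(11)
  for (i in 1:20) {
    L <- matrix(rlnorm(60, 10, 1), 10, 6)
    H <- matrix(rlnorm(60, 10, 1), 10, 6)
    f <- runif(6, 0.5, 2)
    base <- gist_normalize(L, H)
    pert <- gist_normalize(sweep(L, 2, f, `*`), H)
    expect_lt(max(abs(base - pert)), 1e-9)
  }
})

test_that("zero or missing heavy intensities flag values missing, not zero", {
  L <- matrix(c(10, 30, 20, 80), 2)
  H <- matrix(c(5, 0, NA, 20), 2)
  out <- gist_normalize(L, H)
  expect_true(is.na(out[2, 1]))
  expect_true(is.na(out[1, 2]))
  expect_false(any(out == 0, na.rm = TRUE))
})

test_that("peptide-to-site conversion emits one row per site with the least ambiguous representative", {
  pep <- peptide_fixture() |>
    filter_localization() |>
    normalize_peptides()
  sites <- peptides_to_sites(pep)
  # one row per distinct site id
  expect_equal(anyDuplicated(sites$site_id), 0)
  # singly phosphorylated peptide gives protein + residue + position
  expect_true("P1_S473" %in% sites$site_id)
  # doubly phosphorylated peptide emits both sites with shared abundances
  expect_true(all(c("P3_S1134", "P3_T1137") %in% sites$site_id))
  expect_equal(sites$s1[sites$site_id == "P3_S1134"],
               sites$s1[sites$site_id == "P3_T1137"])
})

test_that("a singly phosphorylated peptide outranks a doubly phosphorylated one for a shared site", {
  pep <- tibble::tibble(
    peptide_id = c("a", "b"),
    backbone_sequence = c("AASAK", "AASATK"),
    protein_id = "P",
    positions = c("473", "473;475"),
    residues = c("S", "S;T"),
    n_phospho = c(1L, 2L),
    flr = 0.001, localization_score = 10,
    localized = TRUE,
    s1 = c(100, 7), s2 = c(110, 8)
  )
  sites <- peptides_to_sites(pep)
  expect_equal(sites$s1[sites$site_id == "P_S473"], 100)
})

test_that("replicate CVs follow the direct formula and skip degenerate rows", {
  tab <- tibble::tibble(site_id = c("A_S1", "B_S2"), protein_id = c("A", "B"),
                        localized = TRUE,
                        r1 = c(5, 1), r2 = c(5, 2), r3 = c(5, 3))
  ann <- tibble::tibble(sample_id = c("r1", "r2", "r3"), cell_line = "x",
                        genotype = "WT", treatment = "stimulated",
                        time_min = 10, replicate = 1:3)
  cvs <- compute_cv(tab, ann)
  expect_equal(cvs$cv[cvs$site_id == "A_S1"], 0)
  expect_equal(cvs$cv[cvs$site_id == "B_S2"], 50)
  expect_equal(median(cvs$cv), 25)
  # zero group mean is skipped and counted
  tab0 <- tab
  tab0[1, c("r1", "r2", "r3")] <- list(0, 0, 0)
  cvs0 <- compute_cv(tab0, ann)
  expect_equal(nrow(cvs0), 1)
  expect_equal(attr(cvs0, "n_skipped"), 1L)
})

test_that("normalization removes injected loading errors from synthetic data", {
  # loading factors 0.5-2x and 12% multiplicative noise: the post-normalized
  # CV must beat the raw light-channel CV
  set.seed(21)
  wins <- 0L
  for (i in 1:20) {
    n_pep <- 40; n_samp <- 6
    base <- rlnorm(n_pep, 15, 1)
    load <- runif(n_samp, 0.5, 2)
    noise <- matrix(rlnorm(n_pep * n_samp, 0, sqrt(log(1 + 0.12^2))),
                    n_pep)
    L <- outer(base, load) * noise
    H <- outer(base, rep(1, n_samp)) *
      matrix(rlnorm(n_pep * n_samp, 0, 0.03), n_pep)
    cv_row <- function(m) apply(m, 1, sd) / rowMeans(m) * 100
    raw_cv <- median(cv_row(L))
    norm_cv <- median(cv_row(gist_normalize(L, H)))
    if (norm_cv < raw_cv) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})
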