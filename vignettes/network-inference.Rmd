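---
title: "From phosphoproteomic time courses to a receptor signalling model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From phosphoproteomic time courses to a receptor signalling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

phosphonet turns a stimulated-versus-mock phosphoproteomic time course into
a Boolean model of how a receptor's signal reaches its regulated
phosphosites. This vignette explains the statistical model behind each stage,
the parameters that matter, the design choices that were genuinely open, and
what the synthetic benchmark does and does not demonstrate.

## The experimental design the package expects

The intended input is a spike-in (global internal standard, GIST) experiment:
cells carrying the receptor (and optionally a receptor-knockout derivative)
are stimulated or mock-treated, harvested at several time points (2, 10, 30,
60 and 90 min by default) in biological triplicate, and every light sample is
mixed with the same pooled heavy-labelled standard before digestion and
phosphopeptide enrichment. Quantification yields, per phosphopeptide and
sample, a light and a heavy MS1 intensity, plus a false-localisation-rate
(FLR) score for the phosphate position assignment. The package consumes these
tables; it does not process spectra or compute FLRs.

## Localization filtering and normalization

`filter_localization()` keeps peptides at FLR <= 1% as confidently localized.
Peptides above the threshold are positional isomers of each other; they are
grouped by backbone sequence and phosphate count and represented by the
member with the best localization score, flagged `localized = FALSE` but
retained — an ambiguous peptide can still witness regulation even when the
exact residue is uncertain.

`gist_normalize()` works in two steps on the light/heavy ratio matrix
r = L/H. The per-peptide ratio (step 2) cancels everything the two channels
share: digestion and enrichment losses, injection amount, instrument drift.
The per-sample median rescaling (step 1) removes what they do not share —
the error made when mixing the light sample with the standard. Two anchors
are available for step 1. The default scales every sample's median ratio to
1, which makes the output *exactly* invariant to per-sample multiplicative
errors in the light channel; this invariance is the reason the spike-in
exists, and the test suite asserts it to 1e-9. The alternative
(`anchor = "global_median"`) rescales to the global median of per-sample
medians, preserving the overall ratio scale at the cost of exact invariance
(the anchor is re-estimated from whatever data it is given). All downstream
statistics — CVs, fold changes, t-tests — are ratios within or between
samples and are identical under either anchor.

`peptides_to_sites()` expands each phosphate position into a site row
(`AKT1_S473` style identifiers: host protein, residue letter, 1-based
position). When several peptides cover one site, the row is taken from the
peptide with the fewest phosphates, ties broken by higher median abundance —
the least ambiguous quantification wins. This merge rule is a package choice;
nothing in the upstream data dictates it, and it is deliberately simple and
deterministic.

## Differential testing and target calling

For every time point, `differential_test()` compares stimulated against mock
with a two-sided unpaired Student's t-test (pooled variance; Welch is
available via `var_equal = FALSE`). With three replicates per group the
pooled test is the conventional choice: the Welch degrees-of-freedom
correction has almost no information to estimate unequal variances from.
P-values are Benjamini-Hochberg adjusted *within each time point* — each
time point is its own testing family, matching the per-time-point design.
Degenerate rows that triplicate MS data can produce are handled explicitly:
zero pooled variance with equal means gives p = 1, with unequal means the
smallest representable positive p (flagged by `t = +-Inf`).

A site is a *target* at a time point when q < 0.1 and its fold change
exceeds 1.5 up or down; the fold change is the ratio of group means. The
union of targets over time points drives both the clustering and the network
pruning. Each measurement also receives the model-selection score
s = log2(q / qThresh): zero at the threshold, increasingly negative for
confidently regulated sites, positive for unregulated ones.

## Kinase-activity inference

Two complementary routes point from regulated sites to the kinases that
wrote them.

**Substrate-set enrichment.** For each kinase with at least three measured
substrates, `normalized_enrichment()` computes a weighted running-sum
statistic down the log2-fold-change-ranked site list (hit steps proportional
to |metric|, miss steps uniform; the score is the signed maximal deviation,
in [-1, 1]). The null is substrate-set permutation: random site sets of equal
size, 10,000 draws by default. Sample permutation is not an option with
n = 3. The normalized enrichment value divides the observed score by the
mean same-sign permutation score, so positive values read as activation and
negative as inhibition; p-values use the add-one permutation estimator and
are BH-adjusted across kinases within a time point. The exact running-sum
weighting is a package choice — the statistic is fully specified here,
parameterized, and tested against step-by-step enumeration.

**Cluster enrichment.** Target-site time courses (replicate-averaged,
z-scored per site) are clustered with fuzzy c-means, six clusters by default,
fuzzifier m = 2. The fuzzifier and the argmax hard assignment used for
enrichment are package choices; m = 2 is the standard soft-clustering
default, and six clusters comfortably separate early-transient,
intermediate, sustained and down-regulated shapes in data of this design.
The c-means implementation is in-package so the objective can be traced: it
is asserted non-increasing at every iteration, centers initialize from k
distinct profiles drawn under the caller's seed, and convergence is declared
when the maximal center shift drops below 1e-8 (200 iteration cap). Each
(cluster, kinase) pair is then tested with a one-sided Fisher exact test of
substrate membership against the full identified-site background, BH over
all pairs.

## The prior-knowledge network

`load_pkn()` reads kinase->site edges and signed, directed protein-protein
edges from SIF-like TSVs into a typed multigraph; duplicate edges merge with
the union of their literature references. `apply_grouping()` collapses
isoforms and related G-protein subunits onto group nodes (site identifiers —
which key the measured data — are never renamed; their host annotation is).
`attach_site_coupling()` realizes the path convention kinase -> site -> host
protein, so a path can run through an intermediary kinase's regulatory site;
couplings default to activating, with a per-site override table for known
inhibitory sites, because public resources rarely annotate per-site
functional signs. `prune_to_reachable()` keeps exactly the edges with the
receptor behind them and a regulated site ahead of them — the search space
of all receptor-to-target paths.

Edge signs are carried through assembly, but the baseline model treats
propagation as activation-only Boolean logic. This is deliberate: the
observable is "site responds to stimulation", and with OR-logic propagation
a signed path analysis adds model complexity the data here cannot
discriminate. A signed mode remains a possible extension.

## Subnetwork selection as an integer linear program

The model-selection problem is: choose edges forming a receptor-rooted
subgraph that reaches the confidently regulated sites, wires through as few
unregulated measured sites as possible, and stays parsimonious. `build_ilp()`
encodes it with binary edge variables x_e, protein activities y_v, site
inclusions z_s and depth variables d_v:

* the receptor is active at depth 0;
* an edge can be selected only if its source is active (`x_e <= y_src`,
  `x_e <= z_src` for edges leaving a site);
* a non-receptor protein is active only via a selected incoming edge
  (`y_v <= sum of incoming x`), likewise site inclusion
  (`z_s <= sum of incoming x`);
* `d_tgt >= d_src + 1 - |V| (1 - x_e)` forbids directed cycles;
* edges carried over from earlier time points are fixed to 1.

The objective minimises `sum_s score(s) z_s + epsilon sum x_e` over
non-forced edges. Because scores are negative exactly for regulated sites,
the optimum wires them in; routing through an unregulated measured site
costs its positive score; epsilon (default 0.01) makes any edge that
explains nothing strictly unprofitable and breaks ties toward shorter
routes. `build_ilp()` refuses to run if epsilon is not strictly smaller than
the weakest regulated-site |score|, so parsimony can never override data.

`solve_ilp()` solves this exactly with a branch-and-bound written for this
structure: grounded-frontier branching makes every explored selection
feasible and acyclic by construction, and an admissible bound (committed
cost plus all still-reachable benefits) prunes the rest. Solutions are
provably optimal; a search-node budget plays the role of a time limit, and
exhausting it returns the best incumbent flagged non-optimal. Reporting is
deterministic — fixed variable order, first-found incumbent among exact
ties. Alternate optima do exist in real prior knowledge; the bootstrap
ensemble is the mechanism that surfaces them, which is why single-run edge
lists should not be over-read.

## Time evolution and the bootstrap consensus

`evolve_time_course()` solves the first time point unconstrained, then
forces each solution into the next time point's problem (cost-free), so the
network can only grow — new branches attach as later sites switch on, and
an edge that explained an early response is never retracted when the site
relaxes. Edge sets are therefore nested across time by construction, and
entry times are meaningful.

`bootstrap_ensemble()` repeats the whole evolution, by default 100 times,
each run downsampling the measured site identifiers with replacement and
deduplicating (about 63% unique sites per run). Edge weights count the runs
containing an edge at each time point; an edge's entry time is the first
time its weight reaches the consensus threshold (20 of 100 by default).
Carrying the threshold to other run counts proportionally (e.g. 10 of 50)
keeps the same 20% consensus meaning. `randomized_control()` re-keys the
regulated profiles onto identifiers drawn from the non-regulated pool,
producing the negative control: a network built from it should — and in the
test suite does — lose most of the recovered structure.

## The synthetic benchmark: what it shows and what it cannot

`generate_pkn()` builds a layered receptor-rooted graph (branch heads,
chained kinases linked through regulatory sites, terminal substrate sites,
plus a few random shortcut edges); `choose_truth()` designates some branches
as truly active and schedules every site they write, onset time increasing
with chain depth; `simulate_dataset()` draws lognormal baselines and applies
step-onset fold changes to wild-type stimulated samples only.

The generator's defaults are the study conditions the package is built
around: five time points (2-90 min), biological triplicates, mock and
stimulated arms in wild-type and receptor-knockout genotypes, fold change
2.5 for regulated sites with 20% down-regulated, 12% multiplicative
light-channel noise against a 3% technical heavy channel (so the
post-normalization replicate CV lands in the observed 10-15% range),
per-sample loading factors (sigma 0.3 on the log scale) shared between
channels, and standard-mixing errors (sigma 0.15) that only the median
normalization step can remove. These were chosen once to mirror the scale
and noise structure such experiments report, not tuned to any test outcome.

What the benchmark shows: the full chain — normalize, test, score, prune,
solve, bootstrap — recovers the true subnetwork with mean F1 of at least
0.8 at the 20% consensus threshold across generator seeds (asserted in the
suite at a reduced size: networks under 40 nodes, 50 bootstrap runs), calls
essentially no targets in knockout data, and keeps every run's edge sets
nested. What it cannot show: robustness to missing values beyond
missing-at-random, localization-error structure, transient (pulse-like)
kinetics — the truth uses step onsets so that the Boolean target is
unambiguous, although transient shapes appear in real clusters — or the
literature biases of real prior-knowledge resources, where well-studied
kinases attract edges regardless of context. Conclusions about real data
rest on the real controls (knockout, randomized identifiers), not on the
synthetic recovery number.

## Numerical notes

* All randomness flows through explicit seeds; every stochastic function
  restores the caller's RNG state. Derived seeds stay within 32-bit range.
* Zero q-values are clamped to the smallest positive double before the log
  score; zero-variance t-tests are handled as described above rather than
  erroring.
* Fuzzy c-means guards exact profile-center coincidences (membership
  collapses to the coincident centers).
* The test-suite problem sizes — networks of roughly 30-60 nodes, 20-50
  bootstrap runs, permutation counts of 50-400 in unit tests (10,000 is the
  analysis default) — were chosen as the smallest sizes at which every
  property under test is non-trivially exercised.

## Worked example

```{r example}
library(phosphonet)

params <- generator_params()
study <- synthetic_study(params, n_modules = 3, seed = 1)

sites <- study$data$peptides |>
  filter_localization() |>
  normalize_peptides() |>
  peptides_to_sites()

diff <- differential_test(sites, study$data$annotation)
network <- study$truth$pkn |>
  attach_site_coupling() |>
  prune_to_reachable(regulated_sites = target_union(diff))

ensemble <- bootstrap_ensemble(network,
                               diff[, c("site_id", "time_min", "score")],
                               n_runs = 100, weight_threshold = 20,
                               seed = 1)
glance(ensemble)
evaluate_recovery(ensemble, study$truth)
autoplot(ensemble)
```
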