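#' Read a phosphopeptide quantification table
#'
#' Expects a TSV with columns `peptide_id`, `backbone_sequence`, `protein_id`,
#' `positions` (semicolon-separated 1-based residue coordinates), `residues`
#' (semicolon-separated one-letter codes in S/T/Y), `n_phospho`, `flr`,
#' `localization_score`, followed by paired per-sample intensity columns
#' `light:<sample_id>` and `heavy:<sample_id>`.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per quantified phosphopeptide.
#' @export
read_peptide_table <- function(path) {
  tbl <- read_tsv_quiet(path)
  required <- c("peptide_id", "backbone_sequence", "protein_id", "positions",
                "residues", "n_phospho", "flr", "localization_score")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort_bad_arg(paste0("peptide table is missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  if (length(intensity_cols(tbl, "light")) == 0) {
    abort_bad_arg("peptide table has no 'light:<sample_id>' intensity columns")
  }
  tbl
}

#' Read a sample annotation table
#'
#' @param path TSV with columns `sample_id`, `cell_line`, `genotype` (WT/KO),
#'   `treatment` (stimulated/mock), `time_min`, `replicate`.
#' @return A tibble, one row per sample.
#' @export
read_sample_annotation <- function(path) {
  ann <- read_tsv_quiet(path)
  required <- c("sample_id", "cell_line", "genotype", "treatment",
                "time_min", "replicate")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    abort_bad_arg(paste0("annotation is missing columns: ",
                         paste(missing, collapse = ", ")))
  }
  key <- paste(ann$genotype, ann$treatment, ann$time_min, ann$replicate)
  if (anyDuplicated(key)) {
    abort_bad_arg("annotation has duplicated (genotype, treatment, time_min, replicate) combinations")
  }
  ann
}

#' Filter phosphopeptides by localization confidence and group positional isomers
#'
#' Peptides whose false localisation rate (FLR) is at or below `flr_threshold`
#' pass unchanged and are flagged `localized = TRUE`. Peptides above the
#' threshold are positional isomers without a confident localization; they are
#' grouped by (backbone sequence, number of phosphates) and each group is
#' collapsed to the single member with the highest localization score, whose
#' phosphate positions and intensities represent the group
#' (`localized = FALSE`). Ambiguous groups are retained rather than dropped so
#' that regulated but poorly localized peptides still inform downstream
#' analysis.
#'
#' @param peptides Tibble as returned by [read_peptide_table()].
#' @param flr_threshold FLR cutoff, default 0.01 (1%).
#' @return The filtered tibble with an added logical `localized` column.
#'   Groups in which every member lacks a localization score are rejected with
#'   a warning naming the group.
#' @export
filter_localization <- function(peptides, flr_threshold = 0.01) {
  if (!is.numeric(flr_threshold) || flr_threshold <= 0 || flr_threshold >= 1) {
    abort_bad_arg("flr_threshold must be in (0, 1)")
  }
  if (nrow(peptides) == 0) {
    return(mutate(peptides, localized = logical(0)))
  }
  if (any(peptides$flr < 0 | peptides$flr > 1, na.rm = TRUE)) {
    abort_bad_arg("flr values must lie in [0, 1]")
  }
  confident <- filter(peptides, .data$flr <= flr_threshold) |>
    mutate(localized = TRUE)
  ambiguous <- filter(peptides, .data$flr > flr_threshold)
  if (nrow(ambiguous) == 0) {
    return(confident)
  }
  groups <- split(ambiguous, paste(ambiguous$backbone_sequence,
                                   ambiguous$n_phospho, sep = "//"))
  rejected <- character(0)
  best <- lapply(groups, function(g) {
    if (all(is.na(g$localization_score))) {
      rejected <<- c(rejected, paste0(g$backbone_sequence[1], " (",
                                      g$n_phospho[1], " phosphates)"))
      return(NULL)
    }
    g[which.max(g$localization_score), , drop = FALSE]
  })
  if (length(rejected) > 0) {
    warning("rejected ", length(rejected),
            " ambiguous isomer group(s) without localization scores: ",
            paste(rejected, collapse = "; "), call. = FALSE)
  }
  collapsed <- bind_rows(best[!vapply(best, is.null, logical(1))])
  if (nrow(collapsed) > 0) collapsed$localized <- FALSE
  bind_rows(confident, collapsed)
}

#' Two-step spike-in (global internal standard) normalization
#'
#' Normalizes light MS1 intensities against a pooled heavy spike-in standard.
#' Step 1 corrects sample mixing errors: light/heavy ratios r = L/H are
#' median-normalized across samples by scaling each sample so its median ratio
#' equals a common anchor. Step 2 is peptide-specific: each light intensity is
#' divided by the corresponding heavy intensity, so the returned value is
#' `c_s * L_ps / H_ps` with `c_s = anchor / median_p(r_ps)`.
#'
#' With the default `anchor = "unit"` every sample's median ratio is scaled to
#' 1 and the output is exactly invariant to any per-sample multiplicative
#' factor applied to the light channel -- the property that makes the pooled
#' spike-in remove sample loading and mixing errors. `anchor =
#' "global_median"` instead rescales to the global median of per-sample
#' median ratios, which preserves the overall ratio scale but is only
#' invariant up to a common global factor (the anchor itself is re-estimated
#' from the perturbed data).
#'
#' @param light,heavy Aligned numeric peptide x sample matrices. Entries where
#'   the heavy intensity is zero or missing are returned as `NA` (flagged
#'   missing, never zero).
#' @param anchor `"unit"` (default) or `"global_median"`; see Details.
#' @return A matrix of normalized abundances with the same dimnames as
#'   `light`.
#' @export
gist_normalize <- function(light, heavy, anchor = c("unit", "global_median")) {
  anchor <- match.arg(anchor)
  light <- as.matrix(light)
  heavy <- as.matrix(heavy)
  if (!identical(dim(light), dim(heavy))) {
    abort_bad_arg("light and heavy matrices must have identical dimensions")
  }
  heavy[!is.na(heavy) & heavy <= 0] <- NA_real_
  ratio <- light / heavy
  sample_medians <- apply(ratio, 2, median, na.rm = TRUE)
  if (all(is.na(sample_medians))) {
    abort_bad_arg("no sample has any finite light/heavy ratio")
  }
  target <- switch(anchor,
                   unit = 1,
                   global_median = median(sample_medians, na.rm = TRUE))
  scale <- target / sample_medians
  out <- sweep(ratio, 2, scale, `*`)
  dimnames(out) <- dimnames(light)
  out
}

#' Normalize a phosphopeptide table against its heavy spike-in channel
#'
#' Convenience wrapper applying [gist_normalize()] to the `light:`/`heavy:`
#' column pairs of a peptide tibble. Intensity column pairs are replaced by
#' one normalized abundance column per sample, named by `sample_id`.
#'
#' @param peptides Tibble with paired `light:`/`heavy:` intensity columns.
#' @return Tibble with peptide metadata plus one normalized abundance column
#'   per sample.
#' @export
normalize_peptides <- function(peptides) {
  lcols <- intensity_cols(peptides, "light")
  hcols <- paste0("heavy:", sample_ids_from_cols(lcols))
  missing <- setdiff(hcols, names(peptides))
  if (length(missing) > 0) {
    abort_bad_arg(paste0("missing heavy channel columns: ",
                         paste(missing, collapse = ", ")))
  }
  meta <- peptides[, setdiff(names(peptides), c(lcols, paste0("heavy:", sample_ids_from_cols(lcols)))), drop = FALSE]
  norm <- gist_normalize(as.matrix(peptides[, lcols, drop = FALSE]),
                         as.matrix(peptides[, hcols, drop = FALSE]))
  colnames(norm) <- sample_ids_from_cols(lcols)
  bind_cols_strict(meta, as_tibble(norm))
}

bind_cols_strict <- function(a, b) {
  stopifnot(nrow(a) == nrow(b) || nrow(a) == 0)
  as_tibble(cbind(as.data.frame(a), as.data.frame(b)))
}

#' Convert a phosphopeptide table to a phosphosite table
#'
#' Every phosphate position on every peptide emits a candidate site row with
#' identifier `"<protein>_<residue letter><1-based position>"` (e.g.
#' `AKT1_S473`). Where several peptides report the same site, the
#' representative row is the peptide with the fewest phosphates, ties broken
#' by the highest median abundance, so the least ambiguous quantification
#' wins. Ambiguously localized peptide groups contribute through their most
#' likely positions and keep `localized = FALSE`.
#'
#' @param peptides Normalized peptide tibble as returned by
#'   [normalize_peptides()] (metadata columns plus one abundance column per
#'   sample; a `localized` column is honoured if present).
#' @return A site table tibble: `site_id`, `protein_id`, `localized`, then one
#'   abundance column per sample. Exactly one row per distinct `site_id`.
#' @export
peptides_to_sites <- function(peptides) {
  meta_cols <- c("peptide_id", "backbone_sequence", "protein_id", "positions",
                 "residues", "n_phospho", "flr", "localization_score",
                 "localized")
  sample_cols <- setdiff(names(peptides), meta_cols)
  if (nrow(peptides) == 0) {
    return(tibble(site_id = character(0), protein_id = character(0),
                  localized = logical(0)))
  }
  if (!"localized" %in% names(peptides)) peptides$localized <- TRUE
  rows <- purrr::pmap(
    list(seq_len(nrow(peptides))),
    function(i) {
      pos <- split_field(peptides$positions[i], as_int = TRUE)
      res <- split_field(peptides$residues[i])
      if (length(res) == 1 && length(pos) > 1) res <- rep(res, length(pos))
      tibble(
        site_id = paste0(peptides$protein_id[i], "_", res, pos),
        protein_id = peptides$protein_id[i],
        localized = peptides$localized[i],
        n_phospho = peptides$n_phospho[i],
        .row = i
      )
    }
  ) |> bind_rows()
  ab <- as.matrix(peptides[, sample_cols, drop = FALSE])
  med_ab <- apply(ab, 1, median, na.rm = TRUE)
  med_ab[is.na(med_ab)] <- -Inf
  rows$.med <- med_ab[rows$.row]
  picked <- rows |>
    group_by(.data$site_id) |>
    arrange(.data$n_phospho, dplyr::desc(.data$.med), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$site_id)
  out <- bind_cols_strict(
    picked[, c("site_id", "protein_id", "localized")],
    as_tibble(ab[picked$.row, , drop = FALSE])
  )
  out
}

#' Replicate coefficients of variation per site and replicate group
#'
#' Computes, for every site and every replicate group (unique combination of
#' the grouping columns in the annotation), the coefficient of variation
#' `CV = sd / mean * 100` of the normalized abundances across replicates.
#' Rows with fewer than two finite replicate values, or a zero group mean, are
#' skipped; the number skipped is attached as attribute `n_skipped`.
#'
#' @param site_table Site table from [peptides_to_sites()].
#' @param annotation Sample annotation tibble.
#' @param group_cols Annotation columns defining a replicate group.
#' @return Tibble `site_id`, grouping columns, `cv` (percent). The median CV
#'   over all rows and groups is `median(out$cv)`.
#' @export
compute_cv <- function(site_table, annotation,
                       group_cols = c("genotype", "treatment", "time_min")) {
  samp <- intersect(annotation$sample_id, names(site_table))
  if (length(samp) == 0) abort_bad_arg("no annotation sample_id matches a site-table column")
  ann <- filter(annotation, .data$sample_id %in% samp)
  groups <- split(ann$sample_id, ann[, group_cols, drop = FALSE], drop = TRUE)
  n_skipped <- 0L
  res <- purrr::imap(groups, function(ids, key) {
    m <- as.matrix(site_table[, ids, drop = FALSE])
    mu <- rowMeans(m, na.rm = TRUE)
    nfin <- rowSums(is.finite(m))
    s <- apply(m, 1, sd, na.rm = TRUE)
    ok <- nfin >= 2 & is.finite(mu) & mu != 0
    n_skipped <<- n_skipped + sum(!ok)
    grp <- ann[match(ids[1], ann$sample_id), group_cols, drop = FALSE]
    bind_cols_strict(
      tibble(site_id = site_table$site_id[ok], cv = 100 * s[ok] / mu[ok]),
      grp[rep(1, sum(ok)), , drop = FALSE]
    )
  }) |> bind_rows()
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Write a site table to TSV
#'
#' @param site_table Site table tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_site_table <- function(site_table, path) write_tsv_quiet(site_table, path)

#' Read a site table written by [write_site_table()]
#' @param path Path to the TSV.
#' @return A site table tibble.
#' @export
read_site_table <- function(path) read_tsv_quiet(path)
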