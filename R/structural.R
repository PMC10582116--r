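## Structural-metric comparisons: per-subject normalization to overall brain
## volume, then permutation t-tests with Bonferroni correction across the
## seven-comparison family.

structural_metric_cols <- c("brain_volume_mm3",
                            "thickness_mm_left", "thickness_mm_right",
                            "gm_volume_mm3_left", "gm_volume_mm3_right",
                            "surface_area_mm2_left", "surface_area_mm2_right")

#' Normalize a structural metric to overall brain volume
#'
#' Expresses a per-subject metric as a ratio to that subject's overall
#' brain volume, removing global brain-size differences before group
#' comparison.
#'
#' @param raw_value Positive raw metric (mm, mm^2 or mm^3).
#' @param brain_volume_mm3 Positive overall brain volume.
#'
#' @return The dimensioned ratio `raw_value / brain_volume_mm3`.
#' @export
normalize_metric <- function(raw_value, brain_volume_mm3) {
  if (any(raw_value <= 0) || any(brain_volume_mm3 <= 0)) {
    stop("metric and brain volume must be positive", call. = FALSE)
  }
  raw_value / brain_volume_mm3
}

#' Add volume-normalized ratio columns to a structural table
#'
#' @param records A structural table as produced by
#'   [make_structural_table()], with columns `subject_id`, `group`,
#'   `brain_volume_mm3` and per-hemisphere `thickness_mm_*`,
#'   `gm_volume_mm3_*`, `surface_area_mm2_*`.
#'
#' @return The table with `*_ratio_*` columns appended (each raw metric
#'   divided by the subject's brain volume).
#' @export
normalize_structural_table <- function(records) {
  missing <- setdiff(structural_metric_cols, names(records))
  if (length(missing)) {
    stop("structural table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (hemi in c("left", "right")) {
    records[[paste0("thickness_ratio_", hemi)]] <-
      normalize_metric(records[[paste0("thickness_mm_", hemi)]],
                       records$brain_volume_mm3)
    records[[paste0("gm_volume_ratio_", hemi)]] <-
      normalize_metric(records[[paste0("gm_volume_mm3_", hemi)]],
                       records$brain_volume_mm3)
    records[[paste0("surface_area_ratio_", hemi)]] <-
      normalize_metric(records[[paste0("surface_area_mm2_", hemi)]],
                       records$brain_volume_mm3)
  }
  records
}

#' Compare structural metrics between groups
#'
#' Runs the seven-comparison structural family: overall brain volume (raw)
#' plus the volume-normalized cortical thickness, grey-matter volume, and
#' surface area of each hemisphere, each compared between the groups with a
#' two-tailed [permutation_ttest()] and flagged at the Bonferroni-corrected
#' level `alpha / 7`. Positive t means group A's mean exceeds group B's.
#'
#' @param records_a,records_b Structural tables (one per group) with the
#'   raw metric columns; normalization is applied internally.
#' @param n_perm Permutations per test.
#' @param seed Base RNG seed (one derived seed per metric).
#' @param alpha Family-wise alpha for the Bonferroni flags.
#'
#' @return A data.frame with one row per comparison: `metric`, group means
#'   and SDs, `t`, `dof`, `p`, `cohens_d`, `significant`.
#' @export
compare_structural <- function(records_a, records_b, n_perm = 20000,
                               seed = 1L, alpha = 0.05) {
  if (nrow(records_a) < 2L || nrow(records_b) < 2L) {
    stop("each group needs at least 2 records", call. = FALSE)
  }
  na <- normalize_structural_table(records_a)
  nb <- normalize_structural_table(records_b)
  family <- c("brain_volume_mm3",
              "thickness_ratio_left", "thickness_ratio_right",
              "gm_volume_ratio_left", "gm_volume_ratio_right",
              "surface_area_ratio_left", "surface_area_ratio_right")
  rows <- lapply(seq_along(family), function(i) {
    metric <- family[i]
    va <- na[[metric]]; vb <- nb[[metric]]
    res <- permutation_ttest(va, vb, n_perm = n_perm,
                             seed = derive_seed(seed, i), two_tailed = TRUE)
    data.frame(metric = metric,
               mean_a = mean(va), sd_a = stats::sd(va),
               mean_b = mean(vb), sd_b = stats::sd(vb),
               t = res$t_statistic, dof = res$dof, p = res$p_value,
               cohens_d = res$cohens_d)
  })
  out <- do.call(rbind, rows)
  out$significant <- bonferroni_flags(out$p, m = length(family), alpha = alpha)
  out
}
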