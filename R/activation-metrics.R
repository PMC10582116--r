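#' Count significant voxels in a binary map
#'
#' @param mask A 3D logical or 0/1 array (e.g. from [threshold_map()]).
#'
#' @return The number of nonzero voxels.
#' @export
count_significant_voxels <- function(mask) {
  if (!all(mask %in% c(0, 1, TRUE, FALSE, NA))) {
    stop("`mask` must be binary", call. = FALSE)
  }
  sum(mask != 0, na.rm = TRUE)
}

#' Percent difference of activation extent between groups
#'
#' Difference of group B's voxel count relative to group A's, in percent:
#' `(count_b - count_a) / count_a * 100`. With females as group A and males
#' as group B this is the percent by which the male activation volume
#' exceeds the female one.
#'
#' @param count_a,count_b Non-negative voxel counts; `count_a` must be
#'   positive.
#'
#' @return The raw percent difference (round to 2 decimals for reporting).
#' @examples
#' round(percent_difference(14336, 34774), 2)  # 142.56
#' @export
percent_difference <- function(count_a, count_b) {
  stop_if_not_scalar_number(count_a, "count_a", nonnegative = TRUE)
  stop_if_not_scalar_number(count_b, "count_b", nonnegative = TRUE)
  if (count_a == 0) {
    stop("`count_a` is 0: percent difference is undefined", call. = FALSE)
  }
  (count_b - count_a) / count_a * 100
}

#' Encode an FWE-p map for spatial-similarity analysis
#'
#' Converts an FWE-corrected p map into the quantity that is spatially
#' correlated between groups: `1 - p` at voxels significant at `alpha`,
#' 0 elsewhere.
#'
#' @param fwe_p 3D array of FWE-corrected p-values.
#' @param alpha Significance threshold.
#'
#' @return A 3D array in [0, 1).
#' @export
similarity_input_map <- function(fwe_p, alpha = 0.05) {
  ifelse(fwe_p <= alpha, 1 - fwe_p, 0)
}

#' Spatial similarity of two statistic maps
#'
#' Pearson correlation (demeaned) over in-mask voxels. Non-finite sentinel
#' voxels in either map are excluded pairwise.
#'
#' @param map_a,map_b 3D arrays on a common grid.
#' @param mask 3D logical mask (default: whole grid).
#'
#' @return Pearson r between -1 and 1.
#' @export
spatial_similarity <- function(map_a, map_b, mask = NULL) {
  check_same_dim(map_a, map_b, "maps")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(map_a))
  va <- mask_values(map_a, mask)
  vb <- mask_values(map_b, mask)
  keep <- is.finite(va) & is.finite(vb)
  va <- va[keep]; vb <- vb[keep]
  if (length(va) < 2L) {
    stop("fewer than 2 usable in-mask voxels", call. = FALSE)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("correlation undefined: a map has zero variance in the mask",
         call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Matched-condition spatial similarity between two map sets
#'
#' Computes the full cross-correlation matrix between the two groups'
#' per-condition maps and returns its diagonal — the similarity of each
#' condition's map in group A with the same condition's map in group B.
#' Inter-condition correlations are discarded.
#'
#' @param maps_a,maps_b Named lists of 3D maps, one per condition, with
#'   identical condition names in the same order.
#' @inheritParams spatial_similarity
#'
#' @return A named numeric vector of matched-condition Pearson r values.
#' @export
similarity_by_condition <- function(maps_a, maps_b, mask = NULL) {
  if (!identical(names(maps_a), names(maps_b))) {
    stop("condition lists differ between groups", call. = FALSE)
  }
  cross <- outer(seq_along(maps_a), seq_along(maps_b),
                 Vectorize(function(i, j)
                   spatial_similarity(maps_a[[i]], maps_b[[j]], mask)))
  stats::setNames(diag(cross), names(maps_a))
}

#' Mean and sample standard deviation of per-condition values
#'
#' @param values At least two numeric values (e.g. per-condition percent
#'   differences or similarity coefficients).
#'
#' @return A list with `mean` and the (n-1)-denominator `sd`.
#' @export
summarize_across_conditions <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("at least 2 values are required for a sample SD", call. = FALSE)
  }
  list(mean = mean(values), sd = stats::sd(values))
}

#' Per-condition activation extent summary
#'
#' Assembles the activation-extent comparison: per condition, the two
#' groups' significant-voxel counts, the percent difference of group B
#' relative to group A, and (optionally) the matched-condition spatial
#' similarity; plus across-condition means and sample SDs.
#'
#' @param conditions Character vector of condition names.
#' @param voxels_a,voxels_b Per-condition significant-voxel counts.
#' @param similarity_r Optional per-condition Pearson r values.
#'
#' @return An object of class `activation_summary`: a list with the
#'   per-condition `table` (data.frame) and a `summary` list of
#'   across-condition means and SDs.
#' @export
activation_summary <- function(conditions, voxels_a, voxels_b,
                               similarity_r = NULL) {
  stopifnot(length(conditions) == length(voxels_a),
            length(voxels_a) == length(voxels_b))
  pct <- mapply(percent_difference, voxels_a, voxels_b)
  tab <- data.frame(condition = conditions, voxels_a = voxels_a,
                    voxels_b = voxels_b, percent_difference = pct)
  if (!is.null(similarity_r)) tab$similarity_r <- similarity_r
  summ <- list(voxels_a = summarize_across_conditions(voxels_a),
               voxels_b = summarize_across_conditions(voxels_b),
               percent_difference = summarize_across_conditions(pct))
  if (!is.null(similarity_r)) {
    summ$similarity_r <- summarize_across_conditions(similarity_r)
  }
  structure(list(table = tab, summary = summ), class = "activation_summary")
}
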