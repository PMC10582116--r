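## Between-subject and within-subject (between-run) voxel-wise correlation
## variability statistics, with permutation t-tests over pair-level values.

# Correlation matrix over in-mask voxels of a list of maps, with non-finite
# sentinel voxels excluded pairwise.
masked_cor_matrix <- function(maps, mask) {
  M <- vapply(maps, function(m) {
    check_same_dim(m, mask, "maps")
    mask_values(m, mask)
  }, numeric(sum(mask)))
  M[!is.finite(M)] <- NA
  suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
}

upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' Between-subject pairwise map correlations
#'
#' Pearson correlation over in-mask voxels of every unordered pair of
#' subjects' t-statistic maps. The distribution of these pair-level r values
#' indexes group consistency: a higher mean means lower between-subject
#' variability. Pairs whose correlation is undefined (a zero-variance map)
#' are dropped with a warning.
#'
#' @param tmaps List of per-subject 3D t maps on a common grid (>= 2
#'   subjects).
#' @param mask 3D logical mask (default: whole grid).
#' @param group,condition Optional labels carried through to the result.
#'
#' @return An object of class `pairwise_corr_set`: `values` (one r per
#'   unordered pair, length `n*(n-1)/2` before any exclusions), `pairs`
#'   (subject index pairs), `n_subjects`, `group`, `condition`.
#' @export
pairwise_between_subject <- function(tmaps, mask = NULL, group = NA_character_,
                                     condition = NA_character_) {
  if (length(tmaps) < 2L) stop("at least 2 subjects are required",
                               call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(tmaps[[1L]]))
  cm <- masked_cor_matrix(tmaps, mask)
  pairs <- upper_pairs(length(tmaps))
  values <- cm[pairs]
  if (anyNA(values)) {
    warning(sum(is.na(values)),
            " pair(s) with undefined correlation excluded", call. = FALSE)
    keep <- !is.na(values)
    pairs <- pairs[keep, , drop = FALSE]
    values <- values[keep]
  }
  structure(list(values = values, pairs = pairs, n_subjects = length(tmaps),
                 group = group, condition = condition),
            class = "pairwise_corr_set")
}

#' Within-subject between-run map consistency
#'
#' Mean Pearson correlation over all unordered pairs of one subject's
#' run-level t maps (15 comparisons for 6 runs).
#'
#' @param run_tmaps List of one subject's per-run 3D t maps (>= 2 runs).
#' @inheritParams pairwise_between_subject
#'
#' @return A list with `mean_r`, the individual pair `values`, and
#'   `n_comparisons` (`choose(n_runs, 2)` before exclusions).
#' @export
within_subject_between_run <- function(run_tmaps, mask = NULL) {
  if (length(run_tmaps) < 2L) stop("at least 2 runs are required",
                                   call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(run_tmaps[[1L]]))
  cm <- masked_cor_matrix(run_tmaps, mask)
  values <- cm[upper.tri(cm)]
  if (anyNA(values)) {
    warning(sum(is.na(values)),
            " run pair(s) with undefined correlation excluded", call. = FALSE)
    values <- values[!is.na(values)]
  }
  list(mean_r = mean(values), values = values,
       n_comparisons = choose(length(run_tmaps), 2))
}

#' Pooled-sample Cohen's d from group summaries
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled SD using (n-1) weights.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics.
#' @return Cohen's d.
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  (mean_a - mean_b) / sp
}

#' Two-sample permutation t-test
#'
#' Pooled-variance Student t-statistic, with the null distribution generated
#' by randomly relabelling the observations between groups. The label space
#' is enumerated exhaustively when it has at most `n_perm` elements;
#' otherwise splits are sampled and the add-one convention is used
#' (`p >= 1/(n_perm + 1)`). Positive t means group A's mean exceeds group
#' B's.
#'
#' @param values_a,values_b Numeric observations (>= 2 per group).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param two_tailed If `TRUE` (default) the p-value counts permuted
#'   \eqn{|t| \ge |t_{obs}|}; otherwise it is one-tailed for group A > B.
#'
#' @return An object of class `perm_test_result`: `t_statistic`, `dof`
#'   (`n_a + n_b - 2`), `p_value`, `cohens_d`, `n_perm`, `seed`, `method`,
#'   and `significant_bonferroni` (set by [bonferroni_flags()], `NA` here).
#' @export
permutation_ttest <- function(values_a, values_b, n_perm = 20000, seed = 1L,
                              two_tailed = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  n_a <- length(values_a); n_b <- length(values_b); n <- n_a + n_b
  x <- c(values_a, values_b)
  S <- sum(x); Q <- sum(x^2)
  t_for <- function(idx_a) {
    sa <- sum(x[idx_a])
    ma <- sa / n_a
    mb <- (S - sa) / n_b
    ssp <- max(Q - n_a * ma^2 - n_b * mb^2, 0)
    se <- sqrt(ssp / (n - 2) * (1 / n_a + 1 / n_b))
    d <- ma - mb
    if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
  }
  t_obs <- t_for(seq_len(n_a))
  score <- function(t) if (two_tailed) abs(t) else t
  exhaustive <- choose(n, n_a) <= n_perm
  if (exhaustive) {
    splits <- utils::combn(n, n_a)
    t_null <- apply(splits, 2, t_for)
    n_used <- ncol(splits)
    p <- sum(score(t_null) >= score(t_obs)) / n_used
  } else {
    t_null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      t_for(sample.int(n, n_a)), numeric(1)))
    n_used <- n_perm
    p <- (1 + sum(score(t_null) >= score(t_obs))) / (n_used + 1)
  }
  d <- cohens_d(mean(values_a), stats::sd(values_a), n_a,
                mean(values_b), stats::sd(values_b), n_b)
  structure(list(t_statistic = t_obs, dof = n - 2L, p_value = p,
                 cohens_d = d, n_perm = n_used, seed = seed,
                 method = if (exhaustive) "exhaustive" else "sampled",
                 two_tailed = two_tailed, n_a = n_a, n_b = n_b,
                 significant_bonferroni = NA),
            class = "perm_test_result")
}

#' Bonferroni significance flags
#'
#' Flags each p-value as significant when `p <= alpha / m`; the exact ratio
#' is used, not a rounded threshold.
#'
#' @param p_values Numeric p-values.
#' @param m Number of comparisons in the family (>= 1).
#' @param alpha Family-wise alpha.
#'
#' @return A logical vector.
#' @examples
#' bonferroni_flags(c(0.001, 0.005), m = 12)  # TRUE FALSE
#' @export
bonferroni_flags <- function(p_values, m, alpha = 0.05) {
  stop_if_not_scalar_number(m, "m", positive = TRUE)
  p_values <= alpha / m
}
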