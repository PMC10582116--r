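## Group-level nonparametric inference: max-statistic permutation testing of
## TFCE-enhanced t maps, with family-wise error corrected p-values.

# Large finite stand-in for infinite t sentinels so TFCE stays numeric.
T_SENTINEL <- 1e10

clamp_sentinels <- function(t_values) {
  t_values[is.nan(t_values)] <- 0
  t_values[t_values == Inf] <- T_SENTINEL
  t_values[t_values == -Inf] <- -T_SENTINEL
  t_values
}

# Stack a list of 3D maps into an n x V matrix of in-mask values.
stack_maps <- function(maps, mask) {
  v <- vapply(maps, function(m) {
    check_same_dim(m, mask, "cope maps")
    mask_values(m, mask)
  }, numeric(sum(mask)))
  t(matrix(v, ncol = length(maps)))
}

# One-sample t for each column of X (n x V) under sign vector s.
one_sample_t_signed <- function(X, col_ss, s) {
  n <- nrow(X)
  m <- as.vector(s %*% X) / n
  v <- (col_ss - n * m^2) / (n - 1)
  v[v < 0] <- 0
  ifelse(v > 0, m / sqrt(v / n), ifelse(m == 0, 0, sign(m) * Inf))
}

# Pooled-variance two-sample t from group-A index set, using the invariant
# total sums S and sums of squares Q of the pooled stack.
two_sample_t_indexed <- function(all_X, S, Q, idx_a, n_a, n_b, sign_dir) {
  sa <- if (n_a == 1L) all_X[idx_a, ] else colSums(all_X[idx_a, , drop = FALSE])
  ma <- sa / n_a
  mb <- (S - sa) / n_b
  ss_pooled <- Q - n_a * ma^2 - n_b * mb^2
  ss_pooled[ss_pooled < 0] <- 0
  sp2 <- ss_pooled / (n_a + n_b - 2)
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  diff <- sign_dir * (ma - mb)
  ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
}

max_tfce <- function(t_values, mask, params) {
  tf <- tfce_positive(embed_in_mask(clamp_sentinels(t_values), mask),
                      mask, params)
  max(tf[mask])
}

# FWE-corrected p per voxel from the max-statistic null. `exhaustive` nulls
# already contain the identity permutation, so no add-one is applied there.
fwe_from_null <- function(obs_tfce_values, null_max, exhaustive) {
  sn <- sort(null_max)
  n <- length(sn)
  cnt_ge <- n - findInterval(obs_tfce_values, sn, left.open = TRUE)
  if (exhaustive) cnt_ge / n else (1 + cnt_ge) / (n + 1)
}

all_sign_vectors <- function(n) {
  stopifnot(n <= 20)
  m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(m) <- NULL
  m
}

new_group_perm_result <- function(obs_t, obs_tfce, null_max, fwe_p, mask,
                                  n_perm, seed, params, method, design,
                                  direction = NULL) {
  structure(list(observed_stat = obs_t, observed_tfce = obs_tfce,
                 null_max = null_max, fwe_p = fwe_p, mask = mask,
                 n_perm = n_perm, seed = seed, params = params,
                 method = method, design = design, direction = direction),
            class = "group_perm_result")
}

#' One-sample group inference by sign-flip permutation
#'
#' Tests, voxel-wise, whether the group-mean effect is positive. The
#' observed one-sample t map is TFCE-enhanced (positive part, one-tailed)
#' and compared against the permutation distribution of the image-wide
#' maximum TFCE score obtained by randomly flipping the sign of each
#' subject's effect map, giving family-wise error corrected p-values.
#' When the sign-flip space has at most `n_perm` elements (i.e.
#' \eqn{2^n \le n_perm}) it is enumerated exhaustively; otherwise flips are
#' sampled and the add-one p-value convention is used, so
#' `fwe_p >= 1/(n_perm + 1)`.
#'
#' @param copes List of per-subject 3D effect (cope) maps on a common grid.
#' @param mask 3D logical analysis mask (default: whole grid).
#' @param params [tfce_params()].
#' @param n_perm Number of permutations.
#' @param seed RNG seed; results are reproducible bit-exactly for a fixed
#'   seed and permutation count.
#'
#' @return A `group_perm_result`: `observed_stat` (t map), `observed_tfce`,
#'   `null_max` (the max-TFCE null), `fwe_p` (3D map, 1 outside the mask),
#'   plus bookkeeping (`n_perm`, `seed`, `method`).
#' @export
permutation_one_sample <- function(copes, mask = NULL, params = tfce_params(),
                                   n_perm = 5000, seed = 1L) {
  if (length(copes) < 2L) stop("at least 2 subjects are required",
                               call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(copes[[1L]]))
  X <- stack_maps(copes, mask)
  n <- nrow(X)
  col_ss <- colSums(X^2)
  t_obs <- one_sample_t_signed(X, col_ss, rep(1, n))
  tfce_obs <- tfce_positive(embed_in_mask(clamp_sentinels(t_obs), mask),
                            mask, params)
  exhaustive <- n <= 20 && 2^n <= n_perm
  if (exhaustive) {
    signs <- all_sign_vectors(n)
    null_max <- apply(signs, 1, function(s)
      max_tfce(one_sample_t_signed(X, col_ss, s), mask, params))
    n_used <- nrow(signs)
  } else {
    null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      max_tfce(one_sample_t_signed(X, col_ss, s), mask, params)
    }, numeric(1)))
    n_used <- n_perm
  }
  p_vals <- fwe_from_null(tfce_obs[mask], null_max, exhaustive)
  fwe_p <- embed_in_mask(p_vals, mask, fill = 1)
  new_group_perm_result(embed_in_mask(t_obs, mask), tfce_obs, null_max,
                        fwe_p, mask, n_used, seed, params,
                        if (exhaustive) "exhaustive" else "sampled",
                        design = "one-sample")
}

#' Two-sample group inference by label permutation
#'
#' One-tailed pooled-variance two-sample t-test per voxel in the stated
#' direction, TFCE-enhanced (positive part) and corrected for family-wise
#' error via the permutation distribution of the maximum TFCE score under
#' random relabelling of group membership. Group-size-preserving label
#' splits are enumerated exhaustively when there are at most `n_perm` of
#' them.
#'
#' @param copes_a,copes_b Lists of per-subject 3D effect maps (each group
#'   at least 2 subjects) on a common grid.
#' @param direction `"a_gt_b"` tests group A > group B; `"b_gt_a"` the
#'   reverse.
#' @inheritParams permutation_one_sample
#'
#' @return A `group_perm_result` (see [permutation_one_sample()]) with the
#'   tested `direction` recorded.
#' @export
permutation_two_sample <- function(copes_a, copes_b, mask = NULL,
                                   params = tfce_params(), n_perm = 5000,
                                   seed = 1L,
                                   direction = c("a_gt_b", "b_gt_a")) {
  direction <- match.arg(direction)
  if (length(copes_a) < 2L || length(copes_b) < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(copes_a[[1L]]))
  Xa <- stack_maps(copes_a, mask)
  Xb <- stack_maps(copes_b, mask)
  all_X <- rbind(Xa, Xb)
  n_a <- nrow(Xa); n_b <- nrow(Xb); n <- n_a + n_b
  S <- colSums(all_X)
  Q <- colSums(all_X^2)
  sign_dir <- if (direction == "a_gt_b") 1 else -1
  t_obs <- two_sample_t_indexed(all_X, S, Q, seq_len(n_a), n_a, n_b, sign_dir)
  tfce_obs <- tfce_positive(embed_in_mask(clamp_sentinels(t_obs), mask),
                            mask, params)
  exhaustive <- choose(n, n_a) <= n_perm
  if (exhaustive) {
    splits <- utils::combn(n, n_a)
    null_max <- apply(splits, 2, function(idx)
      max_tfce(two_sample_t_indexed(all_X, S, Q, idx, n_a, n_b, sign_dir),
               mask, params))
    n_used <- ncol(splits)
  } else {
    null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n_a)
      max_tfce(two_sample_t_indexed(all_X, S, Q, idx, n_a, n_b, sign_dir),
               mask, params)
    }, numeric(1)))
    n_used <- n_perm
  }
  p_vals <- fwe_from_null(tfce_obs[mask], null_max, exhaustive)
  fwe_p <- embed_in_mask(p_vals, mask, fill = 1)
  new_group_perm_result(embed_in_mask(t_obs, mask), tfce_obs, null_max,
                        fwe_p, mask, n_used, seed, params,
                        if (exhaustive) "exhaustive" else "sampled",
                        design = "two-sample", direction = direction)
}

#' Threshold an FWE-corrected result at a significance level
#'
#' @param result A `group_perm_result`.
#' @param alpha Family-wise significance level in (0, 1]; `alpha = 1`
#'   returns the full in-mask set since permutation p-values never exceed 1.
#'
#' @return A 3D logical array: `TRUE` where `fwe_p <= alpha` inside the mask.
#' @export
threshold_map <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "group_perm_result"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  (result$fwe_p <= alpha) & result$mask
}
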