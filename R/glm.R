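#' Fit the first-level voxel-wise GLM for one run
#'
#' Ordinary least squares per in-mask voxel. For each condition the contrast
#' selects the task regressor only (the temporal derivative is a nuisance):
#' the cope is the task beta, its variance (varcope) is the residual variance
#' times the corresponding diagonal element of \eqn{(X'X)^{-1}}, and
#' \eqn{t = cope/\sqrt{varcope}}. Voxels with zero residual variance get
#' `t = 0` when the cope is 0 and an infinite sentinel otherwise; sentinels
#' are excluded from downstream correlations.
#'
#' @param run A `bold_run` (see [simulate_run()]) or any list with a 4D
#'   `data` array, a 3D logical `mask`, and `tr_s`.
#' @param design A [build_design_matrix()] result whose row count matches the
#'   run length.
#'
#' @return An object of class `first_level_result`: per-condition lists
#'   `cope`, `varcope`, `tmap` of 3D arrays (0 outside the mask), the
#'   residual degrees of freedom `dof`, `conditions`, and `mask`.
#' @export
fit_glm <- function(run, design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  d <- dim(run$data)
  if (length(d) != 4L) stop("`run$data` must be a 4D array", call. = FALSE)
  if (d[4] != nrow(X)) {
    stop("run has ", d[4], " volumes but the design has ", nrow(X), " rows",
         call. = FALSE)
  }
  mask <- run$mask
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  flat <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
  Y <- t(flat[as.vector(mask), , drop = FALSE])        # time x voxel
  rank <- qr(X)$rank
  if (rank < ncol(X)) stop("degenerate design matrix", call. = FALSE)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- xtx_inv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  dof <- nrow(X) - rank
  # numerically perfect fits: snap RSS (and the tiny copes of constant /
  # all-zero voxels) to exact zero so the degenerate t conventions apply
  denom <- colSums(Y^2)
  rss <- colSums(resid^2)
  rss[rss <= 1e-20 * denom] <- 0
  sigma2 <- rss / dof
  cope_tol <- 1e-8 * sqrt(denom / nrow(X))
  conds <- design$conditions
  cope <- varcope <- tmap <- stats::setNames(vector("list", length(conds)),
                                             conds)
  for (j in seq_along(conds)) {
    cj <- B[design$task_cols[j], ]
    cj[abs(cj) <= cope_tol] <- 0
    vj <- sigma2 * xtx_inv[design$task_cols[j], design$task_cols[j]]
    tj <- ifelse(vj > 0, cj / sqrt(vj), ifelse(cj == 0, 0, sign(cj) * Inf))
    cope[[j]] <- embed_in_mask(cj, mask)
    varcope[[j]] <- embed_in_mask(vj, mask)
    tmap[[j]] <- embed_in_mask(tj, mask)
  }
  structure(list(cope = cope, varcope = varcope, tmap = tmap, dof = dof,
                 conditions = conds, mask = mask),
            class = "first_level_result")
}

#' Fixed-effects combination of run-level estimates
#'
#' Averages a subject's run-level effect estimates into a single activation
#' map per condition: the combined cope is the arithmetic mean of the run
#' copes, its variance follows by propagation as
#' \eqn{\sum_k varcope_k / K^2}, and the combined t is their ratio's
#' square root form. Only within-run variance is propagated (fixed effects);
#' degrees of freedom add across runs.
#'
#' @param run_results A list of two or more [fit_glm()] results on the same
#'   grid with the same conditions.
#'
#' @return An object of class `subject_level_result` with per-condition
#'   `cope`, `varcope`, `tmap`, the summed `dof`, `n_runs_combined`,
#'   `conditions`, and `mask`.
#' @export
fixed_effects_combine <- function(run_results) {
  if (!is.list(run_results) || length(run_results) < 2L) {
    stop("at least two run results are required", call. = FALSE)
  }
  ref <- run_results[[1L]]
  for (r in run_results[-1L]) {
    if (!identical(r$conditions, ref$conditions)) {
      stop("runs disagree on conditions", call. = FALSE)
    }
    check_same_dim(r$mask, ref$mask, "run masks")
  }
  K <- length(run_results)
  conds <- ref$conditions
  cope <- varcope <- tmap <- stats::setNames(vector("list", length(conds)),
                                             conds)
  for (cn in conds) {
    cs <- Reduce(`+`, lapply(run_results, function(r) r$cope[[cn]]))
    vs <- Reduce(`+`, lapply(run_results, function(r) r$varcope[[cn]]))
    cmap <- cs / K
    vmap <- vs / K^2
    tm <- ifelse(vmap > 0, cmap / sqrt(vmap),
                 ifelse(cmap == 0, 0, sign(cmap) * Inf))
    cope[[cn]] <- cmap
    varcope[[cn]] <- vmap
    tmap[[cn]] <- tm
  }
  structure(list(cope = cope, varcope = varcope, tmap = tmap,
                 dof = sum(vapply(run_results, `[[`, numeric(1), "dof")),
                 n_runs_combined = K, conditions = conds, mask = ref$mask),
            class = "subject_level_result")
}
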