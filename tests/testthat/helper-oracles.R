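## Independent brute-force oracles used across tests. These deliberately
## re-derive quantities with naive algorithms, separate from the package's
## implementation paths.

# Connected-component labels of a logical 3D array via BFS flood fill.
label_components_bfs <- function(supra, connectivity = 26) {
  dims <- dim(supra)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, dims)
  next_label <- 0L
  idx_all <- which(supra)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      z <- (cur - 1L) %/% (dims[1] * dims[2])
      y <- ((cur - 1L) %/% dims[1]) %% dims[2]
      x <- (cur - 1L) %% dims[1]
      for (k in seq_len(nrow(offs))) {
        xx <- x + offs[k, 1]; yy <- y + offs[k, 2]; zz <- z + offs[k, 3]
        if (xx < 0 || xx >= dims[1] || yy < 0 || yy >= dims[2] ||
              zz < 0 || zz >= dims[3]) next
        j <- xx + 1L + dims[1] * (yy + dims[2] * zz)
        if (supra[j] && labels[j] == 0L) {
          labels[j] <- next_label
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# TFCE by independent per-threshold component relabelling.
tfce_bruteforce <- function(stat, mask = NULL, E = 0.5, H = 2,
                            n_steps = 100, connectivity = 26) {
  if (is.null(mask)) mask <- array(TRUE, dim(stat))
  out <- array(0, dim(stat))
  h_max <- max(c(stat[mask & stat > 0], 0))
  if (h_max <= 0) return(out)
  dh <- h_max / n_steps
  for (k in seq_len(n_steps)) {
    h <- if (k == n_steps) h_max else k * dh   # top threshold exactly h_max
    supra <- (stat >= h) & mask
    labels <- label_components_bfs(supra, connectivity)
    if (!any(supra)) next
    sizes <- tabulate(labels[supra])
    out[supra] <- out[supra] + sizes[labels[supra]]^E * h^H * dh
  }
  out
}

# Plain-R one-sample t over the columns of an n x V matrix.
one_sample_t_plain <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * Inf))
}

# A small 3D map with a smooth blob at `center`.
blob_map <- function(dims, center, height = 3, width = 1.5) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(height * exp(-d2 / (2 * width^2)), dims)
}

# Fit all first-level runs for every subject of a cohort and return
# subject-level results plus per-run t-maps (conditions as in the spec).
fit_cohort <- function(spec, hrf = hrf_params()) {
  truth <- make_cohort(spec)
  n_t <- motormap:::run_n_timepoints(spec)
  events <- lapply(seq_len(spec$n_runs), function(r)
    make_block_design(spec, r))
  designs <- lapply(events, build_design_matrix, n_timepoints = n_t,
                    tr_s = spec$tr_s, hrf = hrf,
                    conditions = spec$conditions)
  ids <- unique(truth$subject_id)
  subj <- list()
  runs <- list()
  for (si in seq_along(ids)) {
    fl <- lapply(seq_len(spec$n_runs), function(r) {
      run <- simulate_run(truth, events[[r]], spec,
                          seed = motormap:::derive_seed(spec$seed,
                                                        si * 100 + r),
                          subject_id = ids[si], run_index = r, hrf = hrf)
      fit_glm(run, designs[[r]])
    })
    subj[[ids[si]]] <- if (spec$n_runs >= 2) fixed_effects_combine(fl)
                       else fl[[1L]]
    runs[[ids[si]]] <- lapply(fl, `[[`, "tmap")
  }
  groups <- vapply(ids, function(s) truth$group[truth$subject_id == s][1L],
                   character(1))
  list(truth = truth, subjects = subj, run_tmaps = runs, groups = groups,
       ids = ids)
}
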