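#' The twelve movement conditions of the motor-mapping protocol
#'
#' @return Character vector of condition names in protocol order.
#' @export
motor_conditions <- function() {
  c("eyes", "jaw", "lips", "tongue", "upper_arms", "forearms",
    "wrists", "fingers", "left_leg", "right_leg", "ankles", "toes")
}

# Evenly spread condition centers over an interior lattice of the grid.
default_footprint_centers <- function(grid_shape, n_conditions,
                                      margin = NULL) {
  if (is.null(margin)) margin <- round(min(grid_shape) / 4)
  levels_per_axis <- ceiling(n_conditions^(1 / 3))
  ax <- lapply(grid_shape, function(n)
    round(seq(margin, n - 1 - margin, length.out = max(levels_per_axis, 2))))
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(g) <- NULL
  g[seq_len(n_conditions), , drop = FALSE]
}

recycle_group_param <- function(x, k, name) {
  if (is.list(x)) {
    a <- x$a; b <- x$b
  } else {
    a <- b <- x
  }
  for (v in list(a, b)) {
    if (!is.numeric(v) || !length(v) %in% c(1L, k)) {
      stop(sprintf("`%s` must be a scalar or one value per condition (per group)",
                   name), call. = FALSE)
    }
  }
  list(a = rep_len(a, k), b = rep_len(b, k))
}

#' Specification of a synthetic two-group motor-mapping cohort
#'
#' Full generative description of a synthetic cohort: two groups of subjects
#' who each perform a block-design motor protocol over several runs on a
#' shared voxel grid. Each condition activates a spherical footprint whose
#' center is jittered per subject (between-subject spatial variability) and
#' whose radius and amplitude may differ between groups (activation extent
#' and strength). The defaults mirror the acquisition this generator
#' emulates: 12 movement conditions in 16-s blocks performed twice per run,
#' 6 runs, TR of 2 s, 2-mm voxels, and groups of 33 and 28 subjects.
#'
#' @param n_group_a,n_group_b Subjects per group (group A plays the role of
#'   females, group B of males in the emulated study).
#' @param grid_shape Three positive integers, the voxel grid (default
#'   100 x 100 x 72, a 200 x 200 x 144 mm field of view at 2 mm).
#' @param voxel_size_mm Isotropic voxel edge, mm.
#' @param tr_s Repetition time, seconds.
#' @param n_runs Runs per subject.
#' @param conditions Condition names (default [motor_conditions()]).
#' @param block_duration_s Task block duration, seconds.
#' @param blocks_per_run_per_condition Blocks of each condition per run.
#' @param rest_s Rest gap separating blocks (and before the first), seconds.
#' @param footprint_centers Per-condition 3D voxel coordinates (0-based) of
#'   the group-truth activation centers; rows = conditions.
#' @param footprint_radius_vox Footprint radius in voxels; scalar, per-group
#'   `list(a=, b=)`, or per-condition vectors. Controls activation extent.
#' @param amplitude Peak percent signal change of the activation; scalar or
#'   per-group list.
#' @param center_jitter_sd_vox Per-axis SD (voxels) of the Gaussian
#'   between-subject displacement of each footprint center; scalar or
#'   per-group list. Controls between-subject spatial variability.
#' @param noise_sd SD of the additive white Gaussian noise, in scanner
#'   units (the baseline is `baseline` units).
#' @param baseline Baseline signal intensity.
#' @param run_length_s Optional explicit run length; defaults to the exact
#'   span of the scheduled blocks and rests. An explicit value too short to
#'   host all blocks is a scheduling error.
#' @param seed Integer seed; all cohort randomness derives from it.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [demo_cohort_spec()] for a minutes-scale configuration,
#'   [make_cohort()], [make_block_design()], [simulate_run()].
#' @export
cohort_spec <- function(n_group_a = 33, n_group_b = 28,
                        grid_shape = c(100, 100, 72), voxel_size_mm = 2,
                        tr_s = 2, n_runs = 6,
                        conditions = motor_conditions(),
                        block_duration_s = 16,
                        blocks_per_run_per_condition = 2, rest_s = 2,
                        footprint_centers = NULL,
                        footprint_radius_vox = list(a = 4, b = 6),
                        amplitude = 1,
                        center_jitter_sd_vox = list(a = 0.5, b = 1.5),
                        noise_sd = 1, baseline = 100, run_length_s = NULL,
                        seed = 42L) {
  stop_if_not_scalar_number(n_group_a, "n_group_a", positive = TRUE)
  stop_if_not_scalar_number(n_group_b, "n_group_b", positive = TRUE)
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    stop("`grid_shape` must be three positive integers", call. = FALSE)
  }
  stop_if_not_scalar_number(voxel_size_mm, "voxel_size_mm", positive = TRUE)
  stop_if_not_scalar_number(tr_s, "tr_s", positive = TRUE)
  stop_if_not_scalar_number(n_runs, "n_runs", positive = TRUE)
  stop_if_not_scalar_number(block_duration_s, "block_duration_s",
                            positive = TRUE)
  stop_if_not_scalar_number(blocks_per_run_per_condition,
                            "blocks_per_run_per_condition", positive = TRUE)
  stop_if_not_scalar_number(rest_s, "rest_s", nonnegative = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  stop_if_not_scalar_number(baseline, "baseline")
  k <- length(conditions)
  if (k < 1L) stop("at least one condition is required", call. = FALSE)
  if (is.null(footprint_centers)) {
    footprint_centers <- default_footprint_centers(grid_shape, k)
  }
  footprint_centers <- as.matrix(footprint_centers)
  if (nrow(footprint_centers) != k || ncol(footprint_centers) != 3L) {
    stop("`footprint_centers` must be one 3D coordinate per condition",
         call. = FALSE)
  }
  for (ax in 1:3) {
    if (any(footprint_centers[, ax] < 0 |
              footprint_centers[, ax] > grid_shape[ax] - 1)) {
      stop("`footprint_centers` must lie inside the grid", call. = FALSE)
    }
  }
  radius <- recycle_group_param(footprint_radius_vox, k,
                                "footprint_radius_vox")
  if (any(unlist(radius) <= 0)) {
    stop("`footprint_radius_vox` must be positive", call. = FALSE)
  }
  if (any(unlist(radius) >= min(grid_shape) / 2)) {
    stop("`footprint_radius_vox` must be below min(grid_shape)/2",
         call. = FALSE)
  }
  amp <- recycle_group_param(amplitude, k, "amplitude")
  if (any(unlist(amp) < 0)) {
    stop("`amplitude` must be non-negative", call. = FALSE)
  }
  jitter <- recycle_group_param(center_jitter_sd_vox, k,
                                "center_jitter_sd_vox")
  if (any(unlist(jitter) < 0)) {
    stop("`center_jitter_sd_vox` must be non-negative", call. = FALSE)
  }
  spec <- structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    tr_s = tr_s, n_runs = as.integer(n_runs), conditions = conditions,
    block_duration_s = block_duration_s,
    blocks_per_run_per_condition = as.integer(blocks_per_run_per_condition),
    rest_s = rest_s, footprint_centers = footprint_centers,
    footprint_radius_vox = radius, amplitude = amp,
    center_jitter_sd_vox = jitter, noise_sd = noise_sd,
    baseline = baseline, run_length_s = run_length_s,
    seed = as.integer(seed)), class = "cohort_spec")
  needed <- scheduled_run_length_s(spec)
  if (!is.null(run_length_s) && run_length_s < needed) {
    stop(sprintf("run_length_s = %g s is too short to host all blocks (%g s needed)",
                 run_length_s, needed), call. = FALSE)
  }
  spec
}

# Exact span of the scheduled blocks and rest gaps.
scheduled_run_length_s <- function(spec) {
  n_blocks <- length(spec$conditions) * spec$blocks_per_run_per_condition
  spec$rest_s + n_blocks * (spec$block_duration_s + spec$rest_s)
}

run_length_s <- function(spec) {
  if (!is.null(spec$run_length_s)) spec$run_length_s
  else scheduled_run_length_s(spec)
}

run_n_timepoints <- function(spec) {
  as.integer(ceiling(run_length_s(spec) / spec$tr_s))
}

#' Minutes-scale synthetic cohort configuration
#'
#' A scaled-down cohort for demonstration and testing: a 24^3 grid, 4
#' conditions, 2 runs, and 8 + 8 subjects, with the same block structure
#' (16-s blocks, twice per run, TR 2 s) as the full-scale default.
#'
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
demo_cohort_spec <- function(...) {
  defaults <- list(n_group_a = 8, n_group_b = 8, grid_shape = c(24, 24, 24),
                   voxel_size_mm = 2, tr_s = 2, n_runs = 2,
                   conditions = motor_conditions()[1:4],
                   footprint_radius_vox = list(a = 2.5, b = 3.5),
                   amplitude = 2, center_jitter_sd_vox = list(a = 0.5, b = 1.5),
                   noise_sd = 1, baseline = 100, seed = 42L)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

#' Voxels inside a spherical activation footprint
#'
#' @param center 0-based (x, y, z) voxel coordinates of the center.
#' @param radius_vox Radius in voxels.
#' @param grid_shape Grid dimensions.
#'
#' @return Integer vector of 1-based linear voxel indices whose Euclidean
#'   distance from `center` is at most `radius_vox`.
#' @export
footprint_voxel_indices <- function(center, radius_vox, grid_shape) {
  lo <- pmax(ceiling(center - radius_vox), 0)
  hi <- pmin(floor(center + radius_vox), grid_shape - 1)
  if (any(lo > hi)) return(integer(0))
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g <- g[d2 <= radius_vox^2, , drop = FALSE]
  as.integer(g$x + 1L + grid_shape[1] * (g$y + grid_shape[2] * g$z))
}

#' Generate per-subject activation ground truth
#'
#' Draws, for every subject and condition, the subject's activation
#' footprint: the group center displaced by an independent per-axis
#' Gaussian jitter with SD `center_jitter_sd_vox` (truncated by redrawing
#' so the footprint stays inside the grid), with the group's radius and
#' amplitude. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A `cohort_truth` data.frame: `subject_id`, `group` ("A"/"B"),
#'   `condition`, jittered center `cx`, `cy`, `cz` (0-based voxel
#'   coordinates), `radius_vox`, `amplitude`. The spec is attached as
#'   attribute `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- length(spec$conditions)
  grid <- spec$grid_shape
  with_seed(spec$seed, {
    rows <- list()
    for (g in c("a", "b")) {
      n_sub <- if (g == "a") spec$n_group_a else spec$n_group_b
      for (s in seq_len(n_sub)) {
        sid <- sprintf("%s%02d", toupper(g), s)
        for (j in seq_len(k)) {
          center <- spec$footprint_centers[j, ]
          r <- spec$footprint_radius_vox[[g]][j]
          sd_j <- spec$center_jitter_sd_vox[[g]][j]
          pos <- center
          for (try in seq_len(200)) {
            pos <- center + stats::rnorm(3, 0, sd_j)
            if (all(pos - r >= 0) && all(pos + r <= grid - 1)) break
          }
          pos <- pmin(pmax(pos, r), grid - 1 - r)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, group = toupper(g),
            condition = spec$conditions[j],
            cx = pos[1], cy = pos[2], cz = pos[3],
            radius_vox = r, amplitude = spec$amplitude[[g]][j])
        }
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    attr(truth, "spec") <- spec
    class(truth) <- c("cohort_truth", "data.frame")
    truth
  })
}

#' Randomized block schedule for one run
#'
#' Schedules `blocks_per_run_per_condition` blocks of every condition in a
#' seed-determined random order, separated (and preceded) by rest gaps of
#' `rest_s` seconds.
#'
#' @param spec A [cohort_spec()].
#' @param run_index 1-based run number (used only to derive the default
#'   seed).
#' @param seed Optional explicit seed for the block order; defaults to a
#'   value derived from `spec$seed` and `run_index`.
#'
#' @return An event table: `data.frame(onset, duration, trial_type)` in
#'   temporal order.
#' @export
make_block_design <- function(spec, run_index, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- derive_seed(spec$seed, 1000 + run_index)
  blocks <- rep(spec$conditions, each = spec$blocks_per_run_per_condition)
  order <- with_seed(seed, sample.int(length(blocks)))
  blocks <- blocks[order]
  onsets <- spec$rest_s +
    (seq_along(blocks) - 1) * (spec$block_duration_s + spec$rest_s)
  events <- data.frame(onset = onsets,
                       duration = spec$block_duration_s,
                       trial_type = blocks)
  run_len <- run_length_s(spec)
  if (any(events$onset + events$duration > run_len + 1e-9)) {
    stop("run too short to host all scheduled blocks", call. = FALSE)
  }
  events
}

#' Simulate one BOLD run for one subject
#'
#' The expected time course is a constant baseline everywhere; inside a
#' condition's footprint it is additionally modulated by
#' `baseline * amplitude/100` times the condition's convolved task
#' regressor (boxcar convolved with the double-gamma HRF, steady-state
#' normalized, exactly as in [build_design_matrix()]), so a sustained block
#' plateaus at the nominal percent signal change. Independent Gaussian
#' noise with SD `noise_sd` is added at every voxel-timepoint; with
#' `noise_sd = 0` the run is an exact deterministic function of the truth
#' and events.
#'
#' @param truth A [make_cohort()] table (or the rows of one subject).
#' @param events The run's event table, e.g. from [make_block_design()].
#' @param spec The [cohort_spec()].
#' @param seed RNG seed for the noise.
#' @param subject_id Which subject of `truth` to simulate; may be omitted
#'   when `truth` contains a single subject.
#' @param run_index Stored on the returned object.
#' @param hrf HRF parameters used for the signal time course.
#'
#' @return A `bold_run`: list with 4D `data` (x, y, z, t), `tr_s`, logical
#'   `mask` (whole grid), `run_index`, `subject_id`, `group`.
#' @export
simulate_run <- function(truth, events, spec, seed = 1L, subject_id = NULL,
                         run_index = NA_integer_, hrf = hrf_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(subject_id)) {
    ids <- unique(truth$subject_id)
    if (length(ids) != 1L) {
      stop("`truth` holds several subjects; give `subject_id`", call. = FALSE)
    }
    subject_id <- ids
  }
  rows <- truth[truth$subject_id == subject_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown subject_id: ", subject_id,
                             call. = FALSE)
  grid <- spec$grid_shape
  n_t <- run_n_timepoints(spec)
  reg <- condition_regressors(events, n_t, spec$tr_s, hrf,
                              conditions = spec$conditions)
  mat <- matrix(spec$baseline, nrow = prod(grid), ncol = n_t)
  for (i in seq_len(nrow(rows))) {
    cond <- rows$condition[i]
    if (!cond %in% colnames(reg)) next
    idx <- footprint_voxel_indices(c(rows$cx[i], rows$cy[i], rows$cz[i]),
                                   rows$radius_vox[i], grid)
    if (!length(idx)) next
    scale <- spec$baseline * rows$amplitude[i] / 100
    mat[idx, ] <- mat[idx, ] +
      scale * matrix(reg[, cond], nrow = length(idx), ncol = n_t,
                     byrow = TRUE)
  }
  if (spec$noise_sd > 0) {
    mat <- mat + with_seed(seed, matrix(
      stats::rnorm(length(mat), 0, spec$noise_sd), nrow = nrow(mat)))
  }
  structure(list(data = array(mat, dim = c(grid, n_t)), tr_s = spec$tr_s,
                 mask = array(TRUE, dim = grid), run_index = run_index,
                 subject_id = subject_id, group = rows$group[1L]),
            class = "bold_run")
}

#' Group means and SDs for the synthetic structural tables
#'
#' Raw-scale generative parameters (group A emulating females, group B
#' males) chosen so that the normalized ratios reproduce the reported
#' group-level structural statistics of the emulated study: males with
#' larger overall brain volume and surface area, females with thicker
#' cortex relative to brain size.
#'
#' @return A list with `means` and `sds`, each `list(a=, b=)` of named
#'   7-metric vectors.
#' @export
default_structural_params <- function() {
  metrics_a <- c(brain_volume_mm3 = 1099719.2,
                 thickness_mm_left = 2.397, thickness_mm_right = 2.408,
                 gm_volume_mm3_left = 232041, gm_volume_mm3_right = 233140,
                 surface_area_mm2_left = 82479, surface_area_mm2_right = 82479)
  metrics_b <- c(brain_volume_mm3 = 1230966.7,
                 thickness_mm_left = 2.450, thickness_mm_right = 2.450,
                 gm_volume_mm3_left = 263427, gm_volume_mm3_right = 264658,
                 surface_area_mm2_left = 92322, surface_area_mm2_right = 92322)
  sds_a <- c(brain_volume_mm3 = 55040,
             thickness_mm_left = 0.129, thickness_mm_right = 0.129,
             gm_volume_mm3_left = 8798, gm_volume_mm3_right = 8798,
             surface_area_mm2_left = 2199, surface_area_mm2_right = 2199)
  sds_b <- c(brain_volume_mm3 = 110274,
             thickness_mm_left = 0.215, thickness_mm_right = 0.209,
             gm_volume_mm3_left = 8617, gm_volume_mm3_right = 8617,
             surface_area_mm2_left = 2462, surface_area_mm2_right = 2462)
  list(means = list(a = metrics_a, b = metrics_b),
       sds = list(a = sds_a, b = sds_b))
}

#' Generate a synthetic structural-metrics table
#'
#' Draws each metric independently from a lognormal distribution (ensuring
#' positivity) whose mean and SD on the raw scale match the requested
#' moments; a zero SD yields the group mean exactly. Deterministic given
#' the seed.
#'
#' @param spec A [cohort_spec()] (supplies group sizes and subject ids).
#' @param group_means,group_sds Lists `list(a=, b=)` of named metric
#'   vectors (see [default_structural_params()]).
#' @param seed RNG seed.
#'
#' @return A data.frame with `subject_id`, `group`, and the seven raw
#'   metric columns.
#' @export
make_structural_table <- function(spec,
                                  group_means = default_structural_params()$means,
                                  group_sds = default_structural_params()$sds,
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (g in c("a", "b")) {
    if (any(group_means[[g]][structural_metric_cols] <= 0)) {
      stop("group means must be positive", call. = FALSE)
    }
    if (any(group_sds[[g]][structural_metric_cols] < 0)) {
      stop("group SDs must be non-negative", call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- list()
    for (g in c("a", "b")) {
      n_sub <- if (g == "a") spec$n_group_a else spec$n_group_b
      m <- group_means[[g]][structural_metric_cols]
      s <- group_sds[[g]][structural_metric_cols]
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      for (i in seq_len(n_sub)) {
        vals <- stats::rlnorm(length(m), meanlog, sdlog)
        rec <- as.list(vals)
        names(rec) <- structural_metric_cols
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s%02d", toupper(g), i),
          group = toupper(g), rec)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    bad <- out$gm_volume_mm3_left + out$gm_volume_mm3_right >=
      out$brain_volume_mm3
    if (any(bad)) {
      stop("generated grey-matter volume exceeds brain volume for subject(s): ",
           paste(out$subject_id[bad], collapse = ", "), call. = FALSE)
    }
    out
  })
}
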