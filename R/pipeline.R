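#' Pipeline configuration
#'
#' Bundles every constant of the end-to-end analysis: the cohort generator
#' spec, HRF and TFCE parameters, permutation counts (5,000 for the
#' group-level TFCE maps, 20,000 for the pair-level and structural
#' permutation t-tests), the family-wise alpha, and the Bonferroni family
#' sizes (the number of movement conditions for the variability family;
#' 7 for the structural family).
#'
#' @param cohort A [cohort_spec()].
#' @param hrf An [hrf_params()].
#' @param tfce A [tfce_params()].
#' @param n_perm_group Permutations for group-level TFCE inference.
#' @param n_perm_behavioral Permutations for pair-level/structural t-tests.
#' @param alpha Family-wise significance level.
#' @param bonferroni_m_variability Family size for the variability tests;
#'   defaults to the number of conditions (12 at full scale).
#' @param bonferroni_m_structural Family size for the structural tests.
#' @param seed Base seed; every stage derives its own seed from it and the
#'   manifest records each seed actually consumed.
#' @param out_dir Output directory (created if missing).
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = demo_cohort_spec(), hrf = hrf_params(),
                            tfce = tfce_params(), n_perm_group = 5000,
                            n_perm_behavioral = 20000, alpha = 0.05,
                            bonferroni_m_variability = NULL,
                            bonferroni_m_structural = 7,
                            seed = 1L, out_dir = tempfile("motormap_")) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(hrf, "hrf_params"),
            inherits(tfce, "tfce_params"))
  if (is.null(bonferroni_m_variability)) {
    bonferroni_m_variability <- length(cohort$conditions)
  }
  structure(list(cohort = cohort, hrf = hrf, tfce = tfce,
                 n_perm_group = n_perm_group,
                 n_perm_behavioral = n_perm_behavioral, alpha = alpha,
                 bonferroni_m_variability = bonferroni_m_variability,
                 bonferroni_m_structural = bonferroni_m_structural,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys `cohort`, `hrf`, `tfce` hold the argument lists of
#' [cohort_spec()], [hrf_params()] and [tfce_params()]; remaining keys are
#' passed to [pipeline_config()] directly.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$cohort)) {
    ch <- cfg$cohort
    for (f in c("grid_shape")) if (!is.null(ch[[f]])) ch[[f]] <- unlist(ch[[f]])
    if (!is.null(ch$footprint_centers)) {
      ch$footprint_centers <- do.call(rbind, lapply(ch$footprint_centers,
                                                    unlist))
    }
    args$cohort <- do.call(cohort_spec, ch)
  }
  if (!is.null(cfg$hrf)) args$hrf <- do.call(hrf_params, cfg$hrf)
  if (!is.null(cfg$tfce)) args$tfce <- do.call(tfce_params, cfg$tfce)
  rest <- cfg[setdiff(names(cfg), c("cohort", "hrf", "tfce"))]
  if (!is.null(out_dir)) rest$out_dir <- out_dir
  do.call(pipeline_config, c(args, rest))
}

pipeline_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full synthetic motor-mapping analysis
#'
#' Executes every stage end-to-end on a synthetic cohort: simulate runs,
#' fit the first-level GLM per run, combine runs by fixed effects, run
#' one-sample group inference per group and condition and two-sample
#' between-group contrasts (both directions) with TFCE + max-statistic FWE
#' correction, summarize activation extent and spatial similarity, compute
#' between-subject and within-subject correlation variability tables with
#' permutation t-tests, and compare synthetic structural metrics. All
#' tables are written as TSV, group maps as NIfTI, and a JSON manifest
#' records the parameters and every seed consumed. Idempotent for fixed
#' seeds; inputs are never mutated.
#'
#' @param config A [pipeline_config()].
#' @param write_maps Write the group-level NIfTI volumes (default `TRUE`).
#' @param verbose Log one line per stage.
#'
#' @return Invisibly, a report bundle: the cohort `truth`, the
#'   `activation` summary, `between_subject` and `within_subject`
#'   variability tables, the `structural` results, per-condition
#'   `group_results`, and the manifest.
#' @export
run_pipeline <- function(config, write_maps = TRUE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$cohort
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  seeds <- list(cohort = spec$seed)

  pipeline_log(verbose, "simulate", "generating cohort truth (",
               spec$n_group_a, "+", spec$n_group_b, " subjects, ",
               length(spec$conditions), " conditions)")
  truth <- make_cohort(spec)
  write_table_tsv(truth, file.path(out_dir, "cohort_truth.tsv"))

  n_t <- run_n_timepoints(spec)
  run_events <- lapply(seq_len(spec$n_runs), function(r) {
    ev <- make_block_design(spec, r)
    write_events(ev, file.path(out_dir, sprintf("run-%02d_events.tsv", r)))
    ev
  })
  designs <- lapply(run_events, build_design_matrix, n_timepoints = n_t,
                    tr_s = spec$tr_s, hrf = config$hrf,
                    conditions = spec$conditions)

  pipeline_log(verbose, "first-level", "fitting ", spec$n_runs,
               " run(s) for each subject")
  subject_ids <- unique(truth$subject_id)
  subj_level <- list()
  run_tmaps <- list()
  sim_seeds <- integer(0)
  for (si in seq_along(subject_ids)) {
    sid <- subject_ids[si]
    fl <- vector("list", spec$n_runs)
    for (r in seq_len(spec$n_runs)) {
      s_seed <- derive_seed(config$seed, si * 1000 + r)
      sim_seeds <- c(sim_seeds, s_seed)
      run <- simulate_run(truth, run_events[[r]], spec, seed = s_seed,
                          subject_id = sid, run_index = r, hrf = config$hrf)
      fl[[r]] <- fit_glm(run, designs[[r]])
    }
    subj_level[[sid]] <- fixed_effects_combine(fl)
    run_tmaps[[sid]] <- lapply(fl, `[[`, "tmap")
  }
  seeds$simulate <- sim_seeds
  mask <- subj_level[[1L]]$mask
  groups <- vapply(subject_ids, function(s)
    truth$group[truth$subject_id == s][1L], character(1))

  pipeline_log(verbose, "group-level", "one-sample and two-sample TFCE ",
               "permutation inference (", config$n_perm_group, " perms)")
  group_results <- list()
  counts_a <- counts_b <- numeric(length(spec$conditions))
  sim_maps_a <- sim_maps_b <- stats::setNames(
    vector("list", length(spec$conditions)), spec$conditions)
  for (j in seq_along(spec$conditions)) {
    cond <- spec$conditions[j]
    copes_a <- lapply(subject_ids[groups == "A"], function(s)
      subj_level[[s]]$cope[[cond]])
    copes_b <- lapply(subject_ids[groups == "B"], function(s)
      subj_level[[s]]$cope[[cond]])
    seed_a <- derive_seed(config$seed, 20000 + j)
    seed_b <- derive_seed(config$seed, 30000 + j)
    seed_ab <- derive_seed(config$seed, 40000 + j)
    seed_ba <- derive_seed(config$seed, 50000 + j)
    seeds[[paste0("group_", cond)]] <- c(seed_a, seed_b, seed_ab, seed_ba)
    res_a <- permutation_one_sample(copes_a, mask, config$tfce,
                                    config$n_perm_group, seed_a)
    res_b <- permutation_one_sample(copes_b, mask, config$tfce,
                                    config$n_perm_group, seed_b)
    res_ab <- permutation_two_sample(copes_a, copes_b, mask, config$tfce,
                                     config$n_perm_group, seed_ab, "a_gt_b")
    res_ba <- permutation_two_sample(copes_a, copes_b, mask, config$tfce,
                                     config$n_perm_group, seed_ba, "b_gt_a")
    counts_a[j] <- count_significant_voxels(threshold_map(res_a,
                                                          config$alpha))
    counts_b[j] <- count_significant_voxels(threshold_map(res_b,
                                                          config$alpha))
    sim_maps_a[[cond]] <- similarity_input_map(res_a$fwe_p, config$alpha)
    sim_maps_b[[cond]] <- similarity_input_map(res_b$fwe_p, config$alpha)
    if (write_maps) {
      for (nm in c("a", "b", "ab", "ba")) {
        res <- switch(nm, a = res_a, b = res_b, ab = res_ab, ba = res_ba)
        lbl <- switch(nm, a = "group-A", b = "group-B",
                      ab = "contrast-AgtB", ba = "contrast-BgtA")
        write_stat_map(res$observed_stat,
                       file.path(out_dir, sprintf("cond-%s_%s_stat-t.nii.gz",
                                                  cond, lbl)),
                       spec$voxel_size_mm)
        write_stat_map(res$fwe_p,
                       file.path(out_dir, sprintf("cond-%s_%s_stat-fwep.nii.gz",
                                                  cond, lbl)),
                       spec$voxel_size_mm)
      }
    }
    group_results[[cond]] <- list(one_sample_a = res_a, one_sample_b = res_b,
                                  two_sample_a_gt_b = res_ab,
                                  two_sample_b_gt_a = res_ba)
  }

  pipeline_log(verbose, "metrics", "activation extent and spatial similarity")
  similarity <- similarity_by_condition(sim_maps_a, sim_maps_b, mask)
  activation <- activation_summary(spec$conditions, counts_a, counts_b,
                                   similarity)
  write_table_tsv(activation$table, file.path(out_dir, "activation.tsv"))

  pipeline_log(verbose, "variability", "pairwise correlation tests (",
               config$n_perm_behavioral, " perms)")
  between_rows <- within_rows <- list()
  subj_tmaps <- lapply(subj_level, `[[`, "tmap")
  for (j in seq_along(spec$conditions)) {
    cond <- spec$conditions[j]
    tm_a <- lapply(subj_tmaps[groups == "A"], `[[`, cond)
    tm_b <- lapply(subj_tmaps[groups == "B"], `[[`, cond)
    set_a <- pairwise_between_subject(tm_a, mask, "A", cond)
    set_b <- pairwise_between_subject(tm_b, mask, "B", cond)
    seed_bt <- derive_seed(config$seed, 60000 + j)
    seeds[[paste0("between_", cond)]] <- seed_bt
    bt <- permutation_ttest(set_a$values, set_b$values,
                            config$n_perm_behavioral, seed_bt)
    between_rows[[j]] <- data.frame(
      condition = cond,
      mean_a = mean(set_a$values), sd_a = stats::sd(set_a$values),
      mean_b = mean(set_b$values), sd_b = stats::sd(set_b$values),
      t = bt$t_statistic, dof = bt$dof, p = bt$p_value, cohens_d = bt$cohens_d)
    wr_a <- vapply(names(subj_tmaps)[groups == "A"], function(s)
      within_subject_between_run(lapply(run_tmaps[[s]], `[[`, cond),
                                 mask)$mean_r, numeric(1))
    wr_b <- vapply(names(subj_tmaps)[groups == "B"], function(s)
      within_subject_between_run(lapply(run_tmaps[[s]], `[[`, cond),
                                 mask)$mean_r, numeric(1))
    seed_wt <- derive_seed(config$seed, 70000 + j)
    seeds[[paste0("within_", cond)]] <- seed_wt
    wt <- permutation_ttest(wr_a, wr_b, config$n_perm_behavioral, seed_wt)
    within_rows[[j]] <- data.frame(
      condition = cond, mean_a = mean(wr_a), sd_a = stats::sd(wr_a),
      mean_b = mean(wr_b), sd_b = stats::sd(wr_b),
      t = wt$t_statistic, dof = wt$dof, p = wt$p_value, cohens_d = wt$cohens_d)
  }
  between_subject <- do.call(rbind, between_rows)
  between_subject$significant <- bonferroni_flags(
    between_subject$p, config$bonferroni_m_variability, config$alpha)
  within_subject <- do.call(rbind, within_rows)
  within_subject$significant <- bonferroni_flags(
    within_subject$p, config$bonferroni_m_variability, config$alpha)
  write_table_tsv(between_subject,
                  file.path(out_dir, "between_subject_variability.tsv"))
  write_table_tsv(within_subject,
                  file.path(out_dir, "within_subject_variability.tsv"))

  pipeline_log(verbose, "structural", "normalized structural comparisons")
  seeds$structural_table <- derive_seed(config$seed, 80000)
  structural_table <- make_structural_table(spec,
                                            seed = seeds$structural_table)
  write_table_tsv(structural_table, file.path(out_dir, "structural_table.tsv"))
  seeds$structural_tests <- derive_seed(config$seed, 90000)
  structural <- compare_structural(
    structural_table[structural_table$group == "A", ],
    structural_table[structural_table$group == "B", ],
    n_perm = config$n_perm_behavioral, seed = seeds$structural_tests,
    alpha = config$alpha)
  write_table_tsv(structural, file.path(out_dir, "structural_results.tsv"))

  manifest <- list(
    package = "motormap",
    version = as.character(utils::packageVersion("motormap")),
    seeds = seeds,
    params = list(n_perm_group = config$n_perm_group,
                  n_perm_behavioral = config$n_perm_behavioral,
                  alpha = config$alpha,
                  bonferroni_m_variability = config$bonferroni_m_variability,
                  bonferroni_m_structural = config$bonferroni_m_structural,
                  tfce = unclass(config$tfce), hrf = unclass(config$hrf),
                  grid_shape = spec$grid_shape,
                  n_group_a = spec$n_group_a, n_group_b = spec$n_group_b,
                  n_runs = spec$n_runs, conditions = spec$conditions),
    runtime_s = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(verbose, "done", "outputs in ", out_dir)
  invisible(list(truth = truth, activation = activation,
                 between_subject = between_subject,
                 within_subject = within_subject, structural = structural,
                 group_results = group_results, manifest = manifest,
                 out_dir = out_dir))
}
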