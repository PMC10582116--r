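test_that("cohort spec validates its fields", {
  expect_s3_class(demo_cohort_spec(), "cohort_spec")
  expect_error(demo_cohort_spec(footprint_radius_vox = 15),
               "footprint_radius_vox")
  expect_error(demo_cohort_spec(footprint_centers =
                                  matrix(c(30, 5, 5), 4, 3, byrow = TRUE)),
               "footprint_centers")
  expect_error(demo_cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(demo_cohort_spec(run_length_s = 30), "too short")
})

test_that("zero jitter pins every subject's center to the group center", {
  spec <- demo_cohort_spec(center_jitter_sd_vox = 0)
  truth <- make_cohort(spec)
  for (j in seq_along(spec$conditions)) {
    rows <- truth[truth$condition == spec$conditions[j], ]
    expect_true(all(rows$cx == spec$footprint_centers[j, 1]))
    expect_true(all(rows$cy == spec$footprint_centers[j, 2]))
    expect_true(all(rows$cz == spec$footprint_centers[j, 3]))
  }
})

test_that("footprint voxel sets match an exhaustive whole-grid scan", {
  grid <- c(24, 24, 24)
  for (case in list(list(c = c(12, 12, 12), r = 3),
                    list(c = c(6.4, 17.2, 11.9), r = 4.5))) {
    got <- sort(footprint_voxel_indices(case$c, case$r, grid))
    g <- expand.grid(x = 0:23, y = 0:23, z = 0:23)
    keep <- sqrt((g$x - case$c[1])^2 + (g$y - case$c[2])^2 +
                   (g$z - case$c[3])^2) <= case$r
    oracle <- which(array(keep, grid))
    expect_identical(got, oracle)
  }
})

test_that("footprint volume is monotone non-decreasing in radius", {
  grid <- c(20, 20, 20)
  sizes <- vapply(seq(0.5, 8, by = 0.5), function(r)
    length(footprint_voxel_indices(c(10, 10, 10), r, grid)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("cohort generation is deterministic given the seed", {
  spec <- demo_cohort_spec(seed = 99L)
  expect_identical(make_cohort(spec), make_cohort(spec))
})

test_that("block design has the full-protocol structure", {
  spec <- cohort_spec()           # 12 conditions, 2 blocks, 16 s, 6 runs
  ev <- make_block_design(spec, 1)
  expect_equal(nrow(ev), 24)
  expect_equal(sum(ev$duration), 384)
  expect_true(all(table(ev$trial_type) == 2))
  # per-condition task seconds across all runs
  total <- Reduce(`+`, lapply(seq_len(spec$n_runs), function(r) {
    e <- make_block_design(spec, r)
    tapply(e$duration, e$trial_type, sum)
  }))
  expect_true(all(total == 192))
  # blocks never overlap
  ord <- order(ev$onset)
  expect_true(all(diff(ev$onset[ord]) >= ev$duration[ord][-nrow(ev)]))
})

test_that("a one-condition one-block design is a single 16-s row", {
  spec <- demo_cohort_spec(conditions = "fingers",
                           blocks_per_run_per_condition = 1)
  ev <- make_block_design(spec, 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 16)
})

test_that("block order differs between runs but is seed-reproducible", {
  spec <- cohort_spec()
  expect_identical(make_block_design(spec, 3), make_block_design(spec, 3))
  orders <- vapply(1:6, function(r)
    paste(make_block_design(spec, r)$trial_type, collapse = ","),
    character(1))
  expect_gt(length(unique(orders)), 1)
})

test_that("amplitude 0 with no noise gives a constant-baseline run", {
  spec <- demo_cohort_spec(amplitude = 0, noise_sd = 0,
                           grid_shape = c(10, 10, 10),
                           footprint_radius_vox = 2, conditions = "eyes")
  truth <- make_cohort(spec)
  run <- simulate_run(truth, make_block_design(spec, 1), spec, seed = 1,
                      subject_id = "A01")
  expect_true(all(run$data == spec$baseline))
})

test_that("noise-free signal matches an independent convolution oracle", {
  spec <- demo_cohort_spec(amplitude = 1.5, noise_sd = 0,
                           center_jitter_sd_vox = 0,
                           grid_shape = c(12, 12, 12),
                           footprint_radius_vox = 2, conditions = "eyes",
                           blocks_per_run_per_condition = 1,
                           rest_s = 10)
  truth <- make_cohort(spec)
  ev <- make_block_design(spec, 1)
  run <- simulate_run(truth, ev, spec, seed = 1, subject_id = "A01")
  n_t <- dim(run$data)[4]
  # direct convolution: sample the closed-form kernel, integrate against
  # the boxcar by explicit summation at each TR
  dt <- 0.1                             # the kernel's own sampling grid
  tk <- seq(0, 32, by = dt)
  kern <- dgamma(tk, shape = 6, scale = 1) -
    (1 / 6) * dgamma(tk, shape = 16, scale = 1)
  kern <- kern / max(kern)
  steady <- sum(kern) * dt
  reg <- vapply(seq_len(n_t), function(i) {
    t_i <- (i - 1) * spec$tr_s
    u <- t_i - tk                       # stimulus time
    sum(kern[u >= ev$onset & u < ev$onset + ev$duration]) * dt / steady
  }, numeric(1))
  expected <- spec$baseline * (1 + 0.015 * reg)
  center <- spec$footprint_centers[1, ] + 1
  got <- run$data[center[1], center[2], center[3], ]
  expect_lt(max(abs(got - expected)), 1e-6)
  # plateau percent signal change approaches the nominal amplitude
  expect_lt(abs(max(got) / spec$baseline - 1 - 0.015 * max(reg)), 1e-6)
})

test_that("noise-free simulation is bit-reproducible", {
  spec <- demo_cohort_spec(noise_sd = 0, grid_shape = c(10, 10, 10),
                           footprint_radius_vox = 2,
                           conditions = c("eyes", "jaw"))
  truth <- make_cohort(spec)
  ev <- make_block_design(spec, 1)
  r1 <- simulate_run(truth, ev, spec, seed = 5, subject_id = "B01")
  r2 <- simulate_run(truth, ev, spec, seed = 5, subject_id = "B01")
  expect_identical(r1$data, r2$data)
})

test_that("noise SD is recovered from the simulated series", {
  spec <- demo_cohort_spec(amplitude = 0, noise_sd = 10,
                           grid_shape = c(8, 8, 8), conditions = "eyes",
                           footprint_radius_vox = 2)
  truth <- make_cohort(spec)
  run <- simulate_run(truth, make_block_design(spec, 1), spec, seed = 3,
                      subject_id = "A01")
  n_t <- dim(run$data)[4]
  flat <- matrix(run$data, ncol = n_t)
  sds <- apply(flat, 1, sd)
  se <- sd(sds) / sqrt(length(sds))
  expect_lt(abs(mean(sds) - 10), 3 * se + 0.2)
})

test_that("between-subject t-map correlation drops as jitter grows", {
  means <- vapply(c(0.25, 1.5, 3), function(jit) {
    spec <- demo_cohort_spec(grid_shape = c(16, 16, 16), n_runs = 1,
                             n_group_a = 6, n_group_b = 2,
                             conditions = "eyes",
                             footprint_centers = matrix(c(8, 8, 8), 1),
                             footprint_radius_vox = 3, amplitude = 3,
                             center_jitter_sd_vox = list(a = jit, b = jit),
                             noise_sd = 1, seed = 11L)
    fit <- fit_cohort(spec)
    tmaps <- lapply(fit$subjects[fit$groups == "A"], `[[`, "tmap")
    tmaps <- lapply(tmaps, `[[`, "eyes")
    mean(pairwise_between_subject(tmaps)$values)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("structural tables honour their generative moments", {
  spec <- demo_cohort_spec()
  pars <- default_structural_params()
  # zero SD reproduces the group means exactly
  zero_sds <- lapply(pars$sds, function(s) s * 0)
  tab <- make_structural_table(spec, pars$means, zero_sds, seed = 1)
  a_rows <- tab[tab$group == "A", ]
  expect_equal(a_rows$brain_volume_mm3,
               rep(pars$means$a[["brain_volume_mm3"]], nrow(a_rows)))
  expect_equal(a_rows$thickness_mm_left,
               rep(pars$means$a[["thickness_mm_left"]], nrow(a_rows)))
  # law of large numbers at n = 500
  big <- demo_cohort_spec(n_group_a = 500, n_group_b = 500)
  tab2 <- make_structural_table(big, seed = 7)
  for (g in c("a", "b")) {
    rows <- tab2[tab2$group == toupper(g), ]
    expect_lt(abs(mean(rows$brain_volume_mm3) /
                    pars$means[[g]][["brain_volume_mm3"]] - 1), 0.01)
    expect_lt(abs(mean(rows$thickness_mm_left) /
                    pars$means[[g]][["thickness_mm_left"]] - 1), 0.01)
  }
  # determinism and positivity
  expect_identical(make_structural_table(spec, seed = 3),
                   make_structural_table(spec, seed = 3))
  expect_true(all(as.matrix(tab2[, -(1:2)]) > 0))
  expect_error(make_structural_table(spec,
                                     group_means = lapply(pars$means,
                                                          function(x) x * 0),
                                     seed = 1),
               "positive")
})
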