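test_that("double-gamma kernel meets its shape contract", {
  k <- double_gamma_hrf(hrf_params())
  expect_equal(k$values[1], 0)
  expect_equal(max(k$values), 1)
  expect_lt(abs(k$values[length(k$values)]), 0.01)  # decayed by 32 s
  # argmax matches a dense grid search of the closed form
  kf <- double_gamma_hrf(hrf_params(oversample_dt_s = 0.01))
  tg <- seq(0, 32, by = 0.01)
  f <- dgamma(tg, shape = 6, scale = 1) -
    (1 / 6) * dgamma(tg, shape = 16, scale = 1)
  expect_equal(kf$time_s[which.max(kf$values)], tg[which.max(f)])
  expect_error(hrf_params(undershoot_delay_s = 5), "exceed")
  expect_error(hrf_params(undershoot_ratio = 1.2), "undershoot_ratio")
})

test_that("design matrix columns count and derive correctly", {
  spec <- cohort_spec()               # 12 conditions
  ev <- make_block_design(spec, 1)
  n_t <- ceiling((max(ev$onset + ev$duration) + 40) / 2)
  X <- build_design_matrix(ev, n_t, tr_s = 2, conditions = spec$conditions)
  expect_equal(ncol(X$matrix), 25)    # 12 task + 12 derivative + intercept
  expect_equal(colnames(X$matrix)[25], "intercept")
  # derivative column is the scaled first difference of its task column
  tc <- X$matrix[, "jaw"]
  expect_equal(X$matrix[, "jaw_derivative"], c(0, diff(tc)) / 2,
               ignore_attr = TRUE)
  # a 16-s block occupies 8 TR samples of boxcar before convolution, so the
  # convolved regressor integrates (against TR) to ~ its 16 task seconds
  ev1 <- data.frame(onset = 10, duration = 16, trial_type = "wrists")
  r <- condition_regressors(ev1, n_timepoints = 60, tr_s = 2)
  expect_equal(16 / 2, 8)
  expect_lt(abs(sum(r) * 2 - 16), 0.3)
})

test_that("an unused condition yields a zero column and a rank error", {
  ev <- data.frame(onset = 4, duration = 16, trial_type = "eyes")
  r <- condition_regressors(ev, 40, 2, conditions = c("eyes", "jaw"))
  expect_true(all(r[, "jaw"] == 0))
  expect_error(build_design_matrix(ev, 40, 2, conditions = c("eyes", "jaw")),
               "jaw")
  expect_error(build_design_matrix(ev[0, ], 40, 2), "empty")
})

make_run_from_matrix <- function(Y, grid) {
  # lay V voxel time series into a grid x time array (V = prod(grid))
  list(data = array(t(Y), dim = c(grid, nrow(Y))),
       mask = array(TRUE, grid), tr_s = 2)
}

test_that("GLM recovers noise-free coefficients exactly", {
  ev <- data.frame(onset = c(6, 40), duration = 16, trial_type = "fingers")
  X <- build_design_matrix(ev, 40, 2)
  task <- X$matrix[, "fingers"]
  grid <- c(2, 2, 1)
  Y <- cbind(3 * task + 7, 0 * task, -2 * task + 1, 5 + 0 * task)
  fl <- fit_glm(make_run_from_matrix(Y, grid), X)
  copes <- as.vector(fl$cope[["fingers"]])
  expect_equal(copes, c(3, 0, -2, 0), tolerance = 1e-10)
  # zero residuals: varcope 0; t convention 0 for zero cope, sentinel else
  tmaps <- as.vector(fl$tmap[["fingers"]])
  expect_equal(tmaps[2], 0)
  expect_equal(tmaps[4], 0)
  expect_true(is.infinite(tmaps[1]) && tmaps[1] > 0)
  expect_true(is.infinite(tmaps[3]) && tmaps[3] < 0)
  expect_equal(fl$dof, 40 - 3)   # task + derivative + intercept
})

test_that("GLM matches an independent normal-equations solve", {
  set.seed(21)
  ev <- data.frame(onset = c(6, 40), duration = 16, trial_type = "toes")
  X <- build_design_matrix(ev, 20, 4)
  grid <- c(3, 2, 1)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  fl <- fit_glm(make_run_from_matrix(Y, grid), X)
  M <- X$matrix
  beta <- solve(t(M) %*% M) %*% t(M) %*% Y      # independent solve
  expect_equal(as.vector(fl$cope[["toes"]]), beta[1, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # varcope against the explicit formula
  res <- Y - M %*% beta
  s2 <- colSums(res^2) / (20 - 3)
  v_expect <- s2 * solve(t(M) %*% M)[1, 1]
  expect_equal(as.vector(fl$varcope[["toes"]]), v_expect, tolerance = 1e-10,
               ignore_attr = TRUE)
  # residuals orthogonal to every design column
  expect_lt(max(abs(t(M) %*% res)), 1e-8)
})

test_that("t-maps are invariant to positive rescaling of the data", {
  set.seed(22)
  ev <- data.frame(onset = 6, duration = 16, trial_type = "eyes")
  X <- build_design_matrix(ev, 30, 2)
  grid <- c(2, 2, 2)
  Y <- matrix(rnorm(30 * 8), 30, 8) + 2 * X$matrix[, "eyes"]
  t1 <- fit_glm(make_run_from_matrix(Y, grid), X)$tmap[["eyes"]]
  t2 <- fit_glm(make_run_from_matrix(Y * 37.5, grid), X)$tmap[["eyes"]]
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("fixed effects averages copes and propagates variance", {
  set.seed(23)
  ev <- data.frame(onset = 6, duration = 16, trial_type = "eyes")
  X <- build_design_matrix(ev, 30, 2)
  grid <- c(2, 2, 1)
  runs <- lapply(1:6, function(i) {
    Y <- matrix(rnorm(30 * 4), 30, 4) + i * X$matrix[, "eyes"]
    fit_glm(make_run_from_matrix(Y, grid), X)
  })
  fx <- fixed_effects_combine(runs)
  # cope is the arithmetic mean, varcope the sum over K^2, dof the sum
  cope_oracle <- Reduce(`+`, lapply(runs, function(r) r$cope[["eyes"]])) / 6
  var_oracle <- Reduce(`+`, lapply(runs, function(r) r$varcope[["eyes"]])) / 36
  expect_equal(fx$cope[["eyes"]], cope_oracle, tolerance = 1e-12)
  expect_equal(fx$varcope[["eyes"]], var_oracle, tolerance = 1e-12)
  expect_equal(fx$tmap[["eyes"]], cope_oracle / sqrt(var_oracle),
               tolerance = 1e-12)
  expect_equal(fx$dof, sum(vapply(runs, `[[`, numeric(1), "dof")))
  expect_equal(fx$n_runs_combined, 6)
  # K identical runs: cope unchanged, varcope divided by K
  fx2 <- fixed_effects_combine(list(runs[[1]], runs[[1]], runs[[1]]))
  expect_equal(fx2$cope[["eyes"]], runs[[1]]$cope[["eyes"]])
  expect_equal(fx2$varcope[["eyes"]], runs[[1]]$varcope[["eyes"]] / 3)
  expect_error(fixed_effects_combine(runs[1]), "two run")
})

test_that("combined copes (1..6) average to 3.5", {
  ev <- data.frame(onset = 6, duration = 16, trial_type = "eyes")
  X <- build_design_matrix(ev, 30, 2)
  grid <- c(1, 1, 1)
  runs <- lapply(1:6, function(i) {
    Y <- matrix(i * X$matrix[, "eyes"] + 0.001 * rnorm(30, 0, 1), 30, 1)
    fit_glm(make_run_from_matrix(Y, grid), X)
  })
  set.seed(24)
  fx <- fixed_effects_combine(runs)
  expect_equal(as.vector(fx$cope[["eyes"]]), 3.5, tolerance = 0.01)
})

test_that("fixed-effects t grows like sqrt(K) over replicate runs", {
  set.seed(25)
  ev <- data.frame(onset = c(6, 40), duration = 16, trial_type = "eyes")
  X <- build_design_matrix(ev, 40, 2)
  grid <- c(2, 2, 1)
  all_runs <- lapply(1:8, function(i) {
    Y <- matrix(rnorm(40 * 4), 40, 4) + 1.5 * X$matrix[, "eyes"]
    fit_glm(make_run_from_matrix(Y, grid), X)
  })
  mean_t <- vapply(c(2, 4, 8), function(K)
    mean(fixed_effects_combine(all_runs[1:K])$tmap[["eyes"]]), numeric(1))
  expect_true(all(diff(mean_t) > 0))
  # ratio roughly sqrt(2) per doubling
  expect_equal(mean_t[3] / mean_t[1], 2, tolerance = 0.35)
})

test_that("in-footprint copes exceed out-of-footprint copes", {
  spec <- demo_cohort_spec(grid_shape = c(14, 14, 14), n_runs = 1,
                           n_group_a = 1, n_group_b = 1,
                           conditions = "eyes",
                           footprint_centers = matrix(c(7, 7, 7), 1),
                           footprint_radius_vox = 3, amplitude = 2,
                           noise_sd = 1, seed = 31L)
  fit <- fit_cohort(spec)
  truth <- fit$truth
  r1 <- truth[truth$subject_id == "A01", ]
  idx <- footprint_voxel_indices(c(r1$cx, r1$cy, r1$cz), r1$radius_vox,
                                 spec$grid_shape)
  cop <- as.vector(fit$subjects[["A01"]]$cope[["eyes"]])
  expect_gt(mean(cop[idx]), mean(cop[-idx]) + 0.5)
})
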