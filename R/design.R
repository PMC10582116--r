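#' Convolved task regressors for a block design
#'
#' Builds, for each condition, the boxcar stimulus function on the
#' oversampled HRF grid, convolves it with the double-gamma kernel, and
#' samples the result at the repetition time. The regressor is scaled by the
#' kernel's steady-state response (its time integral), so a sustained block
#' asymptotes to 1; the simulated percent signal change at a long-block
#' plateau therefore equals the nominal amplitude.
#'
#' @param events An event table (`data.frame` with columns `onset`,
#'   `duration`, `trial_type`).
#' @param n_timepoints Number of volumes in the run.
#' @param tr_s Repetition time, seconds.
#' @param hrf An [hrf_params()] object.
#' @param conditions Condition order for the output columns; defaults to the
#'   order of first appearance in `events`.
#'
#' @return A `n_timepoints` x `length(conditions)` matrix of task regressors.
#' @export
condition_regressors <- function(events, n_timepoints, tr_s,
                                 hrf = hrf_params(), conditions = NULL) {
  validate_events(events)
  stop_if_not_scalar_number(tr_s, "tr_s", positive = TRUE)
  run_length_s <- n_timepoints * tr_s
  if (any(events$onset + events$duration > run_length_s + 1e-9)) {
    stop("events extend past the end of the run (", run_length_s, " s)",
         call. = FALSE)
  }
  if (is.null(conditions)) conditions <- unique(events$trial_type)
  kernel <- double_gamma_hrf(hrf)
  dt <- kernel$dt_s
  steady_state <- sum(kernel$values) * dt
  n_fine <- ceiling(run_length_s / dt) + length(kernel$values)
  t_fine <- (seq_len(n_fine) - 1) * dt
  sample_idx <- round((seq_len(n_timepoints) - 1) * tr_s / dt) + 1L
  out <- matrix(0, nrow = n_timepoints, ncol = length(conditions),
                dimnames = list(NULL, conditions))
  for (j in seq_along(conditions)) {
    rows <- events[events$trial_type == conditions[j], , drop = FALSE]
    box <- numeric(n_fine)
    for (k in seq_len(nrow(rows))) {
      box[t_fine >= rows$onset[k] - 1e-9 &
            t_fine < rows$onset[k] + rows$duration[k] - 1e-9] <- 1
    }
    conv <- stats::convolve(box, rev(kernel$values), type = "open") * dt
    out[, j] <- conv[sample_idx] / steady_state
  }
  out
}

#' First-level design matrix with temporal derivatives
#'
#' One convolved task regressor per condition, one temporal-derivative
#' column per condition (the first difference of the task column divided by
#' the repetition time, absorbing small response-latency shifts), and an
#' intercept. The derivative columns are not orthogonalized against the task
#' columns.
#'
#' @inheritParams condition_regressors
#'
#' @return An object of class `design_matrix`: a list with the numeric
#'   `matrix` (time x regressor, columns named `<condition>`,
#'   `<condition>_derivative`, `intercept`), `tr_s`, `conditions`, and the
#'   task-column indices `task_cols`.
#' @examples
#' ev <- data.frame(onset = 10, duration = 16, trial_type = "fingers")
#' X <- build_design_matrix(ev, n_timepoints = 40, tr_s = 2)
#' colnames(X$matrix)
#' @export
build_design_matrix <- function(events, n_timepoints, tr_s,
                                hrf = hrf_params(), conditions = NULL) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("`events` is empty: at least one block is required", call. = FALSE)
  }
  if (is.null(conditions)) conditions <- unique(events$trial_type)
  task <- condition_regressors(events, n_timepoints, tr_s, hrf, conditions)
  deriv <- apply(task, 2, function(x) c(0, diff(x)) / tr_s)
  X <- cbind(task, deriv, 1)
  colnames(X) <- c(conditions, paste0(conditions, "_derivative"), "intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(matrix = X, tr_s = tr_s, conditions = conditions,
                 task_cols = seq_along(conditions)),
            class = "design_matrix")
}
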