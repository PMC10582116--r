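#' Double-gamma haemodynamic response parameters
#'
#' Parameterizes the canonical haemodynamic response function (HRF) as a
#' difference of two gamma densities: a positive response peak followed by a
#' scaled undershoot. The defaults are the widely used canonical values
#' (peak at 6 s, undershoot at 16 s, unit dispersions, undershoot one sixth
#' of the peak), which fully determine the kernel shape.
#'
#' @param peak_delay_s Delay of the response peak, seconds.
#' @param undershoot_delay_s Delay of the undershoot, seconds; must exceed
#'   `peak_delay_s`.
#' @param peak_dispersion Dispersion (gamma scale) of the peak, seconds.
#' @param undershoot_dispersion Dispersion of the undershoot, seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot, in (0, 1).
#' @param oversample_dt_s Sampling step of the oversampled kernel grid,
#'   seconds. Stimulus regressors are built on this grid before being
#'   sampled at the repetition time.
#' @param duration_s Kernel support, seconds; the kernel has decayed to
#'   (near) zero by the default 32 s.
#'
#' @return An object of class `hrf_params`.
#' @seealso [double_gamma_hrf()], [build_design_matrix()]
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, oversample_dt_s = 0.1,
                       duration_s = 32) {
  stop_if_not_scalar_number(peak_delay_s, "peak_delay_s", positive = TRUE)
  stop_if_not_scalar_number(undershoot_delay_s, "undershoot_delay_s",
                            positive = TRUE)
  stop_if_not_scalar_number(peak_dispersion, "peak_dispersion", positive = TRUE)
  stop_if_not_scalar_number(undershoot_dispersion, "undershoot_dispersion",
                            positive = TRUE)
  stop_if_not_scalar_number(undershoot_ratio, "undershoot_ratio")
  stop_if_not_scalar_number(oversample_dt_s, "oversample_dt_s", positive = TRUE)
  stop_if_not_scalar_number(duration_s, "duration_s", positive = TRUE)
  if (undershoot_delay_s <= peak_delay_s) {
    stop("`undershoot_delay_s` must exceed `peak_delay_s`", call. = FALSE)
  }
  if (undershoot_ratio <= 0 || undershoot_ratio >= 1) {
    stop("`undershoot_ratio` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 oversample_dt_s = oversample_dt_s,
                 duration_s = duration_s),
            class = "hrf_params")
}

#' Sample the double-gamma haemodynamic response kernel
#'
#' Evaluates the canonical double-gamma HRF on its oversampled time grid and
#' scales it to unit peak. With gamma shape parameters above one the kernel
#' vanishes at `t = 0`.
#'
#' @param params An [hrf_params()] object.
#'
#' @return An object of class `hrf_kernel`: a list with `time_s`, `values`
#'   (peak-normalized), and `dt_s`.
#' @examples
#' k <- double_gamma_hrf(hrf_params())
#' max(k$values)       # 1 by construction
#' k$values[1]         # 0 at t = 0
#' @export
double_gamma_hrf <- function(params = hrf_params()) {
  stopifnot(inherits(params, "hrf_params"))
  t <- seq(0, params$duration_s, by = params$oversample_dt_s)
  peak <- stats::dgamma(t, shape = params$peak_delay_s / params$peak_dispersion,
                        scale = params$peak_dispersion)
  under <- stats::dgamma(t, shape = params$undershoot_delay_s /
                           params$undershoot_dispersion,
                         scale = params$undershoot_dispersion)
  h <- peak - params$undershoot_ratio * under
  h <- h / max(h)
  structure(list(time_s = t, values = h, dt_s = params$oversample_dt_s),
            class = "hrf_kernel")
}
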