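#' TFCE parameters
#'
#' Tuning constants for threshold-free cluster enhancement. The defaults —
#' height exponent `H = 2`, extent exponent `E = 0.5`, 100 integration
#' steps, 26-neighbour connectivity — are the established volumetric
#' defaults of the TFCE literature.
#'
#' @param height_exponent Exponent on the threshold height H.
#' @param extent_exponent Exponent on the cluster extent E.
#' @param n_steps Number of integration steps; the step is `max/n_steps`.
#' @param connectivity Voxel neighbourhood: 6 (faces), 18 (+edges), or
#'   26 (+corners).
#'
#' @return An object of class `tfce_params`.
#' @export
tfce_params <- function(height_exponent = 2, extent_exponent = 0.5,
                        n_steps = 100, connectivity = 26) {
  stop_if_not_scalar_number(height_exponent, "height_exponent",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(extent_exponent, "extent_exponent",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(n_steps, "n_steps", positive = TRUE)
  if (!connectivity %in% c(6, 18, 26)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  structure(list(height_exponent = height_exponent,
                 extent_exponent = extent_exponent,
                 n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

# Positive-part TFCE of a 3D map (used directly for one-tailed contrasts).
tfce_positive <- function(stat, mask, params) {
  v <- tfce_positive_cpp(as.double(stat), as.logical(mask),
                         as.integer(dim(stat)),
                         params$extent_exponent, params$height_exponent,
                         params$n_steps, params$connectivity)
  array(v, dim = dim(stat))
}

#' Threshold-free cluster enhancement
#'
#' Enhances a voxel-wise statistic map by integrating, over all thresholds
#' `h` from 0 to the map maximum in steps of `max/n_steps`, the quantity
#' `extent(h)^E * h^H * dh`, where `extent(h)` is the size of the connected
#' supra-threshold component containing the voxel. Positive and negative
#' parts are enhanced separately and recombined with sign, so de-activations
#' are treated symmetrically.
#'
#' @param stat A 3D array of finite statistic values.
#' @param mask A 3D logical array; voxels outside it are ignored (default:
#'   everywhere).
#' @param params A [tfce_params()] object.
#'
#' @return A 3D array of TFCE scores with the sign of the input statistic.
#' @examples
#' m <- array(0, c(5, 5, 5)); m[3, 3, 3] <- 2
#' tfce_transform(m, params = tfce_params(n_steps = 1000))[3, 3, 3]  # ~ 2^3/3
#' @export
tfce_transform <- function(stat, mask = NULL, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  if (length(dim(stat)) != 3L) stop("`stat` must be a 3D array", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(stat))
  check_same_dim(stat, mask, "stat and mask")
  if (any(!is.finite(stat[mask]))) {
    stop("`stat` must be finite inside the mask", call. = FALSE)
  }
  tfce_positive(stat, mask, params) - tfce_positive(-stat, mask, params)
}
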