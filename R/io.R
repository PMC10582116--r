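## File I/O: NIfTI-1 volumes, BIDS-style event TSVs, and generic TSV tables.

validate_events <- function(events) {
  if (!is.data.frame(events)) {
    stop("events must be a data.frame", call. = FALSE)
  }
  for (col in c("onset", "duration", "trial_type")) {
    if (!col %in% names(events)) {
      stop("events table is missing column \"", col, "\"", call. = FALSE)
    }
  }
  if (nrow(events) == 0L) stop("events table is empty", call. = FALSE)
  if (!is.numeric(events$onset) || anyNA(events$onset) ||
        any(events$onset < 0)) {
    stop("column \"onset\" must be non-negative numbers", call. = FALSE)
  }
  if (!is.numeric(events$duration) || anyNA(events$duration) ||
        any(events$duration <= 0)) {
    stop("column \"duration\" must be positive numbers", call. = FALSE)
  }
  invisible(events)
}

#' Read / write a 3D statistic map as NIfTI-1
#'
#' Volumes are written with a diagonal affine of the voxel size and double
#' precision, so a write-then-read round trip reproduces the array
#' bit-exactly.
#'
#' @param map 3D numeric array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return `read_stat_map` returns the 3D array; `write_stat_map` returns
#'   `path` invisibly.
#' @export
write_stat_map <- function(map, path, voxel_size_mm = 2) {
  attr(map, "pixdim") <- rep(voxel_size_mm, 3)
  img <- RNifti::asNifti(map, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Read / write a BIDS-style event table
#'
#' Tab-separated with a header row and columns `onset`, `duration`,
#' `trial_type` (seconds, '.' decimal). Malformed files raise a parse error
#' naming the offending column.
#'
#' @param events `data.frame(onset, duration, trial_type)`.
#' @param path File path (`.tsv`).
#' @return `read_events` returns the validated data.frame; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_events(tab)
}

#' Read / write a generic TSV table
#'
#' UTF-8, tab-separated, '.' decimal, header row.
#'
#' @param table A data.frame.
#' @param path File path.
#' @return `read_table_tsv` returns a data.frame; `write_table_tsv` returns
#'   `path` invisibly.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    encoding = "UTF-8")
}
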