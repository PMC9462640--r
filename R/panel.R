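#' Subject-by-condition scan panel
#'
#' The input container for pattern derivation: a complete subject x ordered
#' condition x in-mask voxel array of (typically standardized fALFF) map
#' values over a common mask.
#'
#' @param data numeric array `subjects x conditions x in-mask voxels`, or a
#'   list of per-subject lists of volumes/`falff_map`s (one per condition).
#' @param subject_ids character vector of subject identifiers.
#' @param condition_labels ordered condition labels (length >= 2); their
#'   order defines the ordinal trend.
#' @param mask logical volume shared by all maps (required when `data` is
#'   an array of in-mask values; taken from the maps otherwise).
#' @return object of class `scan_panel`.
#' @export
scan_panel <- function(data, subject_ids, condition_labels, mask = NULL) {
  if (is.list(data)) {
    stopifnot(!is.null(mask) || inherits(data[[1]][[1]], "falff_map"))
    if (is.null(mask)) mask <- data[[1]][[1]]$mask
    vals <- function(x) {
      v <- if (inherits(x, "falff_map")) x$values else x
      stopifnot(all(dim(v) == dim(mask)))
      v[mask]
    }
    arr <- array(NA_real_, dim = c(length(data), length(data[[1]]),
                                   sum(mask)))
    for (s in seq_along(data))
      for (k in seq_along(data[[s]]))
        arr[s, k, ] <- vals(data[[s]][[k]])
    data <- arr
  }
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[2] < 2L) stop("need at least 2 ordered conditions")
  if (anyNA(data)) stop("panel must be complete (no missing cells)")
  if (!is.null(mask) && sum(mask) != dim(data)[3])
    stop("mask voxel count does not match panel data")
  if (missing(subject_ids) || is.null(subject_ids))
    subject_ids <- sprintf("S%02d", seq_len(dim(data)[1]))
  if (missing(condition_labels) || is.null(condition_labels))
    condition_labels <- sprintf("c%d", seq_len(dim(data)[2]))
  stopifnot(length(subject_ids) == dim(data)[1],
            length(condition_labels) == dim(data)[2])
  structure(list(data = data, subject_ids = subject_ids,
                 condition_labels = condition_labels, mask = mask),
            class = "scan_panel")
}

#' @export
print.scan_panel <- function(x, ...) {
  cat("Scan panel:", dim(x$data)[1], "subjects x", dim(x$data)[2],
      "conditions (", paste(x$condition_labels, collapse = " < "),
      ") x", dim(x$data)[3], "voxels\n")
  invisible(x)
}

## scans-by-voxel matrix view, rows subject-major (all conditions of
## subject 1, then subject 2, ...).
panel_matrix <- function(panel) {
  d <- panel$data
  s <- dim(d)[1]; k <- dim(d)[2]; v <- dim(d)[3]
  m <- matrix(NA_real_, s * k, v)
  for (i in seq_len(s)) m[(i - 1L) * k + seq_len(k), ] <- d[i, , ]
  m
}

#' Restrict a panel to a sub-mask
#'
#' Returns the panel over the voxels of `submask` only, e.g. a single
#' hemisphere for hemispheric pattern derivation. The result is identical
#' to building the panel from maps pre-restricted to `submask`.
#'
#' @param panel a [scan_panel()].
#' @param submask logical volume; must be a subset of the panel mask.
#' @return a [scan_panel()] over the restricted mask.
#' @export
subset_panel <- function(panel, submask) {
  stopifnot(inherits(panel, "scan_panel"), !is.null(panel$mask))
  submask <- array(as.logical(submask), dim = dim(panel$mask))
  if (any(submask & !panel$mask))
    stop("submask must be contained in the panel mask")
  sel <- submask[panel$mask]
  scan_panel(panel$data[, , sel, drop = FALSE], panel$subject_ids,
             panel$condition_labels, mask = submask)
}

#' Split a mask at the first-axis midline
#'
#' @param mask logical volume.
#' @return list with logical volumes `left` (first axis <= midline) and
#'   `right`.
#' @export
split_hemispheres <- function(mask) {
  dims <- dim(mask)
  xs <- slice.index(mask, 1)
  left <- mask & (xs <= dims[1] / 2)
  right <- mask & (xs > dims[1] / 2)
  list(left = left, right = right)
}
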