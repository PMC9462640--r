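#' Topographic profile rating of a single scan
#'
#' Thin wrapper over [predict.ort_cva()] for one scan: raw score =
#' dot(scan - derivation grand mean, weights); standardized score uses the
#' pattern's stored baseline reference.
#'
#' @param scan_map volume array, `falff_map`, or in-mask vector.
#' @param pattern an [ort_cva()] fit.
#' @return list with `raw_score` and `standardized_score`.
#' @export
compute_tpr <- function(scan_map, pattern) {
  stopifnot(inherits(pattern, "ort_cva"))
  p <- predict(pattern, scan_map, type = "both")
  list(raw_score = p$raw_score[1], standardized_score = p$standardized_score[1])
}

#' Score a batch of scans into a longitudinal expression table
#'
#' Applies [compute_tpr()] to every scan of a manifest and assembles the
#' long-format expression score table, ordered by (group, subject,
#' timepoint). Scans that fail to score are dropped with a warning; the
#' table is still produced for the valid rows.
#'
#' @param manifest data frame with columns `subject_id`,
#'   `timepoint_months`, optionally `group` (`"patient"`/`"control"`,
#'   default `"patient"`), and a list-column `scan` holding the maps — or
#'   supply the scans separately via `scans` (list parallel to the rows).
#' @param pattern an [ort_cva()] fit.
#' @param scans optional list of scans, one per manifest row.
#' @return data frame: subject_id, group, timepoint_months, raw_score,
#'   standardized_score.
#' @export
batch_tpr <- function(manifest, pattern, scans = NULL) {
  stopifnot(inherits(pattern, "ort_cva"), is.data.frame(manifest))
  if (is.null(scans)) scans <- manifest$scan
  if (nrow(manifest) == 0L)
    return(data.frame(subject_id = character(0), group = character(0),
                      timepoint_months = numeric(0), raw_score = numeric(0),
                      standardized_score = numeric(0)))
  stopifnot(length(scans) == nrow(manifest))
  grp <- if ("group" %in% names(manifest)) as.character(manifest$group)
  else rep("patient", nrow(manifest))
  rows <- vector("list", nrow(manifest))
  failed <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sc <- tryCatch(compute_tpr(scans[[i]], pattern), error = function(e) e)
    if (inherits(sc, "error")) {
      failed <- c(failed, sprintf("%s/m%g: %s", manifest$subject_id[i],
                                  manifest$timepoint_months[i],
                                  conditionMessage(sc)))
      next
    }
    rows[[i]] <- data.frame(subject_id = as.character(manifest$subject_id[i]),
                            group = grp[i],
                            timepoint_months = manifest$timepoint_months[i],
                            raw_score = sc$raw_score,
                            standardized_score = sc$standardized_score,
                            stringsAsFactors = FALSE)
  }
  if (length(failed) > 0)
    warning("failed to score ", length(failed), " scan(s): ",
            paste(failed, collapse = "; "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[order(out$group, out$subject_id, out$timepoint_months), , drop = FALSE]
}
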