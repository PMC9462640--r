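#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti keeping plain R arrays as the in-memory
#' representation.
#'
#' @param x numeric/logical array (3D or 4D).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param ... passed to [RNifti::writeNifti()].
#' @return `read_volume`: an array; `write_volume`: the path, invisibly.
#' @export
write_volume <- function(x, path, ...) {
  RNifti::writeNifti(RNifti::asNifti(x * 1), path, ...)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  a <- RNifti::readNifti(path)
  array(as.numeric(a), dim = dim(a))
}

#' Write a simulated cohort to disk
#'
#' Writes per-scan NIfTI series, the mask and ground-truth pattern as
#' NIfTI, the clinical table as CSV, and a JSON ground-truth sidecar.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$scans))
    write_volume(cohort$scans[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  write_volume(cohort$mask, file.path(dir, "mask.nii.gz"))
  write_volume(cohort$truth$pattern_map, file.path(dir, "pattern.nii.gz"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  truth <- list(true_expression = cohort$truth$true_expression,
                responder = cohort$truth$responder,
                config = unclass(cohort$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an atlas (labels NIfTI + region lookup TSV)
#'
#' @param atlas result of [make_atlas()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(atlas$labels, file.path(dir, "atlas.nii.gz"))
  utils::write.table(atlas$regions, file.path(dir, "regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a fitted pattern (weights/z-map NIfTI + JSON sidecar)
#'
#' @param fit an [ort_cva()] fit (requires a mask).
#' @param dir output directory.
#' @param zmap optional result of [bootstrap_zmap()] to save alongside.
#' @param permutation optional result of [permutation_test()].
#' @return `dir`, invisibly.
#' @export
write_pattern <- function(fit, dir, zmap = NULL, permutation = NULL) {
  stopifnot(inherits(fit, "ort_cva"), !is.null(fit$mask))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(coef(fit, as_volume = TRUE), file.path(dir, "weights.nii.gz"))
  if (!is.null(zmap)) {
    zv <- zmap$zmap
    zv[!is.finite(zv)] <- sign(zv[!is.finite(zv)]) * 1e6
    write_volume(zv, file.path(dir, "zmap.nii.gz"))
  }
  side <- list(subject_ids = fit$subject_ids,
               condition_labels = fit$condition_labels,
               derivation_scores = fit$derivation_scores,
               violator_count = fit$violator_count,
               selected_bias = fit$selected_bias, pc_k = fit$pc_k,
               score_reference = as.list(fit$score_reference),
               sign_convention = fit$sign_convention,
               options = fit$options,
               permutation_p = if (!is.null(permutation)) permutation$p,
               software = paste0("ortcva ",
                                 as.character(utils::packageVersion("ortcva"))))
  jsonlite::write_json(side, file.path(dir, "pattern.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a regions-by-genes expression table
#'
#' @param expression regions x genes matrix (rownames = region ids).
#' @param path TSV path; first column `region_id`.
#' @return `read_gene_matrix`: a matrix with region-id rownames.
#' @export
write_gene_matrix <- function(expression, path) {
  df <- data.frame(region_id = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gene_matrix
#' @export
read_gene_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
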