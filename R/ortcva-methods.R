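#' @export
print.ort_cva <- function(x, ...) {
  S <- length(x$subject_ids); K <- length(x$condition_labels)
  cat("Ordinal-trend covariance pattern\n")
  cat(sprintf("  %d subjects x %d conditions (%s), %d voxels\n", S, K,
              paste(x$condition_labels, collapse = " < "),
              length(x$weights)))
  cat(sprintf("  retained PCs: %d; covariance mixing weight: %g\n",
              x$pc_k, x$selected_bias))
  cat(sprintf("  ordinal-trend violators: %d / %d\n", x$violator_count, S))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p: %.4g\n", x$permutation_p))
  invisible(x)
}

#' @export
summary.ort_cva <- function(object, ...) {
  cm <- colMeans(object$derivation_scores)
  ans <- list(fit = object, condition_means = cm,
              change = object$derivation_scores[, ncol(object$derivation_scores)] -
                object$derivation_scores[, 1])
  class(ans) <- "summary.ort_cva"
  ans
}

#' @export
print.summary.ort_cva <- function(x, ...) {
  print(x$fit)
  cat("  condition mean expression:\n")
  print(round(x$condition_means, 4))
  cat(sprintf("  mean last-vs-first change: %.4f (SD %.4f)\n",
              mean(x$change), stats::sd(x$change)))
  invisible(x)
}

#' Voxel weights of a fitted pattern
#'
#' @param object an [ort_cva()] fit.
#' @param as_volume return a full volume (0 outside mask) instead of the
#'   in-mask vector.
#' @param ... unused.
#' @return numeric vector of unit-norm in-mask voxel weights, or a volume.
#' @export
coef.ort_cva <- function(object, as_volume = FALSE, ...) {
  if (!as_volume) return(object$weights)
  stopifnot(!is.null(object$mask))
  v <- array(0, dim = dim(object$mask))
  v[object$mask] <- object$weights
  v
}

#' @export
fitted.ort_cva <- function(object, ...) object$derivation_scores

#' Score new scans with a fitted pattern (topographic profile rating)
#'
#' Forward-applies the derived pattern: the raw score of a scan is the dot
#' product of its grand-mean-removed map with the pattern weights; the
#' standardized score anchors it to the derivation baseline scores
#' (`(raw - reference mean) / reference SD`).
#'
#' @param object an [ort_cva()] fit.
#' @param newdata a volume array, a `falff_map`, an in-mask numeric vector,
#'   a scans-by-voxel matrix, or a list of any of these.
#' @param type `"both"` (data frame), `"raw"`, or `"standardized"`.
#' @param ... unused.
#' @return numeric vector, or data frame with `raw_score` and
#'   `standardized_score`.
#' @export
predict.ort_cva <- function(object, newdata,
                            type = c("both", "raw", "standardized"), ...) {
  type <- match.arg(type)
  m <- tpr_matrix(object, newdata)
  raw <- as.numeric(sweep(m, 2, object$grand_mean) %*% object$weights)
  std <- (raw - object$score_reference["mean"]) / object$score_reference["sd"]
  switch(type, raw = raw, standardized = unname(std),
         both = data.frame(raw_score = raw, standardized_score = unname(std)))
}

## Coerce scans of assorted shapes into a scans-by-voxel matrix matching
## the pattern's mask, with informative dimension errors.
tpr_matrix <- function(object, newdata) {
  V <- length(object$weights)
  one <- function(x) {
    if (inherits(x, "falff_map")) {
      if (!is.null(object$mask) && !identical(dim(x$mask), dim(object$mask)))
        stop("scan mask dims (", paste(dim(x$mask), collapse = "x"),
             ") do not match pattern mask (",
             paste(dim(object$mask), collapse = "x"), ")")
      if (!is.null(object$mask) && !identical(which(x$mask), which(object$mask)))
        stop("scan mask does not match the pattern mask")
      return(x$values[object$mask])
    }
    if (is.array(x) && length(dim(x)) == 3L) {
      if (is.null(object$mask))
        stop("pattern has no mask; supply in-mask vectors")
      if (!identical(dim(x), dim(object$mask)))
        stop("scan dims (", paste(dim(x), collapse = "x"),
             ") do not match pattern mask (",
             paste(dim(object$mask), collapse = "x"), ")")
      return(x[object$mask])
    }
    x <- as.numeric(x)
    if (length(x) != V)
      stop("scan has ", length(x), " values; pattern expects ", V)
    x
  }
  if (is.list(newdata) && !inherits(newdata, "falff_map")) {
    m <- t(vapply(newdata, one, numeric(V)))
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) != V)
      stop("scan matrix has ", ncol(newdata), " columns; pattern expects ", V)
    m <- newdata
  } else {
    m <- matrix(one(newdata), nrow = 1)
  }
  m
}

#' Plot derivation expression trajectories
#'
#' Spaghetti plot of per-subject pattern expression across the ordered
#' conditions, with the condition means overlaid; violators drawn dashed.
#'
#' @param x an [ort_cva()] fit.
#' @param standardized plot baseline-anchored scores instead of raw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ort_cva <- function(x, standardized = TRUE, ...) {
  sc <- x$derivation_scores
  if (standardized)
    sc <- (sc - x$score_reference["mean"]) / x$score_reference["sd"]
  viol <- apply(sc, 1, function(v) any(diff(v) <= 0))
  graphics::matplot(t(sc), type = "b", pch = 16, lty = ifelse(viol, 2, 1),
                    col = ifelse(viol, "tomato", "grey40"),
                    xaxt = "n", xlab = "condition",
                    ylab = if (standardized) "expression (baseline-anchored)"
                    else "expression", ...)
  graphics::axis(1, at = seq_len(ncol(sc)), labels = colnames(sc))
  graphics::lines(seq_len(ncol(sc)), colMeans(sc), lwd = 3, col = "black")
  invisible(x)
}
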