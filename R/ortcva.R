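## Core ordinal-trend CVA fit in an arbitrary orthonormal coordinate basis.
##
## The public interface reduces the scans-by-voxel matrix to its row-space
## coordinates once (one thin SVD); every refit (bias-grid search,
## permutation, bootstrap, leave-one-out) then runs in at most
## n_scans-dimensional coordinates, which leaves all results bit-identical
## to fitting in voxel space while making resampling inference cheap.
##
## Steps per candidate covariance-mixing weight w:
##   Y  = scans minus grand mean; W = scans minus each subject's mean
##   Zw = w*Y + (1-w)*W, PCA by SVD, retain PCs by the retention rule
##   canonical direction in PC-score space: whitened (within-subject,
##   within-condition residual covariance) regression of condition means on
##   condition rank; map back, unit-normalize, orient so mean expression
##   increases along the condition order
## The w minimizing the violator count wins; ties go to the larger paired
## t statistic of the last-vs-first expression change.

retained_k <- function(d, rank, retention, n_subjects) {
  if (retention >= 1) {
    k <- as.integer(retention)
    if (k > rank) stop("PC retention (", k, ") larger than rank (", rank, ")")
    return(k)
  }
  cum <- cumsum(d^2) / sum(d^2)
  k <- which(cum >= retention)[1]
  min(k, n_subjects - 1L, rank)
}

fit_core <- function(C, subj, cond, retention, bias_grid, shrink = 0.1) {
  n <- nrow(C)
  S <- max(subj)
  K <- max(cond)
  m0 <- colMeans(C)
  Y <- sweep(C, 2, m0)
  subj_mean <- rowsum(C, subj) / K
  W <- C - subj_mean[subj, , drop = FALSE]
  rr <- seq_len(K) - (K + 1) / 2
  best <- NULL
  for (w in bias_grid) {
    Z <- w * Y + (1 - w) * W
    sv <- svd(Z)
    rank <- sum(sv$d > max(sv$d) * 1e-8)
    if (rank == 0L) next
    k <- retained_k(sv$d, rank, retention, S)
    Vk <- sv$v[, seq_len(k), drop = FALSE]
    Tm <- Z %*% Vk
    Ts <- rowsum(Tm, subj) / K
    Tc <- rowsum(Tm, cond) / S
    Tg <- colMeans(Tm)
    Rres <- Tm - Ts[subj, , drop = FALSE] - Tc[cond, , drop = FALSE] +
      matrix(Tg, n, k, byrow = TRUE)
    Sw <- crossprod(Rres) / ((S - 1) * (K - 1))
    d_dir <- as.numeric(crossprod(Tc, rr))
    tr_sw <- sum(diag(Sw))
    scale0 <- sum(Tm^2) / n
    degenerate <- tr_sw <= 1e-12 * max(scale0, .Machine$double.xmin)
    if (degenerate) {
      if (sum(d_dir^2) <= 1e-20 * max(scale0, .Machine$double.xmin))
        stop("degenerate panel: zero within-subject variance and no ",
             "between-condition separation")
      a <- d_dir
    } else {
      ## shrinkage-regularized whitening: guards against near-zero-variance
      ## PC directions blowing up the canonical direction
      a <- solve((1 - shrink) * Sw + diag(shrink * tr_sw / k, k), d_dir)
    }
    u <- as.numeric(Vk %*% a)
    nu <- sqrt(sum(u^2))
    if (nu == 0) next
    u <- u / nu
    e <- as.numeric(Y %*% u)
    slope <- sum(rr * (rowsum(e, cond) / S))
    if (slope < 0) { u <- -u; e <- -e }
    ord <- order(subj, cond)
    em <- matrix(e[ord], nrow = K)           # conditions x subjects
    viol <- sum(apply(em, 2, function(x) any(diff(x) <= 0)))
    diffs <- em[K, ] - em[1, ]
    sdd <- stats::sd(diffs)
    tstat <- if (sdd > 0) mean(diffs) / (sdd / sqrt(S)) else
      sign(mean(diffs)) * Inf
    cand <- list(u = u, e = e, violators = viol, bias = w, k = k,
                 tstat = tstat, degenerate = degenerate)
    if (is.null(best) || viol < best$violators ||
        (viol == best$violators && tstat > best$tstat)) best <- cand
  }
  if (is.null(best)) stop("degenerate panel: no usable covariance mixture")
  best
}

#' Derive an ordinal-trend spatial covariance pattern
#'
#' Fits the within-subject covariance pattern whose subject expression
#' increases across the panel's ordered conditions in as many subjects as
#' possible: grand-mean removal, a one-parameter family mixing the full and
#' the subject-centered covariance, PCA, and a whitened canonical direction
#' maximizing between-condition separation relative to within-subject,
#' within-condition variation. The mixing weight minimizing the number of
#' ordinal-trend violators is selected. Expression of a scan is the dot
#' product of its grand-mean-removed map with the unit-norm voxel weights.
#'
#' @param panel a [scan_panel()] (>= 4 subjects, >= 2 ordered conditions,
#'   complete).
#' @param n_components PC retention: a fraction in (0,1) retains the
#'   smallest k with that cumulative variance (capped at n_subjects - 1);
#'   an integer >= 1 fixes k.
#' @param bias_grid candidate covariance-mixing weights in \[0, 1\]
#'   (1 = full covariance, 0 = subject-centered).
#' @param shrink shrinkage weight in \[0, 1\] mixing the within-scatter
#'   with an isotropic target before whitening the canonical direction;
#'   stabilizes against near-singular within-covariance estimates.
#' @param log_transform take natural logs of the panel values before
#'   fitting (requires strictly positive data).
#' @param seed master seed stored with the fit; inference functions derive
#'   their default seeds from it.
#' @return object of class `ort_cva` with elements `weights` (unit-norm
#'   in-mask voxel weights), `grand_mean`, `derivation_scores`
#'   (subject x condition), `violator_count`, `selected_bias`, `pc_k`,
#'   `score_reference` (baseline mean/SD), `mask`, ids/labels, and options.
#' @export
ort_cva <- function(panel, n_components = 0.5,
                    bias_grid = c(0, 0.25, 0.5, 0.75, 1),
                    shrink = 0.1, log_transform = FALSE, seed = 1L) {
  stopifnot(inherits(panel, "scan_panel"))
  S <- dim(panel$data)[1]; K <- dim(panel$data)[2]; V <- dim(panel$data)[3]
  if (S < 4L) stop("need at least 4 subjects")
  if (V < 2L) stop("need at least 2 voxels")
  if (any(bias_grid < 0 | bias_grid > 1)) stop("bias_grid values must be in [0,1]")
  X <- panel_matrix(panel)
  if (log_transform) {
    if (any(X <= 0)) stop("log_transform requires strictly positive values")
    X <- log(X)
  }
  subj <- rep(seq_len(S), each = K)
  cond <- rep(seq_len(K), S)
  m_vox <- colMeans(X)
  Yv <- sweep(X, 2, m_vox)
  sv <- svd(Yv)
  keep <- sv$d > max(sv$d) * 1e-10
  if (!any(keep)) stop("degenerate panel: all scans identical")
  B <- sv$v[, keep, drop = FALSE]                       # V x r
  C <- sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], nrow = sum(keep))                  # n x r
  fit <- fit_core(C, subj, cond, n_components, bias_grid, shrink)
  w_vox <- as.numeric(B %*% fit$u)
  scores <- matrix(fit$e[order(subj, cond)], nrow = K)  # cond x subj
  scores <- t(scores)
  dimnames(scores) <- list(panel$subject_ids, panel$condition_labels)
  ref <- c(mean = mean(scores[, 1]), sd = stats::sd(scores[, 1]))
  structure(list(
    weights = w_vox, grand_mean = m_vox,
    derivation_scores = scores,
    violator_count = fit$violators,
    permutation_p = NULL, zmap = NULL,
    selected_bias = fit$bias, pc_k = fit$k,
    degenerate_within = fit$degenerate,
    score_reference = ref, sign_convention = "increasing",
    mask = panel$mask,
    subject_ids = panel$subject_ids,
    condition_labels = panel$condition_labels,
    options = list(n_components = n_components, bias_grid = bias_grid,
                   shrink = shrink,
                   log_transform = log_transform, seed = as.integer(seed)),
    internal = list(B = B, C = C, subj = subj, cond = cond)
  ), class = "ort_cva")
}

#' Count ordinal-trend violators
#'
#' A violator is a subject whose expression sequence across the ordered
#' conditions is not strictly increasing; ties count as violations.
#'
#' @param scores numeric matrix or data frame, subjects in rows, ordered
#'   conditions in columns (>= 2).
#' @return integer count.
#' @export
count_violators <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least 2 ordered conditions")
  sum(apply(scores, 1, function(x) any(diff(x) <= 0)))
}

#' Permutation test of the ordinal trend
#'
#' Shuffles condition labels independently within each subject, re-runs the
#' complete fit (including bias-grid selection) per draw, and compares the
#' observed violator count against the null counts with the add-one
#' estimator: `p = (1 + #\{null at least as extreme\}) /
#' (1 + n_permutations)`. Because the violator count is integer-valued and
#' its null distribution is concentrated on few values, ties are broken by
#' the paired t statistic of the last-vs-first expression change (the same
#' tie-break the fit itself uses): a null draw counts as at least as
#' extreme when its violator count is lower, or equal with a t statistic at
#' least as large.
#'
#' @param object an [ort_cva()] fit.
#' @param n_permutations number of label-shuffle draws (>= 100).
#' @param seed RNG seed (default: fit's master seed + 1).
#' @param ... unused.
#' @return list: `p`, `observed`, `observed_t`, `null_distribution`
#'   (integer vector of null violator counts), `null_t`, `n_permutations`.
#' @export
permutation_test <- function(object, ...) UseMethod("permutation_test")

#' @rdname permutation_test
#' @export
permutation_test.ort_cva <- function(object, n_permutations = 1000L,
                                     seed = object$options$seed + 1L, ...) {
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  it <- object$internal
  S <- length(object$subject_ids); K <- length(object$condition_labels)
  obs_fit <- fit_core(it$C, it$subj, it$cond, object$options$n_components,
                      object$options$bias_grid, object$options$shrink)
  set.seed(seed)
  blocks <- split(seq_len(S * K), it$subj)
  null_counts <- integer(n_permutations)
  null_t <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    idx <- unlist(lapply(blocks, function(ii) ii[sample.int(length(ii))]),
                  use.names = FALSE)
    f <- fit_core(it$C[idx, , drop = FALSE], it$subj, it$cond,
                  object$options$n_components, object$options$bias_grid,
                  object$options$shrink)
    null_counts[b] <- f$violators
    null_t[b] <- f$tstat
  }
  extreme <- null_counts < obs_fit$violators |
    (null_counts == obs_fit$violators & null_t >= obs_fit$tstat)
  p <- (1 + sum(extreme)) / (1 + n_permutations)
  list(p = p, observed = object$violator_count, observed_t = obs_fit$tstat,
       null_distribution = null_counts, null_t = null_t,
       n_permutations = n_permutations)
}

#' Bootstrap voxel-reliability z-map
#'
#' Resamples subjects with replacement, refits the pattern per draw
#' (sign-aligned to the full-sample weights), and reports
#' `z(v) = full-sample weight(v) / bootstrap SD of weight(v)`. Voxels
#' outside the mask are 0. Draws with fewer than 3 distinct subjects are
#' redrawn (counted in `n_redraws`).
#'
#' @param object an [ort_cva()] fit.
#' @param n_bootstrap number of resamplings (>= 100).
#' @param seed RNG seed (default: fit's master seed + 2).
#' @param ... unused.
#' @return list: `zmap` (volume if the fit has a mask, else in-mask
#'   vector), `z` (in-mask vector), `boot_sd`, `n_redraws`, `n_bootstrap`.
#' @export
bootstrap_zmap <- function(object, ...) UseMethod("bootstrap_zmap")

#' @rdname bootstrap_zmap
#' @export
bootstrap_zmap.ort_cva <- function(object, n_bootstrap = 500L,
                                   seed = object$options$seed + 2L, ...) {
  if (n_bootstrap < 100L) stop("n_bootstrap must be >= 100")
  it <- object$internal
  S <- length(object$subject_ids); K <- length(object$condition_labels)
  set.seed(seed)
  u_full <- crossprod(it$B, object$weights)
  U <- matrix(NA_real_, ncol(it$B), n_bootstrap)
  n_redraws <- 0L
  for (b in seq_len(n_bootstrap)) {
    repeat {
      sidx <- sample.int(S, S, replace = TRUE)
      if (length(unique(sidx)) >= 3L) break
      n_redraws <- n_redraws + 1L
    }
    rows <- as.vector(t(outer(sidx, seq_len(K), function(s, k) (s - 1L) * K + k)))
    f <- fit_core(it$C[rows, , drop = FALSE], it$subj, it$cond,
                  object$options$n_components, object$options$bias_grid,
                  object$options$shrink)
    u <- f$u
    if (sum(u * u_full) < 0) u <- -u
    U[, b] <- u
  }
  Wb <- it$B %*% U                                     # V x n_bootstrap
  sdv <- sqrt(pmax(0, rowMeans(Wb^2) - rowMeans(Wb)^2) *
                n_bootstrap / (n_bootstrap - 1))
  ## float-level weights/SDs count as exact zeros so that noise-free
  ## panels threshold to the planted support exactly
  eps <- 1e-10 * max(abs(object$weights))
  w0 <- ifelse(abs(object$weights) < eps, 0, object$weights)
  s0 <- ifelse(sdv < eps, 0, sdv)
  z <- ifelse(s0 > 0, w0 / s0, ifelse(w0 == 0, 0, sign(w0) * Inf))
  zvol <- NULL
  if (!is.null(object$mask)) {
    zvol <- array(0, dim = dim(object$mask))
    zvol[object$mask] <- z
  }
  list(zmap = if (is.null(zvol)) z else zvol, z = z, boot_sd = sdv,
       n_redraws = n_redraws, n_bootstrap = n_bootstrap)
}

#' Leave-one-out validation of a pattern
#'
#' Refits the pattern with each subject held out, scores the held-out
#' subject's scans with the fold's pattern, and reports the voxel-wise
#' Pearson correlation matrix between fold patterns (sign-aligned to the
#' full-sample fit).
#'
#' @param object an [ort_cva()] fit on >= 5 subjects.
#' @param ... unused.
#' @return list: `patterns` (voxels x folds matrix),
#'   `pattern_correlations` (folds x folds, unit diagonal),
#'   `heldout_scores` (data frame: subject_id, condition, raw_score).
#' @export
loo_validation <- function(object, ...) UseMethod("loo_validation")

#' @rdname loo_validation
#' @export
loo_validation.ort_cva <- function(object, ...) {
  it <- object$internal
  S <- length(object$subject_ids); K <- length(object$condition_labels)
  if (S < 5L) stop("leave-one-out needs at least 5 subjects")
  u_full <- crossprod(it$B, object$weights)
  P <- matrix(NA_real_, nrow(it$B), S,
              dimnames = list(NULL, object$subject_ids))
  held <- vector("list", S)
  for (s in seq_len(S)) {
    keep <- it$subj != s
    f <- tryCatch(
      fit_core(it$C[keep, , drop = FALSE], rep(seq_len(S - 1L), each = K),
               it$cond[keep], object$options$n_components,
               object$options$bias_grid, object$options$shrink),
      error = function(e) stop("leave-one-out fold for subject ",
                               object$subject_ids[s], " failed: ",
                               conditionMessage(e)))
    u <- f$u
    if (sum(u * u_full) < 0) u <- -u
    P[, s] <- as.numeric(it$B %*% u)
    m_fold <- colMeans(it$C[keep, , drop = FALSE])
    e_out <- sweep(it$C[!keep, , drop = FALSE], 2, m_fold) %*% u
    held[[s]] <- data.frame(subject_id = object$subject_ids[s],
                            condition = object$condition_labels,
                            raw_score = as.numeric(e_out),
                            stringsAsFactors = FALSE)
  }
  list(patterns = P, pattern_correlations = stats::cor(P),
       heldout_scores = do.call(rbind, held))
}
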