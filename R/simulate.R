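#' Cohort configuration for the synthetic generator
#'
#' Bundles and validates the parameters of a simulated treatment cohort:
#' paired (or longitudinal) resting-state scans in which a planted spatial
#' pattern's subject expression increases after treatment in a configurable
#' fraction of subjects, together with anticorrelated tremor ratings.
#'
#' Defaults emulate a 24-patient thalamotomy cohort followed over months
#' with a strong treatment effect: most subjects' pattern expression rises
#' post-operatively and the paired effect size of the expression change is
#' of the order reported for thalamotomy cohorts (|d| in the 3-4 range).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param timepoints months at which scans exist; strictly increasing,
#'   must include 0 (baseline).
#' @param grid_dims integer length-3 voxel grid dimensions.
#' @param tr repetition time in seconds.
#' @param n_volumes frames per 4D series (> 10).
#' @param responder_fraction fraction of subjects whose expression increases
#'   with time; the rest stay flat.
#' @param effect_size expression increase per month (pattern units) in
#'   responders.
#' @param noise_sd SD of white voxelwise noise added to every frame.
#' @param baseline_amp baseline amplitude of the in-band oscillation.
#' @param expr_sd SD of the subject-level baseline expression.
#' @param clinical_noise_sd SD of additive noise on clinical scores.
#' @param seed RNG seed; identical configs give bit-identical cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24L,
                          timepoints = c(0, 6),
                          grid_dims = c(16L, 16L, 16L),
                          tr = 2,
                          n_volumes = 120L,
                          responder_fraction = 0.9,
                          effect_size = 0.5,
                          noise_sd = 0.1,
                          baseline_amp = 1,
                          expr_sd = 0.3,
                          clinical_noise_sd = 1,
                          seed = 1L) {
  stopifnot(length(grid_dims) == 3L, n_volumes > 10L, tr > 0)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must lie in [0, 1]")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (!0 %in% timepoints) stop("timepoints must include 0 (baseline)")
  if (any(grid_dims < 8L))
    stop("grid too small to hold the pattern support; need each dimension >= 8")
  structure(list(
    n_subjects = as.integer(n_subjects), timepoints = timepoints,
    grid_dims = as.integer(grid_dims), tr = tr,
    n_volumes = as.integer(n_volumes),
    responder_fraction = responder_fraction, effect_size = effect_size,
    noise_sd = noise_sd, baseline_amp = baseline_amp, expr_sd = expr_sd,
    clinical_noise_sd = clinical_noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

## Ellipsoid brain-like mask; semi-axes 0.45 * grid dimension.
default_mask <- function(grid_dims) {
  ctr <- (grid_dims + 1) / 2
  ax <- 0.45 * grid_dims
  g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                   z = seq_len(grid_dims[3]))
  r2 <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2
  array(r2 <= 1, dim = grid_dims)
}

#' Planted ground-truth pattern map
#'
#' Deterministic two-lobed Gaussian pattern (one positive, one negative
#' lobe) with compact support inside the mask, unit Euclidean norm over
#' in-mask voxels and exact zeros outside its support.
#'
#' @param grid_dims length-3 grid dimensions.
#' @param mask logical volume; default ellipsoid mask.
#' @return volume array of voxel weights.
#' @export
make_pattern <- function(grid_dims, mask = default_mask(grid_dims)) {
  ctr <- (grid_dims + 1) / 2
  c1 <- ctr + c(-0.18, -0.12, 0.10) * grid_dims
  c2 <- ctr + c(0.18, 0.14, -0.08) * grid_dims
  sg <- max(1.2, grid_dims[1] / 10)
  g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                   z = seq_len(grid_dims[3]))
  d1 <- (g$x - c1[1])^2 + (g$y - c1[2])^2 + (g$z - c1[3])^2
  d2 <- (g$x - c2[1])^2 + (g$y - c2[2])^2 + (g$z - c2[3])^2
  p <- exp(-d1 / (2 * sg^2)) - 0.8 * exp(-d2 / (2 * sg^2))
  p[abs(p) < 1e-3 * max(abs(p))] <- 0
  p <- array(p, dim = grid_dims)
  p[!mask] <- 0
  p / sqrt(sum(p^2))
}

## Static smooth "anatomical" profile modulating the baseline low-frequency
## amplitude across voxels. Shared by every scan of a cohort, it gives the
## maps the large stable spatial structure real fALFF maps have (so per-map
## standardization is driven by anatomy, not by the planted signal), and
## cancels exactly in within-subject difference maps. When a pattern and
## mask are supplied the profile is orthogonalized against the pattern over
## the in-mask voxels, so the planted ground truth stays identifiable under
## per-map standardization.
make_background <- function(grid_dims, amplitude = 0.35, pattern = NULL,
                            mask = NULL) {
  g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                   z = seq_len(grid_dims[3]))
  u <- sweep(as.matrix(g), 2, grid_dims, "/")
  h <- cos(2 * pi * u[, 1]) + 0.8 * sin(2 * pi * u[, 2]) +
    0.6 * cos(2 * pi * (u[, 3] + u[, 1]))
  h <- h / stats::sd(h) * amplitude
  h <- array(pmax(-0.6, pmin(0.6, h)), dim = grid_dims)
  if (!is.null(pattern) && !is.null(mask)) {
    p <- pattern[mask]
    h[mask] <- h[mask] - sum(h[mask] * p) / sum(p^2) * p
  }
  h
}

## Snap a target frequency (Hz) onto the DFT grid of an n-frame series so
## that each oscillation occupies exactly one spectral bin.
snap_freq <- function(f, n, tr) {
  k <- max(1L, round(f * n * tr))
  k / (n * tr)
}

## Non-noise part of the cohort: responders, baseline expressions, phases.
## Consumes RNG in a fixed order so that series- and map-level generators
## produce bit-identical cohorts from the same config.
cohort_plan <- function(config) {
  n <- config$n_subjects
  tp <- config$timepoints
  n_resp <- round(config$responder_fraction * n)
  responder <- rep(FALSE, n)
  responder[sample.int(n, n_resp)] <- TRUE
  b <- stats::rnorm(n, 0, config$expr_sd)
  expr <- outer(b, rep(1, length(tp))) +
    outer(ifelse(responder, config$effect_size, 0), tp)
  dimnames(expr) <- list(sprintf("S%02d", seq_len(n)), as.character(tp))
  phases <- matrix(stats::runif(n * 5L, 0, 2 * pi), n, 5L)
  list(responder = responder, expression = expr, phases = phases,
       subject_ids = rownames(expr))
}

## Clinical score table from true expression; scores anticorrelated with
## expression, truncated at zero, total = A + B + C.
clinical_from_expression <- function(expr, clinical_noise_sd) {
  subj <- rownames(expr); tp <- as.numeric(colnames(expr))
  long <- expand.grid(subject_id = subj, timepoint_months = tp,
                      stringsAsFactors = FALSE)
  e <- expr[cbind(match(long$subject_id, subj),
                  match(long$timepoint_months, tp))]
  ns <- nrow(long)
  noise <- matrix(stats::rnorm(4L * ns, 0, clinical_noise_sd), ns, 4L)
  long$hand_tremor <- pmax(0, 16 - 4.5 * e + noise[, 1])
  long$crst_a <- pmax(0, 20 - 4.0 * e + noise[, 2])
  long$crst_b <- pmax(0, 20 - 3.0 * e + noise[, 3])
  long$crst_c <- pmax(0, 20 - 4.0 * e + noise[, 4])
  long$crst_total <- long$crst_a + long$crst_b + long$crst_c
  long[order(long$subject_id, long$timepoint_months), ]
}

## One 4D series for a given expression value. The in-band amplitude is
## baseline_amp + expression * pattern(v); a deterministic out-of-band pair
## carries the complementary amplitude so the total spectral amplitude is
## constant, making fALFF exactly affine in the planted expression.
simulate_series_one <- function(expression, pattern, config, phase,
                                background = 0) {
  dims <- config$grid_dims
  n <- config$n_volumes
  tt <- (seq_len(n) - 1L) * config$tr
  f_low <- vapply(c(0.02, 0.04, 0.06), snap_freq, 0, n = n, tr = config$tr)
  f_high <- vapply(c(0.15, 0.20), snap_freq, 0, n = n, tr = config$tr)
  lowsum <- rowSums(vapply(seq_along(f_low), function(k)
    sin(2 * pi * f_low[k] * tt + phase[k]), numeric(n)))
  highsum <- rowSums(vapply(seq_along(f_high), function(k)
    sin(2 * pi * f_high[k] * tt + phase[3L + k]), numeric(n)))
  a_low <- pmax(0, config$baseline_amp * (1 + as.vector(background)) +
                  expression * as.vector(pattern))
  a_high <- pmax(0, 2 * config$baseline_amp - a_low)
  nv <- prod(dims)
  m <- tcrossprod(cbind(lowsum, highsum), cbind(a_low / 3, a_high / 2))
  if (config$noise_sd > 0)
    m <- m + matrix(stats::rnorm(n * nv, 0, config$noise_sd), n, nv)
  array(t(m), dim = c(dims, n))
}

#' Simulate a complete synthetic cohort
#'
#' Generates per-subject, per-timepoint 4D resting-state series carrying a
#' planted spatial covariance pattern, a brain mask, the ground truth
#' (pattern map and subject-by-timepoint expression) and a clinical score
#' table (hand tremor plus CRST subscores) anticorrelated with expression.
#'
#' @param config a [cohort_config()].
#' @return list with elements `scans` (named list of 4D arrays, one per
#'   subject-timepoint, names `"<subject>_m<months>"`), `mask`, `truth`
#'   (list: `pattern_map`, `true_expression`, `responder`), `clinical`
#'   (long data frame) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  mask <- default_mask(config$grid_dims)
  pattern <- make_pattern(config$grid_dims, mask)
  background <- make_background(config$grid_dims, pattern = pattern, mask = mask)
  plan <- cohort_plan(config)
  clinical <- clinical_from_expression(plan$expression, config$clinical_noise_sd)
  scans <- list()
  for (s in seq_len(config$n_subjects)) {
    for (j in seq_along(config$timepoints)) {
      nm <- sprintf("%s_m%g", plan$subject_ids[s], config$timepoints[j])
      scans[[nm]] <- simulate_series_one(plan$expression[s, j], pattern,
                                         config, plan$phases[s, ], background)
    }
  }
  list(scans = scans, mask = mask,
       truth = list(pattern_map = pattern,
                    true_expression = plan$expression,
                    responder = plan$responder),
       clinical = clinical, config = config)
}

#' Simulate a cohort and return its fALFF scan panel directly
#'
#' Memory-light variant of [simulate_cohort()]: generates each 4D series,
#' reduces it immediately to a (optionally standardized) fALFF map, and
#' assembles the subject-by-condition panel used for pattern derivation.
#' Bit-identical ground truth and clinical table to [simulate_cohort()]
#' under the same config.
#'
#' @param config a [cohort_config()].
#' @param standardize per-map standardization before the panel:
#'   `"zscore_in_mask"` (default), `"divide_by_mask_mean"`, or `"none"`.
#' @param band fALFF band in Hz.
#' @return list: `panel` (a [scan_panel()] over all timepoints), `truth`,
#'   `clinical`, `mask`, `config`.
#' @export
simulate_falff_panel <- function(config, standardize = "zscore_in_mask",
                                 band = c(0.01, 0.08)) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  mask <- default_mask(config$grid_dims)
  pattern <- make_pattern(config$grid_dims, mask)
  background <- make_background(config$grid_dims, pattern = pattern, mask = mask)
  plan <- cohort_plan(config)
  clinical <- clinical_from_expression(plan$expression, config$clinical_noise_sd)
  nsub <- config$n_subjects
  ntp <- length(config$timepoints)
  vin <- sum(mask)
  dat <- array(NA_real_, dim = c(nsub, ntp, vin))
  for (s in seq_len(nsub)) {
    for (j in seq_len(ntp)) {
      ser <- simulate_series_one(plan$expression[s, j], pattern, config,
                                 plan$phases[s, ], background)
      fm <- compute_falff(ser, mask, tr = config$tr, band = band)
      if (standardize != "none") fm <- standardize_map(fm, standardize)
      dat[s, j, ] <- fm$values[mask]
    }
  }
  panel <- scan_panel(dat, subject_ids = plan$subject_ids,
                      condition_labels = sprintf("m%g", config$timepoints),
                      mask = mask)
  list(panel = panel,
       truth = list(pattern_map = pattern,
                    true_expression = plan$expression,
                    responder = plan$responder),
       clinical = clinical, mask = mask, config = config)
}

#' Synthetic contiguous atlas parcellation
#'
#' Tiles the in-mask voxels with `n_regions` spatially contiguous integer-
#' labelled regions grown from random seed voxels, split by the first-axis
#' midline into left/right hemispheres (no region straddles the midline).
#'
#' @param grid_dims length-3 grid dimensions.
#' @param n_regions number of regions (>= 2, <= in-mask voxel count).
#' @param seed RNG seed.
#' @param mask logical volume; default ellipsoid mask.
#' @return object of class `atlas`: `labels` (integer volume, 0 outside
#'   mask), `regions` (data frame: region_id, name, hemisphere, n_voxels,
#'   cx, cy, cz), `mask`.
#' @export
make_atlas <- function(grid_dims, n_regions, seed = 1L,
                       mask = default_mask(grid_dims)) {
  if (n_regions < 2L) stop("n_regions must be >= 2")
  nv <- sum(mask)
  if (n_regions > nv) stop("n_regions exceeds in-mask voxel count")
  set.seed(seed)
  dims <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  mid <- dims[1] / 2
  left <- coords[, 1] <= mid
  n_l <- round(n_regions * sum(left) / nv)
  n_l <- min(max(1L, n_l), sum(left), n_regions - 1L)
  n_r <- n_regions - n_l
  if (n_r > sum(!left)) { n_r <- sum(!left); n_l <- n_regions - n_r }
  labels <- array(0L, dim = dims)
  grow <- function(idx_lin, k, label_offset) {
    seeds <- sample(idx_lin, k)
    labels[seeds] <<- label_offset + seq_len(k)
    domain <- array(FALSE, dim = dims); domain[idx_lin] <- TRUE
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    repeat {
      grew <- FALSE
      for (o in sample(nrow(offs))) {
        src <- which(labels > label_offset & domain, arr.ind = TRUE)
        if (nrow(src) == 0L) next
        dst <- sweep(src, 2, offs[o, ], "+")
        ok <- dst[, 1] >= 1 & dst[, 1] <= dims[1] &
          dst[, 2] >= 1 & dst[, 2] <= dims[2] &
          dst[, 3] >= 1 & dst[, 3] <= dims[3]
        src <- src[ok, , drop = FALSE]; dst <- dst[ok, , drop = FALSE]
        dl <- dst[, 1] + (dst[, 2] - 1L) * dims[1] +
          (dst[, 3] - 1L) * dims[1] * dims[2]
        sl <- src[, 1] + (src[, 2] - 1L) * dims[1] +
          (src[, 3] - 1L) * dims[1] * dims[2]
        free <- labels[dl] == 0L & domain[dl]
        if (any(free)) {
          labels[dl[free]] <<- labels[sl[free]]
          grew <- TRUE
        }
      }
      if (!grew) break
    }
  }
  lin <- which(mask)
  grow(lin[left], n_l, 0L)
  grow(lin[!left], n_r, n_l)
  hemi <- c(rep("L", n_l), rep("R", n_r))
  cent <- t(vapply(seq_len(n_regions), function(r) {
    colMeans(coords[labels[lin] == r, , drop = FALSE])
  }, numeric(3)))
  regions <- data.frame(
    region_id = seq_len(n_regions),
    name = sprintf("R%03d_%s", seq_len(n_regions), hemi),
    hemisphere = hemi,
    n_voxels = as.integer(tabulate(labels[lin], n_regions)),
    cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
    stringsAsFactors = FALSE)
  structure(list(labels = labels, regions = regions, mask = mask),
            class = "atlas")
}

#' Synthetic regional gene-expression matrix
#'
#' Builds a regions-by-genes expression table in which `n_causal` genes
#' covary spatially (positively) with a supplied per-region pattern profile
#' and the remaining genes are smooth spatial random fields independent of
#' the pattern.
#'
#' @param atlas an [make_atlas()] result (its centroids set the spatial
#'   smoothness of the noise genes).
#' @param pattern_region_values numeric vector, one value per atlas region.
#' @param n_genes total gene count.
#' @param n_causal number of pattern-coupled genes (`<= n_genes`).
#' @param gene_noise_sd SD of noise added to causal genes (0 gives |r| = 1
#'   with the pattern profile).
#' @param smooth_noise if `TRUE` (default) non-causal genes are spatially
#'   smooth random fields (realistic transcriptomic autocorrelation); if
#'   `FALSE` they are white noise across regions (the exchangeable null
#'   under which shuffle permutation is exactly calibrated).
#' @param seed RNG seed.
#' @return list: `expression` (regions x genes matrix, rownames region ids,
#'   colnames gene ids), `causal_gene_ids`.
#' @export
simulate_gene_expression <- function(atlas, pattern_region_values,
                                     n_genes = 200L, n_causal = 10L,
                                     gene_noise_sd = 0.3, smooth_noise = TRUE,
                                     seed = 1L) {
  stopifnot(inherits(atlas, "atlas"))
  nr <- nrow(atlas$regions)
  if (length(pattern_region_values) != nr)
    stop("pattern_region_values length (", length(pattern_region_values),
         ") does not match atlas region count (", nr, ")")
  if (n_causal > n_genes) stop("n_causal must be <= n_genes")
  set.seed(seed)
  p <- as.numeric(scale(pattern_region_values))
  cent <- as.matrix(atlas$regions[, c("cx", "cy", "cz")])
  cent <- sweep(cent, 2, apply(cent, 2, min))
  rng <- apply(cent, 2, max); rng[rng == 0] <- 1
  cent <- sweep(cent, 2, rng, "/")
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  causal_idx <- if (n_causal > 0) sort(sample.int(n_genes, n_causal)) else integer(0)
  expr <- matrix(NA_real_, nr, n_genes, dimnames = list(
    atlas$regions$region_id, gene_ids))
  for (j in seq_len(n_genes)) {
    if (j %in% causal_idx) {
      a <- stats::runif(1, 0.8, 1.2)
      expr[, j] <- a * p + stats::rnorm(nr, 0, gene_noise_sd)
    } else if (smooth_noise) {
      mu <- matrix(stats::runif(12), 4, 3)
      cf <- stats::rnorm(4)
      g <- rowSums(vapply(1:4, function(m) {
        d2 <- rowSums(sweep(cent, 2, mu[m, ])^2)
        cf[m] * exp(-d2 / (2 * 0.3^2))
      }, numeric(nr)))
      if (stats::sd(g) > 0) g <- as.numeric(scale(g))
      expr[, j] <- g + stats::rnorm(nr, 0, 0.1)
    } else {
      expr[, j] <- stats::rnorm(nr)
    }
  }
  list(expression = expr, causal_gene_ids = gene_ids[causal_idx])
}
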