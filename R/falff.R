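#' Minimal temporal preprocessing of a 4D series
#'
#' Drops initial frames and optionally removes a per-voxel linear trend
#' and/or supplied nuisance regressors by ordinary least squares.
#'
#' @param series 4D array (x, y, z, time).
#' @param n_discard number of initial frames to drop.
#' @param detrend remove a per-voxel least-squares line (intercept+slope)?
#' @param nuisance optional numeric matrix of nuisance regressors, one row
#'   per remaining frame; residuals after regressing these out (with an
#'   intercept) are returned.
#' @return 4D array with `dim(series)[4] - n_discard` frames.
#' @export
preprocess_series <- function(series, n_discard = 0L, detrend = FALSE,
                              nuisance = NULL) {
  stopifnot(length(dim(series)) == 4L)
  nt <- dim(series)[4]
  if (n_discard >= nt) stop("n_discard must be smaller than the frame count")
  if (n_discard > 0L) series <- series[, , , -(seq_len(n_discard)), drop = FALSE]
  nt <- dim(series)[4]
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nt)
      stop("nuisance has ", nrow(nuisance), " rows but the series has ",
           nt, " frames after discarding")
  }
  if (detrend || !is.null(nuisance)) {
    x <- cbind(intercept = 1,
               if (detrend) seq_len(nt) else NULL,
               nuisance)
    m <- matrix(series, ncol = nt)          # voxels x time
    beta <- solve(crossprod(x), crossprod(x, t(m)))
    series <- array(t(t(m) - x %*% beta), dim = dim(series))
  }
  series
}

#' Fractional amplitude of low-frequency fluctuation
#'
#' For each in-mask voxel, the ratio of the summed amplitude spectrum over
#' the low-frequency band to the summed amplitude spectrum over all
#' positive frequencies up to Nyquist, computed from the DFT of the
#' mean-removed series. Band inclusion is half-open: `f_low <= f < f_high`.
#'
#' @param series 4D array (x, y, z, time).
#' @param mask logical volume.
#' @param tr repetition time, seconds.
#' @param band length-2 band in Hz, inside (0, Nyquist).
#' @return object of class `falff_map`: `values` volume (0 outside mask),
#'   `mask`, `band`, `tr`, `standardized`, `method`, and an attribute
#'   `n_constant` counting constant-series voxels (set to 0, warned).
#' @export
compute_falff <- function(series, mask, tr, band = c(0.01, 0.08)) {
  stopifnot(length(dim(series)) == 4L, is.logical(mask) || is.numeric(mask))
  mask <- array(as.logical(mask), dim = dim(series)[1:3])
  nt <- dim(series)[4]
  if (nt < 32L) stop("need at least 32 frames to estimate fALFF")
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] > nyq || band[1] >= band[2])
    stop("band must satisfy 0 < f_low < f_high <= Nyquist (", nyq, " Hz)")
  m <- matrix(series, ncol = nt)[mask, , drop = FALSE]   # voxels x time
  m <- m - rowMeans(m)
  nf <- floor(nt / 2)
  amp <- Mod(stats::mvfft(t(m)))[1L + seq_len(nf), , drop = FALSE]
  freqs <- seq_len(nf) / (nt * tr)
  in_band <- freqs >= band[1] & freqs < band[2]
  if (!any(in_band)) stop("no DFT frequency bin falls inside the band")
  denom <- colSums(amp)
  num <- colSums(amp[in_band, , drop = FALSE])
  vals <- ifelse(denom > 0, num / denom, 0)
  n_const <- sum(denom == 0)
  if (n_const > 0)
    warning(n_const, " constant in-mask series; fALFF set to 0 there")
  out <- array(0, dim = dim(mask))
  out[mask] <- vals
  structure(list(values = out, mask = mask, band = band, tr = tr,
                 standardized = FALSE, method = NA_character_),
            class = "falff_map", n_constant = n_const)
}

#' Standardize a fALFF map within its mask
#'
#' @param map a `falff_map` (or any list with `values` and `mask`).
#' @param method `"zscore_in_mask"` (in-mask mean 0, SD 1) or
#'   `"divide_by_mask_mean"` (in-mask mean 1).
#' @return the map with standardized values, `standardized = TRUE` and the
#'   method recorded.
#' @export
standardize_map <- function(map, method = c("zscore_in_mask",
                                            "divide_by_mask_mean")) {
  method <- match.arg(method)
  v <- map$values[map$mask]
  if (length(v) == 0L) stop("empty mask")
  if (method == "zscore_in_mask") {
    s <- stats::sd(v)
    if (s == 0) stop("zero in-mask SD; cannot z-score")
    v <- (v - mean(v)) / s
  } else {
    mu <- mean(v)
    if (mu == 0) stop("zero in-mask mean; cannot divide")
    v <- v / mu
  }
  map$values[map$mask] <- v
  map$values[!map$mask] <- 0
  map$standardized <- TRUE
  map$method <- method
  map
}
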