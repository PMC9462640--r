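## Internal: per-gene z-scoring across regions; constant genes get zero
## columns (they cannot carry weight) and are reported via attribute.
standardize_genes <- function(genes) {
  mu <- colMeans(genes)
  sdv <- apply(genes, 2, stats::sd)
  const <- sdv == 0
  sdv[const] <- 1
  xs <- sweep(sweep(genes, 2, mu), 2, sdv, "/")
  xs[, const] <- 0
  attr(xs, "constant_genes") <- colnames(genes)[const]
  xs
}

pls1_weights <- function(xs, y) {
  yc <- y - mean(y)
  w <- as.numeric(crossprod(xs, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("all gene-response covariances are zero")
  w / nw
}

#' First-component partial least squares of a regional map on genes
#'
#' Relates a per-region response (typically the pattern z-map aggregated
#' to atlas regions) to a regions-by-genes expression matrix. Genes are
#' z-scored across regions internally; the first PLS component is the
#' unit-norm gene-weight vector proportional to the gene-response
#' covariances, with region scores `X w`. The sign is fixed so the score-
#' response correlation is non-negative; variance explained is that
#' squared correlation.
#'
#' @param genes numeric regions x genes matrix (rownames = region ids).
#' @param response numeric per-region vector aligned to the rows.
#' @return object of class `pls1_fit`: `gene_weights`, `region_scores`,
#'   `variance_explained`, `gene_ids`, `response`.
#' @export
fit_pls1 <- function(genes, response) {
  genes <- as.matrix(genes)
  if (nrow(genes) < 10L) stop("need at least 10 regions")
  if (length(response) != nrow(genes))
    stop("response length (", length(response),
         ") does not match region count (", nrow(genes), ")")
  if (stats::sd(response) == 0) stop("constant response")
  xs <- standardize_genes(genes)
  w <- pls1_weights(xs, response)
  scores <- as.numeric(xs %*% w)
  r <- stats::cor(scores, response)
  if (r < 0) { w <- -w; scores <- -scores; r <- -r }
  structure(list(gene_weights = stats::setNames(w, colnames(genes)),
                 region_scores = scores, variance_explained = r^2,
                 gene_ids = colnames(genes), response = response),
            class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d regions x %d genes; variance explained %.3f\n",
              length(x$response), length(x$gene_weights),
              x$variance_explained))
  invisible(x)
}

## Project region centroids onto the unit sphere around their centroid.
sphere_coords <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- sweep(coords, 2, colMeans(coords))
  nr <- sqrt(rowSums(ctr^2))
  nr[nr == 0] <- 1
  ctr / nr
}

## Random 3D rotation (Haar via QR, det forced to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Greedy bijective nearest-centroid matching after rotating coords: picks
## globally smallest distances first, so the permuted response is an exact
## rearrangement (value multiset preserved).
spin_permutation <- function(coords) {
  rot <- coords %*% t(random_rotation())
  d2 <- outer(rowSums(rot^2), rowSums(coords^2), "+") -
    2 * rot %*% t(coords)
  n <- nrow(coords)
  ord <- order(d2)
  perm <- integer(n)
  used_r <- logical(n); used_c <- logical(n)
  filled <- 0L
  for (k in ord) {
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (used_r[i] || used_c[j]) next
    perm[i] <- j
    used_r[i] <- TRUE; used_c[j] <- TRUE
    filled <- filled + 1L
    if (filled == n) break
  }
  perm
}

#' Permutation significance of PLS1 variance explained
#'
#' Builds a null distribution of the PLS1 variance explained under either
#' uniform shuffling of the response or spatial spin permutation (random
#' 3D rotation of region coordinates on the unit sphere with bijective
#' nearest-centroid reassignment, preserving the response's value
#' multiset). `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param genes regions x genes matrix.
#' @param response per-region response vector.
#' @param n_perm number of permutations.
#' @param method `"shuffle"` or `"spin"`.
#' @param coords regions x 3 centroid coordinates (required for spin).
#' @param seed RNG seed.
#' @return list: `p`, `observed`, `null` (numeric vector), `method`.
#' @export
pls_permutation <- function(genes, response, n_perm = 1000L,
                            method = c("shuffle", "spin"), coords = NULL,
                            seed = 1L) {
  method <- match.arg(method)
  if (method == "spin" && is.null(coords))
    stop("spin permutation requires region coordinates")
  genes <- as.matrix(genes)
  obs <- fit_pls1(genes, response)$variance_explained
  xs <- standardize_genes(genes)
  sph <- if (method == "spin") sphere_coords(coords) else NULL
  set.seed(seed)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yb <- if (method == "shuffle") sample(response)
    else response[spin_permutation(sph)]
    if (stats::sd(yb) == 0) { null[b] <- 1; next }
    wb <- pls1_weights(xs, yb)
    null[b] <- stats::cor(as.numeric(xs %*% wb), yb)^2
  }
  list(p = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs,
       null = null, method = method)
}

#' Bootstrap gene weighting and ranked gene list
#'
#' Resamples regions with replacement, refits PLS1 per draw (sign-aligned
#' to the full-sample weights), and reports
#' `z(gene) = full-sample weight / bootstrap SD`, with the gene list ranked
#' by z descending. Draws with fewer than 3 distinct regions or a constant
#' resampled response are redrawn.
#'
#' @param genes regions x genes matrix.
#' @param response per-region response vector.
#' @param n_boot number of resamplings (>= 100).
#' @param seed RNG seed.
#' @return list: `z` (named per gene), `ranked_genes`, `boot_sd`,
#'   `n_redraws`, `fit` (the full-sample [fit_pls1()]).
#' @export
bootstrap_gene_weights <- function(genes, response, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  genes <- as.matrix(genes)
  full <- fit_pls1(genes, response)
  wf <- full$gene_weights
  n <- nrow(genes)
  set.seed(seed)
  W <- matrix(NA_real_, length(wf), n_boot)
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 3L && stats::sd(response[idx]) > 0) break
      n_redraws <- n_redraws + 1L
    }
    xs <- standardize_genes(genes[idx, , drop = FALSE])
    wb <- pls1_weights(xs, response[idx])
    if (sum(wb * wf) < 0) wb <- -wb
    W[, b] <- wb
  }
  sdv <- apply(W, 1, stats::sd)
  z <- ifelse(sdv > 0, wf / sdv, ifelse(wf == 0, 0, sign(wf) * Inf))
  names(z) <- names(wf)
  ord <- order(-z, names(z))
  list(z = z, ranked_genes = names(z)[ord], boot_sd = sdv,
       n_redraws = n_redraws, fit = full)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the upper-tail hypergeometric probability of the
#' observed or larger overlap between the selection and the set (both
#' intersected with the background), with Benjamini-Hochberg adjustment
#' across sets.
#'
#' @param selected character vector of selected gene ids (subset of
#'   `background`).
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param background character vector of all scored gene ids.
#' @return data frame: set, set_size, overlap, p, q (ordered by p).
#' @export
enrichment_ora <- function(selected, sets, background) {
  if (length(selected) == 0L) stop("empty selection")
  if (length(background) == 0L) stop("empty background")
  if (!all(selected %in% background))
    stop("selected genes must be a subset of the background")
  selected <- unique(selected); background <- unique(background)
  n_bg <- length(background); n_sel <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    k <- length(intersect(s, selected))
    p <- stats::phyper(k - 1, length(s), n_bg - length(s), n_sel,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out[order(out$p, out$set), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' @param path path to a tab-separated GMT file (set name, description,
#'   member gene ids).
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
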