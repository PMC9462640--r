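#' Aggregate a z-map to an atlas parcellation
#'
#' Per-region mean of the in-mask z values, ranked by absolute mean
#' (`abs_rank`), with the top fraction flagged. Regions with no in-mask
#' voxels are excluded (recorded in the `"excluded_regions"` attribute).
#'
#' @param zmap volume array (or list with `zmap`/`values`), same grid as
#'   the atlas.
#' @param atlas an [make_atlas()] result, or a list with integer `labels`
#'   volume and a `regions` data frame (region_id, name, hemisphere).
#' @param mask optional logical volume restricting the aggregation;
#'   defaults to the atlas mask (else all labelled voxels).
#' @param fraction top fraction flagged in `top_flag`.
#' @return data frame: region_id, name, hemisphere, n_voxels, mean_z,
#'   abs_rank, top_flag.
#' @export
aggregate_to_atlas <- function(zmap, atlas, mask = NULL, fraction = 0.1) {
  if (is.list(zmap) && !is.array(zmap))
    zmap <- if (!is.null(zmap$zmap)) zmap$zmap else zmap$values
  labels <- atlas$labels
  if (!identical(dim(zmap), dim(labels)))
    stop("zmap and atlas grids differ: ", paste(dim(zmap), collapse = "x"),
         " vs ", paste(dim(labels), collapse = "x"))
  if (is.null(mask)) mask <- if (!is.null(atlas$mask)) atlas$mask else labels > 0
  sel <- mask & labels > 0
  if (!any(sel)) stop("no in-mask labelled voxels overlap the z-map")
  lab <- labels[sel]
  zz <- zmap[sel]
  ids <- sort(unique(lab))
  mz <- vapply(split(zz, lab), mean, 0)
  nv <- vapply(split(zz, lab), length, 0L)
  reg <- atlas$regions
  excluded <- setdiff(reg$region_id, ids)
  tab <- data.frame(region_id = ids,
                    name = reg$name[match(ids, reg$region_id)],
                    hemisphere = reg$hemisphere[match(ids, reg$region_id)],
                    n_voxels = as.integer(nv), mean_z = unname(mz),
                    stringsAsFactors = FALSE)
  ord <- order(-abs(tab$mean_z), tab$region_id)
  tab$abs_rank <- NA_integer_
  tab$abs_rank[ord] <- seq_len(nrow(tab))
  tab$top_flag <- tab$abs_rank <= ceiling(fraction * nrow(tab))
  if (length(excluded) > 0) {
    message(length(excluded), " atlas region(s) had no in-mask voxels")
    attr(tab, "excluded_regions") <- excluded
  }
  tab
}

#' Top fraction of a ranked region table
#'
#' Returns the `ceiling(fraction * R)` regions with the largest absolute
#' mean z; ties at the boundary are broken by ascending region id.
#'
#' @param table a region table from [aggregate_to_atlas()].
#' @param fraction fraction in (0, 1].
#' @return subset of `table`, ordered by decreasing `|mean_z|`.
#' @export
top_fraction <- function(table, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ord <- order(-abs(table$mean_z), table$region_id)
  utils::head(table[ord, , drop = FALSE], ceiling(fraction * nrow(table)))
}

## connectivity: 6 (face), 18 (face+edge), 26 (face+edge+vertex)
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(g))
  lim <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3,
                stop("connectivity must be 6, 18 or 26"))
  g[s > 0 & s <= lim, , drop = FALSE]
}

## label connected components of a logical volume; returns integer volume
connected_components <- function(vol, connectivity = 26) {
  dims <- dim(vol)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, dim = dims)
  cur <- 0L
  todo <- which(vol)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- matrix(arrayInd(start, dims), ncol = 3)
    while (nrow(frontier) > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        sweep(frontier, 2, offs[i, ], "+")))
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1L) * dims[1] +
                      (cand[, 3] - 1L) * dims[1] * dims[2])
      lin <- lin[vol[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- arrayInd(lin, dims)
      if (!is.matrix(frontier)) frontier <- matrix(frontier, ncol = 3)
    }
  }
  lab
}

#' Threshold a z-map and filter clusters by extent
#'
#' Labels connected components of suprathreshold voxels — positive and
#' negative exceedances separately — and removes components smaller than
#' the extent cutoff.
#'
#' @param zmap volume array (or list with `zmap`/`values`).
#' @param z_thresh voxel threshold on `|z|` (> 0).
#' @param min_extent minimum cluster size in voxels (>= 1).
#' @param connectivity 6, 18 or 26 (default 26, vertex-adjacent).
#' @param atlas optional atlas; surviving clusters report overlapping
#'   region ids.
#' @return list: `labels` (integer volume, 0 outside surviving clusters)
#'   and `clusters` (data frame: cluster_id, sign, n_voxels, peak_absz,
#'   peak_x/y/z, regions).
#' @export
threshold_clusters <- function(zmap, z_thresh = 1.96, min_extent = 50,
                               connectivity = 26, atlas = NULL) {
  if (is.list(zmap) && !is.array(zmap))
    zmap <- if (!is.null(zmap$zmap)) zmap$zmap else zmap$values
  if (z_thresh <= 0) stop("z_thresh must be > 0")
  if (min_extent < 1) stop("min_extent must be >= 1")
  dims <- dim(zmap)
  out <- array(0L, dim = dims)
  comps <- list()
  for (sgn in c(1, -1)) {
    vol <- if (sgn > 0) zmap > z_thresh else zmap < -z_thresh
    lab <- connected_components(vol, connectivity)
    for (cid in seq_len(max(lab))) {
      vox <- which(lab == cid)
      if (length(vox) < min_extent) next
      pk <- vox[which.max(abs(zmap[vox]))]
      comps[[length(comps) + 1L]] <- list(sign = sgn, vox = vox,
                                          n = length(vox),
                                          peak = abs(zmap[pk]),
                                          peak_idx = pk)
    }
  }
  if (length(comps) == 0L) {
    message("no cluster survives |z| > ", z_thresh, " at extent >= ",
            min_extent)
    return(list(labels = out,
                clusters = data.frame(cluster_id = integer(0),
                                      sign = character(0),
                                      n_voxels = integer(0),
                                      peak_absz = numeric(0),
                                      peak_x = integer(0), peak_y = integer(0),
                                      peak_z = integer(0),
                                      regions = character(0))))
  }
  ord <- order(-vapply(comps, `[[`, 0L, "n"),
               vapply(comps, function(c) min(c$vox), 0))
  comps <- comps[ord]
  rows <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    cc <- comps[[i]]
    out[cc$vox] <- i
    pk <- arrayInd(cc$peak_idx, dims)
    regs <- ""
    if (!is.null(atlas))
      regs <- paste(sort(unique(atlas$labels[cc$vox][atlas$labels[cc$vox] > 0])),
                    collapse = ",")
    rows[[i]] <- data.frame(cluster_id = i,
                            sign = if (cc$sign > 0) "+" else "-",
                            n_voxels = cc$n, peak_absz = cc$peak,
                            peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
                            regions = regs, stringsAsFactors = FALSE)
  }
  list(labels = out, clusters = do.call(rbind, rows))
}

#' Per-label mean of a voxel map
#'
#' @param map volume array.
#' @param labels integer label volume (0 = background), same grid.
#' @param mask optional logical volume restricting the computation.
#' @return data frame: label, n_voxels, mean.
#' @export
extract_region_means <- function(map, labels, mask = NULL) {
  if (!identical(dim(map), dim(labels)))
    stop("map and label grids differ")
  sel <- labels > 0
  if (!is.null(mask)) {
    dropped <- sort(unique(labels[sel & !mask]))
    sel <- sel & mask
    if (length(setdiff(dropped, unique(labels[sel]))) > 0)
      message("label(s) with no in-mask voxels excluded: ",
              paste(setdiff(dropped, unique(labels[sel])), collapse = ", "))
  }
  if (!any(sel))
    return(data.frame(label = integer(0), n_voxels = integer(0),
                      mean = numeric(0)))
  lab <- labels[sel]
  vals <- map[sel]
  data.frame(label = sort(unique(lab)),
             n_voxels = as.integer(vapply(split(vals, lab), length, 0L)),
             mean = unname(vapply(split(vals, lab), mean, 0)))
}
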